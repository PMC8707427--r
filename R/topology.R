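# Genome topology inference: combine coverage anomalies and inconsistent-pair
# clusters into a junction graph, then match the graph against the
# structural patterns resolvable from single-scaffold paired-end evidence:
# a single circular map, two circles bridged by a substoichiometric linear
# segment, a plain linear molecule, or an unresolved report.

#' Split a scaffold into coverage-homogeneous segments
#'
#' The scaffold is split at anomaly boundaries; each segment carries its
#' kind ("normal"/"dip"/"spike") and median depth (the anomaly's region
#' median, or the genome median for normal segments; recomputed from
#' `profile` when supplied).
#'
#' @param anomalies Tibble from [detect_anomalies()] (possibly zero rows).
#' @param scaffold_length Scaffold length in bases.
#' @param profile Optional [compute_depth()] result for exact segment
#'   medians.
#' @return Tibble of segments: `segment`, `start`, `end`, `length`, `kind`,
#'   `median_depth`.
#' @export
segment_scaffold <- function(anomalies, scaffold_length, profile = NULL) {
  scaffold_length <- as.integer(scaffold_length)
  stopifnot(scaffold_length > 0)
  a <- as_tibble(anomalies)
  if (nrow(a) > 0 && (any(a$start < 1L) || any(a$end > scaffold_length))) {
    abort("anomaly outside scaffold bounds")
  }
  gmed <- if (!is.null(profile)) profile$median
  else if (nrow(a)) a$genome_median[1] else NA_real_

  bounds <- sort(unique(c(1L, scaffold_length + 1L, a$start, a$end + 1L)))
  segs <- tibble(
    start = bounds[-length(bounds)],
    end = bounds[-1] - 1L
  )
  segs$kind <- "normal"
  segs$median_depth <- gmed
  for (i in seq_len(nrow(a))) {
    hit <- segs$start >= a$start[i] & segs$end <= a$end[i]
    segs$kind[hit] <- a$kind[i]
    segs$median_depth[hit] <- a$region_median[i]
  }
  if (!is.null(profile)) {
    segs$median_depth <- vapply(
      seq_len(nrow(segs)),
      function(i) stats::median(profile$depth[segs$start[i]:segs$end[i]]),
      1.0
    )
  }
  segs %>%
    mutate(
      segment = row_number(), length = .data$end - .data$start + 1L
    ) %>%
    select("segment", "start", "end", "length", "kind", "median_depth")
}

#' Build a junction graph from segments and clusters
#'
#' Nodes are coverage-homogeneous segments; edges are of two types:
#' adjacency edges between consecutive segments, and cluster edges derived
#' from inconsistent-pair clusters. Each cluster endpoint is assigned a role
#' — scaffold left/right end, or left/right flank of a dip segment — when
#' its window range lies within `flank_tol` windows of the corresponding
#' boundary.
#'
#' @param segments Tibble from [segment_scaffold()].
#' @param clusters Tibble from [detect_clusters()] (possibly zero rows).
#' @param scaffold_length Scaffold length in bases.
#' @param window Window size used when binning (must match).
#' @param flank_tol Role-matching tolerance in windows.
#' @return A list of class `junction_graph`: `nodes` (segments), `edges`
#'   (tibble: `type`, `from_segment`, `to_segment`, `support`, `cluster`,
#'   `role_a`, `role_b`), `scaffold_length`, `window`.
#' @export
build_junction_graph <- function(segments, clusters, scaffold_length,
                                 window = 1000L, flank_tol = 2L) {
  scaffold_length <- as.integer(scaffold_length)
  W <- as.integer(ceiling(scaffold_length / window))
  cl <- as_tibble(clusters)
  if (nrow(cl) > 0 && any(cl$wb_end > W)) {
    abort("cluster window beyond the scaffold")
  }
  adj <- if (nrow(segments) > 1L) {
    tibble(
      type = "adjacency",
      from_segment = segments$segment[-nrow(segments)],
      to_segment = segments$segment[-1],
      support = NA_integer_, cluster = NA_integer_,
      role_a = NA_character_, role_b = NA_character_
    )
  } else {
    tibble(
      type = character(), from_segment = integer(), to_segment = integer(),
      support = integer(), cluster = integer(),
      role_a = character(), role_b = character()
    )
  }

  dips <- segments[segments$kind == "dip", ]
  seg_of_window <- function(wid) {
    pos <- pmin((wid - 1L) * window + 1L, scaffold_length)
    findInterval(pos, segments$start)
  }
  role_of <- function(w_lo, w_hi) {
    if (w_lo <= 1L + flank_tol) return("left_end")
    if (w_hi >= W - flank_tol) return("right_end")
    # nearest qualifying dip flank wins: for a dip only a few windows wide,
    # both flanks can fall inside the tolerance of one window range
    best <- "internal"
    best_d <- flank_tol + 1L
    for (i in seq_len(nrow(dips))) {
      wl <- ceiling(dips$start[i] / window)
      wr <- ceiling(dips$end[i] / window)
      dl <- min(abs(w_lo - wl), abs(w_hi - wl))
      dr <- min(abs(w_lo - wr), abs(w_hi - wr))
      if (dl < best_d) {
        best <- paste0("dip", i, "_left_flank")
        best_d <- dl
      }
      if (dr < best_d) {
        best <- paste0("dip", i, "_right_flank")
        best_d <- dr
      }
    }
    best
  }

  cedges <- purrr::map_dfr(seq_len(nrow(cl)), function(i) {
    tibble(
      type = "cluster",
      from_segment = seg_of_window(cl$wa_start[i]),
      to_segment = seg_of_window(cl$wb_end[i]),
      support = cl$support[i], cluster = cl$cluster[i],
      role_a = role_of(cl$wa_start[i], cl$wa_end[i]),
      role_b = role_of(cl$wb_start[i], cl$wb_end[i])
    )
  })
  structure(
    list(
      nodes = segments, edges = bind_rows(adj, cedges),
      scaffold_length = scaffold_length, window = as.integer(window)
    ),
    class = "junction_graph"
  )
}

#' Infer the genome topology model from a junction graph
#'
#' Pattern rules, applied in order:
#' 1. exactly one cluster edge, joining the two scaffold ends, and no dip
#'    segments: **single_circle** — one circular molecule of full scaffold
#'    length;
#' 2. exactly one dip segment D, with one cluster edge joining the left
#'    scaffold end to the left flank of D and another joining the right end
#'    to the right flank of D (and no other cluster edges):
#'    **circles_with_bridge** — circle A = `[1 .. D$start - 1]` circularized
#'    through the left junction, circle B = `[D$end + 1 .. L]` circularized
#'    through the right junction, plus the bridge D as a linear molecule at
#'    reduced copy number;
#' 3. no cluster edges: **linear**;
#' 4. anything else: **unresolved**, with the raw edge list preserved as
#'    evidence (never a guess).
#'
#' Relative copy numbers are filled from segment medians when available
#' (normalized so the maximum is 1); [assign_copy_numbers()] recomputes them
#' from a coverage profile.
#'
#' @param graph A [build_junction_graph()] result.
#' @return An object of class `topology_model`: list with `classification`,
#'   `molecules` (tibble: `molecule`, `topology`, `start`, `end`, `length`,
#'   `copy_number`), `evidence` (cluster edges used), `scaffold_length`.
#' @export
infer_topology <- function(graph) {
  stopifnot(inherits(graph, "junction_graph"))
  L <- graph$scaffold_length
  ce <- graph$edges[graph$edges$type == "cluster", ]
  dips <- graph$nodes[graph$nodes$kind == "dip", ]
  gmed <- stats::median(
    rep(graph$nodes$median_depth, graph$nodes$length)
  )

  roles <- function(e) sort(c(e$role_a, e$role_b))
  model <- NULL

  if (nrow(ce) == 1L && nrow(dips) == 0L &&
    identical(roles(ce[1, ]), c("left_end", "right_end"))) {
    model <- list(
      classification = "single_circle",
      molecules = tibble(
        molecule = "circle", topology = "circular",
        start = 1L, end = L, length = L, copy_number = 1
      ),
      evidence = ce
    )
  } else if (nrow(dips) == 1L && nrow(ce) == 2L) {
    d <- dips[1, ]
    left_j <- vapply(seq_len(nrow(ce)), function(i) {
      identical(roles(ce[i, ]), sort(c("left_end", "dip1_left_flank")))
    }, TRUE)
    right_j <- vapply(seq_len(nrow(ce)), function(i) {
      identical(roles(ce[i, ]), sort(c("right_end", "dip1_right_flank")))
    }, TRUE)
    if (sum(left_j) == 1L && sum(right_j) == 1L) {
      meds <- c(
        circle_left = seg_median(graph$nodes, 1L, d$start - 1L),
        circle_right = seg_median(graph$nodes, d$end + 1L, L),
        bridge = d$median_depth
      )
      cn <- if (all(is.finite(meds)) && max(meds) > 0) meds / max(meds) else rep(NA_real_, 3)
      model <- list(
        classification = "circles_with_bridge",
        molecules = tibble(
          molecule = c("circle_left", "circle_right", "bridge"),
          topology = c("circular", "circular", "linear"),
          start = c(1L, d$end + 1L, d$start),
          end = c(d$start - 1L, L, d$end),
          copy_number = unname(cn)
        ) %>% mutate(length = .data$end - .data$start + 1L) %>%
          select("molecule", "topology", "start", "end", "length", "copy_number"),
        evidence = ce
      )
    }
  }
  if (is.null(model) && nrow(ce) == 0L) {
    model <- list(
      classification = "linear",
      molecules = tibble(
        molecule = "linear", topology = "linear",
        start = 1L, end = L, length = L, copy_number = 1
      ),
      evidence = ce
    )
  }
  if (is.null(model)) {
    model <- list(
      classification = "unresolved",
      molecules = tibble(
        molecule = character(), topology = character(), start = integer(),
        end = integer(), length = integer(), copy_number = double()
      ),
      evidence = ce
    )
  }
  structure(
    c(model, list(scaffold_length = L, genome_median = gmed)),
    class = "topology_model"
  )
}

# Depth-weighted median over [start, end] from segment summaries.
seg_median <- function(nodes, start, end) {
  if (end < start) return(NA_real_)
  ov <- nodes[nodes$end >= start & nodes$start <= end, ]
  if (nrow(ov) == 0L || any(!is.finite(ov$median_depth))) return(NA_real_)
  w <- pmin(ov$end, end) - pmax(ov$start, start) + 1L
  stats::median(rep(ov$median_depth, w))
}

#' Re-estimate molecule copy numbers from a coverage profile
#'
#' Each molecule's copy number is the median depth over its own interval
#' (molecule intervals are exclusive by construction: the circles exclude
#' the bridge), normalized so the maximum is 1. Bridge molecules thus carry
#' the dip median.
#'
#' @param model A [infer_topology()] result.
#' @param profile A [compute_depth()] result.
#' @return The model with `copy_number` recomputed.
#' @export
assign_copy_numbers <- function(model, profile) {
  stopifnot(inherits(model, "topology_model"), inherits(profile, "coverage_profile"))
  if (nrow(model$molecules) == 0L) return(model)
  meds <- vapply(seq_len(nrow(model$molecules)), function(i) {
    stats::median(profile$depth[model$molecules$start[i]:model$molecules$end[i]])
  }, 1.0)
  model$molecules$copy_number <- meds / max(meds)
  model
}

#' @export
print.topology_model <- function(x, ...) {
  cat(sprintf("<topology_model> classification: %s\n", x$classification))
  for (i in seq_len(nrow(x$molecules))) {
    m <- x$molecules[i, ]
    cat(sprintf(
      "  %-14s %-8s [%s..%s]  %s bp (~%d kb)  copy %.3g\n",
      m$molecule, m$topology,
      format(m$start, big.mark = ","), format(m$end, big.mark = ","),
      format(m$length, big.mark = ","), round(m$length / 1000), m$copy_number
    ))
  }
  invisible(x)
}

#' @export
tidy.topology_model <- function(x, ...) x$molecules

#' @export
glance.topology_model <- function(x, ...) {
  bridge <- x$molecules[x$molecules$molecule == "bridge", ]
  tibble(
    classification = x$classification,
    n_molecules = nrow(x$molecules),
    scaffold_length = x$scaffold_length,
    bridge_length = if (nrow(bridge)) bridge$length else NA_integer_,
    bridge_copy_number = if (nrow(bridge)) bridge$copy_number else NA_real_
  )
}

#' Serialize a topology model as JSON
#'
#' Schema: `classification`, `scaffold_length`, `molecules` (array of
#' objects with `molecule`, `topology`, `start`, `end`, `length`,
#' `copy_number`) and `evidence` (cluster edges).
#'
#' @param model A [infer_topology()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(model, path) {
  stopifnot(inherits(model, "topology_model"))
  jsonlite::write_json(
    list(
      classification = model$classification,
      scaffold_length = model$scaffold_length,
      molecules = model$molecules,
      evidence = model$evidence[, c(
        "from_segment", "to_segment", "support", "role_a", "role_b"
      )]
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Run the full structural-assessment pipeline
#'
#' Convenience wrapper chaining depth profiling, anomaly detection, pair
#' classification, inconsistent-pair clustering, junction-graph
#' construction, topology inference, and copy-number assignment.
#'
#' @param placements Mate placements from [map_reads()] or equivalent.
#' @param pairs Pair records from [pair_up()]; computed from `placements`
#'   when `NULL`.
#' @param scaffold_length Scaffold length in bases.
#' @param insert,tol Insert model passed to [classify_pairs()].
#' @param window Binning/scan window in bases.
#' @param min_support Cluster support threshold.
#' @param spike_factor,dip_factor,min_len Passed to [detect_anomalies()].
#' @return A list of class `structure_assessment`: `profile`, `anomalies`,
#'   `classified`, `clusters`, `graph`, `model`.
#' @export
assess_structure <- function(placements, scaffold_length, pairs = NULL,
                             insert = 800, tol = 0.5, window = 1000L,
                             min_support = 5L, spike_factor = 2.0,
                             dip_factor = 0.6, min_len = 2000L) {
  profile <- compute_depth(placements, scaffold_length)
  anomalies <- detect_anomalies(profile,
    window = window, spike_factor = spike_factor,
    dip_factor = dip_factor, min_len = min_len
  )
  if (is.null(pairs)) pairs <- pair_up(placements)
  classified <- classify_pairs(pairs, insert = insert, tol = tol)
  clusters <- detect_clusters(
    bin_inconsistent(classified, window = window),
    min_support = min_support
  )
  segments <- segment_scaffold(anomalies, scaffold_length, profile = profile)
  graph <- build_junction_graph(segments, clusters, scaffold_length, window = window)
  model <- assign_copy_numbers(infer_topology(graph), profile)
  structure(
    list(
      profile = profile, anomalies = anomalies, classified = classified,
      clusters = clusters, graph = graph, model = model
    ),
    class = "structure_assessment"
  )
}

#' @export
print.structure_assessment <- function(x, ...) {
  print(x$profile)
  cat(sprintf(
    "  %d anomaly region(s), %d junction cluster(s)\n",
    nrow(x$anomalies), nrow(x$clusters)
  ))
  print(x$model)
  invisible(x)
}
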