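# Classification of read pairs against the library insert model and
# clustering of inconsistent pairs into candidate structural junctions.

#' Classify read pairs as consistent or inconsistent with the insert model
#'
#' A pair is *consistent* when both mates map uniquely, in head-to-head
#' (inward-facing, FR) orientation — leftmost mate on "+", rightmost on "-" —
#' and the outer distance (rightmost `ref_end` - leftmost `ref_start` + 1)
#' lies within `insert * (1 - tol)` to `insert * (1 + tol)`, bounds
#' inclusive. Pairs with an unmapped or ambiguous (multi-mapping) mate are
#' *unresolved*: they carry no localizable junction signal and are excluded
#' from binning. Everything else is *inconsistent*.
#'
#' @param pairs Pair records from [pair_up()] or [ingest_alignments()].
#' @param insert Expected insert (fragment) length in bases.
#' @param tol Fractional tolerance around `insert` (0.5 means +/- 50%).
#' @return The input with columns `outer_distance`, `orientation`
#'   ("head_to_head"/"other"/`NA`) and `status`
#'   ("consistent"/"inconsistent"/"unresolved") appended.
#' @export
classify_pairs <- function(pairs, insert = 800, tol = 0.5) {
  stopifnot(tol >= 0, insert > 0)
  p <- as_tibble(pairs)
  both <- !is.na(p$m1_start) & !is.na(p$m2_start)
  m1_left <- both & (p$m1_start < p$m2_start |
    (p$m1_start == p$m2_start & p$m1_end <= p$m2_end))
  left_strand <- if_else(m1_left, p$m1_strand, p$m2_strand)
  right_strand <- if_else(m1_left, p$m2_strand, p$m1_strand)
  outer <- if_else(both,
    pmax(p$m1_end, p$m2_end) - pmin(p$m1_start, p$m2_start) + 1L,
    NA_integer_
  )
  h2h <- both & left_strand == "+" & right_strand == "-"
  lo <- insert * (1 - tol)
  hi <- insert * (1 + tol)
  p$outer_distance <- outer
  p$orientation <- if_else(both, if_else(h2h, "head_to_head", "other"), NA_character_)
  p$status <- case_when(
    !both | p$ambiguous ~ "unresolved",
    h2h & outer >= lo & outer <= hi ~ "consistent",
    TRUE ~ "inconsistent"
  )
  p
}

#' Bin inconsistent pairs into 1-kb window pairs
#'
#' Each inconsistent pair contributes one count to the unordered pair of
#' windows containing its two mate start positions, with window index
#' `ceiling(position / window)`.
#'
#' @param classified Output of [classify_pairs()].
#' @param window Window size in bases.
#' @return Tibble with columns `window_a`, `window_b` (`window_a <=
#'   window_b`), `n` (pair count) and `read_ids` (list column of member
#'   ids). Zero rows when there are no inconsistent pairs.
#' @export
bin_inconsistent <- function(classified, window = 1000L) {
  stopifnot(window >= 1L)
  inc <- classified[classified$status == "inconsistent" &
    !is.na(classified$m1_start) & !is.na(classified$m2_start), ]
  if (nrow(inc) == 0L) {
    return(tibble(
      window_a = integer(), window_b = integer(), n = integer(),
      read_ids = list()
    ))
  }
  w1 <- as.integer(ceiling(inc$m1_start / window))
  w2 <- as.integer(ceiling(inc$m2_start / window))
  tibble(
    window_a = pmin(w1, w2), window_b = pmax(w1, w2), read_id = inc$read_id
  ) %>%
    group_by(.data$window_a, .data$window_b) %>%
    summarise(
      n = n(), read_ids = list(.data$read_id), .groups = "drop"
    ) %>%
    arrange(.data$window_a, .data$window_b)
}

#' Detect clusters of inconsistent read pairs
#'
#' Window-pair cells whose indices are each within +/- 1 of one another are
#' merged (connected components), support is summed over the component, and
#' components with support below `min_support` are discarded — the support
#' threshold is applied after merging, so a junction straddling a window
#' boundary is not double-reported or split below threshold.
#'
#' @param bins Output of [bin_inconsistent()].
#' @param min_support Minimum summed read-pair support per cluster.
#' @return Tibble with one row per cluster: `cluster`, `wa_start`, `wa_end`,
#'   `wb_start`, `wb_end` (merged window ranges on each side), `support`,
#'   `read_ids` (list column).
#' @export
detect_clusters <- function(bins, min_support = 5L) {
  empty <- tibble(
    cluster = integer(), wa_start = integer(), wa_end = integer(),
    wb_start = integer(), wb_end = integer(), support = integer(),
    read_ids = list()
  )
  if (nrow(bins) == 0L) return(empty)
  # union-find over cells adjacent in both window indices
  parent <- seq_len(nrow(bins))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(nrow(bins))) {
    near <- which(
      abs(bins$window_a - bins$window_a[i]) <= 1L &
        abs(bins$window_b - bins$window_b[i]) <= 1L
    )
    for (j in near) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(nrow(bins)), find, 1L)
  out <- bins %>%
    mutate(.comp = comp) %>%
    group_by(.data$.comp) %>%
    summarise(
      wa_start = min(.data$window_a), wa_end = max(.data$window_a),
      wb_start = min(.data$window_b), wb_end = max(.data$window_b),
      support = sum(.data$n),
      read_ids = list(unlist(.data$read_ids)),
      .groups = "drop"
    ) %>%
    filter(.data$support >= min_support) %>%
    arrange(.data$wa_start, .data$wb_start) %>%
    mutate(cluster = row_number()) %>%
    select(
      "cluster", "wa_start", "wa_end", "wb_start", "wb_end", "support", "read_ids"
    )
  if (nrow(out) == 0L) empty else out
}

#' Write pair classifications or clusters as TSV
#'
#' @param x Output of [classify_pairs()] or [detect_clusters()].
#' @param path Output path. List columns (member read ids) are collapsed
#'   with commas.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(x, path) {
  df <- as.data.frame(x)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], paste, "", collapse = ",")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
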