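# Per-base depth-of-coverage, anomaly (spike/dip) detection, and
# stoichiometry ratios. Depth counts every qualifying mate placement, so
# multi-mapping reads (e.g. over plastid-derived segments present twice)
# inflate depth and surface as spikes, while reduced-copy segments surface
# as dips.

#' Compute a per-base coverage profile
#'
#' Depth at base i is the number of mate alignments covering i. All
#' qualifying placements contribute (including every placement of a
#' multi-mapping mate), so the conservation identity
#' `sum(depth) == sum(aligned span lengths)` holds exactly.
#'
#' @param placements Tibble with columns `ref_start`, `ref_end` (rows with
#'   `NA` are dropped), e.g. from [map_reads()].
#' @param scaffold_length Scaffold length in bases.
#' @param scaffold_id Identifier used in exports and reports.
#' @return An object of class `coverage_profile`: list with `scaffold_id`,
#'   `depth` (integer vector of length `scaffold_length`), `mean`, `median`.
#' @export
compute_depth <- function(placements, scaffold_length, scaffold_id = "scaffold") {
  scaffold_length <- as.integer(scaffold_length)
  stopifnot(scaffold_length > 0)
  st <- placements$ref_start
  en <- placements$ref_end
  keep <- !is.na(st) & !is.na(en)
  st <- st[keep]; en <- en[keep]
  if (any(st < 1L) || any(en > scaffold_length) || any(en < st)) {
    abort("placement outside scaffold bounds")
  }
  depth <- if (length(st)) {
    as.integer(IRanges::coverage(IRanges::IRanges(st, en), width = scaffold_length))
  } else {
    integer(scaffold_length)
  }
  structure(
    list(
      scaffold_id = scaffold_id, depth = depth,
      mean = mean(depth), median = stats::median(depth)
    ),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(
    "<coverage_profile> %s: %s bp, mean %.1fx, median %.1fx\n",
    x$scaffold_id, format(length(x$depth), big.mark = ","), x$mean, x$median
  ))
  invisible(x)
}

#' @export
tidy.coverage_profile <- function(x, ...) {
  tibble(position = seq_along(x$depth), depth = x$depth)
}

#' @export
glance.coverage_profile <- function(x, ...) {
  tibble(
    scaffold_id = x$scaffold_id, length = length(x$depth),
    mean = x$mean, median = x$median, total_bases = sum(as.numeric(x$depth))
  )
}

#' Detect coverage spikes and dips
#'
#' Windows whose median depth deviates from the genome-wide median beyond
#' the spike/dip factors are merged into maximal same-kind runs; runs whose
#' window-level extent reaches `min_len` are reported, with exact base
#' boundaries refined to the first/last base (within one window of the run)
#' whose depth crosses the threshold. `min_len` is applied to the window-run
#' extent, before refinement, so a feature shorter than `min_len` that
#' dominates `ceiling(min_len / window)` windows is still reported with its
#' refined (shorter) boundaries.
#'
#' @param profile A [compute_depth()] result.
#' @param window Window size in bases for the median scan.
#' @param spike_factor Report windows with median > `spike_factor` x genome
#'   median as spikes.
#' @param dip_factor Report windows with median < `dip_factor` x genome
#'   median as dips.
#' @param min_len Minimum window-run extent in bases.
#' @return Tibble with columns `kind` ("spike"/"dip"), `start`, `end`,
#'   `length`, `region_median`, `genome_median`,
#'   `ratio_to_genome_median`; zero rows if the profile is uniform.
#' @export
detect_anomalies <- function(profile, window = 1000L, spike_factor = 2.0,
                             dip_factor = 0.6, min_len = 2000L) {
  stopifnot(inherits(profile, "coverage_profile"), window >= 1L)
  depth <- profile$depth
  L <- length(depth)
  if (L == 0L) abort("empty coverage profile")
  gmed <- profile$median
  w <- ceiling(seq_len(L) / window)
  wmed <- tapply(depth, w, stats::median)
  kind <- rep(NA_character_, length(wmed))
  if (gmed > 0) {
    kind[wmed > spike_factor * gmed] <- "spike"
    kind[wmed < dip_factor * gmed] <- "dip"
  }

  # boundary refinement runs on a running-median-smoothed depth: exact on
  # step-like profiles, robust to single-base sampling noise
  kmed <- min(51L, if (L %% 2L == 1L) L else L - 1L)
  smooth <- if (kmed >= 3L) stats::runmed(depth, kmed) else depth

  out <- list()
  r <- rle(ifelse(is.na(kind), "normal", kind))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    kd <- r$values[i]
    if (kd == "normal") next
    w0 <- starts[i]; w1 <- ends[i]
    extent <- min(w1 * window, L) - ((w0 - 1L) * window + 1L) + 1L
    if (extent < min_len) next
    thr <- if (kd == "spike") spike_factor * gmed else dip_factor * gmed
    lo <- max((w0 - 2L) * window + 1L, 1L)
    hi <- min((w1 + 1L) * window, L)
    seg <- smooth[lo:hi]
    cross <- if (kd == "spike") seg > thr else seg < thr
    if (!any(cross)) next
    b0 <- lo + which(cross)[1] - 1L
    b1 <- lo + tail(which(cross), 1L) - 1L
    rmed <- stats::median(depth[b0:b1])
    out[[length(out) + 1L]] <- tibble(
      kind = kd, start = b0, end = b1, length = b1 - b0 + 1L,
      region_median = rmed, genome_median = gmed,
      ratio_to_genome_median = if (gmed > 0) rmed / gmed else NA_real_
    )
  }
  if (!length(out)) {
    return(tibble(
      kind = character(), start = integer(), end = integer(), length = integer(),
      region_median = double(), genome_median = double(),
      ratio_to_genome_median = double()
    ))
  }
  bind_rows(out) %>% arrange(.data$start)
}

#' Stoichiometry ratio of the genome to a region
#'
#' The ratio of genome-wide median depth to the median depth over a region,
#' interpreted as the relative copy-number deficit of that region (e.g. a
#' substoichiometric bridge segment). Both medians are medians of
#' `window`-sized window means rather than raw per-base values: window
#' means give fractional resolution (a 6x region's per-base median can
#' only be an integer, which cannot resolve a 5-fold ratio at 30x), while
#' the outer median keeps the estimate robust to local anomalies. A region
#' with zero median returns `Inf`.
#'
#' @param profile A [compute_depth()] result.
#' @param start,end 1-based closed bounds of the region.
#' @param window Averaging window in bases (about one read length).
#' @return A single number: `genome_median / region_median`.
#' @export
#' @examples
#' p <- compute_depth(
#'   tibble::tibble(ref_start = 1, ref_end = 100), 100
#' )
#' stoichiometry_ratio(p, 10, 20)
stoichiometry_ratio <- function(profile, start, end, window = 125L) {
  stopifnot(inherits(profile, "coverage_profile"))
  L <- length(profile$depth)
  if (end < start) abort("empty region")
  if (start < 1L || end > L) abort("region outside scaffold bounds")
  med_of_window_means <- function(x) {
    w <- ceiling(seq_along(x) / window)
    stats::median(tapply(x, w, mean))
  }
  rmed <- med_of_window_means(profile$depth[start:end])
  if (rmed == 0) return(Inf)
  med_of_window_means(profile$depth) / rmed
}

#' Export a coverage profile as bedGraph
#'
#' Runs of equal depth are collapsed; coordinates follow the bedGraph
#' convention (0-based, half-open).
#'
#' @param profile A [compute_depth()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "coverage_profile"))
  r <- rle(profile$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  df <- data.frame(
    chrom = profile$scaffold_id, start = starts - 1L, end = ends, depth = r$values
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Export anomaly regions as BED
#'
#' Coordinates are converted to BED's 0-based half-open convention.
#'
#' @param anomalies Tibble from [detect_anomalies()].
#' @param path Output path.
#' @param scaffold_id Chromosome column value.
#' @return `path`, invisibly.
#' @export
write_anomaly_bed <- function(anomalies, path, scaffold_id = "scaffold") {
  df <- data.frame(
    chrom = scaffold_id, start = anomalies$start - 1L, end = anomalies$end,
    name = anomalies$kind,
    score = round(1000 * pmin(anomalies$ratio_to_genome_median, 1)),
    strand = "."
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
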