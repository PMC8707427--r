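# Seeded gapless read mapping under the 90%-length / 90%-identity match
# criterion, plus pairing of mate placements and ingestion of external
# SAM/BAM alignments into the same tabular contract.

#' Map reads to a reference with exact-seed anchoring and gapless extension
#'
#' Places each read on both strands of a single reference by exact k-mer
#' anchoring followed by gapless placement with mismatch counting. A
#' placement is reported when at least `min_len_frac` of the read aligns
#' within the reference (reads overhanging a reference end are clipped) and
#' the identity over the aligned span is at least `min_identity`. All
#' qualifying placements are returned, so multi-mapping reads (e.g. inside
#' dispersed repeats) yield several rows per mate. N bases never match and
#' seeds containing N are skipped.
#'
#' The mapper is substitution-only (no indels), which matches the synthetic
#' read model; alignments of real data from a gapped external mapper can be
#' brought into the same contract with [ingest_alignments()].
#'
#' @param reads Tibble with columns `read_id`, `mate` (1 or 2), `seq`.
#' @param reference Reference sequence: character scalar (optionally named).
#' @param min_len_frac Minimum aligned span as a fraction of read length.
#' @param min_identity Minimum identity over the aligned span.
#' @param k Seed length (exact-match k-mer anchor).
#' @param seed_stride Spacing of seed offsets along each read; the final
#'   offset is always probed.
#' @return Tibble of placements: `read_id`, `mate`, `ref_start`, `ref_end`
#'   (1-based closed), `strand`, `aligned_frac`, `identity`.
#' @export
map_reads <- function(reads, reference, min_len_frac = 0.90, min_identity = 0.90,
                      k = 31L, seed_stride = 10L) {
  stopifnot(all(c("read_id", "mate", "seq") %in% names(reads)))
  reference <- check_acgtn(reference[[1]], "reference")
  if (nchar(reference) < k) abort("reference shorter than the seed length")
  reads <- as_tibble(reads)
  reads$seq <- check_acgtn(reads$seq, "read")
  if (any(nchar(reads$seq) < k)) {
    abort(sprintf("reads shorter than the seed length (k = %d) cannot be mapped", k))
  }

  ref_tab <- reference_kmer_table(reference, k)
  fwd <- seed_candidates(reads$seq, ref_tab, k, seed_stride)
  rev <- seed_candidates(revcomp(reads$seq), ref_tab, k, seed_stride)
  cand <- bind_rows(
    if (nrow(fwd)) mutate(fwd, strand = "+"),
    if (nrow(rev)) mutate(rev, strand = "-")
  )
  if (is.null(cand) || nrow(cand) == 0L) return(empty_placements())

  qseq <- ifelse(cand$strand == "+", reads$seq[cand$ridx], revcomp(reads$seq)[cand$ridx])
  hits <- score_candidates(qseq, cand$start, reference)
  out <- tibble(
    read_id = reads$read_id[cand$ridx],
    mate = as.integer(reads$mate[cand$ridx]),
    ref_start = hits$ref_start, ref_end = hits$ref_end,
    strand = cand$strand,
    aligned_frac = hits$span / nchar(qseq),
    identity = ifelse(hits$span > 0, 1 - hits$mm / hits$span, 0)
  )
  out <- out[out$aligned_frac >= min_len_frac & out$identity >= min_identity, ]
  distinct(out, .data$read_id, .data$mate, .data$ref_start, .data$strand,
    .keep_all = TRUE
  ) %>% arrange(.data$read_id, .data$mate, .data$ref_start)
}

empty_placements <- function() {
  tibble(
    read_id = character(), mate = integer(), ref_start = integer(),
    ref_end = integer(), strand = character(), aligned_frac = double(),
    identity = double()
  )
}

reference_kmer_table <- function(reference, k) {
  n <- nchar(reference)
  pos <- seq_len(n - k + 1L)
  kmer <- substring(reference, pos, pos + k - 1L)
  keep <- !grepl("N", kmer, fixed = TRUE)
  tibble(kmer = kmer[keep], pos = pos[keep])
}

# Candidate (read index, reference start) diagonals from exact seed matches.
seed_candidates <- function(seqs, ref_tab, k, stride) {
  out <- vector("list", 0L)
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    offs <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
    q <- tibble(
      ridx = rep(idx, each = length(offs)),
      off = rep(offs, times = length(idx))
    )
    q$kmer <- substring(seqs[q$ridx], q$off, q$off + k - 1L)
    q <- q[!grepl("N", q$kmer, fixed = TRUE), ]
    j <- inner_join(q, ref_tab, by = "kmer", relationship = "many-to-many")
    if (nrow(j)) {
      out[[length(out) + 1L]] <- distinct(
        tibble(ridx = j$ridx, start = j$pos - j$off + 1L)
      )
    }
  }
  if (!length(out)) tibble(ridx = integer(), start = integer()) else distinct(bind_rows(out))
}

# Gapless scoring of candidate placements: clip to the reference, count
# mismatches over the aligned span. N never matches (either side).
score_candidates <- function(qseq, start, reference) {
  n_ref <- nchar(reference)
  L <- nchar(qseq)
  astart <- pmax(start, 1L)
  aend <- pmin(start + L - 1L, n_ref)
  span <- pmax(aend - astart + 1L, 0L)
  mm <- integer(length(qseq))

  qs_clip <- substring(qseq, astart - start + 1L, aend - start + 1L)
  has_n <- grepl("N", qs_clip, fixed = TRUE)
  widths <- ifelse(span > 0, span, NA_integer_)

  for (w in unique(stats::na.omit(widths[!has_n]))) {
    i <- which(!has_n & span == w)
    ra <- charToRaw(paste(substring(reference, astart[i], aend[i]), collapse = ""))
    rb <- charToRaw(paste(qs_clip[i], collapse = ""))
    neq <- which(ra != rb)
    mm[i] <- tabulate((neq - 1L) %/% w + 1L, nbins = length(i))
  }
  for (i in which(has_n & span > 0)) {
    a <- charToRaw(substring(reference, astart[i], aend[i]))
    b <- charToRaw(qs_clip[i])
    mm[i] <- sum(a != b | b == charToRaw("N") | a == charToRaw("N"))
  }
  list(ref_start = astart, ref_end = aend, span = span, mm = mm)
}

#' Map a single mate sequence
#'
#' Convenience wrapper over [map_reads()] for one read.
#'
#' @param read A single read sequence (character scalar), length >= `k`.
#' @inheritParams map_reads
#' @return Tibble of placements (`ref_start`, `ref_end`, `strand`,
#'   `aligned_frac`, `identity`).
#' @export
map_mate <- function(read, reference, min_len_frac = 0.90, min_identity = 0.90,
                     k = 31L, seed_stride = 10L) {
  stopifnot(is.character(read), length(read) == 1L)
  map_reads(
    tibble(read_id = "read", mate = 1L, seq = read), reference,
    min_len_frac = min_len_frac, min_identity = min_identity,
    k = k, seed_stride = seed_stride
  ) %>% select(-"read_id", -"mate")
}

#' Pair mate placements into per-pair records
#'
#' Collapses a placement table to one record per read pair. The best
#' placement per mate is chosen by identity, ties broken by leftmost
#' position; a pair is flagged ambiguous when either mate has more than one
#' qualifying placement. Unmapped mates yield `NA` columns (partial records);
#' read ids with no mapped mate at all do not appear.
#'
#' @param placements Tibble from [map_reads()] or [ingest_alignments()].
#' @return Tibble with one row per read pair: `read_id`, `m1_start`,
#'   `m1_end`, `m1_strand`, `m1_identity`, `m2_start`, `m2_end`, `m2_strand`,
#'   `m2_identity`, `n1`, `n2` (qualifying placements per mate) and
#'   `ambiguous`.
#' @export
pair_up <- function(placements) {
  if (nrow(placements) == 0L) {
    return(tibble(
      read_id = character(), m1_start = integer(), m1_end = integer(),
      m1_strand = character(), m1_identity = double(), m2_start = integer(),
      m2_end = integer(), m2_strand = character(), m2_identity = double(),
      n1 = integer(), n2 = integer(), ambiguous = logical()
    ))
  }
  best <- placements %>%
    group_by(.data$read_id, .data$mate) %>%
    arrange(desc(.data$identity), .data$ref_start, .by_group = TRUE) %>%
    mutate(.n = n()) %>%
    slice(1L) %>%
    ungroup()
  wide <- best %>%
    select("read_id", "mate", "ref_start", "ref_end", "strand", "identity", ".n") %>%
    tidyr::pivot_wider(
      names_from = "mate",
      values_from = c("ref_start", "ref_end", "strand", "identity", ".n"),
      names_sep = "_m"
    )
  for (col in c(
    "ref_start_m1", "ref_end_m1", "strand_m1", "identity_m1", ".n_m1",
    "ref_start_m2", "ref_end_m2", "strand_m2", "identity_m2", ".n_m2"
  )) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }
  wide %>%
    mutate(
      n1 = as.integer(tidyr::replace_na(.data$.n_m1, 0L)),
      n2 = as.integer(tidyr::replace_na(.data$.n_m2, 0L)),
      ambiguous = .data$n1 > 1L | .data$n2 > 1L
    ) %>%
    select(
      read_id = "read_id",
      m1_start = "ref_start_m1", m1_end = "ref_end_m1",
      m1_strand = "strand_m1", m1_identity = "identity_m1",
      m2_start = "ref_start_m2", m2_end = "ref_end_m2",
      m2_strand = "strand_m2", m2_identity = "identity_m2",
      "n1", "n2", "ambiguous"
    ) %>%
    arrange(.data$read_id)
}

#' Ingest external SAM/BAM alignments as pair records
#'
#' Builds the same per-pair records as [map_reads()] + [pair_up()] from an
#' external mapper's output. Only primary alignments are used; secondary and
#' supplementary records are ignored, so `ambiguous` is always `FALSE` here.
#' Identity is computed from the `NM` tag when present (substitutions =
#' NM - inserted - deleted bases), otherwise mismatches are taken as zero
#' over the aligned span; the aligned fraction is the sum of `M`/`=`/`X`
#' CIGAR operations over the read length. Records failing the thresholds are
#' treated as unmapped mates. Malformed records are skipped with a message.
#'
#' @param path SAM or BAM file (SAM is converted in a temporary directory).
#' @inheritParams map_reads
#' @return Tibble of pair records as from [pair_up()].
#' @export
ingest_alignments <- function(path, min_len_frac = 0.90, min_identity = 0.90) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("qname", "flag", "pos", "cigar", "seq"), tag = "NM"
  )
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(b$qname)
  if (n == 0L) return(pair_up(empty_placements()))

  ops <- parse_cigars(b$cigar)
  bad <- is.na(b$pos) | is.na(ops$aligned) | ops$read_len == 0L
  if (any(bad)) inform(sprintf("skipped %d malformed alignment record(s)", sum(bad)))

  nm <- b$tag$NM %||% rep(NA_integer_, n)
  subs <- pmax(nm - ops$ins - ops$del, 0L)
  subs[is.na(subs)] <- 0L

  pl <- tibble(
    read_id = b$qname,
    mate = if_else(bitwAnd(b$flag, 64L) > 0L, 1L, 2L),
    ref_start = as.integer(b$pos),
    ref_end = as.integer(b$pos) + ops$ref_span - 1L,
    strand = if_else(bitwAnd(b$flag, 16L) > 0L, "-", "+"),
    aligned_frac = ops$aligned / ops$read_len,
    identity = if_else(ops$aligned > 0L, 1 - subs / ops$aligned, 0)
  )[!bad, ]
  pl <- pl[pl$aligned_frac >= min_len_frac & pl$identity >= min_identity, ]
  pair_up(pl)
}

parse_cigars <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  agg <- function(x, which_ops) {
    if (is.null(x) || nrow(x) == 0L || any(is.na(x[, 1]))) return(NA_integer_)
    sum(as.integer(x[x[, 3] %in% which_ops, 2]))
  }
  aligned <- vapply(m, agg, 1L, which_ops = c("M", "=", "X"))
  ins <- vapply(m, agg, 1L, which_ops = "I")
  del <- vapply(m, agg, 1L, which_ops = c("D", "N"))
  soft <- vapply(m, agg, 1L, which_ops = c("S", "H"))
  list(
    aligned = aligned, ins = ins, del = del,
    ref_span = aligned + del, read_len = aligned + ins + soft
  )
}
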