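# Thresholded local similarity scanning: dispersed repeats (self-comparison),
# plastid-derived segments / MIPTs (cross-comparison at a looser identity
# floor), and homology-based gene location. The engine is k-mer anchored,
# gapless (substitution-only): score-based X-drop extension with the
# mismatch penalty pinned at the identity floor, a gentle boundary polish,
# then per-hit length and identity filters. Both direct and inverted
# orientations are scanned.

#' Find dispersed repeats by genome self-comparison
#'
#' Reports pairs of intervals within one genome whose gapless alignment is
#' at least `min_len` bases long at identity strictly greater than
#' `min_identity` (the repeat criterion is an open bound: ">90%"). Trivial
#' self-hits and symmetric duplicates are removed; hits are canonicalized so
#' the first interval starts no later than the second. Direct and inverted
#' repeats are both reported.
#'
#' @param genome Genome sequence (character scalar) or a
#'   [generate_genome()] result.
#' @param min_len Minimum alignment span in bases.
#' @param min_identity Identity floor (strict: hits must exceed it).
#' @param k Seed length.
#' @return Tibble of hits: `q_start`, `q_end`, `s_start`, `s_end`, `strand`
#'   ("+" direct, "-" inverted), `length`, `identity`.
#' @export
find_repeats <- function(genome, min_len = 100L, min_identity = 0.90, k = 16L) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$genome
  genome <- check_acgtn(genome, "genome")
  if (nchar(genome) < 2L * min_len) {
    abort("genome shorter than twice the minimum repeat length")
  }
  scan_similarity(genome, genome,
    min_len = min_len, min_identity = min_identity,
    k = k, self = TRUE, strict = TRUE
  )
}

#' Find plastid-derived segments (MIPTs)
#'
#' Cross-compares a mitogenome against a plastome with the same engine at a
#' looser (inclusive) identity floor. Hits are reported on mitogenome
#' coordinates (`q_*`) with plastome provenance (`s_*`).
#'
#' @param genome Mitogenome sequence (character scalar) or a
#'   [generate_genome()] result.
#' @param plastome Plastome sequence (character scalar); defaults to the
#'   companion plastome of a [generate_genome()] result.
#' @param min_len Minimum alignment span in bases.
#' @param min_identity Identity floor (inclusive).
#' @param k Seed length.
#' @return Tibble of hits as for [find_repeats()].
#' @export
find_mipts <- function(genome, plastome = NULL, min_len = 100L,
                       min_identity = 0.80, k = 12L) {
  if (inherits(genome, "synthetic_genome")) {
    plastome <- plastome %||% genome$plastome
    genome <- genome$genome
  }
  if (is.null(plastome)) abort("a plastome sequence is required")
  genome <- check_acgtn(genome, "genome")
  plastome <- check_acgtn(plastome, "plastome")
  if (!nchar(genome) || !nchar(plastome)) abort("empty sequence")
  scan_similarity(genome, plastome,
    min_len = min_len, min_identity = min_identity,
    k = k, self = FALSE, strict = FALSE
  )
}

#' Locate genes by homology
#'
#' Finds the best-scoring placement of each reference gene in a genome,
#' keeping placements whose identity and reference coverage (fraction of
#' the reference gene aligned) both reach their floors. The extracted
#' genome sequence is reverse-complemented for minus-strand loci. Genes
#' with no qualifying placement are absent from the output (a message
#' names them).
#'
#' @param genome Genome sequence (character scalar) or a
#'   [generate_genome()] result.
#' @param reference_genes Named character vector of reference gene
#'   sequences.
#' @param min_identity Identity floor (inclusive).
#' @param min_ref_cov Minimum fraction of the reference gene aligned.
#' @param k Seed length.
#' @return Tibble of loci: `gene`, `start`, `end`, `strand`, `identity`,
#'   `ref_coverage`, `sequence`.
#' @export
locate_genes <- function(genome, reference_genes, min_identity = 0.70,
                         min_ref_cov = 0.70, k = 12L) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$genome
  genome <- check_acgtn(genome, "genome")
  if (!length(reference_genes)) abort("reference gene set is empty")
  if (is.null(names(reference_genes)) || any(!nzchar(names(reference_genes)))) {
    abort("reference genes must be named")
  }
  out <- list()
  missing <- character()
  for (g in names(reference_genes)) {
    glen <- nchar(reference_genes[[g]])
    hits <- scan_similarity(genome, reference_genes[[g]],
      min_len = max(1L, ceiling(min_ref_cov * glen)),
      min_identity = min_identity, k = k, self = FALSE, strict = FALSE
    )
    if (nrow(hits) == 0L) {
      missing <- c(missing, g)
      next
    }
    best <- hits %>%
      mutate(score = .data$length * .data$identity) %>%
      arrange(desc(.data$score), .data$q_start) %>%
      slice(1L)
    seq <- substr(genome, best$q_start, best$q_end)
    if (best$strand == "-") seq <- revcomp(seq)
    out[[g]] <- tibble(
      gene = g, start = best$q_start, end = best$q_end,
      strand = best$strand, identity = best$identity,
      ref_coverage = best$length / glen, sequence = seq
    )
  }
  if (length(missing)) {
    inform(sprintf("no qualifying placement for: %s", paste(missing, collapse = ", ")))
  }
  if (!length(out)) {
    return(tibble(
      gene = character(), start = integer(), end = integer(),
      strand = character(), identity = double(), ref_coverage = double(),
      sequence = character()
    ))
  }
  bind_rows(out)
}

# ---- engine ---------------------------------------------------------------

# k-mer anchored gapless scan of `query` vs `subject` on both strands.
# Returns hits with 1-based closed intervals on the forward coordinates of
# both sequences; strand refers to the subject.
scan_similarity <- function(query, subject, min_len, min_identity, k,
                            self = FALSE, strict = FALSE, ext_window = 20000L) {
  hits <- list()
  for (strand in c("+", "-")) {
    s2 <- if (strand == "-") revcomp(subject) else subject
    h <- scan_one_strand(query, s2, min_len, min_identity, k,
      self = self && strand == "+", strict = strict, ext_window = ext_window
    )
    if (nrow(h)) {
      if (strand == "-") {
        sn <- nchar(subject)
        tmp_start <- sn - h$s_end + 1L
        h$s_end <- sn - h$s_start + 1L
        h$s_start <- tmp_start
      }
      h$strand <- strand
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- bind_rows(hits)
  if (self) {
    # canonical order within a pair; drop palindromic self-identical hits
    swap <- out$s_start < out$q_start
    qs <- out$q_start; qe <- out$q_end
    out$q_start[swap] <- out$s_start[swap]; out$q_end[swap] <- out$s_end[swap]
    out$s_start[swap] <- qs[swap]; out$s_end[swap] <- qe[swap]
    out <- out[!(out$q_start == out$s_start & out$q_end == out$s_end), ]
    out <- distinct(out, .data$q_start, .data$q_end, .data$s_start, .data$s_end,
      .data$strand,
      .keep_all = TRUE
    )
  }
  merge_redundant_hits(out)
}

empty_hits <- function() {
  tibble(
    q_start = integer(), q_end = integer(), s_start = integer(),
    s_end = integer(), strand = character(), length = integer(),
    identity = double()
  )
}

scan_one_strand <- function(q, s, min_len, min_identity, k, self, strict,
                            ext_window) {
  qn <- nchar(q); sn <- nchar(s)
  if (qn < k || sn < k) return(empty_hits()[, 1:4])
  qpos <- seq_len(qn - k + 1L)
  qk <- substring(q, qpos, qpos + k - 1L)
  spos <- seq_len(sn - k + 1L)
  sk <- substring(s, spos, spos + k - 1L)
  keepq <- !grepl("N", qk, fixed = TRUE)
  keeps <- !grepl("N", sk, fixed = TRUE)
  cand <- inner_join(
    tibble(kmer = qk[keepq], qpos = qpos[keepq]),
    tibble(kmer = sk[keeps], spos = spos[keeps]),
    by = "kmer", relationship = "many-to-many"
  )
  if (self) cand <- cand[cand$spos > cand$qpos, ]
  if (nrow(cand) == 0L) return(empty_hits()[, 1:4])

  qr <- charToRaw(q)
  sr <- charToRaw(s)
  rawN <- charToRaw("N")
  # permissive extension penalty (neutral near 60% identity, matching the
  # reward:penalty ratio of standard nucleotide local search): a diverged
  # homologous region is delineated as ONE alignment and then accepted or
  # rejected whole by the identity floor, rather than mined for short
  # above-floor islands inside a below-floor region
  pen <- 1.5
  xdrop <- 30
  rho <- 1 - min_identity
  eps <- if (strict) -1e-9 else 1e-9

  cand$diag <- cand$spos - cand$qpos
  cand <- cand[order(cand$diag, cand$qpos), ]
  res <- list()
  d_prev <- NA_integer_
  covered_to <- -1L
  for (row in seq_len(nrow(cand))) {
    d <- cand$diag[row]
    seed <- cand$qpos[row]
    if (!identical(d, d_prev)) {
      d_prev <- d
      covered_to <- -1L
    }
    if (seed <= covered_to) next
    i0 <- max(1L, 1L - d)
    i1 <- min(qn, sn - d)
    lo <- max(i0, seed - ext_window)
    hi <- min(i1, seed + k - 1L + ext_window)
    qa <- qr[lo:hi]
    sa <- sr[(lo + d):(hi + d)]
    mm <- qa != sa | qa == rawN | sa == rawN
    sl <- seed - lo + 1L         # seed start, local coords
    se <- sl + k - 1L            # seed end, local coords
    span <- xdrop_extend(mm, sl, se, pen, xdrop)
    # score-maximal endpoints first (tight boundaries); fall back to the
    # longest floor-satisfying subsegment when the extension as a whole
    # misses the identity floor
    span <- polish_boundaries(mm, span[1], span[2])
    slen <- span[2] - span[1] + 1L
    smm <- sum(mm[span[1]:span[2]])
    ok <- slen >= min_len && (smm - rho * slen <= eps)
    best <- if (ok) c(span[1], span[2], smm) else NULL
    if (!is.null(best)) {
      q_start <- lo + best[1] - 1L
      q_end <- lo + best[2] - 1L
      res[[length(res) + 1L]] <- tibble(
        q_start = q_start, q_end = q_end,
        s_start = q_start + d, s_end = q_end + d,
        length = q_end - q_start + 1L,
        identity = 1 - best[3] / (q_end - q_start + 1L)
      )
      covered_to <- q_end
    } else {
      covered_to <- max(covered_to, lo + span[2] - 1L - k)
    }
  }
  if (!length(res)) return(empty_hits()[, 1:4])
  bind_rows(res)
}

# Score-based X-drop extension of a seed over a local mismatch vector:
# match +1, mismatch -pen; extension stops when the running score falls
# more than `xdrop` below its running maximum, and the boundary is placed
# at the maximum. Returns the local [start, end] of the extended span.
xdrop_extend <- function(mm, seed_start, seed_end, pen, xdrop) {
  n <- length(mm)
  w <- ifelse(mm, -pen, 1)
  right <- seed_end
  if (seed_end < n) {
    cs <- cumsum(w[(seed_end + 1L):n])
    cm <- cummax(cs)
    stop_at <- which(cs < cm - xdrop)[1]
    upto <- if (is.na(stop_at)) length(cs) else stop_at
    best <- which.max(cs[seq_len(upto)])
    if (cs[best] > 0) right <- seed_end + best
  }
  left <- seed_start
  if (seed_start > 1L) {
    cs <- cumsum(w[(seed_start - 1L):1L])
    cm <- cummax(cs)
    stop_at <- which(cs < cm - xdrop)[1]
    upto <- if (is.na(stop_at)) length(cs) else stop_at
    best <- which.max(cs[seq_len(upto)])
    if (cs[best] > 0) left <- seed_start - best
  }
  c(left, right)
}

# Boundary polish: re-extend the score-maximal core at +1/-2 weights with a
# short X-drop, then trim endpoints to matches. The gentle penalty walks
# through mutation clusters at a feature's edge (local identity > 2/3) but
# halts within a base or two of random flanking sequence (~25% identity).
polish_boundaries <- function(mm, b0, b1, xdrop = 6) {
  n <- length(mm)
  if (b1 < n) {
    cs <- cumsum(ifelse(mm[(b1 + 1L):n], -2L, 1L))
    stop_at <- which(cs < cummax(cs) - xdrop)[1]
    upto <- if (is.na(stop_at)) length(cs) else stop_at
    bi <- which.max(cs[seq_len(upto)])
    if (cs[bi] > 0L) b1 <- b1 + bi
  }
  if (b0 > 1L) {
    cs <- cumsum(ifelse(mm[(b0 - 1L):1L], -2L, 1L))
    stop_at <- which(cs < cummax(cs) - xdrop)[1]
    upto <- if (is.na(stop_at)) length(cs) else stop_at
    bi <- which.max(cs[seq_len(upto)])
    if (cs[bi] > 0L) b0 <- b0 - bi
  }
  while (b0 < b1 && mm[b0]) b0 <- b0 + 1L
  while (b1 > b0 && mm[b1]) b1 <- b1 - 1L
  c(b0, b1)
}

# Drop hits redundant with a longer hit: same strand, both query and
# subject intervals overlapping >= 50% of the shorter interval.
merge_redundant_hits <- function(hits) {
  if (nrow(hits) <= 1L) {
    return(select(
      hits, "q_start", "q_end", "s_start", "s_end", "strand", "length", "identity"
    ))
  }
  hits <- hits %>%
    mutate(score = .data$length * .data$identity) %>%
    arrange(desc(.data$score))
  keep <- rep(TRUE, nrow(hits))
  ov_frac <- function(a1, a2, b1, b2) {
    ov <- pmax(0L, pmin(a2, b2) - pmax(a1, b1) + 1L)
    ov / pmin(a2 - a1 + 1L, b2 - b1 + 1L)
  }
  for (i in seq_len(nrow(hits))[-1]) {
    prev <- which(keep[seq_len(i - 1L)])
    qo <- ov_frac(hits$q_start[prev], hits$q_end[prev], hits$q_start[i], hits$q_end[i])
    so <- ov_frac(hits$s_start[prev], hits$s_end[prev], hits$s_start[i], hits$s_end[i])
    same <- hits$strand[prev] == hits$strand[i]
    if (any(same & qo >= 0.5 & so >= 0.5)) keep[i] <- FALSE
  }
  hits[keep, ] %>%
    select("q_start", "q_end", "s_start", "s_end", "strand", "length", "identity") %>%
    arrange(.data$q_start, .data$s_start)
}

#' Export similarity hits as TSV or BED
#'
#' The BED export uses the query interval (0-based half-open) with the hit
#' identity in the score column.
#'
#' @param hits Tibble from [find_repeats()] or [find_mipts()].
#' @param path Output path.
#' @param scaffold_id Chromosome column value for BED.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_bed <- function(hits, path, scaffold_id = "scaffold") {
  df <- data.frame(
    chrom = scaffold_id, start = hits$q_start - 1L, end = hits$q_end,
    name = paste0("hit", seq_len(nrow(hits))),
    score = round(1000 * hits$identity), strand = hits$strand
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Export gene loci as GFF3
#'
#' @param loci Tibble from [locate_genes()].
#' @param path Output path.
#' @param scaffold_id Sequence id column value.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path, scaffold_id = "scaffold") {
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\tmitostructr\tgene\t%d\t%d\t%.3f\t%s\t.\tID=%s;Name=%s",
      scaffold_id, loci$start, loci$end, loci$identity, loci$strand,
      loci$gene, loci$gene
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Import external tabular similarity hits
#'
#' Reads a tab-separated table of local-similarity hits (e.g. from a gapped
#' external search tool) into the package's hit contract. The file must
#' carry columns `q_start`, `q_end`, `s_start`, `s_end`, `strand`,
#' `length`, `identity` (identity as a proportion in \[0, 1\]).
#'
#' @param path TSV path with a header row.
#' @return Tibble of hits as from [find_repeats()].
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("q_start", "q_end", "s_start", "s_end", "strand", "length", "identity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("hit table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  as_tibble(df[, need])
}
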