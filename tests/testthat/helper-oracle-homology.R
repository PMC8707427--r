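# Independent oracles for the homology scanner.

# Brute-force windowed diagonal oracle: scans EVERY diagonal of the
# query-subject comparison (both orientations) and reports whether any
# window of exactly `win` bases has at most floor(rho * win) mismatches —
# a necessary condition for any gapless hit of length >= win at identity
# >= 1 - rho to exist. Vectorized per diagonal, no seeding, independent of
# the package's k-mer/X-drop path.
brute_any_qualifying_window <- function(query, subject, win, min_identity) {
  rho <- 1 - min_identity
  max_mm <- floor(rho * win + 1e-9)
  scan <- function(q, s) {
    qr <- charToRaw(q); sr <- charToRaw(s)
    qn <- length(qr); sn <- length(sr)
    for (d in (1L - qn):(sn - 1L)) {
      i0 <- max(1L, 1L - d); i1 <- min(qn, sn - d)
      if (i1 - i0 + 1L < win) next
      mm <- as.integer(qr[i0:i1] != sr[(i0 + d):(i1 + d)])
      cs <- c(0L, cumsum(mm))
      n <- length(mm)
      if (any(cs[(win + 1L):(n + 1L)] - cs[1:(n - win + 1L)] <= max_mm)) {
        return(TRUE)
      }
    }
    FALSE
  }
  scan(query, subject) || scan(query, revcomp(subject))
}

# blastn oracle: tabular hits from the NCBI blastn binary (the field's
# canonical local-similarity search), as intervals on the query/subject.
blastn_hits <- function(query, subject, perc_identity) {
  td <- withr::local_tempdir()
  qf <- file.path(td, "q.fasta"); sf <- file.path(td, "s.fasta")
  write_fasta(c(q = query), qf)
  write_fasta(c(s = subject), sf)
  out <- system2("blastn",
    c(
      "-query", qf, "-subject", sf, "-task", "blastn", "-dust", "no",
      "-perc_identity", perc_identity,
      "-outfmt", shQuote("6 qstart qend sstart send pident length")
    ),
    stdout = TRUE
  )
  if (!length(out)) {
    return(tibble::tibble(
      q_start = integer(), q_end = integer(), s_start = integer(),
      s_end = integer(), identity = double(), length = integer(),
      strand = character()
    ))
  }
  f <- utils::read.table(text = out)
  names(f) <- c("q_start", "q_end", "s_start", "s_end", "identity", "length")
  strand <- ifelse(f$s_start <= f$s_end, "+", "-")
  tibble::tibble(
    q_start = f$q_start, q_end = f$q_end,
    s_start = pmin(f$s_start, f$s_end), s_end = pmax(f$s_start, f$s_end),
    identity = f$identity / 100, length = f$length, strand = strand
  )
}

# Reciprocal overlap fraction of two closed intervals.
reciprocal_overlap <- function(a1, a2, b1, b2) {
  ov <- max(0L, min(a2, b2) - max(a1, b1) + 1L)
  ov / max(a2 - a1 + 1L, b2 - b1 + 1L)
}

# Does every hit in `a` have a counterpart in `b` with >= `frac` reciprocal
# overlap on both query and subject intervals?
hits_matched <- function(a, b, frac = 0.95) {
  if (nrow(a) == 0L) return(TRUE)
  vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      reciprocal_overlap(a$q_start[i], a$q_end[i], b$q_start[j], b$q_end[j]) >= frac &&
        reciprocal_overlap(a$s_start[i], a$s_end[i], b$s_start[j], b$s_end[j]) >= frac
    }, TRUE))
  }, TRUE)
}
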