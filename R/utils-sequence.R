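# Sequence helpers shared across modules. Sequences travel as plain (optionally
# named) uppercase character vectors; Biostrings does the heavy lifting for IO
# and complementation.

#' Reverse-complement nucleotide sequences
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return Character vector of the same length, reverse-complemented.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANN"))
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Generate a random DNA sequence
#'
#' Draws i.i.d. bases at a given GC fraction. Uses the current RNG state;
#' callers that need reproducibility wrap this in [withr::with_seed()].
#'
#' @param n Sequence length in bases.
#' @param gc GC fraction in \[0, 1\].
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.44) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Substitute bases so the result has exactly round((1 - identity) * len)
# differences from `seq`, each at a distinct position. Substitution-only;
# uses the current RNG state.
mutate_to_identity <- function(seq, identity) {
  stopifnot(identity >= 0, identity <= 1)
  len <- nchar(seq)
  n_sub <- round((1 - identity) * len)
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(len, n_sub)
  bases <- c("A", "C", "G", "T")
  chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(bases, b), 1L), "")
  paste(chars, collapse = "")
}

# Apply a per-base substitution error model to a vector of reads.
add_read_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    len <- nchar(s)
    hit <- which(runif(len) < error_rate)
    if (!length(hit)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) {
      alt <- setdiff(bases, b)
      if (length(alt) < 4L) sample(alt, 1L) else sample(bases, 1L)
    }, "")
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings returning/accepting named character vectors.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write paired FASTQ files
#'
#' Mate order is preserved between the two files; read ids must match
#' line-for-line (trailing `/1`, `/2` suffixes are stripped).
#'
#' @param path1,path2 Paths to the mate-1 and mate-2 FASTQ files.
#' @param reads Long tibble with columns `read_id`, `mate` (1 or 2), `seq`,
#'   and optionally `qual`.
#' @return `read_fastq_pairs()` returns a tibble with columns `read_id`,
#'   `mate`, `seq`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  rd <- function(p, mate) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    ids <- sub("[/ ].*$", "", names(x))
    tibble(read_id = ids, mate = mate, seq = unname(as.character(x)))
  }
  out <- bind_rows(rd(path1, 1L), rd(path2, 2L))
  n1 <- sum(out$mate == 1L)
  if (n1 != sum(out$mate == 2L)) {
    abort("mate files differ in read count")
  }
  out
}

#' @rdname read_fastq_pairs
#' @export
write_fastq_pairs <- function(reads, path1, path2) {
  stopifnot(all(c("read_id", "mate", "seq") %in% names(reads)))
  for (m in 1:2) {
    sub <- reads[reads$mate == m, ]
    x <- Biostrings::DNAStringSet(sub$seq)
    names(x) <- paste0(sub$read_id, "/", m)
    q <- if ("qual" %in% names(sub)) sub$qual else strrep("I", nchar(sub$seq))
    Biostrings::writeXStringSet(x, if (m == 1) path1 else path2,
      format = "fastq", qualities = Biostrings::BStringSet(q)
    )
  }
  invisible(c(path1, path2))
}

# Validate a sequence over the mapping alphabet.
check_acgtn <- function(x, what = "read") {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside A/C/G/T/N (first offender: %s)",
      what, x[which(bad)[1]]
    ))
  }
  toupper(x)
}
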