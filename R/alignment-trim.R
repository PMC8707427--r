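# Conserved-block trimming of multiple sequence alignments, following the
# published five-step block-selection procedure with the "relaxed" setting
# family (-t=d -b1=half -b2=half -b3=8 -b4=5 -b5=half), plus batch trimming
# and concatenation for multi-gene matrices. Columns are only ever dropped,
# never reordered or edited.

#' Coerce to an alignment (named character vector of equal-width rows)
#'
#' Accepts a named character vector, a `Biostrings` string set, or a FASTA
#' path.
#'
#' @param x Alignment input.
#' @return Named character vector with unique names and equal row widths.
#' @export
as_msa <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- read_fasta(x)
  } else if (methods::is(x, "XStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  stopifnot(is.character(x), length(x) >= 1L)
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    abort("alignment rows must carry unique taxon names")
  }
  if (length(unique(nchar(x))) != 1L) {
    abort("alignment rows differ in length")
  }
  toupper(x)
}

#' Trimming parameters
#'
#' `b1` is the minimum number of sequences for a conserved position and
#' `b2` for a highly conserved (flank) position; the "half" setting for
#' either resolves to `floor(n/2) + 1` (minimum majority — note the +1:
#' an off-by-one here changes outputs). `b3` is the maximum run of
#' contiguous nonconserved positions kept inside a block, `b4` the minimum
#' block length, and `b5` the gap tolerance: `"none"` disqualifies any
#' column with a gap, `"half"` disqualifies columns with gaps in more than
#' half the rows, `"all"` never disqualifies on gaps alone.
#'
#' @param n Number of rows (taxa) in the alignment.
#' @param b1,b2 Conservation thresholds in sequences; `NULL` means "half".
#' @param b3 Maximum contiguous nonconserved positions (>= 0).
#' @param b4 Minimum block length (>= 2).
#' @param b5 Gap tolerance mode: "half", "none" or "all".
#' @return A list of class `trim_params`.
#' @export
trim_params <- function(n, b1 = NULL, b2 = NULL, b3 = 8L, b4 = 5L,
                        b5 = c("half", "none", "all")) {
  b5 <- match.arg(b5)
  half <- floor(n / 2) + 1L
  b1 <- as.integer(b1 %||% half)
  b2 <- as.integer(b2 %||% half)
  stopifnot(b1 <= b2, b2 <= n, b3 >= 0L, b4 >= 2L)
  structure(
    list(n = as.integer(n), b1 = b1, b2 = b2, b3 = as.integer(b3),
         b4 = as.integer(b4), b5 = b5),
    class = "trim_params"
  )
}

#' Classify alignment columns by conservation
#'
#' A column is first tested against the gap rule (`b5`); gap-disqualified
#' columns are nonconserved regardless of residues. Otherwise the count of
#' the modal residue decides: `>= b1` is conserved, `>= b2` highly
#' conserved, else nonconserved. Both `-` and `.` count as gaps; ambiguity
#' codes (N, R, Y, ...) are non-gap residues that never contribute to the
#' modal count.
#'
#' @param msa Alignment (see [as_msa()]).
#' @param params A [trim_params()]; defaults to the relaxed setting for
#'   the alignment's row count.
#' @return Tibble with columns `column`, `gap_count`, `modal_count`,
#'   `gap_position` (logical) and `status`
#'   ("nonconserved"/"conserved"/"highly_conserved").
#' @export
classify_columns <- function(msa, params = NULL) {
  msa <- as_msa(msa)
  n <- length(msa)
  params <- params %||% trim_params(n)
  stopifnot(inherits(params, "trim_params"))
  if (nchar(msa[1]) == 0L) abort("empty alignment")
  m <- matrix(unlist(strsplit(msa, "", fixed = TRUE), use.names = FALSE),
    nrow = n, byrow = TRUE
  )
  gap_count <- colSums(m == "-" | m == ".")
  modal_count <- apply(m, 2L, function(col) {
    res <- col[col %in% c("A", "C", "G", "T")]
    if (!length(res)) 0L else max(tabulate(factor(res, levels = c("A", "C", "G", "T"))))
  })
  gap_position <- switch(params$b5,
    none = gap_count > 0L,
    half = gap_count > n / 2,
    all = rep(FALSE, ncol(m))
  )
  status <- case_when(
    gap_position ~ "nonconserved",
    modal_count >= params$b2 ~ "highly_conserved",
    modal_count >= params$b1 ~ "conserved",
    TRUE ~ "nonconserved"
  )
  tibble(
    column = seq_len(ncol(m)), gap_count = as.integer(gap_count),
    modal_count = as.integer(modal_count), gap_position = gap_position,
    status = status
  )
}

#' Select conserved blocks from column classifications
#'
#' The five selection steps, in order: (1) per-column classification (the
#' input); (2) runs of more than `b3` contiguous nonconserved columns are
#' rejected; (3) each remaining candidate block is trimmed from both ends
#' until its terminal columns are highly conserved; (4) gap-disqualified
#' columns inside blocks are removed together with any contiguous run of
#' nonconserved columns adjacent to them (which may split a block); (5)
#' blocks shorter than `b4` are rejected. Kept columns are the union of
#' surviving blocks, in original order.
#'
#' @param statuses Tibble from [classify_columns()].
#' @param params The [trim_params()] used for classification.
#' @return A list of class `block_selection`: `kept_columns` (increasing
#'   integer vector of original column indices) and `blocks` (tibble
#'   `start`, `end`, `length` in original coordinates).
#' @export
select_blocks <- function(statuses, params) {
  stopifnot(inherits(params, "trim_params"))
  st <- statuses$status
  gap <- statuses$gap_position
  ncol <- length(st)
  alive <- rep(TRUE, ncol)

  # step 2: long nonconserved stretches
  r <- rle(st == "nonconserved")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] > params$b3) alive[starts[i]:ends[i]] <- FALSE
  }

  # step 3: anchor block ends at highly conserved columns
  alive <- purrr::reduce(
    block_ranges(alive),
    function(a, b) {
      idx <- b[1]:b[2]
      hc <- which(st[idx] == "highly_conserved")
      a[idx] <- FALSE
      if (length(hc)) a[idx[min(hc)]:idx[max(hc)]] <- TRUE
      a
    },
    .init = alive
  )

  # step 4: gap positions and adjacent nonconserved runs
  for (b in block_ranges(alive)) {
    idx <- b[1]:b[2]
    kill <- gap[idx]
    if (!any(kill)) next
    for (g in which(kill)) {
      j <- g - 1L
      while (j >= 1L && st[idx[j]] == "nonconserved") {
        kill[j] <- TRUE
        j <- j - 1L
      }
      j <- g + 1L
      while (j <= length(idx) && st[idx[j]] == "nonconserved") {
        kill[j] <- TRUE
        j <- j + 1L
      }
    }
    alive[idx[kill]] <- FALSE
  }

  # step 5: minimum block length
  for (b in block_ranges(alive)) {
    if (b[2] - b[1] + 1L < params$b4) alive[b[1]:b[2]] <- FALSE
  }

  blocks <- block_ranges(alive)
  structure(
    list(
      kept_columns = which(alive),
      blocks = tibble(
        start = vapply(blocks, `[`, 1L, 1L),
        end = vapply(blocks, `[`, 1L, 2L)
      ) %>% mutate(length = .data$end - .data$start + 1L)
    ),
    class = "block_selection"
  )
}

# Maximal runs of TRUE as a list of c(start, end).
block_ranges <- function(alive) {
  if (!any(alive)) return(list())
  r <- rle(alive)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map(which(r$values), ~ c(starts[.x], ends[.x]))
}

#' @export
print.block_selection <- function(x, ...) {
  cat(sprintf(
    "<block_selection> %d column(s) kept in %d block(s)\n",
    length(x$kept_columns), nrow(x$blocks)
  ))
  invisible(x)
}

#' Trim an alignment to its conserved blocks
#'
#' @param msa Alignment (see [as_msa()]).
#' @param params A [trim_params()]; defaults to the relaxed setting.
#' @return A list of class `trimmed_msa`: `msa` (trimmed named character
#'   vector) and `selection` (a `block_selection`).
#' @export
trim_msa <- function(msa, params = NULL) {
  msa <- as_msa(msa)
  params <- params %||% trim_params(length(msa))
  sel <- select_blocks(classify_columns(msa, params), params)
  kept <- sel$kept_columns
  trimmed <- vapply(msa, function(s) {
    paste(strsplit(s, "", fixed = TRUE)[[1]][kept], collapse = "")
  }, "", USE.NAMES = TRUE)
  structure(
    list(msa = trimmed, selection = sel, params = params,
         total_columns = nchar(msa[[1]])),
    class = "trimmed_msa"
  )
}

#' @export
print.trimmed_msa <- function(x, ...) {
  cat(sprintf(
    "<trimmed_msa> %d taxa, %d of %d column(s) kept\n",
    length(x$msa), length(x$selection$kept_columns), x$total_columns
  ))
  invisible(x)
}

#' Trim several gene alignments and concatenate them
#'
#' Each gene is trimmed independently (batch mode), then the trimmed
#' alignments are concatenated in input order over the union of taxa;
#' taxa missing from a gene are padded with all-gap rows before trimming
#' (and a message reports the padding). A partition table maps each gene
#' to its concatenated coordinate range; genes whose selection is empty
#' contribute zero columns and an `NA` range.
#'
#' @param msas Named list of alignments (see [as_msa()]).
#' @param params Optional [trim_params()] shared across genes; defaults to
#'   the relaxed setting for the union taxa count.
#' @return A list of class `concat_msa`: `msa` (concatenated named
#'   character vector), `partitions` (tibble `gene`, `start`, `end`,
#'   `kept`, `total`), `selections` (named list of `block_selection`).
#' @export
concat_and_trim <- function(msas, params = NULL) {
  stopifnot(is.list(msas), length(msas) >= 1L)
  if (is.null(names(msas))) names(msas) <- paste0("gene", seq_along(msas))
  msas <- purrr::map(msas, as_msa)
  taxa <- unique(unlist(purrr::map(msas, names)))
  params <- params %||% trim_params(length(taxa))

  padded <- purrr::imap(msas, function(m, gene) {
    missing <- setdiff(taxa, names(m))
    if (length(missing)) {
      inform(sprintf(
        "gene %s: padding %d missing taxa with all-gap rows", gene, length(missing)
      ))
      m <- c(m, stats::setNames(rep(strrep("-", nchar(m[1])), length(missing)), missing))
    }
    m[taxa]
  })

  trimmed <- purrr::map(padded, trim_msa, params = params)
  kept_n <- unname(purrr::map_int(trimmed, ~ length(.x$selection$kept_columns)))
  ends <- cumsum(kept_n)
  starts <- ends - kept_n + 1L
  partitions <- tibble(
    gene = names(msas),
    start = if_else(kept_n > 0L, as.integer(starts), NA_integer_),
    end = if_else(kept_n > 0L, as.integer(ends), NA_integer_),
    kept = kept_n,
    total = unname(purrr::map_int(msas, ~ nchar(.x[1])))
  )
  concat <- vapply(taxa, function(tx) {
    paste(purrr::map_chr(trimmed, ~ .x$msa[[tx]]), collapse = "")
  }, "", USE.NAMES = TRUE)
  structure(
    list(
      msa = concat, partitions = partitions,
      selections = purrr::map(trimmed, "selection")
    ),
    class = "concat_msa"
  )
}

#' Write a RAxML-style partition table
#'
#' @param partitions Tibble from [concat_and_trim()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path) {
  keep <- !is.na(partitions$start)
  writeLines(
    sprintf("DNA, %s = %d-%d", partitions$gene[keep],
      partitions$start[keep], partitions$end[keep]),
    path
  )
  invisible(path)
}
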