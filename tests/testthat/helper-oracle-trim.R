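# Independent reference transcription of the published conserved-block
# selection procedure (the five steps), written as plain per-column loops
# with no shared code with the package implementation. Used as the oracle
# for the trimmer, and by scripts/make-trim-fixtures.R to freeze fixture
# outputs.

reference_block_selection <- function(rows, b1 = NULL, b2 = NULL, b3 = 8L,
                                      b4 = 5L, b5 = "half") {
  n <- length(rows)
  if (is.null(b1)) b1 <- floor(n / 2) + 1L
  if (is.null(b2)) b2 <- floor(n / 2) + 1L
  m <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  ncol <- ncol(m)

  # step 1: classify every position
  status <- character(ncol)
  gap_pos <- logical(ncol)
  for (j in seq_len(ncol)) {
    col <- m[, j]
    gaps <- sum(col == "-" | col == ".")
    counts <- c(
      sum(col == "A"), sum(col == "C"), sum(col == "G"), sum(col == "T")
    )
    top <- max(counts)
    gp <- switch(b5,
      none = gaps > 0L,
      half = gaps > n / 2,
      all = FALSE
    )
    gap_pos[j] <- gp
    status[j] <- if (gp) "nonconserved"
    else if (top >= b2) "highly_conserved"
    else if (top >= b1) "conserved"
    else "nonconserved"
  }

  keep <- rep(TRUE, ncol)

  # step 2: reject stretches of more than b3 contiguous nonconserved
  j <- 1L
  while (j <= ncol) {
    if (status[j] == "nonconserved") {
      j2 <- j
      while (j2 < ncol && status[j2 + 1L] == "nonconserved") j2 <- j2 + 1L
      if (j2 - j + 1L > b3) keep[j:j2] <- FALSE
      j <- j2 + 1L
    } else {
      j <- j + 1L
    }
  }

  blocks_of <- function(keep) {
    out <- list()
    j <- 1L
    while (j <= ncol) {
      if (keep[j]) {
        j2 <- j
        while (j2 < ncol && keep[j2 + 1L]) j2 <- j2 + 1L
        out[[length(out) + 1L]] <- c(j, j2)
        j <- j2 + 1L
      } else {
        j <- j + 1L
      }
    }
    out
  }

  # step 3: trim block ends back to highly conserved positions
  for (b in blocks_of(keep)) {
    a <- b[1]; z <- b[2]
    while (a <= z && status[a] != "highly_conserved") {
      keep[a] <- FALSE
      a <- a + 1L
    }
    while (z >= a && status[z] != "highly_conserved") {
      keep[z] <- FALSE
      z <- z - 1L
    }
  }

  # step 4: remove gap positions inside blocks plus adjacent nonconserved runs
  for (b in blocks_of(keep)) {
    for (j in b[1]:b[2]) {
      if (!gap_pos[j]) next
      keep[j] <- FALSE
      jj <- j - 1L
      while (jj >= b[1] && status[jj] == "nonconserved") {
        keep[jj] <- FALSE
        jj <- jj - 1L
      }
      jj <- j + 1L
      while (jj <= b[2] && status[jj] == "nonconserved") {
        keep[jj] <- FALSE
        jj <- jj + 1L
      }
    }
  }

  # step 5: drop blocks shorter than b4
  for (b in blocks_of(keep)) {
    if (b[2] - b[1] + 1L < b4) keep[b[1]:b[2]] <- FALSE
  }

  which(keep)
}

# Random toy alignment generator: a mix of clean conserved columns, noisy
# columns, and gappy columns, seeded for reproducibility.
random_toy_alignment <- function(n_taxa, n_col, seed) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    cols <- vapply(seq_len(n_col), function(j) {
      type <- sample(c("clean", "noisy", "gappy", "mixed"), 1,
        prob = c(0.45, 0.3, 0.15, 0.1)
      )
      col <- switch(type,
        clean = {
          x <- rep(sample(bases, 1), n_taxa)
          k <- sample(0:1, 1)
          if (k) x[sample(n_taxa, k)] <- sample(bases, k, replace = TRUE)
          x
        },
        noisy = sample(bases, n_taxa, replace = TRUE),
        gappy = {
          x <- rep(sample(bases, 1), n_taxa)
          x[sample(n_taxa, sample(ceiling(n_taxa / 3):n_taxa, 1))] <- "-"
          x
        },
        mixed = {
          x <- sample(bases, n_taxa, replace = TRUE)
          x[sample(n_taxa, sample(0:floor(n_taxa / 3), 1))] <- "-"
          x
        }
      )
      paste(col, collapse = "")
    }, "")
    mat <- do.call(rbind, strsplit(cols, "", fixed = TRUE))
    rows <- apply(mat, 2, paste, collapse = "")
    stats::setNames(rows, paste0("taxon", seq_len(n_taxa)))
  })
}
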