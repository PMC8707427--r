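#!/usr/bin/env Rscript
# Regenerates the trimmer oracle fixtures under tests/testthat/fixtures/trim/:
# 12 seeded toy alignments plus the column sets kept by the independent
# reference transcription of the block-selection procedure (see
# tests/testthat/helper-oracle-trim.R and fixtures/trim/README.md).
# Run from the repository root:  Rscript scripts/make-trim-fixtures.R

library(mitostructr)
source("tests/testthat/helper-oracle-trim.R")

dir.create("tests/testthat/fixtures/trim", recursive = TRUE, showWarnings = FALSE)

set <- expand.grid(seed = 1:12)
for (i in seq_len(nrow(set))) {
  seed <- 1000L + set$seed[i]
  n_taxa <- 6L + (seed %% 7L)
  n_col <- 120L + 10L * (seed %% 9L)
  aln <- random_toy_alignment(n_taxa, n_col, seed)
  kept <- reference_block_selection(unname(aln))
  base <- sprintf("tests/testthat/fixtures/trim/case_%02d", i)
  write_fasta(aln, paste0(base, ".fasta"))
  writeLines(paste(kept, collapse = " "), paste0(base, ".kept.txt"))
  cat(sprintf(
    "case_%02d: %d taxa x %d cols -> %d kept\n", i, n_taxa, n_col, length(kept)
  ))
}
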