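test_that("exact substrings map uniquely with full identity on either strand", {
  g <- generate_genome(genome_spec(20000, seed = 61))
  read <- substr(g$genome, 5001, 5125)
  hit <- map_mate(read, g$genome)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$ref_start, 5001)
  expect_equal(hit$ref_end, 5125)
  expect_equal(hit$strand, "+")
  expect_equal(hit$identity, 1)
  expect_equal(hit$aligned_frac, 1)

  hit_rc <- map_mate(revcomp(read), g$genome)
  expect_equal(nrow(hit_rc), 1)
  expect_equal(hit_rc$ref_start, 5001)
  expect_equal(hit_rc$strand, "-")

  expect_error(map_mate("ACGTX", g$genome), "A/C/G/T/N")
})

test_that("the 90% identity threshold is a sharp boundary at 12 vs 13 substitutions in 125 bp", {
  g <- generate_genome(genome_spec(20000, seed = 62))
  read <- substr(g$genome, 9001, 9125)
  corrupt <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    pos <- seq(40, by = 5, length.out = n) # clustered mid-read, seeds at ends stay intact
    ch[pos] <- vapply(ch[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
    paste(ch, collapse = "")
  }
  ok <- map_mate(corrupt(read, 12), g$genome) # identity 113/125 = 0.904
  expect_equal(nrow(ok), 1)
  expect_equal(ok$identity, 113 / 125)
  bad <- map_mate(corrupt(read, 13), g$genome) # identity 112/125 = 0.896
  expect_equal(nrow(bad), 0)
})

test_that("every reported placement satisfies both thresholds on randomly mutated reads", {
  g <- generate_genome(genome_spec(20000, seed = 63))
  withr::with_seed(64, {
    for (i in 1:40) {
      s <- sample(19000, 1)
      read <- substr(g$genome, s, s + 124)
      n_mut <- sample(0:16, 1)
      if (n_mut > 0) {
        ch <- strsplit(read, "")[[1]]
        pos <- sample(125, n_mut)
        ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        read <- paste(ch, collapse = "")
      }
      hits <- map_mate(read, g$genome)
      if (nrow(hits)) {
        expect_true(all(hits$identity >= 0.9))
        expect_true(all(hits$aligned_frac >= 0.9))
      }
      # with seed offsets every 10 bp, up to 3 scattered substitutions
      # always leave one intact 31-mer seed
      if (n_mut <= 3) expect_gte(nrow(hits), 1)
    }
  })
})

test_that("reads from an exact two-copy repeat map twice and flag the pair ambiguous", {
  spec <- genome_spec(20000,
    repeats = tibble::tibble(
      length = 400, identity = 1, source_start = 3001, copy_start = 12001
    ),
    seed = 65
  )
  g <- generate_genome(spec)
  read <- substr(g$genome, 3101, 3225) # inside the repeat
  hits <- map_mate(read, g$genome)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$ref_start, c(3101, 12101))

  pl <- map_reads(
    tibble::tibble(read_id = "p1", mate = 1:2,
      seq = c(read, revcomp(substr(g$genome, 3701, 3825)))),
    g$genome
  )
  pairs <- pair_up(pl)
  expect_true(pairs$ambiguous)
  expect_equal(pairs$n1, 2)
  # identity tie at two positions: leftmost chosen as the representative
  expect_equal(pairs$m1_start, 3101)
})

test_that("pair_up builds partial records for unmapped mates and is symmetric under mate relabeling", {
  g <- generate_genome(genome_spec(20000, seed = 66))
  reads <- tibble::tibble(
    read_id = c("a", "a", "b", "b"),
    mate = c(1L, 2L, 1L, 2L),
    seq = c(
      substr(g$genome, 1001, 1125), revcomp(substr(g$genome, 1601, 1725)),
      substr(g$genome, 5001, 5125), strrep("A", 125) # mate 2 unmappable
    )
  )
  pairs <- pair_up(map_reads(reads, g$genome))
  a <- pairs[pairs$read_id == "a", ]
  expect_equal(a$m1_start, 1001)
  expect_equal(a$m2_start, 1601)
  expect_false(a$ambiguous)
  b <- pairs[pairs$read_id == "b", ]
  expect_true(is.na(b$m2_start))
  expect_equal(b$m1_start, 5001)

  swapped <- reads
  swapped$mate <- c(2L, 1L, 2L, 1L)
  pairs_sw <- pair_up(map_reads(swapped, g$genome))
  a_sw <- pairs_sw[pairs_sw$read_id == "a", ]
  expect_equal(sort(c(a_sw$m1_start, a_sw$m2_start)), sort(c(a$m1_start, a$m2_start)))
  expect_equal(a_sw$m1_start, a$m2_start)
})

test_that("error-free reads from a repeat-free genome recover their truth placement", {
  fxl <- fx_linear()
  expected <- truth_placements(fxl$sim, fxl$iso)
  got <- fxl$placements
  j <- dplyr::inner_join(
    expected, got,
    by = c("read_id", "mate", "ref_start", "ref_end", "strand")
  )
  expect_gte(nrow(j) / nrow(expected), 0.999)
})

test_that("SAM ingestion honors flags, NM-based identity, and skips malformed rows", {
  td <- withr::local_tempdir()
  sam <- file.path(td, "toy.sam")
  ref <- strrep("ACGT", 500)
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:scaffold\tLN:2000",
    # proper pair, clean
    paste("p1", 99, "scaffold", 101, 60, "125M", "=", 801, 825,
      strrep("A", 125), strrep("I", 125), "NM:i:2", sep = "\t"),
    paste("p1", 147, "scaffold", 801, 60, "125M", "=", 101, -825,
      strrep("A", 125), strrep("I", 125), "NM:i:0", sep = "\t"),
    # secondary alignment: ignored
    paste("p1", 355, "scaffold", 1501, 0, "125M", "=", 801, 0,
      "*", "*", "NM:i:1", sep = "\t"),
    # pair failing the identity threshold (13 mismatches)
    paste("p2", 99, "scaffold", 201, 60, "125M", "=", 901, 825,
      strrep("C", 125), strrep("I", 125), "NM:i:13", sep = "\t"),
    paste("p2", 147, "scaffold", 901, 60, "125M", "=", 201, -825,
      strrep("C", 125), strrep("I", 125), "NM:i:0", sep = "\t")
  )
  writeLines(lines, sam)
  pairs <- ingest_alignments(sam)
  p1 <- pairs[pairs$read_id == "p1", ]
  expect_equal(nrow(p1), 1)
  expect_equal(p1$m1_start, 101)
  expect_equal(p1$m2_start, 801)
  expect_equal(p1$m1_strand, "+")
  expect_equal(p1$m2_strand, "-")
  expect_equal(p1$m1_identity, 123 / 125)
  # p2 mate 1 fails 90% identity -> partial record
  p2 <- pairs[pairs$read_id == "p2", ]
  expect_true(is.na(p2$m1_start))
  expect_equal(p2$m2_start, 901)
})

test_that("pair classifications agree with an external mapper on error-free reads", {
  g <- generate_genome(genome_spec(30000, seed = 71))
  iso <- tibble::tibble(
    molecule = "m", start = 1, end = 30000, topology = "circular", copy_number = 1
  )
  sim <- simulate_pairs(build_isoforms(g, iso), library_spec(depth = 8, seed = 72))
  internal <- classify_pairs(pair_up(map_reads(sim$reads, g$genome)))

  td <- withr::local_tempdir()
  fa <- file.path(td, "ref.fasta")
  f1 <- file.path(td, "r_1.fastq"); f2 <- file.path(td, "r_2.fastq")
  write_fasta(c(scaffold = g$genome), fa)
  write_fastq_pairs(sim$reads, f1, f2)
  system2("bwa", c("index", fa), stdout = FALSE, stderr = FALSE)
  sam <- file.path(td, "aln.sam")
  system2("bwa", c("mem", fa, f1, f2), stdout = sam, stderr = FALSE)
  external <- classify_pairs(ingest_alignments(sam))

  j <- dplyr::inner_join(
    internal[, c("read_id", "status")], external[, c("read_id", "status")],
    by = "read_id", suffix = c("_int", "_ext")
  )
  expect_gte(nrow(j) / nrow(internal), 0.95)
  expect_gte(mean(j$status_int == j$status_ext), 0.99)
})
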