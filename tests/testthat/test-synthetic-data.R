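test_that("genome generation is deterministic and respects the requested spec", {
  spec <- genome_spec(10000, gc = 0.40, seed = 7)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$plastome, g2$plastome)
  expect_equal(nchar(g1$genome), 10000)
  expect_false(grepl("[^ACGT]", g1$genome))
  gc_obs <- sum(strsplit(g1$genome, "")[[1]] %in% c("G", "C")) / 10000
  expect_lt(abs(gc_obs - 0.40), 0.03)
  g3 <- generate_genome(genome_spec(10000, gc = 0.40, seed = 8))
  expect_false(identical(g1$genome, g3$genome))
})

test_that("planted repeats and MIPTs appear in the truth table at the requested size and identity", {
  spec <- genome_spec(30000,
    repeats = tibble::tibble(
      length = 483, identity = 1.0, source_start = 2000, copy_start = 20000
    ),
    mipts = tibble::tibble(
      donor_start = 501, donor_end = 2200, insert_start = 10000, identity = 0.85
    ),
    plastome_length = 10000, seed = 11
  )
  g <- generate_genome(spec)
  feats <- g$features
  rep_row <- feats[feats$type == "repeat", ]
  expect_equal(nrow(rep_row), 1)
  expect_equal(rep_row$length, 483)
  # both copies exist and are identical at identity 1.0
  src <- substr(g$genome, rep_row$partner_start, rep_row$partner_end)
  cpy <- substr(g$genome, rep_row$start, rep_row$end)
  expect_equal(nchar(src), 483)
  expect_identical(src, cpy)

  mipt_row <- feats[feats$type == "mipt", ]
  expect_equal(mipt_row$length, 1700)
  donor <- substr(g$plastome, mipt_row$partner_start, mipt_row$partner_end)
  inserted <- substr(g$genome, mipt_row$start, mipt_row$end)
  mm <- sum(charToRaw(donor) != charToRaw(inserted))
  expect_equal(mm, round(0.15 * 1700))
})

test_that("overlapping planted intervals are rejected with a message naming the conflict", {
  expect_error(
    genome_spec(10000, repeats = tibble::tibble(
      length = 500, identity = 1, source_start = c(1000, 1200),
      copy_start = c(5000, 8000)
    )),
    "overlap.*1000.*1499|overlap.*1200"
  )
  expect_error(
    genome_spec(10000, repeats = tibble::tibble(
      length = 500, identity = 1, source_start = 1000, copy_start = 9700
    )),
    "outside"
  )
})

test_that("build_isoforms concatenates oriented segments and supports the bridged two-circle layout", {
  g <- generate_genome(genome_spec(6000, seed = 5))
  # identity case: one circular molecule covering the scaffold
  iso <- tibble::tibble(
    molecule = "m", start = 1, end = 6000, topology = "circular", copy_number = 1
  )
  mol <- build_isoforms(g, iso)
  expect_equal(mol$length, 6000)
  expect_identical(mol$seq, g$genome)
  expect_equal(mol$topology, "circular")

  # minus-strand segment is reverse-complemented
  iso2 <- tibble::tibble(
    molecule = "m", start = c(1, 3001), end = c(3000, 6000),
    strand = c("+", "-"), topology = "linear", copy_number = 1
  )
  mol2 <- build_isoforms(g, iso2)
  expect_identical(
    mol2$seq,
    paste0(substr(g$genome, 1, 3000), revcomp(substr(g$genome, 3001, 6000)))
  )

  # bridged layout: the bridge interval may appear in several molecules
  iso3 <- tibble::tibble(
    molecule = c("A", "A", "B", "B", "bridge"),
    start = c(1, 2001, 2001, 4001, 2001),
    end = c(2000, 4000, 4000, 6000, 4000),
    topology = c("circular", "circular", "circular", "circular", "linear"),
    copy_number = c(1, 1, 1, 1, 0.3)
  )
  mol3 <- build_isoforms(g, iso3)
  expect_equal(nrow(mol3), 3)
  expect_setequal(mol3$molecule, c("A", "B", "bridge"))
  expect_equal(sort(mol3$length), c(2000, 4000, 4000))

  expect_error(
    build_isoforms(g, tibble::tibble(molecule = "m", start = 10, end = 9)),
    "zero"
  )
})

test_that("read sampling weights molecules by copy number x length", {
  g <- generate_genome(genome_spec(24000, seed = 21))
  iso <- tibble::tibble(
    molecule = c("hi", "lo"), start = c(1, 12001), end = c(12000, 24000),
    topology = "linear", copy_number = c(2, 1)
  )
  sim <- simulate_pairs(build_isoforms(g, iso), library_spec(depth = 40, seed = 22))
  counts <- table(sim$truth$molecule)
  # equal lengths, copies 2:1 -> expected proportion 2/3 for "hi"
  test <- stats::binom.test(counts[["hi"]], sum(counts), p = 2 / 3)
  expect_gt(test$p.value, 1e-4)
})

test_that("insert lengths follow the truncated-Normal library model", {
  g <- generate_genome(genome_spec(30000, seed = 31))
  iso <- tibble::tibble(
    molecule = "m", start = 1, end = 30000, topology = "linear", copy_number = 1
  )
  lib <- library_spec(insert_mean = 800, insert_sd = 80, depth = 100, seed = 32)
  sim <- simulate_pairs(build_isoforms(g, iso), lib)
  expect_gte(nrow(sim$truth), 10000)
  se <- 80 / sqrt(nrow(sim$truth))
  expect_lt(abs(mean(sim$truth$insert_length) - 800), 2 * se + 0.5)
  expect_true(all(sim$truth$insert_length >= 250))
  expect_true(all(sim$truth$insert_length <= 30000))
})

test_that("every emitted pair is logged in the truth table and placed within its molecule", {
  fx <- fx_circle()
  sim <- fx$sim
  expect_equal(nrow(sim$truth), nrow(sim$reads) / 2)
  expect_identical(sort(unique(sim$reads$read_id)), sort(sim$truth$read_id))
  expect_true(all(sim$truth$start >= 1 & sim$truth$start <= fx$length))
  # circular sampling wraps the origin for some inserts
  expect_gt(sum(sim$truth$start + sim$truth$insert_length - 1 > fx$length), 0)
  # linear molecules never wrap
  fxl <- fx_linear()
  expect_true(all(
    fxl$sim$truth$start + fxl$sim$truth$insert_length - 1 <= fxl$length
  ))
})

test_that("molecules too short for the library are rejected", {
  g <- generate_genome(genome_spec(900, seed = 41))
  short_lin <- tibble::tibble(
    molecule = "m", start = 1, end = 900, topology = "linear", copy_number = 1
  )
  expect_error(
    simulate_pairs(build_isoforms(g, short_lin), library_spec(seed = 1)),
    "insert_mean"
  )
  g2 <- generate_genome(genome_spec(200, seed = 42))
  tiny <- tibble::tibble(
    molecule = "m", start = 1, end = 200, topology = "circular", copy_number = 1
  )
  expect_error(
    simulate_pairs(build_isoforms(g2, tiny), library_spec(seed = 1)),
    "read lengths"
  )
})

test_that("simulation and FASTA/FASTQ round trips are byte-reproducible", {
  g <- generate_genome(genome_spec(8000, seed = 51))
  iso <- tibble::tibble(
    molecule = "m", start = 1, end = 8000, topology = "circular", copy_number = 1
  )
  mol <- build_isoforms(g, iso)
  s1 <- simulate_pairs(mol, library_spec(depth = 5, seed = 52))
  s2 <- simulate_pairs(mol, library_spec(depth = 5, seed = 52))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)

  td <- withr::local_tempdir()
  f1 <- file.path(td, "r_1.fastq"); f2 <- file.path(td, "r_2.fastq")
  write_fastq_pairs(s1$reads, f1, f2)
  back <- read_fastq_pairs(f1, f2)
  expect_identical(back$seq, s1$reads$seq[order(s1$reads$mate, s1$reads$read_id)])
  fa <- file.path(td, "g.fasta")
  write_fasta(c(scaffold = g$genome), fa)
  expect_identical(unname(read_fasta(fa)[1]), g$genome)
})

test_that("simulated depth matches the target over the central region", {
  fxl <- fx_linear()
  pl <- truth_placements(fxl$sim, fxl$iso)
  prof <- compute_depth(pl, fxl$length)
  core <- prof$depth[2000:38000]
  expect_gte(stats::median(core), 25 * 0.9)
  expect_lte(stats::median(core), 25 * 1.1)
})
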