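# Shared synthetic fixtures, built once per test run. Sizes are kept modest
# (tens of kb) so the whole suite stays fast; the acceptance tests pin the
# study-scale condition (100 kb) themselves.

# Project simulated truth onto scaffold coordinates as mate placements.
# Handles single-segment molecules (all fixtures here): molecule coordinate
# m maps to scaffold position seg_start + m - 1, with wrap on circles.
# Mates whose span crosses a circular origin are dropped, mirroring what a
# gapless mapper can recover.
truth_placements <- function(sim, iso, read_length = 125L) {
  iso <- dplyr::group_by(tibble::as_tibble(iso), molecule) |>
    dplyr::summarise(
      seg_start = dplyr::first(start), seg_end = dplyr::last(end),
      topology = dplyr::first(topology), .groups = "drop"
    )
  tr <- dplyr::left_join(sim$truth, iso, by = "molecule")
  lm <- tr$seg_end - tr$seg_start + 1L
  # a mate carries the insert's trailing end (reverse strand) when
  # xor(mate == 2, flipped)
  one_mate <- function(mate) {
    is_end <- xor(mate == 2L, tr$flipped)
    s <- ifelse(is_end, tr$start + tr$insert_length - read_length, tr$start)
    wrap <- tr$topology == "circular"
    s2 <- ifelse(wrap, (s - 1L) %% lm + 1L, s)
    e2 <- s2 + read_length - 1L
    keep <- e2 <= lm
    tibble::tibble(
      read_id = tr$read_id[keep], mate = mate,
      ref_start = as.integer(tr$seg_start[keep] + s2[keep] - 1L),
      ref_end = as.integer(tr$seg_start[keep] + e2[keep] - 1L),
      strand = ifelse(is_end[keep], "-", "+"),
      aligned_frac = 1, identity = 1
    )
  }
  dplyr::bind_rows(one_mate(1L), one_mate(2L)) |> dplyr::arrange(read_id, mate)
}

# Pair records straight from truth placements (unambiguous, both mates
# required), bypassing the mapper where only classification is under test.
truth_pairs <- function(sim, iso, read_length = 125L) {
  pair_up(truth_placements(sim, iso, read_length))
}

# Random genome with an exact duplicate of `len` bases whose flanking bases
# are forced to mismatch across the repeat diagonal, so the planted pair's
# alignable span is exactly `len` (no lucky one-base extensions).
planted_exact_repeat <- function(len, seed, L = 20000L, src = 3000L, dst = 12000L) {
  withr::with_seed(seed, {
    g <- random_dna(L, 0.44)
    substr(g, dst, dst + len - 1L) <- substr(g, src, src + len - 1L)
    flip <- c(A = "C", C = "A", G = "T", T = "G")
    for (pos in c(dst - 1L, dst + len)) {
      partner <- substr(g, src + (pos - dst), src + (pos - dst))
      if (substr(g, pos, pos) == partner) {
        substr(g, pos, pos) <- flip[[partner]]
      }
    }
    g
  })
}

fx_env <- new.env()

fx_circle <- function() {
  if (is.null(fx_env$circle)) {
    g <- generate_genome(genome_spec(50000, seed = 301))
    iso <- tibble::tibble(
      molecule = "circle", start = 1L, end = 50000L,
      topology = "circular", copy_number = 1
    )
    sim <- simulate_pairs(build_isoforms(g, iso), library_spec(depth = 25, seed = 302))
    pl <- map_reads(sim$reads, g$genome)
    fx_env$circle <- list(genome = g, iso = iso, sim = sim, placements = pl, length = 50000L)
  }
  fx_env$circle
}

fx_linear <- function() {
  if (is.null(fx_env$linear)) {
    g <- generate_genome(genome_spec(40000, seed = 311))
    iso <- tibble::tibble(
      molecule = "mol", start = 1L, end = 40000L,
      topology = "linear", copy_number = 1
    )
    sim <- simulate_pairs(build_isoforms(g, iso), library_spec(depth = 25, seed = 312))
    pl <- map_reads(sim$reads, g$genome)
    fx_env$linear <- list(genome = g, iso = iso, sim = sim, placements = pl, length = 40000L)
  }
  fx_env$linear
}

fx_bridge <- function() {
  if (is.null(fx_env$bridge)) {
    L <- 60000L
    g <- generate_genome(genome_spec(L, seed = 321))
    iso <- two_circle_bridge_spec(L, 35001L, 38000L, circle_copy = 3, bridge_copy = 1)
    sim <- simulate_pairs(build_isoforms(g, iso), library_spec(depth = 30, seed = 322))
    pl <- map_reads(sim$reads, g$genome)
    fx_env$bridge <- list(
      genome = g, iso = iso, sim = sim, placements = pl, length = L,
      bridge_start = 35001L, bridge_end = 38000L
    )
  }
  fx_env$bridge
}
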