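mk_anomaly <- function(kind, start, end, region_median, genome_median) {
  tibble::tibble(
    kind = kind, start = start, end = end, length = end - start + 1L,
    region_median = region_median, genome_median = genome_median,
    ratio_to_genome_median = region_median / genome_median
  )
}

mk_cluster <- function(cluster, wa, wb, support) {
  tibble::tibble(
    cluster = cluster, wa_start = wa, wa_end = wa, wb_start = wb, wb_end = wb,
    support = support, read_ids = list(character())
  )
}

empty_anomalies <- function() mk_anomaly(character(), integer(), integer(), double(), double())
empty_clusters <- function() mk_cluster(integer(), integer(), integer(), integer())

test_that("scaffolds segment at anomaly boundaries", {
  expect_equal(nrow(segment_scaffold(empty_anomalies(), 50000)), 1)

  segs <- segment_scaffold(
    mk_anomaly("dip", 165852L, 170296L, 10.9, 28.1), 366000
  )
  expect_equal(nrow(segs), 3)
  expect_equal(segs$start, c(1L, 165852L, 170297L))
  expect_equal(segs$end, c(165851L, 170296L, 366000L))
  expect_equal(segs$kind, c("normal", "dip", "normal"))
  expect_equal(segs$median_depth, c(28.1, 10.9, 28.1))

  five <- segment_scaffold(
    mk_anomaly(c("spike", "spike"), c(246000L, 259000L), c(247700L, 260300L),
      c(60, 60), c(35, 35)),
    365000
  )
  expect_equal(nrow(five), 5)
  expect_equal(sum(five$kind == "spike"), 2)
})

test_that("cluster edges adopt end and flank roles in the junction graph", {
  segs <- segment_scaffold(empty_anomalies(), 50000)
  g <- build_junction_graph(segs, mk_cluster(1L, 1L, 50L, 46L), 50000)
  ce <- g$edges[g$edges$type == "cluster", ]
  expect_equal(nrow(ce), 1)
  expect_setequal(c(ce$role_a, ce$role_b), c("left_end", "right_end"))

  segs2 <- segment_scaffold(mk_anomaly("dip", 165852L, 170296L, 10.9, 28.1), 366000)
  g2 <- build_junction_graph(
    segs2,
    dplyr::bind_rows(mk_cluster(1L, 1L, 166L, 57L), mk_cluster(2L, 171L, 366L, 71L)),
    366000
  )
  ce2 <- g2$edges[g2$edges$type == "cluster", ]
  expect_setequal(
    sort(c(ce2$role_a, ce2$role_b)),
    sort(c("left_end", "dip1_left_flank", "dip1_right_flank", "right_end"))
  )
  # adjacency edges connect consecutive segments
  expect_equal(sum(g2$edges$type == "adjacency"), 2)

  expect_error(
    build_junction_graph(segs, mk_cluster(1L, 1L, 99L, 10L), 50000),
    "beyond"
  )
})

test_that("an end-joining cluster with uniform coverage gives a single circle", {
  segs <- segment_scaffold(empty_anomalies(), 50000)
  g <- build_junction_graph(segs, mk_cluster(1L, 1L, 50L, 46L), 50000)
  m <- infer_topology(g)
  expect_equal(m$classification, "single_circle")
  expect_equal(m$molecules$length, 50000L)
  expect_equal(m$molecules$topology, "circular")
  expect_equal(m$molecules$copy_number, 1)
})

test_that("the printed two-circle worked example is reproduced exactly", {
  segs <- segment_scaffold(mk_anomaly("dip", 165852L, 170296L, 10.9, 28.1), 366000)
  g <- build_junction_graph(
    segs,
    dplyr::bind_rows(mk_cluster(1L, 1L, 166L, 57L), mk_cluster(2L, 171L, 366L, 71L)),
    366000
  )
  m <- infer_topology(g)
  expect_equal(m$classification, "circles_with_bridge")
  mol <- m$molecules
  bridge <- mol[mol$molecule == "bridge", ]
  expect_equal(bridge$length, 4445L)
  expect_equal(round(bridge$length / 1000, 1), 4.4)
  left <- mol[mol$molecule == "circle_left", ]
  expect_equal(left$length, 165851L)
  expect_equal(round(left$length / 1000), 166)
  expect_equal(left$topology, "circular")
  expect_equal(bridge$topology, "linear")
  # copy numbers from the printed medians, normalized to the circles
  expect_equal(left$copy_number, 1)
  expect_equal(round(bridge$copy_number, 3), 0.388)
  # idempotence
  expect_identical(infer_topology(g)$molecules, m$molecules)
})

test_that("no clusters means linear; contradictory evidence stays unresolved", {
  segs <- segment_scaffold(empty_anomalies(), 50000)
  lin <- infer_topology(build_junction_graph(segs, empty_clusters(), 50000))
  expect_equal(lin$classification, "linear")

  internal <- infer_topology(
    build_junction_graph(segs, mk_cluster(1L, 20L, 30L, 12L), 50000)
  )
  expect_equal(internal$classification, "unresolved")
  expect_equal(nrow(internal$molecules), 0)
  expect_equal(nrow(internal$evidence), 1)
})

test_that("simulation classifications are recovered for each planted topology", {
  for (s in 1:3) {
    # circle
    g <- generate_genome(genome_spec(30000, seed = 400 + s))
    iso_c <- tibble::tibble(
      molecule = "m", start = 1, end = 30000, topology = "circular", copy_number = 1
    )
    sim <- simulate_pairs(build_isoforms(g, iso_c), library_spec(depth = 20, seed = 410 + s))
    res <- assess_structure(truth_placements(sim, iso_c), 30000)
    expect_equal(res$model$classification, "single_circle")

    # linear
    iso_l <- dplyr::mutate(iso_c, topology = "linear")
    sim_l <- simulate_pairs(build_isoforms(g, iso_l), library_spec(depth = 20, seed = 420 + s))
    res_l <- assess_structure(truth_placements(sim_l, iso_l), 30000)
    expect_equal(res_l$model$classification, "linear")

    # two circles with a bridge
    iso_b <- two_circle_bridge_spec(40000L, 22001L, 25000L, circle_copy = 3)
    gb <- generate_genome(genome_spec(40000, seed = 430 + s))
    sim_b <- simulate_pairs(build_isoforms(gb, iso_b), library_spec(depth = 25, seed = 440 + s))
    res_b <- assess_structure(truth_placements(sim_b, iso_b), 40000)
    expect_equal(res_b$model$classification, "circles_with_bridge")
  }
})

test_that("copy numbers re-estimated from coverage recover the planted ratio", {
  fxb <- fx_bridge()
  res <- assess_structure(fxb$placements, fxb$length)
  expect_equal(res$model$classification, "circles_with_bridge")
  bridge_cn <- res$model$molecules$copy_number[res$model$molecules$molecule == "bridge"]
  expect_gte(bridge_cn, 1 / 3 * 0.85)
  expect_lte(bridge_cn, 1 / 3 * 1.15)
  expect_equal(max(res$model$molecules$copy_number), 1)
})

test_that("topology models serialize to the documented JSON schema", {
  segs <- segment_scaffold(empty_anomalies(), 50000)
  m <- infer_topology(build_junction_graph(segs, mk_cluster(1L, 1L, 50L, 46L), 50000))
  td <- withr::local_tempdir()
  f <- write_topology_json(m, file.path(td, "model.json"))
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$classification, "single_circle")
  expect_equal(back$scaffold_length, 50000)
  expect_equal(back$molecules$length, 50000)
  g <- glance(m)
  expect_equal(g$classification, "single_circle")
  expect_equal(nrow(tidy(m)), 1)
})
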