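# abundance integration, normalization, cluster assignment, matching

test_that("total abundance is exact for constants and linears, close for modes", {
  g <- make_grid(2, 21)
  expect_equal(total_abundance(matrix(3.7, 21, 21), g), 3.7, tolerance = 1e-12)
  ax <- grid_axis(g)
  expect_equal(total_abundance(outer(ax, rep(1, 21)), g), 0.5,
               tolerance = 1e-12)
  g2 <- make_grid(2, 101)
  ax2 <- grid_axis(g2)
  f <- outer(sin(pi * ax2), sin(pi * ax2))
  expect_equal(total_abundance(f, g2), 4 / pi^2, tolerance = 1e-3)
  # 1D and 3D
  g1 <- make_grid(1, 101)
  expect_equal(total_abundance(sin(pi * grid_axis(g1)), g1), 2 / pi,
               tolerance = 1e-3)
  g3 <- make_grid(3, 11)
  expect_equal(total_abundance(array(2, c(11, 11, 11)), g3), 2,
               tolerance = 1e-12)
})

test_that("normalization maps extremes onto [0, 12] and rejects degeneracy", {
  expect_equal(normalize_series(c(2, 8)), c(0, 12))
  expect_equal(normalize_series(c(0, 3, 6)), c(0, 6, 12))
  x <- c(0.3, 1.7, 0.9)
  expect_identical(normalize_series(x, "identity"), x)
  expect_error(normalize_series(rep(5, 4)), "constant")
  expect_error(normalize_series(numeric(0)), "non-empty")
})

test_that("cluster assignment reproduces the scale and its gap rule", {
  sc <- cluster_scale()
  # interval membership straight from the tabulated bounds
  expect_identical(assign_cluster(c(0, 3, 5, 12), sc), c(1L, 2L, 3L, 4L))
  expect_identical(assign_cluster(c(2.265458, 2.267602), sc), c(1L, 2L))
  expect_identical(assign_cluster(c(7.001413, 7.002388), sc), c(3L, 4L))
  # gap values cut at the midpoint; the first gap midpoint is
  # (2.265458 + 2.267602)/2 = 2.26653, and 2.2665 lies below it
  expect_identical(assign_cluster(2.2665, sc), 1L)
  expect_identical(assign_cluster(sc$gap_thresholds, sc), c(2L, 3L, 4L))
  expect_error(assign_cluster(NaN, sc), "NA")
  expect_warning(out <- assign_cluster(12.5, sc), "clamped")
  expect_identical(out, 4L)
})

test_that("cluster assignment is total, idempotent, and monotone on [0, 12]", {
  sc <- cluster_scale()
  vals <- seq(0, 12, length.out = 4001)
  ks <- assign_cluster(vals, sc)
  expect_true(all(ks %in% 1:4))
  expect_true(all(diff(ks) >= 0))
  # idempotence: re-assigning a representative of the cluster's interval
  # returns the same cluster
  reps <- (sc$bounds[, 1] + sc$bounds[, 2]) / 2
  expect_identical(assign_cluster(reps, sc), 1:4)
  # each value gets exactly one cluster: assignment is a function (single
  # deterministic output), checked by re-evaluation
  expect_identical(ks, assign_cluster(vals, sc))
})

test_that("patterns derive from trajectories through the condition map", {
  g <- make_grid(2, 15)
  st <- seeded_state(g, seed = 1)
  traj <- simulate_pde(get_model(1), st, bc_spec("dirichlet"),
                       integrator_config(t_end = 4))
  p <- cluster_pattern(traj, gene_label = "demo")
  expect_s3_class(p, "rd_pattern")
  expect_identical(names(p$clusters), c("NT", "LE1h", "LE2h", "LE4h"))
  expect_true(all(p$clusters %in% 1:4))
  # the normalized series spans [0, 12], so both extreme clusters appear
  normed <- normalize_series(traj$abundance_m)
  expect_identical(unname(p$clusters),
                   assign_cluster(normed[match(c(0, 1, 2, 4), traj$times)]))
  # missing mapped time
  expect_error(cluster_pattern(traj, condition_map = c(NT = 0, LE1h = 1,
                                                       LE2h = 2, LE4h = 3.5)),
               "snapshot times")
  # monotone normalized series gives non-decreasing clusters
  fake <- traj
  fake$abundance_m <- c(0.1, 1, 2, 3, 4)
  expect_true(all(diff(cluster_pattern(fake)$clusters) >= 0))
})

test_that("pattern records validate their invariants", {
  p <- pattern_record(c(4, 2, 2, 2), gene_label = "SMEK1")
  expect_identical(unname(p$clusters), c(4L, 2L, 2L, 2L))
  expect_error(pattern_record(c(1, 2, 3)), "4 conditions|per condition")
  expect_error(pattern_record(c(0, 1, 2, 3)), "1..4")
  expect_error(pattern_record(c(1, 2, 3, 5)), "1..4")
})

test_that("matching minimises L1 distance with lowest-id tie-breaking", {
  lib <- list(`1` = pattern_record(c(1, 1, 1, 1)),
              `2` = pattern_record(c(1, 2, 1, 1)),
              `3` = pattern_record(c(4, 4, 4, 4)),
              `4` = pattern_record(c(1, 1, 1, 1)))
  # self-consistency: a library pattern matches itself completely
  hit <- match_models(pattern_record(c(4, 4, 4, 4)), lib)
  expect_identical(hit$model_id, 3L)
  expect_identical(hit$fit_kind, "complete")
  expect_identical(hit$distance, 0L)
  # tie at distance 0 resolves to the lowest id, other id listed
  tie <- match_models(pattern_record(c(1, 1, 1, 1)), lib)
  expect_identical(tie$model_id, 1L)
  expect_true(4L %in% tie$runner_ups)
  # plain L1 distance
  d <- match_models(pattern_record(c(1, 1, 1, 1)), lib["2"])
  expect_identical(d$distance, 1L)
  expect_identical(d$fit_kind, "best")
  expect_error(match_models(pattern_record(c(1, 1, 1, 1)), list()), "empty")
  expect_error(
    match_models(pattern_record(c(1, 1, 1, 1)),
                 list(`1` = pattern_record(c(1, 1, 1, 1),
                                           conditions = c("a", "b", "c", "d")))),
    "conditions")
})

test_that("the L1 pattern distance is a metric on random patterns", {
  set.seed(99)
  dist_of <- function(a, b) {
    match_models(a, list(`1` = b))$distance
  }
  for (rep in 1:25) {
    a <- pattern_record(sample(1:4, 4, replace = TRUE))
    b <- pattern_record(sample(1:4, 4, replace = TRUE))
    c3 <- pattern_record(sample(1:4, 4, replace = TRUE))
    expect_identical(dist_of(a, a), 0L)
    expect_identical(dist_of(a, b), dist_of(b, a))
    expect_lte(dist_of(a, c3), dist_of(a, b) + dist_of(b, c3))
  }
})

test_that("pattern tables round-trip and drive batch matching", {
  df <- data.frame(gene_label = c("g1", "g2"),
                   NT = c(1L, 4L), LE1h = c(2L, 4L),
                   LE2h = c(2L, 4L), LE4h = c(2L, 4L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_table(df, p)
  back <- read_pattern_table(p)
  expect_identical(back$NT, df$NT)
  lib <- list(`1` = pattern_record(c(1, 2, 2, 2)),
              `2` = pattern_record(c(4, 4, 4, 4)))
  rep <- match_pattern_table(back, lib)
  expect_identical(rep$model_id, c(1L, 2L))
  expect_identical(rep$fit_kind, c("complete", "complete"))
  jp <- withr::local_tempfile(fileext = ".json")
  write_match_report(rep, jp)
  expect_identical(jsonlite::read_json(jp, simplifyVector = TRUE)$model_id,
                   c(1L, 2L))
  bad <- df
  bad$NT[1] <- 9L
  pb <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_table(bad, pb)
  expect_error(read_pattern_table(pb), "1..4")
})
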