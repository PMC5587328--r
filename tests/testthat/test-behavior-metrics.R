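test_that("movement entropy matches hand-computed occupancies and its bounds", {
  expect_equal(movement_entropy(rep(1, 50), rep(0.2, 50)), 0)

  # two equally occupied (v, h) pairs -> 1 bit
  v <- rep(c(0, 1), 20)
  h <- rep(c(0, 0.5), 20)
  expect_equal(movement_entropy(v, h), 1)

  # occupancy (1/2, 1/4, 1/4) -> 1.5 bits
  v3 <- c(0, 0, 1, 2)
  h3 <- rep(0, 4)
  expect_equal(movement_entropy(v3, h3), 1.5)

  # bound: 0 <= H <= 2 log2(n_bins)
  set.seed(3)
  for (i in 1:10) {
    H <- movement_entropy(stats::runif(200), stats::runif(200), n_bins = 8)
    expect_gte(H, 0)
    expect_lte(H, 2 * log2(8))
  }
  expect_error(movement_entropy(numeric(0), numeric(0)), "non-empty")
  expect_error(movement_entropy(1:3, 1:2), "equal length")
})

test_that("box-counting dimension calibrates on lines and filled rasters", {
  a <- arena(20, 20)
  line <- cbind(seq(0.5, 19.5, length.out = 4000),
                seq(0.5, 19.5, length.out = 4000))
  fd_line <- fractal_dimension(line, a, resolution = 1024)
  expect_lt(abs(fd_line$dimension - 1), 0.05)

  g <- as.matrix(expand.grid(x = seq(0.1, 19.9, length.out = 300),
                             y = seq(0.1, 19.9, length.out = 300)))
  fd_fill <- fractal_dimension(g, a, resolution = 256)
  expect_lt(abs(fd_fill$dimension - 2), 0.05)

  same <- matrix(c(5, 5, 5, 5), 2, 2)
  fd0 <- fractal_dimension(same, a)
  expect_true(fd0$degenerate)
  expect_equal(fd0$dimension, 0)

  expect_error(fractal_dimension(line, a, resolution = 1000), "power of 2")
})

test_that("box counts agree with an independent grid-scanning oracle", {
  a <- arena(20, 20)
  set.seed(31)
  # reflected random walk
  n <- 2e4
  steps <- matrix(stats::rnorm(2 * n, sd = 0.3), n, 2)
  xy <- apply(steps, 2, cumsum)
  xy <- abs(xy + 10)
  xy <- 20 - abs(20 - (xy %% 40))
  res <- 256L
  cells <- embodiedGH:::rasterize_trajectory(as.data.frame(xy), a, res)
  for (s in c(128L, 64L, 32L, 16L, 8L, 4L)) {
    expect_equal(embodiedGH:::box_count(cells, res, s),
                 oracle_box_count(cells, res, s))
  }
  fd <- fractal_dimension(xy, a, resolution = res)
  expect_gt(fd$dimension, 1)
  expect_lt(fd$dimension, 2)
})

test_that("fractal dimension never decreases when points are added", {
  a <- arena(20, 20)
  set.seed(17)
  base <- cbind(stats::runif(200, 1, 19), stats::runif(200, 1, 19))
  more <- rbind(base, cbind(stats::runif(400, 1, 19),
                            stats::runif(400, 1, 19)))
  f1 <- fractal_dimension(base, a, resolution = 256)
  f2 <- fractal_dimension(more, a, resolution = 256)
  # occupied boxes can only grow at every scale
  expect_true(all(f2$log2_counts >= f1$log2_counts))
})

test_that("wall distances are the minimum over the four bounds", {
  a <- arena(20, 20)
  expect_equal(wall_distance_series(cbind(10, 10), a), 10)
  expect_equal(wall_distance_series(cbind(1, 10), a), 1)
  expect_equal(wall_distance_series(cbind(0.5, 0.3), a), 0.3)
  expect_equal(wall_distance_series(rbind(c(10, 10), c(19, 4)), a), c(10, 1))
  expect_error(wall_distance_series(cbind(21, 5), a), "outside")
})

test_that("coupling correlations recover perfect and degenerate relations", {
  con <- test_connectome()
  run <- run_simulation(con, config = model_config(epochs = 300, seed = 6,
                                                   variant = "local"))
  cc <- coupling_correlations(run)
  expect_true(all(abs(c(cc$r_wall_activity, cc$r_wall_threshold,
                        cc$r_threshold_activity)) <= 1))

  # degenerate: static variant has constant thresholds
  run2 <- run_simulation(con, config = model_config(epochs = 50, seed = 6,
                                                    variant = "static"))
  cc2 <- coupling_correlations(run2)
  expect_equal(cc2$r_wall_threshold, 0)
  expect_true(cc2$degenerate[["wall_threshold"]])

  # hand-computed 5-point Pearson correlation
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  expect_equal(embodiedGH:::safe_cor(x, y)$r, r_hand)
})

test_that("pooled t-test matches hand computation, df rule, and antisymmetry", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  ab <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  # pooled s2 = 1, se = sqrt(2/3), t = -3/se
  expect_equal(ab$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(ab$t_statistic, -3.674, tolerance = 1e-3)
  expect_equal(ab$degrees_of_freedom, 4)

  ba <- compare_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ba$t_statistic, -ab$t_statistic)

  big <- compare_groups(stats::rnorm(30), stats::rnorm(30))
  expect_equal(big$degrees_of_freedom, 58)

  dg <- compare_groups(c(1, 1), c(2, 2))
  expect_true(dg$degenerate)
  expect_identical(dg$t_statistic, -Inf)

  expect_error(compare_groups(1, c(1, 2)), ">= 2")
})

test_that("per-run correlation test uses Fisher z with df = n - 1", {
  z0 <- one_sample_correlation_test(c(0, 0, 0, 0))
  expect_equal(z0$t_statistic, 0)

  n27 <- one_sample_correlation_test(seq(-0.4, 0.4, length.out = 27))
  expect_equal(n27$degrees_of_freedom, 26)

  const <- one_sample_correlation_test(rep(0.5, 4))
  expect_true(const$degenerate)

  expect_error(one_sample_correlation_test(c(0.2, 1, 0.3)), "overflow")
  expect_error(one_sample_correlation_test(c(0.1, 0.2)), ">= 3")
})

test_that("run metrics assemble the full per-run summary row", {
  con <- test_connectome()
  run <- run_simulation(con, config = model_config(epochs = 400, seed = 2,
                                                   variant = "combined"))
  m <- run_metrics(run, resolution = 256)
  expect_equal(nrow(m), 1)
  expect_true(all(c("mean_activity", "activity_node_sd", "movement_entropy",
                    "fractal_dimension", "r_wall_activity", "threshold_sd",
                    "threshold_cv") %in% names(m)))
  expect_gte(m$movement_entropy, 0)
  expect_gte(m$fractal_dimension, 0)
  expect_lte(m$fractal_dimension, 2)
})
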