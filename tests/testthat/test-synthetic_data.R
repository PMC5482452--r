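test_that("covariate fields are standardized, seeded and smooth", {
  g <- build_grid(c(0, 0, 40, 40), 4) # 10x10
  f <- simulate_covariate_field(g, 3, seed = 1)
  expect_lt(abs(mean(f)), 1e-9)
  expect_lt(abs(sd(f) - 1), 1e-9)
  expect_identical(f, simulate_covariate_field(g, 3, seed = 1))
  expect_false(identical(f, simulate_covariate_field(g, 3, seed = 2)))
  expect_error(simulate_covariate_field(g, 0, seed = 1), "smoothness")
  # generator must not disturb the caller's RNG stream
  set.seed(42); a <- rnorm(1)
  set.seed(42); invisible(simulate_covariate_field(g, 3, seed = 9)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("smoothness -> 0 limit gives an uncorrelated field", {
  g5 <- build_grid(c(0, 0, 20, 20), 4)
  ac <- vapply(1:200, function(s) {
    v <- simulate_covariate_field(g5, 1e-6, seed = s)
    m <- matrix(v, 5, 5, byrow = TRUE)
    cor(as.numeric(m[, -5]), as.numeric(m[, -1]))
  }, 0)
  expect_lt(abs(mean(ac)), 3 * sd(ac) / sqrt(200) + 0.02)
})

test_that("smoothed fields show significant positive Moran's I", {
  g <- build_grid(c(0, 0, 40, 40), 4)
  mi <- vapply(1:100, function(s) moran_i(simulate_covariate_field(g, 3, s), g), 0)
  base <- simulate_covariate_field(g, 3, seed = 1)
  null <- with_seed_local(99, vapply(1:999, function(i) {
    moran_i(sample(base), g)
  }, 0))
  expect_gt(mean(mi), quantile(null, 0.975))
})

test_that("iCAR draws honour the sum-to-zero constraint and variance scaling", {
  g <- build_grid(c(0, 0, 40, 40), 4)
  r <- simulate_icar_field(g, 1e-12, seed = 3)
  expect_lt(max(abs(r)), 1e-4) # degenerate variance

  g2 <- grid_2cell()
  r2 <- simulate_icar_field(g2, 4, seed = 7)
  expect_equal(r2[1], -r2[2], tolerance = 1e-12)

  r1 <- simulate_icar_field(g, 2, seed = 5)
  expect_lt(abs(sum(r1)), 1e-9)
  expect_identical(r1, simulate_icar_field(g, 2, seed = 5))
  expect_error(simulate_icar_field(g, -1, seed = 1), "V_rho")
})

test_that("iCAR sample covariance matches the pseudo-inverse precision oracle", {
  g <- build_grid(c(0, 0, 16, 16), 4) # 4x4
  C <- 2 * pinv_sym(occuCAR:::icar_precision(g))
  draws <- vapply(1:5000, function(s) simulate_icar_field(g, 2, seed = s),
                  numeric(16))
  S <- cov(t(draws))
  mc_se <- sqrt((outer(diag(C), diag(C)) + C^2) / 5000)
  expect_lt(max(abs(S - C) / mc_se), 5)
})

test_that("occupancy datasets obey the hierarchical structure", {
  g <- build_grid(c(0, 0, 40, 40), 4)
  # perfect detection: any-detection indicator equals latent z exactly
  simp <- simulate_occupancy_dataset(g, beta = c(0, 1), gamma = c(20),
                                     V_rho = 1, visits_per_cell = 2, seed = 2)
  expect_identical(as.integer(any_detection(simp$data)),
                   as.integer(simp$truth$z))

  # structural zeros: no detection where z = 0, across seeds
  for (s in 1:5) {
    sim <- simulate_occupancy_dataset(g, beta = c(0, 1), gamma = c(0, 0.5, -0.4),
                                      V_rho = 1, seed = s)
    expect_true(all(sim$data$y[sim$truth$z[sim$data$visit_cell] == 0] == 0))
    expect_true(all(sim$truth$pi > 0 & sim$truth$pi < 1))
    expect_true(all(sim$truth$delta > 0 & sim$truth$delta < 1))
    expect_true(all(sim$truth$z %in% 0:1))
    expect_lt(abs(sum(sim$truth$rho)), 1e-9)
    expect_equal(length(sim$truth$rho), g$n_cells)
  }

  # determinism
  s1 <- simulate_occupancy_dataset(g, beta = c(-1, 1), gamma = c(0, 0.3), seed = 11)
  s2 <- simulate_occupancy_dataset(g, beta = c(-1, 1), gamma = c(0, 0.3), seed = 11)
  expect_identical(s1$data$y, s2$data$y)
  expect_identical(s1$truth$rho, s2$truth$rho)
})

test_that("marginal occupancy rate matches the binomial sampling oracle", {
  g <- build_grid(c(0, 0, 200, 160), 4) # 50x40 = 2000 cells
  sim <- simulate_occupancy_dataset(g, beta = c(qlogis(0.3), 0),
                                    gamma = c(0), V_rho = 0,
                                    visits_per_cell = 1, seed = 13)
  expect_lt(abs(mean(sim$truth$z) - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("traffic generator matches its null and sign oracles", {
  g <- build_grid(c(0, 0, 80, 80), 4) # 400 cells
  tr0 <- simulate_traffic_dataset(g, beta = c(0, 0), V_rho = 0, seed = 21)
  expect_lt(abs(mean(tr0$data$presence) - 0.5), 3 * sqrt(0.25 / g$n_cells))

  g5 <- build_grid(c(0, 0, 100, 80), 4) # 25x20 = 500 cells
  signs <- vapply(1:100, function(s) {
    tr <- simulate_traffic_dataset(g5, beta = c(0, 1), V_rho = 0.2, seed = s)
    cor(tr$X[, "dist_coast"], tr$data$presence) > 0
  }, TRUE)
  expect_gte(sum(signs), 95)

  t1 <- simulate_traffic_dataset(g, beta = c(0, 0.67), V_rho = 0.5, seed = 3)
  t2 <- simulate_traffic_dataset(g, beta = c(0, 0.67), V_rho = 0.5, seed = 3)
  expect_identical(t1$data, t2$data)
  expect_error(simulate_traffic_dataset(g, beta = c(0), seed = 1), "dist_coast")
})

test_that("datasets round-trip through the CSV dialect", {
  g <- build_grid(c(0, 0, 20, 20), 4)
  sim <- simulate_occupancy_dataset(g, beta = c(-0.5, 1), gamma = c(0, 0.4, -0.3),
                                    seed = 4)
  dir <- withr_local_tempdir()
  files <- write_dataset(sim, dir, seed = 4)
  expect_true(all(file.exists(files)))
  sites <- read.csv(files[1]); visits <- read.csv(files[2])
  expect_equal(names(sites)[1:3], c("cell_id", "x", "y"))
  expect_equal(names(visits)[1:2], c("cell_id", "visit_index"))
  expect_equal(nrow(sites), g$n_cells)
  expect_equal(nrow(visits), sum(sim$data$visits))
  expect_equal(visits$detected, sim$data$y)
  truth <- jsonlite::read_json(files[3], simplifyVector = TRUE)
  expect_equal(truth$beta, c(-0.5, 1))
})
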