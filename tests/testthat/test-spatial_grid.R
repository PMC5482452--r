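test_that("build_grid tiles bounding boxes with ceiling arithmetic", {
  g <- build_grid(c(0, 0, 16, 16), 4)
  expect_equal(g$n_cells, 16L)
  expect_equal(c(g$n_rows, g$n_cols), c(4L, 4L))

  g2 <- build_grid(c(0, 0, 10, 10), 4)
  expect_equal(g2$n_cells, 9L) # 3x3 with partial edge cells

  # study-area scale: ~5,500 km^2 at 4 km -> ceil per axis
  g3 <- build_grid(c(0, 0, 100, 55), 4)
  expect_equal(g3$n_cells, ceiling(100 / 4) * ceiling(55 / 4))
  expect_lt(abs(g3$n_cells - 5500 / 16) / (5500 / 16), 0.05)

  expect_error(build_grid(c(0, 0, 0, 10), 4), "extent")
  expect_error(build_grid(c(0, 0, 10, 10), -1), "cell_size")
})

test_that("adjacency matches lattice combinatorics for queen and rook", {
  g1 <- build_grid(c(0, 0, 4, 4), 4)
  expect_equal(nrow(g1$edges), 0L)

  g3q <- build_grid(c(0, 0, 12, 12), 4, scheme = "queen")
  deg <- tabulate(c(g3q$edges), nbins = 9)
  expect_equal(deg[5], 8L) # center
  expect_equal(deg[1], 3L) # corner
  expect_true(all(g3q$edges[, 1] < g3q$edges[, 2])) # no self loops, canonical

  g3r <- build_grid(c(0, 0, 12, 12), 4, scheme = "rook")
  degr <- tabulate(c(g3r$edges), nbins = 9)
  expect_equal(degr[5], 4L)
  expect_equal(nrow(g3r$edges), 12L) # exhaustive enumeration: 2*3*2 per axis
})

test_that("adjacency is invariant under cell relabeling (graph isomorphism)", {
  g <- build_grid(c(0, 0, 12, 8), 4)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  e1 <- g$edges
  e2 <- cbind(perm[e1[, 1]], perm[e1[, 2]])
  e2 <- cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
  # same edge count, same degree sequence, same sorted neighbour-degree lists
  expect_equal(nrow(e2), nrow(e1))
  d1 <- tabulate(c(e1), g$n_cells); d2 <- tabulate(c(e2), g$n_cells)
  expect_equal(sort(d1), sort(d2))
})

test_that("points map to cells by the half-open convention", {
  g <- build_grid(c(0, 0, 12, 12), 4)
  # interior boundary point goes to the higher-index cell
  expect_equal(assign_points_to_cells(4, 2, g), 2L)
  expect_equal(assign_points_to_cells(2, 4, g), 4L)
  # bbox max corner is outside the half-open extent
  expect_warning(res <- assign_points_to_cells(12, 12, g), "outside")
  expect_true(is.na(res))
  # conservation: every record assigned or flagged
  suppressWarnings(ids <- assign_points_to_cells(c(1, 5, 13), c(1, 5, 1), g))
  expect_equal(sum(!is.na(ids)) + sum(is.na(ids)), 3L)
})

test_that("uniform points land uniformly across cells", {
  g <- build_grid(c(0, 0, 20, 20), 4)
  pts <- with(list(), {
    set.seed(31); cbind(runif(1000, 0, 20), runif(1000, 0, 20))
  })
  ids <- assign_points_to_cells(pts[, 1], pts[, 2], g)
  counts <- tabulate(ids, nbins = 25)
  p <- stats::chisq.test(counts, p = rep(1 / 25, 25))$p.value
  expect_gt(p, 0.001)
})

test_that("effort counts visits per cell and round-trips the simulator", {
  g <- build_grid(c(0, 0, 12, 12), 4)
  expect_equal(compute_effort(integer(0), g), rep(0L, 9))
  expect_equal(compute_effort(c(1L, 1L, 2L), g)[1:2], c(2L, 1L))
  expect_error(compute_effort(c(1L, 99L), g), "unknown cell")

  sim <- simulate_occupancy_dataset(g, beta = c(0, 0.5), gamma = c(0, 0.3),
                                    seed = 5)
  expect_identical(compute_effort(sim$data$visit_cell, g),
                   as.integer(sim$data$visits))
  expect_equal(sum(compute_effort(sim$data$visit_cell, g)),
               length(sim$data$visit_cell))
})

test_that("weighted_cell_average computes sum(wv)/sum(w) per cell", {
  g <- build_grid(c(0, 0, 8, 4), 4)
  expect_equal(weighted_cell_average(7, 2, 1L, g), c(7, NA))
  expect_equal(weighted_cell_average(c(2, 4), c(1, 1), c(1L, 1L), g)[1], 3)
  expect_equal(weighted_cell_average(c(1, 3), c(3, 1), c(2L, 2L), g)[2], 1.5)
  expect_error(weighted_cell_average(1, 0, 1L, g), "positive")
})

test_that("prepare_covariates standardizes exactly and screens correlation", {
  set.seed(8)
  raw <- data.frame(a = rnorm(50, 10, 3), b = rnorm(50))
  pc <- prepare_covariates(raw)
  expect_true(all(abs(colMeans(pc$X)) < 1e-9))
  expect_true(all(abs(apply(pc$X, 2, sd) - 1) < 1e-9))
  # idempotence: standardizing a standardized column leaves it unchanged
  pc2 <- prepare_covariates(pc$X)
  expect_equal(unclass(pc2$X)[, ], unclass(pc$X)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # round trip
  expect_equal(destandardize(pc$X), as.matrix(raw), tolerance = 1e-12,
               ignore_attr = TRUE)
  # duplicated covariate flagged at r = 1
  dup <- prepare_covariates(data.frame(a = raw$a, b = raw$a + 0))
  expect_equal(dup$screening$r, 1)
  expect_true(dup$screening$flagged)
  expect_error(prepare_covariates(data.frame(a = raw$a, cst = rep(1, 50))),
               "cst")
})

test_that("independent smooth fields are almost never flagged", {
  g <- build_grid(c(0, 0, 80, 80), 4) # 400 cells
  flags <- vapply(1:100, function(s) {
    f1 <- simulate_covariate_field(g, 2, seed = s)
    f2 <- simulate_covariate_field(g, 2, seed = 10000 + s)
    any(prepare_covariates(cbind(a = f1, b = f2))$screening$flagged)
  }, TRUE)
  expect_gte(sum(!flags), 95)
})
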