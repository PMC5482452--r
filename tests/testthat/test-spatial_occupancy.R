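test_that("chains are deterministic and respect structural constraints", {
  g <- build_grid(c(0, 0, 40, 40), 4)
  sim <- simulate_occupancy_dataset(g, beta = c(-0.5, 1), gamma = c(0.5, 0, -0.3),
                                    V_rho = 1, visits_per_cell = 3, seed = 17)
  spec <- model_spec(ecological = "x1", detection = "sea_state")
  f1 <- fit_site_occupancy_icar(sim$data, spec, quick_mcmc(seed = 3))
  f2 <- fit_site_occupancy_icar(sim$data, spec, quick_mcmc(seed = 3))
  expect_identical(f1$beta_draws, f2$beta_draws)
  expect_identical(f1$rho_draws, f2$rho_draws)

  # z fixed at 1 wherever a detection occurred, in every retained draw
  det <- which(any_detection(sim$data))
  expect_true(all(f1$z_draws[, det] == 1L))
  expect_true(all(f1$z_draws %in% 0:1))
  # every rho draw sums to zero (single component grid)
  expect_lt(max(abs(rowSums(f1$rho_draws))), 1e-6)
  # V_rho stays inside its uniform prior bounds
  expect_true(all(f1$Vrho_draws > 0 & f1$Vrho_draws < 10))
  # acceptance rates are reported and sane after adaptation
  expect_true(all(f1$acceptance_rates$beta > 0.1 & f1$acceptance_rates$beta < 0.9))
})

test_that("descriptive errors on degenerate inputs", {
  g <- build_grid(c(0, 0, 12, 12), 4)
  sim <- simulate_occupancy_dataset(g, beta = c(5), gamma = c(20),
                                    visits_per_cell = 2, seed = 1)
  expect_error(
    fit_site_occupancy_icar(sim$data, model_spec(), quick_mcmc()),
    "every cell has a detection")
  sim2 <- simulate_occupancy_dataset(g, beta = c(-1, 1), gamma = c(0, 0.2),
                                     seed = 2)
  expect_error(
    fit_site_occupancy_icar(sim2$data, model_spec(ecological = "bogus"),
                            quick_mcmc()),
    "bogus")
  expect_error(
    fit_site_occupancy_icar(sim2$data,
                            model_spec(detection = "nothere"), quick_mcmc()),
    "nothere")
  expect_error(fit_binomial_icar(matrix(rnorm(9)), trials = rep(1L, 9),
                                 successes = rep(2L, 9), g, model_spec()),
               "successes > trials")
})

test_that("binomial fit reduces to the Bernoulli GLM without spatial effect", {
  g <- build_grid(c(0, 0, 80, 80), 4) # 400 cells
  tr <- simulate_traffic_dataset(g, beta = c(-0.2, 0.8), V_rho = 0, seed = 23)
  spec <- model_spec(ecological = "dist_coast", spatial = FALSE)
  fit <- fit_binomial_icar(tr$X[, -1, drop = FALSE], tr$data$trials,
                           tr$data$presence, g, spec,
                           quick_mcmc(seed = 6, n_iter = 4000, burnin = 2000))
  mle <- stats::glm(tr$data$presence ~ tr$X[, "dist_coast"], family = "binomial")
  pm <- colMeans(fit$beta_draws)
  ps <- apply(fit$beta_draws, 2, sd)
  expect_true(all(abs(pm - coef(mle)) < 2 * ps))
})

test_that("all-successes data push posterior presence medians above 1/2", {
  g <- build_grid(c(0, 0, 16, 16), 4)
  X <- matrix(with_seed_local(4, rnorm(16)), dimnames = list(NULL, "x1"))
  fit <- fit_binomial_icar(X, trials = rep(2L, 16), successes = rep(2L, 16),
                           g, model_spec(ecological = "x1"), quick_mcmc(seed = 2))
  surf <- predict_surface(fit)
  expect_true(all(surf$prob_median >= 0.5))
})

test_that("predict_surface summarizes draws correctly", {
  g <- build_grid(c(0, 0, 12, 12), 4)
  sim <- simulate_occupancy_dataset(g, beta = c(0, 1), gamma = c(0.5),
                                    visits_per_cell = 2, seed = 5)
  spec <- model_spec(ecological = "x1", detection = character(0))
  fit <- fit_site_occupancy_icar(sim$data, spec, quick_mcmc(seed = 9))

  # beta draws all zero, rho zero -> median 0.5 everywhere
  f0 <- fit
  f0$beta_draws[] <- 0
  f0$rho_draws[] <- 0
  expect_equal(predict_surface(f0)$prob_median, rep(0.5, g$n_cells))

  # a single draw is its own median
  f1 <- fit
  f1$beta_draws <- fit$beta_draws[1, , drop = FALSE]
  f1$rho_draws <- fit$rho_draws[1, , drop = FALSE]
  pi1 <- plogis(drop(fit$X_design %*% fit$beta_draws[1, ]) + fit$rho_draws[1, ])
  expect_equal(predict_surface(f1)$prob_median, pi1)

  # monotonicity under an (effectively) all-positive coefficient
  f2 <- fit
  f2$beta_draws[, "x1"] <- abs(f2$beta_draws[, "x1"]) + 0.1
  Xup <- fit$X_design; Xup[, "x1"] <- Xup[, "x1"] + 1
  expect_true(all(predict_surface(f2, Xup, use_rho = TRUE)$prob_median >=
                    predict_surface(f2, use_rho = TRUE)$prob_median))

  # column mismatch errors; new cells fall back to rho = 0 with flag
  expect_error(predict_surface(fit, matrix(1, 9, 1, dimnames = list(NULL, "zz"))),
               "lacks column")
  half <- predict_surface(fit, fit$X_design[1:4, ])
  expect_false(attr(half, "rho_used"))
  expect_true(all(half$prob_median >= 0 & half$prob_median <= 1))
})

test_that("DIC limits behave: zero-complexity and perfect fit", {
  g <- build_grid(c(0, 0, 12, 12), 4)
  sim <- simulate_occupancy_dataset(g, beta = c(0, 1), gamma = c(0.5),
                                    visits_per_cell = 2, seed = 5)
  spec <- model_spec(ecological = "x1", detection = character(0))
  fit <- fit_site_occupancy_icar(sim$data, spec, quick_mcmc(seed = 9))

  # degenerate posterior: all draws identical -> pD = 0, DIC = that deviance
  fd <- fit
  nd <- nrow(fd$beta_draws)
  fd$beta_draws <- fd$beta_draws[rep(1, nd), , drop = FALSE]
  fd$gamma_draws <- fd$gamma_draws[rep(1, nd), , drop = FALSE]
  fd$rho_draws <- fd$rho_draws[rep(1, nd), , drop = FALSE]
  d <- compute_dic(fd)
  expect_equal(d$pD, 0, tolerance = 1e-8)
  expect_equal(d$DIC, d$Dbar, tolerance = 1e-8)

  # saturated perfect-fit toy: cells 1-2 detected on every visit, 3-4 never;
  # pi -> 1 where detected, -> 0 elsewhere, delta -> 1 gives likelihood 1
  fs <- list(
    model = "siteocc",
    beta_draws = matrix(0, 2, 1, dimnames = list(NULL, "(Intercept)")),
    gamma_draws = matrix(40, 2, 1, dimnames = list(NULL, "(Intercept)")),
    rho_draws = matrix(rep(c(40, 40, -40, -40), each = 2), 2),
    X_design = matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)")),
    W_design = matrix(1, 8, 1, dimnames = list(NULL, "(Intercept)")),
    data = list(y = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
                visit_cell = rep(1:4, each = 2))
  )
  class(fs) <- "posterior_samples"
  d2 <- compute_dic(fs)
  expect_lt(d2$Dbar, 1e-6)
})

test_that("posterior summaries are label-equivariant for deterministic stages", {
  g <- build_grid(c(0, 0, 16, 12), 4)
  sim <- simulate_occupancy_dataset(g, beta = c(0, 1), gamma = c(0.5),
                                    visits_per_cell = 2, seed = 8)
  spec <- model_spec(ecological = "x1", detection = character(0))
  fit <- fit_site_occupancy_icar(sim$data, spec, quick_mcmc(seed = 10))
  perm <- rev(seq_len(g$n_cells))
  # permuting prediction inputs permutes the surface identically
  s_full <- predict_surface(fit, use_rho = FALSE)
  s_perm <- predict_surface(fit, fit$X_design[perm, ], use_rho = FALSE)
  expect_equal(s_perm$prob_median, s_full$prob_median[perm])
})
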