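#' Spatially smooth standardized covariate field
#'
#' Generates a stand-in for gridded environmental covariates (SST, NPP,
#' depth, ...) by kernel-smoothing lattice white noise with a separable
#' Gaussian kernel of bandwidth `smoothness` cells, then z-scoring. As
#' `smoothness -> 0` the field approaches i.i.d. standard normal noise.
#'
#' @param grid a `lattice_grid`.
#' @param smoothness positive kernel bandwidth in cell units.
#' @param seed integer seed; the function is a pure function of
#'   (grid, smoothness, seed).
#' @return numeric vector of length `n_cells`, exact mean 0 and sd 1.
#' @export
simulate_covariate_field <- function(grid, smoothness, seed) {
  stopifnot_scalar_pos(smoothness, "smoothness")
  z <- with_seed(seed, matrix(rnorm(grid$n_cells), grid$n_rows, grid$n_cols))
  half <- max(1L, ceiling(3 * smoothness))
  k <- exp(-0.5 * ((-half):half / smoothness)^2)
  k <- k / sum(k)
  sm <- t(smooth_rows(t(smooth_rows(z, k)), k)) # rows then columns
  v <- as.numeric(t(sm)) # row-major flatten matches cell-id order
  (v - mean(v)) / stats::sd(v)
}

# 1-D convolution of each matrix row with kernel k, truncated and
# renormalized at the edges (no wrap-around).
smooth_rows <- function(m, k) {
  half <- (length(k) - 1L) / 2L
  nc <- ncol(m)
  out <- matrix(0, nrow(m), nc)
  for (j in seq_len(nc)) {
    lo <- max(1L, j - half); hi <- min(nc, j + half)
    kk <- k[(lo - j + half + 1L):(hi - j + half + 1L)]
    kk <- kk / sqrt(sum(kk^2)) # preserve unit variance under truncation
    out[, j] <- m[, lo:hi, drop = FALSE] %*% kk
  }
  out
}

#' Draw an intrinsic CAR (iCAR) spatial field
#'
#' Exact draw from the intrinsic conditional autoregressive distribution on
#' the grid's adjacency graph: eigendecompose the graph Laplacian `Q`,
#' sample independent normals with variance `V_rho / lambda_k` in the
#' non-null eigenspace, and map back. The null space (per-component constant
#' vectors) carries no mass, so each connected component sums to zero
#' exactly — the standard identifiability constraint. Cost is O(n^3), fine
#' at desk scale (n up to ~2,500 cells).
#'
#' @param grid a `lattice_grid`.
#' @param V_rho positive spatial-effect variance (logit-scale units^2).
#' @param seed integer seed.
#' @return numeric vector `rho` of length `n_cells`; `sum(rho) == 0` per
#'   connected component to machine precision.
#' @export
simulate_icar_field <- function(grid, V_rho, seed) {
  stopifnot_scalar_pos(V_rho, "V_rho")
  n <- grid$n_cells
  Q <- icar_precision(grid)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values
  pos <- lam > max(lam) * 1e-10
  z <- with_seed(seed, rnorm(sum(pos)))
  coefs <- sqrt(V_rho / lam[pos]) * z
  as.numeric(eg$vectors[, pos, drop = FALSE] %*% coefs)
}

# dense graph Laplacian D - A of the grid adjacency
icar_precision <- function(grid) {
  n <- grid$n_cells
  Q <- matrix(0, n, n)
  if (nrow(grid$edges)) {
    for (r in seq_len(nrow(grid$edges))) {
      i <- grid$edges[r, 1]; j <- grid$edges[r, 2]
      Q[i, j] <- Q[i, j] - 1
      Q[j, i] <- Q[j, i] - 1
      Q[i, i] <- Q[i, i] + 1
      Q[j, j] <- Q[j, j] + 1
    }
  }
  Q
}

#' Simulate a lattice site-occupancy survey
#'
#' Generates one full synthetic dataset with the statistical structure the
#' occupancy model assumes: standardized smooth ecological covariates `X`
#' (plus intercept), an iCAR spatial effect `rho`, latent occupancy
#' `z_i ~ Bernoulli(pi_i)` with `logit(pi) = X beta + rho`, a visit plan,
#' per-visit detection covariates `W` (intercept, effort, sea state, wind)
#' and detections `y_it ~ Bernoulli(z_i * delta_it)` with
#' `logit(delta) = W gamma`.
#'
#' Effort enters `W` as the cell's total visit count (the survey quantified
#' effort as the number of times a cell was visited); sea state and wind are
#' correlated ordinal covariates on 0–4 (calm conditions dominate, matching
#' a summer survey run only in workable weather). Detection covariates are
#' z-scored before applying `gamma`, so `gamma` is on the standardized
#' scale just like `beta`.
#'
#' @param grid a `lattice_grid`.
#' @param beta ecological coefficients incl. intercept (length p). The p - 1
#'   non-intercept terms get independent smooth covariate fields.
#' @param gamma detection coefficients incl. intercept, then effort, sea
#'   state, wind (length 4; trailing terms may be dropped, minimum 1).
#' @param V_rho spatial-effect variance; `0` disables the spatial effect.
#' @param visits_per_cell integer scalar (same number of visits everywhere),
#'   integer vector per cell, or `NULL` for the default right-skewed plan:
#'   `1 + NegBin(size = 1, mu = 1.5)`, many cells visited once or twice, a
#'   few visited often.
#' @param covariate_smoothness kernel bandwidth for the ecological fields.
#' @param seed integer seed.
#' @return list with `data` (a `site_dataset`: grid, `X`, visit-level `W`,
#'   `visit_cell`, `y`, `visits`) and `truth` (a `simulation_truth`: beta,
#'   gamma, V_rho, rho, z, pi, delta).
#' @export
simulate_occupancy_dataset <- function(grid, beta, gamma, V_rho = 1,
                                       visits_per_cell = NULL,
                                       covariate_smoothness = 2, seed = 1) {
  n <- grid$n_cells
  p <- length(beta)
  if (p < 1L || length(gamma) < 1L || length(gamma) > 4L) {
    stop("beta needs length >= 1 and gamma length 1..4", call. = FALSE)
  }
  if (V_rho < 0) stop("V_rho must be >= 0", call. = FALSE)
  with_seed(seed, {
    X <- matrix(1, n, p)
    if (p > 1L) {
      for (j in 2:p) {
        X[, j] <- simulate_covariate_field(grid, covariate_smoothness,
                                           seed = sample.int(2^31 - 2, 1))
      }
    }
    colnames(X) <- c("(Intercept)", if (p > 1L) paste0("x", seq_len(p - 1L)))
    rho <- if (V_rho > 0) {
      simulate_icar_field(grid, V_rho, seed = sample.int(2^31 - 2, 1))
    } else {
      numeric(n)
    }
    pi <- invlogit(drop(X %*% beta) + rho)
    z <- rbinom(n, 1L, pi)

    visits <- if (is.null(visits_per_cell)) {
      1L + rnbinom(n, size = 1, mu = 1.5)
    } else if (length(visits_per_cell) == 1L) {
      rep(as.integer(visits_per_cell), n)
    } else {
      as.integer(visits_per_cell)
    }
    if (length(visits) != n || any(visits < 1L)) {
      stop("visits_per_cell must give >= 1 visit for every cell", call. = FALSE)
    }
    visit_cell <- rep(seq_len(n), times = visits)
    V <- length(visit_cell)
    # correlated ordinal sea conditions: shared latent calm/rough tendency
    lat <- rnorm(V)
    sea <- pmin(4L, pmax(0L, round(1 + 0.8 * lat + 0.5 * rnorm(V))))
    wind <- pmin(4L, pmax(0L, round(1 + 0.8 * lat + 0.5 * rnorm(V))))
    Wraw <- cbind(effort = visits[visit_cell], sea_state = sea, wind = wind)
    Wstd <- scale(Wraw)
    Wstd[is.nan(Wstd)] <- 0 # constant column (e.g. fixed visit plan) -> 0
    W <- cbind("(Intercept)" = 1, Wstd)[, seq_along(gamma), drop = FALSE]
    delta <- invlogit(drop(W %*% gamma))
    y <- rbinom(V, 1L, z[visit_cell] * delta)

    data <- structure(list(grid = grid, X = X, W = W,
                           visit_cell = visit_cell, y = y, visits = visits),
                      class = "site_dataset")
    truth <- structure(list(beta = beta, gamma = gamma, V_rho = V_rho,
                            rho = rho, z = z, pi = pi, delta = delta),
                       class = "simulation_truth")
    list(data = data, truth = truth)
  })
}

#' Simulate per-cell vessel-traffic presence
#'
#' Bernoulli presence/absence of vessels per cell from
#' `logit^-1(X beta + rho)`. The design always contains a distance-to-coast
#' column (the traffic model's selected covariate), computed as the
#' standardized distance from each cell centre to the nearest edge of the
#' domain (the coast is taken to surround the study rectangle); with
#' `length(beta) > 2`, smooth depth and slope fields are appended.
#'
#' @param grid a `lattice_grid`.
#' @param beta coefficients for (intercept, dist_coast\[, depth, slope\]);
#'   length 2..4.
#' @param V_rho spatial-effect variance; 0 disables.
#' @param seed integer seed.
#' @return list with `data` (data.frame: cell_id, covariates, trials = 1,
#'   presence) , `X` (design matrix) and `truth` (beta, rho, pi).
#' @export
simulate_traffic_dataset <- function(grid, beta, V_rho = 0.5, seed = 1) {
  if (length(beta) < 2L || length(beta) > 4L) {
    stop("beta must cover (intercept, dist_coast[, depth, slope])", call. = FALSE)
  }
  if (V_rho < 0) stop("V_rho must be >= 0", call. = FALSE)
  n <- grid$n_cells
  with_seed(seed, {
    dx <- pmin(grid$cell_x - grid$origin[["x0"]],
               grid$origin[["x0"]] + grid$n_cols * grid$cell_size - grid$cell_x)
    dy <- pmin(grid$cell_y - grid$origin[["y0"]],
               grid$origin[["y0"]] + grid$n_rows * grid$cell_size - grid$cell_y)
    dist_coast <- pmin(dx, dy)
    dist_coast <- if (stats::sd(dist_coast) > 0) {
      (dist_coast - mean(dist_coast)) / stats::sd(dist_coast)
    } else {
      dist_coast * 0
    }
    X <- cbind("(Intercept)" = 1, dist_coast = dist_coast)
    if (length(beta) >= 3L) {
      X <- cbind(X, depth = simulate_covariate_field(
        grid, 2, seed = sample.int(2^31 - 2, 1)))
    }
    if (length(beta) == 4L) {
      X <- cbind(X, slope = simulate_covariate_field(
        grid, 2, seed = sample.int(2^31 - 2, 1)))
    }
    rho <- if (V_rho > 0) {
      simulate_icar_field(grid, V_rho, seed = sample.int(2^31 - 2, 1))
    } else {
      numeric(n)
    }
    pi <- invlogit(drop(X %*% beta) + rho)
    presence <- rbinom(n, 1L, pi)
    list(
      data = data.frame(cell_id = seq_len(n), X[, -1, drop = FALSE],
                        trials = 1L, presence = presence),
      X = X,
      truth = list(beta = beta, V_rho = V_rho, rho = rho, pi = pi)
    )
  })
}

#' Write a simulated survey to the package's CSV dialect
#'
#' `sites.csv`: cell_id, x, y, one column per ecological covariate.
#' `visits.csv`: cell_id, visit_index, effort, sea_state, wind, detected.
#' `truth.json`: beta, gamma, V_rho, seed. UTF-8, '.' decimal separator.
#'
#' @param sim result of [simulate_occupancy_dataset()].
#' @param dir output directory (created if needed).
#' @param seed the seed used, recorded in `truth.json`.
#' @return invisible character vector of the three file paths.
#' @export
write_dataset <- function(sim, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- sim$data
  g <- d$grid
  sites <- data.frame(cell_id = seq_len(g$n_cells), x = g$cell_x, y = g$cell_y,
                      d$X[, -1, drop = FALSE], check.names = FALSE)
  vis_idx <- sequence(d$visits)
  visits <- data.frame(cell_id = d$visit_cell, visit_index = vis_idx,
                       d$W[, -1, drop = FALSE], detected = d$y,
                       check.names = FALSE)
  f1 <- file.path(dir, "sites.csv"); f2 <- file.path(dir, "visits.csv")
  f3 <- file.path(dir, "truth.json")
  utils::write.csv(sites, f1, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(visits, f2, row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(list(beta = sim$truth$beta, gamma = sim$truth$gamma,
                            V_rho = sim$truth$V_rho, seed = seed),
                       f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}
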