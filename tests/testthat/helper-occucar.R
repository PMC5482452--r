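# shared fixtures and independent oracles

grid_2cell <- function() build_grid(c(0, 0, 8, 4), 4)

# hand-built 2-cell dataset: cell 1 detected twice in 3 visits, cell 2 never
toy_2cell_dataset <- function() {
  structure(list(
    grid = grid_2cell(),
    X = matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)")),
    W = matrix(1, 6, 1, dimnames = list(NULL, "(Intercept)")),
    visit_cell = c(1L, 1L, 1L, 2L, 2L, 2L),
    y = c(1L, 0L, 1L, 0L, 0L, 0L),
    visits = c(3L, 3L)
  ), class = "site_dataset")
}

quick_mcmc <- function(seed = 1, n_iter = 2000, burnin = 1000, thin = 2) {
  mcmc_config(n_chains = 1, n_iter = n_iter, burnin = burnin, thin = thin,
              seed = seed)
}

# brute-force AUC oracle: fraction of concordant (pos, neg) pairs, ties 1/2
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Moran's I with binary queen weights (row-standardization-free form)
moran_i <- function(v, grid) {
  e <- grid$edges
  vc <- v - mean(v)
  num <- 2 * sum(vc[e[, 1]] * vc[e[, 2]])
  (length(v) / (2 * nrow(e))) * num / sum(vc^2)
}

# Moore-Penrose pseudo-inverse via eigendecomposition
pinv_sym <- function(M) {
  eg <- eigen(M, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
}

with_seed_local <- function(seed, expr) occuCAR:::with_seed(seed, expr)

# fresh scratch directory under the session tempdir (cleaned up by R itself)
withr_local_tempdir <- function() {
  d <- tempfile("occucar-test-")
  dir.create(d)
  d
}

any_detection <- function(data) {
  tabulate(data$visit_cell[data$y == 1], nbins = data$grid$n_cells) > 0
}
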