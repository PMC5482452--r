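#' Enumerate candidate model specifications
#'
#' All non-empty subsets of the main effects (intercept always included),
#' optionally augmented with pairwise interactions whose both mains are in
#' the subset — the hierarchy-respecting "all possible combinations of
#' variables and interaction terms" search. The list is truncated at `cap`
#' with a warning when truncation is permitted, otherwise exceeding the cap
#' is an error.
#'
#' @param covariates character vector of main-effect names.
#' @param detection detection terms copied into every candidate.
#' @param max_interactions max number of interaction terms per candidate
#'   (0 = main effects only).
#' @param cap maximum number of candidates returned.
#' @param truncate permit truncation at `cap`?
#' @param include_intercept_only also include the intercept-only model?
#' @param spatial,prior_Vrho,prior_coef_variance passed to [model_spec()].
#' @return list of `model_spec` objects.
#' @export
enumerate_candidates <- function(covariates, detection = character(0),
                                 max_interactions = 0, cap = 200,
                                 truncate = TRUE,
                                 include_intercept_only = FALSE,
                                 spatial = TRUE, prior_Vrho = c(0, 10),
                                 prior_coef_variance = 100) {
  if (cap < 1) stop("cap must be >= 1", call. = FALSE)
  k <- length(covariates)
  out <- list()
  mk <- function(eco, ints) {
    model_spec(ecological = eco, detection = detection,
               interactions = if (length(ints)) ints else NULL,
               spatial = spatial, prior_Vrho = prior_Vrho,
               prior_coef_variance = prior_coef_variance)
  }
  if (include_intercept_only) out[[length(out) + 1L]] <- mk(character(0), list())
  if (k > 0) {
    for (m in 1:(2^k - 1)) {
      eco <- covariates[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0]
      pairs <- if (length(eco) >= 2L && max_interactions > 0) {
        utils::combn(eco, 2, simplify = FALSE)
      } else {
        list()
      }
      np <- length(pairs)
      nsub <- if (np) 2^np else 1
      for (s in 0:(nsub - 1)) {
        ints <- if (np) pairs[bitwAnd(s, bitwShiftL(1L, seq_len(np) - 1L)) > 0] else list()
        if (length(ints) > max_interactions) next
        out[[length(out) + 1L]] <- mk(eco, ints)
      }
    }
  }
  if (length(out) > cap) {
    if (!truncate) {
      stop(sprintf("candidate set (%d) exceeds cap (%d)", length(out), cap),
           call. = FALSE)
    }
    warning(sprintf("candidate set truncated from %d to cap = %d",
                    length(out), cap), call. = FALSE)
    out <- out[seq_len(cap)]
  }
  out
}

#' Select the model with the lowest DIC
#'
#' Ties are broken toward the spec with fewer parameters, then toward the
#' lexicographically smaller term list.
#'
#' @param fits list where each element has `$spec` (a `model_spec`) and
#'   `$dic` (numeric).
#' @return the winning element of `fits`.
#' @export
select_model <- function(fits) {
  if (!length(fits)) stop("empty candidate list", call. = FALSE)
  dics <- vapply(fits, function(f) f$dic, 0)
  sizes <- vapply(fits, function(f) n_terms(f$spec), 0L)
  labels <- vapply(fits, function(f) format(f$spec), "")
  fits[[order(dics, sizes, labels)[1]]]
}

#' Area under the ROC curve
#'
#' Mann–Whitney formulation with tie correction: the probability a random
#' positive's score exceeds a random negative's, ties counting one half.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  check_two_class(labels)
  stopifnot(length(labels) == length(scores))
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_two_class <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (!any(labels == 1)) stop("no positive labels present", call. = FALSE)
  if (!any(labels == 0)) stop("no negative labels present", call. = FALSE)
  invisible(TRUE)
}

#' True Skill Statistic
#'
#' `TSS = sensitivity + specificity - 1` at a threshold; a record is
#' classified positive when `score >= threshold`. The default rule scans the
#' observed scores as cut-points and maximizes sensitivity + specificity.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores.
#' @param threshold_rule `"max_sens_spec"` (default) or `"fixed"`.
#' @param threshold the cut-point when `threshold_rule = "fixed"`.
#' @return list with `TSS`, `threshold`, `sensitivity`, `specificity`.
#' @export
tss <- function(labels, scores, threshold_rule = c("max_sens_spec", "fixed"),
                threshold = 0.5) {
  threshold_rule <- match.arg(threshold_rule)
  check_two_class(labels)
  stopifnot(length(labels) == length(scores))
  eval_at <- function(th) {
    pred <- scores >= th
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    c(sens = sens, spec = spec)
  }
  if (threshold_rule == "fixed") {
    ss <- eval_at(threshold)
    th <- threshold
  } else {
    cand <- sort(unique(scores))
    best <- -Inf; th <- cand[1]; ss <- c(sens = NA, spec = NA)
    for (cc in cand) {
      v <- eval_at(cc)
      if (sum(v) > best + 1e-15) { best <- sum(v); th <- cc; ss <- v }
    }
  }
  list(TSS = unname(ss["sens"] + ss["spec"] - 1), threshold = th,
       sensitivity = unname(ss["sens"]), specificity = unname(ss["spec"]))
}

#' Repeated random-split cross-validation of an occupancy model
#'
#' `repeats` random 75/25 train/test splits at the cell level (cells with at
#' least one visit are the modelled units; splitting by cell avoids leakage
#' through shared spatial effects). Per repeat the model is refit on the
#' training cells, and held-out cells are scored by the posterior median of
#' the observable-presence probability
#' `pi * (1 - prod_t (1 - delta_t))` over that cell's planned visits, with
#' `rho = 0` for held-out cells (their spatial effect is not identified from
#' the training fold). The evaluation target is the held-out any-detection
#' indicator. Splits with a one-class test set are re-drawn (up to 50
#' times, logged via message).
#'
#' @param data a `site_dataset`.
#' @param spec a `model_spec`.
#' @param repeats number of random splits (study convention: 10).
#' @param train_frac training fraction (study convention: 0.75).
#' @param seed integer seed controlling split membership.
#' @param mcmc reduced-budget [mcmc_config()] used for each refit.
#' @return object of class `cv_result`: per-repeat AUC/TSS/threshold, split
#'   membership, and mean AUC / mean TSS.
#' @export
cross_validate <- function(data, spec, repeats = 10, train_frac = 0.75,
                           seed = 1,
                           mcmc = mcmc_config(n_chains = 1, n_iter = 3000,
                                              burnin = 1500, thin = 3)) {
  stopifnot(inherits(data, "site_dataset"))
  visited <- which(data$visits > 0)
  det_cell <- tabulate(data$visit_cell[data$y == 1],
                       nbins = data$grid$n_cells) > 0
  res <- data.frame(repeat_id = seq_len(repeats), AUC = NA_real_,
                    TSS = NA_real_, threshold = NA_real_)
  splits <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    split <- NULL
    for (try in 1:50) {
      cand <- with_seed(derive_seed(seed, sprintf("cv-split-%d-%d", r, try)), {
        tr <- sample(visited, round(train_frac * length(visited)))
        list(train = sort(tr), test = sort(setdiff(visited, tr)))
      })
      if (length(unique(det_cell[cand$test])) == 2L &&
          length(unique(det_cell[cand$train])) == 2L) { split <- cand; break }
      message(sprintf("cv repeat %d: one-class split, resampling (try %d)", r, try))
    }
    if (is.null(split)) {
      stop("could not form a two-class test set after 50 resamples", call. = FALSE)
    }
    splits[[r]] <- split
    sub <- subset_cells(data, split$train)
    fit <- fit_site_occupancy_icar(
      sub, spec, mcmc = mcmc_config(n_chains = mcmc$n_chains,
                                    n_iter = mcmc$n_iter, burnin = mcmc$burnin,
                                    thin = mcmc$thin,
                                    seed = derive_seed(seed, paste0("cv-fit-", r))))
    scores <- predict_observable(fit, data, cells = split$test)
    labels <- as.integer(det_cell[split$test])
    res$AUC[r] <- auc(labels, scores)
    t_ <- tss(labels, scores)
    res$TSS[r] <- t_$TSS
    res$threshold[r] <- t_$threshold
  }
  structure(list(per_repeat = res, mean_AUC = mean(res$AUC),
                 mean_TSS = mean(res$TSS), splits = splits,
                 repeats = repeats, train_frac = train_frac, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d repeats (%.0f/%.0f split) mean AUC %.3f, mean TSS %.3f\n",
              x$repeats, 100 * x$train_frac, 100 * (1 - x$train_frac),
              x$mean_AUC, x$mean_TSS))
  invisible(x)
}

# restrict a site_dataset to a cell subset; the grid (and hence the iCAR
# graph) is kept whole so neighbour structure is preserved, but visits and
# the detection likelihood only cover `cells`.
subset_cells <- function(data, cells) {
  keep <- data$visit_cell %in% cells
  structure(list(grid = data$grid, X = data$X,
                 W = data$W[keep, , drop = FALSE],
                 visit_cell = data$visit_cell[keep], y = data$y[keep],
                 visits = ifelse(seq_len(data$grid$n_cells) %in% cells,
                                 data$visits, 0L)),
            class = "site_dataset")
}

# posterior-median observable-presence probability for `cells`, using each
# cell's planned visits from `data` and rho = 0 (held-out cells)
predict_observable <- function(fit, data, cells) {
  Xn <- build_design(data$X, fit$spec)[cells, , drop = FALSE]
  eta_occ <- fit$beta_draws %*% t(Xn) # draws x cells
  pi <- invlogit(eta_occ)
  Wn <- fit$W_design
  vapply(seq_along(cells), function(k) {
    i <- cells[k]
    rows <- which(data$visit_cell == i)
    if (!length(rows)) return(stats::median(pi[, k]))
    Wi <- cbind("(Intercept)" = 1,
                data$W[rows, fit$spec$detection, drop = FALSE])
    eta_det <- fit$gamma_draws %*% t(Wi) # draws x visits
    p_nodet <- apply(1 - invlogit(eta_det), 1, prod)
    stats::median(pi[, k] * (1 - p_nodet))
  }, 0)
}
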