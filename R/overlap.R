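#' Normalize a prediction surface to a probability distribution
#'
#' Overlap statistics treat each surface as a probability distribution over
#' the cells of the shared grid, so surfaces are divided by their sum
#' (recorded for transparency). Cells present in only one of two compared
#' surfaces are dropped pairwise upstream, never imputed.
#'
#' @param surface numeric vector of nonnegative per-cell values, or a
#'   `prediction_surface` (its `prob_median` column is used).
#' @return numeric vector summing to 1; attribute `sum_before` holds the
#'   pre-normalization total.
#' @export
normalize_surface <- function(surface) {
  v <- if (inherits(surface, "prediction_surface")) surface$prob_median else surface
  v <- as.numeric(v)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("surface values must be finite and nonnegative", call. = FALSE)
  }
  s <- sum(v)
  if (s <= 0) stop("surface is all zero: cannot normalize", call. = FALSE)
  structure(v / s, sum_before = s)
}

check_prob_pair <- function(pX, pY) {
  if (length(pX) != length(pY)) {
    stop("surfaces must share an identical cell set", call. = FALSE)
  }
  for (p in list(pX, pY)) {
    if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9) {
      stop("input is not normalized (|sum - 1| > 1e-9); use normalize_surface()",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Schoener's D niche-overlap statistic
#'
#' `D = 1 - 0.5 * sum_i |pX_i - pY_i|`: 1 for identical distributions, 0 for
#' disjoint supports.
#'
#' @param pX,pY normalized per-cell probability vectors on a shared cell set.
#' @return D in `[0, 1]`.
#' @export
schoeners_d <- function(pX, pY) {
  check_prob_pair(pX, pY)
  1 - 0.5 * sum(abs(pX - pY))
}

#' Hellinger distance between two surfaces
#'
#' `H = sqrt(sum_i (sqrt(pX_i) - sqrt(pY_i))^2)`, in `[0, sqrt(2)]`.
#'
#' @inheritParams schoeners_d
#' @return H in `[0, sqrt(2)]`.
#' @export
hellinger_distance <- function(pX, pY) {
  check_prob_pair(pX, pY)
  sqrt(sum((sqrt(pX) - sqrt(pY))^2))
}

#' Warren's I niche-overlap statistic
#'
#' `I = 1 - H^2 / 2` where `H` is the Hellinger distance: 1 for identical
#' distributions, 0 for disjoint supports.
#'
#' @inheritParams schoeners_d
#' @return I in `[0, 1]`.
#' @export
warrens_i <- function(pX, pY) {
  1 - hellinger_distance(pX, pY)^2 / 2
}

#' Overlap between two prediction surfaces
#'
#' Convenience wrapper: drops cells missing (NA) in either surface pairwise
#' (logged), normalizes both, and returns Schoener's D, the Hellinger
#' distance H and Warren's I together with the normalization record.
#'
#' @param sX,sY per-cell surfaces (numeric vectors or `prediction_surface`s)
#'   on the same grid.
#' @return object of class `overlap_result`: list with `D`, `H`, `I`,
#'   `n_cells_compared`, `n_cells_dropped`, `normalization_record`.
#' @export
niche_overlap <- function(sX, sY) {
  vX <- if (inherits(sX, "prediction_surface")) sX$prob_median else as.numeric(sX)
  vY <- if (inherits(sY, "prediction_surface")) sY$prob_median else as.numeric(sY)
  if (length(vX) != length(vY)) {
    stop("surfaces must share an identical cell set", call. = FALSE)
  }
  ok <- !is.na(vX) & !is.na(vY)
  dropped <- sum(!ok)
  if (dropped) {
    message(sprintf("niche_overlap: dropped %d cell(s) missing in either surface",
                    dropped))
  }
  pX <- normalize_surface(vX[ok])
  pY <- normalize_surface(vY[ok])
  H <- hellinger_distance(pX, pY)
  structure(list(D = schoeners_d(pX, pY), H = H, I = 1 - H^2 / 2,
                 n_cells_compared = sum(ok), n_cells_dropped = dropped,
                 normalization_record = c(sum_X = attr(pX, "sum_before"),
                                          sum_Y = attr(pY, "sum_before"))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: D = %.3f, I = %.3f (H = %.3f) over %d cells\n",
              x$D, x$I, x$H, x$n_cells_compared))
  invisible(x)
}
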