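#' Build a regular analysis lattice
#'
#' Tiles a bounding box with square cells of side `cell_size` (the survey
#' analyses use 4 km cells). Cell extents are half-open
#' `[x, x + cell_size) x [y, y + cell_size)` with the origin at the lower-left
#' corner; partial edge cells are included, so the tiled extent can exceed the
#' bounding box by less than one cell per axis. Cell ids are consecutive
#' integers in row-major order from the lower-left cell (`id = (row - 1) *
#' n_cols + col`, rows counted from the bottom).
#'
#' @param bbox numeric length-4 vector `(xmin, ymin, xmax, ymax)` in projected
#'   units (km or m); geographic coordinates must be projected beforehand.
#' @param cell_size positive cell side length in the same units.
#' @param scheme neighbourhood scheme for the adjacency, `"queen"` (8
#'   neighbours, default) or `"rook"` (4).
#' @return an object of class `lattice_grid`: list with `origin`, `cell_size`,
#'   `n_rows`, `n_cols`, `n_cells`, cell-centre coordinates `cell_x`/`cell_y`,
#'   an `edges` matrix of symmetric neighbour pairs and a neighbour list `nb`.
#' @export
build_grid <- function(bbox, cell_size, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  if (length(bbox) != 4L || !is.numeric(bbox)) {
    stop("`bbox` must be numeric (xmin, ymin, xmax, ymax)", call. = FALSE)
  }
  xmin <- bbox[1]; ymin <- bbox[2]; xmax <- bbox[3]; ymax <- bbox[4]
  if (!(xmax > xmin) || !(ymax > ymin)) {
    stop("invalid extent: need xmax > xmin and ymax > ymin", call. = FALSE)
  }
  stopifnot_scalar_pos(cell_size, "cell_size")
  n_cols <- as.integer(ceiling((xmax - xmin) / cell_size - 1e-12))
  n_rows <- as.integer(ceiling((ymax - ymin) / cell_size - 1e-12))
  n <- n_rows * n_cols
  col <- rep(seq_len(n_cols), times = n_rows)
  row <- rep(seq_len(n_rows), each = n_cols)
  g <- structure(list(
    origin = c(x0 = xmin, y0 = ymin),
    cell_size = cell_size,
    n_rows = n_rows, n_cols = n_cols, n_cells = n,
    cell_row = row, cell_col = col,
    cell_x = xmin + (col - 0.5) * cell_size,
    cell_y = ymin + (row - 0.5) * cell_size,
    scheme = scheme
  ), class = "lattice_grid")
  adj <- build_adjacency(g, scheme)
  g$edges <- adj$edges
  g$nb <- adj$nb
  g
}

#' @export
print.lattice_grid <- function(x, ...) {
  cat(sprintf("lattice_grid: %d x %d cells (n = %d), cell size %g, %s adjacency, %d edges\n",
              x$n_rows, x$n_cols, x$n_cells, x$cell_size, x$scheme, nrow(x$edges)))
  invisible(x)
}

#' Lattice adjacency structure
#'
#' Symmetric neighbour pairs under the queen (8-neighbour) or rook
#' (4-neighbour) scheme. Queen is the package default for lattice CAR
#' species-distribution models.
#'
#' @param grid a `lattice_grid`.
#' @param scheme `"queen"` or `"rook"`.
#' @return list with `edges` (2-column integer matrix, each row `i < j`) and
#'   `nb` (per-cell integer vector of neighbour ids).
#' @export
build_adjacency <- function(grid, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  nr <- grid$n_rows; nc <- grid$n_cols
  id <- function(r, c) (r - 1L) * nc + c
  offs <- if (scheme == "rook") {
    list(c(0L, 1L), c(1L, 0L))
  } else {
    list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  }
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r <- rep(seq_len(nr), times = nc); c <- rep(seq_len(nc), each = nr)
    r2 <- r + o[1]; c2 <- c + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    from <- c(from, id(r[ok], c[ok]))
    to <- c(to, id(r2[ok], c2[ok]))
  }
  edges <- cbind(pmin(from, to), pmax(from, to))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  nb <- vector("list", grid$n_cells)
  for (k in seq_len(grid$n_cells)) nb[[k]] <- integer(0)
  if (nrow(edges)) {
    all_i <- c(edges[, 1], edges[, 2]); all_j <- c(edges[, 2], edges[, 1])
    sp <- split(all_j, all_i)
    for (nm in names(sp)) nb[[as.integer(nm)]] <- sort(sp[[nm]])
  }
  list(edges = edges, nb = nb)
}

# connected components of the adjacency graph (integer label per cell)
grid_components <- function(grid) {
  n <- grid$n_cells
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, grid$nb[[v]][comp[grid$nb[[v]]] == 0L])
    }
  }
  comp
}

#' Assign point records to grid cells
#'
#' Half-open membership: a point exactly on an interior cell boundary belongs
#' to the cell with the larger index; a point on the upper/right edge of the
#' tiled extent (e.g. the bbox max corner when the tiling is exact) is outside
#' every cell and is flagged with `NA` plus a warning, never silently dropped.
#'
#' @param x,y point coordinates (projected units).
#' @param grid a `lattice_grid`.
#' @return integer vector of cell ids, `NA` for out-of-grid points.
#' @export
assign_points_to_cells <- function(x, y, grid) {
  stopifnot(length(x) == length(y))
  col <- floor((x - grid$origin[["x0"]]) / grid$cell_size) + 1
  row <- floor((y - grid$origin[["y0"]]) / grid$cell_size) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows &
    is.finite(col) & is.finite(row)
  out <- rep(NA_integer_, length(x))
  out[ok] <- (as.integer(row[ok]) - 1L) * grid$n_cols + as.integer(col[ok])
  if (any(!ok)) {
    warning(sprintf("%d point(s) fall outside the grid and were flagged NA",
                    sum(!ok)), call. = FALSE)
  }
  out
}

#' Survey effort per cell
#'
#' Effort is the number of times a cell was visited: the count of visit
#' records per cell.
#'
#' @param visit_cells integer vector of cell ids, one per visit record.
#' @param grid a `lattice_grid`.
#' @return integer vector of length `n_cells`; sums to `length(visit_cells)`.
#' @export
compute_effort <- function(visit_cells, grid) {
  if (length(visit_cells) &&
      (anyNA(visit_cells) || any(visit_cells < 1L | visit_cells > grid$n_cells))) {
    stop("visit records reference unknown cell ids", call. = FALSE)
  }
  tabulate(visit_cells, nbins = grid$n_cells)
}

#' Weighted per-cell average of record-level values
#'
#' Collapses record-level measurements (e.g. per-visit sea state or wind) to
#' one value per cell as `sum(w * v) / sum(w)`. Cells with no records get
#' `NA`.
#'
#' @param values,weights,cell_ids equal-length record vectors; weights must be
#'   strictly positive.
#' @param grid a `lattice_grid`.
#' @return numeric vector of length `n_cells`.
#' @export
weighted_cell_average <- function(values, weights, cell_ids, grid) {
  stopifnot(length(values) == length(weights), length(values) == length(cell_ids))
  if (any(weights <= 0)) stop("weights must be strictly positive", call. = FALSE)
  num <- tapply(values * weights, factor(cell_ids, levels = seq_len(grid$n_cells)),
                sum)
  den <- tapply(weights, factor(cell_ids, levels = seq_len(grid$n_cells)), sum)
  out <- as.numeric(num) / as.numeric(den)
  out[is.na(as.numeric(den))] <- NA_real_
  out
}

#' Standardize covariates and screen pairwise correlation
#'
#' Z-score standardization (mean 0, sd 1) of every column, plus a screening
#' report of all pairwise Pearson correlations with flags at `|r| >= 0.6`.
#' Flagged pairs are reported, never auto-dropped — the analyst decides.
#'
#' @param raw data.frame or matrix of per-cell covariates (no intercept).
#' @param r_flag flag threshold on `|r|`, default 0.6.
#' @return list with `X` (standardized matrix carrying `center`/`scale`
#'   attributes for exact destandardization) and `screening` (data.frame of
#'   pairs, r, flagged).
#' @export
prepare_covariates <- function(raw, r_flag = 0.6) {
  raw <- as.matrix(raw)
  if (ncol(raw) < 1L) stop("need at least one covariate", call. = FALSE)
  if (nrow(raw) < 2L) stop("need at least two cells", call. = FALSE)
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, stats::sd)
  zero <- which(scl == 0 | !is.finite(scl))
  if (length(zero)) {
    stop(sprintf("zero-variance covariate(s): %s",
                 paste(colnames(raw)[zero], collapse = ", ")), call. = FALSE)
  }
  X <- sweep(sweep(raw, 2, ctr, "-"), 2, scl, "/")
  attr(X, "center") <- ctr
  attr(X, "scale") <- scl
  screening <- NULL
  if (ncol(raw) >= 2L) {
    cm <- stats::cor(X)
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    screening <- data.frame(
      var1 = colnames(raw)[idx[, 1]],
      var2 = colnames(raw)[idx[, 2]],
      r = cm[idx],
      flagged = abs(cm[idx]) >= r_flag,
      stringsAsFactors = FALSE
    )
  } else {
    screening <- data.frame(var1 = character(0), var2 = character(0),
                            r = numeric(0), flagged = logical(0))
  }
  list(X = X, screening = screening)
}

#' Invert the standardization produced by [prepare_covariates()]
#' @param X standardized matrix with `center` and `scale` attributes.
#' @return matrix on the original scale.
#' @export
destandardize <- function(X) {
  sweep(sweep(X, 2, attr(X, "scale"), "*"), 2, attr(X, "center"), "+")
}
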