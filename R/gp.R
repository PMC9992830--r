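#' Fit the spatiotemporal Gaussian-process interpolation model
#'
#' Models each ancestry component as a draw from a Gaussian process over
#' (easting, northing, time) with the anisotropic squared-exponential
#' kernel of [kernel_params()]. The mean function is constant: each
#' component is centred by its training mean (or a supplied fixed offset)
#' and predictions revert to that offset far from data. Components are
#' fitted independently and may carry individual kernels.
#'
#' @param X Numeric `n x 3` matrix of training coordinates `(x, y, t)` in
#'   meters/meters/years.
#' @param Y Numeric `n x k` matrix (or length-`n` vector) of observed
#'   ancestry-component values.
#' @param params A single [kernel_params()] shared by all components, or a
#'   list of one per component.
#' @param mean_offset Optional numeric vector of fixed prior means, one per
#'   component; default `NULL` uses each component's training mean.
#' @return An object of class `gp_model` holding the training coordinates,
#'   per-component offsets, Cholesky factors and weight vectors.
#' @export
fit_gp <- function(X, Y, params, mean_offset = NULL) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 2) stop("at least 2 training points are required")
  if (ncol(X) != 3) stop("X must have columns (x, y, t)")
  if (any(!is.finite(X))) stop("non-finite training coordinates")
  k <- ncol(Y)
  if (inherits(params, "kernel_params")) {
    params <- rep(list(params), k)
  }
  if (length(params) != k) {
    stop("need one kernel_params per component (", k, "), got ",
         length(params))
  }
  # exact-duplicate coordinates with eta = 0 and conflicting values make
  # the covariance singular in a way jitter should not paper over
  key <- paste(X[, 1], X[, 2], X[, 3])
  if (anyDuplicated(key)) {
    for (j in seq_len(k)) {
      if (params[[j]]$eta > 0) next
      vals <- split(Y[, j], key)
      conflict <- vapply(vals, function(v) length(unique(v)) > 1,
                         logical(1))
      if (any(conflict)) {
        stop("duplicate coordinates with differing component values and ",
             "eta = 0 give a singular covariance; use a positive nugget")
      }
    }
  }
  comps <- vector("list", k)
  for (j in seq_len(k)) {
    p <- params[[j]]
    K <- kernel_matrix(X, X, p, nugget = "diagonal", symmetric = TRUE)
    L <- tryCatch(t(chol(K)), error = function(e) NULL)
    if (is.null(L)) {
      warning("covariance factorization failed; adding jitter ",
              format(1e-8 * p$tau2), " to the diagonal")
      K <- K + diag(1e-8 * p$tau2, nrow(K))
      L <- t(chol(K))
    }
    offset <- if (is.null(mean_offset)) mean(Y[, j]) else mean_offset[j]
    yc <- Y[, j] - offset
    alpha <- backsolve(t(L), forwardsolve(L, yc))
    comps[[j]] <- list(params = p, offset = offset, L = L, alpha = alpha,
                       y_centered = yc)
  }
  structure(list(X = X, components = comps, n = nrow(X), k = k),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat("<gp_model> ", x$n, " training points, ", x$k, " component(s)\n",
      sep = "")
  invisible(x)
}

#' Predictive mean and standard deviation at query points
#'
#' Standard Gaussian-process conditioning: per component,
#' `mean = offset + k*' K^-1 (y - offset)` and
#' `var = tau2 + eta - k*' K^-1 k*`, floored at zero. The cross-covariance
#' `k*` picks up the nugget only where a query coincides bitwise with a
#' training coordinate, so predictions at training points with `eta = 0`
#' reproduce the observations exactly.
#'
#' @param model A [fit_gp()] result.
#' @param Xq Numeric `m x 3` matrix of query coordinates.
#' @return List with `mean` and `sd`, both `m x k` matrices.
#' @export
gp_predict <- function(model, Xq) {
  stopifnot(inherits(model, "gp_model"))
  Xq <- matrix(as.numeric(Xq), ncol = 3)
  mean_out <- matrix(NA_real_, nrow(Xq), model$k)
  sd_out <- matrix(NA_real_, nrow(Xq), model$k)
  for (j in seq_len(model$k)) {
    cm <- model$components[[j]]
    Ks <- kernel_matrix(model$X, Xq, cm$params)  # n x m
    mean_out[, j] <- cm$offset + drop(crossprod(Ks, cm$alpha))
    v <- forwardsolve(cm$L, Ks)
    var_ <- cm$params$tau2 + cm$params$eta - colSums(v^2)
    sd_out[, j] <- sqrt(pmax(var_, 0))
  }
  list(mean = mean_out, sd = sd_out)
}

#' Evaluate the fitted field on a regular grid at given times
#'
#' Lays a lattice of square cell centres over the bounding box (first
#' centre at `min + spacing/2`, cells entirely inside the box) and returns
#' one field slice per requested time, with per-cell predictive mean and sd
#' for every component. Cells are ordered row-major: northing ascending,
#' easting fastest — the tie-break order used downstream.
#'
#' @param model A [fit_gp()] result.
#' @param bbox Numeric `c(xmin, xmax, ymin, ymax)` in meters.
#' @param spacing Cell edge length in meters.
#' @param times Numeric vector of slice times (years calBC/AD).
#' @param cell_budget Maximum number of cells per slice (guards against
#'   accidentally dense grids).
#' @return List of `field_slice` objects: `time`, vectors `x`, `y` of cell
#'   centres, `spacing`, and `mean` / `sd` cell-by-component matrices.
#' @export
predict_field_grid <- function(model, bbox, spacing, times,
                               cell_budget = 2e5) {
  stopifnot(length(bbox) == 4, spacing > 0)
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) {
    stop("degenerate bounding box")
  }
  nx <- floor((bbox[2] - bbox[1]) / spacing)
  ny <- floor((bbox[4] - bbox[3]) / spacing)
  if (nx < 1 || ny < 1) stop("bounding box smaller than one cell")
  if (nx * ny > cell_budget) {
    stop("grid of ", nx * ny, " cells exceeds the cell budget (",
         cell_budget, "); use a coarser spacing")
  }
  xs <- bbox[1] + spacing / 2 + (seq_len(nx) - 1) * spacing
  ys <- bbox[3] + spacing / 2 + (seq_len(ny) - 1) * spacing
  cells <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  lapply(times, function(tt) {
    pred <- gp_predict(model, cbind(cells$x, cells$y, tt))
    structure(list(time = tt, x = cells$x, y = cells$y,
                   nx = nx, ny = ny, spacing = spacing,
                   mean = pred$mean, sd = pred$sd),
              class = "field_slice")
  })
}

#' Export field slices as a long-format table
#'
#' @param slices List of `field_slice` objects from
#'   [predict_field_grid()].
#' @param path Optional TSV output path; when `NULL` the table is returned
#'   only.
#' @return A `data.frame` with columns `x`, `y`, `t`, `component`, `mean`,
#'   `sd`.
#' @export
field_slices_to_table <- function(slices, path = NULL) {
  rows <- lapply(slices, function(sl) {
    k <- ncol(sl$mean)
    do.call(rbind, lapply(seq_len(k), function(j) {
      data.frame(x = sl$x, y = sl$y, t = sl$time,
                 component = paste0("C", j),
                 mean = sl$mean[, j], sd = sl$sd[, j])
    }))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  out
}
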