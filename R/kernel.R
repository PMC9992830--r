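#' Anisotropic squared-exponential kernel parameters
#'
#' The covariance between two space-time points is
#' `Cov(a, b) = tau2 * exp(-sum_k (a_k - b_k)^2 / theta_k) + eta * delta(a, b)`
#' over the three independent dimensions (easting, northing, time). The
#' `theta_k` are squared-distance divisors: `theta_x`/`theta_y` in m^2,
#' `theta_t` in years^2 — use [lengthscale_to_theta()] to enter them as
#' plain lengthscales. `tau2` is the process variance on the ancestry-
#' component scale and `eta` the nugget — independent per-observation
#' variance absorbing local ancestry heterogeneity and noise. The
#' Kronecker delta is realized per observation in the training covariance
#' (diagonal), and on exact coordinate coincidence in point-to-point and
#' cross covariances.
#'
#' @param theta_x,theta_y,theta_t Positive squared-distance divisors
#'   (m^2, m^2, years^2).
#' @param tau2 Positive process variance.
#' @param eta Non-negative nugget variance.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(theta_x, theta_y, theta_t, tau2 = 1, eta = 0) {
  vals <- c(theta_x = theta_x, theta_y = theta_y, theta_t = theta_t,
            tau2 = tau2, eta = eta)
  if (any(!is.finite(vals))) stop("kernel parameters must be finite")
  if (any(vals[1:4] <= 0)) stop("theta_* and tau2 must be > 0")
  if (eta < 0) stop("eta must be >= 0")
  structure(as.list(vals), class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat("<kernel_params> lengthscales: x ",
      format(sqrt(x$theta_x) / 1000, digits = 4), " km, y ",
      format(sqrt(x$theta_y) / 1000, digits = 4), " km, t ",
      format(sqrt(x$theta_t), digits = 4), " y; tau2 ",
      format(x$tau2, digits = 4), ", eta ", format(x$eta, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Convert between lengthscales and squared-distance divisors
#'
#' `theta = lengthscale^2`; at separation equal to the lengthscale the
#' correlation has decayed to `exp(-1)`.
#'
#' @param l A lengthscale (same units as the coordinate axis).
#' @return The corresponding `theta` (or lengthscale).
#' @export
lengthscale_to_theta <- function(l) l^2

#' @rdname lengthscale_to_theta
#' @param theta A squared-distance divisor.
#' @export
theta_to_lengthscale <- function(theta) sqrt(theta)

#' Kernel covariance between two space-time points
#'
#' @param a,b Numeric length-3 vectors `(x, y, t)` in meters/meters/years.
#' @param params A [kernel_params()] object.
#' @return The scalar covariance; the nugget contributes only when `a` and
#'   `b` are exactly (bitwise) equal.
#' @export
kernel_value <- function(a, b, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (any(!is.finite(c(a, b)))) stop("non-finite coordinates")
  d2 <- (a[1] - b[1])^2 / params$theta_x +
    (a[2] - b[2])^2 / params$theta_y +
    (a[3] - b[3])^2 / params$theta_t
  params$tau2 * exp(-d2) + params$eta * all(a == b)
}

# Cross-covariance matrix between two point sets (rows = (x, y, t)).
# nugget = "coincide": eta added wherever coordinates coincide bitwise
# (cross-covariance between a query and the training set); "diagonal":
# eta added per observation (i == j) — the training covariance, where two
# observations at the same site carry independent nugget noise; "none".
kernel_matrix <- function(X1, X2, params,
                          nugget = c("coincide", "diagonal", "none"),
                          symmetric = FALSE) {
  nugget <- match.arg(nugget)
  sq <- function(col1, col2, theta) outer(col1, col2, "-")^2 / theta
  d2 <- sq(X1[, 1], X2[, 1], params$theta_x) +
    sq(X1[, 2], X2[, 2], params$theta_y) +
    sq(X1[, 3], X2[, 3], params$theta_t)
  K <- params$tau2 * exp(-d2)
  if (params$eta > 0 && nugget == "coincide") {
    eq <- outer(X1[, 1], X2[, 1], "==") & outer(X1[, 2], X2[, 2], "==") &
      outer(X1[, 3], X2[, 3], "==")
    K <- K + params$eta * eq
  }
  if (params$eta > 0 && nugget == "diagonal") {
    if (nrow(X1) != nrow(X2)) stop("diagonal nugget needs square K")
    K <- K + diag(params$eta, nrow(X1))
  }
  if (symmetric) K <- (K + t(K)) / 2
  K
}
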