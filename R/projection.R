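# Ellipsoidal Lambert azimuthal equal-area projection (Snyder's formulas)
# with the ETRS89-LAEA "European grid" parameterisation (EPSG:3035):
# centre 10E/52N, false easting 4321000 m, false northing 3210000 m, GRS80.
# Equal-area is load-bearing downstream: a uniform prior over grid cells is
# then a uniform spatial prior.

laea_constants <- function(lon0_deg = 10, lat0_deg = 52,
                           false_e = 4321000, false_n = 3210000,
                           a = 6378137, inv_f = 298.257222101) {
  f <- 1 / inv_f
  e2 <- f * (2 - f)
  e <- sqrt(e2)
  qfun <- function(phi) {
    s <- sin(phi)
    (1 - e2) * (s / (1 - e2 * s^2) -
                  (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
  }
  phi0 <- lat0_deg * pi / 180
  qp <- qfun(pi / 2)
  q1 <- qfun(phi0)
  beta1 <- asin(q1 / qp)
  Rq <- a * sqrt(qp / 2)
  m1 <- cos(phi0) / sqrt(1 - e2 * sin(phi0)^2)
  D <- a * m1 / (Rq * cos(beta1))
  list(lon0 = lon0_deg * pi / 180, beta1 = beta1, Rq = Rq, D = D,
       qp = qp, e = e, e2 = e2, a = a,
       false_e = false_e, false_n = false_n, qfun = qfun)
}

#' Forward Lambert azimuthal equal-area projection
#'
#' Projects geographic coordinates to planar easting/northing in meters on
#' the European ETRS89-LAEA grid (EPSG:3035 parameters). Points (numerically)
#' antipodal to the projection centre are outside the projection's validity
#' and come back as `NA` with a warning.
#'
#' @param lon,lat Numeric vectors of geographic coordinates in degrees.
#' @return A `data.frame` with columns `x`, `y` (meters) and logical `valid`.
#' @export
laea_forward <- function(lon, lat) {
  k <- laea_constants()
  phi <- lat * pi / 180
  dlam <- lon * pi / 180 - k$lon0
  q <- k$qfun(phi)
  beta <- asin(pmin(1, pmax(-1, q / k$qp)))
  denom <- 1 + sin(k$beta1) * sin(beta) + cos(k$beta1) * cos(beta) * cos(dlam)
  valid <- is.finite(denom) & denom > 1e-10
  B <- k$Rq * sqrt(2 / denom)
  x <- B * k$D * cos(beta) * sin(dlam) + k$false_e
  y <- (B / k$D) * (cos(k$beta1) * sin(beta) -
                      sin(k$beta1) * cos(beta) * cos(dlam)) + k$false_n
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  if (any(!valid)) {
    warning("point(s) antipodal to the projection centre cannot be projected")
  }
  data.frame(x = x, y = y, valid = valid)
}

#' Inverse Lambert azimuthal equal-area projection
#'
#' @param x,y Numeric vectors of planar coordinates in meters (EPSG:3035
#'   easting/northing).
#' @return A `data.frame` with columns `lon`, `lat` in degrees.
#' @export
laea_inverse <- function(x, y) {
  k <- laea_constants()
  xr <- (x - k$false_e) / k$D
  yr <- k$D * (y - k$false_n)
  rho <- sqrt(xr^2 + yr^2)
  ce <- 2 * asin(pmin(1, rho / (2 * k$Rq)))
  q <- ifelse(rho == 0, k$qp * sin(k$beta1),
              k$qp * (cos(ce) * sin(k$beta1) +
                        yr * sin(ce) * cos(k$beta1) / rho))
  lam <- k$lon0 + atan2((x - k$false_e) * sin(ce),
                        k$D * rho * cos(k$beta1) * cos(ce) -
                          k$D^2 * (y - k$false_n) * sin(k$beta1) * sin(ce))
  lam[rho == 0] <- k$lon0
  # latitude from the authalic quantity q by fixed-point iteration
  phi <- asin(pmin(1, pmax(-1, q / 2)))
  for (i in 1:30) {
    s <- sin(phi)
    corr <- (1 - k$e2 * s^2)^2 / (2 * cos(phi)) *
      (q / (1 - k$e2) - s / (1 - k$e2 * s^2) +
         (1 / (2 * k$e)) * log((1 - k$e * s) / (1 + k$e * s)))
    corr[!is.finite(corr)] <- 0  # poles: cos(phi) = 0, already converged
    phi <- phi + corr
    if (max(abs(corr)) < 1e-14) break
  }
  data.frame(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Fill planar coordinates in a sample table
#'
#' Projects each record's lon/lat onto the equal-area plane used by all
#' downstream kernel distances and grids. Records outside the projection's
#' validity are flagged (logical column `projection_valid`), not dropped.
#'
#' @param samples A sample table (see [read_sample_table()]).
#' @param projection_spec Projection identifier; only the European
#'   ETRS89-LAEA grid (`"EPSG:3035"`) is supported.
#' @return The table with `x`, `y` (meters) and `projection_valid` filled.
#' @export
project_coordinates <- function(samples, projection_spec = "EPSG:3035") {
  validate_sample_table(samples)
  if (!identical(toupper(projection_spec), "EPSG:3035")) {
    stop("unsupported projection_spec '", projection_spec,
         "'; only EPSG:3035 is implemented")
  }
  p <- laea_forward(samples$lon, samples$lat)
  samples$x <- p$x
  samples$y <- p$y
  samples$projection_valid <- p$valid
  samples
}
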