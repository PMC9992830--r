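#' Likelihood of an ancestry-component value under the local field
#'
#' Gaussian density of a sample's component value `z` given the field's
#' predictive mean and sd at a location, with the nugget added to the
#' variance so that locally heterogeneous ancestry keeps support even where
#' the field is tightly constrained by data.
#'
#' @param z Sample component value (scalar or vector).
#' @param mu Field predictive mean (recycled against `z`).
#' @param sigma Field predictive sd (`>= 0`).
#' @param eta Nugget variance (`>= 0`).
#' @param log Return log densities?
#' @return The density (or log density). A degenerate `sigma^2 + eta = 0`
#'   with `z == mu` returns `Inf` (point-mass sentinel for the caller);
#'   with `z != mu` it is an error.
#' @export
component_likelihood <- function(z, mu, sigma, eta, log = FALSE) {
  if (any(sigma < 0) || any(eta < 0)) stop("sigma and eta must be >= 0")
  n <- max(length(z), length(mu), length(sigma))
  z <- rep_len(z, n)
  mu <- rep_len(mu, n)
  var_tot <- rep_len(sigma^2 + eta, n)
  degen <- var_tot == 0
  if (any(degen & z != mu)) {
    stop("zero total variance with z != mu has no density")
  }
  out <- numeric(n)
  out[degen] <- Inf  # point-mass sentinel; caller decides
  out[!degen] <- stats::dnorm(z[!degen], mu[!degen], sqrt(var_tot[!degen]),
                              log = log)
  out
}

#' Similarity probability surface for one sample in a past time slice
#'
#' Evaluates, per grid cell, the likelihood that the sample's ancestry-
#' component values emerge from the field's predictive distribution there,
#' multiplies the per-component likelihoods, and normalises over cells with
#' a uniform prior (uniform over equal-area cells = uniform spatial prior,
#' by Bayes' formula). All accumulation is in log space; the result is a
#' proper probability distribution over the slice's cells. Because the
#' predictive sd grows toward `sqrt(tau2 + eta)` away from data, the
#' surface is only peaked where the field is actually supported by samples.
#'
#' @param z Numeric vector of the sample's component values (length = the
#'   slice's component count).
#' @param slice A `field_slice` from [predict_field_grid()].
#' @param eta Numeric vector of per-component nugget variances (recycled).
#' @param sample_id Optional identifier carried in the result.
#' @return An object of class `similarity_surface`: `sample_id`,
#'   `slice_time`, cell centre vectors `x`, `y`, `nx`, `ny`, `spacing`, and
#'   `probability` summing to 1.
#' @export
similarity_surface <- function(z, slice, eta, sample_id = NA_character_) {
  stopifnot(inherits(slice, "field_slice"))
  k <- ncol(slice$mean)
  if (length(z) != k) {
    stop("sample has ", length(z), " component value(s) but the slice has ",
         k)
  }
  eta <- rep_len(eta, k)
  loglik <- rep(0, length(slice$x))
  for (j in seq_len(k)) {
    loglik <- loglik + component_likelihood(z[j], slice$mean[, j],
                                            slice$sd[, j], eta[j],
                                            log = TRUE)
  }
  m <- max(loglik)
  if (!is.finite(m)) {
    stop("similarity surface underflowed to zero everywhere for sample ",
         sample_id, " at slice ", slice$time)
  }
  p <- exp(loglik - m)
  p <- p / sum(p)
  structure(list(sample_id = sample_id, slice_time = slice$time,
                 x = slice$x, y = slice$y, nx = slice$nx, ny = slice$ny,
                 spacing = slice$spacing, probability = p),
            class = "similarity_surface")
}

#' @export
print.similarity_surface <- function(x, ...) {
  cat("<similarity_surface> sample ", x$sample_id, ", slice ",
      x$slice_time, ", ", length(x$probability), " cells, max p = ",
      format(max(x$probability), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Maximum-probability cell of a similarity surface
#'
#' Ties (within exact floating-point equality) are broken deterministically
#' by row-major cell order (smallest northing, then smallest easting) and
#' flagged.
#'
#' @param surface A [similarity_surface()] result.
#' @return List with `x`, `y` (cell centre, meters), `time`, `probability`,
#'   logical `tie`, and `n_tied`.
#' @export
max_similarity_point <- function(surface) {
  stopifnot(inherits(surface, "similarity_surface"))
  p <- surface$probability
  i <- which.max(p)  # first max in row-major order
  n_tied <- sum(p == p[i])
  list(x = surface$x[i], y = surface$y[i], time = surface$slice_time,
       probability = p[i], tie = n_tied > 1, n_tied = n_tied)
}

#' Export a similarity surface as TSV plus a JSON sidecar
#'
#' The TSV holds `(x, y, probability)`; the sidecar records the sample id,
#' slice time, the maximum-probability point and its tie flag.
#'
#' @param surface A [similarity_surface()] result.
#' @param path TSV output path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_similarity_surface <- function(surface, path) {
  stopifnot(inherits(surface, "similarity_surface"))
  utils::write.table(
    data.frame(x = surface$x, y = surface$y,
               probability = surface$probability),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- max_similarity_point(surface)
  jsonlite::write_json(
    list(sample_id = surface$sample_id, slice_time = surface$slice_time,
         max_point = mp[c("x", "y", "probability")], tie = mp$tie,
         n_tied = mp$n_tied),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
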