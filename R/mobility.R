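#' Monte-Carlo draws from a sample's age distribution
#'
#' Reflects calibrated-age uncertainty in the mobility estimation. When a
#' calibrated age probability table is attached to the sample it is drawn
#' from directly; otherwise draws come from a normal centred on the median
#' age with `sd = (age_hi - age_lo) / 4` (the 2-sigma range spans 4 sd),
#' truncated to the 2-sigma bounds by inverse-CDF sampling. Deterministic
#' given the seed.
#'
#' @param sample One-row sample table (or list) with `age_median`,
#'   `age_lo`, `age_hi` and optionally `age_pmf` (a `data.frame` with
#'   columns `year`, `probability`).
#' @param n Number of draws (default 25).
#' @param seed Integer RNG seed.
#' @return Numeric vector of `n` ages (years calBC/AD).
#' @export
resample_ages <- function(sample, n = 25, seed = 1) {
  stopifnot(n >= 1)
  pmf <- if ("age_pmf" %in% names(sample)) {
    p <- sample$age_pmf
    if (is.data.frame(p)) p else p[[1]]
  } else NULL
  lo <- as.numeric(sample$age_lo)
  hi <- as.numeric(sample$age_hi)
  med <- as.numeric(sample$age_median)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  if (!is.null(pmf) && is.data.frame(pmf)) {
    if (any(pmf$probability < 0) || abs(sum(pmf$probability) - 1) > 1e-9) {
      stop("age_pmf probabilities must be non-negative and sum to 1")
    }
    idx <- sample.int(nrow(pmf), n, replace = TRUE,
                      prob = pmf$probability)
    return(pmf$year[idx])
  }
  if (lo == hi) return(rep(lo, n))
  sd_ <- (hi - lo) / 4
  plo <- stats::pnorm(lo, med, sd_)
  phi <- stats::pnorm(hi, med, sd_)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, med, sd_)
}

#' Mobility vector from a burial location to a surface maximum
#'
#' The displacement from where a sample was buried to the maximum-
#' probability cell of its similarity surface in a past time slice — the
#' summary used to proxy individual (or ancestral) mobility. Direction is
#' a compass bearing (0 = North, clockwise, `[0, 360)`) and is undefined
#' for a zero-length vector.
#'
#' @param burial Numeric `c(x, y)` planar burial location in meters.
#' @param surface A [similarity_surface()] result.
#' @return One-row `data.frame` with `origin_x`, `origin_y`, `dx`, `dy`,
#'   `length_km`, `direction_deg` (`NA` when length 0), `tie`,
#'   `slice_time`.
#' @export
mobility_vector <- function(burial, surface) {
  mp <- max_similarity_point(surface)
  dx <- mp$x - burial[1]
  dy <- mp$y - burial[2]
  len_km <- sqrt(dx^2 + dy^2) / 1000
  dir <- if (len_km > 0) (atan2(dx, dy) * 180 / pi) %% 360 else NA_real_
  data.frame(origin_x = mp$x, origin_y = mp$y, dx = dx, dy = dy,
             length_km = len_km, direction_deg = dir, tie = mp$tie,
             slice_time = surface$slice_time)
}

#' Per-sample mobility estimate with age-uncertainty resampling
#'
#' For each of `n_runs` age draws, slices the fitted ancestry field at
#' `age - retrospection` years, computes the sample's similarity surface
#' and its mobility vector. The summary is the component-wise mean vector
#' (mean dx, mean dy — which can cancel when runs disagree on direction)
#' and the standard deviation of the per-run vector lengths.
#'
#' @param sample One-row sample table with planar `x`, `y` filled and age
#'   fields.
#' @param z Numeric vector of the sample's ancestry-component values.
#' @param model A [fit_gp()] result.
#' @param bbox,spacing Grid specification passed to
#'   [predict_field_grid()].
#' @param retrospection Years to look back from each resampled age
#'   (default 667).
#' @param n_runs Number of age resampling runs (default 25).
#' @param seed Integer RNG seed for the age draws.
#' @return An object of class `mobility_estimate`: `sample_id`, the
#'   per-run `data.frame` `runs` (run, age_draw, slice_time, vector
#'   fields), `mean_dx`, `mean_dy`, `mean_length_km`, `mean_direction_deg`,
#'   `sd_length_km`, and the 2-sigma age bounds.
#' @export
per_sample_mobility <- function(sample, z, model, bbox, spacing,
                                retrospection = 667, n_runs = 25,
                                seed = 1) {
  stopifnot(retrospection > 0, n_runs >= 1)
  ages <- resample_ages(sample, n = n_runs, seed = seed)
  burial <- c(as.numeric(sample$x), as.numeric(sample$y))
  eta <- vapply(model$components, function(cm) cm$params$eta, numeric(1))
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    slice_time <- ages[r] - retrospection
    res <- tryCatch({
      slice <- predict_field_grid(model, bbox, spacing, slice_time)[[1]]
      surf <- similarity_surface(z, slice, eta,
                                 sample_id = as.character(sample$sample_id))
      cbind(data.frame(run = r, age_draw = ages[r]),
            mobility_vector(burial, surf))
    }, error = function(e) e)
    runs[[r]] <- res
  }
  failed <- vapply(runs, inherits, logical(1), "error")
  if (all(failed)) {
    stop("all ", n_runs, " runs failed for sample ", sample$sample_id,
         "; first error: ", conditionMessage(runs[[1]]))
  }
  if (any(failed)) {
    warning(sum(failed), " run(s) failed for sample ", sample$sample_id,
            " and were excluded")
  }
  runs <- do.call(rbind, runs[!failed])
  mean_dx <- mean(runs$dx)
  mean_dy <- mean(runs$dy)
  mean_len <- sqrt(mean_dx^2 + mean_dy^2) / 1000
  mean_dir <- if (mean_len > 0) (atan2(mean_dx, mean_dy) * 180 / pi) %% 360
  else NA_real_
  structure(list(sample_id = as.character(sample$sample_id), runs = runs,
                 mean_dx = mean_dx, mean_dy = mean_dy,
                 mean_length_km = mean_len, mean_direction_deg = mean_dir,
                 sd_length_km = if (nrow(runs) > 1) {
                   stats::sd(runs$length_km)
                 } else 0,
                 age_lo = as.numeric(sample$age_lo),
                 age_hi = as.numeric(sample$age_hi)),
            class = "mobility_estimate")
}

#' @export
print.mobility_estimate <- function(x, ...) {
  cat("<mobility_estimate> sample ", x$sample_id, ": mean vector ",
      format(x$mean_length_km, digits = 4), " km",
      if (!is.na(x$mean_direction_deg)) {
        paste0(" at ", format(x$mean_direction_deg, digits = 4), " deg")
      }, " over ", nrow(x$runs), " runs\n", sep = "")
  invisible(x)
}

#' Regional diachronic mobility series
#'
#' Moving mean of mobility-vector lengths in centred time windows. The
#' window anchor of a run is its resampled sample age (the quantity plotted
#' on the regional time axis), and by default every resampled run
#' contributes equally to the mean ("runs" pooling); "samples" pooling
#' averages per-sample mean lengths instead. The uncertainty band is twice
#' the standard error of the per-sample mean lengths in the window, and is
#' infinite when a window holds fewer than two samples.
#'
#' @param estimates List of [per_sample_mobility()] results (one region).
#' @param window Window width in years (default 400).
#' @param step Window step in years (default 50; the step is a
#'   visualisation grain the source method leaves open).
#' @param pool `"runs"` (default) or `"samples"`.
#' @param region_tag Optional label carried into the output.
#' @return A `data.frame` with `region_tag`, `center`, `mean_length_km`,
#'   `band_halfwidth_km` (`Inf` when `n_samples < 2`), `n_samples`,
#'   `n_runs`.
#' @export
regional_series <- function(estimates, window = 400, step = 50,
                            pool = c("runs", "samples"),
                            region_tag = NA_character_) {
  pool <- match.arg(pool)
  if (length(estimates) == 0) {
    return(data.frame(region_tag = character(0), center = numeric(0),
                      mean_length_km = numeric(0),
                      band_halfwidth_km = numeric(0),
                      n_samples = integer(0), n_runs = integer(0)))
  }
  runs <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(sample_id = e$sample_id, age = e$runs$age_draw,
               length_km = e$runs$length_km,
               sample_mean_length = mean(e$runs$length_km))
  }))
  centers <- seq(floor(min(runs$age) / step) * step,
                 ceiling(max(runs$age) / step) * step, by = step)
  rows <- lapply(centers, function(ct) {
    sel <- runs$age >= ct - window / 2 & runs$age < ct + window / 2
    w <- runs[sel, , drop = FALSE]
    n_samp <- length(unique(w$sample_id))
    per_sample_means <- tapply(w$length_km, w$sample_id, mean)
    mean_len <- if (nrow(w) == 0) NA_real_ else if (pool == "runs") {
      mean(w$length_km)
    } else {
      mean(per_sample_means)
    }
    band <- if (n_samp < 2) Inf else {
      2 * stats::sd(per_sample_means) / sqrt(n_samp)
    }
    data.frame(region_tag = region_tag, center = ct,
               mean_length_km = mean_len, band_halfwidth_km = band,
               n_samples = n_samp, n_runs = nrow(w))
  })
  do.call(rbind, rows)
}

#' Compass-bin counts of mobility-vector directions
#'
#' Equal-width half-open bins starting at North (`[0, 360/n)`, ...),
#' zero-length vectors (undefined direction) excluded.
#'
#' @param vectors A `data.frame` with a `direction_deg` column (e.g.
#'   stacked [mobility_vector()] rows), or a numeric vector of bearings.
#' @param n_bins Number of bins (default 8).
#' @return Integer vector of counts named by bin start angle.
#' @export
direction_bins <- function(vectors, n_bins = 8) {
  stopifnot(n_bins >= 2)
  dirs <- if (is.data.frame(vectors)) vectors$direction_deg else vectors
  dirs <- dirs[!is.na(dirs)] %% 360
  width <- 360 / n_bins
  idx <- floor(dirs / width) + 1
  counts <- tabulate(idx, nbins = n_bins)
  names(counts) <- format(width * (seq_len(n_bins) - 1))
  counts
}
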