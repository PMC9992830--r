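#' Run the full mobility-estimation pipeline
#'
#' Fits the spatiotemporal Gaussian-process ancestry field on all supplied
#' samples and derives, for each sample (optionally restricted to a
#' median-age window), a resampled mobility estimate. Per-sample RNG seeds
#' are drawn once from the pipeline seed, so the whole run — including the
#' exported result table — is a deterministic function of inputs, settings
#' and seed.
#'
#' @param samples A sample table with planar `x`, `y` filled.
#' @param ancestry An `ancestry_coords` object covering (at least) the
#'   samples; matched by `sample_id`.
#' @param params Kernel parameters (single [kernel_params()] or
#'   per-component list).
#' @param bbox,spacing Analysis grid in planar meters.
#' @param retrospection Retrospection distance in years (default 667).
#' @param n_runs Age resampling runs per sample (default 25).
#' @param seed Integer pipeline seed.
#' @param age_window Optional `c(from, to)`: only samples whose median age
#'   falls inside (inclusive) are estimated.
#' @return List with `model` (the fitted `gp_model`), `estimates` (list of
#'   `mobility_estimate`), and `result_table` (long-format `data.frame`,
#'   one row per sample and run; see [write_results()]).
#' @export
run_mobility_pipeline <- function(samples, ancestry, params, bbox, spacing,
                                  retrospection = 667, n_runs = 25,
                                  seed = 1, age_window = NULL) {
  validate_sample_table(samples)
  stopifnot(inherits(ancestry, "ancestry_coords"))
  idx <- match(samples$sample_id, ancestry$sample_ids)
  if (anyNA(idx)) {
    stop("no ancestry coordinates for sample(s): ",
         paste(samples$sample_id[is.na(idx)], collapse = ", "))
  }
  Z <- ancestry$coords[idx, , drop = FALSE]
  model <- fit_gp(cbind(samples$x, samples$y, samples$age_median), Z,
                  params)

  targets <- seq_len(nrow(samples))
  if (!is.null(age_window)) {
    targets <- which(samples$age_median >= age_window[1] &
                       samples$age_median <= age_window[2])
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1, nrow(samples))
  if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }

  estimates <- vector("list", length(targets))
  rows <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    s <- targets[i]
    est <- per_sample_mobility(samples[s, , drop = FALSE], Z[s, ], model,
                               bbox, spacing,
                               retrospection = retrospection,
                               n_runs = n_runs, seed = sample_seeds[s])
    estimates[[i]] <- est
    rows[[i]] <- cbind(data.frame(sample_id = est$sample_id),
                       est$runs[, c("run", "age_draw", "slice_time",
                                    "origin_x", "origin_y", "dx", "dy",
                                    "length_km", "direction_deg", "tie")])
  }
  result_table <- do.call(rbind, rows)
  rownames(result_table) <- NULL
  validate_result_table(result_table)
  list(model = model, estimates = estimates, result_table = result_table)
}
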