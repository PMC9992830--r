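# Synthetic spatiotemporal ancestry datasets: spatially structured
# populations with drifting ancestry centroids, observation noise and
# discrete migration events, so the field/similarity/mobility machinery is
# testable end-to-end without external data.

#' Build a simulation configuration
#'
#' @param regions Named list of rectangles `c(xmin, xmax, ymin, ymax)` in
#'   planar meters.
#' @param populations Named list; each element a list with `region` (name
#'   into `regions`), `n` (non-migrant sample count), `window`
#'   `c(t_from, t_to)` in years, and `centroid` — a `data.frame` with a
#'   `t` column and one column per ancestry component, interpolated
#'   piecewise-linearly over time (a single row means a stable centroid).
#' @param noise_sd Per-component observation noise sd (recycled).
#' @param migrations List of migration events, each a list with `source`
#'   (population name), `dest_region` (region name), `time` (years) and
#'   `n` (migrant count). May be empty.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(regions, populations, noise_sd, migrations = list(),
                       seed = 1) {
  stopifnot(length(regions) >= 1, length(populations) >= 1)
  if (any(noise_sd <= 0)) stop("noise sd must be > 0")
  for (p in populations) {
    if (!p$region %in% names(regions)) {
      stop("population region '", p$region, "' is not a configured region")
    }
    if (p$n < 0) stop("negative sampling budget")
  }
  spans <- range(unlist(lapply(populations, `[[`, "window")))
  for (m in migrations) {
    if (!m$source %in% names(populations)) {
      stop("migration source '", m$source, "' is not a population")
    }
    if (!m$dest_region %in% names(regions)) {
      stop("migration destination '", m$dest_region,
           "' is not a configured region")
    }
    if (m$time < spans[1] || m$time > spans[2]) {
      stop("migration time ", m$time, " outside the simulated span")
    }
  }
  structure(list(regions = regions, populations = populations,
                 noise_sd = noise_sd, migrations = migrations, seed = seed),
            class = "sim_config")
}

centroid_at <- function(centroid, tt) {
  comp_cols <- setdiff(names(centroid), "t")
  if (nrow(centroid) == 1) {
    return(as.numeric(centroid[1, comp_cols]))
  }
  vapply(comp_cols, function(cc) {
    stats::approx(centroid$t, centroid[[cc]], xout = tt, rule = 2)$y
  }, numeric(1))
}

#' The documented reference scenario: two adjacent populations
#'
#' Two adjacent 500 km x 500 km regions with temporally stable ancestry
#' centroids separated by four observation-noise standard deviations in
#' component space, 100 non-migrant samples per population spread over
#' 2,000 years, and 20 migrants (source population A buried in region B)
#' at mid-span. The attached `pipeline` element carries the kernel, grid
#' and retrospection settings used to analyse it: 250 km spatial and 500 y
#' temporal lengthscales, process variance matching the between-population
#' component variance, nugget equal to the observation-noise variance,
#' 25 km grid, 500 y retrospection.
#'
#' @param seed Integer seed.
#' @return A `sim_config` with an extra `pipeline` element.
#' @export
two_pop_reference <- function(seed = 1) {
  km <- 1000
  noise <- 0.05
  cfg <- sim_config(
    regions = list(A = c(0, 500 * km, 0, 500 * km),
                   B = c(500 * km, 1000 * km, 0, 500 * km)),
    populations = list(
      A = list(region = "A", n = 100, window = c(-4000, -2000),
               centroid = data.frame(t = 0, C1 = 0, C2 = 0)),
      B = list(region = "B", n = 100, window = c(-4000, -2000),
               centroid = data.frame(t = 0, C1 = 4 * noise, C2 = 0))),
    noise_sd = noise,
    migrations = list(list(source = "A", dest_region = "B", time = -3000,
                           n = 20)),
    seed = seed)
  cfg$pipeline <- list(
    params = kernel_params(theta_x = (250 * km)^2,
                           theta_y = (250 * km)^2,
                           theta_t = 500^2,
                           tau2 = (2 * noise)^2, eta = noise^2),
    bbox = c(0, 1000 * km, 0, 500 * km),
    spacing = 25 * km,
    retrospection = 500)
  cfg
}

#' Simulate a spatiotemporal ancestry dataset
#'
#' Non-migrants get a uniform random location in their population's region
#' and a uniform age in its window; their ancestry is the population
#' centroid at that age plus independent Gaussian noise per component.
#' Migrants are buried in the destination region at the event time but
#' carry ancestry drawn around the *source* population's centroid — the
#' displaced individuals the origin-recovery analysis must detect.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_dataset`: `samples` (a sample table with
#'   planar coordinates and point-mass ages), `ancestry` (an
#'   `ancestry_coords` object), and `truth` (`data.frame` with
#'   `sample_id`, `population`, `is_migrant`, `source_population`,
#'   `source_region`, `sampling_region`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  comp_cols <- setdiff(names(cfg$populations[[1]]$centroid), "t")
  k <- length(comp_cols)
  noise <- rep_len(cfg$noise_sd, k)
  rows <- list()
  coords <- list()
  truth <- list()
  counter <- 0

  draw_point <- function(rect) {
    c(stats::runif(1, rect[1], rect[2]), stats::runif(1, rect[3], rect[4]))
  }

  for (pn in names(cfg$populations)) {
    p <- cfg$populations[[pn]]
    rect <- cfg$regions[[p$region]]
    for (i in seq_len(p$n)) {
      counter <- counter + 1
      id <- sprintf("%s_%03d", pn, i)
      loc <- draw_point(rect)
      age <- stats::runif(1, p$window[1], p$window[2])
      z <- centroid_at(p$centroid, age) + stats::rnorm(k, 0, noise)
      rows[[counter]] <- data.frame(sample_id = id, x = loc[1], y = loc[2],
                                    age = age, region = p$region)
      coords[[counter]] <- z
      truth[[counter]] <- data.frame(sample_id = id, population = pn,
                                     is_migrant = FALSE,
                                     source_population = NA_character_,
                                     source_region = NA_character_,
                                     sampling_region = p$region)
    }
  }
  for (mi in seq_along(cfg$migrations)) {
    m <- cfg$migrations[[mi]]
    src <- cfg$populations[[m$source]]
    rect <- cfg$regions[[m$dest_region]]
    if (identical(src$region, m$dest_region)) {
      stop("migration ", mi, " has source region equal to destination")
    }
    for (i in seq_len(m$n)) {
      counter <- counter + 1
      id <- sprintf("mig%d_%03d", mi, i)
      loc <- draw_point(rect)
      z <- centroid_at(src$centroid, m$time) + stats::rnorm(k, 0, noise)
      rows[[counter]] <- data.frame(sample_id = id, x = loc[1], y = loc[2],
                                    age = m$time, region = m$dest_region)
      coords[[counter]] <- z
      truth[[counter]] <- data.frame(sample_id = id, population = m$source,
                                     is_migrant = TRUE,
                                     source_population = m$source,
                                     source_region = src$region,
                                     sampling_region = m$dest_region)
    }
  }
  base <- do.call(rbind, rows)
  samples <- data.frame(sample_id = base$sample_id,
                        lon = NA_real_, lat = NA_real_,
                        x = base$x, y = base$y,
                        age_median = base$age, age_lo = base$age,
                        age_hi = base$age,
                        n_autosomal_snps = 1e5,
                        molecular_sex = "female",
                        x_contamination = NA_real_,
                        region_tag = base$region,
                        stringsAsFactors = FALSE)
  cm <- do.call(rbind, coords)
  dimnames(cm) <- list(samples$sample_id, paste0("C", seq_len(k)))
  ancestry <- structure(list(sample_ids = samples$sample_id, coords = cm,
                             eigenvalues = rep(NA_real_, k)),
                        class = "ancestry_coords")
  structure(list(samples = samples, ancestry = ancestry,
                 truth = do.call(rbind, truth), regions = cfg$regions),
            class = "sim_dataset")
}

point_in_rect <- function(x, y, rect) {
  x >= rect[1] & x <= rect[2] & y >= rect[3] & y <= rect[4]
}

#' Can the similarity search recover migrants' regions of origin?
#'
#' Fits the ancestry field on the non-migrant samples only, then computes
#' each migrant's similarity surface in the slice `retrospection` years
#' before its age and asks whether the maximum-probability point falls
#' inside the true source region. Surfaces whose maximum is tied are
#' flagged ambiguous and never counted as recovered.
#'
#' @param sim A [simulate_dataset()] result containing migrants.
#' @param params Kernel parameters for the field fit (single
#'   [kernel_params()] or per-component list).
#' @param bbox,spacing Analysis grid (planar meters).
#' @param retrospection Years to look back (default 500).
#' @return List with `per_migrant` (`data.frame`: `sample_id`, `max_x`,
#'   `max_y`, `tie`, `recovered`) and `fraction_recovered` over all
#'   migrants.
#' @export
evaluate_origin_recovery <- function(sim, params, bbox, spacing,
                                     retrospection = 500) {
  stopifnot(inherits(sim, "sim_dataset"))
  mig <- sim$truth$is_migrant
  if (!any(mig)) stop("simulation contains no migrants")
  train <- which(!mig)
  model <- fit_gp(cbind(sim$samples$x[train], sim$samples$y[train],
                        sim$samples$age_median[train]),
                  sim$ancestry$coords[train, , drop = FALSE], params)
  eta <- vapply(model$components, function(cm) cm$params$eta, numeric(1))
  mig_idx <- which(mig)
  slice_times <- sim$samples$age_median[mig_idx] - retrospection
  slices <- lapply(unique(slice_times), function(tt) {
    predict_field_grid(model, bbox, spacing, tt)[[1]]
  })
  names(slices) <- as.character(unique(slice_times))
  rows <- lapply(seq_along(mig_idx), function(i) {
    s <- mig_idx[i]
    surf <- similarity_surface(sim$ancestry$coords[s, ],
                               slices[[as.character(slice_times[i])]], eta,
                               sample_id = sim$samples$sample_id[s])
    mp <- max_similarity_point(surf)
    data.frame(sample_id = sim$samples$sample_id[s], max_x = mp$x,
               max_y = mp$y, tie = mp$tie,
               source_region = sim$truth$source_region[s])
  })
  per <- do.call(rbind, rows)
  regions <- sim$regions
  per$recovered <- FALSE
  for (i in seq_len(nrow(per))) {
    rect <- regions[[per$source_region[i]]]
    per$recovered[i] <- !per$tie[i] &&
      point_in_rect(per$max_x[i], per$max_y[i], rect)
  }
  list(per_migrant = per, fraction_recovered = mean(per$recovered))
}

#' Two-population genotype fixture
#'
#' Generates biallelic genotypes for two populations whose per-locus
#' alternate-allele frequencies differ by a fixed shift (an FST-like
#' divergence knob), for exercising the IBS-distance and MDS stages.
#' Genotypes are binomial(2, freq); deterministic given the seed.
#'
#' @param n_per_pop Samples per population.
#' @param n_loci Number of loci (>= 10).
#' @param fst_like_divergence Allele-frequency shift between the two
#'   populations, in `[0, 0.9]`; population 1 frequencies are uniform in
#'   `[0.05, 0.95]` and population 2 frequencies are shifted and clamped
#'   to that range.
#' @param seed Integer seed.
#' @return List with `genotypes` (a [genotype_matrix()]) and `labels`
#'   (character vector `"pop1"` / `"pop2"`).
#' @export
make_genotype_fixture <- function(n_per_pop, n_loci, fst_like_divergence,
                                  seed = 1) {
  if (n_loci < 10) stop("need at least 10 loci")
  if (fst_like_divergence < 0 || fst_like_divergence > 0.9) {
    stop("fst_like_divergence must be in [0, 0.9]")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  p1 <- stats::runif(n_loci, 0.05, 0.95)
  p2 <- pmin(pmax(p1 + fst_like_divergence, 0.05), 0.95)
  calls <- cbind(
    matrix(stats::rbinom(n_loci * n_per_pop, 2, p1), nrow = n_loci),
    matrix(stats::rbinom(n_loci * n_per_pop, 2, p2), nrow = n_loci))
  ids <- c(sprintf("pop1_%03d", seq_len(n_per_pop)),
           sprintf("pop2_%03d", seq_len(n_per_pop)))
  loci <- data.frame(id = sprintf("rs%05d", seq_len(n_loci)),
                     chrom = "1", pos = seq_len(n_loci) * 1000L,
                     stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(calls, ids, loci),
       labels = rep(c("pop1", "pop2"), each = n_per_pop))
}
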