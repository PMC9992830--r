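test_that("age resampling honours point masses, pmfs and bounds", {
  pt <- list(age_median = -3000, age_lo = -3000, age_hi = -3000)
  expect_equal(resample_ages(pt, n = 7, seed = 1), rep(-3000, 7))

  pm <- list(age_median = -3000, age_lo = -3100, age_hi = -2900,
             age_pmf = data.frame(year = -3000, probability = 1))
  expect_equal(resample_ages(pm, n = 5, seed = 2), rep(-3000, 5))

  pmf2 <- list(age_median = -3000, age_lo = -3100, age_hi = -2900,
               age_pmf = data.frame(year = c(-3100, -2900),
                                    probability = c(0.25, 0.75)))
  draws <- resample_ages(pmf2, n = 4000, seed = 3)
  expect_true(all(draws %in% c(-3100, -2900)))
  expect_equal(mean(draws == -2900), 0.75, tolerance = 0.03)

  # truncated normal: inside bounds, unbiased, deterministic given seed
  tn <- list(age_median = -3000, age_lo = -3200, age_hi = -2800)
  d1 <- resample_ages(tn, n = 10000, seed = 4)
  expect_true(all(d1 >= -3200 & d1 <= -2800))
  se <- (3200 - 2800) / 4 / sqrt(10000)
  expect_lt(abs(mean(d1) - (-3000)), 3 * se)
  expect_identical(d1, resample_ages(tn, n = 10000, seed = 4))
  expect_false(identical(d1[1:10], resample_ages(tn, n = 10, seed = 5)))
})

fixed_surface <- function(peak_cell, ncell = 5, spacing = 1e5,
                          time = -3000) {
  p <- rep(1e-6, ncell)
  p[peak_cell] <- 1 - sum(p[-peak_cell])
  structure(list(sample_id = "s", slice_time = time,
                 x = spacing / 2 + (seq_len(ncell) - 1) * spacing,
                 y = rep(spacing / 2, ncell), nx = ncell, ny = 1,
                 spacing = spacing, probability = p),
            class = "similarity_surface")
}

test_that("mobility vectors follow compass arithmetic", {
  surf <- fixed_surface(1)
  # max at the burial cell: zero length, undefined direction
  v0 <- mobility_vector(c(surf$x[1], surf$y[1]), surf)
  expect_equal(v0$length_km, 0)
  expect_true(is.na(v0$direction_deg))

  # origin 100 km due east -> 90 degrees
  v_east <- mobility_vector(c(surf$x[2] - 1e5, surf$y[2]),
                            fixed_surface(2))
  expect_equal(v_east$length_km, 100, tolerance = 1e-9)
  expect_equal(v_east$direction_deg, 90, tolerance = 1e-9)

  # 30/40/50 right triangle -> atan2(30, 40) = 36.8699 degrees
  v_tri <- mobility_vector(c(surf$x[3] - 3e4, surf$y[3] - 4e4),
                           fixed_surface(3))
  expect_equal(v_tri$length_km, 50, tolerance = 1e-9)
  expect_equal(v_tri$direction_deg, atan2(30, 40) * 180 / pi,
               tolerance = 1e-9)

  # due north and due west axis cases
  v_n <- mobility_vector(c(surf$x[2], surf$y[2] - 5e4), fixed_surface(2))
  expect_equal(v_n$direction_deg, 0)
  v_w <- mobility_vector(c(surf$x[2] + 7e4, surf$y[2]), fixed_surface(2))
  expect_equal(v_w$direction_deg, 270)
})

test_that("per-sample mobility slices at resampled age minus retrospection", {
  fx <- random_gp_fixture(n = 25, seed = 8)
  model <- fit_gp(fx$X, fx$y, fx$params)
  samp <- data.frame(sample_id = "a", x = 5e5, y = 5e5,
                     age_median = -3000, age_lo = -3000, age_hi = -3000)
  est <- per_sample_mobility(samp, z = 0.1, model, bbox = c(0, 1e6, 0, 1e6),
                             spacing = 2e5, retrospection = 667,
                             n_runs = 1, seed = 1)
  expect_equal(est$runs$slice_time, -3667)
  expect_equal(nrow(est$runs), 1)
  expect_equal(est$mean_length_km, est$runs$length_km)
  expect_equal(est$sd_length_km, 0)

  # point-mass age: all runs identical -> sd of lengths 0, mean = single
  est3 <- per_sample_mobility(samp, z = 0.1, model, c(0, 1e6, 0, 1e6),
                              2e5, retrospection = 667, n_runs = 3,
                              seed = 2)
  expect_equal(est3$sd_length_km, 0)
  expect_equal(est3$mean_length_km, est3$runs$length_km[1])
})

test_that("opposite equal-length vectors cancel in the mean vector", {
  runs <- data.frame(run = 1:2, age_draw = c(-3000, -3000),
                     dx = c(1e5, -1e5), dy = c(0, 0),
                     length_km = c(100, 100))
  # arithmetic the estimate summary must honour
  expect_equal(sqrt(mean(runs$dx)^2 + mean(runs$dy)^2) / 1000, 0)
  expect_equal(sd(runs$length_km), 0)
})

test_that("mean-vector length never exceeds the mean run length", {
  fx <- random_gp_fixture(n = 30, seed = 21)
  model <- fit_gp(fx$X, fx$y, fx$params)
  for (seed in 1:4) {
    samp <- data.frame(sample_id = "b", x = 3e5, y = 4e5,
                       age_median = -2500, age_lo = -2900, age_hi = -2100)
    est <- per_sample_mobility(samp, z = 0.2, model, c(0, 1e6, 0, 1e6),
                               1e5, retrospection = 500, n_runs = 8,
                               seed = seed)
    expect_lte(est$mean_length_km, mean(est$runs$length_km) + 1e-9)
    expect_lte(est$mean_length_km, max(est$runs$length_km) + 1e-9)
  }
})

make_estimate <- function(id, ages, lengths) {
  structure(list(sample_id = id,
                 runs = data.frame(run = seq_along(ages), age_draw = ages,
                                   length_km = lengths),
                 mean_length_km = mean(lengths),
                 sd_length_km = sd(lengths)),
            class = "mobility_estimate")
}

test_that("regional series matches hand-computed moving mean and SE", {
  # 3 samples x 2 runs, all ages inside one 400-y window centred at -3000
  es <- list(make_estimate("a", c(-3000, -3000), c(10, 20)),
             make_estimate("b", c(-2950, -2950), c(30, 30)),
             make_estimate("c", c(-3050, -3050), c(50, 70)))
  rs <- regional_series(es, window = 400, step = 50)
  w <- rs[rs$center == -3000, ]
  expect_equal(w$mean_length_km, mean(c(10, 20, 30, 30, 50, 70)))
  means <- c(15, 30, 60)
  expect_equal(w$band_halfwidth_km, 2 * sd(means) / sqrt(3))
  expect_equal(w$n_samples, 3)
  expect_equal(w$n_runs, 6)
  # sample-level pooling averages the per-sample means instead
  rs_s <- regional_series(es, window = 400, step = 50, pool = "samples")
  expect_equal(rs_s$mean_length_km[rs_s$center == -3000], mean(means))
})

test_that("windows with a single sample get an infinite band", {
  es <- list(make_estimate("solo", c(-3000, -2990), c(10, 12)))
  rs <- regional_series(es, window = 400, step = 100)
  expect_true(all(is.infinite(rs$band_halfwidth_km[rs$n_samples == 1])))
  # all lengths equal -> zero band once two samples share a window
  es2 <- c(es, list(make_estimate("twin", c(-3000, -2990), c(11, 11))))
  rs2 <- regional_series(es2, window = 400, step = 100)
  two <- rs2[rs2$n_samples == 2, ]
  expect_true(all(is.finite(two$band_halfwidth_km)))
  expect_equal(regional_series(list())$center, numeric(0))
})

test_that("direction bins use half-open compass sectors from North", {
  expect_equal(unname(direction_bins(c(90), 4)), c(0, 1, 0, 0))
  expect_equal(unname(direction_bins(c(0), 4)), c(1, 0, 0, 0))
  expect_equal(unname(direction_bins(c(359.9), 4)), c(0, 0, 0, 1))
  # zero-length vectors (NA direction) are excluded
  df <- data.frame(direction_deg = c(NA, 45, 225))
  expect_equal(unname(direction_bins(df, 4)), c(1, 0, 1, 0))
  # scan oracle on uniform directions
  set.seed(101)
  dirs <- runif(1000, 0, 360)
  counts <- direction_bins(dirs, 8)
  brute <- table(cut(dirs, seq(0, 360, 45), right = FALSE))
  expect_equal(unname(counts), as.vector(brute))
  expect_equal(sum(counts), 1000)
})
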