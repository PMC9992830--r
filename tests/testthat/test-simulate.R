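test_that("the same seed reproduces the dataset bit for bit", {
  a <- simulate_dataset(two_pop_reference(seed = 5))
  b <- simulate_dataset(two_pop_reference(seed = 5))
  expect_identical(a$samples, b$samples)
  expect_identical(a$ancestry$coords, b$ancestry$coords)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_dataset(two_pop_reference(seed = 6))
  expect_false(identical(a$samples$x, c_$samples$x))
})

test_that("the noiseless limit collapses samples onto their centroids", {
  km <- 1000
  cfg <- sim_config(
    regions = list(R = c(0, 100 * km, 0, 100 * km)),
    populations = list(P = list(region = "R", n = 10,
                                window = c(-1000, 0),
                                centroid = data.frame(t = c(-1000, 0),
                                                      C1 = c(0, 1)))),
    noise_sd = 1e-12, seed = 2)
  sim <- simulate_dataset(cfg)
  # piecewise-linear centroid: C1 = (age + 1000) / 1000
  expect_equal(drop(sim$ancestry$coords),
               (sim$samples$age_median + 1000) / 1000, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("samples sit nearer their own centroid than the other's", {
  km <- 1000
  cfg <- sim_config(
    regions = list(A = c(0, 500 * km, 0, 500 * km),
                   B = c(500 * km, 1000 * km, 0, 500 * km)),
    populations = list(
      A = list(region = "A", n = 250, window = c(-2000, 0),
               centroid = data.frame(t = 0, C1 = 0, C2 = 0)),
      B = list(region = "B", n = 250, window = c(-2000, 0),
               centroid = data.frame(t = 0, C1 = 1, C2 = 1))),
    noise_sd = 0.05, seed = 3)
  sim <- simulate_dataset(cfg)
  own <- rbind(matrix(0, 250, 2), matrix(1, 250, 2))
  other <- rbind(matrix(1, 250, 2), matrix(0, 250, 2))
  d_own <- sqrt(rowSums((sim$ancestry$coords - own)^2))
  d_other <- sqrt(rowSums((sim$ancestry$coords - other)^2))
  expect_gte(mean(d_own < d_other), 0.99)
})

test_that("migrant bookkeeping marks source != sampling region", {
  sim <- simulate_dataset(two_pop_reference(seed = 7))
  mig <- sim$truth[sim$truth$is_migrant, ]
  expect_equal(nrow(mig), 20)
  expect_true(all(mig$source_region != mig$sampling_region))
  expect_true(all(sim$samples$region_tag[sim$truth$is_migrant] == "B"))
  non <- sim$truth[!sim$truth$is_migrant, ]
  expect_equal(nrow(non), 200)
  expect_true(all(is.na(non$source_region)))
  # locations fall inside the configured sampling regions
  cfg <- two_pop_reference(seed = 7)
  for (rn in names(cfg$regions)) {
    r <- cfg$regions[[rn]]
    sel <- sim$samples$region_tag == rn
    expect_true(all(sim$samples$x[sel] >= r[1] & sim$samples$x[sel] <= r[2]))
    expect_true(all(sim$samples$y[sel] >= r[3] & sim$samples$y[sel] <= r[4]))
  }
})

test_that("config validation rejects inconsistent setups", {
  km <- 1000
  regions <- list(A = c(0, km, 0, km))
  pops <- list(P = list(region = "A", n = 5, window = c(-100, 0),
                        centroid = data.frame(t = 0, C1 = 0)))
  expect_error(sim_config(regions, pops, noise_sd = 0), "noise")
  expect_error(sim_config(regions,
                          list(P = modifyList(pops$P, list(region = "Z"))),
                          0.1), "not a configured region")
  expect_error(sim_config(regions, pops, 0.1,
                          migrations = list(list(source = "P",
                                                 dest_region = "A",
                                                 time = 500, n = 1))),
               "outside the simulated span")
})

test_that("migrants from a unique source centroid are recovered", {
  cfg <- two_pop_reference(seed = 11)
  sim <- simulate_dataset(cfg)
  pl <- cfg$pipeline
  rec <- evaluate_origin_recovery(sim, pl$params, pl$bbox, pl$spacing,
                                  pl$retrospection)
  expect_gte(rec$fraction_recovered, 0.9)
  expect_equal(nrow(rec$per_migrant), 20)
  expect_error(evaluate_origin_recovery(
    structure(list(truth = data.frame(is_migrant = FALSE)),
              class = "sim_dataset"),
    pl$params, pl$bbox, pl$spacing), "no migrants")
})

test_that("recovery degrades as noise grows or centroids converge", {
  km <- 1000
  run_frac <- function(sep_sds, noise) {
    cfg <- two_pop_reference(seed = 13)
    cfg$noise_sd <- noise
    cfg$populations$B$centroid$C1 <- sep_sds * noise
    sim <- simulate_dataset(cfg)
    pl <- cfg$pipeline
    pl$params$eta <- noise^2
    evaluate_origin_recovery(sim, pl$params, pl$bbox, pl$spacing,
                             pl$retrospection)$fraction_recovered
  }
  # shrinking the donor/receptor separation cannot improve recovery
  f_wide <- run_frac(4, 0.05)
  f_narrow <- run_frac(0.5, 0.05)
  expect_lte(f_narrow, f_wide)
})

test_that("genotype fixtures expose the configured divergence", {
  fx <- make_genotype_fixture(1, 20, 0.3, seed = 1)
  D <- ibs_distance_matrix(fx$genotypes)
  expect_equal(dim(D$d), c(2, 2))
  expect_equal(unname(diag(D$d)), c(0, 0))
  expect_equal(D$d[1, 2], D$d[2, 1])

  # no divergence: between ~ within distance
  fx0 <- make_genotype_fixture(20, 800, 0, seed = 2)
  D0 <- ibs_distance_matrix(fx0$genotypes)
  same <- outer(fx0$labels, fx0$labels, "==") & upper.tri(D0$d)
  diff_ <- outer(fx0$labels, fx0$labels, "!=") & upper.tri(D0$d)
  expect_lt(abs(mean(D0$d[same]) - mean(D0$d[diff_])), 0.01)

  # strong divergence: MDS axis 1 separates the populations by sign
  fx3 <- make_genotype_fixture(25, 2000, 0.3, seed = 3)
  ac <- classical_mds(ibs_distance_matrix(fx3$genotypes), k = 2)
  side <- ac$coords[, 1] > 0
  acc <- max(mean(side == (fx3$labels == "pop1")),
             mean(side == (fx3$labels == "pop2")))
  expect_gte(acc, 0.95)

  expect_error(make_genotype_fixture(5, 5, 0.1), "at least 10 loci")
  expect_error(make_genotype_fixture(5, 100, 2), "0, 0.9")
})
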