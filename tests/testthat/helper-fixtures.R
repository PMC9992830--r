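# Shared fixtures and independent oracles.

# A valid sample table built in code.
make_sample_table <- function(n = 3, seed = 1) {
  set.seed(seed)
  med <- runif(n, -6000, 1000)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             lon = runif(n, -5, 25), lat = runif(n, 40, 58),
             x = NA_real_, y = NA_real_,
             age_median = med, age_lo = med - 100, age_hi = med + 100,
             n_autosomal_snps = round(runif(n, 3e4, 9e5)),
             molecular_sex = sample(c("male", "female"), n, TRUE),
             x_contamination = runif(n, 0, 0.05),
             region_tag = "test",
             stringsAsFactors = FALSE)
}

# Random space-time design plus random valid kernel, for GP fixtures.
random_gp_fixture <- function(n = 20, seed = 1, eta_zero = FALSE) {
  set.seed(seed)
  X <- cbind(runif(n, 0, 1e6), runif(n, 0, 1e6), runif(n, -5000, 0))
  p <- kernel_params(theta_x = runif(1, 1e10, 1e12),
                     theta_y = runif(1, 1e10, 1e12),
                     theta_t = runif(1, 1e5, 1e7),
                     tau2 = runif(1, 0.5, 2),
                     eta = if (eta_zero) 0 else runif(1, 0.01, 0.2))
  K <- mobfield:::kernel_matrix(X, X, p, symmetric = TRUE)
  y <- drop(t(chol(K + diag(1e-10, n))) %*% rnorm(n))
  list(X = X, y = y, params = p)
}

# Independent dense-inverse GP oracle: explicit kernel formula, solve(),
# no code shared with the package's factorized path.
gp_oracle_predict <- function(X, y, Xq, p) {
  kv <- function(a, b) {
    d2 <- (a[1] - b[1])^2 / p$theta_x + (a[2] - b[2])^2 / p$theta_y +
      (a[3] - b[3])^2 / p$theta_t
    p$tau2 * exp(-d2) + if (all(a == b)) p$eta else 0
  }
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- kv(X[i, ], X[j, ])
  Kinv <- solve(K)
  off <- mean(y)
  t(apply(Xq, 1, function(q) {
    ks <- vapply(seq_len(n), function(i) kv(X[i, ], q), numeric(1))
    m <- off + drop(ks %*% Kinv %*% (y - off))
    v <- p$tau2 + p$eta - drop(ks %*% Kinv %*% ks)
    c(mean = m, sd = sqrt(max(v, 0)))
  }))
}

# A field slice built directly (bypassing a GP fit) for similarity tests.
make_slice <- function(mu, sd_, time = -1000, spacing = 50000) {
  ncell <- length(mu) / ncol(as.matrix(mu))
  mu <- as.matrix(mu)
  sd_ <- matrix(sd_, nrow = nrow(mu), ncol = ncol(mu))
  nx <- nrow(mu)
  structure(list(time = time,
                 x = spacing / 2 + (seq_len(nx) - 1) * spacing,
                 y = rep(spacing / 2, nx),
                 nx = nx, ny = 1, spacing = spacing,
                 mean = mu, sd = sd_),
            class = "field_slice")
}

# Random similarity surface via random 1-row-grid field and sample value.
random_surface <- function(ncell = 40, k = 2, seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(ncell * k), ncell, k)
  sd_ <- matrix(runif(ncell * k, 0.2, 1), ncell, k)
  slice <- make_slice(mu, sd_)
  similarity_surface(rnorm(k), slice, eta = runif(k, 0, 0.1))
}
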