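# Shared fixtures and independent oracles for the test suite.

# a small, fully reported observation table built in code
make_obs_table <- function(n = 6) {
  data.frame(
    study_id = rep(c("s1", "s2", "s3"), length.out = n),
    obs_id = paste0("o", seq_len(n)),
    practice = rep(c("RFR", "EE", "CC", "EE"), length.out = n),
    crop = rep(c("wheat", "maize", "rice"), length.out = n),
    mean_t = rep(c(35, 42, 39, 44, 37, 41, 36, 45), length.out = n),
    mean_c = rep(c(30, 33, 35, 31, 34, 32, 29, 36), length.out = n),
    sd_t = rep(4, n), sd_c = rep(3, n),
    n_t = rep(3, n), n_c = rep(3, n),
    n_rate = rep(c(100, 240, 180, 90, 300, 150, 210, 120), length.out = n),
    mat = rep(c(5, 22, 11, 27, 8, 17, 14, 2), length.out = n),
    map = rep(c(300, 1500, 700, 2100, 450, 1100, 900, 600), length.out = n),
    soc = rep(c(5, 38, 12, 7, 29, 18, 45, 22), length.out = n),
    clay = rep(c(10, 42, 25, 33, 15, 48, 20, 38), length.out = n),
    ph = rep(c(5, 7.8, 6.1, 5.6, 7.2, 6.6, 8, 4.9), length.out = n),
    lat = rep(40, n), lon = rep(-90, n),
    stringsAsFactors = FALSE)
}

# the toy observation used for the closed-form effect-size checks
toy_obs <- function() {
  data.frame(study_id = "s1", obs_id = "o1", practice = "RFR",
             crop = "wheat", mean_t = 40, mean_c = 32,
             sd_t = 4, sd_c = 3, n_t = 3, n_c = 3,
             n_rate = 150, mat = 10, map = 800, soc = 20, clay = 25,
             ph = 6.5, stringsAsFactors = FALSE)
}

# independent dense-matrix evaluation of the (restricted) log-likelihood of
# the compound-symmetry model; deliberately naive (O(k^3)), used as oracle
naive_cs_loglik <- function(tau2, rho, y, v, X, study, reml = TRUE) {
  k <- length(y)
  p <- ncol(X)
  same <- outer(study, study, `==`)
  D <- tau2 * rho * same
  diag(D) <- tau2
  M <- D + diag(v, k)
  Mi <- solve(M)
  XtMiX <- t(X) %*% Mi %*% X
  beta <- solve(XtMiX, t(X) %*% Mi %*% y)
  r <- drop(y - X %*% beta)
  quad <- drop(t(r) %*% Mi %*% r)
  ld <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  if (reml) {
    -0.5 * ((k - p) * log(2 * pi) + ld +
              as.numeric(determinant(XtMiX, logarithm = TRUE)$modulus) + quad)
  } else {
    -0.5 * (k * log(2 * pi) + ld + quad)
  }
}

# dense grid search of the restricted likelihood over (tau2, rho)
grid_search_cs <- function(y, v, X, study,
                           tau2_grid = NULL, rho_grid = seq(0, 0.95, by = 0.05)) {
  if (is.null(tau2_grid)) {
    t0 <- max(mean(v), stats::var(y) / 2, 1e-3)
    tau2_grid <- c(0, exp(seq(log(t0 / 100), log(t0 * 50), length.out = 50)))
  }
  best <- list(ll = -Inf)
  for (t2 in tau2_grid) for (r in rho_grid) {
    ll <- naive_cs_loglik(t2, r, y, v, X, study)
    if (ll > best$ll) best <- list(ll = ll, tau2 = t2, rho = r)
  }
  best$tau2_grid <- tau2_grid
  best$rho_grid <- rho_grid
  best
}

# random small CS-model instance with known structure (for oracle tests)
random_instance <- function(seed, n_study = 6, per_study = 3,
                            tau2 = 2, rho = 0.5, p_extra = 1) {
  set.seed(seed)
  k <- n_study * per_study
  study <- rep(paste0("s", seq_len(n_study)), each = per_study)
  X <- cbind(intercept = 1,
             matrix(rnorm(k * p_extra), k,
                    dimnames = list(NULL, paste0("x", seq_len(p_extra)))))
  beta <- c(2, rep(1, p_extra))
  v <- runif(k, 0.3, 1.5)
  shared <- rnorm(n_study, 0, sqrt(rho * tau2))[rep(seq_len(n_study),
                                                    each = per_study)]
  u <- shared + rnorm(k, 0, sqrt((1 - rho) * tau2))
  y <- drop(X %*% beta) + u + rnorm(k, 0, sqrt(v))
  list(y = y, v = v, X = X, study = study)
}
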