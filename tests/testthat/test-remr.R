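test_that("the fixed-effect limit reproduces weighted least squares exactly", {
  y <- c(10, 20)
  v <- c(1, 4)
  fit <- nue_remr(y, v, study = c("a", "b"), constraints = list(tau2 = 0))
  expect_equal(unname(coef(fit)), 12, tolerance = 1e-10)
  expect_equal(sqrt(vcov(fit)[1, 1]), 1 / sqrt(1.25), tolerance = 1e-10)

  inst <- random_instance(17, n_study = 5, per_study = 2, p_extra = 2)
  fe <- nue_remr(inst$y, inst$v, mods = inst$X, study = inst$study,
                 constraints = list(tau2 = 0))
  w <- 1 / inst$v
  beta_wls <- solve(crossprod(inst$X, inst$X * w),
                    crossprod(inst$X, inst$y * w))
  expect_equal(unname(coef(fe)), unname(drop(beta_wls)), tolerance = 1e-10)
})

test_that("one effect per study with equal variances gives the arithmetic mean", {
  y <- c(3, 9, 6, 12)
  fit <- nue_remr(y, rep(2, 4), study = paste0("s", 1:4))
  expect_equal(unname(coef(fit)), mean(y), tolerance = 1e-8)
  expect_false(fit$rho_identifiable)
  expect_equal(fit$q_params, 1 + 1)   # intercept + tau2 only
})

test_that("the fast block likelihood matches the naive dense evaluation", {
  inst <- random_instance(5)
  gi <- as.integer(factor(inst$study, levels = unique(inst$study)))
  for (pars in list(c(0, 0.5), c(1.7, 0.2), c(4, 0.9), c(0.3, 0))) {
    for (reml in c(TRUE, FALSE)) {
      expect_equal(
        nuemeta:::.cs_loglik(pars[1], pars[2], inst$y, inst$v, inst$X, gi,
                             reml = reml),
        naive_cs_loglik(pars[1], pars[2], inst$y, inst$v, inst$X,
                        inst$study, reml = reml),
        tolerance = 1e-8)
    }
  }
})

test_that("REML estimates agree with an independent dense likelihood grid search", {
  for (seed in c(2, 9, 31)) {
    inst <- random_instance(seed, n_study = 6, per_study = 3)
    fit <- nue_remr(inst$y, inst$v, mods = inst$X, study = inst$study)
    gs <- grid_search_cs(inst$y, inst$v, inst$X, inst$study)
    ll_fit <- naive_cs_loglik(fit$tau2, fit$rho, inst$y, inst$v, inst$X,
                              inst$study)
    # the optimiser must dominate every grid point of the oracle likelihood
    expect_gte(ll_fit, gs$ll - 1e-6)
    expect_lte(abs(fit$rho - gs$rho), 0.075)
  }
})

test_that("fits agree with metafor's multilevel model on a shared instance", {
  skip_if_not_installed("metafor")
  inst <- random_instance(12, n_study = 8, per_study = 3, p_extra = 2)
  fit <- nue_remr(inst$y, inst$v, mods = inst$X, study = inst$study)
  dat <- data.frame(yi = inst$y, vi = inst$v, study = inst$study,
                    obs = seq_along(inst$y),
                    x1 = inst$X[, "x1"], x2 = inst$X[, "x2"])
  mv <- metafor::rma.mv(yi, vi, mods = ~ x1 + x2,
                        random = ~ 1 | study / obs, data = dat,
                        method = "REML")
  tau2_mv <- sum(mv$sigma2)
  rho_mv <- mv$sigma2[1] / tau2_mv
  expect_equal(unname(coef(fit)), unname(coef(mv)), tolerance = 1e-4)
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(mv$se), tolerance = 1e-4)
  expect_equal(fit$tau2, tau2_mv, tolerance = 1e-3)
  expect_equal(fit$rho, rho_mv, tolerance = 1e-3)
})

test_that("estimates are invariant to row permutation", {
  inst <- random_instance(23, n_study = 5, per_study = 4)
  fit <- nue_remr(inst$y, inst$v, mods = inst$X, study = inst$study)
  set.seed(1)
  perm <- sample(length(inst$y))
  fit_p <- nue_remr(inst$y[perm], inst$v[perm],
                    mods = inst$X[perm, , drop = FALSE],
                    study = inst$study[perm])
  expect_equal(coef(fit_p), coef(fit), tolerance = 1e-10)
  expect_equal(fit_p$tau2, fit$tau2, tolerance = 1e-8)
  expect_equal(fit_p$rho, fit$rho, tolerance = 1e-8)
  expect_equal(fit_p$loglik_reml, fit$loglik_reml, tolerance = 1e-10)
})

test_that("contract violations are rejected", {
  expect_error(nue_remr(1:3, c(1, 1, -1), study = c("a", "b", "c")),
               "positive")
  expect_error(nue_remr(1:2, c(1, 1), mods = cbind(1, 1:2),
                        study = c("a", "b")), "underdetermined")
  X <- cbind(1, c(1, 0, 1, 0), c(2, 0, 2, 0))
  expect_error(nue_remr(1:4, rep(1, 4), mods = X, study = letters[1:4]),
               "rank")
})

test_that("Wald moderator tests reproduce hand-derived chi-square values", {
  inst <- random_instance(7, n_study = 6, per_study = 3, p_extra = 2)
  fit <- nue_remr(inst$y, inst$v, mods = inst$X, study = inst$study)
  # force a clean single-coefficient case: beta/se = 2 -> chi2 = 4
  fit2 <- fit
  fit2$beta["x1"] <- 2 * sqrt(fit$vb["x1", "x1"])
  w <- wald_test(fit2, "x1")
  expect_equal(w$chi2, 4, tolerance = 1e-10)
  expect_equal(w$df, 1)
  expect_equal(w$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(round(w$p, 5), 0.0455)

  # zero coefficients give chi2 = 0, p = 1
  fit2$beta[c("x1", "x2")] <- 0
  w0 <- wald_test(fit2, c("x1", "x2"))
  expect_equal(w0$chi2, 0)
  expect_equal(w0$p, 1)

  # two independent unit-z terms add to chi2 = 2 on 2 df
  fit3 <- fit
  fit3$vb <- diag(c(1, 1, 1))
  dimnames(fit3$vb) <- dimnames(fit$vb)
  fit3$beta[] <- c(0, 1, 1)
  w2 <- wald_test(fit3, c("x1", "x2"))
  expect_equal(w2$chi2, 2, tolerance = 1e-12)
  expect_equal(w2$df, 2)

  expect_error(wald_test(fit, "nosuch"), "unknown")
})

test_that("the residual heterogeneity statistic matches hand and loop oracles", {
  # exact-fit data: QE = 0, p = 1
  X <- cbind(1, c(0, 1, 2, 3))
  y <- drop(X %*% c(1, 2))
  q0 <- qe_test(y, rep(1, 4), X)
  expect_equal(q0$qe, 0, tolerance = 1e-12)
  expect_equal(q0$p, 1)

  # intercept-only hand case
  q1 <- qe_test(c(10, 20), c(1, 1), cbind(c(1, 1)))
  expect_equal(q1$qe, 50, tolerance = 1e-12)
  expect_equal(q1$df, 1)

  # random instances against an explicit residual loop
  for (seed in c(4, 8)) {
    inst <- random_instance(seed)
    q <- qe_test(inst$y, inst$v, inst$X)
    w <- 1 / inst$v
    bfe <- solve(crossprod(inst$X, inst$X * w),
                 crossprod(inst$X, inst$y * w))
    acc <- 0
    for (i in seq_along(inst$y)) {
      acc <- acc + (inst$y[i] - sum(inst$X[i, ] * bfe))^2 / inst$v[i]
    }
    expect_equal(q$qe, acc, tolerance = 1e-10)
    expect_equal(q$df, length(inst$y) - ncol(inst$X))
  }
})

test_that("information criteria count parameters and track the likelihood", {
  inst <- random_instance(3)
  fit <- nue_remr(inst$y, inst$v, mods = inst$X, study = inst$study)
  ic <- information_criteria(fit)
  expect_equal(ic$q, fit$p + 2)
  expect_equal(ic$aic_ml, -2 * fit$loglik_ml + 2 * (fit$p + 2))
  expect_equal(ic$aic_reml, -2 * fit$loglik_reml + 2 * (fit$p + 2))
  # the ML value matches an independent dense likelihood evaluation
  expect_equal(fit$loglik_ml,
               naive_cs_loglik(fit$tau2, fit$rho, inst$y, inst$v, inst$X,
                               inst$study, reml = FALSE), tolerance = 1e-8)
  # a model nested above another never has higher ML likelihood below it
  fit0 <- nue_remr(inst$y, inst$v, study = inst$study,
                   constraints = list(tau2 = fit$tau2, rho = fit$rho))
  expect_gte(fit$loglik_ml, fit0$loglik_ml - 1e-8)
})

test_that("McFadden pseudo-R2 behaves like a likelihood ratio on [0, 1)", {
  inst <- random_instance(6, p_extra = 1)
  fit <- nue_remr(inst$y, inst$v, mods = inst$X, study = inst$study)
  null <- nue_remr(inst$y, inst$v, study = inst$study)
  expect_equal(pseudo_r2(null, null), 0)
  expect_equal(1 - (-50) / (-100), 0.5)  # definition sanity
  r2 <- pseudo_r2(fit, null)
  expect_lt(r2, 1)
  expect_identical(pseudo_r2(fit), r2)
})

test_that("strong moderators raise the pseudo-R2 over a moderator-free refit", {
  cfg <- nue_sim_config(n_studies = 15, obs_per_study = 4, drop_sd_frac = 0,
                        seed = 31)
  sim <- simulate_observations(cfg)
  fit <- nue_meta_model(sim$observations, cfg$spec)
  expect_gt(pseudo_r2(fit), 0.05)
})

test_that("fixed-effects prediction obeys its closed forms and CI contract", {
  fit <- nue_remr(c(10, 20), c(1, 4), study = c("a", "b"),
                  constraints = list(tau2 = 0))
  pr <- predict(fit, newmods = 1)
  expect_equal(pr$mean, 12, tolerance = 1e-10)
  expect_equal(pr$se, 1 / sqrt(1.25), tolerance = 1e-10)
  expect_equal(round(c(pr$ci_low, pr$ci_high), 3), c(10.247, 13.753))

  inst <- random_instance(2, p_extra = 2)
  f <- nue_remr(inst$y, inst$v, mods = inst$X, study = inst$study)
  newx <- rbind(c(1, 0.5, -1), c(1, 0, 0), c(1, 2, 2))
  pr2 <- predict(f, newmods = newx)
  expect_equal(pr2$ci_high - pr2$ci_low, 2 * 1.96 * pr2$se, tolerance = 1e-12)
  expect_true(all(pr2$ci_low <= pr2$mean & pr2$mean <= pr2$ci_high))
  expect_equal(pr2$mean[2], unname(coef(f)[1]))
  expect_error(predict(f, newmods = c(1, 2)), "columns")
  # prediction intervals widen by the heterogeneity variance
  pr3 <- predict(f, newmods = newx, interval = "prediction")
  expect_equal(pr3$se^2 - pr2$se^2, rep(f$tau2, 3), tolerance = 1e-10)
})

test_that("simulate() reproduces the fitted marginal moments", {
  inst <- random_instance(14, n_study = 8, per_study = 3)
  fit <- nue_remr(inst$y, inst$v, mods = inst$X, study = inst$study)
  sims <- simulate(fit, nsim = 400, seed = 99)
  mu <- drop(inst$X %*% coef(fit))
  err <- rowMeans(as.matrix(sims)) - mu
  expect_lt(max(abs(err)), 4 * sqrt(max(fit$tau2 + inst$v) / 400) * 3)
})
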