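# Likelihood machinery for the compound-symmetry multilevel model.
#
# Marginal covariance: M = D + diag(v), with D block-diagonal by study,
# D_s = tau2 * ((1 - rho) I + rho J). Each block is a diagonal plus a
# rank-one update, so M^{-1} and log|M| have closed forms (Sherman-Morrison):
#   a_i = v_i + tau2 (1 - rho),  c = tau2 rho,
#   M^{-1} z = z/a - c/(1 + c S_s) * (sum_{i in s} z_i/a_i) / a,
#   log|M| = sum log a_i + sum_s log(1 + c S_s),  S_s = sum_{i in s} 1/a_i.
# Everything is vectorised over studies via rowsum(), so likelihood
# evaluations are O(k p) rather than O(k^3).

.cs_loglik <- function(tau2, rho, y, v, X, gi, reml = TRUE) {
  k <- length(y)
  p <- ncol(X)
  a <- v + tau2 * (1 - rho)
  cc <- tau2 * rho
  if (any(a <= 0)) return(-Inf)
  u <- 1 / a
  S1 <- rowsum(u, gi)[, 1]
  d <- 1 + cc * S1
  if (any(d <= 0)) return(-Inf)
  Z <- cbind(X, y)
  Z1 <- Z * u
  Zs <- rowsum(Z1, gi)
  W <- Z1 - ((cc / d)[gi] * u) * Zs[gi, , drop = FALSE]   # M^{-1} [X y]
  XtMX <- crossprod(X, W[, seq_len(p), drop = FALSE])
  XtMy <- crossprod(X, W[, p + 1L])
  ch <- tryCatch(chol(XtMX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtMy))
  quad <- sum(y * W[, p + 1L]) - sum(beta * XtMy)
  logdetM <- sum(log(a)) + sum(log(d))
  if (reml) {
    ll <- -0.5 * ((k - p) * log(2 * pi) + logdetM +
                    2 * sum(log(diag(ch))) + quad)
  } else {
    ll <- -0.5 * (k * log(2 * pi) + logdetM + quad)
  }
  as.numeric(ll)
}

# GLS solution and coefficient covariance at given variance components
.cs_gls <- function(tau2, rho, y, v, X, gi) {
  p <- ncol(X)
  a <- v + tau2 * (1 - rho)
  cc <- tau2 * rho
  u <- 1 / a
  S1 <- rowsum(u, gi)[, 1]
  d <- 1 + cc * S1
  Z <- cbind(X, y)
  Z1 <- Z * u
  Zs <- rowsum(Z1, gi)
  W <- Z1 - ((cc / d)[gi] * u) * Zs[gi, , drop = FALSE]
  XtMX <- crossprod(X, W[, seq_len(p), drop = FALSE])
  XtMy <- crossprod(X, W[, p + 1L])
  vb <- solve(XtMX)
  beta <- drop(vb %*% XtMy)
  names(beta) <- colnames(X)
  dimnames(vb) <- list(colnames(X), colnames(X))
  list(beta = beta, vb = vb)
}

#' Multilevel meta-regression with compound-symmetric study random effects
#'
#' Fits the mixed-effects meta-regression
#' \deqn{y_i = \mathbf{x}_i^\top \boldsymbol{\beta} + u_i + e_i,}
#' where \eqn{y_i} is a per-observation effect size with known sampling
#' variance \eqn{v_i} (\eqn{e_i \sim N(0, v_i)}) and the true-effect
#' deviations \eqn{u_i} of observations within the same study share a
#' compound-symmetric covariance: \eqn{\mathrm{Var}(u_i) = \tau^2} and
#' \eqn{\mathrm{Cor}(u_i, u_j) = \rho} for \eqn{i \ne j} in one study.
#' Variance components are estimated by restricted maximum likelihood
#' (default) or full maximum likelihood; \eqn{\boldsymbol{\beta}} is the
#' generalized least-squares solution at the optimum, with covariance
#' \eqn{(\mathbf{X}^\top \mathbf{M}^{-1} \mathbf{X})^{-1}}.
#'
#' Optimisation is deterministic: \eqn{(\log\tau^2, \mathrm{logit}\,\rho)}
#' is screened on a fixed 5 x 5 start grid, local quasi-Newton refinement
#' (\code{nlminb}) is run from the best starts, and the \eqn{\tau^2 = 0}
#' boundary is always evaluated and compared. When every study contributes a
#' single effect, \eqn{\rho} is not identifiable: the model reduces to a
#' standard random-effects fit in \eqn{\tau^2} alone and the returned
#' \eqn{\rho} is flagged accordingly.
#'
#' @param yi Effect sizes, or a column name/expression evaluated in
#'   \code{data}.
#' @param vi Sampling variances (all > 0), likewise.
#' @param mods Fixed-effects structure: a one-sided formula (evaluated in
#'   \code{data}), a design matrix (used as-is, including any intercept), or
#'   \code{NULL} for an intercept-only model.
#' @param study Study labels defining the random-effect blocks, likewise.
#' @param data Optional data.frame in which \code{yi}, \code{vi},
#'   \code{study} and a formula \code{mods} are evaluated.
#' @param method \code{"REML"} (default) or \code{"ML"}.
#' @param constraints Optional named list fixing variance components, e.g.
#'   \code{list(tau2 = 0)} (fixed-effect limit) or \code{list(rho = 0.5)}.
#' @param control List overriding optimiser settings: \code{rel_tol}
#'   (default 1e-8 on the log-likelihood), \code{iter_max} (500),
#'   \code{n_start} (number of refined starts, default 3).
#' @return Object of class \code{nue_remr}: coefficients \code{beta} and
#'   covariance \code{vb}; variance components \code{tau2}, \code{rho} (with
#'   \code{rho_identifiable}); restricted and full log-likelihoods at the
#'   fitted parameters; the residual-heterogeneity test \code{qe}; \code{k},
#'   \code{p}, and the parameter count \code{q_params} used by
#'   [information_criteria()].
#' @examples
#' y <- c(2, 4, 3, 8, 7, 5)
#' v <- c(1, 1.5, 0.8, 1.2, 0.9, 1.1)
#' st <- c("a", "a", "b", "b", "c", "c")
#' fit <- nue_remr(y, v, study = st)
#' summary(fit)
#' @export
nue_remr <- function(yi, vi, mods = NULL, study, data = NULL,
                     method = c("REML", "ML"), constraints = NULL,
                     control = list()) {
  method <- match.arg(method)
  if (!is.null(data)) {
    yi <- eval(substitute(yi), data, parent.frame())
    vi <- eval(substitute(vi), data, parent.frame())
    study <- eval(substitute(study), data, parent.frame())
  }
  if (inherits(mods, "formula")) {
    X <- stats::model.matrix(mods, data = if (is.null(data))
      parent.frame() else data)
  } else if (is.null(mods)) {
    X <- matrix(1, length(yi), 1, dimnames = list(NULL, "intercept"))
  } else {
    X <- as.matrix(mods)
    if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  }
  k <- length(yi)
  p <- ncol(X)
  if (length(vi) != k || nrow(X) != k || length(study) != k) {
    stop("yi, vi, mods and study must agree in length", call. = FALSE)
  }
  if (any(!is.finite(vi) | vi <= 0)) {
    stop("all sampling variances must be finite and positive", call. = FALSE)
  }
  if (k <= p) {
    stop("underdetermined model: k = ", k, " effects for p = ", p,
         " coefficients", call. = FALSE)
  }
  if (qr(X)$rank < p) {
    stop("rank-deficient design matrix", call. = FALSE)
  }
  ctrl <- utils::modifyList(list(rel_tol = 1e-8, iter_max = 500, n_start = 3),
                            control)
  gi <- as.integer(factor(study, levels = unique(study)))
  reml <- method == "REML"
  multi <- any(tabulate(gi) > 1L)

  fix_tau2 <- constraints$tau2
  fix_rho <- constraints$rho
  if (!is.null(fix_rho) && (fix_rho < 0 || fix_rho >= 1)) {
    stop("rho must lie in [0, 1)", call. = FALSE)
  }
  rho_identifiable <- multi && is.null(fix_rho)
  if (!multi && is.null(fix_rho)) fix_rho <- 0

  obj <- function(tau2, rho) {
    -.cs_loglik(tau2, rho, yi, vi, X, gi, reml = reml)
  }

  # deterministic start grid anchored on the data scale
  t0 <- max(mean(vi), stats::var(yi) / 2, 1e-3)
  tau2_grid <- t0 * c(0.05, 0.25, 1, 4, 20)
  rho_grid <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  lb_lt <- log(t0) - 25; ub_lt <- log(t0) + 25
  lb_lr <- stats::qlogis(1e-6); ub_lr <- stats::qlogis(1 - 1e-6)

  convergence <- 0L
  if (!is.null(fix_tau2) && !is.null(fix_rho)) {
    tau2_hat <- fix_tau2; rho_hat <- fix_rho
  } else if (!is.null(fix_tau2)) {
    if (fix_tau2 == 0) {
      tau2_hat <- 0; rho_hat <- if (is.null(fix_rho)) 0 else fix_rho
      rho_identifiable <- FALSE
    } else {
      fits <- lapply(stats::qlogis(rho_grid), function(s) {
        stats::nlminb(s, function(lr) obj(fix_tau2, stats::plogis(lr)),
                      lower = lb_lr, upper = ub_lr,
                      control = list(rel.tol = ctrl$rel_tol,
                                     iter.max = ctrl$iter_max))
      })
      best <- fits[[which.min(vapply(fits, `[[`, 0, "objective"))]]
      tau2_hat <- fix_tau2; rho_hat <- stats::plogis(best$par)
      convergence <- best$convergence
    }
  } else {
    rho_for_1d <- if (is.null(fix_rho)) 0 else fix_rho
    if (rho_identifiable) {
      # 2-D: screen the 5 x 5 grid, refine the best starts
      grid <- expand.grid(lt = log(tau2_grid), lr = stats::qlogis(rho_grid))
      grid$val <- mapply(function(lt, lr) obj(exp(lt), stats::plogis(lr)),
                         grid$lt, grid$lr)
      ord <- order(grid$val)
      starts <- grid[ord[seq_len(min(ctrl$n_start, nrow(grid)))], , drop = FALSE]
      fits <- lapply(seq_len(nrow(starts)), function(i) {
        stats::nlminb(c(starts$lt[i], starts$lr[i]),
                      function(th) obj(exp(th[1]), stats::plogis(th[2])),
                      lower = c(lb_lt, lb_lr), upper = c(ub_lt, ub_lr),
                      control = list(rel.tol = ctrl$rel_tol,
                                     iter.max = ctrl$iter_max))
      })
      best <- fits[[which.min(vapply(fits, `[[`, 0, "objective"))]]
      tau2_hat <- exp(best$par[1]); rho_hat <- stats::plogis(best$par[2])
      best_obj <- best$objective
      convergence <- best$convergence
    } else {
      fits <- lapply(log(tau2_grid), function(s) {
        stats::nlminb(s, function(lt) obj(exp(lt), rho_for_1d),
                      lower = lb_lt, upper = ub_lt,
                      control = list(rel.tol = ctrl$rel_tol,
                                     iter.max = ctrl$iter_max))
      })
      best <- fits[[which.min(vapply(fits, `[[`, 0, "objective"))]]
      tau2_hat <- exp(best$par); rho_hat <- rho_for_1d
      best_obj <- best$objective
      convergence <- best$convergence
    }
    # tau2 = 0 boundary always considered
    if (obj(0, rho_for_1d) <= best_obj + 1e-10) {
      tau2_hat <- 0
      rho_hat <- rho_for_1d
      rho_identifiable <- FALSE
    }
  }
  if (convergence != 0L) {
    warning("variance-component optimiser reported convergence code ",
            convergence, call. = FALSE)
  }

  gls <- .cs_gls(tau2_hat, rho_hat, yi, vi, X, gi)
  ll_reml <- .cs_loglik(tau2_hat, rho_hat, yi, vi, X, gi, reml = TRUE)
  ll_ml <- .cs_loglik(tau2_hat, rho_hat, yi, vi, X, gi, reml = FALSE)

  n_varpar <- 2L
  if (!rho_identifiable || !is.null(fix_rho)) n_varpar <- n_varpar - 1L
  if (!is.null(fix_tau2)) n_varpar <- n_varpar - 1L
  n_varpar <- max(n_varpar, 0L)

  qe <- qe_test(yi, vi, X)

  structure(list(beta = gls$beta, vb = gls$vb,
                 tau2 = tau2_hat, rho = rho_hat,
                 rho_identifiable = rho_identifiable,
                 method = method, loglik_reml = ll_reml, loglik_ml = ll_ml,
                 qe = qe, k = k, p = p, q_params = p + n_varpar,
                 yi = yi, vi = vi, X = X, study = study,
                 constraints = constraints, call = match.call()),
            class = "nue_remr")
}

#' Residual heterogeneity test
#'
#' Cochran-type test of whether effect-size variability unexplained by the
#' moderators exceeds pure sampling variability:
#' \eqn{Q_E = (\mathbf{y} - \mathbf{X}\hat\beta_{FE})^\top \mathbf{W}
#' (\mathbf{y} - \mathbf{X}\hat\beta_{FE})} with \eqn{\mathbf{W} =
#' \mathrm{diag}(1/v_i)} and \eqn{\hat\beta_{FE}} the weighted least-squares
#' fit at \eqn{\tau^2 = 0}; referred to \eqn{\chi^2_{k-p}}.
#'
#' @param y Effect sizes.
#' @param v Sampling variances.
#' @param X Design matrix.
#' @return List with \code{qe}, \code{df}, \code{p}.
#' @export
qe_test <- function(y, v, X) {
  X <- as.matrix(X)
  w <- 1 / v
  XtWX <- crossprod(X, X * w)
  beta_fe <- solve(XtWX, crossprod(X, y * w))
  r <- y - drop(X %*% beta_fe)
  qe <- sum(w * r^2)
  df <- length(y) - ncol(X)
  list(qe = qe, df = df,
       p = if (df > 0) stats::pchisq(qe, df, lower.tail = FALSE) else NA_real_)
}

#' Wald test of a set of moderator coefficients
#'
#' Omnibus chi-square test that the selected coefficients are jointly zero:
#' \eqn{\chi^2 = \hat\beta_S^\top \mathrm{Cov}(\hat\beta_S)^{-1} \hat\beta_S}
#' on \eqn{|S|} degrees of freedom. This is the linear-contrast ANOVA used to
#' judge each moderator's contribution.
#'
#' @param model A fitted [nue_remr()] model.
#' @param terms Coefficient names or integer indices to test jointly.
#' @return List with \code{chi2}, \code{df}, \code{p}.
#' @export
wald_test <- function(model, terms) {
  stopifnot(inherits(model, "nue_remr"))
  if (is.character(terms)) {
    idx <- match(terms, names(model$beta))
    if (anyNA(idx)) {
      stop("unknown coefficient(s): ",
           paste(terms[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- as.integer(terms)
    if (any(idx < 1 | idx > model$p)) stop("coefficient index out of range",
                                           call. = FALSE)
  }
  b <- model$beta[idx]
  V <- model$vb[idx, idx, drop = FALSE]
  chi2 <- tryCatch(drop(t(b) %*% solve(V, b)),
                   error = function(e) stop("singular covariance for the selected coefficients",
                                            call. = FALSE))
  df <- length(idx)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Information criteria for a fitted meta-regression
#'
#' \eqn{AIC = -2\,\ell + 2q} with \eqn{q = p + } (number of free variance
#' components): two (\eqn{\tau^2}, \eqn{\rho}) in the general model, one when
#' \eqn{\rho} is unidentifiable or fixed. Both the full-likelihood value
#' (comparable across different moderator sets, used for model selection and
#' McFadden pseudo-R2) and the restricted-likelihood value (comparable only
#' across models sharing one fixed-effects structure) are reported.
#'
#' @param model A fitted [nue_remr()] model.
#' @return List with \code{aic_ml}, \code{aic_reml}, \code{q}.
#' @export
information_criteria <- function(model) {
  stopifnot(inherits(model, "nue_remr"))
  q <- model$q_params
  list(aic_ml = -2 * model$loglik_ml + 2 * q,
       aic_reml = -2 * model$loglik_reml + 2 * q,
       q = q)
}

#' McFadden pseudo-R2 of a meta-regression against its null model
#'
#' \eqn{R^2_{McF} = 1 - \ell_{model}/\ell_{null}} on full (ML) log-likelihoods,
#' where the null model is intercept-only with the same random-effects
#' structure, responses and variances. If \code{null} is not supplied it is
#' refitted from the model's own data.
#'
#' @param model A fitted [nue_remr()] model.
#' @param null Optional intercept-only [nue_remr()] fit on the same data.
#' @return The pseudo-R2 value.
#' @export
pseudo_r2 <- function(model, null = NULL) {
  stopifnot(inherits(model, "nue_remr"))
  if (is.null(null)) {
    null <- nue_remr(model$yi, model$vi, mods = NULL, study = model$study,
                     method = model$method, constraints = model$constraints)
  }
  ll1 <- model$loglik_ml
  ll0 <- null$loglik_ml
  if (ll0 == 0) stop("null-model log-likelihood is zero; pseudo-R2 undefined",
                     call. = FALSE)
  1 - ll1 / ll0
}
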