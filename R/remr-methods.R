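#' @export
print.nue_remr <- function(x, digits = 4, ...) {
  cat("Multilevel meta-regression (", x$method,
      ", compound-symmetric study random effects)\n", sep = "")
  cat(sprintf("k = %d effects in %d studies; p = %d coefficients\n",
              x$k, length(unique(x$study)), x$p))
  cat(sprintf("tau^2 = %.*f; rho = %s\n", digits, x$tau2,
              if (x$rho_identifiable) sprintf("%.*f", digits, x$rho)
              else sprintf("%.*f (not identifiable)", digits, x$rho)))
  cat("Coefficients:\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' @export
coef.nue_remr <- function(object, ...) object$beta

#' @export
vcov.nue_remr <- function(object, ...) object$vb

#' @export
logLik.nue_remr <- function(object, type = c("fit", "ML", "REML"), ...) {
  type <- match.arg(type)
  val <- switch(type,
                fit = if (object$method == "REML") object$loglik_reml
                      else object$loglik_ml,
                ML = object$loglik_ml,
                REML = object$loglik_reml)
  structure(val, df = object$q_params, nobs = object$k, class = "logLik")
}

#' @export
summary.nue_remr <- function(object, ...) {
  se <- sqrt(diag(object$vb))
  z <- object$beta / se
  pval <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  stars <- symnum(pval, corr = FALSE, na = FALSE,
                  cutpoints = c(0, 0.001, 0.01, 0.05, 1),
                  symbols = c("***", "**", "*", " "))
  coefs <- data.frame(estimate = object$beta, se = se, z = z, p = pval,
                      sig = format(stars), stringsAsFactors = FALSE)
  ic <- information_criteria(object)
  structure(list(fit = object, coefficients = coefs, ic = ic),
            class = "summary.nue_remr")
}

#' @export
print.summary.nue_remr <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficient table:\n")
  ct <- x$coefficients
  ct$estimate <- round(ct$estimate, digits)
  ct$se <- round(ct$se, digits)
  ct$z <- round(ct$z, 2)
  ct$p <- signif(ct$p, 3)
  print(ct)
  cat(sprintf("\nQ_E = %.2f on %d df (p = %.3g)\n",
              x$fit$qe$qe, x$fit$qe$df, x$fit$qe$p))
  cat(sprintf("logLik (REML) = %.3f; logLik (ML) = %.3f; AIC (ML) = %.2f; AIC (REML) = %.2f\n",
              x$fit$loglik_reml, x$fit$loglik_ml, x$ic$aic_ml, x$ic$aic_reml))
  invisible(x)
}

#' Fixed-effects prediction with 95% confidence intervals
#'
#' Computes \eqn{\hat\mu = \mathbf{x}^\top \hat\beta} for one or more design
#' rows, with \eqn{se = \sqrt{\mathbf{x}^\top \mathrm{Cov}(\hat\beta)
#' \mathbf{x}}} and the normal-theory 95% interval
#' \eqn{\hat\mu \pm 1.96\, se}. Only fixed-effects uncertainty enters;
#' with \code{interval = "prediction"} the between-effect heterogeneity
#' \eqn{\tau^2} is added to the variance.
#'
#' @param object A fitted [nue_remr()] model.
#' @param newmods Matrix (or vector) of full design rows, one column per
#'   coefficient, in the fitted coefficient order and on the fitted
#'   (scaled) covariate scale.
#' @param interval \code{"confidence"} (default) or \code{"prediction"}.
#' @param ... Unused.
#' @return data.frame with \code{mean}, \code{se}, \code{ci_low},
#'   \code{ci_high}.
#' @export
predict.nue_remr <- function(object, newmods = NULL,
                             interval = c("confidence", "prediction"), ...) {
  interval <- match.arg(interval)
  if (is.null(newmods)) {
    newmods <- object$X
  }
  if (is.null(dim(newmods))) newmods <- matrix(newmods, nrow = 1)
  newmods <- as.matrix(newmods)
  if (ncol(newmods) != object$p) {
    stop("newmods has ", ncol(newmods), " columns; model has ", object$p,
         " coefficients", call. = FALSE)
  }
  mu <- drop(newmods %*% object$beta)
  var_mu <- rowSums((newmods %*% object$vb) * newmods)
  if (interval == "prediction") var_mu <- var_mu + object$tau2
  se <- sqrt(pmax(var_mu, 0))
  data.frame(mean = mu, se = se,
             ci_low = mu - 1.96 * se, ci_high = mu + 1.96 * se)
}

#' @export
residuals.nue_remr <- function(object, type = c("marginal", "standardized"),
                               ...) {
  type <- match.arg(type)
  r <- object$yi - drop(object$X %*% object$beta)
  if (type == "standardized") r <- r / sqrt(object$vi + object$tau2)
  r
}

#' Simulate effect-size vectors from a fitted meta-regression
#'
#' Draws new effect vectors from the fitted marginal model
#' \eqn{\mathbf{y} \sim N(\mathbf{X}\hat\beta, \mathbf{D}(\hat\tau^2,
#' \hat\rho) + \mathrm{diag}(v))}, preserving the study blocking.
#'
#' @param object A fitted [nue_remr()] model.
#' @param nsim Number of simulated vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return data.frame with \code{nsim} columns, \code{k} rows.
#' @export
simulate.nue_remr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gi <- as.integer(factor(object$study, levels = unique(object$study)))
  mu <- drop(object$X %*% object$beta)
  n_study <- max(gi)
  out <- replicate(nsim, {
    shared <- stats::rnorm(n_study, 0, sqrt(object$rho * object$tau2))[gi]
    own <- stats::rnorm(object$k, 0, sqrt((1 - object$rho) * object$tau2))
    mu + shared + own + stats::rnorm(object$k, 0, sqrt(object$vi))
  })
  as.data.frame(out)
}

#' Coefficient (forest-style) plot of a fitted meta-regression
#'
#' Draws point estimates with 95% Wald intervals for each coefficient,
#' excluding the intercept by default.
#'
#' @param x A fitted [nue_remr()] model.
#' @param intercept Include the intercept row? Default \code{FALSE}.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nue_remr <- function(x, intercept = FALSE, ...) {
  keep <- if (intercept) seq_len(x$p) else setdiff(seq_len(x$p),
                                                   which(names(x$beta) == "intercept"))
  b <- x$beta[keep]
  se <- sqrt(diag(x$vb))[keep]
  lo <- b - 1.96 * se
  hi <- b + 1.96 * se
  n <- length(b)
  graphics::plot(b, seq_len(n), xlim = range(lo, hi, 0), yaxt = "n",
                 xlab = "coefficient (95% CI)", ylab = "", pch = 16, ...)
  graphics::segments(lo, seq_len(n), hi, seq_len(n))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n), labels = names(b), las = 1, cex.axis = 0.8)
  invisible(x)
}
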