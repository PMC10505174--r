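#' Inverse-variance pooling of published meta-analytic estimates
#'
#' Combines effect estimates for the same management practice reported by
#' several published meta-analyses into one common-effect estimate:
#' \deqn{\bar{x} = \frac{\sum x_i/\sigma_i^2}{\sum 1/\sigma_i^2}, \qquad
#'       \sigma_{\bar{x}} = \frac{1}{\sqrt{\sum 1/\sigma_i^2}}.}
#' This is the fixed-effect (common-effect) pool; no between-source
#' heterogeneity variance is added. When the Cochran Q statistic across
#' sources exceeds its degrees of freedom, a heterogeneity warning is issued
#' so the user can judge whether a common effect is tenable.
#'
#' @param x Numeric vector of source estimates \eqn{x_i}.
#' @param se Numeric vector of their standard errors \eqn{\sigma_i} (> 0).
#' @return A list with \code{x_bar}, \code{se_bar}, \code{k}, \code{q}
#'   (Cochran Q) and \code{q_df}.
#' @export
pool_estimates <- function(x, se) {
  if (!length(x)) stop("no estimates to pool", call. = FALSE)
  if (length(x) != length(se)) stop("x and se differ in length", call. = FALSE)
  if (any(!is.finite(se) | se <= 0)) {
    stop("all standard errors must be finite and positive", call. = FALSE)
  }
  w <- 1 / se^2
  x_bar <- sum(w * x) / sum(w)
  se_bar <- 1 / sqrt(sum(w))
  q <- sum(w * (x - x_bar)^2)
  q_df <- length(x) - 1L
  if (q_df > 0 && q > q_df) {
    warning(sprintf("heterogeneity across sources (Q = %.2f on %d df) exceeds its df; the common-effect pool may understate uncertainty",
                    q, q_df), call. = FALSE)
  }
  list(x_bar = x_bar, se_bar = se_bar, k = length(x), q = q, q_df = q_df)
}

#' Pool a table of published estimates by practice
#'
#' Applies [pool_estimates()] within each management practice of a
#' summary table of published meta-analytic results. Sources reporting the
#' same practice under different effect-size metrics are never pooled across
#' metrics: mixed metrics for one practice are refused with a diagnostic.
#'
#' @param estimates A data.frame with columns \code{source_id},
#'   \code{practice}, \code{metric}, \code{x_i}, \code{se_i}.
#' @return A data.frame with one row per practice: \code{practice},
#'   \code{metric}, \code{x_bar}, \code{se_bar}, \code{k}.
#' @export
pool_by_practice <- function(estimates) {
  need <- c("source_id", "practice", "metric", "x_i", "se_i")
  missing_cols <- setdiff(need, names(estimates))
  if (length(missing_cols)) {
    stop("estimate table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(estimates, estimates$practice), function(d) {
    if (length(unique(d$metric)) > 1L) {
      stop("practice '", d$practice[1],
           "' mixes effect-size metrics (",
           paste(unique(d$metric), collapse = ", "),
           "); pool within one metric", call. = FALSE)
    }
    p <- pool_estimates(d$x_i, d$se_i)
    data.frame(practice = d$practice[1], metric = d$metric[1],
               x_bar = p$x_bar, se_bar = p$se_bar, k = p$k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
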