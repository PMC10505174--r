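#' Per-observation effect sizes for paired NUEr observations
#'
#' Computes, for every control--treatment pair, one of three effect sizes and
#' its sampling variance:
#' \describe{
#'   \item{ROM}{log ratio of means, \eqn{y_i = \ln(X_t/X_c)} with variance
#'     \eqn{v_i = s_t^2/(n_t X_t^2) + s_c^2/(n_c X_c^2)}.}
#'   \item{MD}{raw mean difference in NUEr percentage points,
#'     \eqn{y_i = X_t - X_c} with variance \eqn{v_i = s_t^2/n_t + s_c^2/n_c}.}
#'   \item{SMD}{standardized mean difference
#'     \eqn{y_i = (X_t - X_c)/SD_p} with pooled SD
#'     \eqn{SD_p = \sqrt{((n_t-1)s_t^2 + (n_c-1)s_c^2)/(n_t+n_c-2)}} and
#'     variance \eqn{v_i = (n_t+n_c)/(n_t n_c) + y_i^2/(2(n_t+n_c))}.}
#' }
#' The SMD is the plain (Cohen-type) standardized difference; the Hedges
#' small-sample correction \eqn{J = 1 - 3/(4(n_t+n_c-2)-1)} is available via
#' \code{hedges = TRUE} but off by default.
#'
#' Rows where the ROM is undefined (\code{mean_c <= 0} or \code{mean_t <= 0})
#' are dropped for \code{method = "ROM"} with a message; they are retained for
#' MD and SMD. SDs and replicate counts must be complete (impute first; see
#' [impute_missing_sd()] and [impute_missing_replicates()]).
#'
#' @param table Observation table with complete \code{sd_t, sd_c, n_t, n_c}.
#' @param method One of \code{"ROM"}, \code{"MD"}, \code{"SMD"}.
#' @param hedges Apply the Hedges small-sample correction to SMD
#'   (default \code{FALSE}).
#' @return A data.frame with columns \code{obs_id}, \code{study_id},
#'   \code{method}, \code{yi}, \code{vi} (and \code{pooled_sd} for SMD).
#' @export
effect_sizes <- function(table, method = c("ROM", "MD", "SMD"), hedges = FALSE) {
  method <- match.arg(method)
  need <- c("sd_t", "sd_c", "n_t", "n_c")
  incomplete <- need[vapply(need, function(cn) anyNA(table[[cn]]), logical(1))]
  if (length(incomplete)) {
    stop("missing values in ", paste(incomplete, collapse = ", "),
         "; impute dispersions and replicates first", call. = FALSE)
  }
  if (any(table$n_t < 2 | table$n_c < 2)) {
    stop("replicate counts below 2 are not admissible", call. = FALSE)
  }
  xt <- table$mean_t; xc <- table$mean_c
  st <- table$sd_t;  sc <- table$sd_c
  nt <- table$n_t;   nc <- table$n_c

  if (method == "ROM") {
    ok <- xt > 0 & xc > 0
    if (!all(ok)) {
      message(sum(!ok), " row(s) with non-positive means dropped for ROM")
      table <- table[ok, , drop = FALSE]
      xt <- xt[ok]; xc <- xc[ok]; st <- st[ok]; sc <- sc[ok]
      nt <- nt[ok]; nc <- nc[ok]
    }
    if (!nrow(table)) stop("no rows admissible for ROM", call. = FALSE)
    yi <- log(xt / xc)
    vi <- st^2 / (nt * xt^2) + sc^2 / (nc * xc^2)
    out <- data.frame(obs_id = table$obs_id, study_id = table$study_id,
                      method = method, yi = yi, vi = vi,
                      stringsAsFactors = FALSE)
  } else if (method == "MD") {
    yi <- xt - xc
    vi <- st^2 / nt + sc^2 / nc
    out <- data.frame(obs_id = table$obs_id, study_id = table$study_id,
                      method = method, yi = yi, vi = vi,
                      stringsAsFactors = FALSE)
  } else {
    sdp <- sqrt(((nt - 1) * st^2 + (nc - 1) * sc^2) / (nt + nc - 2))
    if (any(sdp <= 0)) {
      stop("pooled SD is zero at row(s) ",
           paste(utils::head(which(sdp <= 0), 5), collapse = ", "),
           ": SMD is degenerate", call. = FALSE)
    }
    yi <- (xt - xc) / sdp
    if (hedges) yi <- yi * (1 - 3 / (4 * (nt + nc - 2) - 1))
    vi <- (nt + nc) / (nt * nc) + yi^2 / (2 * (nt + nc))
    out <- data.frame(obs_id = table$obs_id, study_id = table$study_id,
                      method = method, yi = yi, vi = vi, pooled_sd = sdp,
                      stringsAsFactors = FALSE)
  }
  if (any(out$vi <= 0)) {
    stop("non-positive sampling variance computed; check SDs", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Relative change implied by a log ratio of means
#'
#' Back-transforms a log response ratio to a percent change:
#' \eqn{(e^{y} - 1) \times 100}.
#'
#' @param yi_rom Log ratio of means (possibly a vector).
#' @return Percent change relative to the control.
#' @export
relative_change <- function(yi_rom) {
  (exp(yi_rom) - 1) * 100
}

#' Per-practice conversion context for absolute-change expressions
#'
#' Absolute NUEr changes (percentage points) are recovered from relative (ROM)
#' and standardized (SMD) effects using practice-group reference quantities:
#' the mean control-group NUEr \eqn{\bar{X}_c} and the mean pooled
#' within-group SD \eqn{\overline{SD}_p} of each management-practice class.
#'
#' @param table Observation table with complete dispersions and replicates.
#' @return A data.frame with one row per practice present: \code{practice},
#'   \code{control_mean} (\eqn{\bar{X}_c}), \code{pooled_sd_mean}
#'   (\eqn{\overline{SD}_p}), \code{n_obs}.
#' @export
conversion_context <- function(table) {
  sdp <- sqrt(((table$n_t - 1) * table$sd_t^2 + (table$n_c - 1) * table$sd_c^2) /
              (table$n_t + table$n_c - 2))
  agg <- do.call(rbind, lapply(split(seq_len(nrow(table)), table$practice),
    function(idx) {
      data.frame(practice = table$practice[idx[1]],
                 control_mean = mean(table$mean_c[idx]),
                 pooled_sd_mean = mean(sdp[idx]),
                 n_obs = length(idx), stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  agg
}

#' Absolute NUEr change from a relative (ROM-based) change
#'
#' \eqn{\Delta_{abs} = (\mathrm{relative\ change}/100) \times \bar{X}_c}:
#' the relative change is treated as a fraction of the practice-group mean
#' control NUEr, so the result is in NUEr percentage points.
#'
#' @param relative_pct Relative change in percent (from [relative_change()]).
#' @param control_mean Practice-group mean control NUEr \eqn{\bar{X}_c} (%).
#' @return Absolute change in NUEr percentage points.
#' @export
absolute_from_rom <- function(relative_pct, control_mean) {
  stopifnot(all(control_mean > 0))
  relative_pct / 100 * control_mean
}

#' Absolute NUEr change from a standardized mean difference
#'
#' \eqn{\Delta_{abs} = SMD \times \overline{SD}_p}, with
#' \eqn{\overline{SD}_p} the practice-group mean pooled within-group SD.
#'
#' @param smd Standardized mean difference (unitless).
#' @param pooled_sd_mean Practice-group mean pooled SD (NUEr %).
#' @return Absolute change in NUEr percentage points.
#' @export
absolute_from_smd <- function(smd, pooled_sd_mean) {
  stopifnot(all(pooled_sd_mean > 0))
  smd * pooled_sd_mean
}
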