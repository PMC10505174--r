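#' Specify the moderator structure of a NUEr meta-regression
#'
#' Describes the fixed-effects (moderator) structure used both when fitting
#' the meta-regression and when encoding prediction scenarios: which
#' management-practice indicators enter, the crop-type factor and its
#' reference level, the continuous site covariates (z-scored to unit
#' variance), the squared N-rate curvature term, and two-way interactions.
#'
#' Treatment coding is used throughout: mineral fertilizer, conventional
#' tillage, monoculture, no cover crop and residue removal are the implicit
#' controls, so each practice indicator is 1 only for rows that applied that
#' practice. The crop reference level defaults to wheat.
#'
#' @param metric Effect-size metric the model is meant for
#'   (\code{"MD"}, \code{"ROM"} or \code{"SMD"}).
#' @param practices Practice indicator terms to include
#'   (subset of [nue_practices]).
#' @param crops Crop levels (first acts as data check only).
#' @param crop_ref Reference crop level (default \code{"wheat"}).
#' @param site_vars Continuous site covariates to include, scaled.
#' @param n_sq Include the squared N application rate (computed from the raw
#'   rate, then scaled as its own variable)? Default \code{TRUE}.
#' @param interactions List of length-2 character vectors naming term pairs,
#'   e.g. \code{list(c("RFP", "crop_maize"), c("n_rate", "soc"))}. Parents
#'   must be practice indicators, crop dummies (\code{crop_<level>}) or
#'   continuous terms already in the spec.
#' @param cor_threshold Pairwise absolute correlation above which a
#'   collinearity warning is issued before fitting (default 0.8).
#' @return An object of class \code{nue_model_spec}.
#' @export
nue_model_spec <- function(metric = c("MD", "ROM", "SMD"),
                           practices = nue_practices,
                           crops = nue_crops,
                           crop_ref = "wheat",
                           site_vars = c("n_rate", "mat", "map", "soc", "clay", "ph"),
                           n_sq = TRUE,
                           interactions = list(),
                           cor_threshold = 0.8) {
  metric <- match.arg(metric)
  stopifnot(all(practices %in% nue_practices), crop_ref %in% crops)
  if (anyDuplicated(practices) || anyDuplicated(site_vars)) {
    stop("duplicated terms in the model specification", call. = FALSE)
  }
  crop_levels <- setdiff(crops, crop_ref)
  crop_terms <- if (length(crop_levels)) paste0("crop_", crop_levels)
                else character(0)
  cont_terms <- c(site_vars, if (n_sq) "n_sq")
  main_terms <- c(practices, crop_terms, cont_terms)
  for (ia in interactions) {
    if (length(ia) != 2L || !all(ia %in% main_terms)) {
      stop("interaction (", paste(ia, collapse = ":"),
           ") has a parent not among the main-effect terms", call. = FALSE)
    }
  }
  structure(list(metric = metric, practices = practices, crops = crops,
                 crop_ref = crop_ref, site_vars = site_vars, n_sq = n_sq,
                 interactions = interactions, cor_threshold = cor_threshold,
                 terms = c("intercept", main_terms,
                           vapply(interactions, paste, "", collapse = ":"))),
            class = "nue_model_spec")
}

#' @export
print.nue_model_spec <- function(x, ...) {
  cat("NUEr meta-regression specification (metric:", x$metric, ")\n")
  cat("  practice terms:", paste(x$practices, collapse = " "), "\n")
  cat("  crop reference:", x$crop_ref, "\n")
  cat("  site covariates:", paste(x$site_vars, collapse = " "),
      if (x$n_sq) "+ n_sq", "\n")
  if (length(x$interactions)) {
    cat("  interactions:", paste(vapply(x$interactions, paste, "",
                                        collapse = ":"), collapse = " "), "\n")
  }
  invisible(x)
}

# raw (unscaled) moderator columns implied by a spec, one row per observation
.moderator_frame <- function(table, spec) {
  out <- data.frame(row.names = seq_len(nrow(table)))
  parts <- strsplit(table$practice, "+", fixed = TRUE)
  for (p in spec$practices) {
    out[[p]] <- as.numeric(vapply(parts, function(s) p %in% s, logical(1)))
  }
  for (cl in setdiff(spec$crops, spec$crop_ref)) {
    out[[paste0("crop_", cl)]] <- as.numeric(table$crop == cl)
  }
  for (v in spec$site_vars) out[[v]] <- table[[v]]
  if (spec$n_sq) out$n_sq <- table$n_rate^2
  out
}

#' Build the design matrix for a NUEr meta-regression
#'
#' Assembles the fixed-effects design matrix from an observation table and a
#' [nue_model_spec()]: an intercept, treatment-coded practice and crop
#' indicators, continuous site covariates z-scored to unit variance (the
#' squared N rate computed from the raw rate before scaling), and the listed
#' interaction products (formed after scaling). Column order is deterministic
#' and matches \code{spec$terms}.
#'
#' Before returning, pairwise correlations among non-constant columns are
#' screened against \code{spec$cor_threshold} (warning), and the matrix rank
#' is checked: a rank-deficient design aborts with the offending columns
#' named.
#'
#' @param table Observation table (validated, covariates complete).
#' @param spec A [nue_model_spec()].
#' @param scaling Optional \code{nue_scaling} from a fitted model; when
#'   supplied, covariates are scaled by it rather than by this table's own
#'   moments (used to encode prediction grids on the training scale).
#' @return List with \code{X} (matrix, one column per term), \code{terms},
#'   and \code{scaling}.
#' @export
build_design <- function(table, spec, scaling = NULL) {
  stopifnot(inherits(spec, "nue_model_spec"))
  mods <- .moderator_frame(table, spec)
  cont <- c(spec$site_vars, if (spec$n_sq) "n_sq")
  if (length(cont)) {
    mods <- scale_covariates(mods, cont, scaling = scaling)
    scaling <- attr(mods, "scaling")
  }
  X <- cbind(intercept = 1, as.matrix(mods))
  for (ia in spec$interactions) {
    X <- cbind(X, X[, ia[1]] * X[, ia[2]])
    colnames(X)[ncol(X)] <- paste(ia, collapse = ":")
  }
  X <- X[, spec$terms, drop = FALSE]

  live <- which(apply(X[, -1, drop = FALSE], 2, stats::sd) > 0)
  if (length(live) > 1) {
    r <- suppressWarnings(stats::cor(X[, -1, drop = FALSE][, live, drop = FALSE]))
    r[!upper.tri(r)] <- 0
    hits <- which(abs(r) > spec$cor_threshold, arr.ind = TRUE)
    if (nrow(hits)) {
      pairs <- apply(hits, 1, function(ij) {
        paste0(rownames(r)[ij[1]], "~", colnames(r)[ij[2]],
               " (r = ", sprintf("%.2f", r[ij[1], ij[2]]), ")")
      })
      warning("highly correlated moderators: ",
              paste(pairs, collapse = ", "), call. = FALSE)
    }
  }
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    dep <- colnames(X)[qd$pivot[(qd$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; linearly dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  list(X = X, terms = colnames(X), scaling = scaling)
}
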