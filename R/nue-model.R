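#' Fit a NUEr management-response model from a paired-observation table
#'
#' The front door of the package: takes a validated observation table and a
#' [nue_model_spec()], completes missing dispersions and replicate counts,
#' computes per-observation effect sizes for the spec's metric, builds the
#' moderator design (scaled covariates, practice/crop indicators,
#' interactions) and fits the compound-symmetry multilevel meta-regression
#' with [nue_remr()]. The returned object carries the spec and the covariate
#' scaling so that scenario predictions on raw grids reuse the training
#' scale.
#'
#' @param table Observation table from [read_observations()] or
#'   [validate_observations()].
#' @param spec A [nue_model_spec()]; defaults to the full main-effects model
#'   on the MD metric.
#' @param method \code{"REML"} (default) or \code{"ML"}.
#' @param impute Impute missing SDs and replicate counts first?
#'   Default \code{TRUE}.
#' @param ... Passed to [nue_remr()] (e.g. \code{constraints},
#'   \code{control}).
#' @return Object of class \code{c("nue_meta_model", "nue_remr")} with extra
#'   fields \code{spec}, \code{scaling}, \code{effects} (the effect-size
#'   table) and \code{imputation}.
#' @examples
#' cfg <- nue_sim_config(n_studies = 10, obs_per_study = 3, seed = 7)
#' sim <- simulate_observations(cfg)
#' fit <- nue_meta_model(sim$observations, cfg$spec)
#' coef(fit)
#' @export
nue_meta_model <- function(table, spec = nue_model_spec(),
                           method = "REML", impute = TRUE, ...) {
  stopifnot(inherits(spec, "nue_model_spec"))
  imp <- NULL
  if (impute) {
    if (anyNA(table$n_t) || anyNA(table$n_c)) {
      table <- impute_missing_replicates(table)
    }
    if (anyNA(table$sd_t) || anyNA(table$sd_c)) {
      table <- impute_missing_sd(table)
      imp <- attr(table, "imputation")
    }
  }
  es <- effect_sizes(table, spec$metric)
  tab <- table[match(es$obs_id, table$obs_id), , drop = FALSE]
  des <- build_design(tab, spec)
  fit <- nue_remr(es$yi, es$vi, mods = des$X, study = es$study_id,
                  method = method, ...)
  fit$spec <- spec
  fit$scaling <- des$scaling
  fit$effects <- es
  fit$imputation <- imp
  class(fit) <- c("nue_meta_model", class(fit))
  fit
}

#' Serialize a fitted model to JSON
#'
#' Writes the fixed effects, their covariance, the variance components, fit
#' statistics and the covariate scaling to a JSON file so that grid
#' prediction can run without refitting.
#'
#' @param model A fitted [nue_meta_model()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "nue_remr"))
  obj <- list(beta = as.list(model$beta),
              cov_beta = unname(as.matrix(model$vb)),
              tau2 = model$tau2, rho = model$rho,
              rho_identifiable = model$rho_identifiable,
              loglik_reml = model$loglik_reml, loglik_ml = model$loglik_ml,
              qe = model$qe, k = model$k, p = model$p,
              method = model$method)
  if (!is.null(model$scaling)) {
    obj$scaling <- list(center = as.list(model$scaling$center),
                        scale = as.list(model$scaling$scale))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Human-readable coefficient table
#'
#' @param model A fitted [nue_remr()] model.
#' @return data.frame with term, estimate, se, z, p and significance stars.
#' @export
coef_table <- function(model) {
  s <- summary(model)$coefficients
  data.frame(term = rownames(s), s, row.names = NULL,
             stringsAsFactors = FALSE)
}
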