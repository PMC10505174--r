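#' Configuration for the synthetic paired-observation generator
#'
#' Describes a simulated multi-study field-trial corpus with known ground
#' truth: study-clustered true effects with compound-symmetric between-study
#' heterogeneity, moderator effects on the chosen effect-size metric, and
#' arm-level sampling noise consistent with the emitted SDs and replicate
#' counts. Defaults emulate the compiled corpus the package is designed for:
#' covariates drawn within the observed field ranges (MAT -0.6 to 29 C, MAP
#' 45 to 2330 mm, SOC 2.7 to 80 g/kg, pH 4.5 to 8.5, clay 8.8 to 53%),
#' control-plot NUEr between 20 and 60%, plot trials with 3-6 replicates,
#' and a 20% fraction of rows reporting no SD.
#'
#' @param n_studies Number of studies.
#' @param obs_per_study Observations per study: a count or a
#'   \code{c(min, max)} range.
#' @param spec [nue_model_spec()] defining the moderators the truth acts
#'   through; the default is a compact MD-metric model with three practices
#'   and an N-rate x SOC interaction.
#' @param true_beta Named coefficients (one per \code{spec$terms} entry), on
#'   the metric scale per unit scaled moderator. The default magnitudes
#'   mirror field-plausible absolute NUEr responses (practice effects of
#'   6-10 percentage points, negative N-rate and clay slopes, positive SOC,
#'   MAP and pH slopes).
#' @param tau2 Between-effect heterogeneity variance of the true effects.
#' @param rho Within-study compound-symmetry correlation, in \code{[0, 1)}.
#' @param sd_range Range of arm-level SDs (NUEr %).
#' @param rep_range Range of replicate counts.
#' @param covariate_ranges Named list of \code{c(low, high)} per site
#'   covariate.
#' @param control_mean_range Range of control-plot NUEr (%).
#' @param practice_mix Named probabilities over \code{spec$practices}
#'   (default uniform) for the primary practice of each treatment arm.
#' @param bundle_frac Fraction of treatment arms that co-apply a second,
#'   distinct practice (written \code{"A+B"} in the practice column;
#'   default 0.3). Multi-practice arms occur throughout field corpora and
#'   keep the practice indicators from summing to the intercept.
#' @param drop_sd_frac Fraction of rows whose SDs are withheld to exercise
#'   imputation (default 0.2).
#' @param seed Integer seed; the generator is bit-reproducible from
#'   (config, seed).
#' @return Object of class \code{nue_sim_config}.
#' @export
nue_sim_config <- function(n_studies = 30, obs_per_study = 5,
                           spec = NULL, true_beta = NULL,
                           tau2 = 4, rho = 0.5,
                           sd_range = c(3, 8), rep_range = c(3, 6),
                           covariate_ranges = list(
                             n_rate = c(50, 350), mat = c(-0.6, 29),
                             map = c(45, 2330), soc = c(2.7, 80),
                             clay = c(8.8, 53), ph = c(4.5, 8.5)),
                           control_mean_range = c(20, 60),
                           practice_mix = NULL, bundle_frac = 0.3,
                           drop_sd_frac = 0.2, seed = 42) {
  if (is.null(spec)) {
    spec <- nue_model_spec(metric = "MD",
                           practices = c("EE", "RFR", "CC"),
                           site_vars = c("n_rate", "mat", "map", "soc",
                                         "clay", "ph"),
                           n_sq = FALSE,
                           interactions = list(c("n_rate", "soc")))
  }
  if (is.null(true_beta)) {
    true_beta <- c(intercept = 5, EE = 8, RFR = 10, CC = 6,
                   crop_maize = 2, crop_rice = -1,
                   n_rate = -2, mat = 0.5, map = 1, soc = 1.5,
                   clay = -1, ph = 1, `n_rate:soc` = 1.5)
  }
  if (!setequal(names(true_beta), spec$terms)) {
    stop("true_beta names must match spec$terms exactly; missing: ",
         paste(setdiff(spec$terms, names(true_beta)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(practice_mix)) {
    practice_mix <- stats::setNames(rep(1 / length(spec$practices),
                                        length(spec$practices)),
                                    spec$practices)
  }
  stopifnot(n_studies >= 1, tau2 >= 0, rho >= 0, rho < 1,
            sd_range[1] > 0, sd_range[1] <= sd_range[2],
            rep_range[1] >= 2, drop_sd_frac >= 0, drop_sd_frac < 1,
            abs(sum(practice_mix) - 1) < 1e-8,
            bundle_frac >= 0, bundle_frac <= 1,
            control_mean_range[1] < control_mean_range[2])
  for (rg in covariate_ranges) stopifnot(rg[1] < rg[2])
  structure(list(n_studies = n_studies, obs_per_study = obs_per_study,
                 spec = spec, true_beta = true_beta[spec$terms],
                 tau2 = tau2, rho = rho, sd_range = sd_range,
                 rep_range = rep_range, covariate_ranges = covariate_ranges,
                 control_mean_range = control_mean_range,
                 practice_mix = practice_mix, bundle_frac = bundle_frac,
                 drop_sd_frac = drop_sd_frac, seed = seed),
            class = "nue_sim_config")
}

.runif_range <- function(n, rg) stats::runif(n, rg[1], rg[2])

#' Generate a synthetic paired-observation table with known ground truth
#'
#' Draws study-clustered observations under the configured model. Per study,
#' true-effect deviations follow the compound-symmetric structure (a shared
#' component of variance \eqn{\rho\tau^2} plus an idiosyncratic component of
#' variance \eqn{(1-\rho)\tau^2}); per observation, covariates, crop and one
#' practice are drawn, the true effect is \eqn{\mathbf{x}^\top\beta + u},
#' and arm means are drawn so that the computed effect size equals the true
#' effect plus sampling error with the variance implied by the emitted SDs
#' and replicate counts (exact for the MD metric; for ROM and SMD the arm
#' means are derived from the target ratio or standardized difference and the
#' sampling error is normal on the arm-mean scale).
#'
#' The truth is defined on the sample-scaled covariate scale: the design is
#' built with the same scaling a downstream fit recomputes from this table,
#' so recovery experiments compare like with like.
#'
#' @param config A [nue_sim_config()].
#' @return List with \code{observations} (a valid observation table) and
#'   \code{truth} (\code{beta}, \code{tau2}, \code{rho}, \code{spec},
#'   \code{scaling}, per-observation \code{true_effect} and study deviation
#'   \code{u}).
#' @export
simulate_observations <- function(config) {
  stopifnot(inherits(config, "nue_sim_config"))
  set.seed(config$seed)
  spec <- config$spec
  sizes <- if (length(config$obs_per_study) == 2L) {
    sample(seq(config$obs_per_study[1], config$obs_per_study[2]),
           config$n_studies, replace = TRUE)
  } else rep(config$obs_per_study, config$n_studies)
  n <- sum(sizes)
  study <- rep(seq_len(config$n_studies), sizes)

  tab <- data.frame(
    study_id = sprintf("s%03d", study),
    obs_id = sprintf("s%03d_o%02d", study,
                     unlist(lapply(sizes, seq_len))),
    practice = sample(names(config$practice_mix), n, replace = TRUE,
                      prob = config$practice_mix),
    crop = sample(spec$crops, n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (config$bundle_frac > 0 && length(spec$practices) > 1) {
    add_second <- stats::runif(n) < config$bundle_frac
    second <- vapply(tab$practice, function(p) {
      sample(setdiff(spec$practices, p), 1)
    }, character(1))
    tab$practice[add_second] <- paste(tab$practice[add_second],
                                      second[add_second], sep = "+")
  }
  for (v in names(config$covariate_ranges)) {
    tab[[v]] <- .runif_range(n, config$covariate_ranges[[v]])
  }
  tab$lat <- stats::runif(n, -50, 60)
  tab$lon <- stats::runif(n, -180, 180)

  des <- build_design(tab, spec)
  xb <- as.numeric(des$X %*% config$true_beta[des$terms])

  shared <- stats::rnorm(config$n_studies, 0,
                         sqrt(config$rho * config$tau2))[study]
  own <- stats::rnorm(n, 0, sqrt((1 - config$rho) * config$tau2))
  u <- shared + own
  delta <- xb + u

  sd_t <- .runif_range(n, config$sd_range)
  sd_c <- .runif_range(n, config$sd_range)
  n_t <- sample(seq(config$rep_range[1], config$rep_range[2]), n,
                replace = TRUE)
  n_c <- sample(seq(config$rep_range[1], config$rep_range[2]), n,
                replace = TRUE)
  mu_c <- .runif_range(n, config$control_mean_range)
  e_c <- stats::rnorm(n, 0, sd_c / sqrt(n_c))
  e_t <- stats::rnorm(n, 0, sd_t / sqrt(n_t))

  if (spec$metric == "MD") {
    mean_c <- mu_c + e_c
    mean_t <- mu_c + delta + e_t
  } else if (spec$metric == "ROM") {
    # delta is a log ratio; sampling error enters on the arm-mean scale
    mean_c <- mu_c + e_c
    mean_t <- mu_c * exp(delta) + e_t
  } else {
    # delta is a standardized difference; convert via the pooled SD
    sdp <- sqrt(((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / (n_t + n_c - 2))
    mean_c <- mu_c + e_c
    mean_t <- mu_c + delta * sdp + e_t
  }
  tab$mean_t <- mean_t
  tab$mean_c <- mean_c
  tab$sd_t <- sd_t
  tab$sd_c <- sd_c
  tab$n_t <- n_t
  tab$n_c <- n_c
  if (config$drop_sd_frac > 0) {
    drop <- stats::runif(n) < config$drop_sd_frac
    # never drop every SD: imputation needs at least one reported pair
    if (all(drop)) drop[1] <- FALSE
    tab$sd_t[drop] <- NA_real_
    tab$sd_c[drop] <- NA_real_
  }
  obs <- validate_observations(tab)
  truth <- list(beta = config$true_beta[des$terms], tau2 = config$tau2,
                rho = config$rho, spec = spec, scaling = des$scaling,
                true_effect = delta, u = u, xb = xb)
  list(observations = obs, truth = truth)
}

#' Generate a synthetic covariate grid
#'
#' Cells with site covariates uniform within the configured ranges, random
#' crop shares summing to at most 1, and positive cropland-area weights.
#'
#' @param n_cells Number of cells (>= 1).
#' @param config A [nue_sim_config()] supplying covariate ranges and crops.
#' @param seed Integer seed (default: the config's seed plus 1).
#' @return data.frame of grid cells compatible with [predict_grid()].
#' @export
simulate_grid <- function(n_cells, config = nue_sim_config(), seed = NULL) {
  stopifnot(n_cells >= 1)
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  g <- data.frame(cell_id = sprintf("c%04d", seq_len(n_cells)),
                  lat = stats::runif(n_cells, -50, 60),
                  lon = stats::runif(n_cells, -180, 180),
                  stringsAsFactors = FALSE)
  for (v in names(config$covariate_ranges)) {
    g[[v]] <- .runif_range(n_cells, config$covariate_ranges[[v]])
  }
  raw <- matrix(stats::runif(3 * n_cells), n_cells, 3)
  tot <- stats::runif(n_cells, 0.3, 1)
  sh <- raw / rowSums(raw) * tot
  crops <- config$spec$crops
  for (j in seq_along(crops)) g[[paste0("share_", crops[j])]] <- sh[, j]
  g$area_weight <- stats::runif(n_cells, 0.1, 1)
  g
}

#' Monte Carlo parameter-recovery experiment
#'
#' Repeatedly simulates a corpus under known truth, runs the full pipeline
#' (imputation if SDs were withheld, effect sizes, design, REML fit), and
#' records per-coefficient 95% Wald CI coverage of the true beta and the
#' heterogeneity estimates. Replicate r uses seed \code{config$seed + r}.
#'
#' @param config A [nue_sim_config()].
#' @param n_rep Number of Monte Carlo replicates (default 200).
#' @return List with \code{coverage} (named per-coefficient coverage
#'   proportions), \code{bias} (mean estimate minus truth),
#'   \code{tau2_mean}, \code{tau2_rel_bias}, \code{rho_mean}, \code{n_rep}.
#' @export
recovery_experiment <- function(config, n_rep = 200) {
  stopifnot(inherits(config, "nue_sim_config"))
  terms <- config$spec$terms
  hits <- matrix(0, n_rep, length(terms), dimnames = list(NULL, terms))
  est <- matrix(NA_real_, n_rep, length(terms), dimnames = list(NULL, terms))
  tau2_hat <- rho_hat <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_observations(cfg)
    fit <- nue_meta_model(sim$observations, cfg$spec)
    b <- coef(fit)[terms]
    se <- sqrt(diag(vcov(fit)))[terms]
    truth <- sim$truth$beta[terms]
    hits[r, ] <- as.numeric(truth >= b - 1.96 * se & truth <= b + 1.96 * se)
    est[r, ] <- b
    tau2_hat[r] <- fit$tau2
    rho_hat[r] <- fit$rho
  }
  list(coverage = colMeans(hits),
       bias = colMeans(est) - config$true_beta[terms],
       tau2_mean = mean(tau2_hat),
       tau2_rel_bias = if (config$tau2 > 0)
         (mean(tau2_hat) - config$tau2) / config$tau2 else NA_real_,
       rho_mean = mean(rho_hat),
       n_rep = n_rep)
}
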