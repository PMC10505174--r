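#' Management practice codes
#'
#' The eleven management-practice classes recognised throughout the package:
#' nutrient management (EE enhanced-efficiency fertilizer, CF combined
#' mineral/organic fertilizer, OF organic fertilizer, RFP right fertilizer
#' placement, RFR right fertilizer rate, RFT right fertilizer timing), crop
#' management (RES residue retention, CC cover cropping, ROT crop rotation)
#' and soil management (ZT zero tillage, RT reduced tillage).
#'
#' @format Character vector of length 11.
#' @export
nue_practices <- c("EE", "CF", "OF", "RFP", "RFR", "RFT",
                   "RES", "CC", "ROT", "ZT", "RT")

#' Crop types covered by the observation model
#' @format Character vector of length 3.
#' @export
nue_crops <- c("wheat", "maize", "rice")

# columns every observation table must carry
.required_cols <- c("study_id", "obs_id", "practice", "crop",
                    "mean_t", "mean_c", "n_rate",
                    "mat", "map", "soc", "clay", "ph")
.numeric_cols <- c("mean_t", "mean_c", "sd_t", "sd_c", "n_t", "n_c",
                   "n_rate", "mat", "map", "soc", "clay", "ph",
                   "lat", "lon", "duration_yr")

#' Read and validate a paired-observation table
#'
#' Reads a CSV of control--treatment pairs of nitrogen recovery efficiency
#' (NUEr, %) observations and validates it against the package's observation
#' schema. Each row is one pair: group means (and, when reported, SDs and
#' replicate counts) of NUEr under a management practice and under the
#' conventional control, plus the site covariates used as moderators
#' (N application rate, MAT, MAP, SOC, clay, pH).
#'
#' The \code{practice} column names the practice applied in the treatment
#' arm; treatment arms combining several practices are written with
#' \code{+}, e.g. \code{"RFR+ZT"}.
#'
#' Rows violating hard invariants (non-positive replicate counts below 2,
#' negative SDs, pH outside 0--14, clay outside 0--100, negative N rate,
#' missing site covariates) are rejected; the returned table carries the
#' row-indexed diagnostics in \code{attr(x, "rejected")}. Rows with
#' \code{mean_c <= 0} or \code{mean_t <= 0} are retained but flagged
#' \code{valid_rom = FALSE}, since the log ratio of means is undefined there
#' while mean-difference effect sizes are not.
#'
#' @param path Path to a CSV file (UTF-8, header row, \code{NA} or empty for
#'   missing).
#' @param schema Optional named character vector mapping package column names
#'   to the file's column names, e.g. \code{c(mean_t = "treat_mean")}.
#' @return A \code{data.frame} of validated observations with attributes
#'   \code{rejected} (diagnostics for dropped rows).
#' @seealso [validate_observations()], [impute_missing_sd()],
#'   [impute_missing_replicates()]
#' @export
read_observations <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop("observation file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!is.null(schema)) {
    for (std in names(schema)) {
      src <- schema[[std]]
      if (!src %in% names(raw)) {
        stop("schema maps '", std, "' to missing column '", src, "'", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  validate_observations(raw)
}

#' Validate an in-memory observation table
#'
#' @param table A data.frame with the observation columns (see
#'   [read_observations()]).
#' @return The validated table; see [read_observations()] for the attached
#'   diagnostics.
#' @export
validate_observations <- function(table) {
  missing_cols <- setdiff(.required_cols, names(table))
  if (length(missing_cols)) {
    stop("observation table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cn in intersect(.numeric_cols, names(table))) {
    if (!is.numeric(table[[cn]])) {
      suppressWarnings(num <- as.numeric(table[[cn]]))
      bad <- which(!is.na(table[[cn]]) & is.na(num))
      if (length(bad)) {
        stop("non-numeric value in column '", cn, "' at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      table[[cn]] <- num
    }
  }
  for (cn in c("sd_t", "sd_c", "n_t", "n_c")) {
    if (!cn %in% names(table)) table[[cn]] <- NA_real_
  }
  practice_parts <- strsplit(table$practice, "+", fixed = TRUE)
  bad_practice <- !vapply(practice_parts, function(p) {
    length(p) > 0 && all(p %in% nue_practices)
  }, logical(1))
  bad_crop <- !table$crop %in% nue_crops
  covars <- c("n_rate", "mat", "map", "soc", "clay", "ph")
  cov_missing <- rowSums(is.na(table[covars])) > 0
  reasons <- list(
    "unknown practice code"      = bad_practice,
    "unknown crop type"          = bad_crop,
    "missing mean"               = is.na(table$mean_t) | is.na(table$mean_c),
    "negative SD"                = (!is.na(table$sd_t) & table$sd_t < 0) |
                                   (!is.na(table$sd_c) & table$sd_c < 0),
    "replicate count below 2"    = (!is.na(table$n_t) & table$n_t < 2) |
                                   (!is.na(table$n_c) & table$n_c < 2),
    "negative N rate"            = !is.na(table$n_rate) & table$n_rate < 0,
    "pH outside [0, 14]"         = !is.na(table$ph) & (table$ph < 0 | table$ph > 14),
    "clay outside [0, 100]"      = !is.na(table$clay) & (table$clay < 0 | table$clay > 100),
    "missing site covariate"     = cov_missing
  )
  reject <- Reduce(`|`, reasons)
  reject[is.na(reject)] <- TRUE
  rejected <- data.frame(row = which(reject),
                         reason = rep(NA_character_, sum(reject)))
  if (nrow(rejected)) {
    rejected$reason <- vapply(rejected$row, function(i) {
      hits <- names(reasons)[vapply(reasons, function(r) isTRUE(r[i]), logical(1))]
      paste(hits, collapse = "; ")
    }, character(1))
  }
  out <- table[!reject, , drop = FALSE]
  rownames(out) <- NULL
  out$valid_rom <- out$mean_c > 0 & out$mean_t > 0
  attr(out, "rejected") <- rejected
  out
}

#' Impute missing standard deviations from the mean coefficient of variation
#'
#' Studies often report group means without dispersions. Missing SDs are
#' filled in as \deqn{SD_i = \overline{CV} \times \bar{x}_i \times 1.25,}
#' where \eqn{\overline{CV}} is the mean coefficient of variation (SD/mean)
#' over all rows that do report an SD, and the factor 1.25 inflates the
#' imputed dispersion to penalise non-reporting. By default one pooled
#' \eqn{\overline{CV}} is computed over treatment and control arms together;
#' \code{pool = "per_arm"} computes one CV per arm.
#'
#' @param table Validated observation table.
#' @param inflation Multiplicative inflation factor for imputed SDs
#'   (default 1.25).
#' @param pool \code{"pooled"} (one CV over both arms, the default) or
#'   \code{"per_arm"}.
#' @return The table with \code{sd_t}/\code{sd_c} completed, logical flags
#'   \code{sd_t_imputed}/\code{sd_c_imputed}, and the imputation parameters
#'   in \code{attr(x, "imputation")} (\code{cv_mean}, per-arm CVs,
#'   \code{inflation}).
#' @export
impute_missing_sd <- function(table, inflation = 1.25,
                              pool = c("pooled", "per_arm")) {
  pool <- match.arg(pool)
  stopifnot(inflation > 0)
  cv_t <- table$sd_t / table$mean_t
  cv_c <- table$sd_c / table$mean_c
  cv_t <- cv_t[is.finite(cv_t)]
  cv_c <- cv_c[is.finite(cv_c)]
  if (!length(cv_t) && !length(cv_c)) {
    stop("cannot impute SDs: no row reports a standard deviation", call. = FALSE)
  }
  cv_all <- mean(c(cv_t, cv_c))
  cv_arm_t <- if (length(cv_t)) mean(cv_t) else cv_all
  cv_arm_c <- if (length(cv_c)) mean(cv_c) else cv_all
  use_t <- if (pool == "pooled") cv_all else cv_arm_t
  use_c <- if (pool == "pooled") cv_all else cv_arm_c
  miss_t <- is.na(table$sd_t)
  miss_c <- is.na(table$sd_c)
  table$sd_t[miss_t] <- use_t * table$mean_t[miss_t] * inflation
  table$sd_c[miss_c] <- use_c * table$mean_c[miss_c] * inflation
  table$sd_t_imputed <- if (is.null(table$sd_t_imputed)) miss_t else table$sd_t_imputed | miss_t
  table$sd_c_imputed <- if (is.null(table$sd_c_imputed)) miss_c else table$sd_c_imputed | miss_c
  attr(table, "imputation") <- list(cv_mean = cv_all, cv_t = cv_arm_t,
                                    cv_c = cv_arm_c, inflation = inflation,
                                    pool = pool)
  table
}

#' Impute missing replicate counts
#'
#' Replicate counts not reported by the primary study are set to a fixed
#' default (3, the typical plot-trial design). Reported counts are left
#' untouched; counts below 2 are a validation error because every sampling
#' variance formula degenerates there.
#'
#' @param table Validated observation table.
#' @param default Replicate count used for missing values (default 3).
#' @return The table with \code{n_t}/\code{n_c} completed and flags
#'   \code{n_t_imputed}/\code{n_c_imputed}.
#' @export
impute_missing_replicates <- function(table, default = 3) {
  stopifnot(default >= 2)
  bad <- which((!is.na(table$n_t) & table$n_t < 2) |
               (!is.na(table$n_c) & table$n_c < 2))
  if (length(bad)) {
    stop("replicate count below 2 at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": variance formulas are degenerate", call. = FALSE)
  }
  miss_t <- is.na(table$n_t)
  miss_c <- is.na(table$n_c)
  table$n_t[miss_t] <- default
  table$n_c[miss_c] <- default
  table$n_t_imputed <- miss_t
  table$n_c_imputed <- miss_c
  table
}

#' Centre and scale continuous covariates to unit variance
#'
#' Z-scores the named columns (subtract the sample mean, divide by the sample
#' SD) and records the centres and scales so that model coefficients and grid
#' predictions can be mapped back to original units. The squared N-rate term
#' used as a curvature moderator is computed from the raw rate first and then
#' scaled as its own variable.
#'
#' @param table Observation table.
#' @param vars Character vector of columns to scale.
#' @param scaling Optional scaling parameters from a previous call (a
#'   \code{nue_scaling} object); when supplied, its centres/scales are applied
#'   instead of re-estimating (as required when preparing prediction grids).
#' @return The table with scaled columns, plus the scaling parameters in
#'   \code{attr(x, "scaling")}: a list with \code{center}, \code{scale} and
#'   \code{range} (observed min/max, used for extrapolation warnings).
#' @export
scale_covariates <- function(table, vars, scaling = NULL) {
  if (is.null(scaling)) {
    center <- vapply(vars, function(v) mean(table[[v]]), numeric(1))
    scl <- vapply(vars, function(v) stats::sd(table[[v]]), numeric(1))
    degenerate <- names(scl)[!is.finite(scl) | scl <= 0]
    if (length(degenerate)) {
      stop("cannot scale constant column(s): ",
           paste(degenerate, collapse = ", "), call. = FALSE)
    }
    rng <- lapply(vars, function(v) range(table[[v]]))
    names(rng) <- vars
    scaling <- structure(list(center = center, scale = scl, range = rng),
                         class = "nue_scaling")
  } else {
    stopifnot(inherits(scaling, "nue_scaling"), all(vars %in% names(scaling$center)))
  }
  for (v in vars) {
    table[[v]] <- (table[[v]] - scaling$center[[v]]) / scaling$scale[[v]]
  }
  attr(table, "scaling") <- scaling
  table
}

#' Invert covariate scaling
#'
#' @param x Numeric vector on the scaled scale.
#' @param var Variable name.
#' @param scaling A \code{nue_scaling} object.
#' @return \code{x} mapped back to original units.
#' @export
unscale_covariate <- function(x, var, scaling) {
  stopifnot(inherits(scaling, "nue_scaling"))
  x * scaling$scale[[var]] + scaling$center[[var]]
}
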