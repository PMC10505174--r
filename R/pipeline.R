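.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full NUEr meta-analysis pipeline from one configuration
#'
#' Orchestrates imputation, effect-size computation, model fitting and
#' (optionally) grid prediction and area-weighted summary, writing every
#' intermediate artifact plus a JSON manifest with content hashes. Rerunning
#' with identical inputs and seed reproduces identical outputs.
#'
#' The configuration is a list (or path to a YAML file) with fields:
#' \describe{
#'   \item{out_dir}{Output directory (created if absent).}
#'   \item{seed}{Integer seed used for any synthetic input.}
#'   \item{observations}{Path to an observation CSV, or \code{NULL} to use
#'     the synthetic generator.}
#'   \item{synthetic}{Named arguments for [nue_sim_config()] (used when
#'     \code{observations} is \code{NULL}).}
#'   \item{spec}{Named arguments for [nue_model_spec()]; interactions may be
#'     given as a list of 2-element vectors.}
#'   \item{grid}{Path to a grid CSV, a list \code{list(n_cells = ...)} for a
#'     synthetic grid, or \code{NULL} to skip upscaling.}
#'   \item{scenario}{List with \code{name} and \code{practices} for the
#'     scenario contrasted against the conventional baseline.}
#' }
#'
#' @param config Configuration list or path to a YAML file.
#' @return The run manifest (named list), invisibly; also written as
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required",
                                    call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  spec_args <- config$spec
  if (!is.null(spec_args$interactions)) {
    spec_args$interactions <- lapply(spec_args$interactions, unlist)
  }
  spec <- .stage("spec", do.call(nue_model_spec, if (is.null(spec_args))
    list() else spec_args))

  files <- character(0)
  counts <- list()
  emit <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    files <<- c(files, path)
    counts[[name]] <<- nrow(obj)
    path
  }

  if (!is.null(config$observations)) {
    obs <- .stage("ingest", read_observations(config$observations,
                                              schema = config$schema))
  } else {
    sim_args <- if (is.null(config$synthetic)) list() else config$synthetic
    sim_args$spec <- spec
    sim_args$seed <- seed
    sim <- .stage("simulate",
                  simulate_observations(do.call(nue_sim_config, sim_args)))
    obs <- sim$observations
  }
  obs <- .stage("impute", {
    if (anyNA(obs$n_t) || anyNA(obs$n_c)) obs <- impute_missing_replicates(obs)
    if (anyNA(obs$sd_t) || anyNA(obs$sd_c)) obs <- impute_missing_sd(obs)
    obs
  })
  emit(obs, "observations_clean.csv")

  es <- .stage("effects", effect_sizes(obs, spec$metric))
  emit(es, "effects.csv")

  fit <- .stage("fit", nue_meta_model(obs, spec, impute = FALSE))
  model_path <- file.path(config$out_dir, "model.json")
  write_model_json(fit, model_path)
  files <- c(files, model_path)
  emit(coef_table(fit), "coefficients.csv")

  if (!is.null(config$grid)) {
    grid <- .stage("grid", {
      if (is.character(config$grid)) {
        utils::read.csv(config$grid, stringsAsFactors = FALSE)
      } else {
        n_cells <- config$grid$n_cells
        simulate_grid(n_cells, nue_sim_config(spec = spec, seed = seed),
                      seed = seed + 1L)
      }
    })
    sc <- config$scenario
    scenario <- .stage("scenario", nue_scenario(
      name = if (is.null(sc$name)) "scenario" else sc$name,
      practices = unlist(sc$practices)))
    pred <- .stage("predict", predict_grid(fit, grid, scenario))
    emit(pred, "predictions.csv")
    emit(.stage("summarize", summarize_grid(pred, grid)), "summary.csv")
  }

  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    package_version = as.character(utils::packageVersion("nuemeta")),
    inputs = list(observations = config$observations, grid = config$grid),
    row_counts = counts,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
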