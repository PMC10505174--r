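#' Define a management scenario
#'
#' A scenario is a set of practice indicators switched on simultaneously in
#' one design row. Bundles (e.g. the 4R nutrient-stewardship set plus
#' enhanced-efficiency, combined and organic fertilizer) are encoded jointly,
#' so interaction terms contribute; a bundle is not the sum of separately
#' predicted single practices.
#'
#' @param name Scenario label.
#' @param practices Character vector of practice codes set to 1
#'   (subset of [nue_practices]); empty for the conventional baseline.
#' @param n_rate Optional N application rate (kg N/ha) overriding the grid
#'   cell's rate (e.g. a rate-optimised variant of RFR).
#' @param description Free-text note.
#' @return Object of class \code{nue_scenario}.
#' @export
nue_scenario <- function(name, practices = character(), n_rate = NULL,
                         description = "") {
  stopifnot(all(practices %in% nue_practices))
  structure(list(name = name, practices = unique(practices),
                 n_rate = n_rate, description = description),
            class = "nue_scenario")
}

#' @export
print.nue_scenario <- function(x, ...) {
  cat("Scenario '", x$name, "': ",
      if (length(x$practices)) paste(x$practices, collapse = " + ")
      else "(baseline, no practices)", "\n", sep = "")
  if (!is.null(x$n_rate)) cat("  N rate override:", x$n_rate, "kg N/ha\n")
  invisible(x)
}

#' Encode a scenario at a grid cell as a model design row
#'
#' Builds the design row for one crop in one grid cell under a scenario:
#' intercept, the scenario's practice indicators, the crop indicator,
#' the cell's site covariates scaled by the training-scale parameters (the
#' squared N rate computed from the raw rate first), and all interaction
#' products. Covariates outside the calibration range recorded in
#' \code{scaling} trigger an extrapolation warning (prediction proceeds).
#'
#' @param scenario A [nue_scenario()].
#' @param cell One-row data.frame (or list) with \code{n_rate}, \code{mat},
#'   \code{map}, \code{soc}, \code{clay}, \code{ph} and optionally
#'   \code{cell_id}.
#' @param crop Crop type for the row.
#' @param spec The [nue_model_spec()] of the fitted model.
#' @param scaling The model's \code{nue_scaling} (training-scale centres,
#'   scales and calibration ranges).
#' @param warn_extrapolation Emit the warning? Default \code{TRUE}.
#' @return Named numeric vector in \code{spec$terms} order.
#' @export
encode_scenario <- function(scenario, cell, crop, spec, scaling,
                            warn_extrapolation = TRUE) {
  stopifnot(inherits(scenario, "nue_scenario"),
            inherits(spec, "nue_model_spec"),
            crop %in% spec$crops)
  raw <- list()
  for (v in spec$site_vars) raw[[v]] <- as.numeric(cell[[v]])
  if (!is.null(scenario$n_rate)) raw$n_rate <- scenario$n_rate
  if (spec$n_sq) raw$n_sq <- raw$n_rate^2

  if (warn_extrapolation && !is.null(scaling$range)) {
    out_of_range <- names(raw)[vapply(names(raw), function(v) {
      rng <- scaling$range[[v]]
      !is.null(rng) && (raw[[v]] < rng[1] || raw[[v]] > rng[2])
    }, logical(1))]
    if (length(out_of_range)) {
      warning("covariate(s) outside the calibration range",
              if (!is.null(cell$cell_id)) paste0(" at cell ", cell$cell_id),
              ": ", paste(out_of_range, collapse = ", "), call. = FALSE)
    }
  }
  x <- numeric(length(spec$terms))
  names(x) <- spec$terms
  x["intercept"] <- 1
  for (p in intersect(scenario$practices, spec$practices)) x[p] <- 1
  if (crop != spec$crop_ref) x[paste0("crop_", crop)] <- 1
  for (v in names(raw)) {
    if (v %in% spec$terms) {
      x[v] <- (raw[[v]] - scaling$center[[v]]) / scaling$scale[[v]]
    }
  }
  for (ia in spec$interactions) {
    x[paste(ia, collapse = ":")] <- x[ia[1]] * x[ia[2]]
  }
  x
}

.grid_share_cols <- function(grid, crops) {
  sc <- paste0("share_", crops)
  missing_cols <- setdiff(sc, names(grid))
  if (length(missing_cols)) {
    stop("grid lacks crop-share column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sh <- as.matrix(grid[sc])
  if (any(sh < 0) || any(rowSums(sh) > 1 + 1e-8)) {
    stop("crop shares must be nonnegative and sum to at most 1 per cell",
         call. = FALSE)
  }
  sh
}

#' Predict the management-induced NUEr change over a covariate grid
#'
#' For every grid cell and every crop with a nonzero share, forms the
#' fixed-effects contrast between the scenario row and the baseline row,
#' averages the contrast vectors with the cell's crop shares, and evaluates
#' \eqn{\Delta \widehat{NUEr} = \mathbf{d}^\top \hat\beta} with
#' \eqn{se = \sqrt{\mathbf{d}^\top \mathrm{Cov}(\hat\beta)\, \mathbf{d}}}
#' and the 95% interval \eqn{\pm 1.96\, se}. Only fixed-effects uncertainty
#' enters the interval; \code{interval = "prediction"} adds the
#' heterogeneity variance \eqn{\tau^2}.
#'
#' @param model A fitted [nue_meta_model()] (must carry spec and scaling).
#'   A warning is emitted if the model metric is not MD, the metric
#'   recommended for upscaling because its scale is NUEr percentage points.
#' @param grid data.frame of cells: \code{cell_id}, site covariates,
#'   \code{share_wheat}/\code{share_maize}/\code{share_rice} and
#'   \code{area_weight} (see [simulate_grid()]).
#' @param scenario A [nue_scenario()].
#' @param baseline Baseline [nue_scenario()]; defaults to the conventional
#'   all-zero scenario.
#' @param interval \code{"confidence"} (default) or \code{"prediction"}.
#' @return data.frame with one row per cell having any crop share:
#'   \code{cell_id}, \code{delta_nuer_mean}, \code{se}, \code{ci_low},
#'   \code{ci_high}.
#' @export
predict_grid <- function(model, grid, scenario,
                         baseline = nue_scenario("conventional"),
                         interval = c("confidence", "prediction")) {
  interval <- match.arg(interval)
  stopifnot(inherits(model, "nue_meta_model"))
  if (!nrow(grid)) stop("empty grid", call. = FALSE)
  spec <- model$spec
  if (spec$metric != "MD") {
    warning("model metric is ", spec$metric,
            "; MD is recommended for upscaling (results are on the ",
            spec$metric, " scale)", call. = FALSE)
  }
  shares <- .grid_share_cols(grid, spec$crops)
  keep <- rowSums(shares) > 0
  if (!any(keep)) stop("no grid cell has a positive crop share", call. = FALSE)
  if (any(!keep)) {
    message(sum(!keep), " cell(s) with zero crop share skipped")
  }
  rows <- which(keep)
  D <- matrix(0, length(rows), length(spec$terms),
              dimnames = list(NULL, spec$terms))
  extrap <- character(0)
  for (j in seq_along(rows)) {
    i <- rows[j]
    cell <- grid[i, , drop = FALSE]
    w <- shares[i, ]
    w <- w / sum(w)
    d <- numeric(length(spec$terms))
    for (cr in spec$crops[w > 0]) {
      xs <- withCallingHandlers(
        encode_scenario(scenario, cell, cr, spec, model$scaling),
        warning = function(cnd) {
          extrap <<- c(extrap, as.character(cell$cell_id))
          invokeRestart("muffleWarning")
        })
      xb <- suppressWarnings(
        encode_scenario(baseline, cell, cr, spec, model$scaling,
                        warn_extrapolation = FALSE))
      d <- d + w[paste0("share_", cr)] * (xs - xb)
    }
    D[j, ] <- d
  }
  if (length(unique(extrap))) {
    warning(length(unique(extrap)),
            " cell(s) have covariates outside the calibration range: ",
            paste(utils::head(unique(extrap), 5), collapse = ", "),
            if (length(unique(extrap)) > 5) ", ...", call. = FALSE)
  }
  pr <- predict.nue_remr(model, newmods = D, interval = interval)
  out <- data.frame(cell_id = grid$cell_id[rows],
                    delta_nuer_mean = pr$mean, se = pr$se,
                    ci_low = pr$ci_low, ci_high = pr$ci_high,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Area-weighted summary of grid predictions
#'
#' Cropland-area-weighted means of the per-cell predicted change and its CI
#' bounds, globally and (when a region map is given) per region. Weights are
#' renormalized over the cells present in \code{predictions}.
#'
#' @param predictions Output of [predict_grid()].
#' @param grid The grid the predictions were computed on (supplies
#'   \code{area_weight} per \code{cell_id}).
#' @param regions Optional named character vector or data.frame
#'   (\code{cell_id}, \code{region}) assigning cells to regions.
#' @return data.frame with rows \code{global} (and one per region):
#'   weighted \code{delta_nuer_mean}, \code{ci_low}, \code{ci_high},
#'   \code{n_cells}, total \code{weight}.
#' @export
summarize_grid <- function(predictions, grid, regions = NULL) {
  idx <- match(predictions$cell_id, grid$cell_id)
  if (anyNA(idx)) stop("predictions contain cell_ids absent from the grid",
                       call. = FALSE)
  w <- grid$area_weight[idx]
  if (any(w < 0)) stop("negative area weights", call. = FALSE)
  wmean <- function(x, w) {
    if (sum(w) <= 0) stop("total area weight is zero", call. = FALSE)
    sum(x * w) / sum(w)
  }
  one <- function(label, sel) {
    data.frame(region = label,
               delta_nuer_mean = wmean(predictions$delta_nuer_mean[sel], w[sel]),
               ci_low = wmean(predictions$ci_low[sel], w[sel]),
               ci_high = wmean(predictions$ci_high[sel], w[sel]),
               n_cells = sum(sel), weight = sum(w[sel]),
               stringsAsFactors = FALSE)
  }
  out <- one("global", rep(TRUE, nrow(predictions)))
  if (!is.null(regions)) {
    if (is.data.frame(regions)) {
      regions <- stats::setNames(regions$region, regions$cell_id)
    }
    reg <- regions[as.character(predictions$cell_id)]
    for (r in sort(unique(stats::na.omit(reg)))) {
      out <- rbind(out, one(r, !is.na(reg) & reg == r))
    }
  }
  rownames(out) <- NULL
  out
}
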