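# small fitted model + grid shared across the upscaling tests
fit_toy_model <- function(seed = 11) {
  cfg <- nue_sim_config(n_studies = 20, obs_per_study = 4,
                        drop_sd_frac = 0, seed = seed)
  sim <- simulate_observations(cfg)
  list(cfg = cfg, fit = nue_meta_model(sim$observations, cfg$spec))
}

test_that("scenario encoding toggles indicators and activates interactions", {
  tm <- fit_toy_model()
  spec <- tm$cfg$spec
  scaling <- tm$fit$scaling
  cell <- list(cell_id = "c1", n_rate = 150, mat = 12, map = 900,
               soc = 20, clay = 25, ph = 6.5)

  base <- encode_scenario(nue_scenario("base"), cell, "wheat", spec, scaling)
  expect_equal(unname(base["intercept"]), 1)
  expect_true(all(base[spec$practices] == 0))

  rfr <- encode_scenario(nue_scenario("rfr", "RFR"), cell, "wheat",
                         spec, scaling)
  expect_equal(unname(rfr["RFR"]), 1)
  expect_equal(rfr[setdiff(names(rfr), "RFR")],
               base[setdiff(names(base), "RFR")])

  # six-practice nutrient bundle: all listed indicators up at once
  bundle <- nue_scenario("nutrient", c("EE", "RFR", "CC"))
  enc <- encode_scenario(bundle, cell, "maize", spec, scaling)
  expect_true(all(enc[c("EE", "RFR", "CC")] == 1))
  expect_equal(unname(enc["crop_maize"]), 1)
  # the interaction column is the product of its scaled parents
  expect_equal(unname(enc["n_rate:soc"]),
               unname(enc["n_rate"] * enc["soc"]))
})

test_that("covariates outside the calibration range warn but still encode", {
  tm <- fit_toy_model()
  cell <- list(cell_id = "cX", n_rate = 5000, mat = 12, map = 900,
               soc = 20, clay = 25, ph = 6.5)
  expect_warning(
    x <- encode_scenario(nue_scenario("rfr", "RFR"), cell, "wheat",
                         tm$cfg$spec, tm$fit$scaling),
    "calibration range")
  expect_true(is.finite(x["n_rate"]))
})

test_that("baseline self-contrast is identically zero with a symmetric CI", {
  tm <- fit_toy_model()
  grid <- simulate_grid(15, tm$cfg)
  base <- nue_scenario("conv")
  pred <- predict_grid(tm$fit, grid, base, base)
  expect_true(all(pred$delta_nuer_mean == 0))
  expect_true(all(pred$se == 0))
  expect_true(all(pred$ci_low <= 0 & pred$ci_high >= 0))
  expect_equal(pred$ci_low, -pred$ci_high)
})

test_that("grid predictions obey the CI-width contract and linear-model algebra", {
  tm <- fit_toy_model()
  grid <- simulate_grid(25, tm$cfg)
  pred <- suppressWarnings(predict_grid(tm$fit, grid, nue_scenario("rfr", "RFR")))
  expect_equal(nrow(pred), 25)
  expect_equal(pred$ci_high - pred$ci_low, 2 * 1.96 * pred$se,
               tolerance = 1e-12)
  expect_true(all(pred$ci_low <= pred$delta_nuer_mean &
                    pred$delta_nuer_mean <= pred$ci_high))
  # RFR enters no interaction, so the contrast is the RFR coefficient itself
  expect_equal(pred$delta_nuer_mean, rep(unname(coef(tm$fit)["RFR"]), 25),
               tolerance = 1e-12)
  expect_equal(pred$se, rep(sqrt(vcov(tm$fit)["RFR", "RFR"]), 25),
               tolerance = 1e-12)
})

test_that("bundle contrasts decompose into singles plus activated interactions", {
  tm <- fit_toy_model()
  spec <- tm$cfg$spec
  cell <- list(cell_id = "c1", n_rate = 150, mat = 12, map = 900,
               soc = 20, clay = 25, ph = 6.5)
  enc <- function(s) encode_scenario(s, cell, "wheat", spec, tm$fit$scaling)
  base <- enc(nue_scenario("b"))
  d_bundle <- enc(nue_scenario("all", c("EE", "RFR", "CC"))) - base
  d_singles <- (enc(nue_scenario("1", "EE")) - base) +
    (enc(nue_scenario("2", "RFR")) - base) +
    (enc(nue_scenario("3", "CC")) - base)
  # no practice x practice interaction is in the spec, so they coincide here
  expect_equal(d_bundle, d_singles, tolerance = 1e-12)

  # with a practice x crop interaction the joint encoding differs by it
  spec2 <- nue_model_spec(metric = "MD", practices = c("EE", "RFR", "CC"),
                          n_sq = FALSE,
                          interactions = list(c("RFR", "crop_maize")))
  enc2 <- function(s, crop) encode_scenario(s, cell, crop, spec2,
                                            tm$fit$scaling)
  d2 <- enc2(nue_scenario("rfr", "RFR"), "maize") -
    enc2(nue_scenario("b"), "maize")
  expect_equal(unname(d2["RFR:crop_maize"]), 1)
})

test_that("predictions differ across cells exactly by interaction algebra", {
  spec <- nue_model_spec(metric = "MD", practices = c("EE", "RFR", "CC"),
                         n_sq = FALSE,
                         interactions = list(c("RFR", "soc")))
  cfg <- nue_sim_config(n_studies = 20, obs_per_study = 4, spec = spec,
                        true_beta = c(intercept = 5, EE = 8, RFR = 10, CC = 6,
                                      crop_maize = 2, crop_rice = -1,
                                      n_rate = -2, mat = 0.5, map = 1,
                                      soc = 1.5, clay = -1, ph = 1,
                                      `RFR:soc` = 2),
                        drop_sd_frac = 0, seed = 31)
  sim <- simulate_observations(cfg)
  fit <- nue_meta_model(sim$observations, spec)
  grid <- simulate_grid(2, cfg)
  grid$soc <- c(10, 30)
  for (v in c("n_rate", "mat", "map", "clay", "ph")) grid[[v]] <- grid[[v]][1]
  for (s in paste0("share_", spec$crops)) grid[[s]] <- grid[[s]][1]
  pred <- predict_grid(fit, grid, nue_scenario("rfr", "RFR"))
  soc_scaled_diff <- diff(grid$soc) / fit$scaling$scale[["soc"]]
  expect_equal(diff(pred$delta_nuer_mean),
               unname(coef(fit)["RFR:soc"]) * soc_scaled_diff,
               tolerance = 1e-10)
})

test_that("area-weighted summaries match hand-computed means and invariants", {
  pred <- data.frame(cell_id = c("a", "b", "c"),
                     delta_nuer_mean = c(10, 20, 30),
                     se = 1, ci_low = c(8, 18, 28), ci_high = c(12, 22, 32))
  grid <- data.frame(cell_id = c("a", "b", "c"), area_weight = c(1, 2, 1))
  s <- summarize_grid(pred, grid)
  expect_equal(s$delta_nuer_mean, 20)
  expect_equal(s$ci_low, 18)
  expect_equal(s$ci_high, 22)

  grid2 <- grid; grid2$area_weight <- grid$area_weight * 2
  expect_equal(summarize_grid(pred, grid2)$delta_nuer_mean, 20)

  grid3 <- grid; grid3$area_weight <- c(1, 0, 0)
  expect_equal(summarize_grid(pred[1:2, ], grid3)$delta_nuer_mean, 10)

  # equal weights reduce to the arithmetic mean; zero total weight errors
  grid4 <- grid; grid4$area_weight <- rep(1, 3)
  expect_equal(summarize_grid(pred, grid4)$delta_nuer_mean, 20)
  grid5 <- grid; grid5$area_weight <- 0
  expect_error(summarize_grid(pred, grid5), "zero")

  # regional splits
  s2 <- summarize_grid(pred, grid, regions = c(a = "asia", b = "asia",
                                               c = "europe"))
  expect_equal(s2$delta_nuer_mean[s2$region == "asia"], 50 / 3,
               tolerance = 1e-12)
  expect_equal(s2$delta_nuer_mean[s2$region == "europe"], 30)
})

test_that("summary bounds stay within the per-cell envelope", {
  tm <- fit_toy_model()
  grid <- simulate_grid(12, tm$cfg)
  pred <- predict_grid(tm$fit, grid, nue_scenario("mix", c("EE", "CC")))
  s <- summarize_grid(pred, grid)
  expect_gte(s$delta_nuer_mean, min(pred$delta_nuer_mean))
  expect_lte(s$delta_nuer_mean, max(pred$delta_nuer_mean))
})

test_that("degenerate grids are refused", {
  tm <- fit_toy_model()
  grid <- simulate_grid(3, tm$cfg)
  expect_error(predict_grid(tm$fit, grid[0, ], nue_scenario("x", "EE")),
               "empty")
  for (s in paste0("share_", tm$cfg$spec$crops)) grid[[s]] <- 0
  expect_error(predict_grid(tm$fit, grid, nue_scenario("x", "EE")),
               "positive crop share")
})
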