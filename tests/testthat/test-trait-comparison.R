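test_that("the default registry matches the published model specifications", {
  reg <- model_registry()
  expect_equal(nrow(reg), 16)
  spec_of <- function(tr) dplyr::filter(reg, trait == tr)

  gaussians <- c("inflorescence_length", "corolla_diameter", "stigma_height",
                 "nectar_volume", "nectar_calories")
  expect_true(all(reg$family[reg$trait %in% gaussians] == "gaussian"))
  gammas <- c("plant_height", "stem_diameter", "corolla_length", "anther_height",
              "stigma_length", "anther_length")
  expect_true(all(reg$family[reg$trait %in% gammas] == "gamma"))
  expect_true(all(reg$link[reg$trait %in% gammas] == "log"))
  counts <- c("n_inflorescences", "n_buds", "n_fruits", "pollen_grains")
  expect_true(all(reg$family[reg$trait %in% counts] == "nb1"))
  expect_equal(spec_of("nectar_concentration")$family, "beta")

  disp <- c("n_fruits", "corolla_length", "anther_height", "anther_length",
            "nectar_volume")
  expect_setequal(reg$trait[reg$dispersion], disp)
  expect_setequal(reg$trait[reg$zero_inflated], "pollen_grains")
  # individual-level traits are independent samplings: no random intercept
  expect_setequal(reg$trait[!reg$random_intercept],
                  c("plant_height", "stem_diameter", "n_inflorescences"))

  reg2 <- model_registry(include_pollen_presence = TRUE)
  expect_equal(nrow(reg2), 17)
  expect_equal(reg2$family[reg2$trait == "pollen_presence"], "binomial")
})

test_that("identity-link marginal means on balanced data equal raw group means", {
  tab <- generate_dataset(small_config(individual_sd = 0), seed = 8)
  fit <- fit_trait_model(tab, "stigma_height")
  expect_true(fit$converged)
  mm <- marginal_means(fit, "cell")
  raw <- tab |>
    dplyr::filter(trait == "stigma_height") |>
    dplyr::group_by(area = as.character(area), morph = as.character(morph)) |>
    dplyr::summarise(raw_mean = mean(value), .groups = "drop")
  j <- dplyr::inner_join(mm, raw, by = c("area", "morph"))
  expect_equal(j$mean, j$raw_mean, tolerance = 1e-4)
})

test_that("log-link cell means equal the hand-assembled inverse-linked predictor", {
  tab <- generate_dataset(small_config(), seed = 15)
  fit <- fit_trait_model(tab, "anther_length")
  expect_true(fit$converged)
  b <- glmmTMB::fixef(fit$model)$cond
  eta <- c(
    no_fire_L = b[["(Intercept)"]],
    fire_L = b[["(Intercept)"]] + b[["areafire"]],
    no_fire_S = b[["(Intercept)"]] + b[["morphS"]],
    fire_S = sum(b)
  )
  mm <- marginal_means(fit, "cell")
  expect_equal(mm$mean, unname(exp(eta)), tolerance = 1e-6)

  # margins average on the link scale over the factor grid, then invert;
  # brute-force grid average as the oracle (unbalanced data would differ
  # under observation weighting)
  mm_area <- marginal_means(fit, "area")
  expect_equal(mm_area$mean,
               unname(exp(c(mean(eta[c(1, 3)]), mean(eta[c(2, 4)])))),
               tolerance = 1e-6)
})

test_that("factor-grid averaging is used even when the design is unbalanced", {
  tab <- generate_dataset(small_config(), seed = 16)
  sub <- tab |> dplyr::filter(trait == "anther_length")
  # unbalance the design: drop most fire-S flowers
  drop_ids <- sub |>
    dplyr::filter(area == "fire", morph == "S") |>
    dplyr::slice_head(n = 15) |>
    dplyr::pull(unit_id)
  unb <- dplyr::filter(sub, !unit_id %in% drop_ids)
  fit <- fit_trait_model(unb, "anther_length")
  b <- glmmTMB::fixef(fit$model)$cond
  eta_nf <- mean(c(b[["(Intercept)"]], b[["(Intercept)"]] + b[["morphS"]]))
  mm_area <- marginal_means(fit, "area")
  expect_equal(mm_area$mean[mm_area$group == "no_fire"], exp(eta_nf),
               tolerance = 1e-6)
})

test_that("NB1 dispersion is recovered on synthetic counts", {
  alphas <- vapply(1:5, function(s) {
    set.seed(100 + s)
    d <- tibble::tibble(
      area = rep(rep(c("no_fire", "fire"), each = 500), 2),
      morph = rep(c("L", "S"), each = 1000),
      individual_id = paste0("i", rep(1:40, each = 50)),
      unit_id = paste0("u", 1:2000),
      trait = "n_buds",
      value = as.double(sample_nb1(2000, mean = 20, alpha = 2))
    )
    fit <- fit_trait_model(d, "n_buds",
                           spec = dplyr::filter(model_registry(), trait == "n_buds"))
    stats::sigma(fit$model)  # glmmTMB sigma for nbinom1 is the NB1 alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 2) / 2, 0.2)
})

test_that("support violations are reported with the offending units", {
  tab <- generate_dataset(small_config(), seed = 6)
  bad <- tab
  bad$value[bad$trait == "nectar_concentration"][1:2] <- 150
  expect_error(fit_trait_model(bad, "nectar_concentration"), "support")

  bad2 <- tab
  bad2$value[bad2$trait == "n_buds"][1] <- 3.7
  expect_error(fit_trait_model(bad2, "n_buds"), "support")

  # degenerate single-factor input cannot identify the factorial model
  one_area <- dplyr::filter(tab, area == "fire")
  expect_error(fit_trait_model(one_area, "stigma_height"), "both areas")

  expect_error(fit_trait_model(tab, "unmeasured_trait"), "not in model registry")
})

test_that("Wald tests report one df per term and detect a strong area effect", {
  cfg <- small_config()
  cfg <- set_trait(cfg, "corolla_length", fire_L = 0.7, fire_S = 0.7)
  tab <- generate_dataset(cfg, seed = 10)
  fit <- fit_trait_model(tab, "corolla_length")
  w <- wald_type2(fit)
  expect_equal(w$term, c("area", "morph", "area:morph"))
  expect_equal(w$df, rep(1, 3))
  expect_true(all(w$p_value > 0 & w$p_value <= 1))
  expect_lt(w$p_value[w$term == "area"], 0.001)
})

test_that("morph-conditioned contrasts isolate a morph-specific effect", {
  cfg <- population_config(n_fruit_inflorescences_per_cell = 100)
  tab <- generate_dataset(cfg, seed = 11)
  fit <- fit_trait_model(tab, "n_fruits")
  cc <- conditional_contrasts(fit)
  expect_equal(sort(cc$morph), c("L", "S"))
  expect_equal(unique(cc$contrast), "fire - no_fire")
  expect_lt(cc$p_value[cc$morph == "S"], 0.05)
  expect_gt(cc$p_value[cc$morph == "L"], 0.05)

  # symmetric fire effects in both morphs give matching contrast estimates
  cfg2 <- set_trait(population_config(n_fruit_inflorescences_per_cell = 100),
                    "n_fruits", fire_L = 1.35, fire_S = 1.35)
  fit2 <- fit_trait_model(generate_dataset(cfg2, seed = 12), "n_fruits")
  cc2 <- conditional_contrasts(fit2)
  expect_equal(cc2$estimate[1], cc2$estimate[2], tolerance = 0.25)

  # a fit without the interaction term cannot be conditioned on morph
  df <- fit$data
  plain <- glmmTMB::glmmTMB(value ~ area + morph, data = df,
                            family = glmmTMB::nbinom1())
  no_int <- structure(
    list(trait = "n_fruits", spec = fit$spec, model = plain, data = df,
         converged = TRUE, re_dropped = FALSE, scale = 1, n = nrow(df)),
    class = "trait_fit"
  )
  expect_error(conditional_contrasts(no_int), "main effects")
})

test_that("tidy and glance expose coefficients and fit summaries", {
  tab <- generate_dataset(small_config(), seed = 13)
  fit <- fit_trait_model(tab, "pollen_grains")
  td <- tidy(fit)
  expect_true(all(c("component", "term", "estimate", "std.error") %in% names(td)))
  expect_true("zi" %in% td$component)
  gl <- glance(fit)
  expect_equal(gl$nobs, sum(tab$trait == "pollen_grains"))
  expect_true(is.finite(gl$logLik))
  expect_true(gl$converged)
})

test_that("percent-scale beta responses are rescaled in marginal means", {
  tab <- generate_dataset(population_config(n_nectar_per_cell = 40), seed = 14)
  fit <- suppressWarnings(fit_trait_model(tab, "nectar_concentration"))
  expect_true(fit$converged)
  mm <- marginal_means(fit, "cell")
  expect_true(all(mm$mean > 1 & mm$mean < 100))  # percent, not proportion
  expect_true(all(abs(mm$mean - 20) < 5))
})
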