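test_that("organ summaries use the sample mean and n-1 variance", {
  tab <- height_table(list(
    "no_fire.L.stigma" = c(16.2, 16.6, 16.4),
    "no_fire.L.anther" = c(10, 10, 10),
    "no_fire.S.stigma" = c(10.1, 10.3, 10.5),
    "no_fire.S.anther" = c(16.0, 16.8, 17.2),
    "fire.L.stigma" = c(16.1, 16.2, 16.3),
    "fire.L.anther" = c(10.6, 10.8, 11.0),
    "fire.S.stigma" = c(10.2, 10.4, 10.6),
    "fire.S.anther" = c(16.3, 16.5, 16.7)
  ))
  s <- summarize_organs(tab)
  ls <- dplyr::filter(s, area == "no_fire", morph == "L", organ == "stigma")
  expect_equal(ls$mean, 16.4)
  expect_equal(ls$variance, 0.04)  # frozen hand-arithmetic value
  expect_equal(ls$level, "high")

  la <- dplyr::filter(s, area == "no_fire", morph == "L", organ == "anther")
  expect_equal(la$mean, 10)
  expect_equal(la$variance, 0)  # constant sample
  expect_equal(la$level, "low")
})

test_that("organ summaries reject incomplete or tiny groups", {
  full <- toy_heights()
  tab <- height_table(full[names(full) != "fire.S.anther"])
  expect_error(summarize_organs(tab), "fire S anther")

  tiny <- full
  tiny[["fire.S.anther"]] <- 16.5
  expect_error(summarize_organs(height_table(tiny)), "at least 2")
})

test_that("inaccuracy_component decomposes bias and imprecision", {
  z <- inaccuracy_component(list(mean = 10, variance = 0, level = "high"),
                            list(mean = 10, variance = 0, level = "high"))
  expect_equal(unlist(z), c(maladaptive_bias = 0, imprecision = 0, inaccuracy = 0))

  r <- inaccuracy_component(list(mean = 12, variance = 0.5, level = "low"),
                            list(mean = 10, variance = 0.3, level = "low"))
  expect_equal(r$maladaptive_bias, 4)
  expect_equal(r$imprecision, 0.8)
  expect_equal(r$inaccuracy, 4.8)

  # frozen independent-oracle triple for the 3-value samples
  a <- list(mean = mean(c(16.2, 16.6, 16.4)), variance = var(c(16.2, 16.6, 16.4)),
            level = "high")
  s <- list(mean = mean(c(16.0, 16.8, 17.2)), variance = var(c(16.0, 16.8, 17.2)),
            level = "high")
  r <- inaccuracy_component(a, s)
  expect_equal(r$maladaptive_bias, 0.071111111111, tolerance = 1e-10)
  expect_equal(r$imprecision, 0.413333333333, tolerance = 1e-10)
  expect_equal(r$inaccuracy, 0.484444444444, tolerance = 1e-10)

  expect_error(
    inaccuracy_component(list(mean = 1, variance = 0, level = "high"),
                         list(mean = 1, variance = 0, level = "low")),
    "illegitimate"
  )
})

test_that("exactly four legitimate combinations, each group in one high and one low slot", {
  combos <- legitimate_combinations()
  expect_equal(nrow(combos), 4)
  # each of the four area x morph groups appears in exactly two combinations
  groups <- c(paste(combos$L_area, "L"), paste(combos$S_area, "S"))
  expect_equal(sort(as.vector(table(groups))), rep(2L, 4))

  # slot assignment for the cross-area pairing: the S member supplies the
  # high anther and low stigma, the L member the high stigma and low anther
  s <- random_summaries(101)
  cb <- dplyr::filter(combos, combination == "no-fire L <-> fire S")
  r <- inaccuracy_for_combination(s, cb)
  pick <- function(area, morph, organ) {
    dplyr::filter(s, area == !!area, morph == !!morph, organ == !!organ)
  }
  ha <- pick("fire", "S", "anther");   hs <- pick("no_fire", "L", "stigma")
  la <- pick("no_fire", "L", "anther"); ls <- pick("fire", "S", "stigma")
  expect_equal(r$maladaptive_bias_high, (ha$mean - hs$mean)^2)
  expect_equal(r$imprecision_high, ha$variance + hs$variance)
  expect_equal(r$maladaptive_bias_low, (la$mean - ls$mean)^2)
  expect_equal(r$imprecision_low, la$variance + ls$variance)

  expect_error(
    inaccuracy_from_summaries(dplyr::filter(s, !(area == "fire" & morph == "S"))),
    "missing organ summary"
  )
})

test_that("symmetric areas give identical results in all four combinations", {
  s <- random_summaries(7)
  # make fire groups exact copies of no-fire groups
  nf <- dplyr::filter(s, area == "no_fire")
  sym <- dplyr::bind_rows(nf, dplyr::mutate(nf, area = "fire"))
  r <- inaccuracy_from_summaries(sym)
  comp <- dplyr::select(r, dplyr::where(is.numeric))
  for (i in 2:4) expect_equal(comp[i, ], comp[1, ], ignore_attr = TRUE)
})

test_that("inaccuracy on the toy 5-value dataset matches the independent oracle", {
  r <- inaccuracy(height_table(toy_heights()))
  frozen <- tibble::tribble(
    ~combination, ~bh, ~ih, ~inh, ~bl, ~il, ~inl, ~tot,
    "no-fire L <-> no-fire S", 0.01, 0.075, 0.085, 0.16, 0.05, 0.21, 0.295,
    "fire L <-> fire S",       0.09, 0.075, 0.165, 0.09, 0.05, 0.14, 0.305,
    "no-fire S <-> fire L",    0.04, 0.075, 0.115, 0.16, 0.05, 0.21, 0.325,
    "no-fire L <-> fire S",    0.04, 0.075, 0.115, 0.09, 0.05, 0.14, 0.255
  )
  expect_equal(r$combination, frozen$combination)
  expect_equal(r$maladaptive_bias_high, frozen$bh, tolerance = 1e-12)
  expect_equal(r$imprecision_high, frozen$ih, tolerance = 1e-12)
  expect_equal(r$inaccuracy_high, frozen$inh, tolerance = 1e-12)
  expect_equal(r$maladaptive_bias_low, frozen$bl, tolerance = 1e-12)
  expect_equal(r$imprecision_low, frozen$il, tolerance = 1e-12)
  expect_equal(r$inaccuracy_low, frozen$inl, tolerance = 1e-12)
  expect_equal(r$total_inaccuracy, frozen$tot, tolerance = 1e-12)
})

test_that("standardized variant divides by the squared mean organ height", {
  s <- random_summaries(13)
  raw <- inaccuracy_from_summaries(s)
  std <- inaccuracy_from_summaries(s, standardize = TRUE)
  cb <- legitimate_combinations()[1, ]
  ha <- dplyr::filter(s, area == cb$S_area, morph == "S", organ == "anther")
  hs <- dplyr::filter(s, area == cb$L_area, morph == "L", organ == "stigma")
  scale_high <- ((ha$mean + hs$mean) / 2)^2
  expect_equal(std$inaccuracy_high[1], raw$inaccuracy_high[1] / scale_high)
  # decomposition identities survive standardization
  expect_equal(std$inaccuracy_high + std$inaccuracy_low, std$total_inaccuracy)
})

test_that("bootstrap intervals are deterministic, ordered, and degenerate for constant data", {
  const <- height_table(list(
    "no_fire.L.stigma" = rep(16, 4), "no_fire.L.anther" = rep(10, 4),
    "no_fire.S.stigma" = rep(10, 4), "no_fire.S.anther" = rep(16, 4),
    "fire.L.stigma" = rep(16, 4), "fire.L.anther" = rep(10, 4),
    "fire.S.stigma" = rep(10, 4), "fire.S.anther" = rep(16, 4)
  ))
  ci <- bootstrap_inaccuracy(const, B = 120, seed = 1)
  expect_equal(ci$lower, ci$estimate)
  expect_equal(ci$upper, ci$estimate)

  tab <- generate_dataset(small_config(), seed = 2)
  c1 <- bootstrap_inaccuracy(tab, B = 150, seed = 5)
  c2 <- bootstrap_inaccuracy(tab, B = 150, seed = 5)
  expect_identical(c1, c2)
  c3 <- bootstrap_inaccuracy(tab, B = 150, seed = 6)
  expect_false(identical(c1$lower, c3$lower))
  expect_true(all(c1$lower <= c1$upper))

  # cluster bootstrap runs and stays ordered
  c4 <- bootstrap_inaccuracy(tab, B = 120, seed = 5, unit = "individual")
  expect_true(all(c4$lower <= c4$upper))

  expect_error(bootstrap_inaccuracy(tab, B = 50, seed = 1), ">= 100")
})

test_that("estimated inaccuracy approaches the configured population value", {
  cfg <- population_config(n_individuals_per_cell = 10,
                           n_flowers_per_cell = 2000, individual_sd = 0)
  est <- inaccuracy(generate_dataset(cfg, seed = 21))
  pop <- population_inaccuracy(cfg)
  rel <- abs(est$total_inaccuracy - pop$total_inaccuracy) / pop$total_inaccuracy
  expect_lt(max(rel), 0.10)
})
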