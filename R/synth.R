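#' Configure a synthetic distylous population
#'
#' Builds the generating configuration for [generate_dataset()]: a two-area
#' (fire / no-fire), two-morph (L / S) factorial sampling design with
#' hierarchical units (individuals, inflorescences, flowers) and one
#' distribution per trait. Defaults emulate the sampling design and the
#' back-transformed group means published for a burned/unburned Cerrado
#' population of *Palicourea rigida*: ~17 individuals per morph per area,
#' ~80 morphometry flowers, ~96 pollen-scored flowers and ~10 nectar flowers
#' per cell, and ~22 (buds) and ~36 (fruits) inflorescences per cell. Fire
#' acts multiplicatively on trait means, with per-morph overrides so
#' morph-specific responses (e.g. an S-morph-only fruit-set boost) can be
#' simulated; by default reproductive organ heights are untouched by fire,
#' which is the regime under which between-morph reciprocity is preserved.
#'
#' The `traits` table interprets its `noise` column per family:
#' standard deviation for `gaussian` (zero-truncated normal), coefficient of
#' variation for `gamma`, the NB1 dispersion `alpha` (so that
#' `Var = mean * (1 + alpha)`) for `nb1`/`zinb1`, and the beta precision
#' `phi` for `beta` (concentration drawn on the proportion scale and
#' rescaled to percent). `zi` is the structural-zero probability for
#' `zinb1`. Individual-level heterogeneity is injected as a lognormal
#' multiplicative intercept on the trait mean, `exp(N(0, individual_sd))`,
#' for all sub-individual sampling units.
#'
#' @param n_individuals_per_cell Individuals sampled per morph x area cell.
#' @param n_flowers_per_cell Morphometry flowers per cell.
#' @param n_pollen_per_cell Pollen-deposition flowers per cell.
#' @param n_nectar_per_cell Bagged nectar flowers per cell.
#' @param n_bud_inflorescences_per_cell Inflorescences measured for length
#'   and bud counts per cell.
#' @param n_fruit_inflorescences_per_cell Inflorescences scored for fruit
#'   counts per cell.
#' @param individual_sd SD of the lognormal individual random intercept
#'   (on the log scale; 0 disables it).
#' @param traits Optional replacement trait table (same columns as the
#'   default; see Details).
#' @return A `population_config` object (a list).
#' @export
#' @examples
#' cfg <- population_config(n_individuals_per_cell = 4, n_flowers_per_cell = 8)
#' cfg$traits
population_config <- function(n_individuals_per_cell = 17,
                              n_flowers_per_cell = 80,
                              n_pollen_per_cell = 96,
                              n_nectar_per_cell = 10,
                              n_bud_inflorescences_per_cell = 22,
                              n_fruit_inflorescences_per_cell = 36,
                              individual_sd = 0.05,
                              traits = NULL) {
  if (is.null(traits)) traits <- default_trait_table()
  cfg <- structure(
    list(
      n_individuals_per_cell = n_individuals_per_cell,
      n_units = c(
        individual = n_individuals_per_cell,
        inflorescence_bud = n_bud_inflorescences_per_cell,
        inflorescence_fruit = n_fruit_inflorescences_per_cell,
        flower = n_flowers_per_cell,
        nectar = n_nectar_per_cell,
        pollen = n_pollen_per_cell
      ),
      # individuals contributing units at each sub-individual level
      n_source_individuals = c(
        individual = n_individuals_per_cell,
        inflorescence_bud = n_individuals_per_cell,
        inflorescence_fruit = min(11L, n_individuals_per_cell),
        flower = min(10L, n_individuals_per_cell),
        nectar = min(10L, n_individuals_per_cell),
        pollen = min(10L, n_individuals_per_cell)
      ),
      individual_sd = individual_sd,
      traits = traits
    ),
    class = "population_config"
  )
  validate_population_config(cfg)
  cfg
}

default_trait_table <- function() {
  tibble::tribble(
    ~trait,                  ~level,                ~family,    ~mean_L, ~mean_S, ~noise, ~zi,  ~fire_L,  ~fire_S,
    "plant_height",          "individual",          "gamma",    1.60,    1.60,    0.20,   0,    1,        1,
    "stem_diameter",         "individual",          "gamma",    25,      25,      0.25,   0,    1,        1,
    "n_inflorescences",      "individual",          "nb1",      15,      15,      2,      0,    1,        1,
    "inflorescence_length",  "inflorescence_bud",   "gaussian", 26.77,   26.77,   4.1,    0,    0.906238, 0.906238,
    "n_buds",                "inflorescence_bud",   "nb1",      25,      25,      2,      0,    1,        1,
    "n_fruits",              "inflorescence_fruit", "nb1",      89.77,   89.77,   8,      0,    1,        1.353125,
    "corolla_length",        "flower",              "gamma",    14.21,   14.21,   0.065,  0,    0.952850, 0.952850,
    "corolla_diameter",      "flower",              "gaussian", 4.5,     4.5,     0.6,    0,    1,        1,
    "stigma_height",         "flower",              "gaussian", 16.46,   10.42,   1.2,    0,    1,        1,
    "anther_height",         "flower",              "gamma",    10.83,   16.51,   0.075,  0,    1,        1,
    "stigma_length",         "flower",              "gamma",    1.55,    3.89,    0.22,   0,    0.664516, 1,
    "anther_length",         "flower",              "gamma",    3.70,    3.70,    0.10,   0,    0.940541, 0.940541,
    "nectar_volume",         "nectar",              "gaussian", 13.95,   15.78,   3.0,    0,    1,        1,
    "nectar_concentration",  "nectar",              "beta",     20,      20,      60,     0,    1,        1,
    "pollen_grains",         "pollen",              "zinb1",    25,      25,      3,      0.3,  1,        1
  )
}

validate_population_config <- function(cfg) {
  tr <- cfg$traits
  needed <- c("trait", "level", "family", "mean_L", "mean_S", "noise", "zi",
              "fire_L", "fire_S")
  if (!all(needed %in% names(tr))) {
    abort(paste0("config traits table must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (any(cfg$n_units < 1)) abort("all per-cell unit counts must be >= 1")
  if (cfg$individual_sd < 0) abort("individual_sd must be >= 0")
  if (any(tr$mean_L <= 0) || any(tr$mean_S <= 0)) {
    abort("trait means must be strictly positive")
  }
  if (any(tr$noise < 0)) abort("trait noise parameters must be >= 0")
  if (any(tr$zi < 0 | tr$zi >= 1)) abort("zero-inflation probabilities must lie in [0, 1)")
  if (any(tr$fire_L <= 0) || any(tr$fire_S <= 0)) {
    abort("fire multipliers must be strictly positive")
  }
  bad_fam <- setdiff(tr$family, c("gaussian", "gamma", "nb1", "zinb1", "beta"))
  if (length(bad_fam)) abort(paste0("unknown trait family: ", paste(bad_fam, collapse = ", ")))
  beta_tr <- tr[tr$family == "beta", ]
  if (nrow(beta_tr) && any(beta_tr$mean_L >= 100 | beta_tr$mean_S >= 100)) {
    abort("beta-family trait means are percentages and must lie in (0, 100)")
  }
  invisible(cfg)
}

#' Modify one trait in a population configuration
#'
#' Convenience editor for scenario construction: override the baseline
#' means, noise parameter, zero-inflation probability, or the per-morph
#' fire multipliers of a single trait.
#'
#' @param config A [population_config()].
#' @param trait Trait name present in `config$traits`.
#' @param mean_L,mean_S,noise,zi,fire_L,fire_S Replacement values; `NULL`
#'   leaves the current value.
#' @return The modified `population_config`.
#' @export
set_trait <- function(config, trait, mean_L = NULL, mean_S = NULL,
                      noise = NULL, zi = NULL, fire_L = NULL, fire_S = NULL) {
  stopifnot(inherits(config, "population_config"))
  i <- which(config$traits$trait == trait)
  if (length(i) != 1L) abort(paste0("unknown trait: ", trait))
  for (field in c("mean_L", "mean_S", "noise", "zi", "fire_L", "fire_S")) {
    val <- get(field)
    if (!is.null(val)) config$traits[[field]][i] <- val
  }
  validate_population_config(config)
  config
}

#' Draw from the NB1 (linear-parameterization) negative binomial
#'
#' Samples counts with `E[X] = mean` and `Var[X] = mean * (1 + alpha)`,
#' i.e. the negative binomial whose variance is linear in the mean.
#' Implemented as a gamma-Poisson mixture with gamma shape `mean / alpha`
#' and scale `alpha`, which has exactly these two moments; `alpha = 0`
#' short-circuits to the Poisson limit.
#'
#' @param n Number of draws.
#' @param mean Mean, strictly positive.
#' @param alpha NB1 dispersion, `>= 0`.
#' @return Integer vector of length `n`.
#' @export
#' @examples
#' x <- sample_nb1(1e4, mean = 10, alpha = 2)
#' c(mean(x), var(x))  # ~10 and ~30
sample_nb1 <- function(n, mean, alpha) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) abort("n must be a single count >= 1")
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0) {
    abort("mean must be a single strictly positive number")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    abort("alpha must be a single non-negative number")
  }
  if (alpha == 0) {
    return(rpois(n, lambda = mean))
  }
  lambda <- rgamma(n, shape = mean / alpha, scale = alpha)
  rpois(n, lambda = lambda)
}

#' Draw from a zero-inflated NB1 distribution
#'
#' With probability `pi` emits a structural zero, otherwise an NB1 draw
#' (see [sample_nb1()]); hence `E[X] = (1 - pi) * mean`.
#'
#' @inheritParams sample_nb1
#' @param pi Structural-zero probability in `[0, 1)`.
#' @return Integer vector of length `n`.
#' @export
sample_zi_nb1 <- function(n, mean, alpha, pi) {
  if (!is.numeric(pi) || length(pi) != 1L || !is.finite(pi) || pi < 0 || pi >= 1) {
    abort("pi must be a single probability in [0, 1)")
  }
  x <- sample_nb1(n, mean, alpha)
  structural <- rbinom(n, size = 1L, prob = pi) == 1L
  x[structural] <- 0L
  x
}

# Zero-truncated normal via rejection; at the CVs used for physical traits
# the truncated mass is negligible (< 1e-10) so this is effectively rnorm.
sample_truncnorm <- function(n, mean, sd) {
  if (sd == 0) return(rep_len(mean, n))
  mean <- rep_len(mean, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

# Vectorized over `mean` (per-unit means after individual intercepts).
sample_trait_values <- function(n, family, mean, noise, zi) {
  switch(family,
    gaussian = sample_truncnorm(n, mean, noise),
    gamma = {
      if (noise == 0) rep_len(mean, n)
      else rgamma(n, shape = 1 / noise^2, scale = mean * noise^2)
    },
    nb1 = {
      if (noise == 0) rpois(n, lambda = mean)
      else rpois(n, lambda = rgamma(n, shape = mean / noise, scale = noise))
    },
    zinb1 = {
      x <- if (noise == 0) rpois(n, lambda = mean)
           else rpois(n, lambda = rgamma(n, shape = mean / noise, scale = noise))
      x[rbinom(n, 1L, zi) == 1L] <- 0L
      x
    },
    beta = {
      m <- mean / 100
      if (noise == 0) rep_len(mean, n)
      else 100 * rbeta(n, shape1 = m * noise, shape2 = (1 - m) * noise)
    },
    abort(paste0("unknown trait family: ", family))
  )
}

#' Generate a synthetic trait table
#'
#' Simulates a tidy long-format trait table from a [population_config()]:
#' every morph x area cell receives its configured number of individuals
#' and sampling units, each sub-individual unit inherits its individual's
#' lognormal intercept, fire multipliers are applied to the fire-area cell
#' means, and per-flower nectar calories are derived from the simulated
#' volume and concentration via [nectar_energy()]. Re-running with the same
#' config and seed reproduces the table exactly.
#'
#' @param config A [population_config()].
#' @param seed Integer RNG seed.
#' @return A tibble with columns `area` (`no_fire`/`fire`), `morph`
#'   (`L`/`S`), `individual_id`, `unit_id`, `trait`, `value`, carrying class
#'   `trait_tbl` and a `seed` attribute.
#' @export
#' @examples
#' tab <- generate_dataset(population_config(n_individuals_per_cell = 4,
#'                                           n_flowers_per_cell = 8), seed = 1)
#' dplyr::count(tab, area, morph, trait)
generate_dataset <- function(config = population_config(), seed = 1L) {
  validate_population_config(config)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("seed must be a single integer")
  }
  set.seed(as.integer(seed))

  cells <- tidyr::expand_grid(area = c("no_fire", "fire"), morph = c("L", "S"))
  tr <- config$traits
  n_ind <- config$n_individuals_per_cell

  # one lognormal intercept per individual x trait, drawn up-front in a
  # fixed order so generation is reproducible
  cell_tag <- function(area, morph) {
    paste0(ifelse(area == "fire", "F", "NF"), "-", morph)
  }
  intercepts <- list()
  for (ci in seq_len(nrow(cells))) {
    tag <- cell_tag(cells$area[ci], cells$morph[ci])
    z <- matrix(rnorm(n_ind * nrow(tr), 0, config$individual_sd),
                nrow = n_ind, ncol = nrow(tr))
    intercepts[[tag]] <- z
  }

  out <- vector("list", nrow(tr) * nrow(cells))
  k <- 0L
  for (ti in seq_len(nrow(tr))) {
    trait <- tr$trait[ti]
    level <- tr$level[ti]
    n_unit <- config$n_units[[level]]
    n_src <- config$n_source_individuals[[level]]
    for (ci in seq_len(nrow(cells))) {
      area <- cells$area[ci]
      morph <- cells$morph[ci]
      tag <- cell_tag(area, morph)
      base_mean <- if (morph == "L") tr$mean_L[ti] else tr$mean_S[ti]
      if (area == "fire") {
        base_mean <- base_mean * if (morph == "L") tr$fire_L[ti] else tr$fire_S[ti]
      }
      ind_idx <- rep_len(seq_len(n_src), n_unit)
      individual_id <- sprintf("%s-%02d", tag, ind_idx)
      unit_id <- if (level == "individual") individual_id else
        sprintf("%s-%s-%03d", tag, level, seq_len(n_unit))
      if (level == "individual") {
        unit_mean <- rep(base_mean, n_unit)
      } else {
        z <- intercepts[[tag]][ind_idx, ti]
        if (tr$family[ti] == "beta") {
          # shift on the logit scale so the support stays in (0, 100)
          m <- stats::plogis(stats::qlogis(base_mean / 100) + z)
          unit_mean <- 100 * m
        } else {
          unit_mean <- base_mean * exp(z)
        }
      }
      value <- sample_trait_values(n_unit, tr$family[ti], unit_mean,
                                   tr$noise[ti], tr$zi[ti])
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        area = area, morph = morph,
        individual_id = individual_id, unit_id = unit_id,
        trait = trait, value = value
      )
    }
  }
  tab <- dplyr::bind_rows(out)

  # derived trait: nectar calories per nectar flower
  nectar <- tab |>
    dplyr::filter(.data$trait %in% c("nectar_volume", "nectar_concentration")) |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  if (nrow(nectar)) {
    cal <- nectar |>
      dplyr::mutate(
        trait = "nectar_calories",
        value = nectar_energy(.data$nectar_volume, .data$nectar_concentration)
      ) |>
      dplyr::select("area", "morph", "individual_id", "unit_id", "trait", "value")
    tab <- dplyr::bind_rows(tab, cal)
  }

  tab <- tab |>
    dplyr::mutate(
      area = factor(.data$area, levels = c("no_fire", "fire")),
      morph = factor(.data$morph, levels = c("L", "S"))
    )
  attr(tab, "seed") <- as.integer(seed)
  class(tab) <- c("trait_tbl", class(tab))
  tab
}

#' Population moments and inaccuracy implied by a configuration
#'
#' Closed-form expected value and variance of each reproductive organ
#' height under a [population_config()], accounting for the lognormal
#' individual intercept, and the population-level inaccuracy decomposition
#' each legitimate morph pairing would attain at infinite sample size.
#' Zero-truncation of the Gaussian heights is ignored (negligible at the
#' default coefficients of variation).
#'
#' @param config A [population_config()].
#' @param standardize Divide components by the squared mean organ height of
#'   the pairing level (non-standard variant; see [inaccuracy()]).
#' @return A tibble like the output of [inaccuracy()], evaluated at the
#'   generating parameter values.
#' @export
population_inaccuracy <- function(config = population_config(), standardize = FALSE) {
  summaries <- population_organ_summaries(config)
  inaccuracy_from_summaries(summaries, standardize = standardize)
}

population_organ_summaries <- function(config) {
  tr <- config$traits
  s2 <- config$individual_sd^2
  grid <- tidyr::expand_grid(
    area = c("no_fire", "fire"), morph = c("L", "S"),
    organ = c("stigma", "anther")
  )
  rows <- purrr::pmap(grid, function(area, morph, organ) {
    trait <- paste0(organ, "_height")
    i <- which(tr$trait == trait)
    if (length(i) != 1L) abort(paste0("config lacks trait ", trait))
    m <- if (morph == "L") tr$mean_L[i] else tr$mean_S[i]
    if (area == "fire") m <- m * (if (morph == "L") tr$fire_L[i] else tr$fire_S[i])
    noise <- tr$noise[i]
    # value = cell_mean * exp(z) (+ family noise); z ~ N(0, individual_sd^2)
    if (tr$family[i] == "gaussian") {
      ev <- m * exp(s2 / 2)
      vv <- noise^2 + m^2 * (exp(2 * s2) - exp(s2))
    } else if (tr$family[i] == "gamma") {
      ev <- m * exp(s2 / 2)
      vv <- m^2 * noise^2 * exp(2 * s2) + m^2 * (exp(2 * s2) - exp(s2))
    } else {
      abort("organ heights must be gaussian or gamma traits")
    }
    tibble::tibble(area = area, morph = morph, organ = organ,
                   level = organ_level(morph, organ),
                   mean = ev, variance = vv, n = Inf)
  })
  dplyr::bind_rows(rows)
}
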