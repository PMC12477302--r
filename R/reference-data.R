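#' Published marginal means for a Cerrado *Palicourea rigida* fire study
#'
#' Back-transformed marginal means (with standard errors) reported for a
#' distylous *Palicourea rigida* population sampled in a burned and a
#' contiguous unburned Cerrado area. Each row is one published pairwise
#' comparison between predicted group means: fire vs. no-fire area effects
#' (the no-fire group is always the reference), between-morph effects, and
#' morph-conditioned area effects found in post-hoc contrasts. These are the
#' inputs for the percent effect sizes the study reports.
#'
#' @return A tibble with one row per published comparison and columns
#'   `trait`, `term` (`"area"`, `"morph"`, or `"area_within_morph"`),
#'   `focal`, `reference` (group labels), `focal_mean`, `focal_se`,
#'   `reference_mean`, `reference_se` (trait units).
#' @seealso [percent_effect()], [effect_table()]
#' @export
#' @examples
#' reference_marginal_means() |>
#'   effect_table()
reference_marginal_means <- function() {
  tibble::tribble(
    ~trait,                 ~term,               ~focal,      ~reference,    ~focal_mean, ~focal_se, ~reference_mean, ~reference_se,
    "inflorescence_length", "area",              "fire",      "no_fire",     24.26,       0.62,      26.77,           0.61,
    "n_fruits",             "area_within_morph", "fire:S",    "no_fire:S",   121.47,      0.09,      89.77,           0.07,
    "corolla_length",       "area",              "fire",      "no_fire",     13.54,       0.02,      14.21,           0.02,
    "stigma_height",        "morph",             "L",         "S",           16.46,       0.21,      10.42,           0.21,
    "anther_height",        "morph",             "S",         "L",           16.51,       0.01,      10.83,           0.01,
    "stigma_length",        "area_within_morph", "fire:L",    "no_fire:L",   1.03,        0.05,      1.55,            0.05,
    "stigma_length",        "morph",             "S",         "L",           3.89,        0.04,      1.29,            0.04,
    "anther_length",        "area",              "fire",      "no_fire",     3.48,        0.02,      3.70,            0.02,
    "nectar_calories",      "morph",             "S",         "L",           13.64,       0.68,      12.06,           0.71
  )
}

# Density of aqueous sucrose solutions at 20 degrees C (g/mL) against
# concentration in % w/w, from standard physico-chemical reference tables.
# Used with linear interpolation by brix_to_sucrose().
sucrose_density_table <- function() {
  tibble::tibble(
    concentration = seq(0, 75, by = 5),
    density = c(
      0.99823, 1.01785, 1.03814, 1.05916, 1.08096, 1.10356, 1.12698, 1.15128,
      1.17648, 1.20254, 1.22946, 1.25731, 1.28608, 1.31579, 1.34643, 1.37797
    )
  )
}
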