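#' Signed percent effect size between two group means
#'
#' The percent difference of a focal group mean relative to a reference
#' group mean, `100 * (focal - reference) / reference`. This is the
#' arithmetic behind published effect sizes such as "9.38% smaller" (fire
#' vs. no-fire) or "57.97% taller" (L vs. S stigmas): the reference is the
#' no-fire group for area effects and the second-named group for morph
#' effects.
#'
#' @param focal,reference Numeric vectors of group means (recycled);
#'   `reference` must be non-zero.
#' @return Numeric vector of signed percent effects.
#' @export
#' @examples
#' percent_effect(24.26, 26.77)   # -9.38
#' percent_effect(121.47, 89.77)  # +35.31
percent_effect <- function(focal, reference) {
  if (!is.numeric(focal) || !is.numeric(reference)) {
    abort("focal and reference must be numeric")
  }
  if (any(reference == 0)) abort("reference mean must be non-zero")
  100 * (focal - reference) / reference
}

#' Tabulate percent effect sizes
#'
#' Builds an effect-size table from a comparison table that carries the
#' focal and reference means (such as [reference_marginal_means()], or the
#' output of [marginal_means()] joined into comparisons). Percent effects
#' are reported to two decimals, with a direction label.
#'
#' @param comparisons A data frame with columns `focal_mean` and
#'   `reference_mean` (any identifying columns are carried through).
#' @return The input tibble plus `percent_effect` (signed, rounded to two
#'   decimals) and `direction` (`"increase"`/`"decrease"`/`"none"`).
#' @export
#' @examples
#' reference_marginal_means() |> effect_table()
effect_table <- function(comparisons) {
  if (!all(c("focal_mean", "reference_mean") %in% names(comparisons))) {
    abort("comparisons must have columns focal_mean and reference_mean")
  }
  comparisons |>
    tibble::as_tibble() |>
    dplyr::mutate(
      percent_effect = round(percent_effect(.data$focal_mean, .data$reference_mean), 2),
      direction = dplyr::case_when(
        .data$percent_effect > 0 ~ "increase",
        .data$percent_effect < 0 ~ "decrease",
        TRUE ~ "none"
      )
    )
}

#' Convert a Brix reading to sucrose equivalents
#'
#' Converts a refractometer sugar concentration (% w/w) into micrograms of
#' sucrose per microlitre of nectar using the density of aqueous sucrose
#' solutions at 20 degrees C: `ug/uL = 10 * C * rho(C)`, with `rho(C)` in
#' g/mL linearly interpolated from an embedded standard density table
#' (0-75% w/w in 5% steps). No temperature correction is applied.
#'
#' @param concentration Sugar concentration in % mass/mass, in `[0, 100)`
#'   (values above 75% exceed the embedded table and are rejected).
#' @return Sucrose equivalents in ug sucrose per uL nectar.
#' @export
#' @examples
#' brix_to_sucrose(20)  # 216.192
brix_to_sucrose <- function(concentration) {
  if (!is.numeric(concentration)) abort("concentration must be numeric")
  if (any(!is.finite(concentration)) ||
      any(concentration < 0) || any(concentration >= 100)) {
    abort("concentration must lie in [0, 100)")
  }
  tab <- sucrose_density_table()
  if (any(concentration > max(tab$concentration))) {
    abort(paste0("concentration above ", max(tab$concentration),
                 "% exceeds the embedded sucrose density table"))
  }
  rho <- stats::approx(tab$concentration, tab$density, xout = concentration,
                       rule = 1)$y
  10 * concentration * rho
}

#' Convert sugar mass to calories
#'
#' Energetic value of nectar sugar at the standard conversion of 4 calories
#' per mg of sugar.
#'
#' @param sugar_mass Sugar mass in mg (non-negative).
#' @return Calories.
#' @export
#' @examples
#' sugar_to_calories(1)    # 4
#' sugar_to_calories(2.5)  # 10
sugar_to_calories <- function(sugar_mass) {
  if (!is.numeric(sugar_mass)) abort("sugar_mass must be numeric")
  if (any(sugar_mass < 0)) abort("sugar_mass must be >= 0")
  4 * sugar_mass
}

#' Energetic content of a nectar sample
#'
#' Composes the Brix-to-sucrose and sugar-to-calories conversions: the
#' nectar volume times the sucrose equivalents gives the sugar mass, whose
#' energetic value is 4 cal/mg. Linear (degree 1) in volume.
#'
#' @param volume Nectar volume in uL (non-negative, vectorized).
#' @param concentration Sugar concentration in % w/w (vectorized).
#' @return Calories.
#' @export
#' @examples
#' nectar_energy(10, 20)  # 8.64768
nectar_energy <- function(volume, concentration) {
  if (!is.numeric(volume)) abort("volume must be numeric")
  if (any(volume < 0)) abort("volume must be >= 0")
  sugar_mg <- volume * brix_to_sucrose(concentration) / 1000
  sugar_to_calories(sugar_mg)
}
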