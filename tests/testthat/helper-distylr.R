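# Shared fixtures, built in code.

# A small but fully populated design for fast tests.
small_config <- function(...) {
  population_config(
    n_individuals_per_cell = 5,
    n_flowers_per_cell = 20,
    n_pollen_per_cell = 20,
    n_nectar_per_cell = 6,
    n_bud_inflorescences_per_cell = 8,
    n_fruit_inflorescences_per_cell = 10,
    ...
  )
}

# Build a trait table holding only organ heights from explicit vectors.
# `heights` is a named list "area.morph.organ" -> numeric vector.
height_table <- function(heights) {
  rows <- purrr::imap(heights, function(x, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    tibble::tibble(
      area = parts[1], morph = parts[2],
      individual_id = paste0(parts[1], "-", parts[2], "-", seq_along(x) %% 3 + 1),
      unit_id = paste0(key, "-", seq_along(x)),
      trait = paste0(parts[3], "_height"),
      value = x
    )
  })
  validate_trait_table(dplyr::bind_rows(rows))
}

# The 5-value toy samples used by the hand-arithmetic oracle tests.
toy_heights <- function() {
  list(
    "no_fire.L.stigma" = c(16.1, 16.5, 16.3, 16.7, 16.4),
    "no_fire.L.anther" = c(10.6, 10.9, 10.7, 11.0, 10.8),
    "no_fire.S.stigma" = c(10.3, 10.5, 10.4, 10.6, 10.2),
    "no_fire.S.anther" = c(16.4, 16.6, 16.5, 16.7, 16.3),
    "fire.L.stigma"    = c(16.0, 16.2, 16.4, 16.6, 16.3),
    "fire.L.anther"    = c(10.8, 10.9, 11.0, 10.7, 10.6),
    "fire.S.stigma"    = c(10.4, 10.6, 10.5, 10.3, 10.7),
    "fire.S.anther"    = c(16.5, 16.7, 16.6, 16.4, 16.8)
  )
}

# Organ-summary quadruple sets with random means/variances, for the
# identity/property tests.
random_summaries <- function(seed) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    area = c("no_fire", "fire"), morph = c("L", "S"),
    organ = c("stigma", "anther")
  )
  grid |>
    dplyr::mutate(
      level = organ_level(morph, organ),
      mean = stats::runif(8, 5, 25),
      variance = stats::runif(8, 0, 4),
      n = sample(5:50, 8, replace = TRUE)
    )
}
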