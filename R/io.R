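#' Write a trait table to CSV with a provenance sidecar
#'
#' Writes the tidy long-format trait table as UTF-8 CSV and, when the table
#' carries a `seed` attribute (as tables from [generate_dataset()] do), an
#' adjacent `<path>.provenance.json` recording the seed and row count.
#'
#' @param data A trait table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(data, path) {
  readr::write_csv(as.data.frame(data), path)
  seed <- attr(data, "seed")
  if (!is.null(seed)) {
    jsonlite::write_json(
      list(seed = seed, n_rows = nrow(data),
           traits = sort(unique(data$trait))),
      paste0(path, ".provenance.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

#' Read a trait table from CSV
#'
#' Reads a CSV written by [write_trait_table()] (or user data with the same
#' columns: `area`, `morph`, `individual_id`, `unit_id`, `trait`, `value`)
#' and validates the structural invariants: known factor levels,
#' individuals nested in a single area x morph cell, non-negative integer
#' counts, strictly positive lengths/heights, and concentrations in
#' (0, 100).
#'
#' @param path CSV path.
#' @return A validated `trait_tbl` tibble.
#' @export
read_trait_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           area = readr::col_character(),
                           morph = readr::col_character(),
                           individual_id = readr::col_character(),
                           unit_id = readr::col_character(),
                           trait = readr::col_character(),
                           value = readr::col_double()
                         ))
  tab <- validate_trait_table(tab)
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar)) {
    prov <- jsonlite::read_json(sidecar)
    if (!is.null(prov$seed)) attr(tab, "seed") <- as.integer(prov$seed)
  }
  tab
}

#' Validate a trait table
#'
#' Checks the invariants described in [read_trait_table()] and returns the
#' table with canonical factor levels and the `trait_tbl` class.
#'
#' @param data A data frame with trait-table columns.
#' @return The validated table.
#' @export
validate_trait_table <- function(data) {
  needed <- c("area", "morph", "individual_id", "unit_id", "trait", "value")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("trait table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(as.character(data$area) %in% c("no_fire", "fire"))) {
    abort("area must be 'no_fire' or 'fire'")
  }
  if (!all(as.character(data$morph) %in% c("L", "S"))) {
    abort("morph must be 'L' or 'S'")
  }
  cells <- data |>
    dplyr::distinct(.data$individual_id, .data$area, .data$morph) |>
    dplyr::count(.data$individual_id)
  if (any(cells$n > 1)) {
    abort(paste0("individuals mapped to more than one area x morph cell: ",
                 paste(head(cells$individual_id[cells$n > 1], 5), collapse = ", ")))
  }
  count_traits <- c("n_inflorescences", "n_buds", "n_fruits", "pollen_grains")
  counts <- data$value[data$trait %in% count_traits]
  if (length(counts) && (any(counts < 0) || any(counts != round(counts)))) {
    abort("count traits must be non-negative integers")
  }
  size_traits <- c("plant_height", "stem_diameter", "inflorescence_length",
                   "corolla_length", "corolla_diameter", "stigma_height",
                   "anther_height", "stigma_length", "anther_length")
  sizes <- data$value[data$trait %in% size_traits]
  if (length(sizes) && any(sizes <= 0)) {
    abort("lengths and heights must be strictly positive")
  }
  conc <- data$value[data$trait == "nectar_concentration"]
  if (length(conc) && any(conc <= 0 | conc >= 100)) {
    abort("nectar_concentration must lie in (0, 100)")
  }
  out <- data |>
    tibble::as_tibble() |>
    dplyr::mutate(
      area = factor(as.character(.data$area), levels = c("no_fire", "fire")),
      morph = factor(as.character(.data$morph), levels = c("L", "S"))
    )
  if (!inherits(out, "trait_tbl")) class(out) <- c("trait_tbl", class(out))
  out
}

#' Write or read a population configuration as YAML
#'
#' @param config A [population_config()].
#' @param path YAML file path.
#' @return `write_population_config()` returns `path` invisibly;
#'   `read_population_config()` returns the `population_config`.
#' @export
write_population_config <- function(config, path) {
  stopifnot(inherits(config, "population_config"))
  yaml::write_yaml(
    list(
      n_individuals_per_cell = config$n_individuals_per_cell,
      n_units = as.list(config$n_units),
      n_source_individuals = as.list(config$n_source_individuals),
      individual_sd = config$individual_sd,
      traits = lapply(seq_len(nrow(config$traits)), function(i) as.list(config$traits[i, ]))
    ),
    path
  )
  invisible(path)
}

#' @rdname write_population_config
#' @export
read_population_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- structure(
    list(
      n_individuals_per_cell = raw$n_individuals_per_cell,
      n_units = unlist(raw$n_units),
      n_source_individuals = unlist(raw$n_source_individuals),
      individual_sd = raw$individual_sd,
      traits = dplyr::bind_rows(lapply(raw$traits, tibble::as_tibble))
    ),
    class = "population_config"
  )
  validate_population_config(cfg)
  cfg
}
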