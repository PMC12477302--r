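#' Organ level implied by morph and organ
#'
#' In a distylous flower the "high" organs are the L-morph stigma and the
#' S-morph anther; the "low" organs are the S-morph stigma and the L-morph
#' anther. Legitimate (intermorph) pollination pairs organs at the same
#' level.
#'
#' @param morph `"L"` or `"S"` (vectorized).
#' @param organ `"stigma"` or `"anther"` (vectorized).
#' @return Character vector, `"high"` or `"low"`.
#' @export
organ_level <- function(morph, organ) {
  ifelse((morph == "L" & organ == "stigma") | (morph == "S" & organ == "anther"),
         "high", "low")
}

#' Summarize reproductive-organ heights per group
#'
#' Computes the sample mean, sample variance (n - 1 denominator) and sample
#' size of stigma and anther heights for every area x morph group of a
#' trait table, assigning each summary its organ level (see
#' [organ_level()]). These summaries are the sufficient statistics for the
#' inaccuracy decomposition.
#'
#' @param data A trait table (as from [generate_dataset()] or
#'   [read_trait_table()]) containing `stigma_height` and `anther_height`
#'   records.
#' @return A tibble with columns `area`, `morph`, `organ`, `level`, `mean`,
#'   `variance`, `n`, class `organ_summary_tbl`.
#' @export
#' @examples
#' generate_dataset(population_config(n_individuals_per_cell = 4,
#'                                    n_flowers_per_cell = 12), seed = 1) |>
#'   summarize_organs()
summarize_organs <- function(data) {
  heights <- data |>
    dplyr::filter(.data$trait %in% c("stigma_height", "anther_height")) |>
    dplyr::mutate(organ = sub("_height$", "", .data$trait))
  if (!nrow(heights)) abort("no stigma_height or anther_height records in data")
  out <- heights |>
    dplyr::group_by(area = as.character(.data$area),
                    morph = as.character(.data$morph), organ = .data$organ) |>
    dplyr::summarise(
      mean = mean(.data$value),
      variance = var(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(level = organ_level(.data$morph, .data$organ)) |>
    dplyr::select("area", "morph", "organ", "level", "mean", "variance", "n") |>
    dplyr::arrange(.data$area, .data$morph, .data$organ)
  small <- out |> dplyr::filter(.data$n < 2)
  if (nrow(small)) {
    abort(paste0(
      "need at least 2 records per group x organ; too few for: ",
      paste(paste(small$area, small$morph, small$organ), collapse = "; ")
    ))
  }
  expected <- tidyr::expand_grid(area = c("no_fire", "fire"),
                                 morph = c("L", "S"),
                                 organ = c("stigma", "anther"))
  missing <- dplyr::anti_join(expected, out, by = c("area", "morph", "organ"))
  if (nrow(missing)) {
    abort(paste0(
      "missing organ records for: ",
      paste(paste(missing$area, missing$morph, missing$organ), collapse = "; ")
    ))
  }
  class(out) <- c("organ_summary_tbl", class(out))
  out
}

#' Inaccuracy of one anther-stigma pairing
#'
#' The adaptive-accuracy decomposition for a pair of organ summaries at the
#' same level: maladaptive bias is the squared difference of the organ
#' means, imprecision is the sum of the organ variances, and inaccuracy is
#' their sum. Lower inaccuracy means tighter reciprocity. Pairing a high
#' organ with a low organ is an illegitimate cross and raises an error.
#'
#' @param anther,stigma One-row data frames (or lists) with at least
#'   `mean`, `variance`, and `level`.
#' @return A one-row tibble with `maladaptive_bias`, `imprecision`,
#'   `inaccuracy` (all in squared trait units, mm^2 for heights in mm).
#' @export
#' @examples
#' a <- list(mean = 12, variance = 0.5, level = "high")
#' s <- list(mean = 10, variance = 0.3, level = "high")
#' inaccuracy_component(a, s)  # bias 4, imprecision 0.8, inaccuracy 4.8
inaccuracy_component <- function(anther, stigma) {
  for (x in list(anther, stigma)) {
    if (!all(c("mean", "variance", "level") %in% names(x))) {
      abort("anther and stigma need fields mean, variance, level")
    }
  }
  if (!identical(as.character(anther$level), as.character(stigma$level))) {
    abort(paste0(
      "illegitimate pairing: anther level '", anther$level,
      "' does not match stigma level '", stigma$level, "'"
    ))
  }
  if (anther$variance < 0 || stigma$variance < 0) abort("variances must be >= 0")
  bias <- (anther$mean - stigma$mean)^2
  imprecision <- anther$variance + stigma$variance
  tibble::tibble(
    maladaptive_bias = bias,
    imprecision = imprecision,
    inaccuracy = bias + imprecision
  )
}

#' The four legitimate between-morph combinations
#'
#' Enumerates the four legitimate pollination pairings available in a
#' two-area (fire / no-fire) distylous design: within each area, and the
#' two cross-area morph pairings. Each combination pairs one L-morph group
#' (supplying the high stigma and low anther) with one S-morph group
#' (supplying the high anther and low stigma).
#'
#' @return A tibble with columns `combination`, `L_area`, `S_area`.
#' @export
legitimate_combinations <- function() {
  tibble::tribble(
    ~combination,               ~L_area,   ~S_area,
    "no-fire L <-> no-fire S",  "no_fire", "no_fire",
    "fire L <-> fire S",        "fire",    "fire",
    "no-fire S <-> fire L",     "fire",    "no_fire",
    "no-fire L <-> fire S",     "no_fire", "fire"
  )
}

organ_row <- function(summaries, area, morph, organ) {
  row <- summaries |>
    dplyr::filter(.data$area == .env$area, .data$morph == .env$morph,
                  .data$organ == .env$organ)
  if (nrow(row) != 1L) {
    abort(paste0("missing organ summary for ", area, " ", morph, " ", organ))
  }
  row
}

#' Inaccuracy decomposition for one legitimate combination
#'
#' Applies [inaccuracy_component()] at both organ levels of one legitimate
#' combination: the high level pairs the S-morph anther with the L-morph
#' stigma, the low level pairs the L-morph anther with the S-morph stigma,
#' each drawn from the combination's designated area. Total inaccuracy is
#' the sum of the high and low inaccuracies.
#'
#' @param summaries An `organ_summary_tbl` (see [summarize_organs()]).
#' @param combination One row of [legitimate_combinations()] (or a list
#'   with `combination`, `L_area`, `S_area`).
#' @param standardize If `TRUE`, divides each level's components by the
#'   squared mean of its two organ heights (a dimensionless variant not
#'   used in the original analysis; off by default).
#' @return A one-row tibble with the seven components
#'   `maladaptive_bias_high`, `imprecision_high`, `inaccuracy_high`, the
#'   `_low` triple, and `total_inaccuracy`.
#' @export
inaccuracy_for_combination <- function(summaries, combination,
                                       standardize = FALSE) {
  high_anther <- organ_row(summaries, combination$S_area, "S", "anther")
  high_stigma <- organ_row(summaries, combination$L_area, "L", "stigma")
  low_anther <- organ_row(summaries, combination$L_area, "L", "anther")
  low_stigma <- organ_row(summaries, combination$S_area, "S", "stigma")

  high <- inaccuracy_component(high_anther, high_stigma)
  low <- inaccuracy_component(low_anther, low_stigma)
  if (standardize) {
    hs <- ((high_anther$mean + high_stigma$mean) / 2)^2
    ls <- ((low_anther$mean + low_stigma$mean) / 2)^2
    high <- high / hs
    low <- low / ls
  }
  label <- combination$combination
  l_area <- combination$L_area
  s_area <- combination$S_area
  tibble::tibble(
    combination = label,
    L_area = l_area,
    S_area = s_area,
    maladaptive_bias_high = high$maladaptive_bias,
    imprecision_high = high$imprecision,
    inaccuracy_high = high$inaccuracy,
    maladaptive_bias_low = low$maladaptive_bias,
    imprecision_low = low$imprecision,
    inaccuracy_low = low$inaccuracy,
    total_inaccuracy = high$inaccuracy + low$inaccuracy
  )
}

inaccuracy_from_summaries <- function(summaries, standardize = FALSE) {
  combos <- legitimate_combinations()
  out <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    inaccuracy_for_combination(summaries, combos[i, ], standardize = standardize)
  })
  class(out) <- c("inaccuracy_tbl", class(out))
  out
}

#' Between-morph reciprocity (inaccuracy) across fire and no-fire areas
#'
#' Computes the full inaccuracy decomposition for all four legitimate
#' between-morph combinations of a two-area distylous dataset. Accepts
#' either a raw trait table (organ summaries are computed first) or a
#' precomputed `organ_summary_tbl`.
#'
#' @param data A trait table or an `organ_summary_tbl`.
#' @inheritParams inaccuracy_for_combination
#' @return A tibble with one row per combination and the seven inaccuracy
#'   components (class `inaccuracy_tbl`).
#' @export
#' @examples
#' generate_dataset(population_config(n_individuals_per_cell = 5,
#'                                    n_flowers_per_cell = 20), seed = 1) |>
#'   inaccuracy()
inaccuracy <- function(data, standardize = FALSE) {
  summaries <- if (inherits(data, "organ_summary_tbl")) data else summarize_organs(data)
  inaccuracy_from_summaries(summaries, standardize = standardize)
}

#' Bootstrap confidence intervals for the inaccuracy components
#'
#' Nonparametric bootstrap of the inaccuracy decomposition: organ heights
#' are resampled with replacement within each area x morph group (either
#' individual flowers, or whole individuals for a cluster bootstrap), the
#' four-combination decomposition is recomputed per replicate, and
#' percentile intervals are returned.
#'
#' @param data A trait table containing organ-height records.
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Integer RNG seed.
#' @param level Interval coverage (default 0.95).
#' @param unit `"flower"` (default; resamples flowers, matching the
#'   flower-level variances that enter the statistic) or `"individual"`
#'   (cluster bootstrap on individuals).
#' @param standardize Passed to [inaccuracy_for_combination()].
#' @return A tibble with one row per combination x component: `estimate`,
#'   `lower`, `upper`.
#' @export
bootstrap_inaccuracy <- function(data, B = 1000L, seed = 1L, level = 0.95,
                                 unit = c("flower", "individual"),
                                 standardize = FALSE) {
  unit <- match.arg(unit)
  if (!is.numeric(B) || length(B) != 1L || B < 100) {
    abort("B must be a single count >= 100")
  }
  B <- as.integer(B)
  set.seed(as.integer(seed))

  heights <- data |>
    dplyr::filter(.data$trait %in% c("stigma_height", "anther_height")) |>
    dplyr::mutate(
      organ = sub("_height$", "", .data$trait),
      area = as.character(.data$area), morph = as.character(.data$morph)
    )
  point <- inaccuracy(data, standardize = standardize)

  groups <- split(
    heights,
    paste(heights$area, heights$morph, heights$organ, sep = ".")
  )
  comp_cols <- c("maladaptive_bias_high", "imprecision_high", "inaccuracy_high",
                 "maladaptive_bias_low", "imprecision_low", "inaccuracy_low",
                 "total_inaccuracy")

  # per replicate: resampled mean and variance for each of the 8 group-organ
  # series, then the deterministic decomposition
  boot_stats <- lapply(groups, function(g) {
    x <- g$value
    n <- length(x)
    if (n < 2) abort(paste0("need >= 2 records per group x organ (",
                            g$area[1], " ", g$morph[1], " ", g$organ[1], ")"))
    if (unit == "flower") {
      idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
      xs <- matrix(x[idx], nrow = n)
    } else {
      ind <- g$individual_id
      uids <- unique(ind)
      by_ind <- split(x, ind)[uids]
      picks <- matrix(sample.int(length(uids), length(uids) * B, replace = TRUE),
                      nrow = length(uids))
      xs <- vapply(seq_len(B), function(b) {
        v <- unlist(by_ind[picks[, b]], use.names = FALSE)
        # pad/trim to a fixed length for matrix storage: use moments directly
        c(mean(v), var(v))
      }, numeric(2))
      return(list(mean = xs[1, ], variance = xs[2, ]))
    }
    m <- colMeans(xs)
    v <- (colSums(xs^2) - n * m^2) / (n - 1)
    v[v < 0] <- 0  # guard tiny negative round-off
    list(mean = m, variance = v)
  })

  key <- function(area, morph, organ) paste(area, morph, organ, sep = ".")
  combos <- legitimate_combinations()
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    ha <- boot_stats[[key(cb$S_area, "S", "anther")]]
    hs <- boot_stats[[key(cb$L_area, "L", "stigma")]]
    la <- boot_stats[[key(cb$L_area, "L", "anther")]]
    ls <- boot_stats[[key(cb$S_area, "S", "stigma")]]
    bias_h <- (ha$mean - hs$mean)^2
    impr_h <- ha$variance + hs$variance
    bias_l <- (la$mean - ls$mean)^2
    impr_l <- la$variance + ls$variance
    if (standardize) {
      sh <- ((ha$mean + hs$mean) / 2)^2
      sl <- ((la$mean + ls$mean) / 2)^2
      bias_h <- bias_h / sh; impr_h <- impr_h / sh
      bias_l <- bias_l / sl; impr_l <- impr_l / sl
    }
    reps <- cbind(
      maladaptive_bias_high = bias_h,
      imprecision_high = impr_h,
      inaccuracy_high = bias_h + impr_h,
      maladaptive_bias_low = bias_l,
      imprecision_low = impr_l,
      inaccuracy_low = bias_l + impr_l,
      total_inaccuracy = bias_h + impr_h + bias_l + impr_l
    )
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    qs <- apply(reps, 2, quantile, probs = probs, names = FALSE)
    rows[[i]] <- tibble::tibble(
      combination = cb$combination,
      component = comp_cols,
      estimate = unlist(point[i, comp_cols], use.names = FALSE),
      lower = unname(qs[1, ]),
      upper = unname(qs[2, ])
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "B") <- B
  attr(out, "level") <- level
  attr(out, "unit") <- unit
  out
}
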