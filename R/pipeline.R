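# Deterministic per-stage substreams from one global seed, so stages can be
# re-run in isolation with identical results.
stage_seed <- function(seed, stage) {
  offsets <- c(generate = 1L, bootstrap = 2L, fit = 3L)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]] * 104729) %% 2147483647)
}

#' Run the full fire-distyly analysis pipeline
#'
#' Orchestrates generate -> summarize -> reciprocity -> fit -> effects in a
#' single seeded run: simulates (or accepts) a trait table, computes organ
#' summaries and the four-combination inaccuracy decomposition with
#' bootstrap intervals, fits every registry model, runs type-II Wald tests,
#' extracts back-transformed marginal means, computes morph-conditioned
#' contrasts wherever the interaction is significant at `alpha`, and
#' derives percent effect sizes (fire vs. no-fire per trait, and S vs. L
#' morph effects). The global seed deterministically spawns per-stage
#' seeds, so identical inputs give identical reports.
#'
#' @param config A [population_config()] used to simulate data (ignored if
#'   `data` is supplied).
#' @param data Optional trait table to analyse instead of simulating.
#' @param registry Model registry (default [model_registry()]); use a
#'   subset for partial runs.
#' @param B Bootstrap replicates for the inaccuracy intervals.
#' @param seed Global integer seed.
#' @param alpha Significance level gating the post-hoc contrasts.
#' @return A `run_report`: a list with tibbles `trait_table`,
#'   `organ_summaries`, `inaccuracy`, `inaccuracy_ci`, `wald_tests`,
#'   `marginal_means`, `contrasts`, `effects`, `warnings`, and a
#'   `provenance` list (seed, config hash, package version).
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(population_config(n_individuals_per_cell = 6,
#'                                       n_flowers_per_cell = 24),
#'                     registry = dplyr::filter(model_registry(),
#'                                              trait == "stigma_height"),
#'                     B = 200, seed = 42)
#' rep$inaccuracy
#' }
run_pipeline <- function(config = population_config(), data = NULL,
                         registry = model_registry(), B = 1000L, seed = 1L,
                         alpha = 0.05) {
  warnings <- list()
  note <- function(stagename, msg) {
    warnings[[length(warnings) + 1L]] <<- tibble::tibble(stage = stagename, message = msg)
  }

  if (is.null(data)) {
    data <- generate_dataset(config, seed = stage_seed(seed, "generate"))
  } else {
    data <- validate_trait_table(data)
  }

  organ_summaries <- summarize_organs(data)
  inacc <- inaccuracy(organ_summaries)
  inacc_ci <- bootstrap_inaccuracy(data, B = B, seed = stage_seed(seed, "bootstrap"))

  fits <- list()
  wald <- list()
  mms <- list()
  contrasts <- list()
  for (i in seq_len(nrow(registry))) {
    tr <- registry$trait[i]
    if (!tr %in% data$trait) {
      note("fit", paste0("trait '", tr, "' absent from data; model skipped"))
      next
    }
    fit <- withCallingHandlers(
      tryCatch(fit_trait_model(data, tr, spec = registry[i, ]),
               error = function(e) e),
      warning = function(w) {
        note("fit", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    if (inherits(fit, "error")) {
      note("fit", paste0("model for '", tr, "' failed: ", conditionMessage(fit)))
      next
    }
    if (!fit$converged) {
      note("fit", paste0("model for '", tr, "' did not converge; excluded from tests"))
      next
    }
    fits[[tr]] <- fit
    wald[[tr]] <- wald_type2(fit)
    mms[[tr]] <- marginal_means(fit)
    p_int <- wald[[tr]]$p_value[wald[[tr]]$term == "area:morph"]
    if (length(p_int) == 1L && is.finite(p_int) && p_int < alpha) {
      contrasts[[tr]] <- conditional_contrasts(fit)
    }
  }
  empty_schema <- function(x, proto) if (nrow(x)) x else proto
  wald_tests <- empty_schema(dplyr::bind_rows(wald), tibble::tibble(
    trait = character(), term = character(), chisq = double(),
    df = double(), p_value = double()
  ))
  marginal <- empty_schema(dplyr::bind_rows(mms), tibble::tibble(
    trait = character(), margin = character(), area = character(),
    morph = character(), group = character(), mean = double(),
    se = double(), lower = double(), upper = double()
  ))
  contrast_tbl <- empty_schema(dplyr::bind_rows(contrasts), tibble::tibble(
    trait = character(), morph = character(), contrast = character(),
    estimate = double(), se = double(), z = double(), p_value = double()
  ))

  effects <- pipeline_effects(marginal, contrast_tbl, fits)

  report <- structure(
    list(
      trait_table = data,
      organ_summaries = organ_summaries,
      inaccuracy = inacc,
      inaccuracy_ci = inacc_ci,
      wald_tests = wald_tests,
      marginal_means = marginal,
      contrasts = contrast_tbl,
      effects = effects,
      warnings = if (length(warnings)) dplyr::bind_rows(warnings)
                 else tibble::tibble(stage = character(), message = character()),
      provenance = list(
        seed = as.integer(seed),
        config_hash = rlang::hash(config),
        bootstrap_B = as.integer(B),
        package_version = as.character(utils::packageVersion("distylr"))
      )
    ),
    class = "run_report"
  )
  report
}

# Percent effects on the response scale: fire vs no-fire margin per trait,
# S vs L morph margin per trait, and fire vs no-fire within morph for
# traits with a significant interaction.
pipeline_effects <- function(marginal, contrast_tbl, fits) {
  if (!nrow(marginal)) {
    return(tibble::tibble(trait = character(), term = character(),
                          focal = character(), reference = character(),
                          focal_mean = double(), reference_mean = double(),
                          percent_effect = double(), direction = character()))
  }
  area_eff <- marginal |>
    dplyr::filter(.data$margin == "area") |>
    dplyr::select("trait", "group", "mean") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean") |>
    dplyr::transmute(
      trait = .data$trait, term = "area",
      focal = "fire", reference = "no_fire",
      focal_mean = .data$fire, reference_mean = .data$no_fire
    )
  morph_eff <- marginal |>
    dplyr::filter(.data$margin == "morph") |>
    dplyr::select("trait", "group", "mean") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean") |>
    dplyr::transmute(
      trait = .data$trait, term = "morph",
      focal = "S", reference = "L",
      focal_mean = .data$S, reference_mean = .data$L
    )
  within <- NULL
  if (nrow(contrast_tbl)) {
    cells <- marginal |>
      dplyr::filter(.data$margin == "cell") |>
      dplyr::semi_join(contrast_tbl, by = "trait")
    within <- cells |>
      dplyr::select("trait", "area", "morph", "mean") |>
      tidyr::pivot_wider(names_from = "area", values_from = "mean") |>
      dplyr::transmute(
        trait = .data$trait, term = "area_within_morph",
        focal = paste0("fire:", .data$morph),
        reference = paste0("no_fire:", .data$morph),
        focal_mean = .data$fire, reference_mean = .data$no_fire
      )
  }
  dplyr::bind_rows(area_eff, morph_eff, within) |>
    effect_table()
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$provenance$seed,
      ", ", nrow(x$trait_table), " trait records, ",
      dplyr::n_distinct(x$wald_tests$trait), " models fitted\n", sep = "")
  cat("\nTotal inaccuracy per legitimate combination (mm^2):\n")
  print(as.data.frame(x$inaccuracy[, c("combination", "total_inaccuracy")]),
        row.names = FALSE)
  if (nrow(x$wald_tests)) {
    sig <- x$wald_tests |> dplyr::filter(.data$p_value < 0.05)
    cat("\nSignificant terms (p < 0.05): ",
        if (nrow(sig)) paste(paste0(sig$trait, ":", sig$term), collapse = ", ")
        else "none", "\n", sep = "")
  }
  invisible(x)
}

report_tables <- c("organ_summaries", "inaccuracy", "inaccuracy_ci",
                   "wald_tests", "marginal_means", "contrasts", "effects",
                   "warnings")

#' Serialize a run report to disk
#'
#' Writes every report table as CSV (stable column order), the trait table
#' with its provenance sidecar, a machine-readable `report.json` (all
#' tables plus provenance and warnings), and a short human-readable
#' `summary.txt`. [read_report()] reconstructs an equal report (minus the
#' fitted model objects, which are not serialized).
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) abort(paste0("cannot create output directory: ", dir))
  probe <- file.path(dir, ".write-test")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) abort(paste0("output directory is not writable: ", dir))
  unlink(probe)

  write_trait_table(report$trait_table, file.path(dir, "trait_table.csv"))
  for (nm in report_tables) {
    readr::write_csv(as.data.frame(report[[nm]]), file.path(dir, paste0(nm, ".csv")))
  }
  json <- c(
    lapply(setNames(report_tables, report_tables), function(nm) report[[nm]]),
    list(provenance = report$provenance)
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)

  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Read a serialized run report
#'
#' @param dir Directory written by [write_report()].
#' @return A `run_report` (tables and provenance; fitted model objects are
#'   not serialized and are absent).
#' @export
read_report <- function(dir) {
  if (!dir.exists(dir)) abort(paste0("no such report directory: ", dir))
  tabs <- lapply(setNames(report_tables, report_tables), function(nm) {
    readr::read_csv(file.path(dir, paste0(nm, ".csv")), show_col_types = FALSE)
  })
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  report <- c(
    list(trait_table = read_trait_table(file.path(dir, "trait_table.csv"))),
    tabs,
    list(provenance = js$provenance)
  )
  class(report) <- "run_report"
  report
}
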