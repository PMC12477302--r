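#' The default factorial model registry
#'
#' One row per modelled trait, specifying the response family and link,
#' whether a group-specific (area x morph cell) dispersion parameter is
#' estimated, whether a constant zero-inflation probability is added, and
#' whether a per-individual random intercept is used. Individual-level
#' traits come from independent samplings and carry no random intercept;
#' all sub-individual traits do. The registry covers: Gaussian/identity for
#' inflorescence length, corolla diameter, stigma height, nectar volume and
#' calories; gamma/log for plant height, stem diameter, corolla length,
#' anther height, stigma and anther lengths; NB1/log for the four count
#' traits (with zero inflation for deposited pollen grains); and
#' beta/logit for nectar concentration (a percentage, modelled on the
#' proportion scale).
#'
#' @param include_pollen_presence Also include a binomial/logit model of
#'   pollen presence/absence per stigma (an alternative, proportion-style
#'   view of the pollen-deposition data; off by default).
#' @return A tibble with columns `trait`, `family`, `link`, `dispersion`,
#'   `zero_inflated`, `random_intercept`.
#' @export
model_registry <- function(include_pollen_presence = FALSE) {
  reg <- tibble::tribble(
    ~trait,                  ~family,    ~link,      ~dispersion, ~zero_inflated, ~random_intercept,
    "plant_height",          "gamma",    "log",      FALSE,       FALSE,          FALSE,
    "stem_diameter",         "gamma",    "log",      FALSE,       FALSE,          FALSE,
    "n_inflorescences",      "nb1",      "log",      FALSE,       FALSE,          FALSE,
    "inflorescence_length",  "gaussian", "identity", FALSE,       FALSE,          TRUE,
    "n_buds",                "nb1",      "log",      FALSE,       FALSE,          TRUE,
    "n_fruits",              "nb1",      "log",      TRUE,        FALSE,          TRUE,
    "corolla_length",        "gamma",    "log",      TRUE,        FALSE,          TRUE,
    "corolla_diameter",      "gaussian", "identity", FALSE,       FALSE,          TRUE,
    "stigma_height",         "gaussian", "identity", FALSE,       FALSE,          TRUE,
    "anther_height",         "gamma",    "log",      TRUE,        FALSE,          TRUE,
    "stigma_length",         "gamma",    "log",      FALSE,       FALSE,          TRUE,
    "anther_length",         "gamma",    "log",      TRUE,        FALSE,          TRUE,
    "nectar_volume",         "gaussian", "identity", TRUE,        FALSE,          TRUE,
    "nectar_concentration",  "beta",     "logit",    FALSE,       FALSE,          TRUE,
    "nectar_calories",       "gaussian", "identity", FALSE,       FALSE,          TRUE,
    "pollen_grains",         "nb1",      "log",      FALSE,       TRUE,           TRUE
  )
  if (include_pollen_presence) {
    reg <- dplyr::bind_rows(reg, tibble::tibble(
      trait = "pollen_presence", family = "binomial", link = "logit",
      dispersion = FALSE, zero_inflated = FALSE, random_intercept = TRUE
    ))
  }
  reg
}

family_object <- function(family, link) {
  switch(family,
    gaussian = stats::gaussian(link = link),
    gamma = stats::Gamma(link = link),
    nb1 = glmmTMB::nbinom1(link = link),
    beta = glmmTMB::beta_family(link = link),
    binomial = stats::binomial(link = link),
    abort(paste0("unknown model family: ", family))
  )
}

check_support <- function(values, family, trait, unit_id) {
  offending <- switch(family,
    gaussian = integer(0),
    gamma = which(!(values > 0)),
    nb1 = which(values < 0 | values != round(values)),
    beta = which(!(values > 0 & values < 1)),
    binomial = which(!(values %in% c(0, 1))),
    integer(0)
  )
  if (length(offending)) {
    shown <- head(unit_id[offending], 5)
    abort(paste0(
      "trait '", trait, "' has ", length(offending),
      " value(s) outside the support of the ", family, " family (e.g. units ",
      paste(shown, collapse = ", "), ")"
    ))
  }
}

#' Fit one factorial trait model
#'
#' Fits `trait ~ area * morph` by maximum likelihood with the family, link,
#' dispersion structure, zero inflation and random-intercept setting given
#' by the model registry (or an explicit one-row `spec`). Group-specific
#' dispersion is modelled cell-wise (`~ area * morph` dispersion formula);
#' zero inflation is intercept-only. Percent-scale beta responses (values
#' in (0, 100)) are rescaled to proportions for fitting and back-scaled in
#' [marginal_means()]. Non-convergence is retried once with a larger
#' optimizer budget and otherwise flagged, never silent.
#'
#' @param data A trait table (long format; see [generate_dataset()]).
#' @param trait Trait to model (must appear in `data$trait`).
#' @param spec Optional one-row specification overriding the registry.
#' @param registry Model registry to look the trait up in.
#' @return A `trait_fit` object: a list with the `trait`, `spec`, fitted
#'   `model` (a `glmmTMB` object), `converged` flag, response `scale`, and
#'   the model frame `data`.
#' @export
#' @examples
#' \donttest{
#' tab <- generate_dataset(population_config(n_individuals_per_cell = 6,
#'                                           n_flowers_per_cell = 30), seed = 1)
#' fit <- fit_trait_model(tab, "stigma_height")
#' wald_type2(fit)
#' }
fit_trait_model <- function(data, trait, spec = NULL,
                            registry = model_registry(include_pollen_presence = TRUE)) {
  if (is.null(spec)) {
    spec <- registry |> dplyr::filter(.data$trait == .env$trait)
    if (nrow(spec) != 1L) abort(paste0("trait '", trait, "' not in model registry"))
  }
  df <- data |>
    dplyr::filter(.data$trait == .env$trait) |>
    dplyr::transmute(
      area = factor(as.character(.data$area), levels = c("no_fire", "fire")),
      morph = factor(as.character(.data$morph), levels = c("L", "S")),
      individual_id = as.character(.data$individual_id),
      unit_id = as.character(.data$unit_id),
      value = .data$value
    )
  if (!nrow(df)) abort(paste0("no records for trait '", trait, "'"))
  if (dplyr::n_distinct(df$area) < 2 || dplyr::n_distinct(df$morph) < 2) {
    abort(paste0("trait '", trait,
                 "' needs both areas and both morphs present to fit the factorial model"))
  }

  scale <- 1
  if (spec$family == "beta" && max(df$value) > 1) {
    scale <- 100
    df$value <- df$value / 100
  }
  check_support(df$value, spec$family, trait, df$unit_id)

  rhs <- "area * morph"
  if (spec$random_intercept) rhs <- paste(rhs, "+ (1 | individual_id)")
  form <- as.formula(paste("value ~", rhs))
  dispf <- if (isTRUE(spec$dispersion)) ~ area * morph else ~1
  zif <- if (isTRUE(spec$zero_inflated)) ~1 else ~0
  fam <- family_object(spec$family, spec$link)

  fit_once <- function(formula, control) {
    tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(
        formula, data = df, family = fam, dispformula = dispf, ziformula = zif,
        control = control
      )),
      error = function(e) e
    )
  }
  is_ok <- function(m) {
    inherits(m, "glmmTMB") && isTRUE(m$sdr$pdHess) &&
      identical(m$fit$convergence, 0L)
  }
  re_dropped <- FALSE
  model <- fit_once(form, glmmTMB::glmmTMBControl())
  if (!is_ok(model)) {
    model <- fit_once(form, glmmTMB::glmmTMBControl(
      optCtrl = list(iter.max = 5000, eval.max = 5000)
    ))
  }
  if (!is_ok(model) && spec$random_intercept) {
    # degenerate-design fallback: with one unit per individual (or a
    # boundary variance) the intercept variance is unidentifiable; refit
    # without it and flag the simplification
    model2 <- fit_once(value ~ area * morph, glmmTMB::glmmTMBControl())
    if (is_ok(model2)) {
      model <- model2
      re_dropped <- TRUE
      warn(paste0("random intercept dropped for trait '", trait,
                  "' (unidentifiable variance); fixed-effects model reported"))
    }
  }
  converged <- is_ok(model)
  if (!converged) {
    warn(paste0("model for trait '", trait, "' did not converge; result is flagged"))
  }
  structure(
    list(trait = trait, spec = spec, model = model, data = df,
         converged = converged, re_dropped = re_dropped,
         scale = scale, n = nrow(df)),
    class = "trait_fit"
  )
}

#' @export
print.trait_fit <- function(x, ...) {
  cat("<trait_fit> ", x$trait, ": ", x$spec$family, "(", x$spec$link, ")",
      if (isTRUE(x$spec$dispersion)) " + cell dispersion",
      if (isTRUE(x$spec$zero_inflated)) " + zero inflation",
      if (isTRUE(x$spec$random_intercept)) " + (1 | individual)",
      ", n = ", x$n,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

assert_converged <- function(fit) {
  if (!inherits(fit, "trait_fit")) abort("expected a trait_fit object")
  if (inherits(fit$model, "error")) {
    abort(paste0("model for trait '", fit$trait, "' failed to fit: ",
                 conditionMessage(fit$model)))
  }
  if (!fit$converged) {
    abort(paste0("model for trait '", fit$trait,
                 "' did not converge; tests are not reported for unconverged fits"))
  }
  invisible(fit)
}

#' Type-II Wald chi-square tests for a factorial trait fit
#'
#' Analysis-of-deviance table in the type-II style: each main effect is
#' tested against the model containing the other main effect (ignoring the
#' interaction), and the interaction is tested last, using Wald chi-square
#' statistics from the fitted coefficient covariance. With two-level
#' factors every term has 1 degree of freedom.
#'
#' @param fit A converged `trait_fit`.
#' @return A tibble with columns `trait`, `term`, `chisq`, `df`, `p_value`.
#' @export
wald_type2 <- function(fit) {
  assert_converged(fit)
  a <- car::Anova(fit$model, type = "II")
  tibble::tibble(
    trait = fit$trait,
    term = rownames(a),
    chisq = a[["Chisq"]],
    df = a[["Df"]],
    p_value = a[["Pr(>Chisq)"]]
  )
}

emm_response_col <- function(s) {
  cand <- intersect(c("response", "rate", "prob", "emmean"), names(s))
  if (!length(cand)) abort("could not locate the response column in emmeans output")
  cand[1]
}

#' Back-transformed marginal means of a trait fit
#'
#' Model-based predicted means per area x morph cell and per factor margin:
#' means are formed on the link scale by averaging over the factor grid
#' (not observation-weighted) and then inverse-linked, with delta-method
#' standard errors on the response scale.
#'
#' @param fit A converged `trait_fit`.
#' @param margins Which grids to report: any of `"cell"`, `"area"`,
#'   `"morph"`.
#' @return A tibble with columns `trait`, `margin`, `area`, `morph`,
#'   `group`, `mean`, `se`, `lower`, `upper` (response scale; percent scale
#'   for percent-valued beta responses).
#' @export
marginal_means <- function(fit, margins = c("cell", "area", "morph")) {
  assert_converged(fit)
  margins <- match.arg(margins, several.ok = TRUE)
  out <- purrr::map_dfr(margins, function(mg) {
    spec <- switch(mg, cell = ~ area * morph, area = ~area, morph = ~morph)
    emm <- suppressMessages(emmeans::emmeans(fit$model, spec, type = "response"))
    s <- as.data.frame(suppressMessages(summary(emm)))
    rc <- emm_response_col(s)
    lcl <- intersect(c("asymp.LCL", "lower.CL"), names(s))[1]
    ucl <- intersect(c("asymp.UCL", "upper.CL"), names(s))[1]
    tibble::tibble(
      trait = fit$trait,
      margin = mg,
      area = if ("area" %in% names(s)) as.character(s$area) else NA_character_,
      morph = if ("morph" %in% names(s)) as.character(s$morph) else NA_character_,
      mean = s[[rc]] * fit$scale,
      se = s[["SE"]] * fit$scale,
      lower = if (!is.na(lcl)) s[[lcl]] * fit$scale else NA_real_,
      upper = if (!is.na(ucl)) s[[ucl]] * fit$scale else NA_real_
    )
  })
  out |>
    dplyr::mutate(group = dplyr::case_when(
      !is.na(.data$area) & !is.na(.data$morph) ~ paste(.data$area, .data$morph, sep = ":"),
      !is.na(.data$area) ~ .data$area,
      TRUE ~ .data$morph
    )) |>
    dplyr::select("trait", "margin", "area", "morph", "group",
                  "mean", "se", "lower", "upper")
}

#' Morph-conditioned area contrasts
#'
#' Post-hoc contrasts for a significant area x morph interaction: the fire
#' vs. no-fire comparison within each morph, on the link scale, with Wald
#' z tests.
#'
#' @param fit A converged `trait_fit` whose model contains the area:morph
#'   interaction.
#' @return A tibble with columns `trait`, `morph`, `contrast`, `estimate`
#'   (link scale), `se`, `z`, `p_value`.
#' @export
conditional_contrasts <- function(fit) {
  assert_converged(fit)
  terms_used <- attr(stats::terms(stats::formula(fit$model, fixed.only = TRUE)),
                     "term.labels")
  if (!"area:morph" %in% terms_used) {
    abort("no area:morph interaction in this fit; read the main effects instead")
  }
  emm <- emmeans::emmeans(fit$model, ~ area | morph)
  ct <- emmeans::contrast(emm, method = "revpairwise")
  s <- as.data.frame(summary(ct))
  tibble::tibble(
    trait = fit$trait,
    morph = as.character(s$morph),
    contrast = as.character(s$contrast),
    estimate = s$estimate,
    se = s$SE,
    z = s[[intersect(c("z.ratio", "t.ratio"), names(s))[1]]],
    p_value = s$p.value
  )
}

#' @export
tidy.trait_fit <- function(x, ...) {
  assert_converged(x)
  sm <- summary(x$model)
  comp_tbl <- function(mat, component) {
    if (is.null(mat) || !nrow(mat)) return(NULL)
    tibble::tibble(
      component = component,
      term = rownames(mat),
      estimate = mat[, "Estimate"],
      std.error = mat[, "Std. Error"],
      statistic = mat[, "z value"],
      p.value = mat[, "Pr(>|z|)"]
    )
  }
  dplyr::bind_rows(
    comp_tbl(sm$coefficients$cond, "cond"),
    comp_tbl(sm$coefficients$zi, "zi"),
    comp_tbl(sm$coefficients$disp, "disp")
  )
}

#' @export
glance.trait_fit <- function(x, ...) {
  ll <- tryCatch(logLik(x$model), error = function(e) NA)
  tibble::tibble(
    trait = x$trait,
    nobs = x$n,
    logLik = as.numeric(ll),
    AIC = tryCatch(AIC(x$model), error = function(e) NA_real_),
    BIC = tryCatch(BIC(x$model), error = function(e) NA_real_),
    sigma = tryCatch(stats::sigma(x$model), error = function(e) NA_real_),
    converged = x$converged
  )
}
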