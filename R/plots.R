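#' Plot the inaccuracy decomposition
#'
#' Stacked bars of maladaptive bias and imprecision at each organ level for
#' every legitimate combination, mirroring the usual presentation of the
#' adaptive-accuracy decomposition.
#'
#' @param object An `inaccuracy_tbl` from [inaccuracy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inaccuracy_tbl <- function(object, ...) {
  long <- object |>
    dplyr::select("combination", dplyr::starts_with("maladaptive_bias"),
                  dplyr::starts_with("imprecision")) |>
    tidyr::pivot_longer(-"combination", names_to = "key", values_to = "value") |>
    tidyr::separate_wider_regex(
      "key", c(component = ".*", "_", level = "high|low")
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$combination)) +
    ggplot2::labs(x = "organ level", y = expression(inaccuracy ~ (mm^2)),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot back-transformed marginal means of a trait fit
#'
#' Cell means (area x morph) with their confidence intervals on the
#' response scale.
#'
#' @param object A converged `trait_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_fit <- function(object, ...) {
  mm <- marginal_means(object, margins = "cell")
  ggplot2::ggplot(mm, ggplot2::aes(x = .data$area, y = .data$mean,
                                   colour = .data$morph, group = .data$morph)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.15, position = ggplot2::position_dodge(width = 0.3)
    ) +
    ggplot2::labs(x = NULL, y = object$trait, colour = "morph") +
    ggplot2::theme_minimal()
}

#' Diverging bar chart of percent effect sizes
#'
#' @param effects An effect table (see [effect_table()] or the `effects`
#'   element of a [run_pipeline()] report).
#' @return A ggplot object.
#' @export
plot_effects <- function(effects) {
  if (!all(c("trait", "percent_effect") %in% names(effects))) {
    abort("effects must have columns trait and percent_effect")
  }
  lab <- paste0(effects$trait, " (", effects$focal, " vs ", effects$reference, ")")
  d <- dplyr::mutate(effects, label = lab)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$percent_effect,
                                  y = stats::reorder(.data$label, .data$percent_effect),
                                  fill = .data$percent_effect > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "percent effect (%)", y = NULL) +
    ggplot2::theme_minimal()
}
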