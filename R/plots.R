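#' Plot a scenario comparison
#'
#' Dot plot of the EBV correlations with the reference solve per scenario
#' (genotyped animals and all animals), ordered by the genotyped-animal
#' correlation — the report's main criterion.
#'
#' @param object A `scenario_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_report <- function(object, ...) {
  res <- object$results[object$results$scenario != "NormalG", ]
  long <- tidyr::pivot_longer(res, c("cor_all", "cor_genotyped"),
                              names_to = "criterion", values_to = "correlation")
  long$criterion <- ifelse(long$criterion == "cor_genotyped",
                           "genotyped animals", "all animals")
  ord <- res$scenario[order(res$cor_genotyped)]
  long$scenario <- factor(long$scenario, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$correlation, y = .data$scenario,
                                     colour = .data$criterion)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "correlation of EBV with reference single-step",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the solver's convergence history
#'
#' Relative squared residual per PCG iteration on a log scale.
#'
#' @param object An `ssgblup_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssgblup_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$residual_history),
                       residual = object$residual_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$residual)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "PCG iteration", y = "squared relative residual") +
    ggplot2::theme_minimal()
}

#' Plot per-year core composition
#'
#' Bar chart of the fraction of each birth year's genotyped animals that
#' belong to the core group, one panel per scenario.
#'
#' @param summaries Tibble from row-binding [summarize_core()] results.
#' @return A ggplot object.
#' @export
plot_core_years <- function(summaries) {
  df <- tidyr::unnest(summaries[c("scenario", "per_year")], "per_year")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$birth_year),
                                   y = .data$fraction_in_core)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "birth year", y = "fraction of year's genotyped animals in core") +
    ggplot2::theme_minimal()
}
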