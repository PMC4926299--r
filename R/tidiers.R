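#' Tidy a fitted single-step solution
#'
#' @param x An `ssgblup_fit`.
#' @param ... Unused.
#' @return Tibble with one row per animal: `animal`, `ebv`, and
#'   `genotyped` when the fit carries the genotyped ids.
#' @export
tidy.ssgblup_fit <- function(x, ...) {
  out <- tibble::tibble(animal = names(x$ebv), ebv = unname(x$ebv))
  if (!is.null(x$geno_ids)) out$genotyped <- out$animal %in% x$geno_ids
  out
}

#' One-row summary of a fitted single-step solution
#'
#' @param x An `ssgblup_fit`.
#' @param ... Unused.
#' @export
glance.ssgblup_fit <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario %||% NA_character_,
    n_animals = length(x$ebv),
    iterations = x$iterations,
    converged = x$converged,
    final_residual = tail(x$residual_history, 1),
    tol = x$tol,
    lambda = x$lambda,
    sparsity_pct = x$sparsity_pct %||% NA_real_
  )
}

#' Tidy a scenario comparison report
#'
#' @param x A `scenario_report`.
#' @param ... Unused.
#' @return The per-scenario results tibble.
#' @export
tidy.scenario_report <- function(x, ...) x$results

#' One-row summary of a scenario comparison report
#'
#' @param x A `scenario_report`.
#' @param ... Unused.
#' @export
glance.scenario_report <- function(x, ...) {
  alt <- x$results[x$results$scenario != "NormalG", ]
  tibble::tibble(
    n_scenarios = nrow(x$results),
    n_genotyped = x$n_genotyped,
    best_scenario = alt$scenario[which.max(alt$cor_genotyped)],
    best_cor_genotyped = max(alt$cor_genotyped),
    n_significant_pairs = sum(x$pairwise$p_value < 0.05, na.rm = TRUE)
  )
}
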