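#' Core-group assignments for the sparse single-step scenarios
#'
#' A core assignment names the genotyped animals that form the APY core
#' group under one of the selection scenarios: random subsets of 10/30/50%
#' (across-generation representation), the oldest or youngest animals
#' (single-generation cores), animals ranked by number of genotyped
#' offspring, the offspring/random hybrid that ranks older animals by
#' genotyped offspring but samples the last birth year at random, and a
#' minimum-kinship core found by a genetic algorithm.
#'
#' @param ped A `ped_tbl`.
#' @param fraction Core fraction of the genotyped animals, in (0, 1].
#' @param seed Optional integer seed for the random component.
#' @param counts Optional precomputed [count_genotyped_offspring()] table.
#' @return An object of class `core_assignment`: list with
#'   `scenario`, `fraction`, `core_ids`, `seed`.
#' @name core_selection
NULL

new_core_assignment <- function(scenario, fraction, core_ids, seed = NULL) {
  structure(list(scenario = scenario, fraction = fraction,
                 core_ids = as.character(core_ids), seed = seed),
            class = "core_assignment")
}

#' @exportS3Method base::print
print.core_assignment <- function(x, ...) {
  cat("<core_assignment> ", x$scenario, ": ", length(x$core_ids),
      " core animals (fraction ", x$fraction, ")\n", sep = "")
  invisible(x)
}

#' Tidy a core assignment into a per-animal table
#'
#' @param x A `core_assignment`.
#' @param ped Optional `ped_tbl`; when given, one row per genotyped animal
#'   with an `in_core` flag, otherwise one row per core animal.
#' @param ... Unused.
#' @export
tidy.core_assignment <- function(x, ped = NULL, ...) {
  if (is.null(ped)) {
    return(tibble::tibble(animal = x$core_ids, in_core = TRUE,
                          scenario = x$scenario))
  }
  ped <- as_ped(ped)
  ids <- ped$animal[ped$genotyped]
  tibble::tibble(animal = ids, in_core = ids %in% x$core_ids,
                 scenario = x$scenario)
}

geno_pool <- function(ped) {
  ped <- as_ped(ped)
  ped[ped$genotyped, c("animal", "birth_year")]
}

core_size <- function(n, fraction) {
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  k <- round(fraction * n)
  if (k < 1) abort("fraction rounds to an empty core group")
  as.integer(k)
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' @rdname core_selection
#' @export
select_random <- function(ped, fraction, seed = NULL) {
  pool <- geno_pool(ped)
  k <- core_size(nrow(pool), fraction)
  ids <- with_optional_seed(seed, sample(pool$animal, k))
  new_core_assignment("Random", fraction, sort(ids), seed)
}

#' @rdname core_selection
#' @export
select_oldest <- function(ped, fraction) {
  pool <- geno_pool(ped)
  k <- core_size(nrow(pool), fraction)
  ord <- order(pool$birth_year, pool$animal, method = "radix")
  new_core_assignment("Old", fraction, pool$animal[ord][seq_len(k)])
}

#' @rdname core_selection
#' @export
select_youngest <- function(ped, fraction) {
  pool <- geno_pool(ped)
  k <- core_size(nrow(pool), fraction)
  ord <- order(pool$birth_year, pool$animal, method = "radix")
  new_core_assignment("Young", fraction, tail(pool$animal[ord], k))
}

#' @rdname core_selection
#' @export
select_by_offspring <- function(ped, fraction, counts = NULL) {
  ped <- as_ped(ped)
  if (is.null(counts)) counts <- count_genotyped_offspring(ped)
  k <- core_size(nrow(counts), fraction)
  ord <- order(-counts$n_genotyped_offspring, counts$animal, method = "radix")
  new_core_assignment("Offspring", fraction, sort(counts$animal[ord][seq_len(k)]))
}

#' @rdname core_selection
#' @export
select_offspring_random <- function(ped, fraction, seed = NULL, counts = NULL) {
  ped <- as_ped(ped)
  pool <- geno_pool(ped)
  if (length(unique(pool$birth_year)) < 2) {
    abort("offspring/random core needs at least two genotyped birth years")
  }
  if (is.null(counts)) counts <- count_genotyped_offspring(ped)
  last_year <- max(pool$birth_year)
  young <- pool$animal[pool$birth_year == last_year]
  old <- pool$animal[pool$birth_year < last_year]

  k_total <- core_size(nrow(pool), fraction)
  k_young <- min(round(fraction * length(young)), k_total)
  k_old <- k_total - k_young
  if (k_old > length(old)) {
    k_young <- k_total - length(old)
    k_old <- length(old)
  }
  young_core <- with_optional_seed(
    seed, if (k_young > 0) sample(young, k_young) else character(0)
  )
  oc <- counts[counts$animal %in% old, ]
  ord <- order(-oc$n_genotyped_offspring, oc$animal, method = "radix")
  old_core <- oc$animal[ord][seq_len(k_old)]
  new_core_assignment("OffspringRandom", fraction, sort(c(young_core, old_core)), seed)
}

#' Minimum-relatedness core group via a genetic algorithm
#'
#' Chooses a fixed-size core that minimizes the mean pairwise pedigree
#' relationship (off-diagonal of A22) within the core, by a simulated
#' evolution of candidate subsets driven by recombination and mutation.
#' With elitist survival, the returned fitness is never worse than that of
#' the random initial subsets of the same size.
#'
#' @param A22 Pedigree relationship matrix of the genotyped animals, with
#'   animal ids as dimnames.
#' @param fraction Core fraction in (0, 1].
#' @param seed Optional integer seed.
#' @param params A [ga_params()] object.
#' @return A `core_assignment` with attributes `fitness` (mean within-core
#'   relatedness) and `ga_generations`.
#' @export
select_unrelated <- function(A22, fraction, seed = NULL, params = ga_params()) {
  n <- nrow(A22)
  if (is.null(rownames(A22))) abort("A22 needs animal ids as dimnames")
  k <- core_size(n, fraction)
  fit_fn <- function(idx) mean_offdiag(A22, idx)
  res <- with_optional_seed(seed, ga_subset_min(fit_fn, n, k, params))
  out <- new_core_assignment("Unrelated", fraction, sort(rownames(A22)[res$best]), seed)
  attr(out, "fitness") <- res$fitness
  attr(out, "ga_generations") <- res$generations
  out
}

mean_offdiag <- function(A, idx) {
  k <- length(idx)
  if (k < 2) return(0)
  sub <- A[idx, idx]
  (sum(sub) - sum(diag(sub))) / (k * (k - 1))
}

#' Summary statistics for a core group
#'
#' The per-scenario descriptors reported alongside the accuracy
#' comparisons: mean pairwise pedigree relatedness within the core
#' (off-diagonal A22 values; 0 with a flag for a singleton core), the mean
#' of absolute values of the A22^-1 columns belonging to core animals, the
#' mean number of genotyped offspring of core animals, and the fraction of
#' each birth year's genotyped animals that are in the core.
#'
#' @param assignment A `core_assignment`.
#' @param ped A `ped_tbl`.
#' @param A22 Pedigree relationship matrix of the genotyped animals
#'   (dimnames = animal ids).
#' @param A22_inv Sparse (or dense) A22^-1, same animals and order.
#' @param counts Optional precomputed [count_genotyped_offspring()] table.
#' @return One-row tibble with a `per_year` list-column (tibble of
#'   `birth_year`, `fraction_in_core`).
#' @export
summarize_core <- function(assignment, ped, A22, A22_inv, counts = NULL) {
  stopifnot(inherits(assignment, "core_assignment"))
  ped <- as_ped(ped)
  pool <- geno_pool(ped)
  core <- assignment$core_ids
  pos <- match(core, rownames(A22))
  if (anyNA(pos)) abort("core animals missing from A22")
  if (is.null(counts)) counts <- count_genotyped_offspring(ped)

  singleton <- length(core) < 2
  mean_rel <- mean_offdiag(A22, pos)

  sub <- A22_inv[, pos, drop = FALSE]
  mean_abs_col <- if (is(sub, "sparseMatrix")) {
    gm <- as(as(sub, "generalMatrix"), "CsparseMatrix")
    sum(abs(gm@x)) / prod(dim(sub))
  } else {
    mean(abs(sub))
  }

  mean_off <- mean(counts$n_genotyped_offspring[counts$animal %in% core])
  per_year <- pool |>
    dplyr::mutate(in_core = .data$animal %in% core) |>
    dplyr::group_by(.data$birth_year) |>
    dplyr::summarise(fraction_in_core = mean(.data$in_core), .groups = "drop") |>
    dplyr::arrange(.data$birth_year)

  tibble::tibble(
    scenario = assignment$scenario,
    fraction = assignment$fraction,
    n_core = length(core),
    mean_relatedness = mean_rel,
    singleton_core = singleton,
    mean_abs_col_a22inv = mean_abs_col,
    mean_genotyped_offspring = mean_off,
    per_year = list(per_year)
  )
}
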