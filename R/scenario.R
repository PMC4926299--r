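#' Precompute the shared single-step inputs for scenario comparisons
#'
#' Builds, once per dataset, everything the scenarios share: the sparse
#' inverse pedigree relationship matrix over all animals, the genotyped
#' block A22 and its inverse by absorption (exact and
#' threshold-sparsified), and the blended genomic relationship matrix
#' G = (1 - w_a) G_a + w_a A22 with G_a = beta G_m + alpha rescaled to the
#' pedigree base. Scenarios then differ only in how G^-1 is formed.
#'
#' @param ped A `ped_tbl`.
#' @param geno A `geno_matrix` of the genotyped animals (all of which must
#'   be flagged `genotyped` in the pedigree).
#' @param phenos Tibble with `animal`, `value` and any fixed-effect
#'   covariates.
#' @param vc A [variance_components()] object.
#' @param w_a Weight on pedigree relationships when blending (default
#'   0.25).
#' @param threshold Drop threshold for sparsifying A22^-1 (default 1e-4).
#' @param fixed Fixed-effect formula for the model (default `~ 1`).
#' @param inbreeding Include inbreeding in the relationship inverses.
#' @return List of class `ssgblup_data`.
#' @export
prep_ssgblup <- function(ped, geno, phenos, vc, w_a = 0.25, threshold = 1e-4,
                         fixed = ~1, inbreeding = TRUE) {
  ped <- require_sorted(ped)
  stopifnot(inherits(geno, "geno_matrix"), inherits(vc, "variance_components"))
  ids <- rownames(geno$M)
  bad <- setdiff(ids, ped$animal[ped$genotyped])
  if (length(bad) > 0) {
    abort(paste0("genotyped animals not flagged in pedigree: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  # genotyped block in pedigree order (contiguous mapping kept in geno_index)
  geno_ids <- ped$animal[ped$animal %in% ids]
  M <- geno$M[geno_ids, , drop = FALSE]
  geno <- geno_matrix(M, chrom = geno$chrom, pos = geno$pos)

  a_full_inv <- build_A_inverse(ped, inbreeding = inbreeding)
  a22 <- build_A(ped, subset = geno_ids)
  a22_inv <- build_A22_inverse(ped, geno_ids, inbreeding = inbreeding)
  a22_inv_sparse <- sparsify(a22_inv, threshold)

  p <- allele_frequencies(geno)
  gm <- build_Gm(geno, p)
  sc <- fit_scaling(gm, a22)
  g <- blend_G(rescale_Gm(gm, sc), a22, w_a)

  structure(list(
    ped = ped, phenos = phenos, vc = vc, w_a = w_a, threshold = threshold,
    fixed = fixed, geno_ids = geno_ids,
    geno_index = match(geno_ids, ped$animal),
    A_full_inv = a_full_inv, A22 = a22, A22_inv = a22_inv,
    A22_inv_sparse = a22_inv_sparse, Gm = gm, scaling = sc, G = g
  ), class = "ssgblup_data")
}

#' @exportS3Method base::print
print.ssgblup_data <- function(x, ...) {
  cat("<ssgblup_data> ", nrow(x$ped), " pedigree animals, ",
      length(x$geno_ids), " genotyped, ", nrow(x$phenos), " records\n",
      sep = "")
  invisible(x)
}

#' Solve one single-step scenario
#'
#' Shares one mixed-model/PCG path across scenarios; they differ only in
#' the genotyped-block correction of H^-1:
#' * `NormalG` - the reference: dense inversion of G, exact A22^-1.
#' * `NormalA` - pedigree only: no genomic correction at all.
#' * a `core_assignment` - APY inverse of G for that core, with the
#'   threshold-sparsified A22^-1.
#'
#' @param data An `ssgblup_data` from [prep_ssgblup()].
#' @param scenario `"NormalG"`, `"NormalA"`, or a `core_assignment`.
#' @param tol,max_iter Passed to [pcg_solve()].
#' @param scaling_basis `"all"` (default) keeps the dataset-wide rescaling
#'   of G_m; `"core"` refits beta/alpha on the core animals only.
#' @return An `ssgblup_fit` with extra fields `scenario`, `sparsity_pct`
#'   (of the correction G^-1 - A22^-1; `NA` for NormalA) and `core_size`.
#' @export
solve_scenario <- function(data, scenario, tol = 1e-10, max_iter = 5000,
                           scaling_basis = c("all", "core")) {
  stopifnot(inherits(data, "ssgblup_data"))
  scaling_basis <- match.arg(scaling_basis)
  label <- if (inherits(scenario, "core_assignment")) {
    paste0(scenario$scenario, round(100 * scenario$fraction))
  } else {
    scenario
  }

  if (identical(scenario, "NormalA")) {
    h <- assemble_H_inverse(data$A_full_inv)
    spar <- NA_real_
    core_size <- NA_integer_
  } else if (identical(scenario, "NormalG")) {
    ginv <- invert_dense(data$G)
    corr <- ginv - data$A22_inv
    spar <- sparsity(corr)
    h <- assemble_H_inverse(data$A_full_inv, ginv, data$A22_inv, data$geno_index)
    core_size <- length(data$geno_ids)
  } else if (inherits(scenario, "core_assignment")) {
    g <- data$G
    if (scaling_basis == "core") {
      basis <- match(scenario$core_ids, data$geno_ids)
      sc <- fit_scaling(data$Gm, data$A22, basis = basis)
      g <- blend_G(rescale_Gm(data$Gm, sc), data$A22, data$w_a)
    }
    apy <- apy_inverse(g, scenario$core_ids, ids = data$geno_ids)
    spar <- sparsity(apy$Kinv - data$A22_inv_sparse)
    h <- assemble_H_inverse(data$A_full_inv, apy$Kinv, data$A22_inv_sparse,
                            data$geno_index)
    core_size <- length(scenario$core_ids)
  } else {
    abort("scenario must be 'NormalG', 'NormalA' or a core_assignment")
  }

  mme <- build_mme(data$phenos, h, data$vc, fixed = data$fixed)
  fit <- pcg_solve(mme, tol = tol, max_iter = max_iter)
  fit$scenario <- label
  fit$sparsity_pct <- spar
  fit$core_size <- core_size
  fit$geno_ids <- data$geno_ids
  fit
}

parse_scenario_label <- function(label) {
  m <- regmatches(label, regexec(
    "^(NormalG|NormalA|OffspringRandom|Offspring|Random|Unrelated|Old|Young)([0-9]+)?$",
    label))[[1]]
  if (length(m) == 0) abort(paste0("unknown scenario label: ", label))
  list(kind = m[2],
       fraction = if (m[3] == "") NA_real_ else as.numeric(m[3]) / 100)
}

build_scenario <- function(data, label, seed = NULL, ga = ga_params()) {
  p <- parse_scenario_label(label)
  if (p$kind %in% c("NormalG", "NormalA")) return(p$kind)
  if (is.na(p$fraction)) abort(paste0("scenario ", label, " needs a percentage suffix"))
  switch(p$kind,
    Random = select_random(data$ped, p$fraction, seed),
    Old = select_oldest(data$ped, p$fraction),
    Young = select_youngest(data$ped, p$fraction),
    Offspring = select_by_offspring(data$ped, p$fraction),
    OffspringRandom = select_offspring_random(data$ped, p$fraction, seed),
    Unrelated = select_unrelated(data$A22, p$fraction, seed, params = ga)
  )
}

#' Run a full scenario comparison
#'
#' Solves the reference (`NormalG`) plus the requested scenarios on shared
#' data, correlates each scenario's EBV with the reference over all and
#' over genotyped animals, records PCG iteration counts and the sparsity
#' of the G^-1 - A22^-1 correction, and tests all scenario pairs for
#' different reference correlations with the Hotelling-Williams t test on
#' the genotyped-animal EBV (no multiplicity correction, and n = number of
#' genotyped animals).
#'
#' @param data An `ssgblup_data` from [prep_ssgblup()].
#' @param scenarios Character vector of scenario labels, e.g.
#'   `c("Random10", "Offspring10", "Young10")`; the `NormalG` reference is
#'   always solved.
#' @param seed Master seed; per-scenario seeds for the random selectors
#'   are derived from it so that repeated runs reproduce.
#' @param tol,max_iter Passed to [pcg_solve()].
#' @param ga [ga_params()] for the `Unrelated` scenario.
#' @param scaling_basis Passed to [solve_scenario()].
#' @return Object of class `scenario_report`: `results` tibble (scenario,
#'   cor_all, cor_genotyped, pcg_iterations, sparsity_pct), `pairwise`
#'   tibble of Hotelling-Williams tests, and the genotyped-animal EBV.
#' @export
run_experiment <- function(data, scenarios = c("Random10", "Random30", "Random50",
                                               "Offspring10", "OffspringRandom10",
                                               "Old10", "Young10", "NormalA"),
                           seed = NULL, tol = 1e-10, max_iter = 5000,
                           ga = ga_params(), scaling_basis = "all") {
  stopifnot(inherits(data, "ssgblup_data"))
  scenarios <- setdiff(scenarios, "NormalG")
  sub_seeds <- if (is.null(seed)) {
    rep(list(NULL), length(scenarios))
  } else {
    as.list(withr::with_seed(seed, sample.int(.Machine$integer.max - 1, length(scenarios))))
  }

  ref <- solve_scenario(data, "NormalG", tol = tol, max_iter = max_iter)
  geno_ids <- data$geno_ids

  rows <- list(tibble::tibble(
    scenario = "NormalG", cor_all = 1, cor_genotyped = 1,
    pcg_iterations = ref$iterations, sparsity_pct = ref$sparsity_pct,
    core_size = ref$core_size, converged = ref$converged
  ))
  ebv_geno <- list(NormalG = ref$ebv[geno_ids])

  for (i in seq_along(scenarios)) {
    sc <- build_scenario(data, scenarios[i], seed = sub_seeds[[i]], ga = ga)
    fit <- solve_scenario(data, sc, tol = tol, max_iter = max_iter,
                          scaling_basis = scaling_basis)
    cmp <- compare_to_reference(fit, ref, geno_ids)
    rows[[i + 1]] <- tibble::tibble(
      scenario = fit$scenario, cor_all = cmp$cor_all,
      cor_genotyped = cmp$cor_genotyped, pcg_iterations = fit$iterations,
      sparsity_pct = fit$sparsity_pct, core_size = fit$core_size,
      converged = fit$converged
    )
    ebv_geno[[fit$scenario]] <- fit$ebv[geno_ids]
  }
  results <- dplyr::bind_rows(rows)

  pairwise <- pairwise_williams(results, ebv_geno)
  structure(list(results = results, pairwise = pairwise,
                 ebv_genotyped = ebv_geno, n_genotyped = length(geno_ids),
                 seed = seed),
            class = "scenario_report")
}

pairwise_williams <- function(results, ebv_geno) {
  labs <- setdiff(results$scenario, "NormalG")
  if (length(labs) < 2) {
    return(tibble::tibble(scenario_a = character(0), scenario_b = character(0),
                          t_statistic = numeric(0), df = integer(0),
                          p_value = numeric(0)))
  }
  ref <- ebv_geno[["NormalG"]]
  n <- length(ref)
  out <- list()
  k <- 0
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      a <- labs[i]
      b <- labs[j]
      ra <- results$cor_genotyped[results$scenario == a]
      rb <- results$cor_genotyped[results$scenario == b]
      rab <- pearson(ebv_geno[[a]], ebv_geno[[b]])
      hw <- tryCatch(hotelling_williams(ra, rb, rab, n),
                     error = function(e) tibble::tibble(
                       t_statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
      k <- k + 1
      out[[k]] <- dplyr::bind_cols(tibble::tibble(scenario_a = a, scenario_b = b), hw)
    }
  }
  dplyr::bind_rows(out)
}

#' @exportS3Method base::print
print.scenario_report <- function(x, ...) {
  cat("<scenario_report> ", nrow(x$results), " scenarios, ",
      x$n_genotyped, " genotyped animals\n", sep = "")
  print(x$results)
  invisible(x)
}
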