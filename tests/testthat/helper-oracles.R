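# Independent oracles and fixture builders shared across tests.

# Two founders and two full-sib offspring.
ped4 <- function(geno = c(FALSE, FALSE, TRUE, TRUE)) {
  ped_table(data.frame(
    animal = 1:4, sire = c(NA, NA, 1, 1), dam = c(NA, NA, 2, 2),
    birth_year = c(1, 1, 2, 2), genotyped = geno
  ))
}

# Relationship coefficients by Karigl-style recursive coancestry,
# independent of the package's iterative tabular construction.
# Expects a topologically sorted pedigree; keeps its row order.
kinship_oracle <- function(ped) {
  pos <- ped_positions(ped)
  n <- nrow(ped)
  phi <- matrix(NA_real_, n, n)
  co <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      0.5 * (1 + co(pos$sire[i], pos$dam[i]))
    } else if (j > i) {
      0.5 * (co(i, pos$sire[j]) + co(i, pos$dam[j]))
    } else {
      0.5 * (co(j, pos$sire[i]) + co(j, pos$dam[i]))
    }
    phi[i, j] <<- v
    phi[j, i] <<- v
    v
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * co(i, j)
  A
}

# Random multi-generation pedigree with overlapping parent usage.
random_pedigree <- function(n, n_gen = 4, geno_frac = 0.4, seed = 1) {
  withr::with_seed(seed, {
    per <- ceiling(n / n_gen)
    animal <- as.character(seq_len(per))
    sire <- rep(NA_character_, per)
    dam <- rep(NA_character_, per)
    year <- rep(1L, per)
    for (g in 2:n_gen) {
      prev <- animal[year == g - 1L]
      k <- min(per, n - length(animal))
      if (k <= 0) break
      new <- as.character(length(animal) + seq_len(k))
      half <- length(prev) %/% 2
      males <- prev[seq_len(half)]
      females <- prev[-seq_len(half)]
      sire <- c(sire, sample(males, k, replace = TRUE))
      dam <- c(dam, sample(females, k, replace = TRUE))
      animal <- c(animal, new)
      year <- c(year, rep(g, k))
    }
    geno <- runif(length(animal)) < geno_frac & year >= max(year) - 1L
    ped_table(data.frame(animal = animal, sire = sire, dam = dam,
                         birth_year = year, genotyped = geno))
  })
}

# Textbook Williams t for dependent correlations sharing one variable,
# coded stepwise and independently of the package's vectorized form.
hw_oracle <- function(r12, r13, r23, n) {
  # r12 = cor(a, ref), r13 = cor(b, ref), r23 = cor(a, b)
  detR <- 1 + 2 * r12 * r13 * r23 - r12^2 - r13^2 - r23^2
  rbar <- mean(c(r12, r13))
  num <- (r12 - r13) * sqrt((n - 1) * (1 + r23))
  den <- sqrt(2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3)
  t <- num / den
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 3))
}

# Exhaustive parent-offspring dosage compatibility at one locus.
mendel_compatible <- function(child, s, d) {
  rng <- function(g) {
    if (is.na(g)) return(0:2)
    switch(as.character(g), "0" = 0, "1" = 0:1, "2" = 1)  # gamete alleles
  }
  child %in% outer(rng(s), rng(d), "+")
}

# Small complete genotype fixture.
toy_geno <- function(M, ids = NULL) {
  if (is.null(ids)) ids <- paste0("a", seq_len(nrow(M)))
  rownames(M) <- ids
  if (is.null(colnames(M)) || any(colnames(M) == "")) {
    colnames(M) <- paste0("s", seq_len(ncol(M)))
  }
  geno_matrix(M)
}

small_sim_config <- function(...) {
  args <- list(n_founders = 120, n_generations = 5, n_sires = 12, n_dams = 24,
               litter_size = 5, n_chrom = 3, snps_per_chrom = 80, n_qtl = 40,
               genotyped_years = 2:5, geno_prob = c(0.2, 0.3, 0.4, 0.5))
  dots <- list(...)
  args[names(dots)] <- dots
  if (!is.null(dots$n_generations) && is.null(dots$genotyped_years)) {
    args$genotyped_years <- 2:args$n_generations
    args$geno_prob <- rep(0.4, args$n_generations - 1)
  }
  do.call(sim_config, args)
}
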