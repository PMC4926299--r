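#' Configuration for the breeding-population simulator
#'
#' Defines a discrete-generation, random-mating pig-like population: one
#' birth year per generation, litters of full sibs from dams mated to a
#' smaller pool of sires, founder haplotypes drawn at per-SNP frequencies
#' uniform on `freq_range`, and genotyping restricted to recent birth
#' years with a per-year genotyping probability. The defaults emulate the
#' structure of a routine pig evaluation at desk scale: about 18,000
#' pedigree (and phenotyped) animals over 5 year-classes with roughly
#' 1,500 genotyped animals concentrated in the last four years (a
#' pedigree-to-genotyped ratio near 12), 2,000 SNPs on 5 chromosomes of
#' 1 Morgan, and heritability 0.3.
#'
#' @param n_founders Founder animals (birth year 1).
#' @param n_generations Total generations, one birth year each.
#' @param n_sires,n_dams Parents sampled per generation from the previous
#'   one; each dam produces one litter by a random sire.
#' @param litter_size Offspring per litter.
#' @param n_chrom,snps_per_chrom,chrom_length_morgans Genome layout.
#' @param n_qtl QTL sampled among the simulated loci.
#' @param h2 Heritability in (0, 1].
#' @param sigma2_a Additive genetic variance of the trait.
#' @param mu Trait mean.
#' @param genotyped_years Birth years eligible for genotyping.
#' @param geno_prob Per-year genotyping probability (recycled along
#'   `genotyped_years`).
#' @param freq_range Range of founder allele frequencies.
#' @param n_batches Number of fixed-effect batches (1 = mean-only model).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 3600, n_generations = 5, n_sires = 120,
                       n_dams = 300, litter_size = 12, n_chrom = 5,
                       snps_per_chrom = 400, chrom_length_morgans = 1,
                       n_qtl = 200, h2 = 0.3, sigma2_a = 0.3, mu = 0,
                       genotyped_years = 2:5,
                       geno_prob = c(0.04, 0.07, 0.12, 0.18),
                       freq_range = c(0.05, 0.95), n_batches = 1) {
  if (h2 <= 0 || h2 > 1) abort("h2 must lie in (0, 1]")
  m <- n_chrom * snps_per_chrom
  if (n_qtl > m) abort("n_qtl cannot exceed the total number of SNPs")
  if (n_generations < 1) abort("need at least one generation")
  if (n_generations > 1) {
    if (n_sires + n_dams > n_founders) {
      abort("mating design infeasible: founders cannot supply the parent pools")
    }
    gen_size <- n_dams * litter_size
    if (n_sires + n_dams > gen_size && n_generations > 2) {
      abort("mating design infeasible: generations cannot supply the parent pools")
    }
  }
  if (any(genotyped_years > n_generations)) abort("genotyped_years beyond last generation")
  structure(list(
    n_founders = n_founders, n_generations = n_generations,
    n_sires = n_sires, n_dams = n_dams, litter_size = litter_size,
    n_chrom = n_chrom, snps_per_chrom = snps_per_chrom,
    chrom_length_morgans = chrom_length_morgans, n_qtl = n_qtl, h2 = h2,
    sigma2_a = sigma2_a, mu = mu, genotyped_years = as.integer(genotyped_years),
    geno_prob = rep_len(geno_prob, length(genotyped_years)),
    freq_range = freq_range, n_batches = as.integer(n_batches)
  ), class = "sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations with random mating and no selection: each
#' generation's dams and sires are drawn at random from the previous
#' generation, each dam has one litter by one random sire. Genotyping
#' flags are drawn per birth year with the configured probabilities.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A sorted `ped_tbl`; animal sex is attached as attribute `sex`
#'   (used only by the simulator itself).
#' @export
simulate_pedigree <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_optional_seed(seed, {
    id <- function(k) sprintf("A%06d", k)
    n0 <- config$n_founders
    animal <- id(seq_len(n0))
    sire <- rep(NA_character_, n0)
    dam <- rep(NA_character_, n0)
    year <- rep(1L, n0)
    sex <- sample(rep_len(c("M", "F"), n0))
    next_id <- n0 + 1L
    prev <- seq_len(n0)

    if (config$n_generations > 1) {
      for (g in 2:config$n_generations) {
        prev_ids <- animal[prev]
        prev_sex <- sex[prev]
        males <- prev_ids[prev_sex == "M"]
        females <- prev_ids[prev_sex == "F"]
        if (length(males) < config$n_sires || length(females) < config$n_dams) {
          abort("mating design infeasible: not enough candidate sires or dams")
        }
        sires_g <- sample(males, config$n_sires)
        dams_g <- sample(females, config$n_dams)
        litter_sire <- sample(sires_g, config$n_dams, replace = TRUE)
        n_new <- config$n_dams * config$litter_size
        new_ids <- id(seq(next_id, length.out = n_new))
        animal <- c(animal, new_ids)
        sire <- c(sire, rep(litter_sire, each = config$litter_size))
        dam <- c(dam, rep(dams_g, each = config$litter_size))
        year <- c(year, rep(as.integer(g), n_new))
        sex <- c(sex, sample(rep_len(c("M", "F"), n_new)))
        prev <- seq(next_id, length.out = n_new)
        next_id <- next_id + n_new
      }
    }

    genotyped <- rep(FALSE, length(animal))
    for (i in seq_along(config$genotyped_years)) {
      yy <- config$genotyped_years[i]
      in_year <- which(year == yy)
      genotyped[in_year] <- runif(length(in_year)) < config$geno_prob[i]
    }
    ped <- ped_table(tibble::tibble(animal = animal, sire = sire, dam = dam,
                                    birth_year = year, genotyped = genotyped))
    attr(ped, "sex") <- setNames(sex, animal)
    ped
  })
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotype alleles are drawn at per-SNP frequencies uniform on
#' the configured range; each offspring gamete is formed per chromosome
#' with a Poisson number of crossovers (expectation = chromosome length in
#' Morgans) at uniform positions. Dosage is the sum of the two inherited
#' alleles, so parent-offspring genotypes are Mendelian-consistent at
#' every locus by construction.
#'
#' @param ped A sorted `ped_tbl`.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @param haplotypes Also return the two haplotype matrices (`h1`, `h2`);
#'   off by default to keep memory down.
#' @return List with `genotypes` (a `geno_matrix` for the genotyped
#'   animals), `dosage` (full animals x SNPs dosage matrix), and
#'   `founder_freq`.
#' @export
drop_genotypes <- function(ped, config = sim_config(), seed = NULL,
                           haplotypes = FALSE) {
  ped <- require_sorted(ped)
  pos <- ped_positions(ped)
  m <- config$n_chrom * config$snps_per_chrom
  with_optional_seed(seed, {
    p <- runif(m, config$freq_range[1], config$freq_range[2])
    haps <- genedrop_cpp(pos$sire, pos$dam, p, config$n_chrom,
                         config$snps_per_chrom, config$chrom_length_morgans)
    dosage <- haps$h1 + haps$h2
    snp_ids <- paste0("c", rep(seq_len(config$n_chrom), each = config$snps_per_chrom),
                      "_s", rep(seq_len(config$snps_per_chrom), config$n_chrom))
    dimnames(dosage) <- list(ped$animal, snp_ids)
    chrom <- rep(seq_len(config$n_chrom), each = config$snps_per_chrom)
    posn <- rep((seq_len(config$snps_per_chrom) - 0.5) / config$snps_per_chrom *
                  config$chrom_length_morgans, config$n_chrom)
    geno <- geno_matrix(dosage[ped$genotyped, , drop = FALSE],
                        chrom = chrom, pos = posn)
    out <- list(genotypes = geno, dosage = dosage,
                founder_freq = setNames(p, snp_ids))
    if (haplotypes) {
      dimnames(haps$h1) <- dimnames(haps$h2) <- dimnames(dosage)
      out$h1 <- haps$h1
      out$h2 <- haps$h2
    }
    out
  })
}

#' Simulate phenotypes from gene-dropped genotypes
#'
#' QTL are sampled among the simulated loci, additive effects are drawn
#' standard normal and rescaled so that the realized variance of true
#' breeding values equals `sigma2_a`; phenotypes are
#' y = mu (+ batch) + TBV + e with residual variance
#' sigma2_e = sigma2_a (1 - h2) / h2 (zero when h2 = 1). Every pedigree
#' animal is phenotyped.
#'
#' @param ped A sorted `ped_tbl`.
#' @param dosage Full dosage matrix from [drop_genotypes()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return List with `phenotypes` (tibble `animal`, `value`, `batch`) and
#'   `tbv` (tibble `animal`, `tbv`).
#' @export
simulate_phenotypes <- function(ped, dosage, config = sim_config(), seed = NULL) {
  ped <- as_ped(ped)
  if (config$h2 <= 0) abort("h2 must be positive")
  with_optional_seed(seed, {
    qtl <- sample.int(ncol(dosage), config$n_qtl)
    eff <- rnorm(config$n_qtl)
    raw <- as.numeric(dosage[, qtl, drop = FALSE] %*% eff)
    s <- sd(raw)
    if (s == 0) abort("degenerate QTL sample: no genetic variance")
    tbv <- (raw - mean(raw)) / s * sqrt(config$sigma2_a)
    sigma2_e <- config$sigma2_a * (1 - config$h2) / config$h2
    n <- nrow(ped)
    batch <- if (config$n_batches > 1) {
      sample(rep_len(seq_len(config$n_batches), n))
    } else {
      rep(1L, n)
    }
    batch_eff <- if (config$n_batches > 1) rnorm(config$n_batches, 0, sqrt(config$sigma2_a)) else 0
    e <- if (sigma2_e > 0) rnorm(n, 0, sqrt(sigma2_e)) else numeric(n)
    y <- config$mu + batch_eff[batch] + tbv + e
    list(
      phenotypes = tibble::tibble(animal = ped$animal, value = y,
                                  batch = factor(batch)),
      tbv = tibble::tibble(animal = ped$animal, tbv = tbv)
    )
  })
}

#' Simulate a complete study population
#'
#' Chains [simulate_pedigree()], [drop_genotypes()] and
#' [simulate_phenotypes()] under sub-seeds derived from one master seed,
#' so that one integer reproduces the whole dataset bit-identically.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return Object of class `sim_population`: `pedigree`, `genotypes`,
#'   `phenotypes`, `tbv`, `founder_freq`, `config`, `seed`.
#' @export
simulate_population <- function(config = sim_config(), seed = NULL) {
  seeds <- if (is.null(seed)) rep(list(NULL), 3) else {
    as.list(withr::with_seed(seed, sample.int(.Machine$integer.max - 1, 3)))
  }
  ped <- simulate_pedigree(config, seed = seeds[[1]])
  gd <- drop_genotypes(ped, config, seed = seeds[[2]])
  ph <- simulate_phenotypes(ped, gd$dosage, config, seed = seeds[[3]])
  structure(list(pedigree = ped, genotypes = gd$genotypes,
                 phenotypes = ph$phenotypes, tbv = ph$tbv,
                 founder_freq = gd$founder_freq, config = config, seed = seed),
            class = "sim_population")
}

#' @exportS3Method base::print
print.sim_population <- function(x, ...) {
  cat("<sim_population> ", nrow(x$pedigree), " animals, ",
      sum(x$pedigree$genotyped), " genotyped, ",
      ncol(x$genotypes$M), " SNPs, h2 = ", x$config$h2, "\n", sep = "")
  invisible(x)
}
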