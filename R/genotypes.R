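#' Construct a genotype matrix object
#'
#' Holds SNP genotypes coded 0/1/2 (count of the dosage allele) with `NA`
#' for missing calls, plus marker map information.
#'
#' @param M Integer matrix, animals x SNPs, codes in `{0, 1, 2, NA}`.
#' @param animal_ids Animal identifiers (default: rownames of `M`).
#' @param snp_ids SNP identifiers (default: colnames of `M`).
#' @param chrom Optional per-SNP chromosome labels.
#' @param pos Optional per-SNP positions.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(M, animal_ids = rownames(M), snp_ids = colnames(M),
                        chrom = NULL, pos = NULL) {
  M <- as.matrix(M)
  storage.mode(M) <- "integer"
  if (is.null(animal_ids)) abort("animal_ids required (or set rownames on M)")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(M)))
  animal_ids <- as.character(animal_ids)
  snp_ids <- as.character(snp_ids)
  if (length(animal_ids) != nrow(M)) abort("animal_ids length must match rows of M")
  if (length(snp_ids) != ncol(M)) abort("snp_ids length must match columns of M")
  if (anyDuplicated(animal_ids)) abort("animal_ids must be unique")
  bad <- which(!(M %in% c(0L, 1L, 2L, NA_integer_)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(M))
    abort(paste0("invalid genotype code ", M[bad[1]], " for animal ",
                 animal_ids[rc[1]], " at SNP ", snp_ids[rc[2]]))
  }
  dimnames(M) <- list(animal_ids, snp_ids)
  structure(list(M = M, chrom = chrom, pos = pos), class = "geno_matrix")
}

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$M), " animals x ", ncol(x$M), " SNPs, ",
      sum(is.na(x$M)), " missing calls\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$M)

#' Allele frequencies of the dosage allele
#'
#' Per-SNP frequency of the counted allele over non-missing calls:
#' p_j = mean(codes_j) / 2.
#'
#' @param geno A `geno_matrix`.
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
allele_frequencies <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  nobs <- colSums(!is.na(geno$M))
  if (any(nobs == 0)) {
    abort(paste0("SNP ", colnames(geno$M)[which(nobs == 0)[1]],
                 " has no non-missing calls"))
  }
  colMeans(geno$M, na.rm = TRUE) / 2
}

#' Genotype quality control
#'
#' Applies the standard marker and sample filters in a fixed order:
#' SNP call rate, minor allele frequency, Hardy-Weinberg equilibrium
#' (1-df chi-square on genotype counts), then animal call rate. SNPs with
#' call rate below `snp_call_rate`, MAF below `maf`, or HWE p-value below
#' `hwe_p` are removed; animals with call rate at or below
#' `animal_call_rate` are removed.
#'
#' @param geno A `geno_matrix`.
#' @param snp_call_rate SNP call-rate threshold (default 0.90).
#' @param maf Minor-allele-frequency threshold (default 0.01).
#' @param hwe_p Hardy-Weinberg p-value threshold (default 1e-7).
#' @param animal_call_rate Animal call-rate threshold (default 0.90).
#' @return List with the filtered `genotypes` and a `report` tibble giving
#'   the number removed per rule in application order.
#' @export
qc_filter <- function(geno, snp_call_rate = 0.90, maf = 0.01, hwe_p = 1e-7,
                      animal_call_rate = 0.90) {
  stopifnot(inherits(geno, "geno_matrix"))
  thr <- c(snp_call_rate, maf, animal_call_rate)
  if (any(thr < 0 | thr > 1) || hwe_p < 0 || hwe_p > 1) {
    abort("QC thresholds must lie in [0, 1]")
  }
  M <- geno$M
  report <- list()

  cr <- colMeans(!is.na(M))
  keep <- cr >= snp_call_rate
  report$snp_call_rate <- sum(!keep)
  M <- M[, keep, drop = FALSE]

  p <- colMeans(M, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  keep <- pmin(p, 1 - p) >= maf
  report$maf <- sum(!keep)
  M <- M[, keep, drop = FALSE]

  pv <- apply(M, 2, hwe_chisq_p)
  keep <- pv >= hwe_p
  report$hwe <- sum(!keep)
  M <- M[, keep, drop = FALSE]

  if (ncol(M) == 0) abort("all SNPs removed by QC")

  acr <- rowMeans(!is.na(M))
  keep_a <- acr > animal_call_rate
  report$animal_call_rate <- sum(!keep_a)
  M <- M[keep_a, , drop = FALSE]
  if (nrow(M) == 0) abort("all animals removed by QC")

  snp_keep <- match(colnames(M), colnames(geno$M))
  out <- geno_matrix(M, chrom = geno$chrom[snp_keep], pos = geno$pos[snp_keep])
  rep_tbl <- tibble::tibble(
    rule = c("snp_call_rate", "maf", "hwe", "animal_call_rate"),
    threshold = c(snp_call_rate, maf, hwe_p, animal_call_rate),
    n_removed = unlist(report, use.names = FALSE),
    unit = c("snp", "snp", "snp", "animal")
  )
  list(genotypes = out, report = rep_tbl,
       note = "remaining missing calls are mean-imputed (2p) when building G_m")
}

# 1-df chi-square HWE p-value from one SNP's codes
hwe_chisq_p <- function(codes) {
  codes <- codes[!is.na(codes)]
  n <- length(codes)
  if (n == 0) return(0)
  obs <- c(sum(codes == 0L), sum(codes == 1L), sum(codes == 2L))
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  exp <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(exp == 0)) return(1)
  chi2 <- sum((obs - exp)^2 / exp)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Raw genomic relationship matrix
#'
#' VanRaden-style G_m = (M - 2p1')(M - 2p1')' / sum_j 2 p_j (1 - p_j),
#' with genotypes centered at twice the supplied allele frequencies.
#' Missing calls (if any remain after QC) are imputed to the SNP mean 2p_j,
#' which leaves them without contribution to relationships.
#'
#' @param geno A `geno_matrix`.
#' @param p Allele frequencies; default computed from `geno` over all its
#'   animals.
#' @return Dense symmetric positive semidefinite matrix with animal ids as
#'   dimnames.
#' @export
build_Gm <- function(geno, p = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (is.null(p)) p <- allele_frequencies(geno)
  if (length(p) != ncol(geno$M)) abort("p must have one frequency per SNP")
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) abort("all SNPs are monomorphic: scaling denominator is zero")
  Mc <- sweep(geno$M, 2, 2 * p)
  if (anyNA(Mc)) Mc[is.na(Mc)] <- 0  # missing -> mean dosage 2p after centering
  gm <- tcrossprod(Mc) / denom
  (gm + t(gm)) / 2
}

#' Rescale the genomic relationship matrix to the pedigree base
#'
#' Solves the 2x2 system mean(diag(G_m)) beta + alpha = mean(diag(A22)),
#' mean(G_m) beta + alpha = mean(A22) on the chosen basis animals, so that
#' G_a = beta G_m + alpha (alpha added to every element) matches A22 in
#' both mean diagonal and overall mean.
#'
#' @param Gm Raw genomic relationship matrix.
#' @param A22 Pedigree relationship matrix of the same animals, same order.
#' @param basis Indices (or ids, if dimnames are set) of the animals the
#'   means are taken over; `NULL` uses all animals. Restricting the basis
#'   to the core group matches the core-only scaling variant.
#' @return List of class `scaling_params` with elements `beta`, `alpha`,
#'   `basis`.
#' @export
fit_scaling <- function(Gm, A22, basis = NULL) {
  if (!all(dim(Gm) == dim(A22))) abort("Gm and A22 must be conformable")
  b <- resolve_index(basis, Gm, default_all = TRUE)
  gb <- Gm[b, b, drop = FALSE]
  ab <- A22[b, b, drop = FALSE]
  mdg <- mean(diag(gb))
  mg <- mean(gb)
  mda <- mean(diag(ab))
  ma <- mean(ab)
  if (abs(mdg - mg) < 1e-12 * max(1, abs(mdg))) {
    abort("degenerate scaling system: mean(diag(Gm)) equals mean(Gm) on the basis")
  }
  beta <- (mda - ma) / (mdg - mg)
  alpha <- mda - mdg * beta
  structure(list(beta = beta, alpha = alpha,
                 basis = if (is.null(basis)) "all_genotyped" else "subset"),
            class = "scaling_params")
}

#' Apply scaling parameters to a genomic relationship matrix
#'
#' @param Gm Raw genomic relationship matrix.
#' @param scaling A `scaling_params` object from [fit_scaling()].
#' @return G_a = beta * Gm + alpha.
#' @export
rescale_Gm <- function(Gm, scaling) {
  stopifnot(inherits(scaling, "scaling_params"))
  scaling$beta * Gm + scaling$alpha
}

#' Blend genomic and pedigree relationships
#'
#' G = (1 - w_a) G_a + w_a A22, where w_a is the weight on the pedigree
#' (residual polygenic) relationships. The routine-evaluation default is
#' w_a = 0.25; any w_a > 0 also regularizes G towards positive
#' definiteness.
#'
#' @param Ga Rescaled genomic relationship matrix.
#' @param A22 Pedigree relationship block, same animals and order.
#' @param w_a Blending weight in \[0, 1\] (default 0.25).
#' @return Blended symmetric matrix G.
#' @export
blend_G <- function(Ga, A22, w_a = 0.25) {
  if (w_a < 0 || w_a > 1) abort("w_a must lie in [0, 1]")
  if (!all(dim(Ga) == dim(A22))) abort("Ga and A22 must be conformable")
  g <- (1 - w_a) * Ga + w_a * A22
  (g + t(g)) / 2
}

#' Dense inverse of a positive definite matrix
#'
#' Full (Cholesky-based) inversion, as used for the reference single-step
#' run where no sparsity is exploited.
#'
#' @param G Symmetric positive definite matrix.
#' @return Dense inverse.
#' @export
invert_dense <- function(G) {
  ch <- tryCatch(chol(G), error = function(e) {
    abort("matrix is not positive definite; consider a larger blending weight w_a")
  })
  out <- chol2inv(ch)
  dimnames(out) <- dimnames(G)
  out
}

# basis/index helper: accepts positions, ids, or NULL
resolve_index <- function(idx, m, default_all = FALSE) {
  n <- nrow(m)
  if (is.null(idx)) {
    if (default_all) return(seq_len(n))
    abort("index set required")
  }
  if (is.character(idx)) {
    if (is.null(rownames(m))) abort("matrix has no dimnames; use positions")
    pos <- match(idx, rownames(m))
    if (anyNA(pos)) abort(paste0("ids not found: ", paste(head(idx[is.na(pos)], 5), collapse = ", ")))
    return(pos)
  }
  idx <- as.integer(idx)
  if (any(idx < 1 | idx > n)) abort("index out of range")
  idx
}
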