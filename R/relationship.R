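#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A for a pedigree, or
#' for a subset of its animals. For a subset, the matrix is built on the
#' reduced pedigree (subset plus ancestors) and the subset block is
#' returned, so the full-pedigree A is never materialized; coefficients are
#' identical to the corresponding block of the full A.
#'
#' @param ped A `ped_tbl`.
#' @param subset Character vector of animal ids, or `NULL` for all animals.
#' @return Dense symmetric matrix with animal ids as dimnames; for a
#'   subset, rows/columns follow the order of `subset`.
#' @export
build_A <- function(ped, subset = NULL) {
  ped <- as_ped(ped)
  if (!is.null(subset)) {
    subset <- as.character(subset)
    bad <- setdiff(subset, ped$animal)
    if (length(bad) > 0) {
      abort(paste0("subset ids not in pedigree: ", paste(head(bad, 5), collapse = ", ")))
    }
    red <- extract_reduced_pedigree(ped, subset)
  } else {
    red <- ped
  }
  red <- require_sorted(red)
  pos <- ped_positions(red)
  n <- nrow(red)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pos$sire[i]
    d <- pos$dam[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- 0.5 * ((if (s > 0L) A[prev, s] else 0) + (if (d > 0L) A[prev, d] else 0))
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
  }
  dimnames(A) <- list(red$animal, red$animal)
  if (!is.null(subset)) A <- A[subset, subset, drop = FALSE]
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of A^-1 by Henderson's element-wise rules, with the
#' inbreeding adjustment (Meuwissen-Luo F) by default. Each animal
#' contributes 1/d_i to its own diagonal and the usual -1/2 and 1/4
#' multiples to parent entries, where d_i is the Mendelian sampling
#' variance given the parents' inbreeding.
#'
#' @param ped A `ped_tbl`.
#' @param inbreeding Include inbreeding in the Mendelian sampling variances
#'   (default `TRUE`). With `FALSE`, all animals are treated as non-inbred,
#'   so the result inverts A only for inbreeding-free pedigrees.
#' @return Sparse symmetric matrix (`Matrix::dsCMatrix`) in sorted pedigree
#'   order, with animal ids as dimnames.
#' @export
build_A_inverse <- function(ped, inbreeding = TRUE) {
  ped <- require_sorted(ped)
  pos <- ped_positions(ped)
  n <- nrow(ped)
  f <- if (inbreeding) compute_inbreeding(ped)$F else rep(0, n)
  fs <- rep(-1, n)
  fd <- rep(-1, n)
  fs[pos$sire > 0L] <- f[pos$sire[pos$sire > 0L]]
  fd[pos$dam > 0L] <- f[pos$dam[pos$dam > 0L]]
  b <- 1 / (0.5 - 0.25 * (fs + fd))

  ii <- seq_len(n)
  ti <- ii
  tj <- ii
  tx <- b
  for (p in list(pos$sire, pos$dam)) {
    k <- which(p > 0L)
    ti <- c(ti, k, p[k], p[k])
    tj <- c(tj, p[k], k, p[k])
    tx <- c(tx, -b[k] / 2, -b[k] / 2, b[k] / 4)
  }
  both <- which(pos$sire > 0L & pos$dam > 0L)
  ti <- c(ti, pos$sire[both], pos$dam[both])
  tj <- c(tj, pos$dam[both], pos$sire[both])
  tx <- c(tx, b[both] / 4, b[both] / 4)

  m <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n),
                            dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(m)
}

#' Inverse of the genotyped-animal relationship block by absorption
#'
#' Computes A22^-1, the inverse of the pedigree relationship matrix among
#' genotyped animals, without inverting A22 directly: the inverse
#' relationship matrix of the reduced pedigree (genotyped animals plus
#' ancestors) is partitioned into non-genotyped (1) and genotyped (2)
#' blocks, and the non-genotyped ancestors are absorbed,
#' A22^-1 = A^22 - A^21 (A^11)^-1 A^12. Only the usually small A^11 block
#' is factorized.
#'
#' @param ped A `ped_tbl` (the full pedigree; it is reduced internally).
#' @param geno_ids Animal ids of the genotyped block (default: flagged
#'   animals).
#' @param inbreeding Passed to [build_A_inverse()].
#' @return Dense symmetric matrix in the order of `geno_ids`.
#' @export
build_A22_inverse <- function(ped, geno_ids = NULL, inbreeding = TRUE) {
  ped <- as_ped(ped)
  if (is.null(geno_ids)) geno_ids <- ped$animal[ped$genotyped]
  geno_ids <- as.character(geno_ids)
  red <- extract_reduced_pedigree(ped, geno_ids)
  red <- require_sorted(red)
  ainv <- build_A_inverse(red, inbreeding = inbreeding)
  idx2 <- which(red$animal %in% geno_ids)
  idx1 <- setdiff(seq_len(nrow(red)), idx2)
  if (length(idx1) == 0) {
    out <- as.matrix(ainv)
  } else {
    a11 <- Matrix::forceSymmetric(ainv[idx1, idx1, drop = FALSE])
    a12 <- ainv[idx1, idx2, drop = FALSE]
    ch <- tryCatch(Matrix::Cholesky(a11, perm = TRUE),
                   error = function(e) abort("A11 block is singular; invalid pedigree"))
    s <- Matrix::solve(ch, a12, system = "A")
    out <- as.matrix(ainv[idx2, idx2, drop = FALSE] - Matrix::crossprod(a12, s))
  }
  out <- (out + t(out)) / 2
  dimnames(out) <- list(red$animal[idx2], red$animal[idx2])
  out[geno_ids, geno_ids, drop = FALSE]
}

#' Threshold-sparsify a symmetric matrix
#'
#' Sets entries with absolute value at or below `threshold` to zero and
#' stores the result sparsely; surviving entries are unchanged. This is the
#' device used to make A22^-1 sparse (default threshold 1e-4, i.e. entries
#' in \[-0.0001, 0.0001\] are zeroed). The thresholded matrix is symmetric
#' but need not remain positive definite.
#'
#' @param m Dense or sparse symmetric matrix.
#' @param threshold Non-negative drop threshold (default `1e-4`).
#' @return A `Matrix::dsCMatrix` with attributes `zero_threshold` and
#'   `sparsity_pct`.
#' @export
sparsify <- function(m, threshold = 1e-4) {
  if (threshold < 0) abort("threshold must be >= 0")
  sm <- as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  sm@x[abs(sm@x) <= threshold] <- 0
  sm <- Matrix::drop0(sm)
  out <- Matrix::forceSymmetric(sm)
  attr(out, "zero_threshold") <- threshold
  attr(out, "sparsity_pct") <- sparsity(out)
  out
}

#' Percentage of zero elements in a matrix
#'
#' Elements absent from sparse storage (structural zeros) and stored exact
#' zeros both count as zero.
#'
#' @param m Dense matrix or `Matrix` sparse matrix.
#' @return Percentage in \[0, 100\].
#' @export
sparsity <- function(m) {
  total <- prod(dim(m))
  if (is(m, "sparseMatrix")) {
    nz <- sum(get_x_slot(m) != 0)
    if (is(m, "symmetricMatrix")) {
      gm <- as(m, "generalMatrix")
      nz <- sum(get_x_slot(gm) != 0)
    }
  } else {
    nz <- sum(m != 0)
  }
  100 * (total - nz) / total
}

get_x_slot <- function(m) {
  if (.hasSlot(m, "x")) m@x else rep(1, Matrix::nnzero(m))
}
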