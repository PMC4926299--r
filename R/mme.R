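#' Variance components for the single-trait animal model
#'
#' @param sigma2_a Additive genetic variance (> 0).
#' @param sigma2_e Residual variance (> 0).
#' @return List of class `variance_components` with `sigma2_a`, `sigma2_e`
#'   and the variance ratio `lambda = sigma2_e / sigma2_a`.
#' @export
variance_components <- function(sigma2_a, sigma2_e) {
  if (!is.finite(sigma2_a) || sigma2_a <= 0) abort("sigma2_a must be > 0")
  if (!is.finite(sigma2_e) || sigma2_e <= 0) abort("sigma2_e must be > 0")
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 lambda = sigma2_e / sigma2_a),
            class = "variance_components")
}

#' Assemble the single-step inverse relationship matrix H^-1
#'
#' H^-1 = A_full^-1 + blockdiag(0, G^-1 - A22^-1): the inverse pedigree
#' relationship matrix over all animals, corrected on the genotyped block
#' by the difference between the (possibly APY-approximated) inverse
#' genomic relationship matrix and the (possibly threshold-sparsified)
#' inverse pedigree block. The correction is held sparse; it is never
#' densified into the full matrix.
#'
#' @param A_full_inv Sparse symmetric inverse relationship matrix over all
#'   pedigree animals (dimnames = animal ids).
#' @param G_inv Inverse genomic relationship matrix for the genotyped
#'   animals (dense or sparse), or `NULL` together with `A22_inv` for a
#'   pedigree-only model.
#' @param A22_inv Inverse pedigree relationship block for the same animals
#'   in the same order, or `NULL`.
#' @param geno_index Positions of the genotyped animals within the
#'   pedigree ordering (rows of `G_inv` map to these positions), or their
#'   animal ids.
#' @return List of class `h_inverse` with the sparse symmetric `matrix`
#'   and `geno_index`.
#' @export
assemble_H_inverse <- function(A_full_inv, G_inv = NULL, A22_inv = NULL,
                               geno_index = NULL) {
  n <- nrow(A_full_inv)
  if (is.null(G_inv) != is.null(A22_inv)) {
    abort("supply both G_inv and A22_inv, or neither")
  }
  if (is.null(G_inv)) {
    return(structure(list(matrix = Matrix::forceSymmetric(A_full_inv),
                          geno_index = integer(0)),
                     class = "h_inverse"))
  }
  if (is.character(geno_index)) {
    geno_index <- match(geno_index, rownames(A_full_inv))
    if (anyNA(geno_index)) abort("geno_index ids not found in A_full_inv")
  }
  m <- nrow(G_inv)
  if (length(geno_index) != m || nrow(A22_inv) != m) {
    abort("geno_index, G_inv and A22_inv are misaligned")
  }
  if (any(geno_index < 1 | geno_index > n)) abort("geno_index out of range")

  corr <- as(as(Matrix::Matrix(G_inv - A22_inv, sparse = TRUE),
                "generalMatrix"), "TsparseMatrix")
  corr_full <- Matrix::sparseMatrix(
    i = geno_index[corr@i + 1L], j = geno_index[corr@j + 1L], x = corr@x,
    dims = c(n, n)
  )
  h <- Matrix::forceSymmetric(A_full_inv + corr_full)
  structure(list(matrix = h, geno_index = as.integer(geno_index)),
            class = "h_inverse")
}

#' Positive definiteness check
#'
#' Attempts a (sparse) Cholesky factorization; for small dense inputs the
#' smallest eigenvalue is computed as well. Non-positive-definiteness is a
#' reported status, never an error: the threshold-sparsified A22^-1 is
#' routinely indefinite while the assembled H^-1 remains positive
#' definite.
#'
#' @param m Symmetric matrix (dense or sparse).
#' @param eigen_limit Compute the smallest eigenvalue when the dimension is
#'   at most this (default 2000); otherwise it is `NA`.
#' @return List with `positive_definite` flag and `min_eigenvalue`.
#' @export
check_positive_definite <- function(m, eigen_limit = 2000) {
  if (inherits(m, "h_inverse")) m <- m$matrix
  n <- nrow(m)
  min_eig <- NA_real_
  if (n <= eigen_limit) {
    min_eig <- min(eigen(as.matrix(m), symmetric = TRUE, only.values = TRUE)$values)
    pd <- min_eig > 0
  } else {
    sm <- Matrix::forceSymmetric(Matrix::Matrix(m, sparse = TRUE))
    pd <- !inherits(tryCatch(Matrix::Cholesky(sm, perm = TRUE),
                             error = function(e) e), "error")
  }
  list(positive_definite = pd, min_eigenvalue = min_eig)
}

#' Build Henderson's mixed-model equations
#'
#' Single-trait animal model y = X b + Z u + e with var(u) = H sigma2_a and
#' var(e) = I sigma2_e. The coefficient matrix is
#' \[X'X, X'Z; Z'X, Z'Z + H^-1 lambda\] with lambda = sigma2_e / sigma2_a;
#' animals without records enter through H^-1 only.
#'
#' @param phenos Tibble with columns `animal`, `value`, plus any
#'   fixed-effect covariates referenced by `fixed`.
#' @param H_inv An `h_inverse` (or a sparse symmetric matrix with animal
#'   ids as dimnames).
#' @param vc A [variance_components()] object.
#' @param fixed One-sided formula for the fixed effects (default `~ 1`,
#'   an overall mean). A rank-deficient design beyond the usual intercept
#'   confounding drops aliased columns with a warning.
#' @return List of class `mme`: sparse `lhs`, `rhs`, `effect_map`,
#'   `lambda`.
#' @export
build_mme <- function(phenos, H_inv, vc, fixed = ~1) {
  h <- if (inherits(H_inv, "h_inverse")) H_inv$matrix else H_inv
  stopifnot(inherits(vc, "variance_components"))
  if (nrow(phenos) == 0) abort("no phenotype records")
  if (!all(c("animal", "value") %in% names(phenos))) {
    abort("phenotypes need columns `animal` and `value`")
  }
  ids <- rownames(h)
  if (is.null(ids)) abort("H_inv needs animal ids as dimnames")
  ai <- match(as.character(phenos$animal), ids)
  if (anyNA(ai)) {
    abort(paste0("phenotyped animal not in pedigree: ",
                 phenos$animal[which(is.na(ai))[1]]))
  }
  y <- as.numeric(phenos$value)
  nobs <- length(y)
  na <- nrow(h)

  X <- stats::model.matrix(fixed, data = as.data.frame(phenos))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    warn(paste0("fixed-effect design is rank deficient; dropping ",
                ncol(X) - qrx$rank, " aliased column(s)"))
    X <- X[, keep, drop = FALSE]
  }
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  Z <- Matrix::sparseMatrix(i = seq_len(nobs), j = ai, x = 1, dims = c(nobs, na))

  lambda <- vc$lambda
  lhs <- rbind(
    cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
    cbind(Matrix::crossprod(Z, Xs), Matrix::crossprod(Z) + h * lambda)
  )
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)), as.numeric(Matrix::crossprod(Z, y)))
  structure(list(lhs = as(lhs, "CsparseMatrix"), rhs = rhs,
                 effect_map = list(fixed = colnames(X), animal = ids),
                 lambda = lambda, n_fixed = ncol(X)),
            class = "mme")
}

#' Solve mixed-model equations by preconditioned conjugate gradients
#'
#' Jacobi (diagonal) preconditioner; iteration stops when the squared
#' relative residual r'r / b'b drops below `tol`. The iteration count is
#' reported as an indicator of how well-conditioned the equations are.
#'
#' @param mme An `mme` object (or a list with `lhs` and `rhs`).
#' @param tol Convergence tolerance on r'r / b'b (default 1e-10).
#' @param max_iter Iteration cap (default 5000); reaching it returns the
#'   partial solution with `converged = FALSE`.
#' @return Object of class `ssgblup_fit`: `fixed_effects`, `ebv` (named by
#'   animal), `iterations`, `converged`, `residual_history`.
#' @export
pcg_solve <- function(mme, tol = 1e-10, max_iter = 5000) {
  A <- mme$lhs
  b <- mme$rhs
  if (!all(is.finite(b))) abort("right-hand side contains non-finite values")
  d <- Matrix::diag(A)
  d[d == 0] <- 1
  bb <- sum(b * b)
  if (bb == 0) bb <- 1

  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rho <- sum(r * z)
  history <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    Ap <- as.numeric(A %*% p)
    alpha <- rho / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sum(r * r) / bb
    history <- c(history, rel)
    if (rel < tol) {
      converged <- TRUE
      break
    }
    z <- r / d
    rho_new <- sum(r * z)
    p <- z + (rho_new / rho) * p
    rho <- rho_new
  }
  nf <- mme$n_fixed %||% 0L
  fixed <- if (nf > 0) setNames(x[seq_len(nf)], mme$effect_map$fixed) else numeric(0)
  ebv <- setNames(x[(nf + 1):length(x)], mme$effect_map$animal)
  structure(list(fixed_effects = fixed, ebv = ebv, iterations = iters,
                 converged = converged, residual_history = history,
                 tol = tol, lambda = mme$lambda),
            class = "ssgblup_fit")
}

#' @exportS3Method base::print
print.ssgblup_fit <- function(x, ...) {
  cat("<ssgblup_fit> ", length(x$ebv), " animals; PCG ", x$iterations,
      " iterations (", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  if (!is.null(x$scenario)) cat("  scenario: ", x$scenario, "\n", sep = "")
  invisible(x)
}
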