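#' APY sparse inverse of the genomic relationship matrix
#'
#' Approximates G^-1 by the algorithm for proven and young animals:
#' genotyped animals are split into a core group and a non-core group, the
#' core block G_cc is inverted, and each non-core animal enters only
#' through its relationships to the core and a conditional variance
#' D_nn,ii = G_ii - G_ic G_cc^-1 G_ic'. The assembled matrix
#' \deqn{G^{-1} \approx \begin{pmatrix} G_{cc}^{-1} + G_{cc}^{-1} G_{cn}
#'   D_{nn}^{-1} G_{nc} G_{cc}^{-1} & -G_{cc}^{-1} G_{cn} D_{nn}^{-1} \\
#'   -D_{nn}^{-1} G_{nc} G_{cc}^{-1} & D_{nn}^{-1} \end{pmatrix}}{
#'   [Gcc^-1 + Gcc^-1 Gcn Dnn^-1 Gnc Gcc^-1, -Gcc^-1 Gcn Dnn^-1;
#'    -Dnn^-1 Gnc Gcc^-1, Dnn^-1]}
#' is sparse: dense only on the core block and the core/non-core rims,
#' diagonal among non-core animals. Only the core rows of G and the
#' non-core diagonal are read, so the full G never has to be formed.
#'
#' @param G Either a dense symmetric matrix, or a list with functions
#'   `rows(i)` (returning the requested rows of G as a matrix) and
#'   `diag(i)` (returning the requested diagonal entries) for providers
#'   that never materialize G.
#' @param core Core animals: integer positions or character ids.
#' @param n Number of genotyped animals (required when `G` is a provider
#'   list; otherwise taken from `dim(G)`).
#' @param ids Optional animal ids labelling the genotyped animals.
#' @return Object of class `apy_inverse`: list with `core_index`,
#'   `noncore_index` (positions in the original ordering), `Gcc_inv`,
#'   `Gcn`, `Dnn`, and `Kinv`, the assembled sparse symmetric matrix
#'   (`Matrix::dsCMatrix`) in the original animal ordering.
#' @export
apy_inverse <- function(G, core, n = NULL, ids = NULL) {
  if (is.list(G) && !is.matrix(G)) {
    if (is.null(n)) abort("n (number of genotyped animals) required with a row provider")
    rows_fun <- G$rows
    diag_fun <- G$diag
    if (is.null(rows_fun) || is.null(diag_fun)) {
      abort("provider must be a list with functions rows(i) and diag(i)")
    }
  } else {
    G <- as.matrix(G)
    n <- nrow(G)
    if (is.null(ids)) ids <- rownames(G)
    rows_fun <- function(i) G[i, , drop = FALSE]
    diag_fun <- function(i) diag(G)[i]
  }
  if (is.character(core)) {
    if (is.null(ids)) abort("character core requires animal ids")
    core <- match(core, ids)
    if (anyNA(core)) abort("core ids not found among genotyped animals")
  }
  core <- sort(unique(as.integer(core)))
  if (length(core) == 0) abort("core group is empty")
  if (any(core < 1 | core > n)) abort("core index out of range")
  noncore <- setdiff(seq_len(n), core)
  nc <- length(core)
  nn <- length(noncore)

  grows <- rows_fun(core)
  Gcc <- grows[, core, drop = FALSE]
  Gcc <- (Gcc + t(Gcc)) / 2
  ch <- tryCatch(chol(Gcc), error = function(e) {
    abort("core block G_cc is not positive definite")
  })
  Gcc_inv <- chol2inv(ch)

  if (nn == 0) {
    Kinv <- Matrix::forceSymmetric(Matrix::Matrix(Gcc_inv, sparse = TRUE))
    dimnames(Kinv) <- list(ids, ids)
    return(structure(list(core_index = core, noncore_index = integer(0),
                          Gcc_inv = Gcc_inv, Gcn = matrix(0, nc, 0),
                          Dnn = numeric(0), Kinv = Kinv),
                     class = "apy_inverse"))
  }

  Gcn <- grows[, noncore, drop = FALSE]          # core x non-core rim
  Tn <- t(Gcn) %*% Gcc_inv                        # non-core x core
  dnn <- diag_fun(noncore) - rowSums(Tn * t(Gcn))
  if (any(dnn <= 0)) {
    bad <- noncore[which(dnn <= 0)[1]]
    lbl <- if (!is.null(ids)) ids[bad] else bad
    abort(paste0("non-positive APY conditional variance D_nn for animal ", lbl,
                 "; the core group cannot explain this animal"))
  }

  tl <- Gcc_inv + crossprod(Tn / sqrt(dnn))       # core block
  tr <- -t(Tn / dnn)                              # core x non-core

  ti <- c(rep(core, times = nc), rep(core, times = nn),
          rep(noncore, each = nc), noncore)
  tj <- c(rep(core, each = nc), rep(noncore, each = nc),
          rep(core, times = nn), noncore)
  tx <- c(as.vector(tl), as.vector(tr), as.vector(tr), 1 / dnn)
  Kinv <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  Kinv <- Matrix::forceSymmetric(Kinv)
  if (!is.null(ids)) dimnames(Kinv) <- list(ids, ids)

  structure(list(core_index = core, noncore_index = noncore,
                 Gcc_inv = Gcc_inv, Gcn = Gcn, Dnn = dnn, Kinv = Kinv),
            class = "apy_inverse")
}

#' @exportS3Method base::print
print.apy_inverse <- function(x, ...) {
  n <- length(x$core_index) + length(x$noncore_index)
  cat("<apy_inverse> ", n, " genotyped animals, core ", length(x$core_index),
      " (", round(100 * length(x$core_index) / n, 1), "%), sparsity ",
      round(sparsity(x$Kinv), 1), "%\n", sep = "")
  invisible(x)
}
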