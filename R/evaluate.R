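#' Pearson correlation with input validation
#'
#' Product-moment correlation of two equal-length vectors, the accuracy
#' criterion used to compare scenario EBV against the reference solve.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance: correlation undefined")
  cor(x, y)
}

#' Correlate a scenario solution with the reference solution
#'
#' Computes the two accuracy criteria: the Pearson correlation of EBV over
#' all pedigree animals (`cor_all`) and over genotyped animals only
#' (`cor_genotyped`, the main criterion).
#'
#' @param sol,ref `ssgblup_fit` objects on the same animals in the same
#'   order.
#' @param geno_ids Animal ids of the genotyped animals.
#' @return One-row tibble with `cor_all` and `cor_genotyped`.
#' @export
compare_to_reference <- function(sol, ref, geno_ids) {
  if (!identical(names(sol$ebv), names(ref$ebv))) {
    abort("solutions are not aligned on the same animal ordering")
  }
  geno_ids <- as.character(geno_ids)
  if (!all(geno_ids %in% names(sol$ebv))) abort("genotyped ids missing from solution")
  tibble::tibble(
    cor_all = pearson(sol$ebv, ref$ebv),
    cor_genotyped = pearson(sol$ebv[geno_ids], ref$ebv[geno_ids])
  )
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests whether two correlations with a shared variable differ:
#' here, whether two scenarios' EBV correlate differently with the
#' reference EBV, given the correlation between the two scenarios' EBV.
#' The Williams t statistic with n - 3 degrees of freedom is
#' \deqn{t = (r_{a} - r_{b}) \sqrt{\frac{(n-1)(1+r_{ab})}
#'   {2 \frac{n-1}{n-3} |R| + \bar r^2 (1-r_{ab})^3}}}{
#'   t = (r_a - r_b) sqrt(((n-1)(1+r_ab)) /
#'   (2 ((n-1)/(n-3)) detR + rbar^2 (1-r_ab)^3))}
#' with |R| = 1 - r_a^2 - r_b^2 - r_ab^2 + 2 r_a r_b r_ab and
#' rbar = (r_a + r_b)/2; the p-value is two-sided.
#'
#' @param r_a_ref,r_b_ref Correlations of scenarios a and b with the
#'   shared reference, in (-1, 1).
#' @param r_a_b Correlation between the two scenarios, in (-1, 1).
#' @param n Sample size (> 3).
#' @return One-row tibble: `t_statistic`, `df`, `p_value`.
#' @export
hotelling_williams <- function(r_a_ref, r_b_ref, r_a_b, n) {
  if (n <= 3) abort("n must exceed 3")
  rs <- c(r_a_ref, r_b_ref, r_a_b)
  if (any(abs(rs) >= 1)) abort("correlations must lie strictly in (-1, 1)")
  detR <- 1 - r_a_ref^2 - r_b_ref^2 - r_a_b^2 + 2 * r_a_ref * r_b_ref * r_a_b
  if (detR <= 0) {
    abort("inconsistent correlation triple: determinant of the correlation matrix is not positive")
  }
  rbar <- (r_a_ref + r_b_ref) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_a_b)^3
  t <- (r_a_ref - r_b_ref) * sqrt((n - 1) * (1 + r_a_b) / denom)
  df <- n - 3
  tibble::tibble(t_statistic = t, df = as.integer(df),
                 p_value = 2 * pt(-abs(t), df = df))
}
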