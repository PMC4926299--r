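test_that("H-inverse assembly reduces to A-inverse when the correction vanishes", {
  ped <- random_pedigree(80, seed = 2)
  ped <- topo_sort_pedigree(ped)
  ainv <- build_A_inverse(ped)
  ids <- ped$animal[ped$genotyped]
  a22i <- build_A22_inverse(ped, ids)
  h0 <- assemble_H_inverse(ainv, a22i, a22i, match(ids, ped$animal))
  expect_lt(max(abs(h0$matrix - ainv)), 1e-12)
  expect_equal(assemble_H_inverse(ainv)$matrix, Matrix::forceSymmetric(ainv))
})

test_that("H-inverse equals the block formula through quadratic forms", {
  pop <- simulate_population(small_sim_config(), seed = 6)
  vc <- variance_components(0.3, 0.7)
  dat <- prep_ssgblup(pop$pedigree, pop$genotypes, pop$phenotypes, vc)
  ginv <- invert_dense(dat$G)
  h <- assemble_H_inverse(dat$A_full_inv, ginv, dat$A22_inv, dat$geno_index)
  n <- nrow(dat$ped)
  corr <- ginv - dat$A22_inv
  withr::with_seed(9, {
    for (k in 1:100) {
      x <- rnorm(n)
      q_direct <- as.numeric(t(x) %*% (h$matrix %*% x))
      xg <- x[dat$geno_index]
      q_blocks <- as.numeric(t(x) %*% (dat$A_full_inv %*% x)) +
        as.numeric(t(xg) %*% corr %*% xg)
      expect_lt(abs(q_direct - q_blocks), 1e-8 * max(1, abs(q_blocks)))
    }
  })
  expect_error(assemble_H_inverse(dat$A_full_inv, ginv, dat$A22_inv,
                                  seq_len(5)), "misaligned")
})

test_that("positive definiteness is reported, not enforced", {
  expect_true(check_positive_definite(diag(3))$positive_definite)
  res <- check_positive_definite(matrix(c(1, 2, 2, 1), 2))
  expect_false(res$positive_definite)
  expect_equal(res$min_eigenvalue, -1)
})

test_that("the Henderson system matches the hand-assembled 2x2 example", {
  h <- Matrix::forceSymmetric(Matrix::Matrix(matrix(1), sparse = TRUE))
  dimnames(h) <- list("a1", "a1")
  vc <- variance_components(1, 1)  # lambda = 1
  mme <- build_mme(tibble::tibble(animal = "a1", value = 3), structure(
    list(matrix = h, geno_index = integer(0)), class = "h_inverse"), vc)
  expect_equal(as.matrix(mme$lhs), matrix(c(1, 1, 1, 2), 2), ignore_attr = TRUE)
  expect_equal(mme$rhs, c(3, 3))

  expect_error(build_mme(tibble::tibble(animal = character(0), value = numeric(0)),
                         structure(list(matrix = h), class = "h_inverse"), vc),
               "no phenotype")
  expect_error(build_mme(tibble::tibble(animal = "zz", value = 1),
                         structure(list(matrix = h), class = "h_inverse"), vc),
               "not in pedigree")
})

test_that("EBV shrink to zero as the variance ratio grows", {
  pop <- simulate_population(small_sim_config(n_generations = 3), seed = 14)
  ped <- topo_sort_pedigree(pop$pedigree)
  h <- assemble_H_inverse(build_A_inverse(ped))
  fit1 <- pcg_solve(build_mme(pop$phenotypes, h, variance_components(1, 1)))
  fit_inf <- pcg_solve(build_mme(pop$phenotypes, h, variance_components(1, 1e8)))
  expect_lt(max(abs(fit_inf$ebv)), 1e-4 * max(abs(fit1$ebv)))
})

test_that("PCG solves exactly: identity in one iteration, dense oracle otherwise", {
  id_sys <- structure(list(lhs = Matrix::Diagonal(5), rhs = c(5, 4, 3, 2, 1),
                           effect_map = list(fixed = character(0),
                                             animal = paste0("a", 1:5)),
                           lambda = 1, n_fixed = 0L), class = "mme")
  fit <- pcg_solve(id_sys)
  expect_equal(fit$iterations, 1L)
  expect_equal(unname(fit$ebv), c(5, 4, 3, 2, 1))

  withr::with_seed(11, {
    for (n in c(10, 200, 800)) {
      Z <- matrix(rnorm(n * n), n)
      A <- crossprod(Z) / n + diag(n)
      b <- rnorm(n)
      sys <- structure(list(lhs = Matrix::Matrix(A, sparse = TRUE), rhs = b,
                            effect_map = list(fixed = character(0),
                                              animal = as.character(1:n)),
                            lambda = 1, n_fixed = 0L), class = "mme")
      fit <- pcg_solve(sys, tol = 1e-14)
      expect_true(fit$converged)
      direct <- solve(A, b)
      expect_lt(max(abs(fit$ebv - direct)) / max(abs(direct)), 1e-6)
    }
  })
})

test_that("the solution is invariant to animal reordering", {
  pop <- simulate_population(small_sim_config(n_generations = 3), seed = 21)
  ped <- pop$pedigree
  vc <- variance_components(0.3, 0.7)
  h <- assemble_H_inverse(build_A_inverse(ped))
  fit <- pcg_solve(build_mme(pop$phenotypes, h, vc), tol = 1e-14)
  perm <- withr::with_seed(3, sample(nrow(pop$phenotypes)))
  fit_p <- pcg_solve(build_mme(pop$phenotypes[perm, ], h, vc), tol = 1e-14)
  expect_equal(fit$ebv, fit_p$ebv, tolerance = 1e-8)
})

test_that("zero genomic correction makes single-step equal pedigree BLUP", {
  pop <- simulate_population(small_sim_config(), seed = 16)
  vc <- variance_components(0.3, 0.7)
  dat <- prep_ssgblup(pop$pedigree, pop$genotypes, pop$phenotypes, vc, w_a = 1)
  fit_g <- solve_scenario(dat, "NormalG", tol = 1e-14)
  fit_a <- solve_scenario(dat, "NormalA", tol = 1e-14)
  expect_lt(max(abs(fit_g$ebv - fit_a$ebv)) / max(abs(fit_a$ebv)), 1e-6)
})

test_that("APY with the full core and no thresholding equals the reference", {
  pop <- simulate_population(small_sim_config(), seed = 18)
  vc <- variance_components(0.3, 0.7)
  dat <- prep_ssgblup(pop$pedigree, pop$genotypes, pop$phenotypes, vc,
                      threshold = 0)
  full_core <- select_random(dat$ped, 1, seed = 1)
  fit_apy <- solve_scenario(dat, full_core, tol = 1e-14)
  fit_ref <- solve_scenario(dat, "NormalG", tol = 1e-14)
  expect_lt(max(abs(fit_apy$ebv - fit_ref$ebv)) / max(abs(fit_ref$ebv)), 1e-6)
})

test_that("a batch fixed effect is estimated alongside the mean", {
  pop <- simulate_population(small_sim_config(n_batches = 3), seed = 25)
  ped <- topo_sort_pedigree(pop$pedigree)
  h <- assemble_H_inverse(build_A_inverse(ped))
  mme <- build_mme(pop$phenotypes, h, variance_components(0.3, 0.7),
                   fixed = ~batch)
  fit <- pcg_solve(mme)
  expect_length(fit$fixed_effects, 3)
  expect_true(fit$converged)
})
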