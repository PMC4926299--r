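years_ped <- function() {
  # 12 genotyped animals over 3 birth years, founders non-genotyped
  ped_table(data.frame(
    animal = 1:16,
    sire = c(rep(NA, 4), rep(1, 6), rep(3, 6)),
    dam = c(rep(NA, 4), rep(2, 6), rep(4, 6)),
    birth_year = c(rep(1, 4), rep(2, 6), rep(3, 6)),
    genotyped = c(rep(FALSE, 4), rep(TRUE, 12))
  ))
}

test_that("random cores have the right size and reproduce under a seed", {
  ped <- years_ped()
  expect_setequal(select_random(ped, 1)$core_ids, as.character(5:16))
  expect_length(select_random(ped, 0.1, seed = 1)$core_ids, 1)
  a <- select_random(ped, 0.5, seed = 42)
  b <- select_random(ped, 0.5, seed = 42)
  expect_identical(a$core_ids, b$core_ids)
  expect_error(select_random(ped, 0.001), "empty")
  expect_error(select_random(ped, 1.2), "\\(0, 1\\]")

  # different seeds overlap roughly as expected for sampling w/o replacement
  pop <- simulate_population(small_sim_config(), seed = 3)
  n <- sum(pop$pedigree$genotyped)
  f <- 0.5
  ov <- mean(sapply(1:20, function(s) {
    x <- select_random(pop$pedigree, f, seed = s)$core_ids
    y <- select_random(pop$pedigree, f, seed = s + 1000)$core_ids
    length(setdiff(x, y)) + length(setdiff(y, x))
  }))
  expect_lt(abs(ov - 2 * f * (1 - f) * n), 0.15 * n)
})

test_that("every selector partitions the genotyped animals", {
  pop <- simulate_population(small_sim_config(), seed = 8)
  ped <- pop$pedigree
  geno <- ped$animal[ped$genotyped]
  a22 <- build_A(ped, geno)
  sels <- list(
    select_random(ped, 0.2, seed = 1),
    select_oldest(ped, 0.2),
    select_youngest(ped, 0.2),
    select_by_offspring(ped, 0.2),
    select_offspring_random(ped, 0.2, seed = 2),
    select_unrelated(a22, 0.1, seed = 3,
                     params = ga_params(pop_size = 10, max_generations = 10))
  )
  for (s in sels) {
    expect_true(all(s$core_ids %in% geno))
    expect_false(anyDuplicated(s$core_ids) > 0)
  }
  sizes <- sapply(sels, function(s) length(s$core_ids))
  expect_equal(sizes[1:5], rep(round(0.2 * length(geno)), 5))
})

test_that("offspring ranking breaks ties by ascending animal id", {
  ped <- ped_table(data.frame(
    animal = c("a", "b", "c", "d", "k1", "k2", "k3", "k4", "k5", "k6",
               "k7", "k8", "k9", "k10", "k11"),
    sire = c(rep(NA, 4), rep("a", 5), rep("b", 3), rep("c", 3)),
    dam = c(rep(NA, 4), rep("d", 11)),
    birth_year = c(rep(1, 4), rep(2, 11)),
    genotyped = c(TRUE, TRUE, TRUE, TRUE, rep(TRUE, 11))
  ))
  cnt <- count_genotyped_offspring(ped)
  counts <- setNames(cnt$n_genotyped_offspring, cnt$animal)
  expect_equal(unname(counts[c("a", "b", "c", "d")]), c(5, 3, 3, 11))
  # top 2 among {a:5, b:3, c:3}: d first (11), a second; with fraction for k=2
  sel <- select_by_offspring(ped, 2 / 15)
  expect_setequal(sel$core_ids, c("d", "a"))
  # boundary tie between b and c resolved by id: k=3 adds b, not c
  sel3 <- select_by_offspring(ped, 3 / 15)
  expect_setequal(sel3$core_ids, c("d", "a", "b"))

  # all counts zero: pure id tie-break takes the first k ids
  flat <- years_ped()
  flat$genotyped <- c(rep(FALSE, 4), rep(TRUE, 12))
  young_only <- ped_table(as.data.frame(flat)[c(1:4, 11:16), ])
  sel0 <- select_by_offspring(young_only, 0.5)
  ids <- sort(young_only$animal[young_only$genotyped])
  expect_equal(sel0$core_ids, head(ids, 3))
  expect_setequal(select_by_offspring(ped, 1)$core_ids,
                  ped$animal[ped$genotyped])
})

test_that("old and young selectors take opposite ends of the age order", {
  ped <- years_ped()
  old <- select_oldest(ped, 0.5)
  young <- select_youngest(ped, 0.5)
  expect_setequal(old$core_ids, as.character(5:10))   # the 6 year-2 animals
  expect_setequal(young$core_ids, as.character(11:16))
  expect_length(intersect(old$core_ids, young$core_ids), 0)
  expect_setequal(select_oldest(ped, 1)$core_ids, as.character(5:16))
  expect_setequal(select_youngest(ped, 1)$core_ids, as.character(5:16))
})

test_that("the offspring/random hybrid follows its membership rule", {
  pop <- simulate_population(small_sim_config(), seed = 12)
  ped <- pop$pedigree
  f <- 0.1
  sel <- select_offspring_random(ped, f, seed = 4)
  pool <- ped[ped$genotyped, ]
  last <- max(pool$birth_year)
  n_young <- sum(pool$birth_year == last)
  expect_length(sel$core_ids, round(f * nrow(pool)))
  # last-year share is the per-year fraction
  young_in <- sum(pool$animal[pool$birth_year == last] %in% sel$core_ids)
  expect_equal(young_in, round(f * n_young))
  # older members dominate non-members in genotyped-offspring counts
  cnt <- count_genotyped_offspring(ped)
  counts <- setNames(cnt$n_genotyped_offspring, cnt$animal)
  old_ids <- pool$animal[pool$birth_year < last]
  old_in <- intersect(sel$core_ids, old_ids)
  old_out <- setdiff(old_ids, sel$core_ids)
  expect_gte(min(counts[old_in]), max(0, max(counts[old_out]) - 0))
  one_year <- years_ped()
  one_year$genotyped <- one_year$birth_year == 3
  expect_error(select_offspring_random(ped_table(as.data.frame(one_year)), f),
               "two genotyped birth years")
})

test_that("the GA finds the exhaustive minimum-kinship pair on four animals", {
  ped <- ped4(geno = rep(TRUE, 4))
  a22 <- build_A(ped)
  sel <- select_unrelated(a22, 0.5, seed = 1,
                          params = ga_params(pop_size = 10, max_generations = 30))
  expect_setequal(sel$core_ids, c("1", "2"))
  expect_equal(attr(sel, "fitness"), 0)

  expect_setequal(select_unrelated(a22, 1)$core_ids, as.character(1:4))
  expect_error(select_unrelated(a22, 0.5, params = ga_params(pop_size = 1)),
               "pop_size")
})

test_that("the GA approaches the exhaustive optimum and always beats random", {
  ped <- random_pedigree(60, n_gen = 3, geno_frac = 1, seed = 77)
  ids <- withr::with_seed(1, sample(ped$animal, 14))
  a22 <- build_A(ped, ids)
  k <- 4
  combos <- utils::combn(14, k)
  fits <- apply(combos, 2, function(idx) {
    sub <- a22[idx, idx]
    (sum(sub) - sum(diag(sub))) / (k * (k - 1))
  })
  optimum <- min(fits)
  rand_mean <- mean(fits)
  wins <- 0
  for (seed in 1:10) {
    sel <- select_unrelated(a22, k / 14, seed = seed)
    ga_fit <- attr(sel, "fitness")
    rnd <- withr::with_seed(seed, sort(sample(14, k)))
    rnd_fit <- (sum(a22[rnd, rnd]) - sum(diag(a22)[rnd])) / (k * (k - 1))
    expect_lte(ga_fit, rnd_fit + 1e-12)
    if (ga_fit <= optimum + 0.1 * (rand_mean - optimum)) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("core summaries reproduce hand-computed statistics", {
  ped <- ped4(geno = rep(TRUE, 4))
  a22 <- build_A(ped)
  a22i <- sparsify(build_A22_inverse(ped), 0)
  all_core <- select_random(ped, 1, seed = 1)
  s <- summarize_core(all_core, ped, a22, a22i)
  expect_equal(s$n_core, 4)
  expect_true(all(s$per_year[[1]]$fraction_in_core == 1))
  # pairwise A22 off-diagonals: a12 = 0, a13 = a14 = a23 = a24 = a34 = 0.5
  expect_equal(s$mean_relatedness, mean(c(0, 0.5, 0.5, 0.5, 0.5, 0.5)))
  expect_equal(s$mean_abs_col_a22inv, mean(abs(as.matrix(a22i))))

  single <- new_core <- select_random(ped, 0.25, seed = 2)
  s1 <- summarize_core(single, ped, a22, a22i)
  expect_true(s1$singleton_core)
  expect_equal(s1$mean_relatedness, 0)
})

test_that("young cores have no genotyped offspring when offspring are born later", {
  pop <- simulate_population(small_sim_config(), seed = 19)
  ped <- pop$pedigree
  geno <- ped$animal[ped$genotyped]
  a22 <- build_A(ped, geno)
  a22i <- sparsify(build_A22_inverse(ped, geno), 1e-4)
  young <- select_youngest(ped, 0.1)
  s <- summarize_core(young, ped, a22, a22i)
  expect_equal(s$mean_genotyped_offspring, 0)
})
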