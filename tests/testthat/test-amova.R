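test_that("the R_ST quality filter removes nulls, microvariants and CNVs", {
  rows <- list(c("14", "13", "16", "13,17"),
               c("15", "13", "16", "13,17"),
               c("14", "0", "16", "13,17"),     # null at DYS389I
               c("14", "13", "16", "16.2,17"),  # microvariant at DYS385
               c("14", "13", "16", "13,14,17"), # DYS385 copy-number variant
               c("15", "13", "17", "13,18"),
               c("14", "13", "17", "13,18"))
  ds <- toy_dataset(rows, c("A", "A", "A", "A", "B", "B", "B"))
  flt <- filter_for_rst(ds)
  expect_equal(nrow(flt$dataset$samples), 4L)
  expect_equal(flt$log$sample_id, c("S003", "S004", "S005"))
  expect_equal(flt$log$reason, c("null", "intermediate", "cnv"))

  clean <- toy6()
  flt2 <- filter_for_rst(clean)
  expect_identical(flt2$dataset$geno, clean$geno)
  expect_equal(nrow(flt2$log), 0L)

  # a population reduced below 2 samples is an error naming the population
  tiny <- toy_dataset(list(c("14", "13", "16", "13,17"),
                           c("0", "13", "16", "13,17"),
                           c("14", "13", "16", "13,17"),
                           c("15", "13", "16", "13,17")),
                      c("A", "A", "B", "B"))
  expect_error(filter_for_rst(tiny), "A")
})

test_that("the molecular distance sums squared repeat differences", {
  expect_equal(rst_distance(c(DYS19 = "14", DYS385 = "13,17"),
                            c(DYS19 = "14", DYS385 = "13,17")), 0)
  # two loci differing by 1 and 2 repeats
  expect_equal(rst_distance(c(A = "14", B = "10"), c(A = "15", B = "12")), 5)
  # DYS385 sorted positional pairing: (13,17) vs (14,17) -> 1
  expect_equal(rst_distance(c(DYS385 = "13,17"), c(DYS385 = "17,14")), 1)
  expect_error(rst_distance(c(DYS385 = "13,17"), c(DYS385 = "13,14,17")),
               "arity mismatch")
  expect_error(rst_distance(c(A = "0"), c(A = "14")), "null")
})

test_that("identical population multisets give non-positive R_ST", {
  x <- repeat_matrix(toy6())
  expect_lte(pairwise_rst(x[1:3, ], x[1:3, ]), 1e-12)
})

test_that("internally fixed, different populations give R_ST of 1", {
  a <- matrix(12, 4, 6)
  b <- matrix(14, 5, 6)
  expect_equal(pairwise_rst(a, b), 1)
})

test_that("zero total variance returns 0 with a warning flag", {
  a <- matrix(13, 3, 4)
  expect_warning(r <- pairwise_rst(a, a), "zero total")
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "zero_variance"))
})

test_that("R_ST equals the explicit pairwise-distance enumeration oracle", {
  set.seed(11)
  for (rep in 1:50) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    L <- sample(2:6, 1)
    a <- matrix(sample(10:16, na * L, TRUE), na, L)
    b <- matrix(sample(10:16, nb * L, TRUE), nb, L)
    if (col_ss_zero(a, b)) next
    expect_lt(abs(as.numeric(pairwise_rst(a, b)) - brute_rst(a, b)), 1e-12)
  }
})

test_that("R_ST is symmetric and invariant to sample and locus order", {
  set.seed(5)
  a <- matrix(sample(10:15, 24, TRUE), 4, 6)
  b <- matrix(sample(10:15, 30, TRUE), 5, 6)
  expect_equal(pairwise_rst(a, b), pairwise_rst(b, a), tolerance = 1e-14)
  expect_equal(pairwise_rst(a[sample(4), ], b[sample(5), ]),
               pairwise_rst(a, b), tolerance = 1e-14)
  perm <- sample(6)
  expect_equal(pairwise_rst(a[, perm], b[, perm]), pairwise_rst(a, b),
               tolerance = 1e-14)
})

test_that("random splits of one population give mean R_ST near zero", {
  ds <- simulate_populations(sim_config(n_pops = 1, pop_sizes = 40,
                                        within_generations = 60, mu = 0.005,
                                        seed = 21))
  x <- repeat_matrix(ds)
  set.seed(33)
  vals <- vapply(1:100, function(r) {
    idx <- sample(40, 20)
    as.numeric(pairwise_rst(x[idx, ], x[-idx, ]))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("permutation P-values hit the estimator floor under full separation", {
  # with unequal group sizes and complete separation, only the exact
  # original split reproduces the observed R_ST, so p sits at the
  # (k + 1)/(N + 1) floor unless a permutation redraws that split
  set.seed(123)
  a <- matrix(10, 6, 4) + matrix(rbinom(24, 1, 0.3), 6, 4)
  b <- matrix(20, 14, 4) + matrix(rbinom(56, 1, 0.3), 14, 4)
  res <- permutation_p(a, b, n_permutations = 999, seed = 4)
  expect_equal(res$p, 1 / 1000)
  expect_error(permutation_p(a, b, n_permutations = 50), ">= 99")
})

test_that("permutation P-values are reproducible and exchange-consistent", {
  set.seed(9)
  x <- matrix(sample(10:14, 80, TRUE), 20, 4)
  a <- x[1:10, ]; b <- x[11:20, ]
  r1 <- permutation_p(a, b, 199, seed = 7)
  r2 <- permutation_p(a, b, 199, seed = 7)
  expect_identical(r1, r2)
  # same haplotype multiset in both groups: no evidence of differentiation
  ident <- repeat_matrix(toy6())[c(1:3, 1:3), ]
  expect_gt(permutation_p(ident[1:3, ], ident[4:6, ], 199, seed = 2)$p, 0.5)
})

test_that("the R_ST matrix covers all pairs with Bonferroni threshold", {
  ds <- simulate_populations(sim_config(n_pops = 4, pop_sizes = rep(10, 4),
                                        seed = 17))
  res <- rst_matrix(ds, n_permutations = 99, seed = 2)
  expect_equal(res$m, choose(4, 2))
  expect_equal(res$bonferroni_threshold, 0.05 / 6)
  expect_true(isSymmetric(res$rst))
  expect_equal(unname(diag(res$rst)), rep(0, 4))
  expect_true(isSymmetric(res$pvals))
  expect_true(all(res$pvals[upper.tri(res$pvals)] > 0 &
                    res$pvals[upper.tri(res$pvals)] <= 1))
  # report layout: R_ST below the diagonal, P above
  rep_m <- rst_report_matrix(res)
  expect_equal(rep_m[2, 1], res$rst[2, 1])
  expect_equal(rep_m[1, 2], res$pvals[1, 2])
  # divisor override
  res55 <- rst_matrix(ds, n_permutations = 99, seed = 2, bonferroni_m = 55)
  expect_equal(res55$bonferroni_threshold, 0.05 / 55)
})

test_that("excluding a locus removes its copies from the distance", {
  ds <- simulate_populations(sim_config(n_pops = 2, pop_sizes = c(8, 8),
                                        seed = 13))
  res_all <- rst_matrix(ds, n_permutations = 99, seed = 1)
  res_no385 <- rst_matrix(ds, n_permutations = 99, seed = 1,
                          exclude_loci = "DYS385")
  # both are valid analyses; the excluded run must not error and generally
  # differs from the full-panel run
  expect_true(is.finite(res_no385$rst[1, 2]))
  x <- repeat_matrix(ds)
  keep <- !grepl("^DYS385", colnames(x))
  grp <- ds$samples$population
  expect_equal(res_no385$rst[1, 2],
               as.numeric(pairwise_rst(x[grp == "P01", keep],
                                       x[grp == "P02", keep])))
})
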