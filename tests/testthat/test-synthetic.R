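test_that("zero mutation rate reproduces the founder in every sample", {
  cfg <- sim_config(n_pops = 2, pop_sizes = c(10, 10), generations = 50,
                    within_generations = 50, mu = 0, seed = 3)
  ds <- simulate_populations(cfg)
  expect_equal(haplotype_counts(ds)$k_distinct, 1L)
  for (l in y23_panel()$name)
    expect_equal(unname(gene_diversity(
      allele_frequencies(ds, l), n = 20)), 0)
})

test_that("fixed founder divergence with mu = 0 gives R_ST of exactly 1", {
  n_copies <- sum(y23_panel()$copy_number)
  founders <- rbind(rep(12L, n_copies), rep(12L, n_copies))
  founders[2, 1] <- 15L  # one locus differs by 3 repeats
  cfg <- sim_config(n_pops = 2, pop_sizes = c(8, 8), generations = 0,
                    within_generations = 0, mu = 0,
                    founder_haplotypes = founders, seed = 1)
  ds <- simulate_populations(cfg)
  x <- repeat_matrix(ds)
  grp <- ds$samples$population
  expect_identical(pairwise_rst(x[grp == "P01", ], x[grp == "P02", ]), 1)
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- sim_config(n_pops = 3, pop_sizes = c(12, 12, 12), seed = 99,
                    artifact_rates = c(null = 0.01, intermediate = 0.01,
                                       cnv = 0.05))
  d1 <- simulate_populations(cfg)
  d2 <- simulate_populations(cfg)
  expect_identical(d1$geno, d2$geno)
  expect_identical(attr(d1, "artifact_log"), attr(d2, "artifact_log"))
})

test_that("artifact injection is inert at rate zero and saturates at one", {
  ds <- simulate_populations(sim_config(n_pops = 1, pop_sizes = 15, seed = 5))
  none <- inject_artifacts(ds, c(null = 0, intermediate = 0, cnv = 0))
  expect_identical(none$dataset$geno, ds$geno)
  expect_equal(nrow(none$log), 0L)

  all_null <- inject_artifacts(ds, c(null = 1), seed = 2)
  expect_true(all(cell_values_null(all_null$dataset)))
})

test_that("injected artifact counts follow the binomial rate over seeds", {
  ds <- simulate_populations(sim_config(n_pops = 1, pop_sizes = 40, seed = 8))
  cells <- nrow(ds$geno) * ncol(ds$geno)
  rate <- 0.05
  counts <- vapply(1:20, function(s) {
    inj <- inject_artifacts(ds, c(null = rate), seed = s)
    sum(inj$log$type == "null")
  }, numeric(1))
  # 99% binomial bounds for the total over 20 independent seeds
  total <- sum(counts)
  bounds <- qbinom(c(0.005, 0.995), size = 20L * cells, prob = rate)
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])
})

test_that("mean pairwise R_ST is non-decreasing in founder divergence", {
  gens <- c(0, 8, 40)
  means <- vapply(gens, function(g) {
    mean(vapply(1:20, function(r) {
      cfg <- sim_config(n_pops = 2, pop_sizes = c(25, 25), generations = g,
                        within_generations = 40, mu = 0.005,
                        seed = 1000 * g + r)
      ds <- simulate_populations(cfg)
      x <- repeat_matrix(ds)
      grp <- ds$samples$population
      as.numeric(pairwise_rst(x[grp == "P01", ], x[grp == "P02", ]))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("divergence calibrated for R_ST 0.05 is recovered on average", {
  # true between-group variance fraction ~ g_d / (g_d + g_w) = 5/100
  vals <- vapply(1:50, function(r) {
    ds <- simulate_populations(
      sim_config(n_pops = 2, pop_sizes = c(40, 40), generations = 5,
                 within_generations = 95, mu = 0.005, seed = 20000 + r))
    x <- repeat_matrix(ds)
    grp <- ds$samples$population
    as.numeric(pairwise_rst(x[grp == "P01", ], x[grp == "P02", ]))
  }, numeric(1))
  expect_gte(mean(vals), 0.02)
  expect_lte(mean(vals), 0.08)
})

test_that("within-population gene diversity grows with mutation input", {
  # rank correlation between mu * generations and mean per-locus GD
  grid <- expand.grid(mu = c(0.001, 0.01), gen = c(10, 80))
  gd <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(1:20, function(r) {
      cfg <- sim_config(n_pops = 1, pop_sizes = 30, generations = 0,
                        within_generations = grid$gen[i], mu = grid$mu[i],
                        seed = 7000 + 100 * i + r)
      ds <- simulate_populations(cfg)
      mean(vapply(y23_panel()$name, function(l)
        gene_diversity(allele_frequencies(ds, l)), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(grid$mu * grid$gen, gd, method = "spearman"), 0)
})
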