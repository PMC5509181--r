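test_that("negative distances clamp to zero, idempotently", {
  m <- matrix(c(0, -0.0017, 0.01,
                -0.0017, 0, 0.02,
                0.01, 0.02, 0), 3, byrow = TRUE,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  cl <- clamp_distances(m)
  expect_equal(cl["A", "B"], 0)
  expect_equal(attr(cl, "n_clamped"), 1L)
  cl2 <- clamp_distances(cl)
  expect_equal(unclass(cl2), unclass(cl), ignore_attr = TRUE)
  expect_equal(attr(cl2, "n_clamped"), 0L)

  clean <- clamp_distances(abs(m))
  expect_equal(unclass(clean), abs(m), ignore_attr = TRUE)

  asym <- m; asym[1, 2] <- 5
  expect_error(clamp_distances(asym), "symmetric")
})

test_that("the 3-taxon worked example yields branches (1, 1, 2), SBL 4", {
  m <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(m)
  br <- sort(tr$phylo$edge.length)
  expect_equal(br, c(1, 1, 2))
  expect_equal(sum_branch_lengths(tr), 4)
  expect_equal(to_newick(tr), tr$newick)
  expect_setequal(tr$phylo$tip.label, c("A", "B", "C"))
})

test_that("NJ recovers additive matrices: patristic distances equal inputs", {
  set.seed(14)
  for (rep in 1:100) {
    d <- random_additive_matrix(sample(4:8, 1))
    tr <- neighbor_joining(d)
    pat <- patristic_distances(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(pat - d)), 1e-9)
  }
})

test_that("Newick export round-trips topology and branch lengths exactly", {
  set.seed(8)
  d <- random_additive_matrix(6)
  tr <- neighbor_joining(d)
  back <- ape::read.tree(text = to_newick(tr))
  expect_setequal(back$tip.label, rownames(d))
  expect_equal(sort(back$edge.length), sort(tr$phylo$edge.length))
  # labels with spaces are single-quoted in the serialisation and the
  # string still parses to a tree with all six tips
  rownames(d) <- colnames(d) <- paste("pop", seq_len(6))
  tr2 <- neighbor_joining(d)
  expect_true(grepl("'pop 1'", to_newick(tr2), fixed = TRUE))
  back2 <- ape::read.tree(text = to_newick(tr2))
  expect_equal(ape::Ntip(back2), 6L)
})

test_that("SBL is the arithmetic branch sum, invariant to leaf relabeling", {
  set.seed(3)
  d <- random_additive_matrix(7)
  tr <- neighbor_joining(d)
  expect_equal(sum_branch_lengths(tr), sum(tr$phylo$edge.length))
  relab <- d
  rownames(relab) <- colnames(relab) <- rev(rownames(d))
  expect_equal(sum_branch_lengths(neighbor_joining(relab)),
               sum_branch_lengths(tr), tolerance = 1e-12)
})

test_that("near-star matrices resolve with a near-zero internal branch", {
  m <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  tr <- neighbor_joining(m)
  internal <- tr$phylo$edge.length[tr$phylo$edge[, 2] > 4]
  expect_lt(max(abs(internal)), 1e-12)
})

test_that("MEGA-style clamping transfers negative branch lengths", {
  set.seed(44)
  d <- matrix(runif(25, 0, 0.05), 5, 5)
  d <- d + t(d); diag(d) <- 0
  dimnames(d) <- list(letters[1:5], letters[1:5])
  tr <- neighbor_joining(d, clamp_negative = TRUE)
  expect_true(all(tr$phylo$edge.length >= 0))
})

test_that("nested divergent populations increase the tree's branch sum", {
  # adding deeply diverged populations to a matrix should grow total SBL
  base <- simulate_populations(sim_config(n_pops = 6, pop_sizes = rep(12, 6),
                                          generations = 10,
                                          within_generations = 40,
                                          mu = 0.005, seed = 31))
  far <- simulate_populations(sim_config(n_pops = 3, pop_sizes = rep(12, 3),
                                         generations = 200,
                                         within_generations = 40,
                                         mu = 0.005, seed = 32))
  far$samples$population <- sub("P", "Q", far$samples$population)
  merged <- ystr_dataset(
    c(base$samples$sample_id, paste0("x", far$samples$sample_id)),
    c(base$samples$population, far$samples$population),
    rbind(base$geno, far$geno), base$loci, dys389_adjusted = TRUE)
  r_small <- rst_matrix(base, n_permutations = 99, seed = 1)
  r_big <- rst_matrix(merged, n_permutations = 99, seed = 1)
  sbl_small <- sum_branch_lengths(neighbor_joining(clamp_distances(r_small$rst)))
  sbl_big <- sum_branch_lengths(neighbor_joining(clamp_distances(r_big$rst)))
  expect_gt(sbl_big, sbl_small)
})
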