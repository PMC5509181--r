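# Shared fixtures and independent oracles for the test suite.

# small 4-marker panel (5 chromosomal loci) for fast unit tests
mini_panel <- function() {
  data.frame(name = c("DYS19", "DYS389I", "DYS389II", "DYS385"),
             copy_number = c(1L, 1L, 1L, 2L),
             dys389_adjust = c(FALSE, FALSE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}

# build a dataset from a character genotype matrix given as rows
toy_dataset <- function(rows, pops, panel = mini_panel(), ids = NULL,
                        adjusted = TRUE) {
  geno <- do.call(rbind, rows)
  colnames(geno) <- panel$name
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(rows))
  ystr_dataset(ids, pops, geno, panel, dys389_adjusted = adjusted)
}

# a clean 6-sample, 2-population dataset on the mini panel
toy6 <- function() {
  toy_dataset(
    list(c("14", "13", "16", "13,17"),
         c("14", "13", "16", "13,17"),
         c("15", "13", "17", "13,18"),
         c("15", "12", "16", "14,17"),
         c("16", "12", "16", "14,18"),
         c("15", "12", "17", "13,17")),
    pops = c("A", "A", "A", "B", "B", "B"))
}

# write a dataset out as a delimited table and return the path
write_toy_table <- function(lines, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  writeLines(gsub("\t", sep, lines, fixed = TRUE), path)
  path
}

# TRUE per cell when every token of the cell is the null marker
cell_values_null <- function(ds) {
  vapply(ds$geno, function(cell)
    all(strsplit(cell, ",", fixed = TRUE)[[1]] == "0"), logical(1))
}

subset_toy <- function(ds, idx) {
  ystr_dataset(ds$samples$sample_id[idx], ds$samples$population[idx],
               ds$geno[idx, , drop = FALSE], ds$loci,
               dys389_adjusted = ds$dys389_adjusted)
}

# --- independent oracles -----------------------------------------------------

# R_ST by explicit enumeration of all pairwise squared distances
brute_rst <- function(pop_a, pop_b) {
  x <- rbind(pop_a, pop_b)
  sizes <- c(nrow(pop_a), nrow(pop_b))
  grp <- rep(1:2, sizes)
  N <- nrow(x)
  d2 <- function(i, j) sum((x[i, ] - x[j, ])^2)
  ssd_tot <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) ssd_tot <- ssd_tot + d2(i, j)
  ssd_tot <- ssd_tot / N
  ssd_w <- 0
  for (g in 1:2) {
    idx <- which(grp == g)
    s <- 0
    for (a in seq_along(idx)[-length(idx)])
      for (b in (a + 1):length(idx)) s <- s + d2(idx[a], idx[b])
    ssd_w <- ssd_w + s / sizes[g]
  }
  msa <- (ssd_tot - ssd_w) / 1
  msw <- ssd_w / (N - 2)
  nc <- (N - sum(sizes^2) / N) / 1
  sigma_a <- (msa - msw) / nc
  sigma_a / (sigma_a + msw)
}

# ordered matching pairs (including self pairs) divided by n^2
brute_mp <- function(dataset) {
  key <- apply(dataset$geno, 1L, paste, collapse = "|")
  n <- length(key)
  matches <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if (key[i] == key[j]) matches <- matches + 1L
  matches / n^2
}

# degenerate draw guard: pooled sample has no molecular variance at all
col_ss_zero <- function(a, b) {
  x <- rbind(a, b)
  all(apply(x, 2, function(v) length(unique(v)) == 1))
}

# additive distance matrix from a random ape tree, with its tip labels
random_additive_matrix <- function(n_tips) {
  tr <- ape::rtree(n_tips, br = function(k) stats::runif(k, 0.1, 2))
  as.matrix(stats::cophenetic(tr))
}
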