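## LD loci: the panel's single-copy loci plus the copies of multi-copy loci
## as separate categorical markers (DYS385a = lower sorted copy, DYS385b =
## upper). The combined sorted pair is also addressable as one state under
## the parent name.
#' @keywords internal
ld_locus_names <- function(panel, dys385 = c("split", "combined")) {
  dys385 <- match.arg(dys385)
  unlist(lapply(seq_len(nrow(panel)), function(i) {
    k <- panel$copy_number[i]
    if (k == 1L || dys385 == "combined") panel$name[i]
    else paste0(panel$name[i], letters[seq_len(k)])
  }))
}

#' @keywords internal
ld_states <- function(dataset, locus) {
  panel <- dataset$loci
  if (locus %in% panel$name) return(dataset$geno[, locus])
  parent <- panel$name[vapply(seq_len(nrow(panel)), function(i)
    panel$copy_number[i] > 1L &&
      locus %in% paste0(panel$name[i], letters[seq_len(panel$copy_number[i])]),
    logical(1L))]
  if (!length(parent)) stop(sprintf("locus '%s' not in panel", locus))
  copy <- match(sub(parent, "", locus, fixed = TRUE), letters)
  vapply(dataset$geno[, parent], function(cell) {
    tok <- split_cell(cell)
    tok[min(copy, length(tok))]
  }, character(1L), USE.NAMES = FALSE)
}

#' Two-locus genotype contingency table
#'
#' Counts joint allele-state combinations across samples. States are
#' categorical: canonical allele tokens, with multi-copy loci addressable
#' either combined (`"DYS385"`: the sorted pair is one state) or per sorted
#' copy (`"DYS385a"`, `"DYS385b"`).
#'
#' @param dataset A `ystr_dataset`.
#' @param locus_a,locus_b Locus names.
#' @return A contingency `table` (states of `locus_a` x states of `locus_b`);
#'   marginals equal the single-locus state counts.
#' @export
two_locus_table <- function(dataset, locus_a, locus_b) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  table(a = ld_states(dataset, locus_a), b = ld_states(dataset, locus_b))
}

#' Likelihood-ratio (G) statistic of a contingency table
#'
#' G = 2 * sum over non-empty cells of O * ln(O / E), with expected counts
#' from row/column independence.
#'
#' @param tab A two-way contingency table or count matrix.
#' @return Non-negative G; 0 under exact independence.
#' @export
g_statistic <- function(tab) {
  o <- as.matrix(tab)
  n <- sum(o)
  if (n < 1) stop("empty table")
  e <- outer(rowSums(o), colSums(o)) / n
  pos <- o > 0
  2 * sum(o[pos] * log(o[pos] / e[pos]))
}

#' Permutation G-test of linkage disequilibrium between two loci
#'
#' The null distribution is generated by permuting the second locus' states
#' across samples, which preserves both marginal distributions while
#' breaking the association; p = (k + 1) / (N + 1) with k the number of
#' permutations reaching the observed G.
#'
#' @param dataset A `ystr_dataset`.
#' @param locus_a,locus_b Locus names (see [two_locus_table()]).
#' @param n_permutations Number of permutations (>= 99; default 999).
#' @param seed Integer seed.
#' @return List with `locus_a`, `locus_b`, `G`, `p`, `monomorphic` flag
#'   (either locus with a single state gives G = 0, p = 1 by convention).
#' @export
ld_pair_test <- function(dataset, locus_a, locus_b, n_permutations = 999L,
                         seed = 1L) {
  if (n_permutations < 99L) stop("n_permutations must be >= 99")
  # canonicalise pair order so the permutation scheme (and hence p for a
  # fixed seed) is symmetric in the two loci
  first <- min(locus_a, locus_b)
  second <- max(locus_a, locus_b)
  a <- ld_states(dataset, first)
  b <- ld_states(dataset, second)
  mono <- length(unique(a)) < 2L || length(unique(b)) < 2L
  if (mono)
    return(list(locus_a = locus_a, locus_b = locus_b, G = 0, p = 1,
                monomorphic = TRUE))
  fa <- factor(a); fb <- factor(b)
  ia <- as.integer(fa); ib <- as.integer(fb)
  ka <- nlevels(fa); kb <- nlevels(fb); n <- length(ia)
  # marginals are permutation-invariant, so the expected counts (and their
  # logs) are fixed; only the observed joint counts change per permutation
  loge <- log(outer(tabulate(ia, ka), tabulate(ib, kb)) / n)
  g_of <- function(jb) {
    o <- tabulate(ia + (jb - 1L) * ka, ka * kb)
    pos <- o > 0L
    2 * sum(o[pos] * (log(o[pos]) - loge[pos]))
  }
  g_obs <- g_of(ib)
  g_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i)
      g_of(ib[sample.int(n)]), numeric(1L))
  })
  k <- sum(g_perm >= g_obs - 1e-12)
  list(locus_a = locus_a, locus_b = locus_b, G = g_obs,
       p = (k + 1) / (n_permutations + 1), monomorphic = FALSE)
}

#' Pairwise linkage disequilibrium over the whole panel
#'
#' Runs the permutation G-test for every unordered locus pair. With the
#' default `dys385 = "split"` the two sorted DYS385 copies count as separate
#' markers, giving choose(23, 2) = 253 pairs on the Y23 panel; `"combined"`
#' treats the sorted pair as one marker (231 pairs).
#'
#' @param dataset A `ystr_dataset`.
#' @param n_permutations Permutations per pair (default 999).
#' @param seed Integer master seed (per-pair seeds derived).
#' @param alpha Per-test significance level, uncorrected (default 0.05).
#' @param dys385 `"split"` (default) or `"combined"`.
#' @return Object of class `ld_result`: data.frame `pairs` (locus_a,
#'   locus_b, G, p, significant, monomorphic), `n_pairs`, `n_significant`,
#'   `fraction_significant` and `percent_significant` (1 decimal).
#' @export
ld_matrix <- function(dataset, n_permutations = 999L, seed = 1L,
                      alpha = 0.05, dys385 = c("split", "combined")) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  loci <- ld_locus_names(dataset$loci, match.arg(dys385))
  if (length(loci) < 2L) stop("need >= 2 loci for LD analysis")
  pairs <- utils::combn(loci, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    r <- ld_pair_test(dataset, pairs[1L, k], pairs[2L, k],
                      n_permutations, seed = seed + k)
    data.frame(locus_a = r$locus_a, locus_b = r$locus_b, G = r$G, p = r$p,
               significant = r$p < alpha, monomorphic = r$monomorphic,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(pairs = tab,
                 n_pairs = nrow(tab),
                 n_significant = sum(tab$significant),
                 fraction_significant = mean(tab$significant),
                 percent_significant = round(100 * mean(tab$significant), 1),
                 config = list(n_permutations = n_permutations, seed = seed,
                               alpha = alpha)),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf(
    "<ld_result> %d locus pairs, %d significant at alpha = %g (%.1f%%)\n",
    x$n_pairs, x$n_significant, x$config$alpha, x$percent_significant))
  invisible(x)
}
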