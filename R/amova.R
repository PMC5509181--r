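#' Remove samples unsuitable for R_ST analysis
#'
#' R_ST treats alleles as integer repeat counts, so samples carrying a null
#' allele, an intermediate (microvariant) allele, or a copy-number variant at
#' any locus are removed before analysis. The filter unit is the sample, not
#' the locus.
#'
#' @param dataset A `ystr_dataset` (DYS389-adjusted).
#' @return List with `dataset` (filtered) and `log` (data.frame `sample_id`,
#'   `population`, `reason`; reasons among `"null"`, `"intermediate"`,
#'   `"cnv"`, comma-joined when several apply).
#' @export
filter_for_rst <- function(dataset) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  geno <- dataset$geno
  has_null <- apply(geno, 1L, function(r) any(cell_has_null(r)))
  has_int <- apply(geno, 1L, function(r) any(cell_has_intermediate(r)))
  has_cnv <- dataset$samples$cnv
  drop <- has_null | has_int | has_cnv
  reason <- vapply(which(drop), function(i) {
    paste(c("null", "intermediate", "cnv")[
      c(has_null[i], has_int[i], has_cnv[i])], collapse = ",")
  }, character(1L))
  log <- data.frame(sample_id = dataset$samples$sample_id[drop],
                    population = dataset$samples$population[drop],
                    reason = reason, stringsAsFactors = FALSE)
  out <- if (any(drop)) subset_dataset(dataset, !drop) else dataset
  left <- table(out$samples$population)
  starved <- names(left)[left < 2L]
  lost <- setdiff(unique(dataset$samples$population), names(left))
  if (length(c(starved, lost)))
    stop(sprintf("population reduced below 2 samples by R_ST filter: %s",
                 paste(c(starved, lost), collapse = ", ")))
  list(dataset = out, log = log)
}

#' Squared repeat-count distance between two haplotypes
#'
#' The molecular distance underlying R_ST: the sum over locus copies of
#' squared repeat-count differences. Multi-copy loci contribute one term per
#' copy after ascending sorting of both genotypes (deterministic positional
#' pairing).
#'
#' @param h1,h2 Named character vectors of genotype cells (names = locus
#'   names, multi-copy cells comma-joined), or bare numeric repeat vectors of
#'   equal length.
#' @return Non-negative squared distance; 0 iff identical.
#' @examples
#' rst_distance(c(DYS19 = "14", DYS385 = "13,17"),
#'              c(DYS19 = "15", DYS385 = "14,17"))  # 1 + 1
#' @export
rst_distance <- function(h1, h2) {
  expand <- function(h) {
    if (is.numeric(h)) return(as.numeric(h))
    unlist(lapply(h, function(cell) sort(cell_values(cell), na.last = FALSE)))
  }
  if (!is.numeric(h1) && !is.null(names(h1)) && !is.null(names(h2))) {
    if (!setequal(names(h1), names(h2)))
      stop("haplotypes cover different loci")
    h2 <- h2[names(h1)]
  }
  a <- expand(h1); b <- expand(h2)
  if (length(a) != length(b))
    stop("haplotype arity mismatch (copy-number variant?)")
  if (anyNA(a) || anyNA(b))
    stop("null alleles present; filter haplotypes before computing distances")
  sum((a - b)^2)
}

## per-column ANOVA total sum of squares, summed over columns;
## equals (1/n) * sum over unordered pairs of squared Euclidean distances
#' @keywords internal
col_ss <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(0)
  sum(colSums(x^2) - colSums(x)^2 / n)
}

## one-level AMOVA variance components from within/total sums of squares
#' @keywords internal
amova_components <- function(sst, ssw, group_sizes) {
  G <- length(group_sizes)
  N <- sum(group_sizes)
  msa <- (sst - ssw) / (G - 1)
  msw <- ssw / (N - G)
  nc <- (N - sum(group_sizes^2) / N) / (G - 1)
  sigma_a <- (msa - msw) / nc
  denom <- sigma_a + msw
  rst <- ifelse(denom == 0, 0, sigma_a / denom)
  list(rst = rst, sigma_a = sigma_a, sigma_w = msw,
       zero_variance = sst == 0)
}

#' Pairwise R_ST between two populations
#'
#' One-level AMOVA on squared repeat-count differences: the total and
#' within-group sums of squared distances are converted to among- and
#' within-group variance components via the standard expected mean squares,
#' and R_ST = sigma^2_a / (sigma^2_a + sigma^2_w). Slightly negative values
#' arise by construction and are reported as computed.
#'
#' @param pop_a,pop_b Numeric repeat matrices (samples x locus copies, see
#'   [repeat_matrix()]), each with >= 2 rows, no missing values.
#' @return R_ST estimate (may be negative). If the pooled sample has zero
#'   total variance the estimate is 0 with attribute `zero_variance = TRUE`
#'   and a warning.
#' @export
pairwise_rst <- function(pop_a, pop_b) {
  pop_a <- as.matrix(pop_a); pop_b <- as.matrix(pop_b)
  if (nrow(pop_a) < 2L || nrow(pop_b) < 2L)
    stop("each population needs >= 2 samples")
  if (ncol(pop_a) != ncol(pop_b)) stop("locus-copy columns differ")
  if (anyNA(pop_a) || anyNA(pop_b)) stop("missing repeat values; filter first")
  sst <- col_ss(rbind(pop_a, pop_b))
  ssw <- col_ss(pop_a) + col_ss(pop_b)
  comp <- amova_components(sst, ssw, c(nrow(pop_a), nrow(pop_b)))
  if (comp$zero_variance) {
    warning("zero total molecular variance; R_ST reported as 0")
    return(structure(0, zero_variance = TRUE))
  }
  comp$rst
}

#' Permutation P-value for a pairwise R_ST
#'
#' Sample labels are permuted over the pooled sample preserving group sizes;
#' the P-value is (k + 1) / (N + 1), where k counts permutations with R_ST at
#' least the observed value.
#'
#' @param pop_a,pop_b Numeric repeat matrices as in [pairwise_rst()].
#' @param n_permutations Number of label permutations (>= 99; default 10000).
#' @param seed Integer seed; results are reproducible.
#' @return List with `rst` (observed), `p`, `n_permutations`.
#' @export
permutation_p <- function(pop_a, pop_b, n_permutations = 10000L, seed = 1L) {
  pop_a <- as.matrix(pop_a); pop_b <- as.matrix(pop_b)
  if (n_permutations < 99L) stop("n_permutations must be >= 99")
  na <- nrow(pop_a); nb <- nrow(pop_b); N <- na + nb
  x <- rbind(pop_a, pop_b)
  obs <- pairwise_rst(pop_a, pop_b)
  sst <- col_ss(x)
  t2 <- sum(x^2)
  stot <- colSums(x)
  nc <- (N - (na^2 + nb^2) / N)
  rst_perm <- with_seed(seed, {
    # indicator matrix of permuted group-A memberships: one column per perm
    z <- vapply(seq_len(n_permutations), function(b) {
      zi <- numeric(N); zi[sample.int(N, na)] <- 1; zi
    }, numeric(N))
    sa <- crossprod(x, z)            # locus-copy sums in permuted group A
    sb <- stot - sa
    ssw <- t2 - colSums(sa^2) / na - colSums(sb^2) / nb
    msa <- sst - ssw                 # df_a = 1 for two groups
    msw <- ssw / (N - 2)
    sigma_a <- (msa - msw) / nc
    denom <- sigma_a + msw
    ifelse(denom == 0, 0, sigma_a / denom)
  })
  k <- sum(rst_perm >= as.numeric(obs) - 1e-12)
  list(rst = as.numeric(obs), p = (k + 1) / (n_permutations + 1),
       n_permutations = n_permutations)
}

#' Pairwise R_ST matrix with permutation significance
#'
#' Applies the R_ST quality filter, computes R_ST and a permutation P-value
#' for every unordered pair of populations, and attaches the Bonferroni
#' threshold alpha / m (m = number of pairs by default, overridable).
#'
#' @param dataset A `ystr_dataset` with >= 2 populations.
#' @param n_permutations Permutations per pair (default 10000).
#' @param seed Integer master seed; each pair uses a derived seed so results
#'   do not depend on pair order.
#' @param alpha Family-wise significance level (default 0.05).
#' @param exclude_loci Optional locus names to drop from the molecular
#'   distance (e.g. `"DYS385"` for a DYS385-free run).
#' @param bonferroni_m Override for the Bonferroni divisor m (default
#'   `choose(L, 2)` for L populations).
#' @param filter Apply [filter_for_rst()] first (default `TRUE`).
#' @return Object of class `rst_result`: `labels`, symmetric `rst` and
#'   `pvals` matrices (diagonal 0 resp. NA), `m`, `bonferroni_threshold`,
#'   logical `significant` matrix (p < alpha / m), `filtered_counts` per
#'   population, `filter_log` and the test configuration.
#' @export
rst_matrix <- function(dataset, n_permutations = 10000L, seed = 1L,
                       alpha = 0.05, exclude_loci = NULL,
                       bonferroni_m = NULL, filter = TRUE) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  filter_log <- data.frame(sample_id = character(), population = character(),
                           reason = character(), stringsAsFactors = FALSE)
  if (filter) {
    flt <- filter_for_rst(dataset)
    filter_log <- flt$log
    dataset <- flt$dataset
  }
  labels <- unique(dataset$samples$population)
  L <- length(labels)
  if (L < 2L) stop("need >= 2 populations for an R_ST matrix")
  x <- repeat_matrix(dataset)
  if (!is.null(exclude_loci)) {
    keep <- !(sub("\\.[0-9]+$", "", colnames(x)) %in% exclude_loci)
    x <- x[, keep, drop = FALSE]
  }
  groups <- split(seq_len(nrow(x)), dataset$samples$population)[labels]
  rst <- matrix(0, L, L, dimnames = list(labels, labels))
  pvals <- matrix(NA_real_, L, L, dimnames = list(labels, labels))
  pair_idx <- 0L
  for (i in seq_len(L - 1L)) {
    for (j in seq((i + 1L), L)) {
      pair_idx <- pair_idx + 1L
      res <- tryCatch(
        permutation_p(x[groups[[i]], , drop = FALSE],
                      x[groups[[j]], , drop = FALSE],
                      n_permutations, seed = seed + pair_idx),
        error = function(e) stop(sprintf("pair %s-%s: %s", labels[i],
                                         labels[j], conditionMessage(e)),
                                 call. = FALSE))
      rst[i, j] <- rst[j, i] <- res$rst
      pvals[i, j] <- pvals[j, i] <- res$p
    }
  }
  m <- if (is.null(bonferroni_m)) choose(L, 2L) else bonferroni_m
  threshold <- alpha / m
  structure(list(labels = labels, rst = rst, pvals = pvals,
                 m = m, bonferroni_threshold = threshold,
                 significant = pvals < threshold,
                 filtered_counts = vapply(
                   labels, function(p) sum(filter_log$population == p),
                   integer(1L)),
                 filter_log = filter_log,
                 config = list(n_permutations = n_permutations, seed = seed,
                               alpha = alpha, exclude_loci = exclude_loci)),
            class = "rst_result")
}

#' @export
print.rst_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<rst_result> %d populations, %d pairs, %d permutations/pair\n",
    length(x$labels), x$m, x$config$n_permutations))
  cat(sprintf("  Bonferroni threshold %.4g; %d significant pairs\n",
              x$bonferroni_threshold, sum(x$significant, na.rm = TRUE) / 2))
  m <- round(x$rst, digits)
  m[upper.tri(m)] <- round(x$pvals[upper.tri(x$pvals)], digits)
  cat("  lower triangle: R_ST; upper triangle: permutation P\n")
  print(m)
  invisible(x)
}

#' Lower-R_ST / upper-P combined matrix (report layout)
#'
#' @param x An `rst_result`.
#' @return Numeric matrix with R_ST below the diagonal and permutation
#'   P-values above, zeros on the diagonal.
#' @export
rst_report_matrix <- function(x) {
  stopifnot(inherits(x, "rst_result"))
  m <- x$rst
  m[upper.tri(m)] <- x$pvals[upper.tri(m)]
  m
}
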