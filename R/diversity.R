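#' Allele frequencies at one locus by direct counting
#'
#' For single-copy loci each sample contributes its allele; the duplicated
#' locus DYS385a/b is analysed as a combined genotype, i.e. the ascending-
#' sorted pair counts once per sample as one category. Null alleles form
#' their own category but are excluded from the frequency denominator by
#' default, since a deletion is not a repeat-count allele.
#'
#' @param dataset A `ystr_dataset`.
#' @param locus Locus name from the panel registry.
#' @param include_null Count null alleles as a regular category
#'   (default `FALSE`: samples with a null at the locus are dropped and
#'   reported in the `n_null` field).
#' @return An object of class `ystr_freqtab`: list with `locus`, named
#'   numeric `frequency` (sums to 1), integer `count`, `n` (samples counted)
#'   and `n_null` (samples excluded for a null allele).
#' @export
allele_frequencies <- function(dataset, locus, include_null = FALSE) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  if (!locus %in% dataset$loci$name)
    stop(sprintf("locus '%s' not in panel", locus))
  cells <- dataset$geno[, locus]
  if (!length(cells)) stop("empty dataset")
  has_null <- cell_has_null(cells)
  if (!include_null) cells <- cells[!has_null]
  if (!length(cells))
    stop(sprintf("no non-null genotypes at %s", locus))
  counts <- table(cells)
  # order categories by numeric value of the (first) allele
  first_val <- vapply(names(counts),
                      function(x) {
                        v <- cell_values(x)
                        if (all(is.na(v))) -1 else min(v, na.rm = TRUE)
                      }, numeric(1L))
  counts <- counts[order(first_val, names(counts))]
  structure(list(locus = locus,
                 frequency = stats::setNames(as.numeric(counts) / sum(counts),
                                             names(counts)),
                 count = stats::setNames(as.integer(counts), names(counts)),
                 n = sum(counts),
                 n_null = if (include_null) 0L else sum(has_null)),
            class = "ystr_freqtab")
}

#' @export
print.ystr_freqtab <- function(x, ...) {
  cat(sprintf("<ystr_freqtab> %s: %d categories, n = %d (%d null excluded)\n",
              x$locus, length(x$frequency), x$n, x$n_null))
  print(stats::setNames(round(x$frequency, 4), names(x$count)))
  invisible(x)
}

#' Nei's unbiased gene diversity
#'
#' GD = n/(n-1) * (1 - sum p_i^2), the haploid analogue of expected
#' heterozygosity with small-sample correction.
#'
#' @param freqs A `ystr_freqtab` from [allele_frequencies()], or a bare
#'   numeric frequency vector (then `n` must be given).
#' @param n Sample count (taken from the frequency table when omitted).
#' @return Gene diversity in `[0, n/(n-1)]`; 0 iff monomorphic.
#' @export
gene_diversity <- function(freqs, n = NULL) {
  if (inherits(freqs, "ystr_freqtab")) {
    if (is.null(n)) n <- freqs$n
    p <- freqs$frequency
  } else p <- as.numeric(freqs)
  if (is.null(n) || n < 2) stop("gene diversity undefined for n < 2")
  if (abs(sum(p) - 1) > 1e-9) stop("frequencies must sum to 1")
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Count distinct haplotypes
#'
#' Haplotype identity is the tuple of canonical genotype cells across the
#' panel (DYS385 as sorted pair); null alleles and microvariants are
#' legitimate distinguishing states.
#'
#' @param dataset A `ystr_dataset`.
#' @param loci Optional subset of locus names to define the haplotype over
#'   (default: all panel loci).
#' @return An object of class `haplotype_counts`: list with integer vector
#'   `counts` (named by haplotype string), `n`, `k_distinct`, `k_singleton`.
#' @seealso [as_haplotype_counts()] to build the object from a bare count
#'   vector, e.g. a published haplotype-frequency structure.
#' @export
haplotype_counts <- function(dataset, loci = NULL) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  if (is.null(loci)) loci <- dataset$loci$name
  bad <- setdiff(loci, dataset$loci$name)
  if (length(bad)) stop(sprintf("unknown locus: %s", bad[1L]))
  key <- apply(dataset$geno[, loci, drop = FALSE], 1L, paste, collapse = "|")
  as_haplotype_counts(table(key))
}

#' Build a haplotype-count object from a count vector
#'
#' @param counts Integer vector of per-haplotype occurrence counts
#'   (names optional).
#' @return A `haplotype_counts` object.
#' @examples
#' # the count structure behind DC/MP/HD summary statistics:
#' h <- as_haplotype_counts(c(rep(1L, 908), rep(2L, 4)))
#' discrimination_capacity(h)
#' @export
as_haplotype_counts <- function(counts) {
  counts <- as.integer(counts)
  if (any(counts < 1)) stop("haplotype counts must be positive")
  structure(list(counts = counts,
                 n = sum(counts),
                 k_distinct = length(counts),
                 k_singleton = sum(counts == 1L)),
            class = "haplotype_counts")
}

#' @export
print.haplotype_counts <- function(x, ...) {
  cat(sprintf("<haplotype_counts> n = %d, %d distinct (%d singletons)\n",
              x$n, x$k_distinct, x$k_singleton))
  invisible(x)
}

#' Match probability
#'
#' MP = sum_i (count_i / n)^2: the probability that two samples drawn with
#' replacement share a haplotype.
#'
#' @param counts A `haplotype_counts` object.
#' @return MP in (0, 1]; 1 iff a single haplotype.
#' @export
match_probability <- function(counts) {
  stopifnot(inherits(counts, "haplotype_counts"))
  sum((counts$counts / counts$n)^2)
}

#' Haplotype diversity
#'
#' HD = n/(n-1) * (1 - sum p_i^2): Nei's unbiased diversity applied to whole
#' haplotypes, the complement of the match probability up to the n/(n-1)
#' correction: HD = n/(n-1) * (1 - MP).
#'
#' @param counts A `haplotype_counts` object with `n >= 2`.
#' @return HD in [0, 1] (up to the unbiasedness correction).
#' @export
haplotype_diversity <- function(counts) {
  stopifnot(inherits(counts, "haplotype_counts"))
  n <- counts$n
  if (n < 2) stop("haplotype diversity undefined for n < 2")
  (n / (n - 1)) * (1 - match_probability(counts))
}

#' Discrimination capacity
#'
#' DC = number of distinct haplotypes / sample count.
#'
#' @param counts A `haplotype_counts` object.
#' @return DC in (0, 1].
#' @export
discrimination_capacity <- function(counts) {
  stopifnot(inherits(counts, "haplotype_counts"))
  counts$k_distinct / counts$n
}

#' Full diversity report for a dataset
#'
#' Per-locus Nei gene diversity (DYS385a/b on combined genotypes) plus the
#' forensic haplotype parameters, rounded like forensic reports: GD/DC/MP to
#' 4 decimals, HD to 7.
#'
#' @param dataset A `ystr_dataset`.
#' @return List with `per_locus` (data.frame: locus, n, n_null, k alleles,
#'   GD), `hap` (the `haplotype_counts`), `HD`, `MP`, `DC` (unrounded) and a
#'   `rounded` list mirroring report precision.
#' @export
diversity_report <- function(dataset) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  per_locus <- do.call(rbind, lapply(dataset$loci$name, function(l) {
    f <- allele_frequencies(dataset, l)
    data.frame(locus = l, n = f$n, n_null = f$n_null,
               k = length(f$frequency),
               GD = if (f$n >= 2) gene_diversity(f) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  hap <- haplotype_counts(dataset)
  mp <- match_probability(hap)
  hd <- haplotype_diversity(hap)
  dc <- discrimination_capacity(hap)
  list(per_locus = per_locus, hap = hap, HD = hd, MP = mp, DC = dc,
       rounded = list(GD = round(stats::setNames(per_locus$GD, per_locus$locus), 4),
                      HD = round(hd, 7), MP = round(mp, 4), DC = round(dc, 4)))
}
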