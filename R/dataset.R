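#' Construct a Y-STR population dataset
#'
#' The central container of the package: sample metadata plus a character
#' genotype matrix (one column per registry locus, cells in canonical allele
#' notation, multi-copy genotypes comma-joined and sorted ascending).
#'
#' Most users will not call this directly but obtain datasets from
#' [read_haplotype_table()] or [simulate_populations()].
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param population Character vector of population labels (same length).
#' @param geno Character matrix, `length(sample_id)` rows, one column per
#'   panel locus (column names must match `panel$name`). Cells are allele
#'   tokens; multi-copy cells hold comma- (or dash-) separated tokens.
#' @param panel Locus registry data.frame, see [y23_panel()].
#' @param dys389_adjusted Logical: have DYS389II values already had DYS389I
#'   subtracted? Simulated data is generated on the adjusted scale.
#' @return An object of class `ystr_dataset`: a list with elements `samples`
#'   (data.frame: `sample_id`, `population`, `cnv` flag), `geno` (canonical
#'   character matrix), `loci` (the registry) and `dys389_adjusted`.
#' @export
ystr_dataset <- function(sample_id, population, geno, panel = y23_panel(),
                         dys389_adjusted = FALSE) {
  check_panel(panel)
  sample_id <- as.character(sample_id)
  population <- as.character(population)
  n <- length(sample_id)
  if (n < 1L) stop("dataset needs at least one sample")
  if (length(population) != n)
    stop("sample_id and population lengths differ")
  if (anyDuplicated(sample_id))
    stop(sprintf("duplicate sample ID: '%s'", sample_id[duplicated(sample_id)][1L]))
  if (any(!nzchar(population) | is.na(population)))
    stop("population labels must be non-empty")
  geno <- as.matrix(geno)
  if (nrow(geno) != n) stop("geno row count does not match sample count")
  missing_loci <- setdiff(panel$name, colnames(geno))
  if (length(missing_loci))
    stop(sprintf("missing locus column: %s", paste(missing_loci, collapse = ", ")))
  geno <- geno[, panel$name, drop = FALSE]
  storage.mode(geno) <- "character"
  geno[] <- vapply(geno, normalize_cell, character(1L))
  arity <- vapply(seq_len(ncol(geno)),
                  function(j) cell_arity(geno[, j]), integer(n))
  arity <- matrix(arity, nrow = n)
  expected <- matrix(panel$copy_number, nrow = n, ncol = nrow(panel), byrow = TRUE)
  # single-peak convention at multi-copy loci: one reported allele stands for
  # identical copies, so recycle tokens up to the locus copy number
  short <- which(arity < expected, arr.ind = TRUE)
  if (nrow(short)) {
    for (r in seq_len(nrow(short))) {
      i <- short[r, 1L]; j <- short[r, 2L]
      tok <- split_cell(geno[i, j])
      geno[i, j] <- normalize_cell(
        paste(rep_len(tok, panel$copy_number[j]), collapse = ","))
    }
  }
  cnv <- rowSums(arity > expected) > 0L
  rownames(geno) <- sample_id
  structure(list(
    samples = data.frame(sample_id = sample_id, population = population,
                         cnv = cnv, stringsAsFactors = FALSE),
    geno = geno,
    loci = panel,
    dys389_adjusted = dys389_adjusted
  ), class = "ystr_dataset")
}

#' @export
print.ystr_dataset <- function(x, ...) {
  pops <- table(x$samples$population)
  cat(sprintf("<ystr_dataset> %d samples, %d populations, %d loci (%d markers)\n",
              nrow(x$samples), length(pops), nrow(x$loci), sum(x$loci$copy_number)))
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  cat(sprintf("  DYS389II adjusted: %s; copy-number variants: %d\n",
              x$dys389_adjusted, sum(x$samples$cnv)))
  invisible(x)
}

#' @export
summary.ystr_dataset <- function(object, ...) {
  list(n = nrow(object$samples),
       populations = as.list(table(object$samples$population)),
       n_loci = nrow(object$loci),
       n_markers = sum(object$loci$copy_number),
       dys389_adjusted = object$dys389_adjusted,
       n_cnv = sum(object$samples$cnv),
       n_null = sum(apply(object$geno, 2L, cell_has_null)),
       n_intermediate = sum(apply(object$geno, 2L, cell_has_intermediate)))
}

#' Numeric repeat-count matrix for a dataset
#'
#' Expands the genotype matrix to one numeric column per locus copy
#' (multi-copy loci contribute their ascending-sorted copies as separate
#' columns, e.g. `DYS385.1`, `DYS385.2`). Microvariant steps appear as
#' fractional repeats (16.2); null alleles become `NA`.
#'
#' @param dataset A `ystr_dataset`.
#' @return Numeric matrix, samples x locus copies.
#' @export
repeat_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  cols <- lapply(seq_len(nrow(dataset$loci)), function(i) {
    locus <- dataset$loci$name[i]
    k <- dataset$loci$copy_number[i]
    vals <- lapply(dataset$geno[, locus], cell_values)
    vm <- vapply(vals, function(v) {
      # CNV cells carry extra copies; keep the k lowest (sorted order)
      length(v) <- max(length(v), k)
      v[seq_len(k)]
    }, numeric(k))
    m <- if (k == 1L) matrix(vm, ncol = 1L) else t(vm)
    colnames(m) <- if (k == 1L) locus else paste(locus, seq_len(k), sep = ".")
    m
  })
  m <- do.call(cbind, cols)
  rownames(m) <- dataset$samples$sample_id
  m
}

#' @keywords internal
subset_dataset <- function(dataset, keep) {
  dataset$samples <- dataset$samples[keep, , drop = FALSE]
  dataset$geno <- dataset$geno[keep, , drop = FALSE]
  rownames(dataset$samples) <- NULL
  dataset
}
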