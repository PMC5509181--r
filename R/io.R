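#' Read a delimited Y-STR haplotype table
#'
#' Expects a header row naming the sample-ID column, the population column and
#' one column per panel locus (DYS385a/b as a single `DYS385` column whose
#' cells hold 1--3 comma- or dash-separated alleles). The delimiter (tab or
#' comma) is auto-detected from the header. Allele encodings follow forensic
#' convention: `"0"` is a null allele, `"16.2"` a microvariant.
#'
#' Records with more alleles than the locus copy number are loaded and flagged
#' as copy-number variants rather than rejected: the downstream R_ST quality
#' filter ([filter_for_rst()]) needs to see them.
#'
#' @param path Path to the table.
#' @param panel Locus registry (default [y23_panel()]).
#' @param sample_col,population_col Header names of the ID and population
#'   columns (defaults `"sample_id"`, `"population"`).
#' @param adjust_dys389 Apply the DYS389II minus DYS389I subtraction at load
#'   time (default `TRUE`; the convention under which DYS389II repeat counts
#'   are analysed). Recorded in the dataset so it is never applied twice.
#' @return A [ystr_dataset()].
#' @export
read_haplotype_table <- function(path, panel = y23_panel(),
                                 sample_col = "sample_id",
                                 population_col = "population",
                                 adjust_dys389 = TRUE) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop(sprintf("empty file: %s", path))
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", strip.white = TRUE)
  for (col in c(sample_col, population_col))
    if (!col %in% names(tab))
      stop(sprintf("missing column '%s' in %s", col, path))
  missing_loci <- setdiff(panel$name, names(tab))
  if (length(missing_loci))
    stop(sprintf("missing locus column: %s", paste(missing_loci, collapse = ", ")))
  geno <- as.matrix(tab[, panel$name, drop = FALSE])
  ds <- tryCatch(
    ystr_dataset(tab[[sample_col]], tab[[population_col]], geno, panel),
    error = function(e) stop(sprintf("while reading %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  # NB: the logical argument shadows the binding, but R's call lookup still
  # finds the function adjust_dys389() in the package environment
  if (adjust_dys389) ds <- get("adjust_dys389", mode = "function")(ds)
  ds
}

#' Write a dataset back to a tab-delimited haplotype table
#'
#' Tables on disk follow the forensic reporting convention, in which the
#' DYS389II allele includes the DYS389I repeats; if the dataset carries
#' subtracted DYS389II values they are converted back on the way out, so
#' that [read_haplotype_table()] (which subtracts on load) round-trips.
#'
#' @param dataset A `ystr_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  geno <- dataset$geno
  if (dataset$dys389_adjusted &&
      all(c("DYS389I", "DYS389II") %in% colnames(geno))) {
    v1 <- vapply(geno[, "DYS389I"], function(x) cell_values(x)[1L],
                 numeric(1L), USE.NAMES = FALSE)
    v2 <- vapply(geno[, "DYS389II"], function(x) cell_values(x)[1L],
                 numeric(1L), USE.NAMES = FALSE)
    ok <- !is.na(v1) & !is.na(v2)
    geno[ok, "DYS389II"] <- sub("\\.0$", "",
                                format(v1[ok] + v2[ok], trim = TRUE))
  }
  out <- cbind(dataset$samples[, c("sample_id", "population")],
               as.data.frame(geno, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the DYS389II minus DYS389I adjustment
#'
#' The DYS389II amplicon physically contains the DYS389I repeat stretch, so
#' the reported DYS389II allele includes the DYS389I repeats. For repeat-based
#' statistics the DYS389I count is subtracted from the reported DYS389II
#' value. The operation is idempotent: a dataset already carrying
#' `dys389_adjusted = TRUE` is returned unchanged.
#'
#' Records with a null allele at either DYS389 locus are left unadjusted and
#' flagged in the returned dataset's `dys389_skipped` attribute.
#'
#' @param dataset A `ystr_dataset`.
#' @return The adjusted dataset (`dys389_adjusted = TRUE`).
#' @export
adjust_dys389 <- function(dataset) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  if (dataset$dys389_adjusted) return(dataset)
  loci <- dataset$loci$name
  if (!all(c("DYS389I", "DYS389II") %in% loci)) {
    dataset$dys389_adjusted <- TRUE
    return(dataset)
  }
  v1 <- vapply(dataset$geno[, "DYS389I"], function(x) cell_values(x)[1L],
               numeric(1L), USE.NAMES = FALSE)
  v2 <- vapply(dataset$geno[, "DYS389II"], function(x) cell_values(x)[1L],
               numeric(1L), USE.NAMES = FALSE)
  skipped <- is.na(v1) | is.na(v2)
  adj <- v2 - v1
  if (any(adj[!skipped] < 0))
    stop(sprintf(
      "DYS389II smaller than DYS389I for sample '%s': impossible repeat count",
      dataset$samples$sample_id[!skipped & adj < 0][1L]))
  if (any(adj[!skipped] == 0))
    warning("DYS389II equals DYS389I for some samples; adjusted allele is 0 repeats")
  new_cell <- ifelse(skipped, dataset$geno[, "DYS389II"],
                     sub("\\.0$", "", format(adj, trim = TRUE)))
  dataset$geno[, "DYS389II"] <- vapply(new_cell, normalize_cell, character(1L),
                                       USE.NAMES = FALSE)
  dataset$dys389_adjusted <- TRUE
  attr(dataset, "dys389_skipped") <- dataset$samples$sample_id[skipped]
  dataset
}

#' Write per-locus allele frequency tables
#'
#' Writes a tidy TSV with one row per (locus, allele) pair: columns `locus`,
#' `allele` (combined multi-copy genotypes as `"a-b"` labels), `count`,
#' `frequency`. Refuses to write if any locus' frequencies do not sum to 1.
#'
#' @param freqs A list of frequency tables as returned by
#'   [allele_frequencies()], or a single such table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freqs, path) {
  if (inherits(freqs, "ystr_freqtab")) freqs <- list(freqs)
  rows <- lapply(freqs, function(f) {
    stopifnot(inherits(f, "ystr_freqtab"))
    if (abs(sum(f$frequency) - 1) > 1e-9)
      stop(sprintf("frequencies at %s do not sum to 1; refusing to write",
                   f$locus))
    data.frame(locus = f$locus,
               allele = gsub(",", "-", names(f$frequency), fixed = TRUE),
               count = as.integer(f$count),
               frequency = as.numeric(f$frequency),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a frequency table written by [write_frequency_table()]
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `locus`, `allele`, `count`, `frequency`.
#' @export
read_frequency_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer", "numeric"),
                    check.names = FALSE)
}
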