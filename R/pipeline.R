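#' Run the full haplotype population-structure analysis
#'
#' Orchestrates load/simulate -> DYS389 adjustment -> diversity statistics ->
#' pairwise linkage disequilibrium -> R_ST quality filter -> pairwise R_ST
#' with permutation significance -> neighbor-joining tree -> non-metric MDS,
#' into one reproducible report. All randomness flows from one master seed
#' via fixed per-stage offsets, which are recorded in the provenance block.
#'
#' With fewer than two populations the R_ST, tree and MDS stages are skipped
#' with an explanatory note. When `out_dir` is given, the report artifacts
#' are also written to disk (JSON report, TSV tables, Newick tree).
#'
#' @param input A `ystr_dataset`, a `sim_config` (simulated on the fly), or a
#'   path to a haplotype table readable by [read_haplotype_table()].
#' @param n_permutations Permutations for both the LD and R_ST stages
#'   (default 999).
#' @param seed Master seed (default 1).
#' @param run_ld Toggle the (slow) all-pairs LD stage (default `TRUE`).
#' @param exclude_loci Loci to drop from the R_ST molecular distance.
#' @param bonferroni_m Optional Bonferroni divisor override.
#' @param out_dir Optional output directory for report artifacts.
#' @return List of class `ystr_report`: `summary`, `diversity`, `ld`
#'   (or `NULL`), `rst`, `tree`, `mds`, `skipped` (character notes) and
#'   `provenance` (seeds, stage configuration, filter log).
#' @export
run_full_analysis <- function(input, n_permutations = 999L, seed = 1L,
                              run_ld = TRUE, exclude_loci = NULL,
                              bonferroni_m = NULL, out_dir = NULL) {
  seeds <- list(ld = seed + 101L, rst = seed + 202L, mds = seed + 303L)
  dataset <-
    if (inherits(input, "ystr_dataset")) input
    else if (inherits(input, "sim_config")) simulate_populations(input)
    else read_haplotype_table(input)
  dataset <- adjust_dys389(dataset)
  skipped <- character()

  diversity <- diversity_report(dataset)
  ld <- NULL
  if (run_ld) ld <- ld_matrix(dataset, n_permutations, seed = seeds$ld)
  else skipped <- c(skipped, "ld: disabled by configuration")

  rst <- tree <- mds <- NULL
  n_pops <- length(unique(dataset$samples$population))
  if (n_pops < 2L) {
    skipped <- c(skipped,
                 "rst/tree/mds: fewer than 2 populations in input")
  } else {
    rst <- rst_matrix(dataset, n_permutations, seed = seeds$rst,
                      exclude_loci = exclude_loci,
                      bonferroni_m = bonferroni_m)
    if (length(rst$labels) >= 3L) {
      dclamp <- clamp_distances(rst$rst)
      tree <- neighbor_joining(dclamp)
      mds <- nmds(dclamp, seed = seeds$mds)
    } else {
      skipped <- c(skipped, "tree/mds: fewer than 3 populations")
    }
  }

  report <- structure(list(
    summary = summary(dataset),
    diversity = diversity,
    ld = ld, rst = rst, tree = tree, mds = mds,
    skipped = skipped,
    provenance = list(
      package_version = as.character(utils::packageVersion("ystrkit")),
      master_seed = seed, stage_seeds = seeds,
      n_permutations = n_permutations,
      filter_log = if (!is.null(rst)) rst$filter_log else NULL)
  ), class = "ystr_report")
  if (!is.null(out_dir)) write_report(report, dataset, out_dir)
  report
}

#' @keywords internal
write_report <- function(report, dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  freqs <- lapply(dataset$loci$name,
                  function(l) allele_frequencies(dataset, l))
  write_frequency_table(freqs, p("allele_frequencies.tsv"))
  utils::write.table(report$diversity$per_locus, p("gene_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$ld))
    utils::write.table(report$ld$pairs, p("ld_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$rst)) {
    utils::write.table(round(rst_report_matrix(report$rst), 4),
                       p("rst_matrix.tsv"), sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(report$tree))
    writeLines(to_newick(report$tree), p("tree.nwk"))
  if (!is.null(report$mds))
    utils::write.table(report$mds$coordinates, p("mds_coordinates.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  json <- list(
    summary = report$summary,
    forensic = list(HD = report$diversity$HD, MP = report$diversity$MP,
                    DC = report$diversity$DC,
                    rounded = report$diversity$rounded[c("HD", "MP", "DC")]),
    ld = if (!is.null(report$ld))
      report$ld[c("n_pairs", "n_significant", "percent_significant")],
    rst = if (!is.null(report$rst))
      list(labels = report$rst$labels, m = report$rst$m,
           bonferroni_threshold = report$rst$bonferroni_threshold,
           n_significant = sum(report$rst$significant, na.rm = TRUE) / 2),
    tree = if (!is.null(report$tree)) list(sbl = report$tree$sbl),
    mds = if (!is.null(report$mds))
      list(stress = report$mds$stress,
           stress_initial = report$mds$stress_initial,
           n_iterations = report$mds$n_iterations),
    skipped = report$skipped,
    provenance = report$provenance)
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.ystr_report <- function(x, ...) {
  cat("<ystr_report>\n")
  cat(sprintf("  samples: %d in %d populations\n", x$summary$n,
              length(x$summary$populations)))
  cat(sprintf("  HD = %.7f, MP = %.4f, DC = %.4f\n",
              x$diversity$HD, x$diversity$MP, x$diversity$DC))
  if (!is.null(x$ld))
    cat(sprintf("  LD: %d/%d pairs significant (%.1f%%)\n",
                x$ld$n_significant, x$ld$n_pairs, x$ld$percent_significant))
  if (!is.null(x$rst))
    cat(sprintf("  R_ST: %d pairs, Bonferroni threshold %.4g\n",
                x$rst$m, x$rst$bonferroni_threshold))
  if (!is.null(x$tree))
    cat(sprintf("  NJ tree SBL = %.8f\n", x$tree$sbl))
  if (!is.null(x$mds))
    cat(sprintf("  MDS stress-1 = %.5g\n", x$mds$stress))
  for (s in x$skipped) cat("  skipped ", s, "\n", sep = "")
  invisible(x)
}
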