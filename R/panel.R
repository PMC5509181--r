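#' Locus registry for the PowerPlex Y23 panel
#'
#' Returns the locus registry used throughout the package: one row per
#' amplified marker, with the duplicated locus DYS385a/b held as a single
#' entry of copy number 2. The registry therefore has 22 rows describing the
#' 23 chromosomal Y-STR loci of the panel (21 single-copy loci plus the two
#' DYS385 copies).
#'
#' DYS389II is amplified as a fragment that physically contains the DYS389I
#' repeat stretch; its `dys389_adjust` flag marks it for the conventional
#' subtraction of the DYS389I allele (see [adjust_dys389()]).
#'
#' @return A data.frame with columns `name` (character), `copy_number`
#'   (integer; 2 for DYS385a/b, 1 otherwise) and `dys389_adjust` (logical;
#'   `TRUE` only for DYS389II).
#' @examples
#' p <- y23_panel()
#' nrow(p)                 # 22 registry entries
#' sum(p$copy_number)      # 23 chromosomal loci
#' @export
y23_panel <- function() {
  single <- c("DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
              "DYS393", "DYS437", "DYS438", "DYS439", "DYS448", "DYS456",
              "DYS458", "DYS481", "DYS533", "DYS549", "DYS570", "DYS576",
              "DYS635", "DYS643", "YGATAH4")
  reg <- data.frame(
    name = c(single, "DYS385"),
    copy_number = c(rep(1L, length(single)), 2L),
    dys389_adjust = c(single == "DYS389II", FALSE),
    stringsAsFactors = FALSE
  )
  reg[order(reg$name), , drop = FALSE]
}

#' @keywords internal
check_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("name", "copy_number", "dys389_adjust") %in% names(panel)))
  if (anyDuplicated(panel$name))
    stop("duplicate locus names in panel registry")
  if (any(panel$copy_number < 1))
    stop("locus copy_number must be >= 1")
  invisible(panel)
}
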