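#' Parse a single Y-STR allele designation
#'
#' Y-STR alleles are reported as integer repeat counts, optionally with a
#' partial-repeat "microvariant" step written after a dot (e.g. `"16.2"` for
#' 16 full repeats plus 2 bases). A value of `"0"` denotes a null allele
#' (locus deletion / amplification dropout).
#'
#' @param text A single non-empty allele token, e.g. `"14"`, `"16.2"`, `"0"`.
#' @return An object of class `ystr_allele`: a list with integer `repeats`,
#'   integer `step` (0 for a full repeat, otherwise 1--3) and logical
#'   `is_null`. For a null allele, `repeats` and `step` carry no meaning.
#' @examples
#' parse_allele("16.2")
#' parse_allele("0")$is_null
#' format(parse_allele("10"))
#' @seealso [format.ystr_allele()]
#' @export
parse_allele <- function(text) {
  if (length(text) != 1L || is.na(text))
    stop("parse_allele() expects a single allele token")
  text <- trimws(as.character(text))
  if (!nzchar(text)) stop("empty allele token")
  if (text == "0")
    return(structure(list(repeats = NA_integer_, step = 0L, is_null = TRUE),
                     class = "ystr_allele"))
  if (!grepl("^[0-9]+(\\.[0-9])?$", text))
    stop(sprintf("malformed allele token: '%s'", text))
  parts <- strsplit(text, ".", fixed = TRUE)[[1L]]
  repeats <- as.integer(parts[1L])
  step <- if (length(parts) == 2L) as.integer(parts[2L]) else 0L
  if (step > 3L)
    stop(sprintf("microvariant step outside 1-3 in allele token: '%s'", text))
  structure(list(repeats = repeats, step = step, is_null = FALSE),
            class = "ystr_allele")
}

#' @export
format.ystr_allele <- function(x, ...) {
  if (x$is_null) return("0")
  if (x$step == 0L) as.character(x$repeats) else paste0(x$repeats, ".", x$step)
}

#' @export
print.ystr_allele <- function(x, ...) {
  cat("<ystr_allele>", format(x),
      if (x$is_null) "(null)" else if (x$step != 0L) "(intermediate)" else "",
      "\n")
  invisible(x)
}

## ---- vectorised internals on genotype-cell strings -------------------------
## A "cell" is one sample x locus entry: either a single allele token or, for
## multi-copy loci, several tokens joined by "," (readers also accept "-").

#' @keywords internal
split_cell <- function(cell) strsplit(trimws(cell), "[,-]")[[1L]]

#' @keywords internal
parse_token_values <- function(tokens) {
  tokens <- trimws(tokens)
  bad <- !grepl("^[0-9]+(\\.[0-9])?$", tokens)
  if (any(bad))
    stop(sprintf("malformed allele token: '%s'", tokens[bad][1L]))
  step <- suppressWarnings(as.integer(sub("^[0-9]+\\.?", "", tokens)))
  step[is.na(step)] <- 0L
  if (any(step > 3L & tokens != "0"))
    stop(sprintf("microvariant step outside 1-3 in allele token: '%s'",
                 tokens[step > 3L][1L]))
  v <- as.numeric(tokens)
  v[tokens == "0"] <- NA_real_   # null allele
  v
}

## canonical cell: tokens sorted ascending (nulls first), joined by ","
#' @keywords internal
normalize_cell <- function(cell) {
  tokens <- split_cell(cell)
  if (!length(tokens)) stop("empty genotype cell")
  v <- parse_token_values(tokens)
  tokens <- ifelse(is.na(v), "0", sub("\\.0$", "", format(v, trim = TRUE)))
  paste(tokens[order(ifelse(is.na(v), -Inf, v))], collapse = ",")
}

#' @keywords internal
cell_values <- function(cell) parse_token_values(split_cell(cell))

#' @keywords internal
cell_arity <- function(cell) lengths(strsplit(trimws(cell), "[,-]"))

#' @keywords internal
cell_has_null <- function(cells) {
  vapply(cells, function(x) any(split_cell(x) == "0"), logical(1L),
         USE.NAMES = FALSE)
}

#' @keywords internal
cell_has_intermediate <- function(cells) {
  vapply(cells, function(x) any(grepl("\\.[1-9]$", split_cell(x))),
         logical(1L), USE.NAMES = FALSE)
}
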