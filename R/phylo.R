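#' Clamp negative distances to zero
#'
#' AMOVA-based R_ST matrices routinely contain small negative entries; tree
#' building and ordination require dissimilarities, so negatives are set to 0
#' before those stages. The number of clamped cells is recorded.
#'
#' @param m Symmetric numeric matrix with (near-)zero diagonal.
#' @return The clamped matrix, with attribute `n_clamped`. Idempotent.
#' @export
clamp_distances <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9)
    stop("distance matrix must be symmetric (within 1e-9)")
  if (any(abs(diag(m)) > 1e-9))
    stop("distance matrix diagonal must be zero")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  neg <- m < 0
  m[neg] <- 0
  attr(m, "n_clamped") <- sum(neg) / 2L
  m
}

#' @keywords internal
check_dist_matrix <- function(m, min_labels = 3L) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  if (nrow(m) < min_labels)
    stop(sprintf("need at least %d labels", min_labels))
  if (anyNA(m) || any(!is.finite(m))) stop("non-finite distances")
  m
}

#' @keywords internal
quote_label <- function(x) {
  ifelse(grepl("[][ (),:;']", x),
         paste0("'", gsub("'", "''", x), "'"), x)
}

#' @keywords internal
fmt_len <- function(x) sprintf("%.17g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: repeatedly join the pair minimising the
#' Q-criterion `(m - 2) d_ij - r_i - r_j`, with branch lengths from the
#' standard three-point formulas, until three nodes remain and the tree is
#' closed with a basal trifurcation (unrooted tree). Ties in Q are broken
#' deterministically towards the lowest index pair. Negative branch lengths
#' are kept by default so that patristic distances reproduce additive input
#' matrices exactly; `clamp_negative = TRUE` applies the MEGA-style fix of
#' zeroing a negative branch and transferring its length to the adjacent
#' branch of the joined pair.
#'
#' @param m Symmetric distance matrix (>= 3 labelled rows).
#' @param clamp_negative Zero negative branch lengths, transferring the
#'   deficit to the sister branch (default `FALSE`).
#' @return Object of class `ystr_njtree`: `newick` string (full-precision
#'   branch lengths), `phylo` (the corresponding [ape::read.tree()] object),
#'   `labels`, `sbl` (sum of all branch lengths).
#' @examples
#' m <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' tr <- neighbor_joining(m)
#' sum_branch_lengths(tr)  # 4
#' @export
neighbor_joining <- function(m, clamp_negative = FALSE) {
  d <- check_dist_matrix(m, 3L)
  labels <- rownames(d)
  frags <- quote_label(labels)
  active <- seq_along(labels)
  n <- length(active)
  while (n > 3L) {
    dd <- d
    r <- rowSums(dd)
    # Q over unordered pairs; first lexicographic (i, j) attaining the min
    best <- c(NA_integer_, NA_integer_); best_q <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        q <- (n - 2) * dd[i, j] - r[i] - r[j]
        if (q < best_q - 1e-15) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    bi <- dd[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- dd[i, j] - bi
    if (clamp_negative) {
      if (bi < 0) { bj <- bj + bi; bi <- 0 }
      if (bj < 0) { bi <- bi + bj; bj <- 0 }
    }
    new_frag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt_len(bi),
                        frags[j], fmt_len(bj))
    others <- setdiff(seq_len(n), c(i, j))
    du <- (dd[i, others] + dd[j, others] - dd[i, j]) / 2
    d <- rbind(cbind(dd[others, others, drop = FALSE], du),
               c(du, 0))
    frags <- c(frags[others], new_frag)
    n <- n - 1L
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (clamp_negative) {
    b <- c(b1, b2, b3)
    b[b < 0] <- 0
    b1 <- b[1]; b2 <- b[2]; b3 <- b[3]
  }
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frags[1], fmt_len(b1), frags[2], fmt_len(b2),
                    frags[3], fmt_len(b3))
  phylo <- ape::read.tree(text = newick)
  structure(list(newick = newick, phylo = phylo, labels = labels,
                 sbl = sum(phylo$edge.length)),
            class = "ystr_njtree")
}

#' @export
print.ystr_njtree <- function(x, ...) {
  cat(sprintf("<ystr_njtree> %d tips, sum of branch lengths = %.8f\n",
              length(x$labels), x$sbl))
  invisible(x)
}

#' Sum of branch lengths of a tree
#'
#' @param tree A `ystr_njtree` or an `ape` `phylo` object.
#' @return The arithmetic sum of all branch lengths, internal included.
#' @export
sum_branch_lengths <- function(tree) {
  if (inherits(tree, "ystr_njtree")) tree <- tree$phylo
  stopifnot(inherits(tree, "phylo"))
  sum(tree$edge.length)
}

#' Newick serialisation of a tree
#'
#' Branch lengths are written at full double precision, so parsing the
#' string reproduces topology and lengths exactly.
#'
#' @param tree A `ystr_njtree`.
#' @return A single Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "ystr_njtree"))
  tree$newick
}

#' Patristic (tree-path) distances between tips
#'
#' @param tree A `ystr_njtree` or `phylo`.
#' @return Symmetric matrix of summed branch lengths along tip-to-tip paths.
#' @export
patristic_distances <- function(tree) {
  if (inherits(tree, "ystr_njtree")) tree <- tree$phylo
  stats::cophenetic(tree)
}
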