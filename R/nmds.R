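#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds a dissimilarity matrix in `dims` dimensions by minimising Kruskal's
#' stress-1, `sqrt(sum (d - dhat)^2 / sum d^2)`, where `d` are configuration
#' distances and `dhat` the disparities fitted by monotone (pool-adjacent-
#' violators) regression on the rank order of the input dissimilarities.
#'
#' The configuration is initialised from classical (Torgerson) scaling and
#' improved by Guttman-transform steps with a backtracking line search: a
#' step is only accepted if it lowers stress, halving towards the current
#' configuration otherwise, so the reported stress trace is non-increasing by
#' construction and the final stress can never exceed that of the classical
#' initialiser.
#'
#' @param m Symmetric dissimilarity matrix, zero diagonal, >= 3 labels.
#' @param dims Embedding dimension (default 2; must be < number of labels).
#' @param seed Integer seed (used only to jitter a degenerate initial
#'   configuration; the algorithm is otherwise deterministic).
#' @param max_iter Maximum Guttman iterations (default 500).
#' @param tol Convergence tolerance on the stress decrease (default 1e-6).
#' @return Object of class `nmds_result`: `coordinates` (labels x dims),
#'   `stress` (final stress-1), `stress_initial` (stress of the classical
#'   initialiser), `stress_trace`, `n_iterations`, `converged`, `seed`.
#' @export
nmds <- function(m, dims = 2L, seed = 1L, max_iter = 500L, tol = 1e-6) {
  d <- check_dist_matrix(m, 3L)
  n <- nrow(d)
  if (dims >= n) stop("dims must be smaller than the number of labels")
  if (any(d < 0)) stop("negative dissimilarities; clamp_distances() first")
  delta <- d[lower.tri(d)]
  if (all(delta == 0)) stop("all-zero dissimilarity matrix")
  ord <- order(delta)
  lower_dist <- function(x) {
    dx <- as.matrix(stats::dist(x))
    dx[lower.tri(dx)]
  }
  stress_of <- function(dx) {
    dhat <- numeric(length(dx))
    dhat[ord] <- stats::isoreg(dx[ord])$yf
    sqrt(sum((dx - dhat)^2) / sum(dx^2))
  }
  x <- suppressWarnings(stats::cmdscale(d, k = dims))
  if (ncol(x) < dims)
    x <- cbind(x, matrix(0, n, dims - ncol(x)))
  if (all(lower_dist(x) == 0)) {
    # fully degenerate classical solution: seeded random start
    x <- with_seed(seed, matrix(stats::rnorm(n * dims, sd = stats::sd(delta)),
                                n, dims))
  }
  dx <- lower_dist(x)
  stress <- stress_of(dx)
  trace <- stress
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter && stress > 0) {
    iter <- iter + 1L
    # disparities for the Guttman transform at the current configuration
    dhat <- numeric(length(dx))
    dhat[ord] <- stats::isoreg(dx[ord])$yf
    dm <- matrix(0, n, n); dm[lower.tri(dm)] <- dx; dm <- dm + t(dm)
    hm <- matrix(0, n, n); hm[lower.tri(hm)] <- dhat; hm <- hm + t(hm)
    ratio <- ifelse(dm > 0, hm / dm, 0)
    b <- -ratio
    diag(b) <- rowSums(ratio)
    target <- b %*% x / n
    # backtracking: accept only stress-decreasing steps
    accepted <- FALSE
    cand <- target
    for (h in 1:12) {
      s_cand <- stress_of(lower_dist(cand))
      if (s_cand <= stress) {
        x <- cand; dx <- lower_dist(x)
        accepted <- s_cand < stress - tol
        improvement <- stress - s_cand
        stress <- s_cand
        trace <- c(trace, stress)
        if (improvement < tol) accepted <- FALSE
        break
      }
      cand <- (cand + x) / 2
    }
    if (!accepted) { converged <- TRUE; break }
  }
  if (stress == 0) converged <- TRUE
  coords <- x
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Dim", seq_len(dims))
  structure(list(coordinates = coords, stress = stress,
                 stress_initial = trace[1L], stress_trace = trace,
                 n_iterations = iter, converged = converged,
                 seed = seed, dims = dims),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf(
    "<nmds_result> %d points in %d-D, stress-1 = %.5g after %d iterations%s\n",
    nrow(x$coordinates), x$dims, x$stress, x$n_iterations,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}
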