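#' Configuration for the stepwise-mutation-model population simulator
#'
#' The simulator emulates a set of male-lineage subpopulations genotyped on a
#' Y-STR panel. A single ancestral haplotype is drawn per run (or population
#' founders are supplied explicitly); each population's founder then drifts
#' from the ancestor for `generations` rounds of single-step mutation, and
#' every sampled lineage drifts from its population founder for
#' `within_generations` further rounds. Under this model the expected
#' between-population variance fraction is approximately
#' `generations / (generations + within_generations)`, which is how the
#' defaults are calibrated (5 / 100, i.e. R_ST around 0.05, within the weak
#' differentiation regime typical of regional subpopulations).
#'
#' Default sample sizes mirror a provincial study design: 10 subpopulations
#' totalling 916 males.
#'
#' @param n_pops Number of populations (>= 1).
#' @param pop_sizes Integer vector of population sizes, length `n_pops`
#'   (default: 916 samples split as evenly as possible).
#' @param generations Founder divergence time per population, in mutation
#'   rounds (>= 0).
#' @param within_generations Genealogical depth of sampled lineages below the
#'   population founder, in mutation rounds (>= 0).
#' @param mu Per-locus-copy, per-round mutation probability in [0, 0.1];
#'   scalar or one value per locus copy (recycled).
#' @param founder_haplotypes Optional explicit population founders: a matrix
#'   with `n_pops` rows and one integer repeat count per locus copy (columns
#'   as in [repeat_matrix()]). When supplied, the ancestral drift stage is
#'   skipped; the rows already encode the divergence.
#' @param artifact_rates Named numeric `c(null=, intermediate=, cnv=)`: per-
#'   cell injection rates for the three genotyping artifact classes (defaults
#'   all 0; see [inject_artifacts()]).
#' @param seed Integer RNG seed; the same config is bit-reproducible.
#' @param panel Locus registry (default [y23_panel()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 10L,
                       pop_sizes = NULL,
                       generations = 5L,
                       within_generations = 95L,
                       mu = 0.002,
                       founder_haplotypes = NULL,
                       artifact_rates = c(null = 0, intermediate = 0, cnv = 0),
                       seed = 1L,
                       panel = y23_panel()) {
  check_panel(panel)
  n_pops <- as.integer(n_pops)
  if (is.null(pop_sizes)) {
    # default study scale: 916 males split as evenly as possible
    base <- 916L %/% n_pops
    extra <- 916L %% n_pops
    pop_sizes <- rep(base, n_pops) + c(rep(1L, extra), rep(0L, n_pops - extra))
  }
  pop_sizes <- as.integer(pop_sizes)
  if (n_pops < 1L) stop("n_pops must be >= 1")
  if (length(pop_sizes) != n_pops)
    stop("pop_sizes length must equal n_pops")
  if (any(pop_sizes < 1L)) stop("population sizes must be >= 1")
  if (generations < 0 || within_generations < 0)
    stop("generation counts must be >= 0")
  if (any(mu < 0) || any(mu > 0.1))
    stop("mu must lie in [0, 0.1]")
  ar <- c(null = 0, intermediate = 0, cnv = 0)
  ar[names(artifact_rates)] <- artifact_rates
  if (any(ar < 0 | ar > 1)) stop("artifact rates must lie in [0, 1]")
  n_copies <- sum(panel$copy_number)
  if (!is.null(founder_haplotypes)) {
    founder_haplotypes <- as.matrix(founder_haplotypes)
    if (nrow(founder_haplotypes) != n_pops ||
        ncol(founder_haplotypes) != n_copies)
      stop(sprintf("founder_haplotypes must be %d x %d", n_pops, n_copies))
  }
  structure(list(n_pops = n_pops, pop_sizes = pop_sizes,
                 generations = as.integer(generations),
                 within_generations = as.integer(within_generations),
                 mu = rep_len(mu, n_copies),
                 founder_haplotypes = founder_haplotypes,
                 artifact_rates = ar, seed = as.integer(seed), panel = panel),
            class = "sim_config")
}

## run expr under a seed without disturbing the caller's RNG stream
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## g rounds of strict single-step mutation on an integer repeat matrix;
## each cell mutates with its column's probability mu, +/-1 with equal
## probability, reflecting at 1 repeat (0 -> 2)
#' @keywords internal
smm_drift <- function(x, generations, mu) {
  if (generations == 0L || !length(x)) return(x)
  murow <- matrix(mu, nrow = nrow(x), ncol = ncol(x), byrow = TRUE)
  for (g in seq_len(generations)) {
    hit <- stats::runif(length(x)) < murow
    step <- sample(c(-1L, 1L), length(x), replace = TRUE)
    x <- x + hit * step
    x[x < 1L] <- 2L - x[x < 1L]
  }
  x
}

#' Simulate structured Y-STR populations under the stepwise mutation model
#'
#' See [sim_config()] for the generative model. Output genotypes are on the
#' DYS389II-adjusted scale (`dys389_adjusted = TRUE`); DYS385 copies are
#' reported as the sorted pair. With any artifact rate positive,
#' [inject_artifacts()] is applied after simulation (seed derived from the
#' config seed), so a clean "truth" dataset corresponds to rates 0.
#'
#' @param config A `sim_config`.
#' @return A [ystr_dataset()]. The numeric truth matrix used to build it is
#'   attached as attribute `"truth"`; the artifact injection log (if any) as
#'   attribute `"artifact_log"`.
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$panel
  n_copies <- sum(panel$copy_number)
  with_seed(config$seed, {
    founders <- config$founder_haplotypes
    if (is.null(founders)) {
      ancestor <- sample(9:16, n_copies, replace = TRUE)
      founders <- smm_drift(
        matrix(ancestor, nrow = config$n_pops, ncol = n_copies, byrow = TRUE),
        config$generations, config$mu)
    }
    pops <- lapply(seq_len(config$n_pops), function(k) {
      n_k <- config$pop_sizes[k]
      smm_drift(matrix(founders[k, ], nrow = n_k, ncol = n_copies,
                       byrow = TRUE),
                config$within_generations, config$mu)
    })
    x <- do.call(rbind, pops)
    pop_label <- rep(sprintf("P%02d", seq_len(config$n_pops)),
                     config$pop_sizes)
    sample_id <- sprintf("%s_%04d", pop_label,
                         unlist(lapply(config$pop_sizes, seq_len)))
    geno <- matrix("", nrow = nrow(x), ncol = nrow(panel),
                   dimnames = list(NULL, panel$name))
    col <- 1L
    for (i in seq_len(nrow(panel))) {
      k <- panel$copy_number[i]
      block <- x[, col:(col + k - 1L), drop = FALSE]
      geno[, i] <- apply(block, 1L, function(v)
        paste(sort(v), collapse = ","))
      col <- col + k
    }
    ds <- ystr_dataset(sample_id, pop_label, geno, panel,
                       dys389_adjusted = TRUE)
    attr(ds, "truth") <- x
    if (any(config$artifact_rates > 0)) {
      inj <- inject_artifacts(ds, config$artifact_rates,
                              seed = config$seed + 1L)
      ds <- inj$dataset
      attr(ds, "truth") <- x
      attr(ds, "artifact_log") <- inj$log
    }
    ds
  })
}

#' Inject genotyping artifacts into a clean dataset
#'
#' Randomly selected sample-locus cells become null alleles, gain a +0.2
#' microvariant step on one copy, or (multi-copy loci only) gain an extra
#' allele copy — exactly the three record classes the R_ST quality filter
#' removes, so filter behaviour can be tested against known truth.
#'
#' @param dataset A `ystr_dataset`.
#' @param artifact_rates Named numeric `c(null=, intermediate=, cnv=)`, each
#'   in [0, 1]; per-cell Bernoulli rates. `cnv` applies only to cells of
#'   multi-copy loci.
#' @param seed Integer seed.
#' @return List with `dataset` (modified) and `log` (data.frame: `sample_id`,
#'   `locus`, `type`), one row per injected artifact.
#' @export
inject_artifacts <- function(dataset, artifact_rates, seed = 1L) {
  stopifnot(inherits(dataset, "ystr_dataset"))
  ar <- c(null = 0, intermediate = 0, cnv = 0)
  ar[names(artifact_rates)] <- artifact_rates
  if (any(ar < 0 | ar > 1)) stop("artifact rates must lie in [0, 1]")
  geno <- dataset$geno
  n <- nrow(geno); L <- ncol(geno)
  multi <- dataset$loci$copy_number > 1L
  log <- list()
  with_seed(seed, {
    null_mask <- matrix(stats::runif(n * L) < ar[["null"]], n, L)
    int_mask <- matrix(stats::runif(n * L) < ar[["intermediate"]], n, L)
    cnv_mask <- matrix(stats::runif(n * L) < ar[["cnv"]], n, L)
    cnv_mask[, !multi] <- FALSE
    # precedence: a nulled cell cannot also show a microvariant or extra copy
    int_mask <- int_mask & !null_mask
    cnv_mask <- cnv_mask & !null_mask
    apply_mask <- function(mask, type, fun) {
      idx <- which(mask, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1L]; j <- idx[r, 2L]
        geno[i, j] <<- normalize_cell(fun(geno[i, j]))
      }
      if (nrow(idx))
        data.frame(sample_id = dataset$samples$sample_id[idx[, 1L]],
                   locus = colnames(geno)[idx[, 2L]],
                   type = type, stringsAsFactors = FALSE)
    }
    log$null <- apply_mask(null_mask, "null", function(cell) {
      paste(rep("0", length(split_cell(cell))), collapse = ",")
    })
    log$intermediate <- apply_mask(int_mask, "intermediate", function(cell) {
      tok <- split_cell(cell)
      k <- which(tok != "0" & !grepl("\\.", tok))[1L]
      if (is.na(k)) return(cell)
      tok[k] <- paste0(tok[k], ".2")
      paste(tok, collapse = ",")
    })
    log$cnv <- apply_mask(cnv_mask, "cnv", function(cell) {
      v <- cell_values(cell)
      extra <- if (all(is.na(v))) 10 else max(v, na.rm = TRUE) + 1
      paste(c(cell, format(extra, trim = TRUE)), collapse = ",")
    })
  })
  log <- do.call(rbind, log[!vapply(log, is.null, logical(1L))])
  if (is.null(log))
    log <- data.frame(sample_id = character(), locus = character(),
                      type = character(), stringsAsFactors = FALSE)
  rownames(log) <- NULL
  # rebuild so copy-number flags reflect the injected extra alleles
  out <- ystr_dataset(dataset$samples$sample_id, dataset$samples$population,
                      geno, dataset$loci,
                      dys389_adjusted = dataset$dys389_adjusted)
  list(dataset = out, log = log)
}
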