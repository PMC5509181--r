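---
title: "Y-STR diversity and population structure with ystrkit: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Y-STR diversity and population structure with ystrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrkit)
```

This vignette documents the statistical models behind `ystrkit`, the
conventions and parameter choices baked into the package, and the limits of
what its synthetic-data tests demonstrate.

## Data model and panel conventions

A dataset is a set of male samples, each carrying one haplotype over a
Y-STR panel. The bundled registry (`y23_panel()`) describes the PowerPlex
Y23 panel: 21 single-copy loci plus the duplicated locus DYS385a/b, held as
one registry entry of copy number 2 — 23 chromosomal loci in total. Allele
designations follow forensic convention: an integer repeat count, optionally
with a microvariant step in tenths (`16.2` = 16 repeats + 2 bases, steps 1–3
are meaningful), and `0` for a null allele (dropout/deletion).

Three conventions are enforced at the IO layer:

* **DYS385 normalisation.** The two copies are reported as an unordered
  pair; the package sorts them ascending on load, so permuted input yields an
  identical dataset. A single reported allele at a multi-copy locus is
  expanded by the usual single-peak convention (identical copies). Cells
  with *more* alleles than the copy number are loaded and flagged as
  copy-number variants, because the downstream quality filter needs to see
  them.
* **DYS389II subtraction.** The DYS389II amplicon contains the DYS389I
  repeat stretch, so repeat-based statistics use DYS389II − DYS389I. The
  subtraction is applied at load time behind a flag defaulting to on,
  recorded in the dataset (`dys389_adjusted`) so it can never be applied
  twice; the writer converts back to reporting convention, making the
  read/write round trip the identity. Records with a null at either DYS389
  locus are left unadjusted and flagged rather than dropped.
* **Null alleles** participate in haplotype identity (a dropout genuinely
  distinguishes two profiles) but are excluded from per-locus allele
  frequencies by default, since a deletion is not a repeat-count allele; an
  `include_null` flag restores them as a category.

## Diversity statistics

For a locus with category frequencies \(p_i\) estimated from \(n\) samples,
Nei's unbiased gene diversity is
\(\mathrm{GD} = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)\).
DYS385a/b is analysed as a combined genotype: the sorted pair is one
category, counted once per sample.

Applied to whole-haplotype counts \(c_i\), the same estimator gives the
haplotype diversity \(\mathrm{HD}\); the match probability is
\(\mathrm{MP} = \sum_i (c_i/n)^2\) and the discrimination capacity
\(\mathrm{DC} = k/n\) with \(k\) distinct haplotypes. The identity
\(\mathrm{HD} = \frac{n}{n-1}(1-\mathrm{MP})\) holds at machine precision
and is enforced by a property test. Reports round GD, MP and DC to 4
decimals and HD to 7, the precision these figures are conventionally printed
at.

## Pairwise R_ST by AMOVA

R_ST treats alleles as points on the repeat-count line. The molecular
distance between two filtered haplotypes is
\(d(x,y)=\sum_{\ell}\sum_{c}(x_{\ell c}-y_{\ell c})^2\), with DYS385
contributing two terms after ascending sorting of both genotypes
(deterministic positional pairing; the choice is arbitrary but order-free).
For two populations, the total and within-group sums of squared distances
are converted to variance components via the standard one-level AMOVA
expected mean squares, and \(R_{ST} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)\).
The implementation computes sums of squares per locus-copy column (using
\(\sum_{i<j}(x_i-x_j)^2 = n\sum_i(x_i-\bar x)^2\)); the test suite checks it
against an explicit enumeration of all pairwise distances at an absolute
tolerance of 1e-12.

Estimates may be slightly negative by construction; they are reported as
computed and only clamped (to 0, with a logged count) where tree building
and ordination require genuine dissimilarities. A pooled sample with zero
molecular variance yields 0 with a warning flag rather than 0/0.

**Quality filter.** Before R_ST, every sample carrying any null allele,
any microvariant, or a copy-number variant is removed — the filter unit is
the sample, not the locus — and the removal log records each sample with its
reasons. A population reduced below two samples is an error, not a silent
degenerate estimate.

**Permutation significance.** Population labels are permuted over the pooled
sample preserving group sizes; \(p = (k+1)/(N+1)\) where \(k\) counts
permutations with \(R_{ST}\) at least the observed value (within 1e-12, so
exact ties count). The default is \(N = 10{,}000\) permutations; the
smallest attainable p is then 1/10001. Each population pair derives its own
seed from the master seed by pair index, so results do not depend on the
order pairs are computed in. A Monte Carlo test (400 random splits of one
panmictic simulated population, \(N=999\)) checks that the rejection rate at
0.05 lies in [0.03, 0.07].

**Bonferroni correction.** The family size defaults to the number of pairs
\(m = \binom{L}{2}\) computed from the data; a `bonferroni_m` override
exists because published analyses sometimes use a different divisor, and
reproducing such a table requires matching its family size rather than
recomputing it.

## Linkage disequilibrium

No standard parametric test fits haploid multi-allelic two-locus tables
well, so the package uses a permutation likelihood-ratio test: the statistic
is \(G = 2\sum O \ln(O/E)\) over the joint state table, and the null
distribution comes from permuting one locus' states across samples — which
preserves both marginals exactly, so no sparse-cell corrections or category
pooling are needed. Monomorphic loci give \(G = 0\), \(p = 1\) by
convention, flagged. The pair order is canonicalised internally so the test
is exactly symmetric in its two loci.

For the all-pairs matrix the two sorted DYS385 copies are treated as
separate markers by default, giving \(\binom{23}{2} = 253\) pairs on the Y23
panel — the convention under which panel-wide LD counts are usually quoted —
with a `combined` mode (231 pairs, sorted pair as one state) available.
Significance is assessed at an uncorrected 0.05 per pair, as panel-wide LD
summaries conventionally do; the result object reports the significant
fraction to one decimal in percent.

## Neighbor-joining and Newick export

The Saitou–Nei agglomeration joins, at each step, the pair minimising
\(Q_{ij} = (m-2)d_{ij} - r_i - r_j\); branch lengths come from the standard
three-point formulas, and the final three nodes close the unrooted tree with
a basal trifurcation. Ties in \(Q\) break deterministically towards the
lowest-index pair. Negative branch lengths are kept by default — they are
required for the recovered patristic distances to reproduce an additive
input matrix exactly, which is the correctness oracle (100 random additive
matrices, ≤ 8 leaves, 1e-9) — with an optional MEGA-style clamp that zeroes
a negative branch and transfers the deficit to its sister. The sum of
branch lengths (SBL), a scalar often quoted alongside published trees, is
the plain arithmetic sum including internal branches. Newick serialisation
writes branch lengths at full double precision (`%.17g`), so parsing the
string reproduces the tree bit-for-bit; labels containing structural
characters are single-quoted.

## Non-metric MDS

Kruskal's stress-1,
\(\sqrt{\sum (d - \hat d)^2 / \sum d^2}\), measures the misfit between
configuration distances \(d\) and disparities \(\hat d\) fitted by monotone
(pool-adjacent-violators) regression on the rank order of the input
dissimilarities. The configuration is initialised from classical (Torgerson)
scaling and refined by Guttman-transform steps with a backtracking line
search: a step is accepted only if stress decreases, halving towards the
current configuration otherwise. Two useful guarantees follow by
construction and are asserted in tests: the stress trace is non-increasing
on every run, and the final stress never exceeds that of the classical
initialiser. Iteration stops when the decrease falls below `tol` (default
1e-6) or after `max_iter` (default 500) steps. The embedding dimension
defaults to 2, the universal choice for population-structure plots.

Degenerate inputs are handled explicitly: an all-zero matrix is an error;
a rank-deficient classical start is zero-padded; a fully collapsed start
(all points coincident) falls back to a seeded random configuration — the
only place the `seed` argument is consumed.

Where published MDS plots quote an "initial stress", it is ambiguous whether
stress at initialisation or the final stress of the first configuration is
meant; the result object therefore reports `stress` (final) and
`stress_initial` (classical start) separately rather than guessing.

## The synthetic-data generator

`sim_config()` + `simulate_populations()` implement a strict single-step
stepwise mutation model (SMM): per round, each locus copy mutates with
probability `mu`, moving ±1 repeat with equal probability and reflecting at
1 repeat (a proposed 0 becomes 2) to avoid non-physical alleles. DYS385
mutates per copy. Multi-step mutations are deliberately omitted — the
single-step SMM is the standard first-order model for Y-STRs and the
motivation for R_ST's squared-difference distance; the drift function is the
natural extension point for a geometric step distribution.

Structure is generated by two-level drift rather than a coalescent: one
ancestral haplotype per run (repeat counts drawn uniformly from 9–16), each
population founder drifts from it for `generations` rounds, and each
sampled lineage drifts from its founder for `within_generations` rounds.
Under this model the expected squared difference at a locus between two
lineages is \(2\mu g\) for within-population pairs (\(g\) =
`within_generations`) and \(2\mu(g_d+g_w)\) between populations, so the
expected between-group variance fraction is approximately
\(g_d/(g_d+g_w)\) — a closed-form calibration knob. The defaults
(`generations = 5`, `within_generations = 95`, `mu = 0.002`, 10
subpopulations totalling 916 males) emulate a provincial-scale study:
weak differentiation around \(R_{ST}\approx 0.05\), with per-replicate
estimates scattering widely around that value because a 23-locus panel
carries limited information about small divergences. A parameter-recovery
test checks that the mean estimate over 50 replicates at this calibration
lies in [0.02, 0.08].

An important consequence of the star-shaped within-population genealogy:
lineages are independent given the founder, so a *single* simulated
population shows essentially no between-locus association. Haplotype-block
LD, the hallmark of real Y-chromosome data, appears in simulations only
when deeply diverged founder lineages are pooled — which is how the
LD-saturation test builds its fixture. Passing LD tests therefore
demonstrate the test's calibration and its power against lineage structure,
not a claim that the simulator reproduces real Y-genealogies.

Artifact injection is post-hoc and independent per cell: selected cells
become all-null, gain a +0.2 microvariant on one copy, or (multi-copy loci
only) gain an extra allele one repeat above the largest. Injection happens
after simulation so that every artifact dataset has a clean "truth" twin,
and the injection log is returned for filter tests. Counts follow the
nominal Bernoulli rates; a binomial-bounds test over 20 seeds checks this.

What the generator does *not* emulate: coalescent genealogies (no shared
within-population ancestry), locus-specific mutation rates calibrated to
real Y-STR panels, allele-length constraints beyond the reflecting floor,
haplogroup structure, and genotyping error modes other than the three
artifact classes. Conclusions from passing tests are therefore about the
correctness and calibration of the estimators, not about their behaviour on
any particular real population.

## Reproducibility and problem sizes

All randomness flows through explicit integer seeds: the simulator consumes
its config seed without disturbing the caller's RNG stream, permutation
tests derive per-pair seeds from a master seed, and the pipeline
(`run_full_analysis()`) derives fixed per-stage offsets from one master
seed, recorded in the report's provenance block alongside the filter log and
package version. Identical seeds produce byte-identical output artifacts.

The test suite runs its stochastic properties at desk scale, chosen to make
sampling noise small relative to the asserted effect while keeping the suite
fast: 400 replicates × 999 permutations for type-I-error calibration, 50
replicates for parameter recovery, 20 replicates per grid point for
monotonicity, 100 random matrices for NJ recovery, populations of tens of
samples throughout. The pipeline itself handles the full 916-sample scale
comfortably; the permutation R_ST matrix is the dominant cost and is
vectorised so that all permutations of a pair reduce to one matrix product.

## Known limitations

* R_ST here is the two-group pairwise design only; no hierarchical
  (region/population/individual) AMOVA.
* The LD test is a generic association test; it does not estimate phased
  two-locus measures such as D' or r² (meaningless for haploid Y data
  anyway).
* Negative R_ST estimates are clamped to zero before tree/MDS input, which
  slightly compresses small distances; the clamp count is logged.
* The NJ implementation is O(n³) with a dense matrix — ample for population
  trees (tens of leaves), not intended for thousands of taxa.
* Microvariant arithmetic treats steps as tenths of a repeat on the numeric
  line (16.2 → 16.2); this matters only before filtering, since R_ST removes
  microvariant carriers.
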