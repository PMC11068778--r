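---
title: "Characterizing drug-tolerant persisters: lineage barcodes, signatures, and drug reversal"
author: "dtptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing drug-tolerant persisters: lineage barcodes, signatures, and drug reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtptools)
```

# Background

Targeted cancer therapy rarely eradicates a tumor cell population outright.
A subpopulation of *drug-tolerant persister* (DTP) cells survives the initial
drug exposure in a slow-cycling, reversible state and seeds *residual
disease* (RD) — the on-treatment tumor state from which acquired resistance
later emerges. Characterizing persisters raises a set of recurring
computational questions that this package answers with small, composable
tools:

1. **Which clones survive?** Cells are tagged before treatment with random
   DNA *lineage barcodes* integrated at low multiplicity of infection
   (MOI ~0.1, so most cells carry at most one tag). Sequencing the barcode
   locus yields a count table contaminated by PCR/sequencing errors, and the
   true barcode set must be separated from error artifacts
   (`estimate_whitelist()`).
2. **Does treatment select particular clones?** Clonal composition over a
   treatment course is summarized by a Simpson-type diversity index and a
   per-group enrichment-shift test (`diversity_index()`,
   `enrichment_shift_test()`).
3. **What transcriptional program marks residual disease?** Per-gene
   differential tests, intersection of independently derived up-regulated
   gene sets, a permutation gene-set statistic and per-cell signature scores
   (`per_gene_tstat()`, `build_intersection_signature()`,
   `permutation_set_test()`, `score_cells()`).
4. **Which drugs reverse that program?** A connectivity-style, rank-based
   screen of the signature against a perturbation reference
   (`concordance_screen()`, `select_reversers()`).
5. **Does the protein respond in situ?** Per-nucleus integrated density from
   two-channel fluorescence images (`segment_nuclei()`,
   `integrated_density()`, `relative_integrated_density()`).

Every stage has a paired generator (`gen_*`) that produces synthetic inputs
with known ground truth, so the whole pipeline is testable without any
external download.

# Barcode whitelisting by an empirical Hamming-distance FDR

## Model

An 18-base random DNA barcode spans $4^{18} \approx 6.9\times10^{10}$
sequences, so independently drawn true barcodes are far apart in Hamming
distance, while sequencing errors create low-count satellites within one or
two substitutions of an abundant true barcode. The whitelisting procedure
exploits exactly this geometry:

* rank candidates by read count (ties broken lexicographically, for
  determinism);
* for a candidate whitelist of size $k$, call a candidate a *false positive*
  if it lies within Hamming distance `fp_hd` (default 1) of another
  candidate in the top $k$; the empirical FDR at $k$ is the fraction of
  false positives among the top $k$;
* accept the largest $k$ whose FDR does not exceed the threshold (default
  0.05).

```{r whitelist-example}
counts <- c(AAAA = 100, CCCC = 90, AAAT = 3)
estimate_whitelist(counts)
```

## Design choices

* **Against-higher-ranked comparison (default).** Errors derive from more
  abundant parents, so a candidate is compared only against candidates
  ranked above it; counting mutual pairs would flag the parent as well as
  the error. The all-pairs variant is exposed via `comparison = "all"` for
  sensitivity analysis, and the tests verify it against a brute-force
  evaluation.
* **Largest-$k$ acceptance.** Incremental inclusion has no natural stopping
  rule when the FDR curve dips back under the threshold; taking the largest
  conforming $k$ maximizes recovered clones while honoring the bound.
* **Scale invariance.** Only count ranks enter the procedure, so uniform
  scaling of all counts cannot change the result (tested).

A consequence worth understanding: with $n$ perfectly separated true
barcodes and error barcodes all flagged, the FDR at $k > n$ is
$(k-n)/k$, which stays below a threshold $t$ up to $k \approx n/(1-t)$.
The procedure therefore admits up to a fraction $t$ of flagged-but-accepted
error barcodes — that is what "controlling the empirical FDR at $t$" means —
and returns exactly the true set only when $t < 1/(n+1)$. The test suite
exercises both regimes: exact recovery at a threshold below $1/(n+1)$, and
false-discovery-proportion control at 0.05.

Reads are assigned back to an accepted whitelist with single-mismatch
correction (`assign_reads()`): a read maps to the unique whitelist barcode
within `max_hd`; reads matching none are `unassigned`, reads near two or
more are `ambiguous`, and the four categories always partition the input.

# Clonal diversity and enrichment shifts

The lineage diversity index over group relative abundances $p_i$ is

$$D = 1 - \sum_i p_i^2,$$

zero when one clone dominates and maximal at $1 - 1/n$ for $n$ equally
abundant groups; `scaled_diversity_index()` divides by that maximum so 1
always means perfectly even composition. The index is permutation-invariant
and strictly increases whenever probability mass moves from a larger to a
smaller group (majorization monotonicity; both tested).

Whether treatment enriches particular barcode groups is tested per group by
Fisher's exact test on the 2x2 table (group vs rest, before vs after), with
Benjamini-Hochberg adjustment across groups. The exact test was chosen
because group counts can be small; groups absent at one timepoint enter
with count zero over the union universe, since disappearance is itself a
shift. A clonal search-space helper (`clonal_expansion_space()`) returns
$2^{\text{doublings}}$ exactly — 112 doublings already exceed
$2.6\times10^{33}$ possible daughter cells, which is why barcode-group
frequencies, not individual cell fates, are the tractable observable.

# Residual-disease signature construction and scoring

## Per-gene tests and normalization

"Unpaired t-tests" are implemented as the classical pooled-variance
two-sample t (Welch behind `var_equal = FALSE`). Expression is normalized
per cell to counts-per-10k and log(1+x)-transformed before testing and
scoring; single-cell plots of "normalized expression" rarely state the
transform, and CP10k+log1p is the simplest choice that removes library-size
differences while keeping the t-test on an additive scale. `normalize =
FALSE` gives raw-scale tests. Genes with zero pooled variance and equal
means are reported as $t = 0$, $p = 1$ (and as maximally significant when
the constant means differ).

## Intersection signatures

A robust up-signature is the intersection of genes significantly
up-regulated (BH $q < 0.05$) in *every* one of several independent
comparisons — e.g. a pathway-activation gene set, several cell-line persister
models, and the on-treatment patient timepoint. An empty intersection is a
warning, not an error, because downstream code must be able to distinguish
"no shared program" from a malformed input.

## Permutation set statistic

The set statistic is the mean of the constituent genes' t statistics. Its
null distribution comes from permuting cell class labels, with the add-one
estimator

$$p = \frac{1 + \#\{|T_{perm}| \ge |T_{obs}|\}}{B + 1},$$

which can never return an exact zero. With `exact = TRUE` all
$\binom{n}{n_A}$ distinct label assignments are enumerated instead — at 3+3
cells that is 20 splits, and the suite checks the sampled estimator's exact
cousin against an independent exhaustive enumeration. Per-cell scores are
plain means of normalized signature-gene expression, so a one-gene
signature scores as that gene.

# Drug-concordance screening

## The rank-based score

Each perturbation profile is ranked most-up-regulated-first (ties broken by
gene identifier). With the signature's sorted positions
$p_1 < \dots < p_s$ in a ranking of $N$ genes, the score is built from

$$a = \max_j\left(\frac{j}{s} - \frac{p_j}{N}\right), \qquad
  b = \max_j\left(\frac{p_j}{N} - \frac{j-1}{s}\right),$$

taking $a$ if $a > b$ and $-b$ otherwise. A negative score means the
signature's genes concentrate at the down-regulated end of the drug's
profile — the drug *opposes* the signature, the property sought in a
reversal screen. The published pipelines this score family descends from do
not print formulas, so the two-sided running-sum construction above is fixed
here as the canonical form, with the signed-max convention stated
explicitly.

Numerical care: $a$ and $b$ live on the lattice of multiples of
$1/(sN)$, and near-ties would otherwise be resolved by floating-point
rounding. Both are therefore computed as integer numerators over the common
denominator $sN$, making the $a$ vs $b$ comparison exact. Two boundary
facts follow from the construction and are asserted in the tests rather
than idealized away: a top block of size $s \le N-2$ scores exactly
$1 - s/N$, but at $s = N - 1$ the construction ties $a = b = 1/N$ and the
convention yields $-1/N$; and reversing a ranking negates the score only up
to the $1/N$ grid step ($a \mapsto b - 1/N$, $b \mapsto a + 1/N$), not
exactly.

## Null distribution and selection

The null is the score of $R$ random gene sets of the signature's size drawn
without replacement from the universe — cheap, and distributionally
identical to re-ranking profiles under a fixed signature (either way the
signature occupies a uniformly random $s$-subset of positions; the
`null = "profiles"` flag is accepted for that reason). Empirical p-values
are two-sided on $|score|$ with the add-one estimator and BH-adjusted across
perturbations; `select_reversers()` then combines sign and significance,
keeping negative scores with $q \le \alpha$ (optionally annotated agents
only) sorted most-negative first, so the top row is the greatest significant
negative score.

Note the granularity constraint that follows from the add-one estimator:
the smallest attainable p is $1/(R+1)$, so after BH across $P$
perturbations a lone hit can at best reach $q = P/(R+1)$. Screens should
use $R \gtrsim 20P$ when a single strong reverser must clear $q \le 0.05$;
the defaults ($R = 1000$) suit references up to ~50 perturbations.

# Per-nucleus image quantification

Segmentation of the nuclear-stain channel is a deliberately plain chain:
global Otsu threshold on the normalized channel, hole filling, 8-connected
component labeling, removal of components below `min_area` (default 50
pixels, small enough for any realistic nucleus at usual magnifications,
large enough to reject specks). The source analyses this emulates do not
publish their exact operator settings, so the simplest standard chain is
fixed and documented rather than guessed at. Integrated density is the raw
sum of protein-channel intensities over each nucleus' pixels — no
background subtraction by default, matching the convention that "integrated
density" is a raw sum (a `subtract_background` flag exists). Relative
integrated density divides each treated nucleus by the mean control
integrated density.

# The synthetic-data generators

Each generator emulates the statistical structure the matching analysis
assumes, with an explicit integer seed per call (bit-reproducible, and the
caller's RNG stream is left untouched):

* `gen_true_barcodes()` / `gen_reads()`: distinct equal-length barcodes at a
  minimum pairwise Hamming distance, placed by rejection sampling with a
  capped number of attempts (deterministic failure over silent
  degradation); reads drawn from clone abundances with independent per-base
  substitutions (a substituted base becomes one of the other three
  uniformly). Not modeled, on purpose: PCR amplification bias, UMIs,
  indels, base-quality-dependent errors — so a whitelisting success here
  shows the Hamming-FDR logic is sound, not that it is robust to chimeric
  PCR artifacts. FASTQ output carries a constant high quality score.
* `gen_labeled_expression()`: log-normal expression (per-gene baseline
  log-mean, per-cell normal noise with `sigma` defaulting to 1 on the log
  scale, exponentiated), with signature genes shifted by `effect_size` on
  the log scale in the target class. Log-normality is the simplest model
  preserving positivity while keeping log-scale t-tests well behaved; it
  has none of the zero inflation or overdispersion structure of real
  droplet scRNA-seq counts, so passing tests demonstrate correctness of the
  statistics, not robustness to dropout.
* `gen_drug_reference()`: standard-normal differential-expression values,
  with planted reversers (mimics) shifting signature genes by `-effect`
  (`+effect`, default 4).
* `gen_nuclei_image()`: non-overlapping flat-intensity disks on constant
  backgrounds with optional Gaussian noise; the truth table carries the
  noiseless per-nucleus integrated density.

# Problem sizes and verification

The test suite runs the pipeline at sizes chosen to finish in well under a
minute per file on one CPU while still leaving no statistical ambiguity:
whitelist recovery at 50 true barcodes x 100,000 reads over 10 seeds and
false-discovery control at 100 barcodes x 50,000 reads over 20 seeds;
concordance FDR control at 200 perturbations x 978 genes over 20 seeds;
permutation-test uniformity over 200 replicates; exhaustive KS-score
verification at $N \le 12$ (all $\binom{N}{s}$ placements) against an
independent sup-difference oracle; nucleus recovery over 10 seeded images.
The reproduction script (`scripts/acceptance.R`) runs the whitelisting
study at full desk scale: 500 true barcodes, 200,000 reads per replicate,
20 replicates.

# Known limitations

* Whitelisting assumes the error radius `fp_hd` is small relative to the
  true set's pairwise separation; barcode libraries with near-duplicate
  entries will lose true barcodes as "errors".
* The enrichment-shift test treats reads as independent draws; PCR
  duplicates violate this and inflate significance at high depth.
* The concordance screen operates on one profile per perturbation; dose or
  time replicates must be collapsed upstream.
* Segmentation has no watershed step, so touching nuclei merge; the
  generators enforce a separation margin precisely because the measurement
  chain does not resolve contact.
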