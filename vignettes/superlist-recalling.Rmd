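---
title: "Superlist re-calling and chromatin state classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superlist re-calling and chromatin state classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacrecall)
```

## The problem

Conservative peak callers trade sensitivity for specificity: a weak but real
ATAC-seq peak can be called in one library and rejected in another purely
because it sits near the caller's detection limit. When the question is
*which loci change accessibility between two cell states* — here, naive
embryonic stem cells (ESCs) versus primed epiblast stem cells (EpiSCs), and
the time courses between them — per-library peak lists make absence
ambiguous: "not called" conflates "closed" with "missed".

Superlist re-calling resolves this by separating peak *discovery* from peak
*quantification*:

1. **Superlist.** Take the union of peaks called in *any* library and merge
   overlapping intervals into one disjoint, sorted list. Every downstream
   measurement happens on this shared coordinate set.
2. **Re-call.** For every superlist peak and every library, measure the
   depth-normalized tag density and annotate the pair *open* if the density
   reaches a fixed threshold, *closed* otherwise. A weak peak missed by the
   caller in library B but called in library A is thereby recovered in B if
   its tags support it.
3. **States and dynamic groups.** The two terminal-state calls partition
   peaks into both-open, naive-specific, primed-specific (and a residual
   both-closed class). Intersecting the state-specific peaks with TF
   ChIP-seq peaks yields the four dynamic groups: C1/C2 (primed-open, TF
   bound/unbound) and C3/C4 (naive-open, TF bound/unbound). C3 — loci open
   in the naive state, closed in the primed state, yet bound there by the
   TF — is the group of "closed naive enhancers" the downstream statistics
   interrogate.

## The density statistic

For a peak with summit $s$ in a library with $N$ total unique reads, the
classification statistic is

$$ d = \frac{\#\{\text{cut sites} \in [s - w,\, s + w)\}}{2w} \cdot \frac{10^7}{N}, $$

scaled cut sites per base in a summit-centered window. The depth factor
$10^7/N$ is the standard genome-coverage scaling, supplied as alignment
metadata rather than inferred from the tag file (the post-filter unique
read count is a property of the alignment, not of the cut-site export).
Windows are clipped at chromosome ends and the clipped length is used in
the denominator; a window entirely off its chromosome is an error.

Parameters, defaults, and why:

* **`window_halfwidth = 150`** (a 300-base window). Enhancer-scale ATAC
  peaks concentrate their signal within a few hundred bases of the summit;
  the window must be wide enough to average Poisson noise and narrow
  enough not to bleed into neighbouring elements. Summit-centering matches
  how the pileup heatmaps that accompany this analysis are drawn.
* **`threshold = 0.2734`** scaled tags per base. This is the open/closed
  cutoff the analysis was calibrated with; its absolute value is
  meaningful only in the unit system above (summit window, $10^7/N$
  scaling). It is configuration, not a constant — with different window or
  scaling conventions it must be re-tuned.
* **Boundary rule:** density exactly equal to the threshold is *open*. The
  defining description ("below … closed and above … open") is silent at
  equality; we resolve it upward and state it in the serialized output
  header.
* **Cut sites** are the 5′ ends of tag records (`start` for +, `end − 1`
  for −). No Tn5 +4/−5 shift is applied: if the upstream export applied
  one, applying it again would be wrong, so the reader is a no-op in this
  respect and any shift is the caller's responsibility.

## Interval conventions

All coordinates are 0-based half-open (BED) internally. Merging requires a
strict overlap of at least one base: bookended intervals `[0,100)`,
`[100,200)` stay separate. The merged peak's canonical summit is the summit
of the highest-signal contributing peak, ties broken leftmost — a
deterministic rule that keeps `build_superlist` idempotent and invariant to
library order. ChIP intersection uses interval overlap of at least
`min_overlap = 1` base against the superlist peak (not summit containment):
the weakest reproducible rule, and configurable upward. TSS-to-peak
assignment measures the distance from a TSS to the nearest covered base of
the peak (0 inside), inclusive at the `tss_window = 10000` boundary, strand
ignored; all supplied TSSs of multi-TSS genes are used.

## Downstream statistics

* **Row-wise Z scores** standardize each peak's densities across libraries
  with the *sample* SD (ddof = 1; the divisor is a convention choice and we
  state ours). Rows with zero spread map to zeros rather than NaN.
* **Mann–Whitney U** compares group densities (or Z scores) between two
  libraries. $U$ counts pairs $x_i > y_j$ with ties as ½. The p-value is
  exact by distribution enumeration when $n_x + n_y \le 20$ with no ties,
  otherwise a normal approximation with tie and continuity correction —
  both as in `stats::wilcox.test`, which backs the p-value computation.
  The exact-vs-approximate switch is reported in the result.
* **Moving-average density** over rank-ordered genes uses a centered window
  (default 51 genes, odd by construction) clipped at the edges, so the ends
  of the ranking are averaged over fewer genes rather than padded.
* **Fold-change screens** use a pseudocount of 1 and a strict `>` at the
  threshold; "fold change > 1" is applied on the linear scale (any increase
  passes), with `log2 = TRUE` available because the intent of such screens
  is genuinely ambiguous between conventions.
* **Motif-table filtering** keeps records with $p < 0.01$ and
  target/background percentage ratio $> 1.5$; a zero background with a
  positive target percentage counts as infinitely enriched.

## The synthetic-data generator

`simulate_dataset()` emulates the *structure* of a two-state ATAC study
with a TF ChIP and coupled expression, at desk scale, with full ground
truth:

* a small genome (default 3 × 1 Mb) with loci placed on a grid, at least
  two window-lengths of clearance between locus windows and margin for a
  linked TSS 300 bases downstream of each locus;
* 100 loci per state class by default, the TF bound at 40% of
  primed-specific, 30% of naive-specific and 35% of both-open loci —
  giving planted C-groups of 40/60/30/70 at the default sizes;
* per-library tag counts per locus drawn Poisson with mean
  `multiple × threshold × window_length / scale`, open loci at 5× and
  closed at 0.2× the threshold by default, over a uniform background at
  0.05×; time-course libraries (default fractions 0.25/0.5/0.75 of the
  naive-to-primed transition) interpolate locus means linearly between the
  terminal states;
* per-library read depth is fixed at $10^7$ (scale factor 1), so densities
  are directly interpretable in threshold units;
* expression is negative binomial (dispersion 0.1) with mean 1000
  normalized tag counts where the linked enhancer is open and 50 where
  closed, interpolated along the time course.

One seeded RNG stream drives all draws, and written fixtures use paths
relative to their directory, so identical configurations produce
byte-identical files anywhere.

What the generator does *not* model — and what passing tests therefore do
not establish about real data: fragment-length structure and Tn5 sequence
bias, copy-number and mappability artifacts, replicate variance, peaks of
heterogeneous width, overlapping regulatory elements, and callers that
disagree with the planted "expected density ≥ threshold" rule. Recovery
results on synthetic data validate the *bookkeeping* (union, counting,
normalization, thresholding, set logic), not the biological calibration of
the 0.2734 cutoff.

## Numerical and degenerate-input choices

Densities are exactly scale-invariant: duplicating every tag while
doubling the read count reproduces the matrix to below $10^{-9}$.
Serialized floating-point values are written with 17 significant digits so
read–write round trips are exact. Degenerate inputs are errors, not
guesses: empty samples in the U test, an even or oversized moving-average
window, a zero or negative read total, windows entirely off chromosome,
mismatched gene rosters in screens. Empty *sets* (a C-group with no peaks,
an empty contrast list) are valid and propagate as empty outputs.

## Pipeline determinism and problem sizes

`run_pipeline()` is deterministic end to end; the manifest records
parameter values and MD5 checksums of all inputs and outputs, so a rerun
with identical configuration can be verified bit-for-bit. A failing stage
writes a `FAILED` marker naming itself and keeps earlier outputs.

The test suite and the acceptance script run the generator at modest sizes
chosen to exercise every code path with comfortable statistical margins:
90–500 loci, 3 × 0.3–1 Mb genomes, two to five libraries. At the default
signal-to-noise settings (open 5×, closed 0.2× of threshold, Poisson
counts of order 400 per open window), misclassification probabilities are
of order $10^{-3}$ or smaller, so exact truth recovery on a few hundred
loci is the expected outcome, not a tuned one.

## Known limitations

The threshold is a single global cutoff — no per-library background model,
GC correction or replicate dispersion estimation; libraries are compared
only through depth scaling. The state partition uses one designated
library per terminal state; replicate consensus, if wanted, must be formed
upstream. Gene assignment is distance-only (GREAT-style), with no
expression-weighted linking. These mirror the scope of the original
analysis rather than gaps we intend to close.
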