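# atacrecall

Superlist re-calling and open/closed chromatin state classification for
multi-library ATAC-seq, with the downstream statistics used to dissect
enhancer dynamics between naive and primed pluripotent states.

## The problem and who this is for

Peak callers are conservative: a weak but real peak can be called in one
ATAC-seq library and missed in another, so per-library peak lists cannot
distinguish "closed" from "not detected". For anyone comparing chromatin
accessibility across cell states or a differentiation time course (the
motivating system is the naive ESC ↔ primed EpiSC transition in mouse),
this package implements the *superlist re-calling* strategy:

1. **Superlist** — merge the peaks called in *any* library into one
   disjoint union list (`build_superlist()`), each merged peak carrying
   the summit of its highest-signal contributor.
2. **Re-call** — for every superlist peak × library, measure the
   depth-normalized tag density

   *d* = (cut sites in [summit − w, summit + w)) / 2w × 10⁷/N,

   with `w = 150` and N the library's total unique reads
   (`build_matrix()`), and annotate the pair **open** when
   *d* ≥ 0.2734, **closed** otherwise (`classify_open_closed()`).
3. **States and groups** — the two terminal libraries partition peaks into
   both-open / naive-specific / primed-specific sets
   (`partition_by_state()`); intersection with TF ChIP-seq peaks splits
   the state-specific sets into the dynamic groups **C1–C4**
   (`intersect_chip()`), where C3 = naive-open loci that are closed in the
   primed state yet TF-bound there — the "closed naive enhancers".
4. **Statistics and annotation** — row-wise Z scores (`zscore_rows()`),
   Mann–Whitney U tests (`mann_whitney_u()`), summit-centered pileups
   (`pileup_profile()`), moving-average binding density over ranked genes
   (`moving_average_density()`), fold-change screens
   (`fold_change_screen()`), motif-table filtering (`motif_filter()`), and
   TSS-within-10-kb peak-to-gene assignment (`tss_within_window()`).

A config-driven generator (`simulate_dataset()`) produces multi-library
peak/tag/ChIP/expression fixtures with planted ground truth, so the whole
pipeline is testable end to end without any sequencing data, and
`run_pipeline()` orchestrates the stages over files with a checksummed run
manifest. A thin CLI lives at `inst/cli/atacrecall`
(`simulate` / `run` / `recall` / `classify` / `groups` / `stats` /
`annotate` / `report`).

## Worked example

```r
library(atacrecall)

ds <- simulate_dataset(sim_config(seed = 42))   # 300 loci, 5 libraries
sl <- build_superlist(ds$peaks)
sl
#> superlist: 300 merged peaks from 1300 contributing peaks across 5 library(ies)

dens <- build_matrix(sl, ds$tags, window_halfwidth = 150, layout = ds$layout)
round(dens[1:3, 1:3], 3)
#>           naive npt_d1 npt_d2
#> sl_000001 1.423  1.363  1.437
#> sl_000002 0.063  0.360  0.700
#> sl_000003 0.077  0.353  0.657

oc <- classify_open_closed(dens, threshold = 0.2734)
state <- partition_by_state(oc[, "naive"], oc[, "primed"])
groups <- state_groups(sl$peaks, state,
                       intersect_chip(sl$peaks, state, ds$chip_peaks))
group_summary(groups)
#> $state
#>       both_open  naive_specific primed_specific     both_closed
#>             100             100             100               0
#> $cgroup
#>   C1   C2   C3   C4 none
#>   40   60   30   70  100

z <- zscore_rows(dens)
c3 <- groups$name[groups$cgroup == "C3"]
mw <- mann_whitney_u(z[c3, "naive"], z[c3, "primed"])
#> C3 naive vs primed: U = 900, p = 3.02e-11

truth_report(ds$truth, groups, oc)$open_closed_accuracy
#> [1] 1
```

Reading the numbers: densities are in threshold units-compatible scaled
tags per base — `sl_000001` sits near 1.4 (open everywhere, a both-open
locus), while `sl_000002` climbs from 0.06 (closed in naive) through the
time course to open in primed. The planted C-groups (40/60/30/70) are
recovered exactly, and the C3 loci collapse from high to low accessibility
between naive and primed (U = 900 is complete separation of the 30 + 30
Z scores; two-sided p ≈ 3 × 10⁻¹¹). `truth_report()` scores every
open/closed call against the generator's truth — accuracy 1 at the default
signal-to-noise.

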