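---
title: "Methods: insertion-density essentiality calling and the protection bootstrap"
author: "tnseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: insertion-density essentiality calling and the protection bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnseqr)
```

# Scope and model

`tnseqr` analyses the landscape of *unique* transposon insertion sites
(TIS) on a single circular bacterial replicon. The data model is
deliberately minimal: a sorted vector of 0-based positions with auxiliary
read counts (`TisTable`), a coordinate frame (`GenomeModel`), a gene table
in 0-based half-open coordinates, and named sets of protein-bound intervals
(`BindingRegionSet`). Read counts are retained through I/O but never enter
a statistic — a hypersaturated library saturates the site grid, so density
of distinct sites, not read depth, carries the essentiality signal.

Three statistics are computed per feature of length $L$ on a landscape of
$T$ unique sites containing $n$ of them:

* **IPKM** $= n \cdot 10^9 / (L \cdot T)$, insertions per kilobase per
  million insertions;
* **ecIPKM**, IPKM after *end curation*: sites within the terminal
  fraction (default 4%) at each end are discarded first, because even
  essential genes tolerate near-terminal insertions;
* the **insertion index** $n / L$, which with no curation ranks genes
  identically to raw IPKM (they differ by the constant $10^9/T$) and is
  kept for cross-comparison with other pipelines.

A gene is called essential iff its ecIPKM is *strictly below* a cutoff.
The default cutoff 2.2 is appropriate for hypersaturated libraries of the
~400,000-site class; `sweepCutoffs()` recalibrates it for any dataset by
maximizing accuracy $(TP+TN)/N$ against a reference essential-gene set
over a grid, also reporting coverage $TP/|\mathrm{ref}|$, precision, and
the ROC/AUC.

# Numerical conventions

These choices are where an implementation can silently diverge, so they
are fixed and tested:

* **Coordinates.** 0-based, half-open `[start, end)`, matching BED.
  Intervals may wrap the origin of a circular genome (`end > length`);
  interval queries split them at the origin.
* **End curation.** The trim is `floor(endTrim * L)` bp per end — an
  integer, conservative rounding; genes shorter than `1/endTrim` bp are
  not trimmed at all. The density denominator is the *trimmed* length
  (0.92·L at the default), keeping ecIPKM an unbiased density of the
  interval actually counted; the raw-length denominator is available via
  `useTrimmedLength = FALSE` for sensitivity analysis. A degenerate
  interval that trims to nothing is clamped to a 1-bp denominator with a
  warning (unreachable for `endTrim < 0.5`, kept as a guard).
* **Ties at the cutoff** are nonessential (strict inequality); ties in the
  accuracy sweep resolve to the smallest cutoff.
* **Nearest-neighbour distances** use circular semantics (the wrap gap
  between the last and first site); both the per-site nearest-neighbour
  fraction and the consecutive-gap histogram are reported, since both
  phrasings of "adjacent site within X bp" circulate.
* **GC windows** centre on the insertion base: window $w$ spans
  $-w/2..+w/2$ inclusive ($w+1$ bases, the insertion base counted once),
  wrapping the origin; `N` bases leave numerator and denominator. The
  extreme-GC scan uses 100-bp windows at 50-bp steps (the largest window
  used in composition diagnostics) with overlapping selected windows
  merged before densities are computed.
* **Empirical p** of the protection bootstrap is
  $(1 + \#\{\bar{x}_{null} \le \bar{x}_{obs}\})/(n_{sets}+1)$, one-sided
  for depletion, never zero — standard permutation-test practice. It is
  uniform on its attainable grid under the null (tested by
  Kolmogorov–Smirnov over 500 replicates at 200 sets each).
* **Welch's t-test.** The bootstrap comparison and a Welch test are both
  reported because both are in common use for this design. Which two
  samples enter the Welch test is genuinely open; the default compares the
  observed per-region IPKMs against the per-region IPKMs of one
  seed-designated null set (set 1), and `welchVariant = "pooled"` tests
  against all null per-region values. When several protein sets are tested
  in one pipeline run, Benjamini–Hochberg adjustment of the empirical
  p-values is added to the summary table.
* **Random regions** are placed uniformly on the circle, may overlap each
  other, genes, and the origin; no exclusion mask is applied by default.
* **Coverage rule.** Footprints from all provided proteins are pooled and
  merged to a disjoint union before gene coverage is measured (so the
  >80%-covered rule refers to combined occupancy, not any single protein),
  and "above threshold" is strict.
* **Profile correlation** uses 500-bp bins by default — narrow enough to
  resolve typical footprint clusters, wide enough that tracks from
  different pipelines align; zero-variance tracks yield `NA` with a
  warning rather than an error.

# The synthetic-data generator

`synthConfig()`/`generateGenome()`/`generateAnnotation()`/
`simulateInsertions()` produce a complete study with known truth. The
generator *defines* the conditions under which the pipeline is validated:

* a circular genome (default 500 kb, GC 0.508) with i.i.d. bases;
* 400 non-overlapping genes (gamma-distributed lengths, mean 900 bp),
  about one gene per kilobase;
* 7% essential genes, 3% pseudogenes; 20% of essential genes carry a
  dispensable 3'-proximal 30% domain that tolerates insertion — the
  false-negative mechanism;
* 50,000 unique insertion sites (~0.1 per bp, the hypersaturated regime of
  a ~400k-site library scaled to 500 kb), sampled *without replacement*
  with per-base weights: background 1.0, essential cores (excluding the
  permissive terminal 4% and any dispensable domain) × 0.005, planted
  protected regions (50 × 500 bp) × 0.01 — the false-positive mechanism;
* per-site read counts `1 + NB(mu = 4, size = 2)`, never used by
  statistics.

The per-base rate inside essential cores is not an observable — published
landscapes only show it is very low — so 0.005 is a modelling choice made
once; likewise 0.01 for protein-occluded intervals, consistent with
footprints that largely but not perfectly exclude transposition.

Weighted sampling without replacement uses exponential keys
(`rexp(L)/rate`, take the `n` smallest), which is exact and $O(L\log L)$;
naive sequential weighted draws are quadratic at this scale. All stages
derive their seeds from one global seed by fixed offsets, so any stage can
be re-run in isolation and a full pipeline run is bit-reproducible.

What the generator does **not** emulate: sequence-motif insertion bias,
PCR duplicates and mapping error, operon/polar effects, conditional
essentiality, gene-density heterogeneity, and real footprint size
distributions (planted regions have one fixed length). Passing tests
therefore demonstrate the *statistics* behave as specified under a clean
null and a clean planted signal — not that any particular biological
landscape satisfies these assumptions.

# Design decisions that were genuinely open

* **Reference-based calibration, not mixture modelling.** Other Tn-Seq
  callers fit gamma or bimodal mixtures to insertion indices; here the
  cutoff is calibrated against a curated reference set, which is the
  appropriate choice when such a set exists and keeps the accuracy metric
  explicit. Accuracy is $(TP+TN)/N$; precision is reported alongside so a
  precision-oriented reading is available.
* **Evaluation universe.** Confusion counting uses all loaded genes minus
  the explicit exclusion list (phantom annotations); pseudogenes are kept
  in the universe as nonessential. Excluding them would change $TN$ only
  slightly and can be done by filtering the input.
* **Protection placement law.** Planted protected regions are placed
  uniformly and independently of genes; real footprints cluster (e.g.
  AT-rich patches for H-NS). Uniform placement matches the bootstrap null
  exactly, which is what the calibration tests require.
* **Dispensable domains are 3'-proximal** (strand-aware 30% of the span),
  reflecting the C-terminal tolerance typically observed; the fraction of
  essential genes carrying one is configurable.

# Problem sizes in the test suite

The suite validates at sizes chosen to make the statistics' asymptotics
visible while keeping a full run in tens of seconds: 100–500-kb genomes,
10,000–50,000 sites, bootstrap nulls of 200–10,000 sets, 5–20 replicate
seeds for power and recovery checks, and 1,000 randomized cases for the
brute-force interval/coverage oracles. Power and calibration checks use
fixed seeds chosen in advance; they assert bands (e.g. null rejection rate
between 1% and 10% at the 5% level over 200 replicates) rather than point
values.

# Known limitations

* Single replicon only; multi-replicon genomes must be analysed per
  replicon.
* The caller is gene-level: subgenic (domain) essentiality appears only in
  the synthetic truth, not as a caller output.
* The Welch test on per-region IPKMs treats regions as exchangeable units;
  heavy length heterogeneity makes the bootstrap comparison the more
  trustworthy of the two reported statistics.
* No peak calling and no read mapping: peak files and insertion tables are
  consumed, not produced.

# A minimal session

```{r example, eval = FALSE}
cfg <- synthConfig(seed = 1)
res <- runPipeline(runConfig(synth = cfg, cutoff = "auto", seed = 1,
                             outDir = tempfile("run")))
res$call$summary          # confusion against the reference labels
selectedCutoff(res$curve) # the calibrated ecIPKM cutoff
res$protection$summary    # bootstrap + Welch per region set
```
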