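# tnseqr

Gene essentiality and protein-occlusion analysis for transposon insertion
sequencing (Tn-Seq) on circular bacterial chromosomes.

## The problem

Tn-Seq infers which genes a bacterium needs by flooding the genome with
transposon insertions and sequencing where they landed: genes that tolerate
no insertions are called essential. With a hypersaturated library
(hundreds of thousands of unique insertion sites on a ~4.6-Mb chromosome)
the resolution is high, but two systematic artifacts remain:

* **False negatives** — essential genes whose terminal ends, or whole
  3'-terminal subdomains, tolerate insertion. Counting those insertions
  makes an essential gene look dispensable.
* **False positives** — nonessential regions occluded by abundant
  DNA-binding proteins (nucleoid-associated proteins such as H-NS, StpA,
  Fis, IHF, MukB). A protein footprint keeps the transposase out, so the
  region looks essential even though its knockout is viable.

`tnseqr` implements the statistics used to quantify both effects, for
microbiologists analysing their own insertion tables and for methodologists
studying Tn-Seq artifacts.

## The statistics

For a feature of length `L` bp on a landscape of `T` total unique insertion
sites containing `n` of them, the insertion density is

```
IPKM = n * 1e9 / (L * T)        (insertions per kilobase per million insertions)
```

the Tn-Seq analogue of RPKM. The **end-curated** variant, ecIPKM, first
discards sites in the terminal 4% at each end of the feature (where even
essential genes tolerate insertion) and uses the trimmed length as the
denominator. A gene is called essential when its ecIPKM falls below a
cutoff; the cutoff is calibrated by sweeping a grid against a reference
essential-gene set and maximizing accuracy `(TP + TN) / N`. The classical
insertion index (`n / L`) is computed alongside for cross-comparison.

Protein-mediated occlusion is tested with a bootstrap: the observed
statistic is the mean IPKM of the protein-bound regions, and the null
distribution is the mean IPKM of 10,000 random same-sized region sets
placed uniformly on the circular genome. A one-sided empirical p-value
(`(1 + #{null <= observed}) / (n_sets + 1)`) and Welch's unequal-variance
t-test are reported side by side. Per-gene coverage by the merged protein
footprints (with a >80% rule) attributes false-positive essential calls to
occlusion, and a reference-gene overlap baseline shows the effect is not
driven by proteins preferring essential genes.

A synthetic-data generator produces genomes, annotations, planted protected
regions and insertion landscapes with known ground truth, so the whole
pipeline is testable end to end without sequencing data.

## Worked example

```r
library(tnseqr)

cfg <- synthConfig(seed = 7)           # 500-kb study with planted truth
res <- runPipeline(runConfig(synth = cfg, cutoff = "auto", nSets = 10000,
                             seed = 7), quiet = TRUE)

res$call$summary
#> ConfusionSummary: 34 called essential | reference 28 | TP 28, FP 6, FN 0 | coverage 100.0%

res$cutoff                             # auto-calibrated ecIPKM cutoff
#> [1] 785.1451

100 * res$landscape$distance$fractions[["10"]]
#> [1] 90.042                            # % of sites with a neighbour within 10 bp

res$protection$summary[, c("observed_mean_ipkm", "null_mean",
                           "empirical_p", "welch_p")]
#>  observed_mean_ipkm null_mean empirical_p      welch_p
#>                17.6  2000.216   9.999e-05 5.481853e-36

res$distributions
#>                group   n     min       q1   median        q3       max
#>                  all 400    0.00 1878.259 2152.302 2322.0449 3374.4856
#>  reference_essential  28    0.00    0.000    0.000   36.4715  743.8017
#>           pseudogene  12 1402.64 1965.160 2287.661 2346.0470 2771.7391
```

Reading the output: all 28 planted essential genes are recovered (the six
false positives are genes occluded by planted protected regions — the
artifact the protection test then detects: the planted regions' mean IPKM
of 17.6 is far below the null mean of ~2000, with the empirical p at its
minimum attainable value and Welch's p ≈ 5e-36). Essential genes sit at
ecIPKM ≈ 0 while pseudogenes carry background-level densities, and 90% of
sites have a neighbour within 10 bp, as expected for a hypersaturated
landscape. On real data, replace `synth =` with `paths =` pointing at a
TIS BED/TSV, a GFF3 annotation carrying `essential`/`pseudo` attributes,
an optional genome FASTA and per-protein peak BED files.

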