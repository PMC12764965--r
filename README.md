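# methmap

Deconvolution of cancer methylome changes into normal-process and
disease-specific components.

## The problem

Cancer genomes carry thousands of DNA methylation differences relative to
matched normal cells, but most of them are not caused by the disease.
Long-lived, highly proliferative normal cell populations (memory B cells
are the canonical example) accumulate methylation changes that closely
mirror those seen in malignancies derived from the same lineage. Naively
comparing tumour to normal therefore drowns the handful of truly
disease-driven changes in a sea of proliferation- and
differentiation-related passengers.

`methmap` addresses this for study designs with three kinds of
populations profiled on beta-value methylation arrays:

* a **baseline** population with minimal proliferation history
  (e.g. B-cell progenitors),
* a **proliferated normal** population (e.g. memory B cells),
* one or more **disease** populations, one of which may be arrested at
  the baseline differentiation stage (e.g. ALL).

## The method

1. **DMR calling.** For a two-group comparison, each probe gets a Welch
   t-test on logit-transformed beta values (variance floor 10⁻³) and a
   beta-scale effect size Δβ. Consecutive same-sign significant probes
   (p < 0.01, gaps ≤ 1 kb) are chained; a chain is a DMR when it has
   ≥ 2 CpGs, a direction-aware Stouffer-combined p < 10⁻⁴, and mean
   |Δβ| ≥ 0.2 (or 0.1 in relaxed mode).
2. **Effect profiles.** Every DMR's Δβ is recomputed for each population
   against baseline.
3. **Category mapping.** With "shows the change" = same sign and
   |Δβ| ≥ 0.1, and "lacks the change" = |Δβ| < 0.1 or opposite sign:

   | pattern (vs baseline)                                   | category        |
   |---------------------------------------------------------|-----------------|
   | proliferated normal + all diseases show it               | proliferation   |
   | proliferated normal + mature diseases show it, arrested disease lacks it | differentiation |
   | all diseases show it, proliferated normal lacks it       | cancer-specific |
   | proliferated normal shows it, all diseases lack it       | cancer-absent   |

   Per-disease mode labels DMRs **disease-specific** (|Δβ| ≥ 0.2 in one
   disease, absent everywhere else; a stringent variant requires the
   others' changes to be > 4× smaller) and **disease-absent**.
4. **Characterization & enrichment.** Per-category CpG counts, sizes,
   hyper/hypo splits, TSS proximity (< 1 kb), two-sided Fisher's exact
   contrasts, and SeSAMe-style Fisher enrichment of member probes against
   the full array across island-context, chromHMM, histone and TFBS
   namespaces with BH-FDR per namespace.
5. **Expression integration.** Cancer-category DMRs whose nearest gene's
   expression correlates negatively with DMR methylation across
   population means are nominated as candidate methylation-regulated
   genes, with promoter-proximity and effect-size filters; per-disease
   candidates require reciprocal disease-specific expression.

A synthetic-data generator plants DMRs of every category (with
per-population proliferation "doses" scaling normal-process effect
sizes), enriched annotation features, and expression-linked promoter
genes, so the entire pipeline is validated by parameter recovery.

## Worked example

```r
library(methmap)
run <- run_pipeline(pipeline_config(seed = 11))
print(run)
```

```
Integrative methylation mapping run
  seed 11; DMR cut-off |delta-beta| >= 0.20
  discovery DMRs (combined diseases vs baseline): 34
  pan-mode categories:
    cancer_absent        1  (2.9%)
    cancer_specific      1  (2.9%)
    differentiation      5  (14.7%)
    proliferation       24  (70.6%)
    unclassified         4  (11.8%)
  cross-comparison r = 0.964 (n = 35, 0 opposite-direction)
  planted-truth recovery: detection 100.0%, category accuracy 100.0%
```

The default synthetic study (2,000 probes, 7 populations, 10 samples
each, 40 planted DMRs) is dominated by proliferation-driven changes, as
designed; the 4 "unclassified" regions are planted per-disease
disease-absent DMRs, which the pan-mode rules correctly leave alone.
The cross-comparison correlation (r = 0.96 here) is the per-DMR
agreement between the combined-disease and proliferated-normal effect
sizes — the replicated-landscape signature that motivates the whole
deconvolution. Candidate genes come out of the expression stage:

```r
run$candidates$pan[, c("gene", "dmr_id", "category", "correlation")]
#>    gene  dmr_id        category correlation
#> 1 G0043 DMR0007 cancer_specific  -0.9874941
#> 2 G0159 DMR0035   cancer_absent  -0.9799452
```

Both are the planted promoter-linked loci — recall 100% at default
noise. `plot(run)` draws the cross-comparison scatter; `summary(run)`
adds group characteristics and enrichment.

A thin command-line wrapper (`inst/scripts/methmap.R`) exposes
`simulate`, `dmr`, `classify`, `characterize`, `enrich`, `integrate`
and `run` subcommands over TSV/BED files.

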