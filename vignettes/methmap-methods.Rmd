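---
title: "Methods: deconvolving cancer methylome changes with methmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvolving cancer methylome changes with methmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmap)
```

## The model

Methylation differences between a cancer population and a matched normal
baseline confound three generative processes: the cell's proliferation
history, its differentiation state, and the disease itself. `methmap`
separates them by exploiting a study design in which a *proliferated
normal* population (long-lived, highly proliferative, non-malignant)
and, optionally, a *progenitor-arrested* disease are profiled alongside
the baseline and the mature diseases. Changes shared with the
proliferated normal population cannot be disease-driven; changes absent
from the progenitor-arrested disease but shared by the mature ones track
differentiation; what remains — present only in diseases, or present
only in the proliferated normal cells — is where disease biology lives.

The unit of analysis is the differentially methylated region (DMR): a
run of at least two array CpGs with a jointly significant,
direction-consistent change, summarized by its mean beta-value
difference Δβ. Classification operates on the DMR's *effect profile*,
the vector of Δβ values of every non-baseline population versus
baseline.

## DMR caller

The caller is deliberately simple and fully specified by its contract —
minimum CpGs, region significance, effect cut-off — rather than by the
internals of any particular kernel smoother:

* **Per-probe test.** Welch's two-sided t-test on logit-transformed
  beta values. The logit (M-value-like) scale stabilizes the strong
  mean–variance dependence of beta values; effect sizes are still
  reported on the beta scale, where the cut-offs are defined. Group
  variances are floored at `1e-3` (logit² units) before the statistic
  and the Welch degrees of freedom are formed, so constant (noiseless or
  saturated) probes remain testable instead of producing 0/0. Logit
  inputs are clamped to [0.001, 0.999]. Probes with more than 20%
  missing values in either group are excluded from that comparison;
  otherwise group means ignore missing values.
* **Chaining.** Probes with per-probe p < 0.01 and a consistent sign of
  Δβ are chained along the chromosome while inter-probe gaps stay
  within 1 kb. A non-seed probe, a sign flip, or a larger gap terminates
  the chain, so member probes are always consecutive on the manifest.
  The 1 kb gap echoes the default smoothing bandwidth of widely used
  region callers.
* **Region criteria.** A chain is a DMR when it has ≥ 2 CpGs, a
  combined region p below 10⁻⁴, and |mean Δβ| ≥ 0.2 (0.1 in relaxed
  mode). The region p is a direction-aware Stouffer combination with
  equal weights: zᵢ = sign(Δβᵢ)·Φ⁻¹(1 − pᵢ/2), Z = Σzᵢ/√n. A
  region-level combination was chosen (over per-probe minima or FDR
  machinery) because the contract specifies a single region significance
  cut-off; this choice is documented rather than hidden.
* **Ties.** Probes at identical positions are rejected when the
  manifest is validated; there is no other tie-break to make.

Lowering the effect cut-off from 0.2 to 0.1 can only relax one of three
conjunctive filters, so the relaxed DMR set is a superset of the strict
one — a property the suite asserts.

## Category mapping

Let s be the sign of the discovery comparison's Δβ (combined diseases
vs baseline; for regions contributed by the proliferated-normal
discovery, that comparison's sign — see below). A population **shows**
the change when its Δβ has sign s and magnitude ≥ 0.1
(`corroboration_min_abs_delta`); it **lacks** the change when the
magnitude is < 0.1 or the sign is opposite (`absence_max_abs_delta`,
the published absence rule). The discovery comparison itself must reach
the run's cut-off (`presence_min_abs_delta`, 0.2). Decision order:
proliferation, differentiation, cancer-specific, cancer-absent,
unclassified. The rules are mutually exclusive by construction and a
profile failing every pattern is left unclassified rather than forced
into the nearest category — with corroboration and absence thresholds
both at 0.1 the show/lack predicates are complementary, but the
thresholds may be pulled apart, in which case profiles can fall in the
gap and honesty beats coverage.

Two design points were genuinely open:

* **Discovery universe.** Cancer-absent changes need not reach
  significance in the disease comparison, so the pan-mode universe is
  the union of combined-disease DMRs and proliferated-normal DMRs that
  share no member probe with them. Reported fractions keep the
  combined-disease total as denominator, for parity with how such
  tables are conventionally printed. (The published relaxed-cut-off
  percentages are not internally consistent with any single
  denominator; this implementation always reports fractions of the
  discovery-comparison total.)
* **Direction source for union regions.** For regions that enter via
  the proliferated-normal discovery, |Δβ| of the disease comparison may
  sit below the presence cut-off; the classifier then takes the
  direction from the proliferated-normal Δβ provided it reaches the
  presence cut-off. Without this, cancer-absent regions — whose disease
  Δβ is near zero by definition — could never be classified.

Per-disease mode: a DMR is *disease-specific* when the examined
disease's |Δβ| ≥ 0.2 and every other disease and the proliferated
normal population lack the change; the stringent variant additionally
requires every other disease's |Δβ| ≤ |Δβ_d|/4 (boundary inclusive).
*Disease-absent* is the mirror pattern and is reported as not
computable for the progenitor-arrested disease, where it would be
indistinguishable from differentiation-driven change.

Reported fractions are rounded half-up to one decimal, matching
published-table formatting (base `round()` is half-to-even and
disagrees on exact .05 boundaries).

## Characterization and enrichment

A DMR's TSS distance is the minimum |probe TSS distance| over member
probes; promoter-proximal means strictly < 1000 bp (a DMR at exactly
1000 bp is distal). Group proportion contrasts (hyper/hypo, TSS) use
two-sided Fisher's exact tests; CpG-count means use Welch's t-test. The
exact test was chosen for proportions because several groups are small
(tens of DMRs) and asymptotic tests would be anticonservative.

Enrichment follows the set-vs-array convention: unique member probes of
a DMR group (a probe in two DMRs counts once) against all *other*
manifest probes, crossed with feature membership, for each feature of
each namespace (island context, chromHMM, histone, TFBS). P-values are
two-sided Fisher; the BH-FDR family is one namespace within one group.
The odds ratio reported is the sample cross-product ad/bc (the
conditional-MLE estimate differs slightly and is less interpretable as
a 2×2 summary); when the set equals the background the table degenerates
and the odds ratio is defined as 1 with p = 1. Depleted features
(OR < 1) are reported but excluded from the shared "core set"
computation, which intersects significantly *enriched* features across
groups. Exports carry both −log10(FDR) and OR so either can drive a
heatmap.

## Expression integration

Methylation and expression cohorts are disjoint in the motivating
designs, so correlations are computed across *population-level means*:
one (mean DMR methylation, mean gene expression) pair per population,
Pearson r with a two-sided p over those pairs (n = number of
populations; 7 in the default design). The significance threshold is
0.05, two-sided, unadjusted — candidate nomination is a screening step
and its output carries the correlation and p for downstream filtering.
Genes with zero expression variance across populations (possible in
noiseless synthetic data) are flagged degenerate and skipped rather
than produce undefined correlations.

Pan-mode candidates must fall in a cancer category and correlate
negatively; promoter proximity (< 1 kb) and the effect-size filter
(|Δβ| > 0.2 in every disease for cancer-specific, in the proliferated
normal population for cancer-absent) are annotated and drive the
ranking rather than hard-excluding, mirroring how such shortlists are
audited. Per-disease candidates use a reciprocity rule formalized as:
sign(expr_d − expr_other) = −sign(Δβ_d) for *every* other population —
the strictest reading of "reciprocal specific difference", and
sign-symmetric between hypermethylation/silencing and
hypomethylation/overexpression.

## The synthetic generator

The generator emulates the structure the method needs, not array
physics:

* **Layout.** Dense blocks (4–8 core probes, 50–200 bp spacing)
  alternate between island cores (baseline mean 0.10, shore flanks
  0.35) and shelf cores (0.65), separated by sparse open-sea probes
  (0.85, ≥ 2 kb spacing). Hypermethylated DMRs are planted on island
  blocks and hypomethylated ones on shelf blocks so that shifted means
  stay inside (0,1).
* **Effects.** Each planted DMR has a category, direction and base
  effect (default Δβ = 0.3). The category determines which populations
  receive the shift: proliferation → proliferated normal + all
  diseases; differentiation → proliferated normal + mature diseases;
  cancer-specific → diseases only; cancer-absent → proliferated normal
  only; disease-specific/absent → the obvious per-disease patterns.
  Proliferation *doses* (memory/CLL/MCL 1.0, DLBCL 1.2, ALL/PCNSL 1.5)
  scale proliferation and differentiation effects only, encoding the
  observation that more proliferative cancers show larger changes at
  shared loci — and giving the stringent 4× rule something to stress.
* **Noise.** Per sample, values are drawn from a beta distribution with
  the target mean and concentration 50 (s.d. ≈ 0.07 at mean 0.5),
  which keeps values in [0,1] and reproduces the heteroscedasticity of
  array betas; infinite concentration gives the noiseless limit used by
  the exact-recovery suites. Means are clipped to [0.01, 0.99].
* **Annotation.** Each namespace carries background features at 10%
  membership; each planted category gets one tag feature at 3× the
  background *odds* inside its blocks (an odds multiplier, so the
  planted frequency is 0.25, not 0.30).
* **Expression.** Linked genes (planted cancer-category DMRs, forced
  promoter-proximal) follow baseline − 4·(DMR methylation) on the log
  scale plus N(0, 0.3) noise across a disjoint cohort of 10 samples per
  population; unlinked genes are independent of methylation.

Default problem sizes — 2,000 probes, 2 chromosomes, 7 populations,
10 samples per population, 40 planted DMRs (24 proliferation, 5
differentiation, 1 cancer-specific, 1 cancer-absent, 5
disease-specific, 4 disease-absent) — are desk-scale choices that keep
the full suite fast while leaving every category represented and the
category mix proliferation-dominated, as in real B-cell data. The
planted cancer-specific fraction is kept below 5% of the discovery
universe so the cross-comparison correlation regime matches the
replicated-landscape setting.

What the generator does **not** emulate: probe cross-reactivity,
SNP-affected probes, type I/II chemistry differences, batch effects,
cell-composition mixtures, or genuinely continuous effect-size
distributions. Passing recovery suites therefore demonstrates that the
algorithmic contract is implemented correctly, not that the caller's
power matches any particular real dataset.

## Reproducibility

Generation is a pure function of the simulation spec (which includes
the seed); the pipeline re-run with the same config produces
byte-identical outputs, and every written table embeds a config
fingerprint. All randomness flows from the single seed in
`pipeline_config()`.

## Package shape

The pipeline is exposed as per-stage functions (`call_dmrs()`,
`classify_profiles()`, `enrich()`, `nominate_pan()`, ...) plus one
orchestrator, `run_pipeline()`, returning a classed object with
`print`, `summary` and `plot` methods. A single formula-style model
interface would not fit a multi-stage analysis over matrices and
manifests; the classed-run-object idiom is the closest conventional
shape.

## Known limitations

* The caller is a contract-faithful simplification; it does not
  reproduce kernel-smoothed region statistics numerically.
* Classification thresholds are step functions of Δβ; DMRs near a
  boundary can flip categories under resampling, which is why noisy
  recovery is asserted as a rate, not as exactness.
* The per-disease "absence" rule shares its 0.1 boundary with the
  corroboration rule; designs needing a buffer between them should pull
  `absence_max_abs_delta` below `corroboration_min_abs_delta`, at the
  cost of an unclassified gap.
* Expression integration uses population means (n = populations), so
  its correlation p-values are coarse by construction; they screen, not
  confirm.

```{r example}
run <- run_pipeline(pipeline_config(seed = 11))
run
```
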