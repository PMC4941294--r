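---
title: "Methods: probe-set reannotation, cross-dataset lncRNA signatures, and their synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-set reannotation and lncRNA signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lncsig` reimplements a complete lncRNA-profiling workflow for
case/control microarray studies: reannotating probe sets to lncRNA
transcripts by direct sequence alignment, identifying differentially
expressed lncRNAs across several datasets with a training/validation
intersection, and characterizing the resulting signature (clustering,
positional and biotype tallies, survival on a marker lncRNA,
coexpression, gene-set enrichment). This vignette documents the models,
the defaults and why they were chosen, the numerical conventions, and
what the synthetic test bed does and does not establish.

## 1. Reannotation

**Transcript filter.** A transcript is considered a lncRNA when its
accession carries an `NR_` or `XR_` prefix (curated / model non-coding
RefSeq) and its length is strictly greater than 200 nt — the
conventional length cut for long non-coding RNA. The inequality is
strict: a 200-nt transcript is excluded. Versioned accessions are
accepted and version-stripped for joins; records without a
recognizable prefix are skipped with a counted warning rather than
failing the run.

**Probe alignment.** Each probe (25-mers by default, matching the
HG-U133 Plus 2.0 design) is scanned against every candidate transcript
at every offset on both strands; identity is matching bases divided by
probe length, `N` never matches, and ties are broken deterministically
(forward strand first, then smallest offset). The scan is exact — no
heuristic seeding is applied by default — and is implemented in C++ so
that an all-pairs evaluation of a study-sized catalog stays in
seconds. An optional Smith–Waterman local alignment (match +1,
mismatch −1, gap −2; traceback prefers diagonal, then a gap in the
transcript, then a gap in the probe) rescues single-indel probes;
because a local alignment may trim probe ends, the full-length ungapped
placement is always evaluated as a candidate too, so the gapped
identity is never below the ungapped identity. A lossless pigeonhole
k-mer prefilter (`k = floor(l/(max_mismatches + 1))`) can be enabled
for large catalogs; the retained table is provably identical to the
all-pairs evaluation, which the test suite asserts against an
independent alignment oracle.

**The set-level 90 % rule.** The published rule — a probe set counts as
matched when "≥ 90 % of its sequences" match a transcript — is
ambiguous about what is counted. The default reading
(`probe_fraction`) counts member probes: a probe matches at identity
≥ 0.9 (an introduced, configurable per-probe threshold; short-probe
alignment identities are nearly binary in practice, so results are
insensitive to its exact value), and the set matches when at least 90 %
of its probes do. The alternative reading (`base_fraction`) thresholds
the mean best identity — total matched bases over total probe bases.
Both are implemented and documented; neither is asserted to be the
original authors' intent. Thresholds are inclusive (≥), tested on both
sides of the boundary: planted identity 0.92 is retained, 0.88 is not.
Probe sets mapping to more than one gene symbol are flagged
`ambiguous` and kept by default (`drop_ambiguous` implements the
stricter convention). Merging with an external annotation takes the
union of rows, keeps the sequence-derived numeric fields on conflict,
and records provenance (`sequence_match` / `external` / `both`).

## 2. Differential expression and the signature

Per-dataset testing assumes approximately Gaussian log2 intensities and
uses either Welch's t (Satterthwaite df) or, by default, a
variance-moderated t in the spirit of the GEO2R service the original
analysis used: per-feature pooled variances are shrunk toward a common
prior, `s̃²_g = (d₀ s₀² + d s²_g)/(d₀ + d)`, with the prior degrees of
freedom `d₀` and prior variance `s₀²` estimated by moments from the
distribution of `log s²_g` across features (digamma/trigamma
corrections, trigamma inversion by Newton iteration). `d₀ = 0`
reproduces the ordinary pooled t and `d₀ = ∞` the common-variance
limit; the estimates agree with the established empirical-Bayes
implementation to machine precision in the test suite, though exact
numerical parity with GEO2R itself is not claimed. Degenerate
zero-variance features are handled without division errors (equal
means → t = 0, p = 1; unequal → p = 0).

Benjamini–Hochberg adjustment is applied per dataset and significance
is strict: `p_adj < 0.01`.

**Training/validation scheme.** The study design distinguishes two
larger discovery ("training") datasets from two smaller confirmation
("validation") datasets. How the published signature combined them is
not stated; the package defaults to the strictest reading — a feature
enters the signature only when significant in *every* training AND
*every* validation dataset with a consistent fold-change sign — and
exposes `min_support` and `require_direction` to relax it. Entries are
ranked by combined evidence, the sum of `log10 p_adj` across datasets
(the ranking criterion behind "top 100" lists is likewise unstated;
this choice is monotone in every dataset's evidence and deterministic,
with ties broken by feature id). Features are probe sets until the
annotation join; multiple probe sets per transcript are collapsed by
best combined evidence.

Hierarchical clustering defaults to 1 − Pearson distance with average
linkage — the common defaults of the classic expression-clustering
tools — with Euclidean distance and complete linkage as options;
constant rows are rejected by name under correlation distance.

## 3. Survival, coexpression, GSEA, enrichment

**Survival.** "High" marker expression is defined by a median split
(ties to the low group) — the cutpoint is a documented choice, not an
authorial fact — and compared with the Kaplan–Meier product-limit
estimator, the two-group log-rank test, and a univariate Cox
proportional-hazards fit (Breslow tie handling by default, Efron
optional; Wald 95 % CI). The fits are delegated to the `survival`
package; the test suite checks them against hand-computed product-limit
and O−E/V values and a brute-force maximization of the Breslow partial
likelihood on small fixtures.

**Coexpression and GSEA.** Coexpression is the Pearson correlation of
every coding gene with the marker, computed **within tumor samples**:
the marker carries a planted (and, in real data, biological)
tumor-vs-normal shift, so across mixed samples a median split would
track histology rather than the coexpression factor — an analysis
confound, not a power issue. For the same reason the marker-high vs
marker-low GSEA phenotype is formed among the tumors of the larger
(training) cohort, where the split has the most samples; the dataset
used for GSEA is not stated in the source study. Rankings use the
classic signal-to-noise metric `(μ₁−μ₂)/(σ₁+σ₂)` with each class SD
floored at `0.2·|μ|` (and an absolute floor of 0.2), per the reference
GSEA convention. The enrichment score is the signed extremum of the
weighted Kolmogorov–Smirnov running sum (hits add
`|s|^p/Σ_hits|s|^p` with `p = 1` by default, misses subtract
`1/(N−N_hits)`); the running sum provably returns to zero, which is
asserted for every set and weighting. The permutation null permutes
phenotype labels (default) or resamples same-size gene sets; the
nominal p compares the observed score against the same-sign
permutation scores, `p = (1 + #{|ES_π| ≥ |ES|, same sign})/(1 +
#{same-sign π})` — the convention that makes null p-values uniform —
and `NES = ES / mean |same-sign ES_π|`. Across a collection, one
shared permutation stream serves all sets and BH is applied over the
per-set p-values (the full NES-pooling FDR of the reference tool is
out of scope).

**Enrichment and positions.** Web-service analyses in the original
workflow are replaced by documented, simpler stand-ins, not
reimplementations: over-representation of a query list against GMT
sets is an upper-tail hypergeometric test with BH across sets, and the
regulatory-domain analysis is reduced to a signed, strand-aware
distance from each lncRNA TSS to the nearest coding TSS (negative =
upstream of the coding gene). `2^−ΔΔCt` and `length × width² × 0.5`
are provided as the standard qPCR and xenograft summaries.

## 4. The synthetic study

The generators produce every input with the statistical structure the
analysis assumes, plus machine-readable ground truth, so each stage can
be tested against what was planted. Defaults were fixed once, at the
scale of the emulated study where it states one and at realistic values
otherwise:

| parameter | default | rationale |
|---|---|---|
| transcripts | 300 coding + 200 noncoding; 10 % of noncoding ≤ 200 nt | exercises the length filter |
| probe design | 150 sets × 11 probes × 25 nt; 20 % decoys | the array's probes-per-set and probe length |
| planted identities | 1.0, 0.96, 0.92, 0.88, 0.80 (cycled) | brackets the 0.9 threshold on both sides (25-mer identities are multiples of 0.04) |
| datasets | 2 × (50 t / 50 n) training, 2 × (25 t / 25 n) validation | two larger discovery, two smaller confirmation cohorts |
| planted DE | 40 features at \|log2FC\| = 1.5, σ = 0.7, half up/half down, in all four datasets | effect/noise at which a well-powered scheme should reach near-perfect recovery; restrictable to a dataset subset to test the intersection logic |
| coexpression | one up-regulated marker + 30 coding genes on a latent factor, loading 0.8 | pairwise marker–module correlation ≈ 0.64 |
| survival | n = 200, true log HR = ln 2, 20 % uniform censoring, exponential baseline with median 36 months in the low group | typical resected-cohort scale and risk |
| gene sets | 20 sets of 15–50 genes, 25 % planted from the top 5–10 % of the association ranking | MSigDB-like sizes |

Noise is i.i.d. Gaussian on the log2 scale — the simplest model
matching the t-test assumptions; matrices are generated already
normalized, as downloaded series matrices are consumed. Probe
mismatches are substitution-only by default (an `indels` option plants
1-nt deletions for the gapped aligner). Censoring times are uniform
with the upper bound solved numerically so the expected censored
fraction matches the configured rate. Planted differential features
are drawn only from probe sets the annotation stage can recover
(planted identity ≥ 0.9 on a transcript > 200 nt), so signature
sensitivity measures the DE scheme rather than the annotation filter.
Every generator is seeded and byte-reproducible; stage seeds are
derived from the master seed so stages are independently reproducible.

**What passing tests do and do not show.** The simulator captures the
analysis-relevant structure (planted effects, shared latent factors,
censoring, set enrichment) but none of the physics of real arrays:
probe-level hybridization efficiency, background, normalization
artifacts, batch effects, correlated noise, or annotation errors in
real transcript catalogs. Green tests certify that the implementation
recovers known truth under its stated assumptions — they do not certify
the biological findings of any particular study, and the published
headline numbers (probe sets annotated, signature size, survival hazard
of the specific marker) depend on external downloads and are therefore
out of scope here.

## 5. Numerical conventions and problem sizes

Coordinates are 0-based half-open internally (BED-native); GCT v1.2,
CLS, GMT and probe-tab files follow their public dialects. All
tie-breaks are deterministic (feature/gene id order; forward strand
first and smallest offset in alignment; diagonal-first traceback;
first-best cell in the DP matrix). BH uses the standard step-up with
clipping at 1. `p_perm` uses add-one smoothing. The pipeline writes a
manifest with MD5 hashes of every output; all outputs except the
timing log are byte-identical across re-runs of the same
configuration.

The shipped test suite runs the generators at the scales above or
below; the heavier property checks use 5 000 features × 4 datasets
with 300 planted effects over 5 seeds (plus 20 null seeds), 50
null-calibration seeds for the moderated t, 200 replicate cohorts for
Cox recovery/coverage and log-rank uniformity, 100 null gene sets for
permutation-p uniformity, and a 50 × 200 probe-set-by-transcript
catalog checked exactly against a brute-force alignment oracle —
sizes chosen so the whole suite completes in a few minutes on one CPU
while keeping the Monte-Carlo assertions well away from their
thresholds.

## 6. Known limitations

- The reannotation searches transcript sequences only; genomic
  context (splice junctions, paralogous gene families) can produce
  ambiguous assignments that are flagged but not resolved.
- The moderated test assumes exchangeable per-feature variances around
  one prior; strongly structured variance (batch, intensity-dependent)
  is not modeled.
- The GSEA multi-set correction is BH over per-set permutation
  p-values, not the reference tool's pooled-NES FDR.
- The Cox model is univariate by design; clinical covariates are out
  of scope.
- `base_fraction` mode has no prefilter (the mean-identity statistic
  needs every probe's best identity).
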