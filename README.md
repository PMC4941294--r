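# lncsig

Microarray probe-set reannotation to long non-coding RNAs and
cross-dataset lncRNA signature discovery, with a fully synthetic,
ground-truthed test bed.

## The problem

Most public lung-cancer expression datasets were collected on
protein-coding-oriented microarrays (Affymetrix HG-U133 Plus 2.0 style).
Many of their probe sets nevertheless hybridize to long non-coding RNAs
(lncRNAs) — transcripts longer than 200 nt with `NR_`/`XR_` RefSeq
accessions and no coding capacity — so the arrays can be *reannotated*
and mined for lncRNA biology without new experiments. `lncsig`
implements that workflow end to end for R users:

1. **Reannotation.** Transcripts are filtered to lncRNAs (`NR_`/`XR_`
   prefix, length strictly > 200 nt). Every probe of every probe set is
   aligned to every lncRNA (ungapped Hamming scan over all offsets and
   both strands, with an optional Smith–Waterman refinement). A probe
   *matches* at identity ≥ 0.9, and a probe set is assigned to a
   transcript when at least 90 % of its probes match
   (`probe_fraction` mode; a `base_fraction` mode thresholds the mean
   identity instead). Sequence-derived tables can be merged with an
   external annotation with provenance tracking.
2. **Differential expression.** Per-dataset tumor-vs-normal tests
   (Welch, or an empirical-Bayes variance-moderated t in the GEO2R
   spirit: `s̃²_g = (d₀s₀² + d s²_g)/(d₀ + d)` with (d₀, s₀²) estimated
   by moments from the spread of `log s²_g`), Benjamini–Hochberg
   adjustment, and a **training/validation signature**: a feature enters
   only if `p_adj < 0.01` in *every* training and *every* validation
   dataset with a consistent fold-change direction.
3. **Characterization.** Hierarchical clustering (1 − Pearson,
   average linkage), chromosome/biotype tallies, external-list
   intersection, Kaplan–Meier / log-rank / Cox survival on a
   median-dichotomized marker lncRNA, Pearson coexpression ranking,
   weighted Kolmogorov–Smirnov GSEA with a seeded permutation null
   (`ES` = signed extremum of the running sum; hits add
   `|s|^p/Σ|s_hit|^p`, misses subtract `1/(N−N_hit)`), hypergeometric
   set enrichment, nearest-TSS distances, and the two wet-lab summary
   formulas (`2^−ΔΔCt`, tumor volume `l·w²·0.5`).
4. **Synthetic data.** Every input the pipeline consumes — transcript
   FASTA/BED, Affymetrix-style probe tables with planted per-probe
   identities, four case/control log2 GCT/CLS datasets with planted
   differential lncRNAs and a planted coexpression module, a survival
   cohort with a planted hazard, GMT gene sets with planted enrichment —
   is generated by seeded, byte-reproducible simulators that also emit
   the ground truth, so every stage is testable without downloads.

All user-facing functions take data frames (or small dataset objects)
first and return tibbles; results have `tidy()`/`glance()`/`autoplot()`
methods.

## Worked example

```r
library(lncsig)

cfg   <- sim_config(seed = 1)                  # the default synthetic study
study <- simulate_study(cfg, "study-data")     # writes FASTA/BED/GCT/CLS/GMT/TSV + truth.json

lnc <- filter_lncrna_transcripts(study$transcripts)
ann <- build_annotation_table(study$probes, lnc)
head(ann, 3)
#>   probeset_id accession probe_match_fraction mean_identity source      ambiguous
#> 1 PS00001_at  XR_000041                    1          1    sequence_m… FALSE
#> 2 PS00002_at  XR_000063                    1          0.96 sequence_m… FALSE
#> 3 PS00003_at  NR_000008                    1          0.92 sequence_m… FALSE
```

68 of 150 probe sets are annotated — exactly the targeted sets planted
at per-probe identity ≥ 0.9 on a transcript that survives the length
filter; levels 0.88 and 0.80 and all decoys are abandoned.

```r
datasets <- lapply(study$expr$datasets, \(d)
  expression_dataset(d$matrix, d$labels, d$dataset_id, d$role))
names(datasets) <- sapply(study$expr$datasets, `[[`, "dataset_id")
de    <- lapply(datasets, dataset_de, method = "moderated", alpha = 0.01)
sig   <- train_validate_signature(de, sapply(datasets, `[[`, "role"))
sig_tx <- collapse_to_transcripts(sig, ann)
head(sig_tx[, 1:4], 5)
#>   feature   direction n_support combined
#> 1 XR_000038 up                4    -79.2
#> 2 NR_000113 down              4    -78.3
#> 3 XR_000063 down              4    -78.3
#> 4 NR_000123 up                4    -78.0
#> 5 NR_000131 up                4    -77.1
```

The signature recovers all 40 planted differential lncRNAs with no
false positives (`combined` is the summed log10 adjusted p across the
four datasets — smaller is stronger).

```r
surv <- survival_analysis(study$survival)
tidy(surv$cox)
#>   term       estimate std.error statistic   p.value    hr conf.low conf.high
#> 1 group_high    0.732     0.172      4.27 0.0000198  2.08     1.49      2.91
```

The cohort was simulated with a true high-vs-low log hazard ratio of
ln 2; the fitted HR of 2.08 (95 % CI 1.49–2.91) recovers it.
`autoplot(surv$km)` draws the Kaplan–Meier curves;
`run_pipeline(pipeline_config(seed = 1, outdir = "run"))` executes the
whole flow (simulate → annotate → DE → signature → survival →
coexpression → GSEA → enrichment → TSS distances) with a deterministic
manifest.

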