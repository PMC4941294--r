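#' Simulation configuration
#'
#' Builds the configuration object consumed by every `simulate_*()`
#' generator. Defaults describe a pipeline-scale study: four case/control
#' log2 expression datasets (two larger training sets, two smaller
#' validation sets), a transcript catalog with RefSeq-style accessions, an
#' Affymetrix-style probe design (11 probes of 25 nt per set), a survival
#' cohort with a planted hazard on one marker lncRNA, and gene sets with
#' planted enrichment.
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param n_coding,n_lnc Number of coding (NM_) and noncoding (NR_/XR_)
#'   transcripts.
#' @param lnc_length_range Length range (nt) for long noncoding transcripts.
#' @param short_fraction Fraction of noncoding transcripts generated at or
#'   below 200 nt, to exercise the length filter.
#' @param n_probesets Number of probe sets; `decoy_fraction` of them get no
#'   planted target (pure random sequence).
#' @param probes_per_set,probe_length Probe design (defaults 11 x 25-mers).
#' @param identity_levels Planted per-probe identities assigned cyclically
#'   to targeted probe sets.
#' @param decoy_fraction Fraction of probe sets without a planted target.
#' @param dataset_sizes List of `c(n_tumor, n_normal)` for the four
#'   datasets, largest first; the two largest are flagged `train`.
#' @param n_de Number of planted differentially expressed lncRNA features.
#' @param effect_log2fc Planted absolute log2 fold change (half up, half
#'   down).
#' @param de_datasets Indices of datasets carrying the planted effect
#'   (default all four).
#' @param sigma Per-feature noise SD on the log2 scale.
#' @param coexpr_module_size,coexpr_strength Size and latent-factor loading
#'   (in \[0,1\]) of the coding-gene module coexpressed with the marker
#'   lncRNA.
#' @param surv_n Survival cohort size.
#' @param surv_true_loghr Planted log hazard ratio of the high-expression
#'   group.
#' @param censor_rate Target fraction of censored records, in \[0,1).
#' @param surv_baseline_median Median survival time (months) in the
#'   low-expression group; sets the exponential baseline hazard.
#' @param n_gene_sets Number of gene sets; `enriched_fraction` are planted
#'   as enriched.
#' @param set_size_range Gene-set size range.
#' @param enriched_fraction Fraction of sets sampled from the top of the
#'   true association ranking.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_coding = 300L,
                       n_lnc = 200L,
                       lnc_length_range = c(400L, 3000L),
                       short_fraction = 0.1,
                       n_probesets = 150L,
                       probes_per_set = 11L,
                       probe_length = 25L,
                       identity_levels = c(1.0, 0.96, 0.92, 0.88, 0.80),
                       decoy_fraction = 0.2,
                       dataset_sizes = list(c(50L, 50L), c(50L, 50L),
                                            c(25L, 25L), c(25L, 25L)),
                       n_de = 40L,
                       effect_log2fc = 1.5,
                       de_datasets = NULL,
                       sigma = 0.7,
                       coexpr_module_size = 30L,
                       coexpr_strength = 0.8,
                       surv_n = 200L,
                       surv_true_loghr = log(2),
                       censor_rate = 0.2,
                       surv_baseline_median = 36,
                       n_gene_sets = 20L,
                       set_size_range = c(15L, 50L),
                       enriched_fraction = 0.25) {
  cfg <- as.list(environment())
  cfg$de_datasets <- cfg$de_datasets %||% seq_along(cfg$dataset_sizes)
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) abort("seed must be a single integer")
  if (any(cfg$identity_levels < 0 | cfg$identity_levels > 1)) {
    abort("identity_levels must lie in [0, 1]")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    abort("censor_rate must lie in [0, 1)")
  }
  if (cfg$n_de > cfg$n_lnc) abort("n_de cannot exceed n_lnc")
  if (cfg$sigma <= 0) abort("sigma must be positive")
  if (cfg$short_fraction < 0 || cfg$short_fraction > 1) {
    abort("short_fraction must lie in [0, 1]")
  }
  if (cfg$short_fraction == 1) {
    warn("short_fraction = 1: every noncoding transcript will fail the length filter and the annotation will be empty")
  }
  if (cfg$coexpr_strength < 0 || cfg$coexpr_strength > 1) {
    abort("coexpr_strength must lie in [0, 1]")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  transcripts:", x$n_coding, "coding /", x$n_lnc, "noncoding\n")
  cat("  probesets:  ", x$n_probesets, "x", x$probes_per_set, "probes of",
      x$probe_length, "nt\n")
  sizes <- map_chr(x$dataset_sizes, ~ paste0(.x[1], "v", .x[2]))
  cat("  datasets:   ", paste(sizes, collapse = ", "), "\n")
  cat("  planted DE: ", x$n_de, "at |log2FC| =", x$effect_log2fc,
      "sigma =", x$sigma, "\n")
  invisible(x)
}

# Derive a stage-specific RNG seed from the master seed so that the
# stages are independent and each is individually reproducible.
stage_seed <- function(cfg, stage) {
  offsets <- c(transcriptome = 101L, probesets = 211L, expression = 307L,
               survival = 401L, genesets = 503L)
  (as.integer(cfg$seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

# one uniform-random A/C/G/T string per element of `lengths`
random_dna <- function(lengths) {
  map_chr(lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
}
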