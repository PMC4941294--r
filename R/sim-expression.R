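#' Simulate the four case/control expression datasets
#'
#' Log2 intensities are i.i.d. Gaussian around per-feature baselines
#' (`Normal(baseline_f, sigma^2)`). `n_de` planted lncRNA features get
#' `+/- effect_log2fc` added to tumor samples (half up, half down) in every
#' dataset listed in `config$de_datasets`. One up-regulated lncRNA is
#' designated the marker ("LCAL6-like"): it loads on a per-sample latent
#' factor shared with `coexpr_module_size` coding genes at loading
#' `coexpr_strength`, so that the marker and the module are coexpressed
#' within every dataset. The two largest datasets are flagged `train`, the
#' rest `validation`.
#'
#' @param lnc_features Character vector of lncRNA feature ids, or a data
#'   frame with an `accession` column (e.g. an annotation truth table) from
#'   which the unique non-missing accessions are taken.
#' @param config A [sim_config()] object.
#' @param coding_features Character vector of coding feature ids (defaults
#'   to `config$n_coding` generated symbols).
#' @param de_eligible Optional subset of `lnc_features` that planted DE
#'   features are drawn from (default: all of them). The pipeline
#'   restricts planting to features the annotation stage can recover, so
#'   that signature sensitivity measures the DE scheme and not the
#'   annotation filter.
#' @return A list with `datasets` (list of four: `dataset_id`, `matrix`,
#'   `labels`, `role`), `de_truth` (tibble: `feature`, `direction`,
#'   `effect`), `marker` (feature id) and `coexpr_truth` (module gene ids).
#' @export
simulate_expression <- function(lnc_features, config,
                                coding_features = NULL,
                                de_eligible = NULL) {
  cfg <- validate_sim_config(config)
  if (is.data.frame(lnc_features)) {
    lnc_features <- unique(lnc_features$accession)
    lnc_features <- lnc_features[!is.na(lnc_features)]
  }
  coding_features <- coding_features %||%
    sprintf("GENE%04d", seq_len(cfg$n_coding))
  de_eligible <- de_eligible %||% lnc_features
  stopifnot(all(de_eligible %in% lnc_features))
  if (cfg$n_de > length(de_eligible)) {
    abort("n_de exceeds the number of DE-eligible lncRNA features")
  }
  set.seed(stage_seed(cfg, "expression"))

  features <- c(lnc_features, coding_features)
  n_feat <- length(features)
  baseline <- setNames(rnorm(n_feat, mean = 7, sd = 1.5), features)

  de_feat <- sample(de_eligible, cfg$n_de)
  n_up <- ceiling(cfg$n_de / 2)
  de_truth <- tibble(
    feature = de_feat,
    direction = rep(c("up", "down"), c(n_up, cfg$n_de - n_up)),
    effect = ifelse(rep(c(TRUE, FALSE), c(n_up, cfg$n_de - n_up)),
                    cfg$effect_log2fc, -cfg$effect_log2fc)
  )
  marker <- if (n_up > 0) de_feat[1] else lnc_features[1]
  module <- sample(coding_features,
                   min(cfg$coexpr_module_size, length(coding_features)))
  lam <- cfg$coexpr_strength

  total_n <- map_int(cfg$dataset_sizes, ~ as.integer(sum(.x)))
  roles <- rep("validation", length(cfg$dataset_sizes))
  roles[order(total_n, decreasing = TRUE)[1:2]] <- "train"

  datasets <- imap(cfg$dataset_sizes, function(size, d) {
    n_tum <- size[1]; n_nor <- size[2]
    n <- n_tum + n_nor
    labels <- c(rep("tumor", n_tum), rep("normal", n_nor))
    sample_ids <- sprintf("DS%d_S%03d", d, seq_len(n))

    mat <- matrix(rnorm(n_feat * n, sd = cfg$sigma), n_feat, n,
                  dimnames = list(features, sample_ids))
    z <- rnorm(n)  # latent coexpression factor
    shared <- c(marker, module)
    mat[shared, ] <- sqrt(1 - lam^2) * mat[shared, ] +
      cfg$sigma * lam * matrix(z, length(shared), n, byrow = TRUE)
    mat <- mat + baseline
    if (d %in% cfg$de_datasets && cfg$n_de > 0) {
      mat[de_truth$feature, labels == "tumor"] <-
        mat[de_truth$feature, labels == "tumor"] + de_truth$effect
    }
    list(
      dataset_id = sprintf("SIM%02d", d),
      matrix = mat,
      labels = tibble(sample_id = sample_ids, label = labels),
      role = roles[d]
    )
  })
  list(datasets = datasets, de_truth = de_truth, marker = marker,
       coexpr_truth = module)
}

#' Write simulated expression datasets as GCT + CLS pairs plus a manifest
#'
#' @param expr Result of [simulate_expression()].
#' @param dir Output directory.
#' @return Tibble manifest (`dataset_id`, `role`, `gct`, `cls`), also
#'   written to `manifest.tsv` in `dir`.
#' @export
write_expression_files <- function(expr, dir) {
  manifest <- map_dfr(expr$datasets, function(ds) {
    gct <- file.path(dir, paste0(ds$dataset_id, ".gct"))
    cls <- file.path(dir, paste0(ds$dataset_id, ".cls"))
    write_gct(ds$matrix, gct)
    write_cls(ds$labels$label, cls)
    tibble(dataset_id = ds$dataset_id, role = ds$role,
           gct = basename(gct), cls = basename(cls))
  })
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(manifest)
}
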