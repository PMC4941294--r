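#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].
#' Unknown keys are rejected so a typo in a YAML file cannot silently
#' fall back to a default.
#'
#' @param seed Master seed for the simulation stage.
#' @param outdir Output directory for all stage results.
#' @param simulate List of overrides passed to [sim_config()] (the
#'   simulation stage generates all inputs under `outdir/data`).
#' @param probe_identity,set_fraction Annotation thresholds.
#' @param annotation_mode `"probe_fraction"` or `"base_fraction"`.
#' @param drop_ambiguous Drop multi-gene probe sets from the annotation.
#' @param de_method `"moderated"` or `"welch"`.
#' @param alpha Adjusted-p threshold for differential expression.
#' @param k_top Size of the extracted top signature.
#' @param n_perm GSEA permutations.
#' @param gsea_scheme `"phenotype"` or `"gene_set"`.
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = "lncsig-run",
                            simulate = list(),
                            probe_identity = 0.90, set_fraction = 0.90,
                            annotation_mode = "probe_fraction",
                            drop_ambiguous = FALSE,
                            de_method = "moderated", alpha = 0.01,
                            k_top = 100L, n_perm = 1000L,
                            gsea_scheme = "phenotype") {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", "),
                 "; known keys: ", paste(known, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> annotate -> differential expression ->
#' signature -> downstream characterization on synthetic data, writing
#' every stage's tables under `config$outdir` together with the
#' effective configuration (`config.yaml`), a deterministic run manifest
#' (`manifest.json`, with MD5 hashes of every output) and a timing log
#' (`pipeline.log`; the only file excluded from the byte-identity
#' contract). Re-running with an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()] object (or path to a YAML file).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  data_dir <- file.path(outdir, "data")
  res_dir <- file.path(outdir, "results")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  log_lines <- character(0)
  t_start <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    secs <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    log_lines <<- c(log_lines, sprintf("[%s] finished in %.2fs", name, secs))
    out
  }

  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))

  sim_cfg <- do.call(sim_config, modifyList(list(seed = config$seed),
                                            config$simulate))
  sim <- stage("simulate", simulate_study(sim_cfg, data_dir))

  lnc <- filter_lncrna_transcripts(sim$transcripts)
  annotation <- stage("annotate", build_annotation_table(
    sim$probes, lnc,
    probe_identity_min = config$probe_identity,
    set_fraction_min = config$set_fraction,
    mode = config$annotation_mode,
    drop_ambiguous = config$drop_ambiguous
  ))
  write_annotation(annotation, file.path(res_dir, "annotation.tsv"))

  datasets <- map(sim$expr$datasets, function(ds) {
    expression_dataset(ds$matrix, ds$labels, ds$dataset_id, ds$role)
  })
  names(datasets) <- map_chr(sim$expr$datasets, "dataset_id")
  de_results <- stage("de", map(datasets, dataset_de,
                                method = config$de_method,
                                alpha = config$alpha))
  iwalk(de_results, function(res, id) {
    readr::write_tsv(res, file.path(res_dir, paste0("de_", id, ".tsv")),
                     progress = FALSE)
  })

  roles <- map_chr(datasets, "role")
  signature_ps <- train_validate_signature(de_results, roles,
                                           alpha = config$alpha)
  signature <- collapse_to_transcripts(signature_ps, annotation)
  readr::write_tsv(signature, file.path(res_dir, "signature.tsv"),
                   progress = FALSE)
  top <- suppressWarnings(top_k(signature, config$k_top))
  readr::write_tsv(top, file.path(res_dir, "signature_top.tsv"),
                   progress = FALSE)

  tall_chrom <- tally_by_chromosome(signature, sim$transcripts)
  tall_bio <- tally_by_biotype(signature, sim$transcripts)
  readr::write_tsv(tall_chrom, file.path(res_dir, "tally_chromosome.tsv"),
                   progress = FALSE)
  readr::write_tsv(tall_bio, file.path(res_dir, "tally_biotype.tsv"),
                   progress = FALSE)

  # cluster the samples of the first validation dataset on the top entries
  val <- datasets[[which(roles == "validation")[1]]]
  top_ps <- signature_ps$feature[signature_ps$feature %in%
                                   rownames(val$matrix)]
  clustering <- NULL
  if (length(top_ps) >= 2) {
    sub <- val$matrix[head(top_ps, config$k_top), , drop = FALSE]
    keep <- apply(sub, 2, sd) > 0
    clustering <- hierarchical_cluster(t(sub))
    readr::write_tsv(tibble(sample = clustering$labels[clustering$order]),
                     file.path(res_dir, "cluster_leaf_order.tsv"),
                     progress = FALSE)
  }

  surv_res <- stage("survival", survival_analysis(sim$survival))
  readr::write_tsv(tidy(surv_res$cox) %>%
                     mutate(logrank_chi_square = surv_res$logrank$chi_square,
                            logrank_p = surv_res$logrank$p),
                   file.path(res_dir, "survival_cox.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(surv_res$km), file.path(res_dir, "survival_km.tsv"),
                   progress = FALSE)

  # coexpression and marker-split GSEA are computed within tumor samples
  # only: the marker's tumor-vs-normal shift would otherwise dominate its
  # variance and a median split would track histology, not coexpression
  coexpr_ds <- datasets[[which(roles == "validation")[1]]]
  tumor_cols <- coexpr_ds$labels == "tumor"
  ranking <- correlation_ranking(coexpr_ds$matrix[, tumor_cols, drop = FALSE],
                                 sim$expr$marker,
                                 features = sim$transcripts$gene_symbol[
                                   grepl("^NM_", sim$transcripts$accession)])
  readr::write_tsv(ranking, file.path(res_dir, "coexpression.tsv"),
                   progress = FALSE)

  # GSEA on the marker-high vs marker-low phenotype among the tumors of
  # the larger (training) cohort; class names reuse the tumor/normal slots
  # of the container for the high/low groups
  gsea_src <- datasets[[which(roles == "train")[1]]]
  gsea_tumors <- gsea_src$labels == "tumor"
  marker_expr <- gsea_src$matrix[sim$expr$marker, gsea_tumors]
  gsea_ds <- expression_dataset(
    gsea_src$matrix[ranking$gene, gsea_tumors, drop = FALSE],
    ifelse(marker_expr > median(marker_expr), "tumor", "normal"),
    paste0(gsea_src$dataset_id, "_markersplit"), gsea_src$role
  )
  gsea_res <- stage("gsea", gsea_collection(
    gsea_ds, sim$gene_sets$sets, n_perm = config$n_perm,
    scheme = config$gsea_scheme, seed = config$seed
  ))
  readr::write_tsv(gsea_res, file.path(res_dir, "gsea.tsv"),
                   progress = FALSE)

  coexpr_top <- head(ranking$gene, 50)
  enrich <- hypergeometric_enrichment(coexpr_top, sim$gene_sets$sets,
                                      universe = ranking$gene)
  readr::write_tsv(enrich, file.path(res_dir, "enrichment.tsv"),
                   progress = FALSE)

  lnc_bed <- sim$transcripts %>%
    filter(.data$accession %in% signature$feature) %>%
    select("chrom", "start", "end", name = "accession", "strand")
  cod_bed <- sim$transcripts %>%
    filter(grepl("^NM_", .data$accession)) %>%
    select("chrom", "start", "end", name = "accession", "strand")
  distances <- distance_to_nearest_tss(lnc_bed, cod_bed)
  readr::write_tsv(distances, file.path(res_dir, "tss_distances.tsv"),
                   progress = FALSE)

  outputs <- sort(setdiff(
    list.files(outdir, recursive = TRUE, full.names = TRUE),
    c(log_path, file.path(outdir, "manifest.json"))
  ))
  manifest <- list(
    seed = config$seed,
    config = "config.yaml",
    outputs = map(outputs, function(f) {
      list(path = sub(paste0("^", outdir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_lines <- c(log_lines, sprintf(
    "total %.2fs", as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  writeLines(log_lines, log_path)

  invisible(list(
    simulation = sim, annotation = annotation, de = de_results,
    signature = signature, top = top, clustering = clustering,
    survival = surv_res, coexpression = ranking, gsea = gsea_res,
    enrichment = enrich, tss_distances = distances, manifest = manifest
  ))
}
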