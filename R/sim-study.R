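#' Generate a complete synthetic study
#'
#' Runs every generator in order and writes all pipeline inputs plus the
#' ground-truth file to a directory: transcript FASTA/BED/TSV, the
#' probe-tab table, four GCT/CLS expression datasets with a manifest, a
#' survival cohort TSV, a GMT gene-set collection, and `truth.json`.
#'
#' Expression features are the targeted probe-set ids plus the coding
#' gene symbols; planted differential features are restricted to probe
#' sets the annotation stage can recover (planted identity at or above
#' 0.9 on a transcript longer than 200 nt), so that the downstream
#' signature's sensitivity reflects the DE scheme rather than the
#' annotation filter.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects: `transcripts`,
#'   `probes`, `probe_truth`, `expr`, `survival`, `gene_sets`, `truth`,
#'   `paths`.
#' @export
simulate_study <- function(config, dir) {
  cfg <- validate_sim_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  transcripts <- simulate_transcriptome(cfg)
  tx_paths <- write_transcriptome_files(transcripts, dir)

  ps <- simulate_probesets(transcripts, cfg)
  probe_path <- file.path(dir, "probes.tsv")
  write_probe_tab(ps$probes, probe_path)

  # features the annotation stage can recover at the default thresholds
  lnc_len <- setNames(transcripts$length, transcripts$accession)
  set_truth <- ps$truth %>% distinct(.data$probeset_id, .data$accession,
                                     .data$identity)
  annotatable <- set_truth %>%
    filter(!is.na(.data$accession), .data$identity >= 0.9,
           lnc_len[.data$accession] > 200) %>%
    pull("probeset_id")
  lnc_features <- unique(ps$probes$probeset_id)
  coding <- transcripts %>% filter(grepl("^NM_", .data$accession))

  expr <- simulate_expression(lnc_features, cfg,
                              coding_features = coding$gene_symbol,
                              de_eligible = annotatable)
  expr_manifest <- write_expression_files(expr, dir)

  surv <- simulate_survival(cfg)
  surv_path <- file.path(dir, "survival.tsv")
  write_survival_tsv(surv, surv_path)

  # true association ranking: the planted coexpression module first
  ranking_truth <- c(expr$coexpr_truth,
                     setdiff(coding$gene_symbol, expr$coexpr_truth))
  gs <- simulate_gene_sets(coding$gene_symbol, ranking_truth, cfg)
  gmt_path <- file.path(dir, "sets.gmt")
  write_gmt(gs$sets, gmt_path)

  acc_of <- setNames(set_truth$accession, set_truth$probeset_id)
  truth <- list(
    probe_map = set_truth,
    de_truth = mutate(expr$de_truth,
                      accession = unname(acc_of[.data$feature])),
    marker = expr$marker,
    marker_accession = unname(acc_of[expr$marker]),
    coexpr_module = expr$coexpr_truth,
    enriched_sets = gs$enriched,
    surv_true_loghr = cfg$surv_true_loghr,
    annotatable_probesets = annotatable
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    transcripts = transcripts, probes = ps$probes, probe_truth = ps$truth,
    expr = expr, survival = surv, gene_sets = gs, truth = truth,
    paths = c(tx_paths, probes = probe_path, survival = surv_path,
              gmt = gmt_path, manifest = file.path(dir, "manifest.tsv"),
              truth = file.path(dir, "truth.json"))
  ))
}
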