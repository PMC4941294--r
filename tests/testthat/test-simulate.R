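test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(n_de = 500, n_lnc = 100), "n_de")
  expect_error(sim_config(sigma = 0), "sigma")
  expect_error(sim_config(identity_levels = c(0.5, 1.2)), "identity_levels")
  expect_warning(sim_config(short_fraction = 1), "length filter")
})

test_that("the transcript catalog honors counts, prefixes and the short fraction", {
  cfg <- sim_config(seed = 7, n_coding = 50, n_lnc = 100, short_fraction = 0.1)
  tx <- simulate_transcriptome(cfg)
  lnc <- tx[grepl("^(NR|XR)_", tx$accession), ]
  expect_equal(nrow(lnc), 100)
  expect_equal(sum(lnc$length <= 200), 10)
  expect_equal(sum(grepl("^NM_", tx$accession)), 50)
  expect_true(all(grepl("^[ACGT]+$", tx$sequence)))
  expect_true(all(tx$end - tx$start == tx$length))
  expect_true(all(tx$biotype[grepl("^NM_", tx$accession)] == "protein_coding"))

  # intervals never overlap within a chromosome
  by_chr <- split(tx[order(tx$start), ], tx$chrom[order(tx$start)])
  overlaps <- vapply(by_chr, function(d) {
    nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])
  }, logical(1))
  expect_false(any(overlaps))

  # no coding transcripts: only noncoding accessions remain
  tx0 <- simulate_transcriptome(sim_config(seed = 1, n_coding = 0, n_lnc = 20, n_de = 5))
  expect_true(all(grepl("^(NR|XR)_", tx0$accession)))
})

test_that("generators are byte-identical under a fixed seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 42, n_coding = 20, n_lnc = 30, n_probesets = 8,
                    n_de = 3, decoy_fraction = 0, coexpr_module_size = 5,
                    surv_n = 40,
                    n_gene_sets = 4, set_size_range = c(5L, 10L),
                    dataset_sizes = list(c(10L, 10L), c(10L, 10L),
                                         c(6L, 6L), c(6L, 6L)))
  simulate_study(cfg, dir1)
  simulate_study(cfg, dir2)
  files <- list.files(dir1)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("planted probes carry exactly round((1-identity)*l) substitutions", {
  cfg <- sim_config(seed = 3, n_coding = 0, n_lnc = 30, short_fraction = 0,
                    n_probesets = 10, decoy_fraction = 0, n_de = 5,
                    identity_levels = c(0.88))
  tx <- simulate_transcriptome(cfg)
  ps <- simulate_probesets(tx, cfg)
  seqs <- setNames(tx$sequence, tx$accession)
  # Hamming distance to the planted source window is exactly 3 (0.12*25)
  purrr::pwalk(list(ps$probes$sequence,
                    ps$truth$accession, ps$truth$offset),
               function(p, acc, off) {
    window <- substr(seqs[[acc]], off + 1, off + 25)
    mm <- sum(strsplit(p, "")[[1]] != strsplit(window, "")[[1]])
    expect_equal(mm, 3)
  })

  # identity 1.0 probes are exact substrings
  cfg1 <- sim_config(seed = 4, n_coding = 0, n_lnc = 10, short_fraction = 0,
                     n_probesets = 3, decoy_fraction = 0, n_de = 2,
                     identity_levels = 1.0)
  tx1 <- simulate_transcriptome(cfg1)
  ps1 <- simulate_probesets(tx1, cfg1)
  seqs1 <- setNames(tx1$sequence, tx1$accession)
  ok <- purrr::map2_lgl(ps1$probes$sequence, ps1$truth$accession,
                        ~ grepl(.x, seqs1[[.y]], fixed = TRUE))
  expect_true(all(ok))

  expect_error(
    simulate_probesets(dplyr::mutate(tx1[1, ], length = 10L,
                                     sequence = substr(sequence, 1, 10)),
                       cfg1),
    "long enough")
})

test_that("decoy probe sets stay below 90% identity against real transcripts", {
  cfg <- sim_config(seed = 5, n_coding = 0, n_lnc = 15, short_fraction = 0,
                    lnc_length_range = c(2500L, 2700L), n_probesets = 10,
                    decoy_fraction = 0.5, probes_per_set = 4, n_de = 5)
  tx <- simulate_transcriptome(cfg)
  ps <- simulate_probesets(tx, cfg)
  decoys <- ps$probes[ps$probes$probeset_id %in%
                        ps$truth$probeset_id[is.na(ps$truth$accession)], ]
  mm <- oracle_mismatch_matrix(decoys$sequence, tx$sequence)
  expect_true(all((25 - mm) / 25 < 0.9))
})

test_that("planted expression effects and roles are as configured", {
  cfg <- sim_config(seed = 11, n_de = 20, effect_log2fc = 1.5, sigma = 0.7,
                    dataset_sizes = list(c(50L, 50L), c(50L, 50L),
                                         c(25L, 25L), c(25L, 25L)))
  expr <- simulate_expression(sprintf("L%03d", 1:100), cfg,
                              coding_features = sprintf("G%03d", 1:50))
  expect_equal(length(expr$datasets), 4)
  expect_equal(purrr::map_chr(expr$datasets, "role"),
               c("train", "train", "validation", "validation"))
  ds <- expr$datasets[[1]]
  tum <- ds$labels$label == "tumor"
  # observed effect within 1.5 +/- 0.3 (> 2 SE at n = 50 v 50, sd 0.7)
  up <- expr$de_truth$feature[expr$de_truth$direction == "up"]
  diffs <- rowMeans(ds$matrix[up, tum]) - rowMeans(ds$matrix[up, !tum])
  expect_lt(abs(mean(diffs) - 1.5), 0.15)
  expect_true(all(abs(diffs - 1.5) < 0.5))
  down <- expr$de_truth$feature[expr$de_truth$direction == "down"]
  diffs_d <- rowMeans(ds$matrix[down, tum]) - rowMeans(ds$matrix[down, !tum])
  expect_true(all(abs(diffs_d + 1.5) < 0.5))

  # a zero effect size centers the per-feature differences at zero
  cfg0 <- sim_config(seed = 12, n_de = 20, effect_log2fc = 0)
  expr0 <- simulate_expression(sprintf("L%03d", 1:100), cfg0,
                               coding_features = sprintf("G%03d", 1:50))
  ds0 <- expr0$datasets[[1]]
  tum0 <- ds0$labels$label == "tumor"
  d0 <- rowMeans(ds0$matrix[, tum0]) - rowMeans(ds0$matrix[, !tum0])
  expect_lt(abs(mean(d0)), 0.05)

  # restricting effects to the training datasets only
  cfg_tr <- sim_config(seed = 13, n_de = 10, de_datasets = c(1L, 2L))
  expr_tr <- simulate_expression(sprintf("L%03d", 1:100), cfg_tr,
                                 coding_features = sprintf("G%03d", 1:50))
  val <- expr_tr$datasets[[3]]
  tum_v <- val$labels$label == "tumor"
  dv <- rowMeans(val$matrix[expr_tr$de_truth$feature, tum_v]) -
    rowMeans(val$matrix[expr_tr$de_truth$feature, !tum_v])
  expect_lt(max(abs(dv)), 1)
})

test_that("survival cohorts honor censoring settings and group hazards", {
  cfg0 <- sim_config(seed = 17, censor_rate = 0, surv_n = 100)
  surv0 <- simulate_survival(cfg0)
  expect_true(all(surv0$event == 1))
  expect_true(all(surv0$time > 0))

  cfg <- sim_config(seed = 18, censor_rate = 0.3, surv_n = 2000)
  surv <- simulate_survival(cfg)
  expect_lt(abs(mean(surv$event == 0) - 0.3), 0.05)
  expect_setequal(unique(surv$group), c("high", "low"))
})

test_that("gene-set generation plants enrichment and validates its inputs", {
  genes <- sprintf("G%03d", 1:200)
  ranking <- genes  # G001 strongest
  cfg <- sim_config(seed = 21, n_gene_sets = 8, set_size_range = c(5L, 10L),
                    enriched_fraction = 0.25)
  gs <- simulate_gene_sets(genes, ranking, cfg)
  expect_length(gs$sets, 8)
  expect_length(gs$enriched, 2)
  # planted sets live in the top decile of the ranking
  for (nm in gs$enriched) {
    expect_true(all(gs$sets[[nm]] %in% head(ranking, 20)))
  }
  # a planted set near the top of the ranking has a positive ES
  ranked <- tibble::tibble(gene = genes,
                           score = seq(2, -2, length.out = 200))
  es <- gsea_enrichment_score(ranked, gs$sets[[gs$enriched[1]]])$es
  expect_gt(es, 0)
})

test_that("truth files determine the downstream DE expectations", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 29, n_coding = 40, n_lnc = 60, n_probesets = 30,
                    n_de = 8, coexpr_module_size = 10, surv_n = 50,
                    n_gene_sets = 5,
                    dataset_sizes = list(c(15L, 15L), c(15L, 15L),
                                         c(8L, 8L), c(8L, 8L)))
  study <- simulate_study(cfg, dir)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$de_truth$feature, study$truth$de_truth$feature)
  # every planted DE feature is annotatable by construction
  expect_true(all(truth$de_truth$feature %in% truth$annotatable_probesets))
  # generated files round-trip through the package readers
  tx <- read_transcript_fasta(file.path(dir, "transcripts.fa"))
  expect_equal(nrow(tx), 100)
  man <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                         show_col_types = FALSE)
  ds <- read_expression_dataset(file.path(dir, man$gct[1]),
                                file.path(dir, man$cls[1]),
                                man$dataset_id[1], man$role[1])
  expect_equal(ds$matrix, study$expr$datasets[[1]]$matrix,
               tolerance = 1e-12)
  sets <- read_gmt(file.path(dir, "sets.gmt"))
  expect_identical(sets, study$gene_sets$sets)
})
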