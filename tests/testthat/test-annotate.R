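test_that("lncRNA filter keeps NR_/XR_ transcripts strictly longer than 200 nt", {
  tx <- fixture_transcripts()  # NM_ 2000, NR_ 2616 (marker length), XR_ 150, NR_ 200
  kept <- filter_lncrna_transcripts(tx)
  expect_equal(kept$accession, "NR_152715")

  # boundary: exactly 200 nt is excluded, 201 nt is kept
  tx201 <- tibble::tibble(accession = c("NR_1", "NR_2"),
                          length = c(200L, 201L), sequence = c("", ""))
  expect_equal(filter_lncrna_transcripts(tx201)$accession, "NR_2")

  expect_equal(nrow(filter_lncrna_transcripts(tx[0, ])), 0)

  malformed <- tibble::tibble(accession = c("NR_10", "garbage"),
                              length = c(300L, 300L), sequence = c("", ""))
  expect_warning(out <- filter_lncrna_transcripts(malformed), "skipped")
  expect_equal(out$accession, "NR_10")
})

test_that("set-level match rule counts probes against both thresholds", {
  tx <- list(accession = "NR_1", sequence = random_seq(500, seed = 3))
  probes <- fixture_probeset(tx$sequence, n_probes = 11, identity = 1)

  # 10/11 perfect + 1 ruined probe: 0.909 >= 0.90 -> matched
  ruined <- probes
  ruined$sequence[11] <- random_seq(25)
  row <- match_probeset(ruined, tx)
  expect_equal(nrow(row), 1)
  expect_equal(row$probe_match_fraction, 10 / 11)

  # 9/11 perfect + 2 ruined: 0.818 < 0.90 -> abandoned
  ruined2 <- probes
  ruined2$sequence[10:11] <- c(random_seq(25), random_seq(25))
  expect_equal(nrow(match_probeset(ruined2, tx)), 0)

  # uniform 0.92 probes match under both modes
  p92 <- fixture_probeset(tx$sequence, identity = 0.92, seed = 8)
  expect_equal(nrow(match_probeset(p92, tx, mode = "probe_fraction")), 1)
  expect_equal(nrow(match_probeset(p92, tx, mode = "base_fraction")), 1)

  expect_error(match_probeset(probes, tx, probe_identity_min = 1.2),
               "thresholds")
})

test_that("annotation retains exactly the planted identity levels >= 0.9", {
  cfg <- sim_config(seed = 13, n_coding = 0, n_lnc = 60, short_fraction = 0,
                    lnc_length_range = c(300L, 800L), n_probesets = 25,
                    decoy_fraction = 0.2, n_de = 5)
  tx <- simulate_transcriptome(cfg)
  ps <- simulate_probesets(tx, cfg)
  ann <- build_annotation_table(ps$probes, filter_lncrna_transcripts(tx))

  truth <- dplyr::distinct(ps$truth, probeset_id, accession, identity)
  expected <- truth$probeset_id[!is.na(truth$identity) & truth$identity >= 0.9]
  expect_setequal(unique(ann$probeset_id), expected)
  # decoy sets never appear
  decoys <- truth$probeset_id[is.na(truth$accession)]
  expect_length(intersect(ann$probeset_id, decoys), 0)
  # and every retained row maps to the planted target
  joined <- merge(ann, truth, by = "probeset_id")
  expect_true(all(joined$accession.x == joined$accession.y))
})

test_that("the k-mer prefilter changes nothing", {
  cfg <- sim_config(seed = 17, n_coding = 0, n_lnc = 40, short_fraction = 0,
                    lnc_length_range = c(300L, 600L), n_probesets = 12,
                    n_de = 5)
  tx <- simulate_transcriptome(cfg)
  ps <- simulate_probesets(tx, cfg)
  lnc <- filter_lncrna_transcripts(tx)
  plain <- build_annotation_table(ps$probes, lnc)
  fast <- build_annotation_table(ps$probes, lnc, prefilter = TRUE)
  expect_equal(as.data.frame(fast), as.data.frame(plain))
})

test_that("lowering thresholds never removes an annotation row", {
  cfg <- sim_config(seed = 19, n_coding = 0, n_lnc = 30, short_fraction = 0,
                    lnc_length_range = c(300L, 600L), n_probesets = 10,
                    n_de = 5)
  tx <- simulate_transcriptome(cfg)
  ps <- simulate_probesets(tx, cfg)
  lnc <- filter_lncrna_transcripts(tx)
  strict <- build_annotation_table(ps$probes, lnc)
  loose <- build_annotation_table(ps$probes, lnc,
                                  probe_identity_min = 0.8,
                                  set_fraction_min = 0.8)
  key <- function(x) paste(x$probeset_id, x$accession)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("reverse-complementing every transcript leaves the table invariant", {
  cfg <- sim_config(seed = 23, n_coding = 0, n_lnc = 30, short_fraction = 0,
                    lnc_length_range = c(300L, 600L), n_probesets = 10,
                    n_de = 5)
  tx <- simulate_transcriptome(cfg)
  ps <- simulate_probesets(tx, cfg)
  lnc <- filter_lncrna_transcripts(tx)
  fwd <- build_annotation_table(ps$probes, lnc)
  flipped <- dplyr::mutate(lnc, sequence = vapply(sequence, oracle_revcomp,
                                                  character(1)))
  rev <- build_annotation_table(ps$probes, flipped)
  expect_equal(as.data.frame(rev), as.data.frame(fwd))
})

test_that("probe sets hitting two gene symbols are flagged, not dropped", {
  base <- random_seq(400, seed = 29)
  tx <- tibble::tibble(
    accession = c("NR_1", "NR_2"),
    sequence = c(base, base),  # identical sequence, different genes
    length = 400L, gene_symbol = c("GENEA", "GENEB")
  )
  probes <- fixture_probeset(base, identity = 1)
  ann <- build_annotation_table(probes, tx)
  expect_equal(nrow(ann), 2)
  expect_true(all(ann$ambiguous))
  dropped <- build_annotation_table(probes, tx, drop_ambiguous = TRUE)
  expect_equal(nrow(dropped), 0)
})

test_that("merging with an external annotation unions rows with provenance", {
  prim <- tibble::tibble(
    probeset_id = paste0("PS", 1:5), accession = paste0("NR_", 1:5),
    probe_match_fraction = 1, mean_identity = 0.95,
    source = "sequence_match", ambiguous = FALSE
  )
  ext_disjoint <- tibble::tibble(probeset_id = paste0("PS", 6:8),
                                 accession = paste0("NR_", 6:8))
  merged <- merge_annotation_tables(prim, ext_disjoint)
  expect_equal(nrow(merged), 8)
  expect_setequal(merged$source[merged$probeset_id %in% paste0("PS", 6:8)],
                  "external")

  # identical tables: same rows, all flagged as present in both
  self <- merge_annotation_tables(prim, prim[, c("probeset_id", "accession")])
  expect_equal(nrow(self), 5)
  expect_true(all(self$source == "both"))
  # primary numeric fields survive a conflicting external copy
  ext_conflict <- dplyr::mutate(prim[, c("probeset_id", "accession")],
                                mean_identity = 0.1)
  m2 <- merge_annotation_tables(prim, ext_conflict)
  expect_true(all(m2$mean_identity == 0.95))
  # versioned external accessions are normalized before matching
  ext_ver <- tibble::tibble(probeset_id = "PS1", accession = "NR_1.2")
  m3 <- merge_annotation_tables(prim, ext_ver)
  expect_equal(sum(m3$source == "both"), 1)

  expect_error(merge_annotation_tables(prim, dplyr::mutate(ext_disjoint,
                                                           bogus = 1)),
               "unknown external annotation column")
})

test_that("annotating against an empty transcript list warns and is empty", {
  probes <- fixture_probeset(random_seq(300, seed = 2))
  expect_warning(ann <- build_annotation_table(probes,
                                               fixture_transcripts()[0, ]),
                 "empty")
  expect_equal(nrow(ann), 0)
})
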