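test_that("Welch t matches the closed-form hand computation and t.test", {
  res <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)

  # identical samples: exact null
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # scale invariance of the statistic
  a <- rnorm(8); b <- rnorm(10, 1)
  expect_equal(welch_t_test(a * 10, b * 10)$t, welch_t_test(a, b)$t,
               tolerance = 1e-12)

  # agreement with the standard implementation on random draws
  set.seed(99)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), sd = 2)
    ref <- t.test(x, y)
    mine <- welch_t_test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }

  # zero variance with unequal means: no division error
  degen <- welch_t_test(c(1, 1, 1), c(2, 2, 2))
  expect_equal(degen$p, 0)
})

test_that("moderated t reduces to the pooled t at d0 = 0 and shrinks outliers", {
  ds <- fixture_dataset(n_features = 100, seed = 3)
  res0 <- moderated_t_test(ds, d0 = 0)
  # pooled two-sample t computed directly
  tum <- ds$labels == "tumor"
  pooled_t <- apply(ds$matrix, 1, function(x) {
    t.test(x[tum], x[!tum], var.equal = TRUE)$statistic
  })
  expect_equal(res0$t, unname(pooled_t), tolerance = 1e-10)

  # an outlier-variance feature lands between ordinary and fully pooled t
  mat <- ds$matrix
  mat[1, ] <- mat[1, ] + rnorm(ncol(mat), sd = 5)
  ds2 <- expression_dataset(mat, ds$labels, "X", "train")
  mod <- moderated_t_test(ds2)
  ord <- moderated_t_test(ds2, d0 = 0)
  poo <- moderated_t_test(ds2, d0 = Inf)
  between <- (abs(mod$t[1]) - abs(ord$t[1])) *
    (abs(mod$t[1]) - abs(poo$t[1]))
  expect_lte(between, 0)
})

test_that("moderated t agrees with the established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  ds <- fixture_dataset(n_features = 500, seed = 11)
  # heterogeneous true variances so there is something to shrink
  mat <- 7 + sweep(matrix(rnorm(500 * 20), 500, 20), 1,
                   sqrt(rchisq(500, 4) / 4) * 0.7, `*`)
  dimnames(mat) <- dimnames(ds$matrix)
  ds <- expression_dataset(mat, ds$labels, "X", "train")
  mine <- moderated_t_test(ds)
  design <- stats::model.matrix(~ factor(ds$labels, c("normal", "tumor")))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(attr(mine, "prior")$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(mine$t, fit$t[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(mine$p, fit$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("BH adjustment matches the hand example and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  set.seed(7)
  p <- runif(1000)
  expect_lt(max(abs(bh_adjust(p) - oracle_bh(p))), 1e-12)
  expect_error(bh_adjust(c(0.1, NA)), "missing")
  expect_error(bh_adjust(c(0.1, 1.3)), "0, 1")
})

test_that("dataset_de flags p_adj < alpha strictly and alpha = 1 keeps all", {
  ds <- fixture_dataset(n_features = 300, de_features = 1:20, seed = 5)
  de <- dataset_de(ds, alpha = 1)
  expect_true(all(de$significant))
  de2 <- dataset_de(ds, alpha = 0.01)
  expect_true(all(de2$p_adj[de2$significant] < 0.01))
  expect_equal(de2$direction, ifelse(de2$log2fc >= 0, "up", "down"))
  # planted features dominate the significant set
  planted <- sprintf("F%04d", 1:20)
  expect_gt(mean(planted %in% de2$feature[de2$significant]), 0.8)
})

test_that("the signature requires support in every train and validation set", {
  mk <- function(p_adj, lfc) {
    tibble::tibble(feature = c("A", "B", "C"), log2fc = lfc, p_adj = p_adj)
  }
  res <- list(
    T1 = mk(c(0.001, 0.001, 0.5), c(1, 1, 1)),
    T2 = mk(c(0.001, 0.001, 0.5), c(1, 1, 1)),
    V1 = mk(c(0.001, 0.5, 0.5), c(1, 1, 1)),
    V2 = mk(c(0.001, 0.5, 0.5), c(1, 1, 1))
  )
  roles <- c(T1 = "train", T2 = "train", V1 = "validation", V2 = "validation")
  sig <- train_validate_signature(res, roles)
  # B is significant in both train sets but neither validation set
  expect_equal(sig$feature, "A")

  # direction conflicts are excluded unless the requirement is lifted
  res2 <- res
  res2$V1$p_adj <- res2$V2$p_adj <- c(0.001, 0.001, 0.5)
  res2$V1$log2fc <- c(1, -1, 1)
  sig_dir <- train_validate_signature(res2, roles, require_direction = TRUE)
  expect_false("B" %in% sig_dir$feature)
  sig_nodir <- train_validate_signature(res2, roles, require_direction = FALSE)
  expect_true("B" %in% sig_nodir$feature)
})

test_that("adding a dataset to the scheme never grows the signature", {
  sets <- lapply(1:3, function(i) {
    ds <- fixture_dataset(n_features = 400, de_features = 1:30,
                          n_tumor = 20, n_normal = 20, seed = i,
                          id = paste0("DS", i))
    dataset_de(ds)
  })
  names(sets) <- paste0("DS", 1:3)
  roles2 <- c(DS1 = "train", DS2 = "validation")
  roles3 <- c(DS1 = "train", DS2 = "validation", DS3 = "validation")
  sig2 <- train_validate_signature(sets[1:2], roles2)
  sig3 <- train_validate_signature(sets, roles3)
  expect_true(all(sig3$feature %in% sig2$feature))
})

test_that("top_k is deterministic, order-stable and warns when k is too big", {
  sig <- tibble::tibble(feature = c("b", "a", "c"),
                        combined = c(-10, -10, -5))
  expect_equal(top_k(sig, 2)$feature, c("a", "b"))
  shuffled <- sig[c(3, 1, 2), ]
  expect_equal(top_k(shuffled, 2)$feature, c("a", "b"))
  expect_equal(top_k(sig, 3), dplyr::arrange(sig, combined, feature))
  expect_warning(all_of_them <- top_k(sig, 10), "exceeds")
  expect_equal(nrow(all_of_them), 3)
})

test_that("signature intersection is plain normalized set arithmetic", {
  sig <- tibble::tibble(feature = sprintf("NR_%03d", 1:50),
                        combined = -(50:1) / 10)
  expect_equal(nrow(intersect_signature(sig, c("NM_900", "NM_901"))), 0)
  expect_equal(nrow(intersect_signature(sig, sig$feature)), 50)
  external <- c(sprintf("nr_%03d.2", 44:50), sprintf("XX_%03d", 1:5))
  expect_equal(nrow(intersect_signature(sig, external)), 7)
  expect_warning(empty <- intersect_signature(sig, character(0)), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("chromosome and biotype tallies conserve the signature size", {
  tx <- fixture_transcripts()
  sig <- tibble::tibble(feature = c("NR_152715", "XR_000001", "NR_999999"),
                        direction = c("up", "down", "up"),
                        combined = c(-9, -8, -7))
  tc <- tally_by_chromosome(sig, tx)
  expect_equal(sum(tc$n_up + tc$n_down), nrow(sig))
  expect_equal(tc$n_up[tc$chrom == "chr1"], 1)
  expect_equal(tc$n_down[tc$chrom == "chr2"], 1)
  expect_equal(tc$n_up[tc$chrom == "unlocated"], 1)
  tb <- tally_by_biotype(sig, tx)
  expect_equal(sum(tb$n_up + tb$n_down), nrow(sig))
  expect_equal(sum(tb$n_up[tb$biotype == "antisense"]), 1)
})
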