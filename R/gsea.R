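#' Pearson coexpression ranking against a target feature
#'
#' Ranks every other feature (typically the coding genes) by Pearson
#' correlation with the target feature's expression across samples,
#' descending. Constant rows get score 0 and a flag.
#'
#' @param dataset An [expression_dataset()] (or a plain matrix).
#' @param target_feature Row name of the target.
#' @param features Optional subset of features to rank (default: all rows
#'   except the target).
#' @return A tibble `gene`, `score` (r), `constant`, ordered by
#'   descending score with deterministic ties by gene id.
#' @export
correlation_ranking <- function(dataset, target_feature, features = NULL) {
  mat <- if (inherits(dataset, "expr_dataset")) dataset$matrix else dataset
  if (!target_feature %in% rownames(mat)) {
    abort(paste0("target feature not found: ", target_feature))
  }
  if (ncol(mat) < 4) abort("need at least 4 samples")
  features <- features %||% setdiff(rownames(mat), target_feature)
  target <- mat[target_feature, ]
  sub <- mat[features, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  r <- rep(0, length(features))
  ok <- sds > 0 & sd(target) > 0
  r[ok] <- as.vector(cor(t(sub[ok, , drop = FALSE]), target))
  tibble(gene = features, score = r, constant = !ok) %>%
    arrange(desc(.data$score), .data$gene)
}

#' Signal-to-noise ranking for a two-class comparison
#'
#' The classic GSEA ranking metric `(mu_high - mu_low) / (sd_high +
#' sd_low)`, with each class SD floored at `0.2 * |class mean|` (and at a
#' small absolute floor), per the reference implementation's convention.
#'
#' @param dataset An [expression_dataset()] or matrix.
#' @param labels Two-class character vector per sample; the first class
#'   in `classes` is the "high" class.
#' @param classes Length-2 character vector naming the (high, low)
#'   classes; defaults to `c("tumor", "normal")` or the unique labels.
#' @return A tibble `gene`, `score`, descending, ties by gene id.
#' @export
signal_to_noise_ranking <- function(dataset, labels = NULL,
                                    classes = NULL) {
  mat <- if (inherits(dataset, "expr_dataset")) dataset$matrix else dataset
  labels <- labels %||% if (inherits(dataset, "expr_dataset"))
    dataset$labels else abort("labels required for a plain matrix")
  classes <- classes %||%
    (if (all(c("tumor", "normal") %in% labels)) c("tumor", "normal")
     else unique(labels))
  if (length(classes) != 2 || !all(classes %in% labels)) {
    abort("exactly two classes, both present, are required")
  }
  hi <- labels == classes[1]; lo <- labels == classes[2]
  if (sum(hi) < 3 || sum(lo) < 3) abort("need at least 3 samples per class")
  m1 <- rowMeans(mat[, hi, drop = FALSE])
  m2 <- rowMeans(mat[, lo, drop = FALSE])
  row_sd <- function(x, m) {
    sqrt(pmax(rowSums((x - m)^2), 0) / (ncol(x) - 1))
  }
  floor_sd <- function(s, m) pmax(s, 0.2 * abs(m), 0.2)
  s1 <- floor_sd(row_sd(mat[, hi, drop = FALSE], m1), m1)
  s2 <- floor_sd(row_sd(mat[, lo, drop = FALSE], m2), m2)
  tibble(gene = rownames(mat), score = unname((m1 - m2) / (s1 + s2))) %>%
    arrange(desc(.data$score), .data$gene)
}

# Enrichment score only, for permutation loops: w = |score|^p in ranked
# order, hit = set membership indicator in the same order.
es_fast <- function(w, hit) {
  n <- length(hit)
  n_hit <- sum(hit)
  w_hit_total <- sum(w[hit])
  inc <- ifelse(hit,
                if (w_hit_total > 0) w / w_hit_total else 1 / n_hit,
                -1 / (n - n_hit))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; a gene-set hit at position `i` increments the
#' running sum by `|score_i|^p / sum(|score_hits|^p)`, a miss decrements
#' by `1 / (N - N_hits)`. The enrichment score is the signed extremum of
#' the running sum (largest absolute deviation, earliest position on
#' ties); the running sum always returns to 0 at the end of the list.
#' The leading edge contains the hits at or before a positive extremum
#' (at or after a negative one).
#'
#' @param ranked A tibble `gene`, `score` (descending) from
#'   [correlation_ranking()] or [signal_to_noise_ranking()].
#' @param gene_set Character vector of member genes.
#' @param p_weight Score weighting exponent (0 = classic KS, default 1).
#' @return An object of class `lnc_gsea`: `set_name`, `es`,
#'   `running_sum` (tibble `position`, `gene`, `hit`, `value`),
#'   `leading_edge`.
#' @export
gsea_enrichment_score <- function(ranked, gene_set, p_weight = 1) {
  set_name <- attr(gene_set, "set_name") %||% "gene_set"
  hit <- ranked$gene %in% gene_set
  n <- nrow(ranked)
  n_hit <- sum(hit)
  if (n_hit == 0) {
    abort(paste0("gene set '", set_name,
                 "' has no members in the ranked list"))
  }
  w <- abs(ranked$score)^p_weight
  w_hit_total <- sum(w[hit])
  inc <- ifelse(hit,
                if (w_hit_total > 0) w / w_hit_total else 1 / n_hit,
                -1 / (n - n_hit))
  # when every hit has zero weight, fall back to equal hit increments
  if (w_hit_total == 0) inc[hit] <- 1 / n_hit
  rs <- cumsum(inc)
  i_ext <- which.max(abs(rs))
  es <- rs[i_ext]
  leading <- if (es >= 0) ranked$gene[hit & seq_len(n) <= i_ext]
             else ranked$gene[hit & seq_len(n) >= i_ext]
  structure(
    list(set_name = set_name, es = es,
         running_sum = tibble(position = seq_len(n), gene = ranked$gene,
                              hit = hit, value = rs),
         leading_edge = leading, p_weight = p_weight, n_hits = n_hit),
    class = "lnc_gsea"
  )
}

#' @export
print.lnc_gsea <- function(x, ...) {
  cat(sprintf("<lnc_gsea> %s: ES = %.3f (%d hits, %d leading edge)",
              x$set_name, x$es, x$n_hits, length(x$leading_edge)))
  if (!is.null(x$p_perm)) {
    cat(sprintf(", NES = %.3f, p_perm = %.4g (%d perms)",
                x$nes, x$p_perm, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' Permutation test for a gene set's enrichment score
#'
#' `phenotype` permutations shuffle the class labels, re-rank by
#' signal-to-noise and recompute the enrichment score; `gene_set`
#' permutations rescore random same-size sets on the fixed ranking.
#' The nominal p-value compares the observed score against the same-sign
#' permutation scores, `p_perm = (1 + #\{|ES_perm| >= |ES_obs|, same
#' sign\}) / (1 + #\{same-sign permutations\})` (the classic GSEA
#' convention, which makes null p-values uniform);
#' `NES = ES_obs / mean(|same-sign ES_perm|)`.
#'
#' @param dataset An [expression_dataset()] (phenotype scheme) or a ranked
#'   tibble (gene_set scheme).
#' @param gene_set Character vector of member genes.
#' @param n_perm Number of permutations (>= 100 for reported p-values).
#' @param scheme `"phenotype"` (default) or `"gene_set"`.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param p_weight Score weighting exponent.
#' @return An `lnc_gsea` object with `p_perm`, `nes`, `n_perm` and the
#'   permutation scores attached.
#' @export
gsea_permutation_test <- function(dataset, gene_set, n_perm = 1000,
                                  scheme = c("phenotype", "gene_set"),
                                  seed = 1L, p_weight = 1) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) {
    warn("fewer than 100 permutations: p_perm will be coarse")
  }
  set.seed(seed)
  if (scheme == "phenotype") {
    stopifnot(inherits(dataset, "expr_dataset"))
    if (ncol(dataset$matrix) < 6) abort("too few samples to permute labels")
    ranked <- signal_to_noise_ranking(dataset)
    obs <- gsea_enrichment_score(ranked, gene_set, p_weight)
    perm_es <- map_dbl(seq_len(n_perm), function(i) {
      perm <- dataset
      perm$labels <- sample(dataset$labels)
      r <- signal_to_noise_ranking(perm)
      gsea_enrichment_score(r, gene_set, p_weight)$es
    })
  } else {
    ranked <- dataset
    stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
    obs <- gsea_enrichment_score(ranked, gene_set, p_weight)
    size <- sum(ranked$gene %in% gene_set)
    perm_es <- map_dbl(seq_len(n_perm), function(i) {
      gsea_enrichment_score(ranked, sample(ranked$gene, size), p_weight)$es
    })
  }
  same_sign <- perm_es[sign(perm_es) == sign(obs$es) | perm_es == 0]
  obs$p_perm <- (1 + sum(abs(same_sign) >= abs(obs$es))) /
    (1 + length(same_sign))
  obs$nes <- if (length(same_sign) > 0 && mean(abs(same_sign)) > 0) {
    obs$es / mean(abs(same_sign))
  } else NA_real_
  obs$n_perm <- n_perm
  obs$perm_es <- perm_es
  obs$scheme <- scheme
  obs
}

#' Run GSEA over a gene-set collection
#'
#' Applies [gsea_permutation_test()] to every set with at least
#' `min_overlap` genes in the ranked list and adjusts the permutation
#' p-values across sets with Benjamini-Hochberg.
#'
#' @inheritParams gsea_permutation_test
#' @param gene_sets Named list of member vectors (see [read_gmt()]).
#' @param min_overlap Minimum set/list overlap to test a set.
#' @return A tibble: `set_name`, `size`, `es`, `nes`, `p_perm`, `p_adj`.
#' @export
gsea_collection <- function(dataset, gene_sets, n_perm = 1000,
                            scheme = c("phenotype", "gene_set"),
                            seed = 1L, p_weight = 1, min_overlap = 3) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  ranked <- if (inherits(dataset, "expr_dataset")) {
    signal_to_noise_ranking(dataset)
  } else dataset
  keep <- map_int(gene_sets, ~ sum(.x %in% ranked$gene)) >= min_overlap
  if (!any(keep)) abort("no gene set overlaps the ranked list")
  gene_sets <- gene_sets[keep]

  obs <- imap(gene_sets, function(set, nm) {
    attr(set, "set_name") <- nm
    gsea_enrichment_score(ranked, set, p_weight)
  })

  # permutation null shared across sets: permuted label rankings
  # (phenotype) or random same-size sets on the fixed ranking (gene_set)
  hit_mats <- map(gene_sets, ~ ranked$gene %in% .x)
  perm_es <- matrix(NA_real_, n_perm, length(gene_sets),
                    dimnames = list(NULL, names(gene_sets)))
  if (scheme == "phenotype") {
    stopifnot(inherits(dataset, "expr_dataset"))
    for (b in seq_len(n_perm)) {
      perm <- dataset
      perm$labels <- sample(dataset$labels)
      r <- signal_to_noise_ranking(perm)
      w <- abs(r$score)^p_weight
      for (j in seq_along(gene_sets)) {
        perm_es[b, j] <- es_fast(w, r$gene %in% gene_sets[[j]])
      }
    }
  } else {
    w <- abs(ranked$score)^p_weight
    sizes <- map_int(hit_mats, sum)
    for (b in seq_len(n_perm)) {
      for (j in seq_along(gene_sets)) {
        hit <- seq_len(nrow(ranked)) %in% sample.int(nrow(ranked), sizes[j])
        perm_es[b, j] <- es_fast(w, hit)
      }
    }
  }
  res <- imap(gene_sets, function(set, nm) {
    o <- obs[[nm]]
    pe <- perm_es[, nm]
    same <- pe[sign(pe) == sign(o$es) | pe == 0]
    tibble(
      set_name = nm, size = o$n_hits, es = o$es,
      nes = if (length(same) > 0 && mean(abs(same)) > 0)
        o$es / mean(abs(same)) else NA_real_,
      p_perm = (1 + sum(abs(same) >= abs(o$es))) / (1 + length(same))
    )
  }) %>% bind_rows()
  mutate(res, p_adj = bh_adjust(.data$p_perm)) %>%
    arrange(.data$p_perm, .data$set_name)
}
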