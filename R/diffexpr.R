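#' Construct an expression dataset
#'
#' Bundles a features x samples log2 matrix with per-sample tumor/normal
#' labels and a train/validation role.
#'
#' @param mat Numeric matrix, features in rows, samples in columns, with
#'   dimnames; no missing values.
#' @param labels Character vector (`"tumor"`/`"normal"`) per sample, or a
#'   tibble with `sample_id` and `label`.
#' @param dataset_id Dataset identifier.
#' @param role `"train"` or `"validation"`.
#' @return An object of class `expr_dataset`.
#' @export
expression_dataset <- function(mat, labels, dataset_id,
                               role = c("train", "validation")) {
  role <- match.arg(role)
  if (is.data.frame(labels)) labels <- setNames(labels$label, labels$sample_id)
  if (length(labels) != ncol(mat)) {
    abort("one label per sample column is required")
  }
  if (anyNA(mat)) abort("expression matrix contains missing values")
  if (!all(c("tumor", "normal") %in% labels)) {
    abort("both tumor and normal labels must be present")
  }
  structure(
    list(dataset_id = dataset_id, matrix = mat,
         labels = unname(as.character(labels)), role = role),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("<expr_dataset>", x$dataset_id, "[", x$role, "]:",
      nrow(x$matrix), "features x", ncol(x$matrix), "samples (",
      sum(x$labels == "tumor"), "tumor /", sum(x$labels == "normal"),
      "normal )\n")
  invisible(x)
}

#' Read an expression dataset from a GCT + CLS pair
#'
#' @param gct,cls File paths.
#' @inheritParams expression_dataset
#' @return An `expr_dataset`.
#' @export
read_expression_dataset <- function(gct, cls, dataset_id = basename(gct),
                                    role = "train") {
  expression_dataset(read_gct(gct)$matrix, read_cls(cls), dataset_id, role)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' a two-sided p-value. Degenerate zero-variance inputs are handled
#' without division errors: equal means give `t = 0, p = 1`; unequal
#' means give an infinite statistic and `p = 0`.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @return A one-row tibble: `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("need at least 2 values per group")
  if (!all(is.finite(c(x, y)))) abort("non-finite values in input")
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  delta <- mean(x) - mean(y)
  if (se2 == 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
    return(tibble(t = t, df = n1 + n2 - 2, p = if (delta == 0) 1 else 0))
  }
  t <- delta / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Newton inversion of the trigamma function (for the prior df estimate).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Variance-moderated t-tests for a two-class dataset
#'
#' Empirical-Bayes variance moderation in the GEO2R spirit: per-feature
#' pooled variances are shrunk toward a common prior,
#' `s2_tilde = (d0 * s0^2 + d * s2) / (d0 + d)`, with the prior degrees of
#' freedom `d0` and prior variance `s0^2` estimated by moments from the
#' spread of `log s2` across features. The moderated statistic uses
#' `s2_tilde` and `d0 + d` degrees of freedom; `d0 = 0` recovers the
#' ordinary pooled t, `d0 = Inf` the common-variance limit.
#'
#' @param dataset An [expression_dataset()].
#' @param d0 Optional forced prior degrees of freedom (default: estimated).
#' @return A tibble with one row per feature: `feature`, `mean_tumor`,
#'   `mean_normal`, `log2fc`, `t`, `df`, `p`, plus estimates `d0`, `s0_2`
#'   as attributes.
#' @export
moderated_t_test <- function(dataset, d0 = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  mat <- dataset$matrix
  if (nrow(mat) < 10) {
    abort("variance moderation needs at least 10 features")
  }
  tum <- dataset$labels == "tumor"
  nor <- dataset$labels == "normal"
  n1 <- sum(tum); n2 <- sum(nor)
  if (n1 < 2 || n2 < 2) abort("need at least 2 samples per class")
  m1 <- rowMeans(mat[, tum, drop = FALSE])
  m2 <- rowMeans(mat[, nor, drop = FALSE])
  v1 <- rowSums((mat[, tum, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, nor, drop = FALSE] - m2)^2) / (n2 - 1)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d

  e <- log(s2) - digamma(d / 2) + log(d / 2)
  e_ok <- e[is.finite(e)]
  var_e <- var(e_ok)
  excess <- var_e - trigamma(d / 2)
  if (is.null(d0)) {
    d0 <- if (is.finite(excess) && excess > 0) 2 * trigamma_inverse(excess) else Inf
  }
  s0_2 <- if (is.finite(d0) && d0 > 0) {
    exp(mean(e_ok) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    exp(mean(e_ok))
  }
  s2_tilde <- if (is.infinite(d0)) rep(s0_2, length(s2)) else {
    (d0 * s0_2 + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t <- ifelse(se == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
              (m1 - m2) / se)
  df <- d0 + d
  p <- ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df))
  out <- tibble(
    feature = rownames(mat), mean_tumor = unname(m1),
    mean_normal = unname(m2), log2fc = unname(m1 - m2), t = unname(t),
    df = df, p = unname(p)
  )
  attr(out, "prior") <- list(d0 = d0, s0_2 = s0_2)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjustment (`p_adj(i) = min_{j >= i} m p(j) / j`, clipped at
#' 1, original order restored). Missing or out-of-range values are an
#' error.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals)) abort("missing p-values are not allowed")
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Per-dataset differential expression
#'
#' Tests every feature tumor vs normal with the chosen statistic, adjusts
#' with Benjamini-Hochberg, and flags the significant subset at
#' `p_adj < alpha` (strict).
#'
#' @param dataset An [expression_dataset()].
#' @param method `"moderated"` (default) or `"welch"`.
#' @param alpha Adjusted-p significance threshold.
#' @return A tibble: `feature`, `mean_tumor`, `mean_normal`, `log2fc`,
#'   `t`, `df`, `p`, `p_adj`, `direction`, `significant`.
#' @export
dataset_de <- function(dataset, method = c("moderated", "welch"),
                       alpha = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "expr_dataset"))
  res <- if (method == "moderated") {
    moderated_t_test(dataset)
  } else {
    mat <- dataset$matrix
    tum <- dataset$labels == "tumor"
    nor <- dataset$labels == "normal"
    n1 <- sum(tum); n2 <- sum(nor)
    if (n1 < 2 || n2 < 2) abort("need at least 2 samples per class")
    m1 <- rowMeans(mat[, tum, drop = FALSE])
    m2 <- rowMeans(mat[, nor, drop = FALSE])
    v1 <- rowSums((mat[, tum, drop = FALSE] - m1)^2) / (n1 - 1)
    v2 <- rowSums((mat[, nor, drop = FALSE] - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    t <- ifelse(se2 == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
                (m1 - m2) / sqrt(se2))
    df <- ifelse(se2 == 0, n1 + n2 - 2,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
    p <- ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df))
    tibble(feature = rownames(mat), mean_tumor = unname(m1),
           mean_normal = unname(m2), log2fc = unname(m1 - m2),
           t = unname(t), df = unname(df), p = unname(p))
  }
  res %>%
    mutate(
      p_adj = bh_adjust(.data$p),
      direction = ifelse(.data$log2fc >= 0, "up", "down"),
      significant = .data$p_adj < alpha
    )
}

#' Cross-dataset training/validation signature
#'
#' A feature enters the signature iff it is significant
#' (`p_adj < alpha`) in every training dataset AND every validation
#' dataset (optionally relaxed via `min_support`), and — if
#' `require_direction` — its fold-change signs agree across all datasets.
#' Entries are ordered by combined evidence (sum of `log10 p_adj` across
#' datasets, ascending), ties broken by feature id.
#'
#' @param results_by_dataset Named list of [dataset_de()] tibbles.
#' @param roles Named character vector (`"train"`/`"validation"`) with the
#'   same names as `results_by_dataset`.
#' @param alpha Significance threshold on `p_adj` (strict).
#' @param require_direction Require a consistent fold-change sign.
#' @param min_support Optional relaxation: minimum number of significant
#'   datasets (must still include at least one of each role). Default:
#'   all datasets.
#' @return A tibble of signature entries: `feature`, `direction`,
#'   `n_support`, `combined`, plus `log2fc_<id>` and `p_adj_<id>` columns
#'   per dataset. Features missing from some dataset are excluded and
#'   counted in the `reconciliation` attribute.
#' @export
train_validate_signature <- function(results_by_dataset, roles,
                                     alpha = 0.01,
                                     require_direction = TRUE,
                                     min_support = NULL) {
  stopifnot(length(results_by_dataset) >= 2,
            setequal(names(results_by_dataset), names(roles)))
  if (!any(roles == "train") || !any(roles == "validation")) {
    abort("need at least one train and one validation dataset")
  }
  ids <- names(results_by_dataset)
  shared <- purrr::reduce(map(results_by_dataset, ~ .x$feature), intersect)
  n_dropped <- length(unique(unlist(map(results_by_dataset, ~ .x$feature)))) -
    length(shared)

  long <- imap(results_by_dataset, function(res, id) {
    res %>%
      filter(.data$feature %in% shared) %>%
      mutate(dataset_id = id, role = unname(roles[id])) %>%
      select("feature", "dataset_id", "role", "log2fc", "p_adj")
  }) %>% bind_rows()

  min_support <- min_support %||% length(ids)
  sig <- long %>%
    group_by(.data$feature) %>%
    summarise(
      n_support = sum(.data$p_adj < alpha),
      n_train_sig = sum(.data$p_adj < alpha & .data$role == "train"),
      n_val_sig = sum(.data$p_adj < alpha & .data$role == "validation"),
      consistent = length(unique(sign(.data$log2fc))) == 1,
      direction = ifelse(mean(.data$log2fc) >= 0, "up", "down"),
      combined = sum(log10(pmax(.data$p_adj, .Machine$double.xmin))),
      .groups = "drop"
    ) %>%
    filter(
      .data$n_support >= min_support,
      .data$n_train_sig >= 1, .data$n_val_sig >= 1,
      if (require_direction) .data$consistent else TRUE
    )
  if (min_support >= length(ids)) {
    # strict scheme: significant in every dataset of both roles
    sig <- filter(sig,
                  .data$n_train_sig == sum(roles == "train"),
                  .data$n_val_sig == sum(roles == "validation"))
  }
  wide <- long %>%
    tidyr::pivot_wider(id_cols = "feature",
                       names_from = "dataset_id",
                       values_from = c("log2fc", "p_adj"))
  out <- sig %>%
    select("feature", "direction", "n_support", "combined") %>%
    left_join(wide, by = "feature") %>%
    arrange(.data$combined, .data$feature)
  attr(out, "reconciliation") <- list(
    n_shared_features = length(shared),
    n_excluded_features = n_dropped
  )
  out
}

#' Extract the top of a signature
#'
#' First `k` entries by the signature's combined-evidence order,
#' deterministic ties by feature id. Asking for more entries than exist
#' returns everything with a warning.
#'
#' @param signature Tibble from [train_validate_signature()].
#' @param k Number of entries (default 100).
#' @return The truncated signature tibble.
#' @export
top_k <- function(signature, k = 100) {
  if (k > nrow(signature)) {
    warn(sprintf("k = %d exceeds the signature size (%d); returning all",
                 k, nrow(signature)))
    k <- nrow(signature)
  }
  signature %>%
    arrange(.data$combined, .data$feature) %>%
    slice(seq_len(k))
}

#' Collapse probe-set level signature entries to transcripts
#'
#' Maps probe-set features to transcript accessions through an annotation
#' table; when several probe sets map to one accession the entry with the
#' smallest combined evidence is kept.
#'
#' @param signature Probe-set level signature tibble.
#' @param annotation Annotation tibble (`probeset_id`, `accession`).
#' @return A transcript-level signature tibble whose `feature` column
#'   holds accessions (original probe set in `probeset_id`).
#' @export
collapse_to_transcripts <- function(signature, annotation) {
  signature %>%
    inner_join(select(annotation, "probeset_id", "accession"),
               by = c(feature = "probeset_id"),
               relationship = "many-to-many") %>%
    mutate(probeset_id = .data$feature, feature = .data$accession) %>%
    select(-"accession") %>%
    group_by(.data$feature) %>%
    arrange(.data$combined, .data$probeset_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$combined, .data$feature)
}

#' Intersect a signature with an external id list
#'
#' Ids are normalized (upper case, RefSeq version stripped) before
#' matching; gene-symbol aliases can be supplied so that external lists
#' using symbols still match accession-keyed entries.
#'
#' @param signature Signature tibble.
#' @param external_ids Character vector of external ids.
#' @param aliases Optional named character vector mapping `feature` to an
#'   alias (e.g. gene symbol) also allowed to match.
#' @return The subset of signature entries present in the external list.
#' @export
intersect_signature <- function(signature, external_ids, aliases = NULL) {
  norm <- function(x) toupper(strip_version(x))
  if (length(external_ids) == 0) {
    warn("empty external id list; returning an empty intersection")
    return(signature[0, ])
  }
  ext <- norm(external_ids)
  keep <- norm(signature$feature) %in% ext
  if (!is.null(aliases)) {
    al <- norm(unname(aliases[signature$feature]))
    keep <- keep | (!is.na(al) & al %in% ext)
  }
  signature[keep, ]
}

#' Tally signature entries by chromosome
#'
#' @param signature Signature tibble (features are transcript accessions).
#' @param transcripts Transcript tibble with `accession` and `chrom`.
#' @return A tibble `chrom`, `n_up`, `n_down`; entries without a located
#'   transcript are tallied under `chrom = "unlocated"`. Row sums add up
#'   to the signature size.
#' @export
tally_by_chromosome <- function(signature, transcripts) {
  signature %>%
    left_join(select(transcripts, "accession", "chrom"),
              by = c(feature = "accession")) %>%
    mutate(chrom = ifelse(is.na(.data$chrom), "unlocated", .data$chrom)) %>%
    count(.data$chrom, .data$direction) %>%
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L) %>%
    rename_direction_counts() %>%
    arrange(.data$chrom)
}

#' Tally signature entries by lncRNA biotype
#'
#' @param signature Signature tibble.
#' @param transcripts Transcript tibble with `accession` and `biotype`.
#' @return A tibble `biotype`, `n_up`, `n_down` (missing biotype tallied
#'   as `"unknown"`).
#' @export
tally_by_biotype <- function(signature, transcripts) {
  signature %>%
    left_join(select(transcripts, "accession", "biotype"),
              by = c(feature = "accession")) %>%
    mutate(biotype = ifelse(is.na(.data$biotype), "unknown", .data$biotype)) %>%
    count(.data$biotype, .data$direction) %>%
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L) %>%
    rename_direction_counts() %>%
    arrange(desc(.data$n_up + .data$n_down))
}

rename_direction_counts <- function(tab) {
  if (!"up" %in% names(tab)) tab$up <- 0L
  if (!"down" %in% names(tab)) tab$down <- 0L
  rename(tab, n_up = "up", n_down = "down")
}
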