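#' Agglomerative hierarchical clustering of expression rows
#'
#' Clusters the rows of a matrix with correlation (`1 - Pearson r`) or
#' Euclidean distance and average or complete linkage — the common
#' defaults of classic expression-clustering tools. Leaf order is
#' deterministic for a given input order.
#'
#' @param mat Numeric matrix; rows are the items clustered.
#' @param distance `"one_minus_pearson"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An object of class `lnc_hclust`: the `stats::hclust` tree,
#'   `order` (leaf order), `labels`, and the choices made.
#' @export
hierarchical_cluster <- function(mat,
                                 distance = c("one_minus_pearson", "euclidean"),
                                 linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (nrow(mat) < 2) abort("need at least 2 items to cluster")
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  d <- if (distance == "one_minus_pearson") {
    sds <- apply(mat, 1, sd)
    if (any(sds == 0)) {
      abort(paste0("constant rows are incompatible with correlation distance: ",
                   paste(head(rownames(mat)[sds == 0], 5), collapse = ", ")))
    }
    as.dist(1 - cor(t(mat)))
  } else {
    dist(mat)
  }
  hc <- hclust(d, method = linkage)
  structure(
    list(hclust = hc, order = hc$order, labels = rownames(mat),
         distance = distance, linkage = linkage),
    class = "lnc_hclust"
  )
}

#' @export
print.lnc_hclust <- function(x, ...) {
  cat("<lnc_hclust>", length(x$labels), "items,", x$distance, "distance,",
      x$linkage, "linkage\n")
  invisible(x)
}

#' Cut a hierarchical clustering into k groups
#'
#' @param clustering An [hierarchical_cluster()] result.
#' @param k Number of clusters.
#' @return A tibble `item`, `cluster`.
#' @export
cut_clusters <- function(clustering, k) {
  cl <- cutree(clustering$hclust, k = k)
  tibble(item = names(cl), cluster = unname(cl))
}
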