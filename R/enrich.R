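#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric test of a query gene list against each set
#' of a collection, within a stated gene universe; BH adjustment across
#' sets. This is a deliberately simple over-representation analysis for
#' annotating e.g. the coexpressed-gene list of a marker lncRNA.
#'
#' @param query_genes Character vector; must be contained in `universe`.
#' @param gene_sets Named list of member vectors (see [read_gmt()]); each
#'   set is intersected with the universe.
#' @param universe Character vector: the background gene universe.
#' @return A tibble per set: `set_name`, `k` (query hits in set), `K`
#'   (set size in universe), `n` (query size), `N` (universe size), `p`,
#'   `p_adj`, ordered by `p`.
#' @export
hypergeometric_enrichment <- function(query_genes, gene_sets, universe) {
  if (length(universe) == 0) abort("empty gene universe")
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe)) {
    abort("query genes must be a subset of the universe")
  }
  n <- length(query_genes)
  N <- length(universe)
  res <- imap(gene_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    k <- length(intersect(query_genes, set))
    K <- length(set)
    tibble(set_name = nm, k = k, K = K, n = n, N = N,
           p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }) %>% bind_rows()
  res %>%
    mutate(p_adj = bh_adjust(.data$p)) %>%
    arrange(.data$p, .data$set_name)
}

# strand-aware transcription start site of BED records
tss_position <- function(bed) {
  ifelse(bed$strand == "-", bed$end - 1L, bed$start)
}

#' Signed distance from each lncRNA TSS to the nearest coding TSS
#'
#' For every lncRNA interval, finds the coding transcription start site
#' (strand-aware: `start` on `+`, `end - 1` on `-`) with the smallest
#' absolute distance to the lncRNA's own TSS on the same chromosome. The
#' sign is taken relative to the coding gene's strand: negative when the
#' lncRNA TSS lies upstream of the coding TSS, positive downstream,
#' 0 on exact overlap. lncRNAs on chromosomes absent from the coding set
#' get `NA` distance and a flag.
#'
#' @param lnc_intervals,coding_intervals BED-style tibbles (`chrom`,
#'   `start`, `end`, `name`, `strand`; 0-based half-open).
#' @return A tibble: `name`, `chrom`, `tss`, `nearest_coding`,
#'   `distance`, `no_coding_on_chrom`.
#' @export
distance_to_nearest_tss <- function(lnc_intervals, coding_intervals) {
  lnc <- mutate(as_tibble(lnc_intervals), tss = tss_position(lnc_intervals))
  cod <- mutate(as_tibble(coding_intervals),
                tss = tss_position(coding_intervals))
  by_chrom <- split(cod, cod$chrom)
  rows <- pmap(list(lnc$name, lnc$chrom, lnc$tss), function(nm, chr, tss) {
    cands <- by_chrom[[chr]]
    if (is.null(cands) || nrow(cands) == 0) {
      return(tibble(name = nm, chrom = chr, tss = tss,
                    nearest_coding = NA_character_, distance = NA_real_,
                    no_coding_on_chrom = TRUE))
    }
    d_abs <- abs(tss - cands$tss)
    i <- which.min(d_abs)  # earliest record wins exact ties
    signed <- if (cands$strand[i] == "-") cands$tss[i] - tss
              else tss - cands$tss[i]
    tibble(name = nm, chrom = chr, tss = tss,
           nearest_coding = cands$name[i], distance = signed,
           no_coding_on_chrom = FALSE)
  })
  bind_rows(rows)
}
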