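#' Simulate gene sets with planted enrichment
#'
#' Planted-enriched sets sample their members preferentially from the top
#' of the true association ranking (by default without replacement from
#' its top 5%, falling back to the top decile when a set is larger than
#' that slice); null sets sample uniformly from the whole universe.
#'
#' @param coding_symbols Character vector: the gene universe.
#' @param ranking_truth Character vector of `coding_symbols` ordered by
#'   true association strength, strongest first (e.g. the planted
#'   coexpression module followed by the rest).
#' @param config A [sim_config()] object.
#' @param top_fraction Fraction of the ranking that enriched sets draw
#'   from.
#' @return A list with `sets` (named list of member vectors) and
#'   `enriched` (character vector of planted-enriched set names).
#' @export
simulate_gene_sets <- function(coding_symbols, ranking_truth, config,
                               top_fraction = 0.05) {
  cfg <- validate_sim_config(config)
  stopifnot(all(ranking_truth %in% coding_symbols))
  set.seed(stage_seed(cfg, "genesets"))

  n_enriched <- as.integer(round(cfg$enriched_fraction * cfg$n_gene_sets))
  sizes <- sample(cfg$set_size_range[1]:cfg$set_size_range[2],
                  cfg$n_gene_sets, replace = TRUE)
  if (any(sizes > length(coding_symbols))) {
    abort("gene-set sizes exceed the size of the gene universe")
  }
  nm <- sprintf("SET_%03d", seq_len(cfg$n_gene_sets))
  enriched <- nm[seq_len(n_enriched)]

  sets <- map(seq_len(cfg$n_gene_sets), function(i) {
    if (i <= n_enriched) {
      top_n <- max(sizes[i], ceiling(top_fraction * length(ranking_truth)))
      sample(head(ranking_truth, top_n), sizes[i])
    } else {
      sample(coding_symbols, sizes[i])
    }
  })
  list(sets = setNames(sets, nm), enriched = enriched)
}
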