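# Small fixture builders shared across tests.

fixture_transcripts <- function() {
  tibble::tibble(
    accession = c("NM_000546", "NR_152715", "XR_000001", "NR_000200"),
    sequence = c(strrep("ACGT", 500), strrep("GATC", 654),
                 substr(strrep("TTAA", 38), 1, 150),
                 strrep("CCGG", 50)),
    biotype = c("protein_coding", "antisense", "lincRNA", "lincRNA"),
    chrom = c("chr17", "chr1", "chr2", "chr3"),
    strand = c("+", "-", "+", "+"),
    start = c(1000L, 5000L, 9000L, 12000L),
    gene_symbol = c("TP53", "BLACAT1", "LNC1", "LNC2")
  ) |>
    dplyr::mutate(length = nchar(sequence), end = start + length)
}

# n probes planted on a transcript at a given per-probe identity
fixture_probeset <- function(target_seq, n_probes = 11, identity = 1.0,
                             probe_len = 25, seed = 1,
                             probeset_id = "PS1_at") {
  set.seed(seed)
  n_sub <- round((1 - identity) * probe_len)
  seqs <- vapply(seq_len(n_probes), function(i) {
    off <- sample.int(nchar(target_seq) - probe_len + 1, 1)
    chars <- strsplit(substr(target_seq, off, off + probe_len - 1), "")[[1]]
    if (n_sub > 0) {
      pos <- sample.int(probe_len, n_sub)
      chars[pos] <- vapply(chars[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    paste(chars, collapse = "")
  }, character(1))
  tibble::tibble(
    probeset_id = probeset_id,
    probe_id = sprintf("%s:%02d", probeset_id, seq_len(n_probes)),
    sequence = seqs
  )
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a two-class dataset with optional planted shifts on given features
fixture_dataset <- function(n_features = 200, n_tumor = 10, n_normal = 10,
                            de_features = integer(0), effect = 1.5,
                            sigma = 0.7, seed = 1, id = "DS1",
                            role = "train") {
  set.seed(seed)
  feats <- sprintf("F%04d", seq_len(n_features))
  mat <- matrix(rnorm(n_features * (n_tumor + n_normal), 7, sigma),
                n_features, n_tumor + n_normal,
                dimnames = list(feats, sprintf("S%03d",
                                               seq_len(n_tumor + n_normal))))
  labels <- c(rep("tumor", n_tumor), rep("normal", n_normal))
  if (length(de_features)) {
    mat[de_features, labels == "tumor"] <-
      mat[de_features, labels == "tumor"] + effect
  }
  expression_dataset(mat, labels, id, role)
}
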