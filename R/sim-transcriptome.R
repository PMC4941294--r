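#' Simulate a RefSeq-style transcript catalog
#'
#' Generates coding (NM_) and noncoding (NR_/XR_) transcripts with
#' uniform-random sequences, non-overlapping genomic intervals on
#' chr1..chr22/chrX, strands, gene symbols and lncRNA biotypes. A
#' configurable fraction of noncoding transcripts is generated at or below
#' 200 nt so the downstream length filter has something to remove.
#'
#' @param config A [sim_config()] object.
#' @return A tibble of transcript records with columns `accession`,
#'   `sequence`, `length`, `biotype`, `chrom`, `strand`, `start`, `end`,
#'   `gene_symbol` (coordinates 0-based half-open).
#' @export
simulate_transcriptome <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg, "transcriptome"))

  n_lnc <- cfg$n_lnc
  n_short <- as.integer(round(cfg$short_fraction * n_lnc))
  lnc_len <- c(
    if (n_short > 0) sample(50:200, n_short, replace = TRUE),
    if (n_lnc - n_short > 0)
      sample(max(201L, cfg$lnc_length_range[1]):cfg$lnc_length_range[2],
             n_lnc - n_short, replace = TRUE)
  )
  lnc_len <- sample(lnc_len)  # interleave short and long records
  coding_len <- if (cfg$n_coding > 0)
    sample(500:4000, cfg$n_coding, replace = TRUE) else integer(0)

  n_xr <- n_lnc %/% 3  # mix of curated (NR_) and model (XR_) accessions
  lnc_acc <- c(sprintf("NR_%06d", seq_len(n_lnc - n_xr)),
               sprintf("XR_%06d", seq_len(n_xr)))
  coding_acc <- sprintf("NM_%06d", seq_len(cfg$n_coding))

  biotypes <- c("antisense", "lincRNA", "processed_transcript",
                "sense_intronic")
  records <- tibble(
    accession = c(coding_acc, lnc_acc),
    length = c(coding_len, lnc_len),
    biotype = c(rep("protein_coding", cfg$n_coding),
                sample(biotypes, n_lnc, replace = TRUE,
                       prob = c(0.35, 0.35, 0.2, 0.1))),
    gene_symbol = c(sprintf("GENE%04d", seq_len(cfg$n_coding)),
                    sprintf("LNC%04d", seq_len(n_lnc)))
  )
  n <- nrow(records)
  records <- records %>%
    mutate(
      sequence = random_dna(.data$length),
      chrom = sample(paste0("chr", c(1:22, "X")), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE)
    ) %>%
    group_by(.data$chrom) %>%
    # lay transcripts end to end with random gaps: intervals never overlap
    mutate(
      start = cumsum(c(0L, head(.data$length, -1))) +
        cumsum(sample(1000:10000, n(), replace = TRUE)),
      end = .data$start + .data$length
    ) %>%
    ungroup() %>%
    select("accession", "sequence", "length", "biotype", "chrom",
           "strand", "start", "end", "gene_symbol") %>%
    arrange(match(.data$accession, c(coding_acc, lnc_acc)))
  records
}

#' Write the transcript catalog as FASTA + BED6 + metadata TSV
#'
#' @param transcripts Tibble from [simulate_transcriptome()].
#' @param dir Output directory.
#' @return Named character vector of the written paths.
#' @export
write_transcriptome_files <- function(transcripts, dir) {
  paths <- c(fasta = file.path(dir, "transcripts.fa"),
             bed = file.path(dir, "transcripts.bed"),
             tsv = file.path(dir, "transcripts.tsv"))
  write_transcript_fasta(transcripts, paths[["fasta"]])
  transcripts %>%
    select("chrom", "start", "end") %>%
    mutate(name = transcripts$accession, score = 0,
           strand = transcripts$strand) %>%
    write_bed(paths[["bed"]])
  transcripts %>%
    select("accession", "biotype", "gene_symbol", "length", "chrom",
           "strand", "start", "end") %>%
    readr::write_tsv(paths[["tsv"]], progress = FALSE)
  invisible(paths)
}
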