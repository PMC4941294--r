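#' Filter a transcript catalog down to long noncoding transcripts
#'
#' Keeps records whose accession carries an `NR_` or `XR_` prefix and
#' whose length is strictly greater than `min_length` (the conventional
#' lncRNA definition: longer than 200 nt). Versioned accessions
#' (`NR_123456.2`) are accepted; records without a recognizable
#' `XX_`-style prefix are skipped with a warning.
#'
#' @param records Transcript tibble (see [read_transcript_fasta()] /
#'   [simulate_transcriptome()]); needs `accession` and `length` columns.
#' @param min_length Minimum length in nt, exclusive (default 200).
#' @return The filtered tibble, input order preserved.
#' @export
filter_lncrna_transcripts <- function(records, min_length = 200) {
  if (nrow(records) == 0) return(records)
  prefix_ok <- grepl("^[A-Za-z]+_[0-9]", records$accession)
  if (any(!prefix_ok)) {
    warn(paste0(sum(!prefix_ok),
                " record(s) without a recognizable accession prefix were skipped"))
  }
  records %>%
    filter(prefix_ok,
           grepl("^(NR|XR)_", .data$accession),
           .data$length > min_length)
}

# reverse complement (vectorized, tolerates N)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Best ungapped placement of a probe on a transcript
#'
#' Scans every offset on the forward strand and on the reverse complement
#' of the transcript and reports the placement with the highest identity
#' (matching bases / probe length). Ties are broken by the forward strand
#' first, then the smallest offset. `N` never matches.
#'
#' @param probe_seq Probe sequence (string over A/C/G/T).
#' @param transcript_seq Transcript sequence; must be at least as long as
#'   the probe.
#' @param both_strands Search the reverse complement as well (default
#'   `TRUE`).
#' @param transcript_rc Optional precomputed reverse complement of
#'   `transcript_seq` (an optimization for repeated calls; derived
#'   automatically when absent).
#' @return A one-row tibble: `identity`, `offset` (0-based, on the strand
#'   searched), `strand` (`+`/`-`), `gapped = FALSE`.
#' @export
best_ungapped_alignment <- function(probe_seq, transcript_seq,
                                    both_strands = TRUE,
                                    transcript_rc = NULL) {
  l <- nchar(probe_seq)
  if (l > nchar(transcript_seq)) {
    abort(sprintf("probe (%d nt) is longer than the transcript (%d nt)",
                  l, nchar(transcript_seq)))
  }
  fwd <- hamming_scan_cpp(probe_seq, transcript_seq)
  best <- list(mm = fwd$mismatches, offset = fwd$offset, strand = "+")
  if (both_strands && best$mm > 0) {
    rev <- hamming_scan_cpp(probe_seq, transcript_rc %||% revcomp(transcript_seq))
    if (rev$mismatches < best$mm) {
      best <- list(mm = rev$mismatches, offset = rev$offset, strand = "-")
    }
  }
  tibble(identity = (l - best$mm) / l, offset = as.integer(best$offset),
         strand = best$strand, gapped = FALSE)
}

#' Best local (gapped) alignment of a probe on a transcript
#'
#' Smith-Waterman local alignment with linear gap costs; identity is the
#' number of aligned matching bases divided by the probe length. Because a
#' local alignment may trim probe ends, the full-length ungapped placement
#' is always evaluated as a candidate too, so the reported identity is
#' never below the ungapped identity for the same pair. Traceback is
#' deterministic (diagonal preferred over a gap in the transcript over a
#' gap in the probe). An all-mismatch pair yields the empty local
#' alignment and identity 0.
#'
#' @inheritParams best_ungapped_alignment
#' @param match,mismatch,gap Scoring parameters; the gap penalty must not
#'   be milder than the mismatch penalty.
#' @return A one-row tibble: `identity`, `offset`, `strand`,
#'   `gapped = TRUE`, `score`.
#' @export
best_gapped_alignment <- function(probe_seq, transcript_seq,
                                  match = 1, mismatch = -1, gap = -2,
                                  both_strands = TRUE) {
  l <- nchar(probe_seq)
  if (l > nchar(transcript_seq)) {
    abort(sprintf("probe (%d nt) is longer than the transcript (%d nt)",
                  l, nchar(transcript_seq)))
  }
  if (!all(is.finite(c(match, mismatch, gap)))) {
    abort("scoring parameters must be finite")
  }
  if (gap > mismatch) abort("gap penalty must be <= mismatch penalty")
  fwd <- sw_align_cpp(probe_seq, transcript_seq, match, mismatch, gap)
  best <- c(fwd, strand = "+")
  if (both_strands) {
    rev <- sw_align_cpp(probe_seq, revcomp(transcript_seq),
                        match, mismatch, gap)
    if (rev$score > best$score) best <- c(rev, strand = "-")
  }
  ungapped <- best_ungapped_alignment(probe_seq, transcript_seq,
                                      both_strands = both_strands)
  if (ungapped$identity * l > best$matches) {
    return(mutate(ungapped, gapped = TRUE, score = best$score))
  }
  tibble(identity = best$matches / l, offset = as.integer(best$offset),
         strand = best$strand, gapped = TRUE, score = best$score)
}

# Best identity of every probe in a set against one transcript sequence.
# transcript_rc, precomputed once per transcript, avoids re-deriving the
# reverse complement for every probe.
probe_identities <- function(probe_seqs, transcript_seq, gapped = FALSE,
                             both_strands = TRUE, transcript_rc = NULL) {
  if (both_strands) transcript_rc <- transcript_rc %||% revcomp(transcript_seq)
  if (gapped) {
    return(map_dbl(probe_seqs,
                   ~ best_gapped_alignment(.x, transcript_seq,
                                           both_strands = both_strands)$identity))
  }
  map_dbl(probe_seqs, function(p) {
    l <- nchar(p)
    mm <- hamming_scan_cpp(p, transcript_seq)$mismatches
    if (both_strands && mm > 0) {
      mm <- min(mm, hamming_scan_cpp(p, transcript_rc)$mismatches)
    }
    (l - mm) / l
  })
}

#' Evaluate one probe set against one transcript
#'
#' Implements the set-level match rule used for reannotation: in
#' `probe_fraction` mode a probe matches iff its best identity is at least
#' `probe_identity_min`, and the set matches iff the fraction of matching
#' probes is at least `set_fraction_min` (the "at least 90% of the
#' sequences of a probe set" reading). In `base_fraction` mode the set
#' matches iff the mean best identity across all probes (equivalently,
#' total matched bases over total probe bases) is at least
#' `set_fraction_min`. Non-matching sets return zero rows ("abandoned").
#'
#' @param probeset Tibble with `probeset_id`, `probe_id`, `sequence` rows
#'   of one probe set.
#' @param transcript One transcript record (one-row data frame or list
#'   with `accession` and `sequence`).
#' @param probe_identity_min Per-probe identity threshold (inclusive).
#' @param set_fraction_min Set-level threshold (inclusive).
#' @param mode `"probe_fraction"` (default) or `"base_fraction"`.
#' @param gapped Use the gapped aligner for per-probe identities.
#' @return A zero- or one-row tibble with `probeset_id`, `accession`,
#'   `probe_match_fraction`, `mean_identity`, `source`.
#' @export
match_probeset <- function(probeset, transcript,
                           probe_identity_min = 0.90,
                           set_fraction_min = 0.90,
                           mode = c("probe_fraction", "base_fraction"),
                           gapped = FALSE) {
  mode <- match.arg(mode)
  if (nrow(probeset) == 0) abort("empty probe set")
  if (any(c(probe_identity_min, set_fraction_min) < 0) ||
      any(c(probe_identity_min, set_fraction_min) > 1)) {
    abort("thresholds must lie in [0, 1]")
  }
  ids <- probe_identities(probeset$sequence, transcript$sequence,
                          gapped = gapped,
                          transcript_rc = transcript$rc %||% NULL)
  probe_frac <- mean(ids >= probe_identity_min)
  mean_id <- mean(ids)
  ok <- if (mode == "probe_fraction") probe_frac >= set_fraction_min
        else mean_id >= set_fraction_min
  if (!ok) {
    return(tibble(probeset_id = character(), accession = character(),
                  probe_match_fraction = double(), mean_identity = double(),
                  source = character()))
  }
  tibble(probeset_id = probeset$probeset_id[1],
         accession = transcript$accession,
         probe_match_fraction = probe_frac,
         mean_identity = mean_id,
         source = "sequence_match")
}

# Lossless k-mer seed prefilter for probe_fraction mode: a probe within
# `max_mm` substitutions of a transcript window must share an exact k-mer
# with the transcript for k = floor(l / (max_mm + 1)) (pigeonhole), on one
# of the two strands. Returns candidate (probeset_id, accession) pairs.
seed_candidates <- function(probes, transcripts, probe_identity_min) {
  l <- nchar(probes$sequence[1])
  max_mm <- floor((1 - probe_identity_min) * l)
  k <- max(4L, floor(l / (max_mm + 1)))
  kmers_of <- function(seqs) {
    map(seqs, function(s) {
      n <- nchar(s) - k + 1L
      if (n < 1) character(0) else substring(s, 1:n, k:(k + n - 1L))
    })
  }
  probe_k <- tibble(probeset_id = probes$probeset_id,
                    kmer = kmers_of(probes$sequence)) %>%
    tidyr::unnest("kmer") %>% distinct()
  tx_seqs <- map2(transcripts$sequence, revcomp(transcripts$sequence),
                  ~ c(.x, .y))
  tx_k <- tibble(accession = transcripts$accession,
                 kmer = map(tx_seqs, ~ unique(unlist(kmers_of(.x))))) %>%
    tidyr::unnest("kmer")
  inner_join(probe_k, tx_k, by = "kmer", relationship = "many-to-many") %>%
    distinct(.data$probeset_id, .data$accession)
}

#' Build the probe-set to transcript annotation table
#'
#' Evaluates probe sets against transcripts under the set-level match rule
#' and returns the retained rows. A probe set mapping to more than one
#' distinct gene symbol is flagged `ambiguous` (and optionally dropped).
#' With `prefilter = TRUE` (probe_fraction mode only) a lossless k-mer
#' seed prefilter skips transcript pairs that cannot contain any matching
#' probe; retained rows are identical to the all-pairs evaluation.
#'
#' @param probesets Probe tibble (`probeset_id`, `probe_id`, `sequence`).
#' @param transcripts Transcript tibble; apply
#'   [filter_lncrna_transcripts()] first for the lncRNA pipeline.
#' @param gene_symbols Optional named vector mapping accession to gene
#'   symbol (taken from a `gene_symbol` column of `transcripts` if
#'   present).
#' @param drop_ambiguous Drop rows of probe sets that map to more than one
#'   gene symbol.
#' @param prefilter Use the k-mer seed prefilter.
#' @inheritParams match_probeset
#' @return An annotation tibble: `probeset_id`, `accession`,
#'   `probe_match_fraction`, `mean_identity`, `source`, `ambiguous`,
#'   ordered by (`probeset_id`, `accession`). The number of probe sets
#'   evaluated and retained is attached as attribute `summary`.
#' @export
build_annotation_table <- function(probesets, transcripts,
                                   probe_identity_min = 0.90,
                                   set_fraction_min = 0.90,
                                   mode = c("probe_fraction", "base_fraction"),
                                   gapped = FALSE,
                                   drop_ambiguous = FALSE,
                                   prefilter = FALSE,
                                   gene_symbols = NULL) {
  mode <- match.arg(mode)
  empty <- tibble(probeset_id = character(), accession = character(),
                  probe_match_fraction = double(), mean_identity = double(),
                  source = character(), ambiguous = logical())
  if (nrow(transcripts) == 0) {
    warn("no transcripts to annotate against; returning an empty table")
    return(empty)
  }
  if (is.null(gene_symbols) && "gene_symbol" %in% names(transcripts)) {
    gene_symbols <- setNames(transcripts$gene_symbol, transcripts$accession)
  }
  transcripts <- transcripts[!duplicated(transcripts$accession), ]
  transcripts <- mutate(transcripts, rc = revcomp(.data$sequence))
  set_of <- factor(probesets$probeset_id,
                   levels = unique(probesets$probeset_id))
  set_ids <- levels(set_of)
  probe_len <- nchar(probesets$sequence)

  candidates <- if (prefilter && mode == "probe_fraction") {
    seed_candidates(probesets, transcripts, probe_identity_min)
  } else NULL

  rows <- map(seq_len(nrow(transcripts)), function(t) {
    acc <- transcripts$accession[t]
    keep_sets <- if (is.null(candidates)) set_ids else {
      candidates$probeset_id[candidates$accession == acc]
    }
    if (length(keep_sets) == 0) return(NULL)
    idx <- which(set_of %in% keep_sets)
    if (gapped) {
      ident <- probe_identities(probesets$sequence[idx],
                                transcripts$sequence[t], gapped = TRUE)
    } else {
      mm <- multi_hamming_scan_cpp(probesets$sequence[idx],
                                   transcripts$sequence[t],
                                   transcripts$rc[t])
      ident <- (probe_len[idx] - mm) / probe_len[idx]
    }
    ident[is.na(ident)] <- 0  # probe longer than this transcript
    grp <- droplevels(set_of[idx])
    probe_frac <- tapply(ident >= probe_identity_min, grp, mean)
    mean_id <- tapply(ident, grp, mean)
    ok <- if (mode == "probe_fraction") probe_frac >= set_fraction_min
          else mean_id >= set_fraction_min
    ok[is.na(ok)] <- FALSE
    if (!any(ok)) return(NULL)
    tibble(probeset_id = names(probe_frac)[ok], accession = acc,
           probe_match_fraction = unname(probe_frac[ok]),
           mean_identity = unname(mean_id[ok]),
           source = "sequence_match")
  })
  tab <- bind_rows(c(list(empty), rows))

  if (nrow(tab) > 0 && !is.null(gene_symbols)) {
    tab <- tab %>%
      mutate(symbol = unname(gene_symbols[.data$accession])) %>%
      group_by(.data$probeset_id) %>%
      mutate(ambiguous = dplyr::n_distinct(.data$symbol, na.rm = TRUE) > 1) %>%
      ungroup() %>%
      select(-"symbol")
  } else {
    tab$ambiguous <- rep(FALSE, nrow(tab))
  }
  if (drop_ambiguous) tab <- filter(tab, !.data$ambiguous)
  tab <- arrange(tab, .data$probeset_id, .data$accession)
  attr(tab, "summary") <- list(
    n_probesets = length(set_ids),
    n_retained_probesets = dplyr::n_distinct(tab$probeset_id),
    n_rows = nrow(tab),
    n_ambiguous = dplyr::n_distinct(tab$probeset_id[tab$ambiguous])
  )
  tab
}

#' Merge a sequence-derived annotation table with an external one
#'
#' Takes the union of rows. A (probeset, accession) pair present in both
#' keeps the primary table's numeric fields and gets `source = "both"`;
#' conflicting transcript assignments for one probe set are all retained
#' with their provenance. Output is ordered by (`probeset_id`,
#' `accession`).
#'
#' @param primary Annotation tibble from [build_annotation_table()].
#' @param external Annotation tibble; needs at least `probeset_id` and
#'   `accession` (numeric columns are filled with `NA` if absent; unknown
#'   columns are an error).
#' @return The merged annotation tibble.
#' @export
merge_annotation_tables <- function(primary, external) {
  schema <- c("probeset_id", "accession", "probe_match_fraction",
              "mean_identity", "source", "ambiguous", "gene_symbol")
  if (!all(c("probeset_id", "accession") %in% names(external))) {
    abort("external table must contain probeset_id and accession")
  }
  unknown <- setdiff(names(external), schema)
  if (length(unknown)) {
    abort(paste0("unknown external annotation column(s): ",
                 paste(unknown, collapse = ", "),
                 "; expected a subset of: ", paste(schema, collapse = ", ")))
  }
  external <- external %>%
    mutate(accession = strip_version(.data$accession),
           probe_match_fraction =
             if ("probe_match_fraction" %in% names(external))
               .data$probe_match_fraction else NA_real_,
           mean_identity = if ("mean_identity" %in% names(external))
             .data$mean_identity else NA_real_,
           ambiguous = if ("ambiguous" %in% names(external))
             .data$ambiguous else FALSE,
           source = "external") %>%
    select("probeset_id", "accession", "probe_match_fraction",
           "mean_identity", "source", "ambiguous")
  primary <- mutate(primary, accession = strip_version(.data$accession))
  key <- function(x) paste(x$probeset_id, x$accession)
  in_both <- key(primary) %in% key(external)
  out <- bind_rows(
    mutate(primary, source = ifelse(in_both, "both", .data$source)),
    filter(external, !key(external) %in% key(primary))
  )
  arrange(out, .data$probeset_id, .data$accession)
}

# drop a trailing ".N" version from RefSeq-style accessions
strip_version <- function(x) sub("\\.[0-9]+$", "", x)

#' Write an annotation table and its summary
#'
#' @param annotation Annotation tibble.
#' @param path Output TSV path; a JSON summary (retained / ambiguous
#'   counts) is written next to it with extension `.summary.json`.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path, progress = FALSE)
  s <- attr(annotation, "summary") %||% list(n_rows = nrow(annotation))
  jsonlite::write_json(s, paste0(sub("\\.tsv$", "", path), ".summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
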