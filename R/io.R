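#' Read and write transcript FASTA
#'
#' Transcripts are represented as a tibble with one row per transcript
#' (accession, sequence, length). [read_transcript_fasta()] parses a FASTA
#' file via Biostrings; [write_transcript_fasta()] writes one.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `sequence`, `length`.
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(
    accession = sub("\\s.*$", "", names(seqs)),
    sequence  = unname(as.character(seqs)),
    length    = Biostrings::width(seqs)
  )
}

#' @param transcripts A data frame with `accession` and `sequence` columns.
#' @rdname read_transcript_fasta
#' @export
write_transcript_fasta <- function(transcripts, path) {
  stopifnot(all(c("accession", "sequence") %in% names(transcripts)))
  seqs <- Biostrings::DNAStringSet(transcripts$sequence)
  names(seqs) <- transcripts$accession
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read and write BED6 interval files
#'
#' BED uses 0-based half-open coordinates, which is also the package's
#' internal convention. Reading goes through rtracklayer and converts the
#' returned GRanges back to 0-based starts.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (start 0-based, end exclusive).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,
    end    = GenomicRanges::end(gr),
    name   = gr$name %||% as.character(seq_along(gr)),
    score  = as.numeric(gr$score %||% 0),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @param intervals A data frame with the BED6 columns listed above.
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = intervals$strand
  )
  gr$name <- intervals$name
  gr$score <- intervals$score %||% 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write Affymetrix-style probe-tab tables
#'
#' The probe-tab dialect is a TSV with columns `probeset_id`, `probe_id`,
#' `probe_x`, `probe_y`, `sequence`; only id and sequence columns are used.
#'
#' @param path Path to a probe-tab TSV.
#' @return A tibble with `probeset_id`, `probe_id`, `sequence`.
#' @export
read_probe_tab <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probeset_id", "probe_id", "sequence")
  if (!all(need %in% names(tab))) {
    abort(paste0("probe-tab file must contain columns: ",
                 paste(need, collapse = ", ")))
  }
  tab %>%
    select("probeset_id", "probe_id", "sequence") %>%
    mutate(sequence = toupper(.data$sequence))
}

#' @param probes A data frame with `probeset_id`, `probe_id`, `sequence`.
#' @rdname read_probe_tab
#' @export
write_probe_tab <- function(probes, path) {
  probes %>%
    group_by(.data$probeset_id) %>%
    mutate(probe_x = row_number(), probe_y = 1L) %>%
    ungroup() %>%
    select("probeset_id", "probe_id", "probe_x", "probe_y", "sequence") %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read and write GCT v1.2 expression matrices
#'
#' GCT v1.2: a `#1.2` header line, a dimensions line, then a `NAME`,
#' `Description` + one-column-per-sample table.
#'
#' @param path Path to a GCT file.
#' @return A list with `matrix` (features x samples, rownames = feature ids)
#'   and `description` (per-feature character vector).
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
    abort("not a GCT v1.2 file (missing '#1.2' header)")
  }
  dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]])
  tab <- readr::read_tsv(I(lines[-(1:2)]), show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(tab) != dims[1] || (ncol(tab) - 2L) != dims[2]) {
    abort("GCT dimensions line disagrees with the table")
  }
  mat <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(mat) <- tab$NAME
  if (anyNA(mat)) abort("GCT matrix contains missing values")
  list(matrix = mat, description = tab$Description)
}

#' @param mat Numeric matrix (features x samples) with dimnames.
#' @param description Optional per-feature description column.
#' @rdname read_gct
#' @export
write_gct <- function(mat, path, description = NULL) {
  description <- description %||% rownames(mat)
  tab <- bind_cols(
    tibble(NAME = rownames(mat), Description = description),
    as_tibble(mat)
  )
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read and write two-class CLS phenotype files
#'
#' @param path Path to a CLS file.
#' @return A character vector of per-sample class labels.
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) abort("truncated CLS file")
  hd <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  classes <- strsplit(sub("^#\\s*", "", lines[2]), "\\s+")[[1]]
  idx <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(idx) != hd[1]) abort("CLS label count disagrees with header")
  # labels may be given as 0-based indices or as the class names themselves
  if (all(idx %in% classes)) idx else classes[as.integer(idx) + 1L]
}

#' @param labels Character vector of per-sample class labels (two classes).
#' @rdname read_cls
#' @export
write_cls <- function(labels, path) {
  classes <- unique(labels)
  lines <- c(
    paste(length(labels), length(classes), 1),
    paste("#", paste(classes, collapse = " ")),
    paste(match(labels, classes) - 1L, collapse = " ")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Lines with no members are rejected as malformed, as are duplicate set
#' names.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3 | map_lgl(parts, ~ all(!nzchar(.x[-(1:2)]))))
  if (length(bad)) {
    abort(paste0("malformed GMT line(s) with no members: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  nm <- map_chr(parts, 1)
  if (anyDuplicated(nm)) abort("duplicate gene-set names in GMT")
  sets <- map(parts, ~ unique(.x[-(1:2)][nzchar(.x[-(1:2)])]))
  setNames(sets, nm)
}

#' @param sets Named list of character vectors.
#' @param description Optional per-set description (defaults to set name).
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names")
  if (any(lengths(sets) == 0)) abort("gene sets with no members")
  description <- description %||% names(sets)
  lines <- map_chr(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read and write survival cohort tables
#'
#' TSV with columns `sample_id`, `time` (months), `event` (0/1) and
#' optionally `expression` and `group`.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_survival_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(tab))) {
    abort(paste0("survival table must contain columns: ",
                 paste(need, collapse = ", ")))
  }
  if (any(tab$time <= 0)) abort("survival times must be positive")
  if (!all(tab$event %in% c(0, 1))) abort("event must be 0/1")
  tab
}

#' @param cohort A data frame with the survival columns.
#' @rdname read_survival_tsv
#' @export
write_survival_tsv <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  invisible(path)
}
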