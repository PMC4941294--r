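#' Simulate Affymetrix-style probe sets with planted match identities
#'
#' Each targeted probe set is assigned one target transcript and one
#' identity level from `config$identity_levels` (cycled). Its probes are
#' substrings of the target carrying exactly
#' `round((1 - identity) * probe_length)` point substitutions at random
#' positions (each substitution changes the base). Decoy probe sets are
#' pure random sequence with no target. Optionally a single 1-nt deletion
#' can be planted per probe to exercise the gapped aligner.
#'
#' @param transcripts Tibble from [simulate_transcriptome()]; targets are
#'   drawn from its noncoding records longer than the probe length.
#' @param config A [sim_config()] object.
#' @param indels If `TRUE`, each targeted probe additionally carries one
#'   1-nt deletion relative to its source window.
#' @return A list with `probes` (tibble: `probeset_id`, `probe_id`,
#'   `sequence`), and `truth` (tibble: `probeset_id`, `accession`,
#'   `identity`, `offset` per probe; decoys have `NA` accession).
#' @export
simulate_probesets <- function(transcripts, config, indels = FALSE) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg, "probesets"))

  l <- cfg$probe_length
  targets <- transcripts %>%
    filter(grepl("^(NR|XR)_", .data$accession), .data$length >= l + 1L)
  if (nrow(targets) == 0) {
    abort(paste0("no transcript is long enough to carry a ", l,
                 "-nt probe; shortest available length is ",
                 min(transcripts$length)))
  }

  n_decoy <- as.integer(round(cfg$decoy_fraction * cfg$n_probesets))
  n_target <- cfg$n_probesets - n_decoy
  set_ids <- sprintf("PS%05d_at", seq_len(cfg$n_probesets))
  target_rows <- sample(nrow(targets), n_target, replace = n_target > nrow(targets))
  levels <- rep_len(cfg$identity_levels, n_target)

  make_probe <- function(target_seq, identity) {
    L <- nchar(target_seq)
    win_len <- if (indels) l + 1L else l
    off <- sample.int(L - win_len + 1L, 1L) - 1L
    window <- substr(target_seq, off + 1L, off + win_len)
    if (indels) {
      del <- sample.int(win_len, 1L)
      window <- paste0(substr(window, 1, del - 1L),
                       substr(window, del + 1L, win_len))
    }
    n_sub <- as.integer(round((1 - identity) * l))
    chars <- strsplit(window, "")[[1]]
    if (n_sub > 0) {
      pos <- sample.int(l, n_sub)
      chars[pos] <- map_chr(chars[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      })
    }
    list(sequence = paste(chars, collapse = ""), offset = off)
  }

  probes <- vector("list", cfg$n_probesets)
  truth <- vector("list", cfg$n_probesets)
  for (i in seq_len(cfg$n_probesets)) {
    pid <- sprintf("%s:%02d", set_ids[i], seq_len(cfg$probes_per_set))
    if (i <= n_target) {
      tgt <- targets[target_rows[i], ]
      made <- map(seq_len(cfg$probes_per_set),
                  ~ make_probe(tgt$sequence, levels[i]))
      probes[[i]] <- tibble(probeset_id = set_ids[i], probe_id = pid,
                            sequence = map_chr(made, "sequence"))
      truth[[i]] <- tibble(probeset_id = set_ids[i],
                           accession = tgt$accession,
                           identity = levels[i],
                           offset = map_int(made, ~ as.integer(.x$offset)))
    } else {
      probes[[i]] <- tibble(probeset_id = set_ids[i], probe_id = pid,
                            sequence = random_dna(rep(l, cfg$probes_per_set)))
      truth[[i]] <- tibble(probeset_id = set_ids[i],
                           accession = NA_character_,
                           identity = NA_real_, offset = NA_integer_)
    }
  }
  list(probes = bind_rows(probes), truth = bind_rows(truth))
}
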