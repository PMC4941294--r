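# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (C++ aligner, moderated t, ES code).

# Brute-force best ungapped placement: pure-R scan over every offset and
# both strands. Slow; for small fixtures only.
oracle_ungapped <- function(probe, transcript) {
  pch <- strsplit(probe, "")[[1]]
  best <- length(pch) + 1L
  for (s in c(transcript, oracle_revcomp(transcript))) {
    sch <- strsplit(s, "")[[1]]
    for (off in 0:(length(sch) - length(pch))) {
      mm <- sum(pch != sch[(off + 1):(off + length(pch))] |
                  !(pch %in% c("A", "C", "G", "T")))
      best <- min(best, mm)
    }
  }
  best
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Exhaustive best-mismatch matrix (probes x transcripts, both strands)
# through Biostrings::neditStartingAt over a concatenated subject: one
# C-level sweep per probe over every valid offset. Spacer windows and
# windows spanning two segments are masked out, so only genuine
# placements are considered.
oracle_mismatch_matrix <- function(probe_seqs, transcript_seqs) {
  l <- nchar(probe_seqs[1])
  spacer <- strrep("N", l)
  strands <- c(transcript_seqs,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(transcript_seqs))))
  seg_id <- rep(seq_along(transcript_seqs), 2)
  concat <- paste(strands, collapse = spacer)
  starts <- cumsum(c(1, head(nchar(strands) + l, -1)))
  valid <- unlist(lapply(seq_along(strands), function(i) {
    n_off <- nchar(strands[i]) - l + 1
    if (n_off < 1) integer(0) else starts[i] + 0:(n_off - 1)
  }))
  valid_seg <- rep(seg_id, vapply(seq_along(strands), function(i) {
    max(0L, nchar(strands[i]) - l + 1L)
  }, integer(1)))
  subject <- Biostrings::DNAString(concat)
  out <- matrix(NA_integer_, length(probe_seqs), length(transcript_seqs))
  for (k in seq_along(probe_seqs)) {
    ed <- Biostrings::neditStartingAt(Biostrings::DNAString(probe_seqs[k]),
                                      subject, starting.at = valid,
                                      with.indels = FALSE)
    out[k, ] <- as.integer(tapply(ed, valid_seg, min))
  }
  out
}

# Annotation table from the oracle mismatch matrix (probe_fraction rule).
oracle_annotation <- function(probes, transcripts, probe_identity_min = 0.9,
                              set_fraction_min = 0.9) {
  mm <- oracle_mismatch_matrix(probes$sequence, transcripts$sequence)
  ident <- (nchar(probes$sequence) - mm) / nchar(probes$sequence)
  rows <- list()
  for (sid in unique(probes$probeset_id)) {
    idx <- which(probes$probeset_id == sid)
    for (t in seq_len(nrow(transcripts))) {
      frac <- mean(ident[idx, t] >= probe_identity_min)
      if (frac >= set_fraction_min) {
        rows[[length(rows) + 1]] <- data.frame(
          probeset_id = sid, accession = transcripts$accession[t],
          probe_match_fraction = frac,
          mean_identity = mean(ident[idx, t]))
      }
    }
  }
  out <- do.call(rbind, c(list(data.frame(probeset_id = character(),
                                          accession = character(),
                                          probe_match_fraction = double(),
                                          mean_identity = double())),
                          rows))
  out[order(out$probeset_id, out$accession), , drop = FALSE]
}

# Independent step-up BH.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    running_min <- min(running_min, m * p[o[i]] / i)
    adj[o[i]] <- running_min
  }
  adj
}

# Brute-force GSEA running sum.
oracle_es <- function(genes, scores, set, p_weight = 1) {
  hit <- genes %in% set
  n <- length(genes)
  nh <- sum(hit)
  w <- abs(scores)^p_weight
  denom <- sum(w[hit])
  rs <- 0
  best <- 0
  values <- numeric(n)
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) {
      if (denom > 0) w[i] / denom else 1 / nh
    } else {
      -1 / (n - nh)
    }
    values[i] <- rs
    if (abs(rs) > abs(best)) best <- rs
  }
  list(es = best, running_sum = values)
}

# Breslow partial log-likelihood for a binary covariate; maximized by
# golden-section search as an independent check on the Cox fit.
oracle_cox_beta <- function(time, event, g) {
  loglik <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + beta * g[i] - log(sum(exp(beta * g[risk])))
    }
    ll
  }
  stats::optimize(loglik, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_index <- sum_a * sum_b / n
  ((sum_ij - exp_index) / ((sum_a + sum_b) / 2 - exp_index))
}

# Exact upper-tail hypergeometric mass by combinatorial arithmetic.
oracle_hyper_upper <- function(k, K, n, N) {
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}
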