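# Independent brute-force oracles. These deliberately re-derive quantities by
# exhaustive enumeration, never by calling the implementation under test.

# all substring windows of `protein` with lengths in `lengths` that cover at
# least one position in `positions`
oracle_windows <- function(protein, positions, lengths) {
  n <- nchar(protein)
  out <- character(0)
  starts <- integer(0)
  lens <- integer(0)
  for (L in lengths) {
    if (L > n) next
    for (s in seq_len(n - L + 1L)) {
      if (any(positions >= s & positions <= s + L - 1L)) {
        out <- c(out, substring(protein, s, s + L - 1L))
        starts <- c(starts, s)
        lens <- c(lens, L)
      }
    }
  }
  list(sequences = out, starts = starts, lengths = lens,
       n_windows = length(out), n_distinct = length(unique(out)))
}

# Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie), over all pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# BH step-up, implemented literally from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- ranked * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# product-limit (Kaplan-Meier) survival estimate at each event time
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

random_peptide_str <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}
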