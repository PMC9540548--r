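# Brute-force metric oracles: direct, loop-based evaluations of the metric
# definitions, kept deliberately independent of the package implementations.

oracle_lrap <- function(scores, truth) {
  rows <- numeric(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    true_idx <- which(truth[i, ] == 1)
    precisions <- numeric(length(true_idx))
    for (j in seq_along(true_idx)) {
      s <- scores[i, true_idx[j]]
      ge <- which(scores[i, ] >= s)
      precisions[j] <- length(intersect(ge, true_idx)) / length(ge)
    }
    rows[i] <- mean(precisions)
  }
  mean(rows)
}

oracle_jaccard <- function(pred, truth) {
  rows <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    p <- which(pred[i, ] == 1); t <- which(truth[i, ] == 1)
    u <- union(p, t)
    rows[i] <- if (length(u) == 0) 1 else length(intersect(p, t)) / length(u)
  }
  mean(rows)
}

# descending-score rank with ties broken by the lower label index
oracle_ranks <- function(s) {
  ord <- order(-s, seq_along(s))
  r <- integer(length(s)); r[ord] <- seq_along(s); r
}

oracle_topk <- function(scores, y, k) {
  hits <- 0
  for (i in seq_len(nrow(scores)))
    if (oracle_ranks(scores[i, ])[y[i]] <= k) hits <- hits + 1
  hits / nrow(scores)
}

oracle_rank_curve <- function(scores, truth, kmax) {
  eff <- numeric(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    r <- oracle_ranks(scores[i, ])
    tl <- which(truth[i, ] == 1)
    eff[i] <- max(r[tl]) / length(tl)
  }
  vapply(seq_len(kmax), function(k) mean(eff <= k), numeric(1))
}

# random multi-label instance with at least one true label per row
random_instance <- function(n, k, p = 0.3) {
  scores <- matrix(stats::runif(n * k), n, k)
  truth <- matrix(stats::rbinom(n * k, 1, p), n, k)
  for (i in which(rowSums(truth) == 0))
    truth[i, sample.int(k, 1)] <- 1L
  list(scores = scores, truth = truth)
}
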