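# Evaluation metrics for context prediction: top-k accuracy, label ranking
# average precision, samples Jaccard, the multi-label rank curve,
# per-context sensitivity/specificity, confusion likelihoods, partial
# context agreement and popularity baselines. Ranking ties are always
# broken by the lower label index (the more popular context wins), which
# makes every metric deterministic.

.truthMatrix <- function(truth, k) {
  if (is.matrix(truth)) truth else oneHot(truth, k)
}

# 1-based descending-score rank of every label, ties by lower label index
.scoreRanks <- function(scores) {
  t(apply(scores, 1, function(s) {
    ord <- order(-s, seq_along(s))
    r <- integer(length(s)); r[ord] <- seq_along(s); r
  }))
}

#' Top-k accuracy
#'
#' Fraction of rows whose single true label ranks within the top k scores
#' (descending, ties broken by lower label index).
#'
#' @param scores numeric score matrix (rows = examples, cols = labels).
#' @param truth one-hot matrix with exactly one bit per row, or an integer
#'   vector of 1-based label indices.
#' @param k rank cutoff, in [1, number of labels].
#' @return accuracy in [0, 1].
#' @export
topkAccuracy <- function(scores, truth, k) {
  Tm <- .truthMatrix(truth, ncol(scores))
  stopifnot(identical(dim(Tm), dim(scores)))
  if (any(rowSums(Tm) != 1))
    stop("top-k accuracy requires exactly one true label per row",
         call. = FALSE)
  if (k < 1 || k > ncol(scores))
    stop("k must lie in [1, ", ncol(scores), "]", call. = FALSE)
  y <- max.col(Tm, ties.method = "first")
  s_true <- scores[cbind(seq_len(nrow(scores)), y)]
  col_lt <- matrix(seq_len(ncol(scores)), nrow(scores), ncol(scores),
                   byrow = TRUE) < y
  rank <- rowSums(scores > s_true) + rowSums((scores == s_true) & col_lt) + 1
  mean(rank <= k)
}

#' Label ranking average precision (LRAP)
#'
#' For each true label of a row, the fraction of labels scored at least as
#' high that are themselves true; averaged over the row's true labels, then
#' over rows. 1 when every true label outranks every false one.
#'
#' @param scores numeric score matrix.
#' @param truth multi-hot 0/1 matrix, at least one bit per row.
#' @return LRAP in (0, 1].
#' @export
lrap <- function(scores, truth) {
  stopifnot(identical(dim(truth), dim(scores)))
  if (any(rowSums(truth) == 0))
    stop("every row needs at least one true label", call. = FALSE)
  mean(vapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]; t <- truth[i, ] == 1
    mean(vapply(which(t), function(j) {
      ge <- s >= s[j]
      sum(ge & t) / sum(ge)
    }, numeric(1)))
  }, numeric(1)))
}

#' Samples Jaccard score
#'
#' Per row, |predicted positives intersect true| / |union|, defined as 1
#' when both sets are empty; averaged over rows.
#'
#' @param predPositive binary matrix of positive predictions (e.g. scores
#'   thresholded at 0.5, see \code{\link{positivePredictions}}).
#' @param truth multi-hot 0/1 matrix.
#' @return mean Jaccard in [0, 1].
#' @export
jaccardSamples <- function(predPositive, truth) {
  stopifnot(identical(dim(predPositive), dim(truth)))
  inter <- rowSums(predPositive == 1 & truth == 1)
  uni <- rowSums(predPositive == 1 | truth == 1)
  mean(ifelse(uni == 0, 1, inter / uni))
}

#' Threshold scores into positive predictions
#'
#' @param scores numeric score matrix.
#' @param threshold positive-prediction cutoff (default 0.5).
#' @return binary matrix of the same shape.
#' @export
positivePredictions <- function(scores, threshold = 0.5) {
  mode(scores) <- "numeric"
  (scores >= threshold) * 1L
}

#' Cumulative rank curve for multi-label predictions
#'
#' Per row the effective rank is the descending-score rank of the
#' worst-ranked true label divided by the number of true labels; the curve
#' at k is the fraction of rows with effective rank at most k. For
#' single-truth rows this equals top-k accuracy.
#'
#' @param scores numeric score matrix.
#' @param truth multi-hot 0/1 matrix, at least one bit per row.
#' @param kMax largest k to report (default: number of labels).
#' @return named numeric vector, \code{curve[k]} = cumulative fraction.
#' @export
rankCurve <- function(scores, truth, kMax = ncol(scores)) {
  stopifnot(identical(dim(truth), dim(scores)))
  if (any(rowSums(truth) == 0))
    stop("every row needs at least one true label", call. = FALSE)
  ranks <- .scoreRanks(scores)
  eff <- vapply(seq_len(nrow(scores)), function(i) {
    tl <- which(truth[i, ] == 1)
    max(ranks[i, tl]) / length(tl)
  }, numeric(1))
  stats::setNames(vapply(seq_len(kMax), function(k) mean(eff <= k),
                         numeric(1)), seq_len(kMax))
}

#' Per-context sensitivity and specificity
#'
#' A prediction is positive for context c under the chosen rule: "top1"
#' (the argmax, single-label use) or "threshold" (score >= threshold,
#' multi-label use). Contexts absent from the truth get \code{NA}
#' sensitivity rather than 0.
#'
#' @param scores numeric score matrix.
#' @param truth multi-hot 0/1 matrix.
#' @param positiveRule "top1" or "threshold".
#' @param threshold cutoff for the threshold rule (default 0.5).
#' @return data.frame: context index, sensitivity, specificity, support.
#' @export
sensitivitySpecificity <- function(scores, truth,
                                   positiveRule = c("top1", "threshold"),
                                   threshold = 0.5) {
  positiveRule <- match.arg(positiveRule)
  stopifnot(identical(dim(truth), dim(scores)))
  P <- if (positiveRule == "top1") {
    oneHot(max.col(scores, ties.method = "first"), ncol(scores))
  } else positivePredictions(scores, threshold)
  res <- lapply(seq_len(ncol(scores)), function(c) {
    tp <- sum(P[, c] == 1 & truth[, c] == 1)
    fn <- sum(P[, c] == 0 & truth[, c] == 1)
    fp <- sum(P[, c] == 1 & truth[, c] == 0)
    tn <- sum(P[, c] == 0 & truth[, c] == 0)
    data.frame(context = c,
               sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
               specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
               support = tp + fn)
  })
  do.call(rbind, res)
}

#' Context confusion likelihoods
#'
#' Entry (y, x): the likelihood of predicting context x within the top k,
#' given that the ground-truth context is y. Rows with no single truth
#' (multi-label data) use the highest-scored true label as ground truth.
#' The support-weighted diagonal mean equals the top-k accuracy.
#'
#' @param scores numeric score matrix.
#' @param truth one-hot / multi-hot 0/1 matrix or integer label vector.
#' @param k top-k cutoff (1 or 3 in the standard analyses).
#' @return numeric matrix (truth y in rows, predicted x in columns); rows
#'   for contexts without support are \code{NA}.
#' @export
confusionLikelihood <- function(scores, truth, k = 1L) {
  Tm <- .truthMatrix(truth, ncol(scores))
  stopifnot(identical(dim(Tm), dim(scores)))
  ranks <- .scoreRanks(scores)
  y <- vapply(seq_len(nrow(scores)), function(i) {
    tl <- which(Tm[i, ] == 1)
    tl[which.min(ranks[i, tl])]  # highest-scored truth
  }, integer(1))
  K <- ncol(scores)
  M <- matrix(NA_real_, K, K)
  topk <- ranks <= k
  for (cy in seq_len(K)) {
    rows <- which(y == cy)
    if (length(rows))
      M[cy, ] <- colMeans(topk[rows, , drop = FALSE])
  }
  M
}

#' Partial agreement between two chemical contexts
#'
#' Compares contexts category by category: a category agrees when its
#' sorted species lists are identical, with both-empty counting as
#' agreement. Catalyst and pre-catalyst are merged into one category by
#' default, giving the standard four comparison categories (catalyst,
#' ligand, base, solvent).
#'
#' @param predKey,trueKey context key strings
#'   (\code{\link{buildContextKey}}).
#' @param categories category names to compare; \code{"catalyst"} means
#'   the merged catalyst + pre-catalyst set.
#' @return list: \code{score} (fraction of agreeing categories) and
#'   \code{flags} (named logical per category).
#' @export
partialAgreement <- function(predKey, trueKey,
                             categories = c("catalyst", "ligand", "base",
                                            "solvent")) {
  p <- contextSpecies(predKey)
  t <- contextSpecies(trueKey)
  get <- function(x, cat) {
    if (cat == "catalyst") sort(c(x[["catalyst"]], x[["pre-catalyst"]]))
    else sort(x[[cat]])
  }
  flags <- vapply(categories, function(cat)
    identical(get(p, cat), get(t, cat)), logical(1))
  list(score = mean(flags), flags = flags)
}

#' Aggregate partial agreement over hard examples
#'
#' Restricts to examples whose (highest-scored) true context falls outside
#' the top \code{excludeTopk} predictions, then compares the top-1
#' predicted context with the true context category by category.
#'
#' @param scores numeric score matrix.
#' @param truth one-hot / multi-hot truth matrix or integer vector.
#' @param labelSpace the \linkS4class{LabelSpace} mapping label indices to
#'   context keys.
#' @param excludeTopk consider only rows whose truth ranks below this
#'   cutoff (default 3).
#' @param categories see \code{\link{partialAgreement}}.
#' @return list: \code{n} rows considered, \code{meanScore}, and
#'   \code{categoryLikelihood} (named numeric, per-category agreement
#'   likelihood). All \code{NA} when no row qualifies.
#' @export
aggregatePartialAgreement <- function(scores, truth, labelSpace,
                                      excludeTopk = 3L,
                                      categories = c("catalyst", "ligand",
                                                     "base", "solvent")) {
  Tm <- .truthMatrix(truth, ncol(scores))
  ranks <- .scoreRanks(scores)
  keys <- labelKeys(labelSpace)
  info <- lapply(seq_len(nrow(scores)), function(i) {
    tl <- which(Tm[i, ] == 1)
    best_true <- tl[which.min(ranks[i, tl])]
    if (ranks[i, best_true] <= excludeTopk) return(NULL)
    top1 <- which(ranks[i, ] == 1L)
    partialAgreement(keys[top1], keys[best_true], categories)
  })
  info <- info[!vapply(info, is.null, TRUE)]
  if (!length(info))
    return(list(n = 0L, meanScore = NA_real_,
                categoryLikelihood = stats::setNames(
                  rep(NA_real_, length(categories)), categories)))
  flags <- do.call(rbind, lapply(info, `[[`, "flags"))
  list(n = length(info),
       meanScore = mean(vapply(info, `[[`, numeric(1), "score")),
       categoryLikelihood = colMeans(flags))
}

#' Popularity baselines
#'
#' The baseline predictor scores every context by its popularity in the
#' training data (the label-space counts) and always suggests the most
#' popular contexts in order.
#'
#' @param labelCounts integer usage counts per label, from the training
#'   split only (e.g. \code{labelCounts(labelSpace)}).
#' @param truth one-hot truth matrix or integer label vector for the
#'   evaluation rows.
#' @return list with \code{top1} and \code{top3} baseline accuracies.
#' @export
popularityBaselines <- function(labelCounts, truth) {
  K <- length(labelCounts)
  Tm <- .truthMatrix(truth, K)
  pop <- numeric(K)
  pop[order(-labelCounts, seq_len(K))] <- seq(K, 1)
  base_scores <- matrix(pop, nrow(Tm), K, byrow = TRUE)
  list(top1 = topkAccuracy(base_scores, Tm, 1L),
       top3 = topkAccuracy(base_scores, Tm, min(3L, K)))
}

#' Paired comparison of per-context metrics between two models
#'
#' Standard two-sided paired t-test on per-context metric deltas (e.g.
#' sensitivity of the multi-label vs single-label model).
#'
#' @param a,b numeric vectors of a per-context metric under two models,
#'   aligned by context; \code{NA} pairs are dropped.
#' @return list: \code{meanDelta} (mean of b - a) and \code{pValue}.
#' @export
pairedDeltaTest <- function(a, b) {
  keep <- !(is.na(a) | is.na(b))
  ht <- stats::t.test(b[keep], a[keep], paired = TRUE)
  list(meanDelta = unname(ht$estimate), pValue = ht$p.value)
}

#' Full evaluation report
#'
#' Computes every evaluation analysis for a trained model on held-out
#' examples: top-k accuracies, LRAP, samples Jaccard, the rank curve,
#' per-context sensitivity/specificity, top-1/top-3 confusion likelihoods,
#' partial agreement on hard examples, predicted label cardinality and
#' popularity baselines.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param features difference-fingerprint matrix for the evaluation rows.
#' @param truth one-hot / multi-hot truth matrix or integer label vector.
#' @param threshold positive-prediction cutoff for Jaccard, cardinality
#'   and the threshold sensitivity rule.
#' @return list with components \code{topk}, \code{lrap}, \code{jaccard},
#'   \code{rankCurve}, \code{perContext}, \code{confusionTop1},
#'   \code{confusionTop3}, \code{agreement}, \code{predictedCardinality},
#'   \code{baselines}.
#' @export
evaluateModel <- function(bundle, features, truth, threshold = 0.5) {
  scores <- predictScores(bundle, features)
  K <- ncol(scores)
  Tm <- .truthMatrix(truth, K)
  single_truth <- all(rowSums(Tm) == 1)
  rule <- if (bundle@config$mode == "single") "top1" else "threshold"
  ks <- unique(pmin(c(1L, 3L, 5L, 10L, K), K))
  pred_pos <- positivePredictions(scores, threshold)
  list(
    topk = if (single_truth)
      stats::setNames(vapply(ks, function(k) topkAccuracy(scores, Tm, k),
                             numeric(1)), ks) else NULL,
    lrap = lrap(scores, Tm),
    jaccard = jaccardSamples(pred_pos, Tm),
    rankCurve = rankCurve(scores, Tm),
    perContext = sensitivitySpecificity(scores, Tm, rule, threshold),
    confusionTop1 = confusionLikelihood(scores, Tm, 1L),
    confusionTop3 = confusionLikelihood(scores, Tm, min(3L, K)),
    agreement = aggregatePartialAgreement(scores, Tm, bundle@labelSpace),
    predictedCardinality = mean(rowSums(pred_pos)),
    baselines = if (single_truth)
      popularityBaselines(labelCounts(bundle@labelSpace), Tm) else NULL)
}
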