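# Dataset imbalance/cardinality statistics, per-year context usage and the
# year-ranged retraining experiment.

#' Multi-label imbalance and cardinality summary
#'
#' Per-label imbalance ratio IR(l) = max count over labels / count(l),
#' computed over label occurrences in the multi-label table; the mean and
#' variance are taken over labels with nonzero count (zero-count labels are
#' excluded with a warning). Cardinality is the mean number of true labels
#' per example; density is cardinality divided by the number of labels. A
#' dataset with mean IR above 1.5 is flagged imbalanced (the usual
#' multi-label criterion).
#'
#' @param multiLabels binary label matrix, one row per multi-label example
#'   (\code{multiLabels} from \code{\link{filterAndLabel}}).
#' @param ls optional \linkS4class{LabelSpace} used only to name the
#'   per-label output.
#' @return list: \code{perLabelIR}, \code{meanIR}, \code{varIR},
#'   \code{cvIR}, \code{cardinality}, \code{density}, \code{imbalanced}.
#' @export
imbalanceSummary <- function(multiLabels, ls = NULL) {
  stopifnot(is.matrix(multiLabels), nrow(multiLabels) > 0)
  counts <- colSums(multiLabels)
  ir <- rep(NA_real_, length(counts))
  nz <- counts > 0
  if (!all(nz))
    warning(sum(!nz), " label(s) with zero count excluded from the ",
            "imbalance ratios")
  ir[nz] <- max(counts) / counts[nz]
  if (!is.null(ls)) names(ir) <- labelKeys(ls)
  card <- mean(rowSums(multiLabels))
  list(perLabelIR = ir,
       meanIR = mean(ir[nz]),
       varIR = stats::var(ir[nz]),
       cvIR = stats::sd(ir[nz]) / mean(ir[nz]),
       cardinality = card,
       density = card / ncol(multiLabels),
       imbalanced = mean(ir[nz]) > 1.5)
}

#' Label density from cardinality
#'
#' @param cardinality mean number of labels per example.
#' @param nLabels number of labels.
#' @return density = cardinality / nLabels.
#' @export
labelDensity <- function(cardinality, nLabels) cardinality / nLabels

#' Per-year context usage matrix
#'
#' Counts surviving variations (yield filter applied, contexts restricted
#' to the label space) per calendar year and context. The relative matrix
#' is normalized within each year, reproducing the brightness semantics of
#' a per-year context-usage heatmap.
#'
#' @param ds a \code{ReactionDataset}.
#' @param ls the \linkS4class{LabelSpace} defining the contexts.
#' @param minYield yield filter applied before counting (default 20).
#' @param curated curated role lists.
#' @return list: \code{years} (ordered integer vector), \code{counts}
#'   (|years| x |labels| integer matrix), \code{relative} (row-normalized).
#' @export
yearContextMatrix <- function(ds, ls, minYield = 20,
                              curated = curatedLists()) {
  v <- variations(ds)
  v <- v[v$yield_percent >= minYield, , drop = FALSE]
  v$year <- as.integer(substr(v$date, 1, 4))
  keys <- .variationContextKeys(v, curated)
  keep <- keys %in% labelKeys(ls)
  v <- v[keep, , drop = FALSE]
  lab <- match(keys[keep], labelKeys(ls))
  years <- seq(min(v$year), max(v$year))
  counts <- matrix(0L, length(years), nLabels(ls),
                   dimnames = list(years, NULL))
  for (i in seq_len(nrow(v)))
    counts[as.character(v$year[i]), lab[i]] <-
      counts[as.character(v$year[i]), lab[i]] + 1L
  tot <- rowSums(counts)
  rel <- counts / ifelse(tot == 0, 1, tot)
  list(years = years, counts = counts, relative = rel)
}

#' Year-ranged retraining experiment
#'
#' Trains single-label models on reactions from different spans of years
#' and evaluates all of them on the reactions of a fixed test span,
#' quantifying how model accuracy degrades when training data are
#' temporally distant from the test era. The label space is built once from
#' the full dataset so accuracies are comparable across rows. The test set
#' is a held-out fraction of the test-range reactions, fixed across all
#' training ranges; a test reaction never contributes to training even
#' when a training range overlaps the test range (the remaining test-era
#' reactions may).
#'
#' @param ds a \code{ReactionDataset}.
#' @param trainRanges list of two-element integer vectors
#'   \code{c(from, to)}.
#' @param testRange two-element integer vector \code{c(from, to)}.
#' @param cfg model configuration (default: the optimized single-label
#'   configuration).
#' @param nRuns independent training runs per range; the report gives mean
#'   and standard deviation over runs (default 3).
#' @param k,minYield,curated filtering parameters, see
#'   \code{\link{filterAndLabel}}.
#' @param testFrac fraction of the test-range reactions held out as the
#'   common test set (default 0.5).
#' @param testSeed seed fixing the held-out test sample.
#' @param features optional precomputed feature matrix aligned with the
#'   single-label table (computed when omitted).
#' @return data.frame: train_from, train_to, n_train, n_test, top1_mean,
#'   top1_sd, top3_mean, top3_sd.
#' @export
temporalExperiment <- function(ds, trainRanges, testRange,
                               cfg = defaultModelConfig("single"),
                               nRuns = 3L, k = 30, minYield = 20,
                               curated = curatedLists(), testFrac = 0.5,
                               testSeed = 1L, features = NULL) {
  fl <- filterAndLabel(ds, k = k, minYield = minYield, curated = curated)
  tab <- fl$single
  if (is.null(features)) features <- featurizeReactions(tab)
  test_pool <- which(tab$year >= testRange[1] & tab$year <= testRange[2])
  if (!length(test_pool))
    stop("no reactions in test range ", testRange[1], "-", testRange[2],
         call. = FALSE)
  test_idx <- .withSeed(testSeed,
    sort(sample(test_pool, max(1, round(testFrac * length(test_pool))))))
  Tte <- oneHot(tab$label[test_idx], nLabels(fl$labelSpace))
  Xte <- features[test_idx, , drop = FALSE]
  rows <- lapply(trainRanges, function(rng) {
    tr_idx <- setdiff(which(tab$year >= rng[1] & tab$year <= rng[2]),
                      test_idx)
    if (!length(tr_idx))
      stop("no training reactions in range ", rng[1], "-", rng[2],
           call. = FALSE)
    accs <- vapply(seq_len(nRuns), function(run) {
      run_cfg <- cfg
      run_cfg$seed <- cfg$seed + run - 1L
      b <- trainModel(tab$label[tr_idx], features[tr_idx, , drop = FALSE],
                      run_cfg, fl$labelSpace,
                      weights = tab$weight[tr_idx], splitSeed = run)
      P <- predictScores(b, Xte)
      c(topkAccuracy(P, Tte, 1L),
        topkAccuracy(P, Tte, min(3L, ncol(Tte))))
    }, numeric(2))
    data.frame(train_from = rng[1], train_to = rng[2],
               n_train = length(tr_idx), n_test = length(test_idx),
               top1_mean = mean(accs[1, ]), top1_sd = stats::sd(accs[1, ]),
               top3_mean = mean(accs[2, ]), top3_sd = stats::sd(accs[2, ]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
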