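# Metrics: worked examples frozen from the brute-force oracles, plus
# property-style checks against those oracles and permutation invariance.

test_that("top-k accuracy on hand-checked cases", {
  s <- matrix(c(0.5, 0.3, 0.2), 1, byrow = TRUE)
  expect_equal(topkAccuracy(s, 2L, 1), 0)
  expect_equal(topkAccuracy(s, 2L, 2), 1)
  # truth always the argmax
  s2 <- diag(4) * 0.9 + 0.01
  expect_equal(topkAccuracy(s2, 1:4, 1), 1)
  # k = |labels| is always exhaustive
  expect_equal(topkAccuracy(matrix(runif(40), 10), sample(4, 10, TRUE), 4), 1)
  expect_error(topkAccuracy(s, 2L, 0), "k must")
  expect_error(topkAccuracy(s, 2L, 4), "k must")
  multi <- matrix(c(1, 0, 1), 1)
  expect_error(topkAccuracy(s, multi, 1), "exactly one")
})

test_that("ties in top-k rank the lower label index first", {
  s <- matrix(c(0.4, 0.4, 0.2), 1, byrow = TRUE)
  expect_equal(topkAccuracy(s, 1L, 1), 1)  # index 1 wins the tie
  expect_equal(topkAccuracy(s, 2L, 1), 0)
  expect_equal(topkAccuracy(s, 2L, 2), 1)
})

test_that("LRAP on worked examples", {
  # perfect ranking
  expect_equal(lrap(matrix(c(0.9, 0.8, 0.1), 1), matrix(c(1, 1, 0), 1)), 1)
  # two rows evaluated by the printed definition: truths {1,3} with scores
  # (.75,.5,1) give precision 1 for both truths; single truth {3} with
  # scores (1,.2,.1) gives 1/3; the mean is 2/3
  s <- rbind(c(0.75, 0.5, 1.0), c(1.0, 0.2, 0.1))
  t <- rbind(c(1, 0, 1), c(0, 0, 1))
  expect_equal(lrap(s, t), 2 / 3)
  expect_equal(lrap(s, t), oracle_lrap(s, t))
  # single truth ranked last among L labels scores 1/L
  L <- 5
  expect_equal(lrap(matrix(seq(0.9, 0.5, length.out = L), 1),
                    matrix(c(rep(0, L - 1), 1), 1)), 1 / L)
  expect_error(lrap(s, rbind(c(0, 0, 0), c(1, 0, 0))), "at least one")
})

test_that("samples Jaccard on worked examples", {
  expect_equal(jaccardSamples(matrix(c(1, 1, 0), 1), matrix(c(1, 1, 0), 1)), 1)
  expect_equal(jaccardSamples(matrix(c(1, 1, 0), 1), matrix(c(1, 0, 0), 1)), 0.5)
  expect_equal(jaccardSamples(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1)), 0)
  # both empty counts as perfect agreement
  expect_equal(jaccardSamples(matrix(0, 1, 3), matrix(0, 1, 3)), 1)
})

test_that("rank curve follows the lowest-ranked-truth definition", {
  # single truth ranked 2 contributes from k = 2 on
  s <- matrix(c(0.5, 0.4, 0.1), 1)
  rc <- rankCurve(s, matrix(c(0, 1, 0), 1))
  expect_equal(unname(rc), c(0, 1, 1))
  # truths ranked 1 and 4 -> effective rank 4/2 = 2
  s2 <- matrix(c(0.9, 0.5, 0.4, 0.2), 1)
  rc2 <- rankCurve(s2, matrix(c(1, 0, 0, 1), 1))
  expect_equal(unname(rc2), c(0, 1, 1, 1))
  # perfectly ranked pair -> effective rank 1
  rc3 <- rankCurve(s2, matrix(c(1, 1, 0, 0), 1))
  expect_equal(unname(rc3[1]), 1)
})

test_that("rank curve equals top-k accuracy whenever rows are single-truth", {
  set.seed(11)
  s <- matrix(runif(60), 12, 5)
  y <- sample(5, 12, TRUE)
  rc <- rankCurve(s, oneHot(y, 5))
  for (k in 1:5)
    expect_equal(unname(rc[k]), topkAccuracy(s, y, k))
})

test_that("metrics match the brute-force oracles on random instances", {
  set.seed(42)
  for (rep in 1:25) {
    inst <- random_instance(15, 5)
    expect_equal(lrap(inst$scores, inst$truth),
                 oracle_lrap(inst$scores, inst$truth))
    pred <- positivePredictions(inst$scores, 0.5)
    expect_equal(jaccardSamples(pred, inst$truth),
                 oracle_jaccard(pred, inst$truth))
    expect_equal(unname(rankCurve(inst$scores, inst$truth)),
                 oracle_rank_curve(inst$scores, inst$truth, 5))
  }
})

test_that("metrics are invariant to a simultaneous label permutation", {
  set.seed(99)
  inst <- random_instance(20, 6)
  perm <- sample(6)
  s2 <- inst$scores[, perm]; t2 <- inst$truth[, perm]
  expect_equal(lrap(inst$scores, inst$truth), lrap(s2, t2))
  expect_equal(jaccardSamples(positivePredictions(inst$scores),
                              inst$truth),
               jaccardSamples(positivePredictions(s2), t2))
  expect_equal(unname(rankCurve(inst$scores, inst$truth)),
               unname(rankCurve(s2, t2)))
})

test_that("sensitivity/specificity counts the confusion table per context", {
  # perfect single-label predictions
  y <- c(1L, 2L, 3L, 1L)
  P <- oneHot(y, 3) * 0.9
  ss <- sensitivitySpecificity(P, oneHot(y, 3), "top1")
  expect_equal(ss$sensitivity, rep(1, 3))
  expect_equal(ss$specificity, rep(1, 3))
  expect_equal(ss$support, c(2L, 1L, 1L))
  # constant predictor: context 1 has sensitivity 1 but specificity 0
  Pconst <- matrix(rep(c(0.9, 0.05, 0.05), 4), 4, 3, byrow = TRUE)
  ss2 <- sensitivitySpecificity(Pconst, oneHot(y, 3), "top1")
  expect_equal(ss2$sensitivity, c(1, 0, 0))
  expect_equal(ss2$specificity[1], 0)
  # a context absent from the truth is NA, not 0
  ss3 <- sensitivitySpecificity(Pconst, oneHot(c(1L, 1L, 2L, 2L), 3), "top1")
  expect_true(is.na(ss3$sensitivity[3]))
})

test_that("confusion likelihoods reduce to identity for a perfect predictor", {
  y <- rep(1:4, each = 3)
  P <- oneHot(y, 4) * 0.8 + 0.05
  M <- confusionLikelihood(P, y, 1L)
  expect_equal(M, diag(4))
  # top-3 rows sum to 3 for every supported truth
  M3 <- confusionLikelihood(P, y, 3L)
  expect_equal(unname(rowSums(M3)), rep(3, 4))
})

test_that("support-weighted diagonal of the confusion matrix equals top-k accuracy", {
  set.seed(7)
  P <- matrix(runif(80), 20, 4)
  y <- sample(4, 20, TRUE)
  for (k in c(1L, 3L)) {
    M <- confusionLikelihood(P, y, k)
    supp <- tabulate(y, 4)
    diag_mean <- sum(diag(M) * supp, na.rm = TRUE) / sum(supp)
    expect_equal(diag_mean, topkAccuracy(P, y, k))
  }
})

test_that("partial agreement scores categories with the both-empty rule", {
  cl <- curatedLists()
  sp <- function(smiles, roles) data.frame(smiles = smiles, role = roles,
                                           stringsAsFactors = FALSE)
  full <- buildContextKey(sp(
    c(cl$precatalysts[1], cl$ligands[1], cl$bases[1], cl$solvents[1]),
    c("pre-catalyst", "ligand", "base", "solvent")))
  same_base <- buildContextKey(sp(
    c(cl$precatalysts[2], cl$ligands[2], cl$bases[1], cl$solvents[2]),
    c("pre-catalyst", "ligand", "base", "solvent")))
  expect_equal(partialAgreement(full, full)$score, 1)
  pa <- partialAgreement(full, same_base)
  expect_equal(pa$score, 0.25)
  expect_identical(unname(pa$flags),
                   c(FALSE, FALSE, TRUE, FALSE))
  # both lacking a ligand: ligand flag counts as agreement
  nl1 <- buildContextKey(sp(c(cl$precatalysts[1], cl$bases[1], cl$solvents[1]),
                            c("pre-catalyst", "base", "solvent")))
  nl2 <- buildContextKey(sp(c(cl$precatalysts[2], cl$bases[2], cl$solvents[2]),
                            c("pre-catalyst", "base", "solvent")))
  pa2 <- partialAgreement(nl1, nl2)
  expect_true(pa2$flags[["ligand"]])
  expect_equal(pa2$score, 0.25)
  # catalyst and pre-catalyst are one merged comparison category
  mixed1 <- buildContextKey(sp(c(cl$catalysts[1], cl$bases[1]),
                               c("catalyst", "base")))
  mixed2 <- buildContextKey(sp(c(cl$catalysts[1], cl$bases[1]),
                               c("pre-catalyst", "base")))
  expect_true(partialAgreement(mixed1, mixed2)$flags[["catalyst"]])
})

test_that("popularity baselines enumerate correctly and are monotone", {
  counts <- c(40L, 30L, 20L, 10L)
  y <- rep(1:4, each = 5)  # uniform truth
  b <- popularityBaselines(counts, y)
  expect_equal(b$top1, 0.25)
  expect_equal(b$top3, 0.75)
  # truth always the most popular context
  expect_equal(popularityBaselines(counts, rep(1L, 8))$top1, 1)
  set.seed(3)
  yr <- sample(4, 30, TRUE)
  br <- popularityBaselines(counts, yr)
  expect_gte(br$top3, br$top1)
})

test_that("the paired delta test wraps a two-sided paired t-test", {
  a <- c(0.5, 0.6, 0.7, 0.55, NA)
  b <- c(0.6, 0.65, 0.75, 0.6, 0.9)
  res <- pairedDeltaTest(a, b)
  ht <- t.test(b[1:4], a[1:4], paired = TRUE)
  expect_equal(res$pValue, ht$p.value)
  expect_equal(res$meanDelta, unname(ht$estimate))
})
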