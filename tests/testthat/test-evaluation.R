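mkTruth <- function(edges_mat, signed = FALSE) {
  TruthNetwork(edges_mat, threshold = 0, signed = signed)
}

test_that("AUPRC ratio is exact for perfect and constant predictors", {
  set.seed(71)
  G <- 6
  genes <- paste0("g", 1:G)
  tr <- matrix(0, G, G, dimnames = list(genes, genes))
  tr[matrix(c(2, 1, 3, 2, 5, 4, 1, 6), ncol = 2, byrow = TRUE)] <- 1
  truth <- mkTruth(tr)
  prev <- mean(tr[row(tr) != col(tr)] > 0)
  # truth-as-scores predictor: AUPRC = 1, ratio = 1/prevalence
  expect_equal(auprcRatio(tr, truth), 1 / prev)
  # constant scores: one tie block -> AUPRC = prevalence, ratio = 1
  expect_equal(auprcRatio(matrix(0.3, G, G), truth), 1)
})

test_that("AUPRC matches a brute-force threshold-sweep oracle", {
  set.seed(73)
  for (rep in 1:5) {
    n <- 20
    y <- runif(n) < 0.3
    if (!any(y)) y[1] <- TRUE
    s <- round(runif(n), 1)              # coarse scores force ties
    expect_equal(renge:::.auprc(s, y), bruteAuprc(s, y), tolerance = 1e-12)
  }
  # 4-node toy with hand-set scores
  genes <- paste0("g", 1:4)
  tr <- matrix(0, 4, 4, dimnames = list(genes, genes))
  tr[2, 1] <- 1; tr[3, 1] <- 1; tr[4, 3] <- 1
  sc <- matrix(0, 4, 4, dimnames = list(genes, genes))
  sc[2, 1] <- 0.9; sc[3, 1] <- 0.2; sc[4, 3] <- 0.5; sc[1, 2] <- 0.7
  off <- row(tr) != col(tr)
  expect_equal(auprcRatio(sc, mkTruth(tr)),
               bruteAuprc(sc[off], tr[off] > 0) / mean(tr[off] > 0))
})

test_that("random scores give an AUPRC ratio near one", {
  # balanced 100-pair instance; at low prevalence the AUPRC of a random
  # ranking is biased upward at finite n (see the methods vignette)
  set.seed(79)
  y <- c(rep(TRUE, 50), rep(FALSE, 50))
  ratios <- replicate(200, bruteAuprc(runif(100), y) / 0.5)
  expect_lt(abs(mean(ratios) - 1), 0.1)
  # and the package agrees with the oracle on one such draw
  s <- runif(100)
  expect_equal(renge:::.auprc(s, y), bruteAuprc(s, y))
})

test_that("signed AUPRC ratios floor opposite-sign confidences", {
  genes <- paste0("g", 1:4)
  ts <- matrix(0, 4, 4, dimnames = list(genes, genes))
  ts[2, 1] <- 0.8; ts[3, 1] <- -0.6; ts[4, 2] <- 0.5
  truth <- mkTruth(ts, signed = TRUE)
  # perfect signed scores
  expect_equal(signedAuprcRatio(ts, truth, "+"),
               1 / (2 / 12))
  expect_equal(signedAuprcRatio(ts, truth, "-"), 1 / (1 / 12))
  # mixed toy vs brute-force oracle after flooring
  sc <- ts; sc[2, 1] <- 0.3; sc[1, 3] <- -0.9; sc[4, 2] <- -0.2
  off <- row(ts) != col(ts)
  lab <- (ts > 0)[off]
  expect_equal(signedAuprcRatio(sc, truth, "+"),
               bruteAuprc(pmax(sc, 0)[off], lab) / mean(lab))
  # all-positive truth and sign = "-" -> error
  tp <- mkTruth(abs(ts), signed = TRUE)
  expect_error(signedAuprcRatio(ts, tp, "-"), "signed true edges")
})

test_that("edge classification follows shortest paths in the truth", {
  genes <- c("g1", "g2", "g3")
  tr <- matrix(0, 3, 3, dimnames = list(genes, genes))
  tr[2, 1] <- 1; tr[3, 2] <- 1        # chain 1 -> 2 -> 3
  truth <- mkTruth(tr)
  pred <- data.frame(regulator = c("g1", "g1", "g3"),
                     target = c("g2", "g3", "g1"),
                     coefficient = c(3, 2, 1))
  cls <- classifyEdges(pred, truth)
  expect_equal(cls$class, c("direct", "indirect", "no_path"))
  # a direct edge plus a longer path stays direct (shortest path governs)
  tr2 <- tr; tr2[3, 1] <- 1
  cls2 <- classifyEdges(pred, mkTruth(tr2))
  expect_equal(cls2$class[2], "direct")
  # empty truth: everything unreachable
  cls3 <- classifyEdges(pred, mkTruth(tr * 0 + diag(0, 3)))
  expect_equal(unique(cls3$class), "no_path")
  # partition is exhaustive and exclusive
  expect_true(all(cls$class %in% c("direct", "indirect", "no_path")))
})

test_that("confidence rank correlation equals rank-then-Pearson with ties", {
  genes <- paste0("g", 1:3)
  p <- matrix(c(0, 1, 2, 3, 0, 4, 5, 6, 0), 3, 3,
              dimnames = list(genes, genes))
  expect_equal(confidenceRankCorrelation(p, p), 1)
  expect_equal(confidenceRankCorrelation(p, -p), -1)
  set.seed(83)
  s <- matrix(sample(1:3, 9, replace = TRUE), 3, 3,
              dimnames = list(genes, genes))   # ties by construction
  off <- row(p) != col(p)
  oracle <- cor(rank(p[off]), rank(s[off]))
  expect_equal(confidenceRankCorrelation(p, s), oracle, tolerance = 1e-12)
  expect_error(confidenceRankCorrelation(p[1:2, 1:2, drop = FALSE] * 0 + 1,
                                         p[1:2, 1:2, drop = FALSE]),
               "fewer than 3")
})

test_that("regulatory correlation flags duplicated and negated profiles", {
  set.seed(89)
  a <- rnorm(6)
  A <- cbind(a, a, -a, rnorm(6))
  colnames(A) <- paste0("g", 1:4)
  R <- regulatoryCorrelation(A)
  expect_equal(R[1, 2], 1)
  expect_equal(R[1, 3], -1)
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 4))
  # hand 4x4 check against rank-then-Pearson
  expect_equal(R[1, 4], cor(rank(a), rank(A[, 4])), tolerance = 1e-12)
  # constant column -> NA entries
  A2 <- cbind(A, konst = rep(1, 6))
  R2 <- regulatoryCorrelation(A2)
  expect_true(all(is.na(R2["konst", setdiff(colnames(A2), "konst")])))
})

test_that("degree summaries count and weight significant out-edges", {
  ed <- data.frame(regulator = c("g1", "g1", "g1", "g2"),
                   target = c("g2", "g3", "g4", "g1"),
                   coefficient = c(0.5, 1.5, -0.7, 0.2),
                   p_value = c(0.001, 0.001, 0.002, 0.5),
                   q_value = c(0.004, 0.004, 0.006, 0.5))
  cnt <- degreeSummary(ed, fdr = 0.01, weight = "count")
  expect_equal(cnt$n_pos[cnt$gene == "g1"], 2L)
  expect_equal(cnt$n_neg[cnt$gene == "g1"], 1L)
  expect_equal(cnt$n_pos[cnt$gene == "g2"], 0L)
  ws <- degreeSummary(ed, fdr = 0.01, weight = "abs_sum")
  expect_equal(ws$weighted_outdegree[ws$gene == "g1"], 2.7)
  # nothing passes a tiny FDR
  none <- degreeSummary(ed, fdr = 1e-6, weight = "count")
  expect_true(all(none$n_pos == 0 & none$n_neg == 0))
})

test_that("truth thresholding is monotone and hits the extremes", {
  set.seed(97)
  genes <- paste0("g", 1:5)
  S <- matrix(runif(25, 0, 500), 5, 5, dimnames = list(genes, genes))
  lo <- truthEdges(thresholdTruth(S, -1))
  hi <- truthEdges(thresholdTruth(S, 600))
  mid1 <- truthEdges(thresholdTruth(S, 50))
  mid2 <- truthEdges(thresholdTruth(S, 300))
  expect_true(all(lo[row(lo) != col(lo)]))   # complete off-diagonal network
  expect_false(any(hi))
  expect_true(all(which(mid2) %in% which(mid1)))  # nestedness
})
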