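test_that("confusion metrics reproduce hand-computed values", {
  # perfect classifier
  r <- confusionMetrics(rep(c(1, 0), each = 50), rep(c(1, 0), each = 50))
  expect_equal(c(r@acc, r@mcc, r@sn, r@sp), c(1, 1, 1, 1))

  # all-positive predictor on balanced labels: SN 1, SP 0, MCC 0 by the
  # zero-denominator convention
  r <- confusionMetrics(rep(c(1, 0), each = 10), rep(1, 20))
  expect_equal(c(r@acc, r@mcc, r@sn, r@sp), c(0.5, 0, 1, 0))

  # TP=3, FP=1, TN=4, FN=2, by hand from the defining formulas
  labels <- c(rep(1, 5), rep(0, 5))
  preds <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  r <- confusionMetrics(labels, preds)
  expect_equal(c(r@tp, r@fp, r@tn, r@fn), c(3L, 1L, 4L, 2L))
  expect_equal(r@acc, 0.7)
  expect_equal(r@sn, 3 / 5)
  expect_equal(r@sp, 4 / 5)
  expect_equal(r@mcc, (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6))

  expect_error(confusionMetrics(numeric(0), numeric(0)), "empty")
})

test_that("AUC equals the concordant-pair statistic, with and without ties", {
  # perfect separation
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  set.seed(41)
  for (rep in 1:10) {
    labels <- sample(c(0, 1), 50, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), 50, replace = TRUE)  # many ties
    expect_equal(rocAuc(labels, scores)$auc, bruteAuc(labels, scores))
  }
  expect_error(rocAuc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("ROC curves run from (0,0) to (1,1) and match label-free scores", {
  set.seed(6)
  labels <- rep(c(1, 0), 250)
  scores <- rnorm(500)
  ra <- rocAuc(labels, scores)
  expect_equal(unlist(ra$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(ra$roc[nrow(ra$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(ra$roc$fpr) >= 0), "fpr monotone")
  # scores independent of labels: AUC near 1/2
  expect_equal(ra$auc, 0.5, tolerance = 0.06)
})

test_that("target-jackknife runs one round per real sample and never tests synthetic rows", {
  mws <- simulateWindows(nPos = 10, nNeg = 16, seed = 21)
  fs <- smoteBalance(encodeWindows(mws), k = 3, seed = 2)
  expect_equal(nrow(featureMatrix(fs)), 32L)  # 26 real + 6 synthetic
  tested <- integer(0)
  dummyTrainer <- function(x, labels) {
    structure(list(n = nrow(x)), class = "dummyModel")
  }
  # a trainer-visible probe: each round must train on all rows but one,
  # and the held-out one must be real
  trainer <- function(x, labels) {
    expect_equal(nrow(x), 31L)
    dummyTrainer(x, labels)
  }
  registerS3method("predict", "dummyModel",
                   function(object, newdata, ...) 1,
                   envir = asNamespace("stats"))
  r <- targetJackknife(fs, trainer = trainer)
  expect_equal(attr(r, "rounds"), 26L)
  # all-positive dummy: SN = 1, SP = 0
  expect_equal(r@sn, 1)
  expect_equal(r@sp, 0)
})

test_that("jackknife without synthetic rows is ordinary leave-one-out", {
  mws <- simulateWindows(nPos = 6, nNeg = 6, seed = 31)
  fs <- encodeWindows(mws)
  rounds <- 0L
  trainer <- function(x, labels) {
    rounds <<- rounds + 1L
    trainSVM(x, labels)
  }
  r <- targetJackknife(fs, trainer = trainer)
  expect_equal(rounds, 12L)
  expect_equal(attr(r, "rounds"), 12L)
  expect_equal(r@tp + r@tn + r@fp + r@fn, 12L)
})

test_that("chromosome-parity holdout routes odd-listed to train, even-listed to test", {
  mws <- MethylWindowSet(
    replicate(5, randomSeq(41)),
    label = c("positive", "negative", "positive", "negative", "positive"),
    chrom = c("chr3", "chr4", "chrX", "1", "chr13"),
    pos = 1:5)
  sp <- chromosomeHoldoutSplit(mws)
  expect_equal(unname(windowCoords(sp$train)$chrom), c("chr3", "1"))
  expect_equal(unname(windowCoords(sp$test)$chrom), "chr4")
  expect_length(sp$excluded, 2L)  # chrX and chr13
  noCoord <- MethylWindowSet(c(a = randomSeq(41)), label = "positive")
  expect_error(chromosomeHoldoutSplit(noCoord), "no chromosome")
})

test_that("evaluation reports serialize to key-value text", {
  r <- confusionMetrics(c(1, 1, 0, 0), c(1, 0, 0, 0),
                        scores = c(0.9, 0.4, 0.3, 0.2))
  path <- tempfile()
  rocPath <- tempfile()
  writeEvalReport(r, path, rocPath)
  lines <- readLines(path)
  expect_true(any(grepl("^ACC\t0.75$", lines)))
  roc <- read.delim(rocPath)
  expect_equal(colnames(roc), c("fpr", "tpr"))
})
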