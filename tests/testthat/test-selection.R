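makeInformative <- function(n = 60, pNoise = 20, seed = 2) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(ifelse(y == 1, 1, -1) + rnorm(n, sd = 0.1),
             matrix(rnorm(n * pNoise), n))
  colnames(X) <- c("signal", paste0("noise", seq_len(pNoise)))
  list(X = X, y = y)
}

test_that("a label-aligned feature receives the top importance score", {
  d <- makeInformative()
  sc <- importanceScores(d$X, d$y)
  expect_equal(which.max(sc), 1L, ignore_attr = TRUE)
})

test_that("constant features score zero and permutation permutes scores", {
  d <- makeInformative()
  Xc <- cbind(d$X, const = 5)
  sc <- importanceScores(Xc, d$y)
  expect_equal(unname(sc["const"]), 0)
  perm <- c(3, 1, 2, seq(4, ncol(Xc)))
  sc2 <- importanceScores(Xc[, perm], d$y)
  expect_equal(unname(sc2), unname(sc[perm]), tolerance = 1e-8)
})

test_that("incremental selection recovers a planted informative subset", {
  # ten complementary informative features: each one separates a different
  # tenth of the positives (plus a weak global shift), so accuracy climbs
  # until all ten are in and the arg-max prefix sits near dimension 10
  set.seed(42)
  nPos <- 100; nNeg <- 100
  y <- rep(c(1, 0), c(nPos, nNeg))
  X <- matrix(rnorm((nPos + nNeg) * 40), nPos + nNeg)
  grp <- rep(1:10, each = 10)
  for (i in 1:10) {
    X[y == 1, i] <- X[y == 1, i] + 0.4
    X[which(y == 1)[grp == i], i] <- X[which(y == 1)[grp == i], i] + 4
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  res <- incrementalSelection(X, y, dims = seq_len(25))
  expect_true(all(seq_len(10) %in% res@chosen))
  expect_gte(res@chosenDim, 10)
  expect_lte(res@chosenDim, 10 + 10)
  # the chosen set is a prefix of the ranking, and the curve maximum is
  # attained at the chosen dimension
  expect_equal(res@chosen, res@ranking[seq_len(res@chosenDim)])
  expect_equal(max(res@curve$accuracy),
               res@curve$accuracy[res@curve$dim == res@chosenDim])
})

test_that("selection self-consistency: re-evaluating the chosen subset reproduces the curve maximum", {
  d <- makeInformative(n = 60, pNoise = 10, seed = 7)
  ev <- cvAccuracyEvaluator(folds = 3, seed = 5)
  res <- incrementalSelection(d$X, d$y, evaluator = ev,
                              dims = c(1, 2, 5, 11))
  again <- ev(d$X[, res@chosen, drop = FALSE], d$y)
  expect_equal(again, max(res@curve$accuracy))
})

test_that("full-dimension prefix equals no selection and blocks are reported", {
  mws <- simulateWindows(nPos = 15, nNeg = 15, seed = 17)
  fs <- encodeWindows(mws)
  sc <- importanceScores(fs)
  res <- incrementalSelection(fs, scores = sc, dims = c(50, 612))
  expect_setequal(res@ranking, seq_len(612))
  expect_named(res@composition, c("kgram", "mmi", "dwt", "pseaac"))
  if (res@chosenDim == 612L) {
    expect_equal(unname(res@composition), c(84L, 30L, 312L, 186L))
  } else {
    expect_equal(sum(res@composition), res@chosenDim)
  }
  # report serialization
  path <- tempfile(); curve <- tempfile()
  writeSelectionReport(res, fs, path, curve)
  rep <- read.delim(path)
  expect_equal(nrow(rep), 612L)
  expect_true(all(rep$block %in% c("kgram", "mmi", "dwt", "pseaac")))
  expect_equal(read.delim(curve)$dim, res@curve$dim)
})
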