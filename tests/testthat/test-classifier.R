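# Small Gaussian-blob problems keep these checks fast; the full-window
# pipeline behaviour is covered by the signal-recovery tests.

makeBlobs <- function(n = 50, gap = 3, p = 8, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * p, 0), ncol = p),
             matrix(rnorm(n / 2 * p, gap), ncol = p))
  list(X = X, y = rep(c("negative", "positive"), each = n / 2))
}

test_that("sparse Bayes separates Gaussian blobs with a sparse basis", {
  b <- makeBlobs(n = 100)
  fit <- trainSparseBayes(b$X, b$y)
  expect_true(fit@converged)
  pred <- predict(fit, b$X, type = "class")
  expect_gte(mean(pred == b$y), 0.99)
  # sparsity: relevance vectors are a strict (and small) subset
  expect_lt(nrow(fit@relevanceVectors), 20)
  expect_true(all(is.finite(fit@alpha)) && all(fit@alpha > 0))
})

test_that("scores are probabilities and labels follow the threshold", {
  b <- makeBlobs(n = 60)
  fit <- trainSparseBayes(b$X, b$y)
  sc <- predict(fit, b$X, type = "response")
  expect_true(all(sc >= 0 & sc <= 1))
  both <- predict(fit, b$X, type = "both")
  expect_identical(as.character(both$label),
                   ifelse(both$score >= 0.5, "positive", "negative"))
  strict <- predict(fit, b$X, type = "class", threshold = 0.99)
  expect_true(sum(strict == "positive") <= sum(both$label == "positive"))
})

test_that("flipping all labels complements the predicted probabilities", {
  b <- makeBlobs(n = 60, gap = 2.2, seed = 5)
  flip <- ifelse(b$y == "positive", "negative", "positive")
  probe <- makeBlobs(n = 20, gap = 2.2, seed = 9)$X
  s1 <- predict(trainSparseBayes(b$X, b$y, sigma = 3), probe)
  s2 <- predict(trainSparseBayes(b$X, flip, sigma = 3), probe)
  expect_equal(s1, 1 - s2, tolerance = 0.05)
})

test_that("duplicating every training row leaves the decision function stable", {
  b <- makeBlobs(n = 40, seed = 3)
  probe <- makeBlobs(n = 16, seed = 8)$X
  f1 <- trainSparseBayes(b$X, b$y, sigma = 3)
  f2 <- trainSparseBayes(rbind(b$X, b$X), c(b$y, b$y), sigma = 3)
  expect_equal(predict(f1, probe), predict(f2, probe), tolerance = 0.1)
})

test_that("training-row order does not change predictions", {
  b <- makeBlobs(n = 40, seed = 4)
  probe <- makeBlobs(n = 10, seed = 11)$X
  perm <- sample(seq_len(40))
  f1 <- trainSparseBayes(b$X, b$y, sigma = 3)
  f2 <- trainSparseBayes(b$X[perm, ], b$y[perm], sigma = 3)
  expect_equal(predict(f1, probe), predict(f2, probe), tolerance = 1e-6)
})

test_that("standardization makes predictions invariant to feature rescaling", {
  b <- makeBlobs(n = 40, seed = 6)
  probe <- makeBlobs(n = 10, seed = 12)$X
  scale <- c(1000, rep(1, 7))
  shift <- c(0, 50, rep(0, 6))
  transform <- function(M) sweep(sweep(M, 2, scale, "*"), 2, shift, "+")
  f1 <- trainSparseBayes(b$X, b$y)
  f2 <- trainSparseBayes(transform(b$X), b$y)
  expect_equal(predict(f1, probe), predict(f2, transform(probe)),
               tolerance = 1e-6)
})

test_that("kernel matrix entries are in (0, 1] with unit diagonal", {
  env <- asNamespace("methylWave")
  set.seed(2)
  X <- matrix(rnorm(60), 10)
  K <- env$.gaussKernel(X, X, sigma = 2)
  expect_equal(unname(diag(K)), rep(1, 10))
  expect_true(all(K > 0 & K <= 1))
})

test_that("degenerate inputs are rejected", {
  b <- makeBlobs(n = 20)
  expect_error(trainSparseBayes(b$X, rep("positive", 20)), "single class")
  bad <- b$X; bad[1, 1] <- NA
  expect_error(trainSparseBayes(bad, b$y), "non-finite")
  fit <- trainSparseBayes(b$X, b$y)
  expect_error(predict(fit, b$X[, 1:5]), "feature width mismatch.*8.*5")
})

test_that("the SVM alternative honours the same contract", {
  b <- makeBlobs(n = 60)
  fit <- trainSVM(b$X, b$y)
  expect_gte(mean(predict(fit, b$X, type = "class") == b$y), 0.99)
  sc <- predict(fit, b$X, type = "response")
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(predict(fit, b$X[, 1:3]), "feature width mismatch")
  # lower cost tolerates more training error on noisy data
  set.seed(13)
  noisy <- makeBlobs(n = 80, gap = 1)
  flip <- sample(80, 12)
  yN <- noisy$y; yN[flip] <- ifelse(yN[flip] == "positive", "negative",
                                    "positive")
  accSmall <- mean(predict(trainSVM(noisy$X, yN, cost = 1e-3), noisy$X,
                           type = "class") == yN)
  accBig <- mean(predict(trainSVM(noisy$X, yN, cost = 100), noisy$X,
                         type = "class") == yN)
  expect_gte(accBig, accSmall)
})

test_that("models survive a save/load round trip", {
  b <- makeBlobs(n = 40)
  fit <- trainSparseBayes(b$X, b$y)
  path <- tempfile(fileext = ".rds")
  saveModel(fit, path)
  back <- loadModel(path)
  expect_equal(predict(back, b$X), predict(fit, b$X))
  expect_error(suppressWarnings(loadModel(tempfile())),
               "cannot open|No such")
  junk <- tempfile(); saveRDS(list(a = 1), junk)
  expect_error(loadModel(junk), "not a methylWave model")
})
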