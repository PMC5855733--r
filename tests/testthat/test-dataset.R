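test_that("read-count labeling discards low coverage and ties, keeps majorities", {
  sites <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40),
                      methylated_reads = c(5, 1, 2, 0),
                      total_reads = c(6, 3, 4, 9))
  out <- labelSites(sites)
  expect_equal(out$pos, c(10, 40))
  expect_equal(as.character(out$label), c("positive", "negative"))
  expect_equal(attr(out, "nLowCoverage"), 1L)   # 1/3 discarded by depth
  expect_equal(attr(out, "nTies"), 1L)          # 2/4 tie discarded
  expect_error(labelSites(data.frame(chrom = 1, pos = 1,
                                     methylated_reads = 5,
                                     total_reads = 4)),
               "methylated_reads")
})

test_that("window extraction centres the site and skips impossible windows", {
  sim <- simulateMethylome(nChrom = 2, chromLength = 400, sitesPerChrom = 5,
                           seed = 3)
  labeled <- labelSites(sim$sites)
  mws <- extractWindows(sim$genome, labeled, flank = 20)
  w <- as.character(windowSeqs(mws))
  expect_true(all(nchar(w) == 41))
  expect_true(all(substr(w, 21, 21) == "C"))
  coords <- windowCoords(mws)
  # window content matches the genome at the recorded coordinates
  for (i in seq_len(min(4, length(mws)))) {
    chrSeq <- sim$genome[[coords$chrom[i]]]
    expect_equal(unname(w[i]), as.character(Biostrings::subseq(
      chrSeq, coords$pos[i] - 20, coords$pos[i] + 20)))
  }
  # a site too close to the end of a short toy chromosome is reported
  toy <- Biostrings::DNAStringSet(c(chrT = paste(
    rep("ACGT", 15), collapse = "")))
  sites <- data.frame(chrom = "chrT", pos = 50,
                      label = factor("positive",
                                     levels = c("negative", "positive")))
  expect_error(extractWindows(toy, sites, flank = 100), "no extractable")
  bigger <- extractWindows(
    toy, rbind(sites, data.frame(chrom = "chrT", pos = 30,
                                 label = factor("negative",
                                                levels = c("negative",
                                                           "positive")))),
    flank = 15, requireCenterC = FALSE)
  skipped <- attr(bigger, "skipped")
  expect_equal(skipped$id, "chrT:50")
  expect_match(skipped$reason, "out of chromosome bounds")
})

test_that("flank 100 produces 201-bp windows", {
  sim <- simulateMethylome(nChrom = 1, chromLength = 3000,
                           sitesPerChrom = 8, flank = 100, seed = 5)
  labeled <- labelSites(sim$sites)
  mws <- extractWindows(sim$genome, labeled, flank = 100)
  expect_true(all(Biostrings::width(windowSeqs(mws)) == 201))
})

test_that("deduplication collapses within-class copies and removes conflicts", {
  s1 <- randomSeq(41); s2 <- randomSeq(41); s3 <- randomSeq(41)
  pos <- MethylWindowSet(c(a = s1, b = s1, c = s2), label = "positive")
  neg <- MethylWindowSet(c(d = s3), label = "negative")
  out <- deduplicateWindows(pos, neg)
  expect_equal(unname(as.character(windowSeqs(out$positive))), c(s1, s2))
  expect_equal(length(out$negative), 1L)
  expect_equal(out$report[["duplicates_positive"]], 1L)
  expect_equal(out$report[["conflicts"]], 0L)

  # cross-class conflict removes the sequence from both sides
  pos2 <- MethylWindowSet(c(a = s1), label = "positive")
  neg2 <- MethylWindowSet(c(b = s1), label = "negative")
  out2 <- deduplicateWindows(pos2, neg2)
  expect_equal(length(out2$positive), 0L)
  expect_equal(length(out2$negative), 0L)
  expect_equal(out2$report[["conflicts"]], 1L)

  # disjoint sets unchanged, and the operation is idempotent
  out3 <- deduplicateWindows(out$positive, out$negative)
  expect_equal(as.character(windowSeqs(out3$positive)),
               as.character(windowSeqs(out$positive)))
  expect_equal(sum(out3$report), 0)
})

test_that("SMOTE equalizes classes with on-segment synthetic rows", {
  mws <- simulateWindows(nPos = 12, nNeg = 30, seed = 13)
  fs <- encodeWindows(mws)
  bal <- smoteBalance(fs, k = 5, seed = 99)
  lab <- sampleInfo(bal)$label
  expect_equal(sum(lab == "positive"), sum(lab == "negative"))
  expect_equal(sum(sampleInfo(bal)$origin == "synthetic"), 18L)
  # original rows unchanged, in place
  expect_equal(featureMatrix(bal)[1:42, ], featureMatrix(fs))
  # every synthetic row lies on a segment between a real minority row and
  # one of its k nearest minority neighbours
  X <- featureMatrix(fs)[sampleInfo(fs)$label == "positive", ]
  synth <- featureMatrix(bal)[sampleInfo(bal)$origin == "synthetic", ]
  d <- as.matrix(dist(X)); diag(d) <- Inf
  for (j in seq_len(nrow(synth))) {
    onSegment <- FALSE
    for (a in seq_len(nrow(X))) {
      nn <- order(d[a, ])[1:5]
      for (b in nn) {
        seg <- synth[j, ] - X[a, ]
        dir <- X[b, ] - X[a, ]
        denom <- sum(dir^2)
        u <- if (denom > 0) sum(seg * dir) / denom else 0
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((seg - u * dir)^2)) < 1e-8) {
          onSegment <- TRUE; break
        }
      }
      if (onSegment) break
    }
    expect_true(onSegment, label = paste("synthetic row", j, "on segment"))
  }
})

test_that("SMOTE is a no-op on balanced data and errors on tiny minorities", {
  mws <- simulateWindows(nPos = 8, nNeg = 8, seed = 1)
  fs <- encodeWindows(mws)
  expect_identical(smoteBalance(fs, seed = 1), fs)
  mws2 <- simulateWindows(nPos = 3, nNeg = 10, seed = 1)
  fs2 <- encodeWindows(mws2)
  expect_error(smoteBalance(fs2, k = 5, seed = 1), "more than k")
})

test_that("windows round-trip through the FASTA dialect", {
  sim <- simulateMethylome(nChrom = 2, chromLength = 500, sitesPerChrom = 4,
                           seed = 11)
  mws <- extractWindows(sim$genome, labelSites(sim$sites), flank = 20)
  path <- tempfile(fileext = ".fa")
  writeWindowsFasta(mws, path)
  back <- readWindowsFasta(path)
  expect_equal(as.character(windowSeqs(back)),
               as.character(windowSeqs(mws)))
  expect_equal(as.character(windowLabels(back)),
               as.character(windowLabels(mws)))
  expect_equal(windowCoords(back), windowCoords(mws))
})
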