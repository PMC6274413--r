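test_that("metric identities at the reference confusion tables", {
  perfect <- computeMetrics(list(nPos = 100, nNeg = 200, falseNeg = 0,
                                 falsePos = 0))
  expect_equal(perfect, list(sn = 1, sp = 1, acc = 1, mcc = 1))
  half <- computeMetrics(list(nPos = 200, nNeg = 400, falseNeg = 100,
                              falsePos = 200))
  expect_equal(half$acc, 0.5)
  expect_equal(half$mcc, 0)
  worst <- computeMetrics(list(nPos = 50, nNeg = 70, falseNeg = 50,
                               falsePos = 70))
  expect_equal(worst$acc, 0)
  expect_equal(worst$mcc, -1)
  expect_error(computeMetrics(list(nPos = 0, nNeg = 10, falseNeg = 0,
                                   falsePos = 0)), "non-empty")
  expect_error(computeMetrics(list(nPos = 5, nNeg = 10, falseNeg = 6,
                                   falsePos = 0)), "exceed")
  expect_warning(
    computeMetrics(list(nPos = 4, nNeg = 4, falseNeg = 4, falsePos = 0)),
    "MCC")
})

test_that("error-rate MCC equals the classical Matthews formula", {
  set.seed(60)
  for (trial in 1:200) {
    np <- sample(2:500, 1); nn <- sample(2:500, 1)
    fn <- sample(0:np, 1); fp <- sample(0:nn, 1)
    tp <- np - fn; tn <- nn - fp
    den <- prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    classical <- if (den == 0) 0 else
      (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
    got <- suppressWarnings(
      computeMetrics(list(nPos = np, nNeg = nn, falseNeg = fn,
                          falsePos = fp)))
    expect_equal(got$mcc, classical, tolerance = 1e-9)
    expect_equal(got$sn, tp / np, tolerance = 1e-12)
    expect_equal(got$sp, tn / nn, tolerance = 1e-12)
    expect_equal(got$acc, (tp + tn) / (np + nn), tolerance = 1e-12)
  }
})

test_that("ROC: perfect separation, reversal symmetry, permutation null", {
  lab <- rep(c(TRUE, FALSE), each = 50)
  perf <- rocAuc(c(runif(50, 0.6, 1), runif(50, 0, 0.4)), lab)
  expect_equal(perf$auc, 1)
  expect_equal(perf$curve$fpr[1], 0)
  expect_equal(perf$curve$tpr[nrow(perf$curve)], 1)
  set.seed(71)
  s <- rnorm(300); l <- rnorm(300) > 0
  expect_equal(rocAuc(-s, l)$auc, 1 - rocAuc(s, l)$auc, tolerance = 1e-12)
  # metrics invariant to sample order
  o <- sample(300)
  expect_equal(rocAuc(s[o], l[o])$auc, rocAuc(s, l)$auc, tolerance = 1e-12)
  # labels independent of scores, n = 2000 -> AUC ~ 0.5
  set.seed(72)
  s2 <- rnorm(2000); l2 <- sample(rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(rocAuc(s2, l2)$auc - 0.5), 0.05)
  expect_error(rocAuc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("confusion counts accept logical and signed labels", {
  cc <- confusionCounts(c(1L, 1L, -1L, -1L), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cc, list(nPos = 2L, nNeg = 2L, falseNeg = 1L, falsePos = 1L))
})

test_that("target CV partitions experimental samples exactly once and conserves counts", {
  bm <- smallFixtureBenchmark(seed = 19L)
  cfg <- pipelineConfig(seed = 4L, nTrees = 25L, nFolds = 10L)
  cv <- targetCrossValidation(bm, k = 2L, config = cfg)
  expect_s3_class(cv, "ppbsCVResult")
  expect_equal(nrow(cv$folds), 10L)
  # pooled counts = fold sums = benchmark class sizes
  expect_equal(cv$pooled$nPos, sum(cv$folds$nPos))
  expect_equal(cv$pooled$nPos, nPosBenchmark(bm))
  expect_equal(cv$pooled$nNeg, nNegBenchmark(bm))
  # every sample tested exactly once
  expect_setequal(cv$scores$index, seq_len(ncol(bm)))
  expect_equal(anyDuplicated(cv$scores$index), 0L)
  # pooled metrics recompute from pooled counts
  expect_equal(cv$metrics$acc, computeMetrics(cv$pooled)$acc)
  expect_error(targetCrossValidation(bm, k = 1L,
                                     config = pipelineConfig(nFolds = 200L)),
               "nFolds")
})

test_that("hypothetical samples never reach a test fold", {
  bm <- smallFixtureBenchmark(seed = 29L, nProteins = 5L)
  ts <- asTrainingSet(bm)
  # graft hypothetical positives onto the training set up front
  aug <- ihtsAugment(ts, seed = 3L)
  expect_gt(sum(sampleProvenance(aug) == "hypothetical"), 0L)
  cv <- targetCrossValidation(aug, k = 1L,
                              config = pipelineConfig(seed = 2L, nTrees = 15L))
  tested <- cv$scores$index
  expect_true(all(sampleProvenance(aug)[tested] == "experimental"))
  expect_equal(length(tested), sum(sampleProvenance(aug) == "experimental"))
})

test_that("the fold split is seed-stable, so a K-scan reuses one partition", {
  bm <- smallFixtureBenchmark(seed = 37L, nProteins = 4L)
  cfg <- pipelineConfig(seed = 10L, nTrees = 10L, nFolds = 5L)
  cv1 <- targetCrossValidation(bm, k = 1L, config = cfg)
  cv2 <- targetCrossValidation(bm, k = 3L, config = cfg)
  f1 <- cv1$scores[order(cv1$scores$index), "fold"]
  f2 <- cv2$scores[order(cv2$scores$index), "fold"]
  expect_identical(f1, f2)
})

test_that("K-scan reports the requested curve and the smallest argmax", {
  bm <- smallFixtureBenchmark(seed = 43L, nProteins = 4L)
  cfg <- pipelineConfig(seed = 6L, nTrees = 10L, nFolds = 5L)
  sc <- scanK(bm, kStart = 1L, nValues = 3L, config = cfg)
  expect_equal(nrow(sc$curve), 3L)
  expect_identical(sc$curve$k, 1:3)
  expect_true(sc$bestK %in% 1:3)
  expect_equal(sc$bestK, sc$curve$k[which.max(sc$curve$acc)])
  f <- withr::local_tempfile(fileext = ".json")
  writeCVReport(sc$results[[1]], f)
  rep <- jsonlite::read_json(f)
  expect_named(rep, c("k", "nFolds", "folds", "pooled", "metrics", "roc"),
               ignore.order = TRUE)
  expect_equal(rep$metrics$acc, sc$curve$acc[1])
})
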