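cfgFast <- pipelineConfig(seed = 1L, nTrees = 40L)

test_that("a per-property forest separates well-separated classes", {
  ts <- makeTrainingSet(nPos = 500, nNeg = 500, p = 140L, sep = 3,
                        informative = 20L, seed = 12)
  pred <- trainPropertyPredictor(ts, "H1", cfgFast)  # slice = cols 1..20
  sc <- wavePPBS:::.rfScore(pred, ts@features[, 1:20])
  acc <- mean((sc >= 0.5) == (sampleLabels(ts) == 1L))
  expect_gt(acc, 0.95)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("identical class point clouds give held-out scores near 0.5", {
  set.seed(41)
  X <- matrix(rnorm(400 * 140), 400, 140)
  ts <- TrainingSet(X, rep(c(1L, -1L), each = 200))
  pred <- trainPropertyPredictor(ts, "H2", cfgFast)
  held <- matrix(rnorm(300 * 20), 300, 20)
  sc <- wavePPBS:::.rfScore(pred, held)
  expect_lt(abs(mean(sc) - 0.5), 0.08)
})

test_that("forests are deterministic under a fixed seed", {
  ts <- makeTrainingSet(nPos = 60, nNeg = 60, p = 140L, sep = 1, seed = 6)
  p1 <- trainPropertyPredictor(ts, "V", cfgFast, seed = 7L)
  p2 <- trainPropertyPredictor(ts, "V", cfgFast, seed = 7L)
  Xnew <- matrix(rnorm(50 * 20), 50, 20)
  expect_identical(wavePPBS:::.rfScore(p1, Xnew), wavePPBS:::.rfScore(p2, Xnew))
  p3 <- trainPropertyPredictor(ts, "V", cfgFast, seed = 8L)
  expect_false(identical(wavePPBS:::.rfScore(p1, Xnew),
                         wavePPBS:::.rfScore(p3, Xnew)))
  expect_error(trainPropertyPredictor(
    TrainingSet(matrix(rnorm(280), 2, 140), c(1L, 1L)), "H1", cfgFast),
    "both classes")
})

test_that("the ensemble holds 7 predictors trained on one balanced set", {
  ts <- makeTrainingSet(nPos = 30, nNeg = 120, p = 140L, sep = 2, seed = 13)
  model <- trainEnsemble(ts, cfgFast)
  expect_s4_class(model, "PPBSEnsemble")
  expect_length(model@predictors, 7L)
  expect_setequal(names(model@predictors),
                  c("H1", "H2", "V", "P1", "P2", "SASA", "NCI"))
  expect_equal(model@trainingInfo$nPos, model@trainingInfo$nNeg)
  # end-to-end seeded determinism
  m2 <- trainEnsemble(ts, cfgFast)
  X <- matrix(rnorm(20 * 140), 20, 140)
  expect_identical(predictScores(model, X), predictScores(m2, X))
})

test_that("vote fusion: majority label, mean score, idempotent under identical voters", {
  ts <- makeTrainingSet(nPos = 50, nNeg = 50, p = 140L, sep = 2, seed = 21)
  model <- trainEnsemble(ts, cfgFast, optimize = FALSE)
  X <- matrix(rnorm(40 * 140), 40, 140)
  sc <- predictScores(model, X)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_true(all(sc$votes %in% 0:7))
  expect_identical(sc$call, sc$votes >= 4)
  # fusing 7 copies of one predictor equals that predictor
  clone <- model
  for (p in names(clone@predictors)) {
    f <- model@predictors[["H1"]]
    attr(f, "property") <- p
    clone@predictors[[p]] <- f
  }
  scClone <- predictScores(clone, X)
  single <- wavePPBS:::.rfScore(model@predictors[["H1"]], X[, 1:20])
  # every slice sees different columns, so feed identical features per slice
  Xsame <- X; for (k in 0:6) Xsame[, k * 20 + 1:20] <- X[, 1:20]
  scSame <- predictScores(clone, Xsame)
  expect_equal(scSame$score, single, tolerance = 1e-12)
  expect_identical(scSame$call, single >= 0.5)
  expect_error(predictScores(model, X[, 1:100]), "140")
})

test_that("per-residue prediction covers every residue in order", {
  gen <- generateLabeledProteins(fixtureSpec(nProteins = 3L,
                                             lengthRange = c(40L, 60L),
                                             seed = 14L))
  bm <- buildBenchmark(gen$labeled, gen$sequences, mode = "all")
  model <- trainEnsemble(asTrainingSet(bm), cfgFast)
  res <- predictResidues(model, gen$sequences)
  expect_equal(nrow(res), sum(nchar(gen$sequences)))
  expect_identical(paste(res$residue[res$protein == names(gen$sequences)[1]],
                         collapse = ""), unname(gen$sequences[1]))
  expect_true(all(res$score >= 0 & res$score <= 1))
  expect_true(is.logical(res$call))
  # persistence round-trip preserves predictions
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, f)
  m2 <- loadModel(f)
  expect_identical(predictResidues(m2, gen$sequences)$score, res$score)
  out <- withr::local_tempfile(fileext = ".tsv")
  writePredictionTSV(res, out)
  tab <- read.delim(out)
  expect_identical(names(tab), c("protein", "position", "residue", "score",
                                 "call"))
  expect_true(all(tab$call %in% 0:1))
})
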