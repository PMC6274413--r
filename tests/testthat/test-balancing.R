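test_that("starting K is the truncated imbalance ratio", {
  expect_identical(initialK(2828, 10943), 3L)
  expect_identical(initialK(2828, 24614), 8L)
  expect_identical(initialK(10, 10), 1L)
  expect_identical(initialK(3, 2), 0L)
  expect_error(initialK(0, 100), "at least one positive")
})

test_that("KNN cleaning removes negatives with a positive neighbour (1-D toy)", {
  # positives at 0, negatives at 0.1 and 10 (padded to 140 dims):
  # at k = 1 the 0.1 negative sees the positive, the 10 negative sees 0.1
  X <- matrix(0, 3, 140)
  X[, 1] <- c(0, 0.1, 10)
  ts <- TrainingSet(X, c(1L, -1L, -1L))
  out <- knncFilter(ts, 1L)
  expect_equal(nPositive(out), 1L)
  expect_equal(nNegative(out), 1L)
  expect_equal(out@features[2, 1], 10)
  # k = 0 disables cleaning
  expect_identical(knncFilter(ts, 0L)@features, ts@features)
  # purely negative neighbourhoods -> nothing removed
  X2 <- matrix(0, 4, 140); X2[, 1] <- c(0, 5, 5.1, 5.2)
  ts2 <- TrainingSet(X2, c(1L, -1L, -1L, -1L))
  expect_equal(nNegative(knncFilter(ts2, 2L)), 3L)
})

test_that("KNN cleaning agrees with the exhaustive pairwise oracle", {
  set.seed(17)
  for (trial in 1:30) {
    n <- sample(20:60, 1)
    ts <- makeTrainingSet(nPos = sample(3:10, 1), nNeg = n, p = 12L,
                          sep = runif(1, 0, 2), seed = 1000 + trial)
    k <- sample(1:6, 1)
    out <- knncFilter(ts, k)
    dropOracle <- oracleKnnc(ts@features, ts@label, k)
    expect_equal(nrow(out@features), nrow(ts@features) - length(dropOracle))
    keep <- setdiff(seq_len(nrow(ts@features)), dropOracle)
    expect_equal(out@features, ts@features[keep, , drop = FALSE])
  }
})

test_that("the removal set is nested in k", {
  set.seed(23)
  for (trial in 1:10) {
    ts <- makeTrainingSet(nPos = 8, nNeg = 40, p = 10L, sep = 1,
                          seed = 2000 + trial)
    removed <- lapply(c(1L, 3L, 5L, 8L), function(k)
      setdiff(seq_len(48), oracleKnnc(ts@features, ts@label, k)))
    n3 <- nrow(knncFilter(ts, 3L)@features)
    n5 <- nrow(knncFilter(ts, 5L)@features)
    expect_lte(n5, n3)   # larger k removes at least as many
    # oracle-level nesting of the removal sets
    r3 <- oracleKnnc(ts@features, ts@label, 3L)
    r5 <- oracleKnnc(ts@features, ts@label, 5L)
    expect_true(all(r3 %in% r5))
  }
})

test_that("hypothetical-sample insertion balances exactly and interpolates", {
  ts <- makeTrainingSet(nPos = 5, nNeg = 9, p = 6L, seed = 31)
  out <- ihtsAugment(ts, seed = 77)
  expect_equal(nPositive(out), 9L)
  expect_equal(nNegative(out), 9L)
  hyp <- which(sampleProvenance(out) == "hypothetical")
  expect_length(hyp, 4L)
  expect_true(all(sampleLabels(out)[hyp] == 1L))
  # each hypothetical sample lies on a segment between two experimental
  # positives: recover lambda from one coordinate and check all others
  pos <- ts@features[sampleLabels(ts) == 1L, ]
  for (h in hyp) {
    v <- out@features[h, ]
    onSegment <- FALSE
    for (i in 1:4) for (j in (i + 1):5) {
      d <- pos[j, ] - pos[i, ]
      lam <- (v - pos[i, ])[which.max(abs(d))] / d[which.max(abs(d))]
      if (lam > 0 && lam < 1 &&
          max(abs(pos[i, ] + lam * d - v)) < 1e-9) onSegment <- TRUE
    }
    expect_true(onSegment)
  }
  # balanced input returned unchanged; tiny minority class errors
  bal <- makeTrainingSet(4, 4, p = 5L, seed = 3)
  expect_identical(ihtsAugment(bal, seed = 1)@features, bal@features)
  one <- TrainingSet(matrix(rnorm(10 * 3), 10, 3), c(1L, rep(-1L, 9)))
  expect_error(ihtsAugment(one, seed = 1), "fewer than 2")
})

test_that("augmentation is deterministic under a fixed seed", {
  ts <- makeTrainingSet(nPos = 6, nNeg = 20, p = 8L, seed = 4)
  a <- ihtsAugment(ts, seed = 99)
  b <- ihtsAugment(ts, seed = 99)
  expect_identical(a@features, b@features)
  c2 <- ihtsAugment(ts, seed = 100)
  expect_false(identical(a@features, c2@features))
})

test_that("training-set optimization balances exactly without touching positives", {
  set.seed(55)
  for (trial in 1:10) {
    ts <- makeTrainingSet(nPos = sample(5:12, 1), nNeg = sample(20:60, 1),
                          p = 10L, sep = runif(1, 0, 2), seed = 3000 + trial)
    out <- optimizeTrainingSet(ts, k = sample(1:5, 1), seed = trial)
    expect_equal(nPositive(out), nNegative(out))
    # every experimental positive survives
    posIn <- ts@features[sampleLabels(ts) == 1L, , drop = FALSE]
    expIdx <- which(sampleProvenance(out) == "experimental" &
                      sampleLabels(out) == 1L)
    expect_equal(out@features[expIdx[seq_len(nrow(posIn))], , drop = FALSE],
                 posIn)
    # hypothetical samples only in the (originally) smaller class
    hyp <- sampleProvenance(out) == "hypothetical"
    if (any(hyp)) expect_true(all(sampleLabels(out)[hyp] ==
                                    sampleLabels(out)[hyp][1]))
  }
  # k = 0 (no cleaning) on balanced input is the identity
  bal <- makeTrainingSet(6, 6, p = 5L, seed = 9)
  expect_identical(optimizeTrainingSet(bal, k = 0L, seed = 1)@features,
                   bal@features)
})
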