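#' Confusion counts
#'
#' Tallies predictions against truth in the under/over-prediction form used
#' throughout the package: `nPos`/`nNeg` are the true class totals, `falseNeg`
#' the true binding sites predicted negative, `falsePos` the non-sites
#' predicted positive.
#'
#' @param truth logical (or +1/-1) true labels.
#' @param call logical predicted labels.
#' @return list with `nPos`, `nNeg`, `falseNeg`, `falsePos`.
#' @export
confusionCounts <- function(truth, call) {
  if (!is.logical(truth)) truth <- truth > 0
  list(nPos = sum(truth), nNeg = sum(!truth),
       falseNeg = sum(truth & !call), falsePos = sum(!truth & call))
}

#' Intuitive-form classification metrics
#'
#' Sensitivity, specificity, accuracy and Matthews correlation coefficient in
#' the error-rate form: with `N+`/`N-` the class totals, `N-+` the positives
#' missed and `N+-` the negatives over-called,
#' \deqn{Sn = 1 - N^{-}_{+}/N^{+}, \quad Sp = 1 - N^{+}_{-}/N^{-},}
#' \deqn{Acc = 1 - (N^{-}_{+} + N^{+}_{-})/(N^{+} + N^{-}),}
#' \deqn{Mcc = \frac{1 - (N^{-}_{+}/N^{+} + N^{+}_{-}/N^{-})}
#'   {\sqrt{(1 + (N^{+}_{-} - N^{-}_{+})/N^{+})
#'          (1 + (N^{-}_{+} - N^{+}_{-})/N^{-})}}.}
#' These are algebraically identical to the classical TP/TN/FP/FN
#' formulations; misclassifying half of each class gives `Acc = 0.5`,
#' `Mcc = 0`.
#'
#' @param counts list from [confusionCounts()] (fields `nPos`, `nNeg`,
#'   `falseNeg`, `falsePos`).
#' @return named list `sn`, `sp`, `acc`, `mcc`.  A zero factor in the MCC
#'   denominator yields `mcc = 0` with a warning.
#' @examples
#' computeMetrics(list(nPos = 200, nNeg = 400, falseNeg = 100, falsePos = 200))
#' @export
computeMetrics <- function(counts) {
  np <- counts$nPos; nn <- counts$nNeg
  fn <- counts$falseNeg; fp <- counts$falsePos
  if (np < 1 || nn < 1)
    stop("both classes must be non-empty to compute metrics")
  if (fn > np || fp > nn)
    stop("error counts exceed class totals")
  sn <- 1 - fn / np
  sp <- 1 - fp / nn
  acc <- 1 - (fn + fp) / (np + nn)
  d1 <- 1 + (fp - fn) / np
  d2 <- 1 + (fn - fp) / nn
  mcc <- if (d1 <= 0 || d2 <= 0) {
    warning("MCC denominator factor is zero; reporting MCC = 0")
    0
  } else (1 - (fn / np + fp / nn)) / sqrt(d1 * d2)
  list(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

#' ROC curve and AUC
#'
#' Receiver-operating-characteristic curve over all score thresholds and its
#' trapezoidal area.  Tied scores are grouped (one curve vertex per distinct
#' score), so the AUC equals the Mann-Whitney probability with the usual 1/2
#' tie credit.
#'
#' @param scores numeric prediction scores (larger = more positive).
#' @param labels logical (or +1/-1) true labels; both classes required.
#' @return list with `auc` and `curve`, a data.frame of (`fpr`, `tpr`) points
#'   from (0, 0) to (1, 1).
#' @export
rocAuc <- function(scores, labels) {
  if (!is.logical(labels)) labels <- labels > 0
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stop("ROC needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  lastOf <- cumsum(rle(s)$lengths)          # group tied scores
  tpr <- c(0, cumsum(y)[lastOf] / np)
  fpr <- c(0, cumsum(!y)[lastOf] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
}

## Stratified assignment of n items to nf near-equal folds, in randomized
## order.  Returns an integer fold id per item.
.foldAssign <- function(n, nf) {
  sample(rep_len(seq_len(nf), n))
}

#' Target cross-validation
#'
#' The fold-wise protocol in which only experiment-confirmed residues are ever
#' scored, while each training portion is re-optimized from scratch:
#' \enumerate{
#'   \item positives and negatives are each randomly split into `nFolds`
#'     near-equal parts (seeded, stratified by construction);
#'   \item for each fold, the remaining samples are cleaned (KNNC) and
#'     balanced (hypothetical-sample insertion), and the 7-forest ensemble is
#'     trained on the balanced set;
#'   \item the untouched experimental test fold is scored;
#'   \item all fold scores are pooled into one set of confusion counts,
#'     metrics and a ROC curve.
#' }
#' Hypothetical samples exist only inside training folds; every experimental
#' sample is tested exactly once.
#'
#' @param benchmark a [ResidueBenchmark-class] or [TrainingSet-class].
#' @param k cleaning neighbour count; `NA` = [initialK()] on the full
#'   benchmark.
#' @param config a [pipelineConfig()]; `config$seed` fixes the fold split and
#'   all per-fold randomness, `config$nFolds` the fold count.
#' @return list of class `"ppbsCVResult"`: `k`, `folds` (per-fold counts),
#'   `pooled` (summed counts), `metrics` (`sn`, `sp`, `acc`, `mcc`, `auc`),
#'   `scores` (per-sample fused score, truth and fold id) and `roc`.
#' @export
targetCrossValidation <- function(benchmark, k = NA,
                                  config = pipelineConfig()) {
  ts <- if (is(benchmark, "TrainingSet")) benchmark
        else asTrainingSet(benchmark)
  if (is.na(k)) k <- initialK(nPositive(ts), nNegative(ts))
  nf <- config$nFolds
  exper <- ts@provenance == "experimental"
  posIdx <- which(ts@label == 1L & exper)
  negIdx <- which(ts@label == -1L & exper)
  if (length(posIdx) < nf || length(negIdx) < nf)
    stop("each class needs at least nFolds experimental samples")
  set.seed(config$seed)
  fold <- integer(nrow(ts@features))            # 0 = never tested
  fold[posIdx] <- .foldAssign(length(posIdx), nf)
  fold[negIdx] <- .foldAssign(length(negIdx), nf)

  foldRows <- vector("list", nf)
  allScores <- vector("list", nf)
  for (i in seq_len(nf)) {
    test <- which(fold == i)
    train <- which(fold != i)
    foldSeed <- config$seed + 7919L * i
    tsTrain <- new("TrainingSet",
                   features = ts@features[train, , drop = FALSE],
                   label = ts@label[train],
                   provenance = ts@provenance[train])
    balanced <- optimizeTrainingSet(tsTrain, k = k, seed = foldSeed)
    cfgFold <- config; cfgFold$seed <- foldSeed
    model <- trainEnsemble(balanced, cfgFold, optimize = FALSE)
    sc <- predictScores(model, ts@features[test, , drop = FALSE])
    truth <- ts@label[test] == 1L
    cc <- confusionCounts(truth, sc$call)
    foldRows[[i]] <- data.frame(fold = i, nPos = cc$nPos, nNeg = cc$nNeg,
                                falseNeg = cc$falseNeg,
                                falsePos = cc$falsePos)
    allScores[[i]] <- data.frame(index = test, fold = i, score = sc$score,
                                 call = sc$call, truth = truth)
  }
  folds <- do.call(rbind, foldRows)
  scores <- do.call(rbind, allScores)
  pooled <- list(nPos = sum(folds$nPos), nNeg = sum(folds$nNeg),
                 falseNeg = sum(folds$falseNeg),
                 falsePos = sum(folds$falsePos))
  metrics <- computeMetrics(pooled)
  roc <- rocAuc(scores$score, scores$truth)
  metrics$auc <- roc$auc
  structure(list(k = k, nFolds = nf, folds = folds, pooled = pooled,
                 metrics = metrics, scores = scores, roc = roc$curve),
            class = "ppbsCVResult")
}

#' @export
print.ppbsCVResult <- function(x, ...) {
  cat("Target ", x$nFolds, "-fold cross-validation (K = ", x$k, ")\n",
      sep = "")
  cat(sprintf("  Sn = %.4f  Sp = %.4f  Acc = %.4f  MCC = %.4f  AUC = %.4f\n",
              x$metrics$sn, x$metrics$sp, x$metrics$acc, x$metrics$mcc,
              x$metrics$auc))
  invisible(x)
}

#' Scan the cleaning parameter K
#'
#' Runs [targetCrossValidation()] at `K = kStart, kStart + 1, ...` (the fold
#' split is identical across K values because it is fixed by `config$seed`)
#' and reports the accuracy curve plus the K maximizing pooled accuracy (ties
#' broken toward the smallest K).
#'
#' @param benchmark a [ResidueBenchmark-class] or [TrainingSet-class].
#' @param kStart first K of the scan (e.g. [initialK()] of the benchmark).
#' @param nValues number of consecutive K values (default 10).
#' @param config a [pipelineConfig()].
#' @return list of class `"ppbsKScan"`: `curve` (data.frame `k`, `acc`,
#'   `mcc`, `auc`), `bestK`, and `results` (the per-K CV results).
#' @export
scanK <- function(benchmark, kStart, nValues = 10L,
                  config = pipelineConfig()) {
  stopifnot(kStart >= 1L, nValues >= 1L)
  ks <- seq.int(kStart, kStart + nValues - 1L)
  results <- lapply(ks, function(k)
    targetCrossValidation(benchmark, k = k, config = config))
  curve <- data.frame(k = ks,
                      acc = vapply(results, function(r) r$metrics$acc, 0),
                      mcc = vapply(results, function(r) r$metrics$mcc, 0),
                      auc = vapply(results, function(r) r$metrics$auc, 0))
  structure(list(curve = curve, bestK = ks[which.max(curve$acc)],
                 results = results), class = "ppbsKScan")
}

#' @export
print.ppbsKScan <- function(x, ...) {
  cat("K-scan over", nrow(x$curve), "values; best K =", x$bestK, "\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Write a cross-validation report to JSON
#'
#' @param cv a `"ppbsCVResult"` from [targetCrossValidation()].
#' @param path output JSON path.
#' @param rocPoints maximum ROC vertices to keep (thinned evenly; `Inf` keeps
#'   all).
#' @return `path`, invisibly.
#' @export
writeCVReport <- function(cv, path, rocPoints = 200L) {
  roc <- cv$roc
  if (is.finite(rocPoints) && nrow(roc) > rocPoints)
    roc <- roc[unique(round(seq(1, nrow(roc), length.out = rocPoints))), ]
  jsonlite::write_json(
    list(k = cv$k, nFolds = cv$nFolds, folds = cv$folds,
         pooled = cv$pooled, metrics = cv$metrics, roc = roc),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
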