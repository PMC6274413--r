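## Thin seeded wrappers around the compiled forest.

.rfTrain <- function(X, y01, config, seed) {
  set.seed(seed)
  .rfTrainCpp(X, as.integer(y01), config$nTrees, config$mtry, config$minNode)
}

.rfScore <- function(forest, X) .rfPredictCpp(forest, as.matrix(X))

#' Train one per-property predictor
#'
#' Trains a seeded random forest on the 20 feature components derived from a
#' single physicochemical scale.
#'
#' @param training balanced [TrainingSet-class] (140-column features).
#' @param property property identifier (`"H1"`, ..., `"NCI"`).
#' @param config a [pipelineConfig()].
#' @param seed integer seed for this forest (defaults to `config$seed`).
#' @return an opaque predictor object usable with the internal scorer; carries
#'   attributes `property` and `seed`.
#' @export
trainPropertyPredictor <- function(training, property, config = pipelineConfig(),
                                   seed = config$seed) {
  stopifnot(is(training, "TrainingSet"))
  if (nPositive(training) == 0L || nNegative(training) == 0L)
    stop("both classes must be present to train a predictor")
  sl <- .propertySlice(property)
  forest <- .rfTrain(training@features[, sl, drop = FALSE],
                     (training@label + 1L) %/% 2L, config, seed)
  structure(forest, property = property, seed = seed, class = "ppbsForest")
}

#' Train the 7-member ensemble
#'
#' Optimizes the training set once (negative cleaning + minority
#' augmentation), then trains one random forest per physicochemical property
#' on the same balanced samples, and bundles them into a voting ensemble.
#'
#' @param training a [TrainingSet-class] (possibly imbalanced).
#' @param config a [pipelineConfig()]; `config$kKnnc` sets the cleaning K
#'   (`NA` = imbalance-ratio heuristic), `config$seed` drives balancing and
#'   forest growth.
#' @param optimize logical; set `FALSE` if `training` is already balanced and
#'   should be used as-is.
#' @return a [PPBSEnsemble-class].
#' @export
trainEnsemble <- function(training, config = pipelineConfig(), optimize = TRUE) {
  stopifnot(is(training, "TrainingSet"))
  balanced <- if (optimize)
    optimizeTrainingSet(training, k = config$kKnnc, seed = config$seed)
  else training
  preds <- lapply(seq_along(.PROPERTY_IDS), function(k)
    trainPropertyPredictor(balanced, .PROPERTY_IDS[k], config,
                           seed = config$seed + k))
  names(preds) <- .PROPERTY_IDS
  new("PPBSEnsemble", predictors = preds, config = unclass(config),
      trainingInfo = list(nPos = nPositive(balanced),
                          nNeg = nNegative(balanced),
                          nHypothetical =
                            sum(balanced@provenance == "hypothetical"),
                          seed = config$seed))
}

#' Score samples with the ensemble
#'
#' Each of the 7 per-property forests outputs a positive-class score in
#' [0, 1] and votes positive when its score is at least 0.5.  The fused label
#' is the majority of the 7 votes (odd voter count, so no ties); the fused
#' continuous score — used for ROC curves — is the mean of the 7 scores.
#'
#' @param model a [PPBSEnsemble-class].
#' @param features numeric n x 140 feature matrix (or a
#'   [ResidueBenchmark-class] / [TrainingSet-class]).
#' @return data.frame with `score` (mean of the 7 scores), `votes` (positive
#'   votes out of 7) and `call` (logical fused label).
#' @export
predictScores <- function(model, features) {
  stopifnot(is(model, "PPBSEnsemble"))
  if (is(features, "ResidueBenchmark") || is(features, "TrainingSet"))
    features <- featureMatrix(features)
  features <- as.matrix(features)
  if (ncol(features) != 140L)
    stop("feature matrix must have 140 columns, got ", ncol(features))
  scores <- vapply(.PROPERTY_IDS, function(p)
    .rfScore(model@predictors[[p]],
             features[, .propertySlice(p), drop = FALSE]),
    numeric(nrow(features)))
  scores <- matrix(scores, nrow = nrow(features))
  votes <- rowSums(scores >= 0.5)
  fused <- rowMeans(scores)
  call <- if (identical(model@config$voteRule, "score-mean"))
    fused >= 0.5 else votes > length(.PROPERTY_IDS) / 2
  data.frame(score = fused, votes = votes, call = call)
}

#' Predict binding-site residues for protein sequences
#'
#' Runs the full pipeline on query sequences: one mirror-extended window per
#' residue, wavelet featurization, ensemble scoring.  Emits one row per
#' residue of every protein, in input order.
#'
#' @param model a [PPBSEnsemble-class].
#' @param sequences named character vector of protein sequences (see
#'   [readProteins()]); each must be at least `xi` residues long.
#' @param tables standardized property matrix.
#' @return data.frame with `protein`, `position`, `residue`, `score`,
#'   `votes`, `call`.
#' @export
predictResidues <- function(model, sequences, tables = propertyTables()) {
  xi <- model@config$xi
  rows <- lapply(names(sequences), function(id) {
    seqc <- sequences[[id]]
    w <- extractAllWindows(seqc, xi)
    sc <- predictScores(model, featurizeWindows(w, tables))
    data.frame(protein = id, position = seq_len(nchar(seqc)),
               residue = strsplit(seqc, "")[[1]], sc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write per-residue predictions to TSV
#'
#' @param predictions data.frame from [predictResidues()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictionTSV <- function(predictions, path) {
  out <- predictions[, c("protein", "position", "residue", "score", "call")]
  out$call <- as.integer(out$call)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load an ensemble model
#'
#' Single-file persistence of the trained ensemble (config, the 7 forests,
#' a checksum of the property tables, and a format version tag).
#'
#' @param model a [PPBSEnsemble-class].
#' @param path file path.
#' @return `saveModel`: `path`, invisibly; `loadModel`: the restored
#'   [PPBSEnsemble-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "PPBSEnsemble"))
  payload <- list(format = "wavePPBS-model-1",
                  config = model@config,
                  predictors = model@predictors,
                  trainingInfo = model@trainingInfo,
                  tableChecksum = sum(propertyTables()^2))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "wavePPBS-model-1"))
    stop("not a recognized model file: ", path)
  new("PPBSEnsemble", predictors = payload$predictors,
      config = payload$config, trainingInfo = payload$trainingInfo)
}
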