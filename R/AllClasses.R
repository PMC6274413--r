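#' Pipeline configuration
#'
#' Collects the tunable parameters of the prediction pipeline in one validated
#' list.
#'
#' @param xi window half-width; the working segment has `2 * xi + 1` residues
#'   (default 7, i.e. 15-tuple windows).
#' @param wavelet wavelet family; only `"db1"` (Haar) is supported.
#' @param kKnnc neighbour count for the negative-cleaning step; `NA` means
#'   "use the imbalance-ratio heuristic [initialK()]".
#' @param nFolds number of cross-validation folds (default 10).
#' @param seed integer seed driving every stochastic step (fold split,
#'   oversampling, forest growth).
#' @param nTrees trees per random forest (default 100).
#' @param mtry features tried per split; default `floor(sqrt(20)) = 4`.
#' @param minNode minimum node size to attempt a split (default 2: grow to
#'   purity).
#' @param voteRule `"majority"` (label = majority of the 7 per-property votes)
#'   or `"score-mean"` (label = mean score >= 0.5).
#' @param smoteNeighbors neighbours used when interpolating hypothetical
#'   minority samples (default 5).
#' @return named list of class `"ppbsConfig"`.
#' @examples
#' cfg <- pipelineConfig(seed = 42)
#' @export
pipelineConfig <- function(xi = 7L, wavelet = "db1", kKnnc = NA_integer_,
                           nFolds = 10L, seed = 1L, nTrees = 100L,
                           mtry = 4L, minNode = 2L,
                           voteRule = c("majority", "score-mean"),
                           smoteNeighbors = 5L) {
  voteRule <- match.arg(voteRule)
  stopifnot(xi >= 1L, nFolds >= 2L, nTrees >= 1L, mtry >= 1L,
            identical(tolower(wavelet), "db1"))
  structure(list(xi = as.integer(xi), wavelet = "db1",
                 kKnnc = as.integer(kKnnc), nFolds = as.integer(nFolds),
                 seed = as.integer(seed), nTrees = as.integer(nTrees),
                 mtry = as.integer(mtry), minNode = as.integer(minNode),
                 voteRule = voteRule,
                 smoteNeighbors = as.integer(smoteNeighbors)),
            class = "ppbsConfig")
}

#' Labeled training set of feature blocks
#'
#' Container for the samples a classifier is trained on: a feature matrix
#' (rows = samples, 140 columns), a +1/-1 label per sample, and a provenance
#' flag distinguishing experiment-derived samples from hypothetical
#' (interpolated) ones inserted during balancing.
#'
#' @slot features numeric matrix, one row per sample.
#' @slot label integer vector of +1 (binding site) / -1 per sample.
#' @slot provenance character vector, `"experimental"` or `"hypothetical"`.
#' @export
setClass("TrainingSet",
         representation(features = "matrix", label = "integer",
                        provenance = "character"))

setValidity("TrainingSet", function(object) {
  n <- nrow(object@features)
  if (length(object@label) != n || length(object@provenance) != n)
    return("label and provenance must have one entry per feature row")
  if (!all(object@label %in% c(-1L, 1L)))
    return("labels must be +1 or -1")
  if (!all(object@provenance %in% c("experimental", "hypothetical")))
    return("provenance must be 'experimental' or 'hypothetical'")
  TRUE
})

#' Construct a TrainingSet
#'
#' @param features numeric matrix, rows = samples.
#' @param label vector coercible to +1/-1 (logicals allowed: `TRUE` = +1).
#' @param provenance per-sample provenance; recycled if scalar.
#' @return a [TrainingSet-class] object.
#' @export
TrainingSet <- function(features, label, provenance = "experimental") {
  if (is.logical(label)) label <- ifelse(label, 1L, -1L)
  new("TrainingSet", features = as.matrix(features),
      label = as.integer(label),
      provenance = rep_len(provenance, nrow(features)))
}

#' @describeIn TrainingSet-class number of positive (+1) samples
#' @param x,object a `TrainingSet`
#' @export
nPositive <- function(x) sum(x@label == 1L)

#' @describeIn TrainingSet-class number of negative (-1) samples
#' @export
nNegative <- function(x) sum(x@label == -1L)

#' @describeIn TrainingSet-class feature matrix accessor
#' @export
featureMatrix <- function(x) {
  if (is(x, "TrainingSet")) return(x@features)
  if (is(x, "ResidueBenchmark"))
    return(t(SummarizedExperiment::assay(x, "features")))
  stop("no feature matrix for class ", class(x))
}

#' @describeIn TrainingSet-class +1/-1 label accessor
#' @export
sampleLabels <- function(x) x@label

#' @describeIn TrainingSet-class provenance accessor
#' @export
sampleProvenance <- function(x) x@provenance

setMethod("show", "TrainingSet", function(object) {
  cat("TrainingSet:", nrow(object@features), "samples x",
      ncol(object@features), "features\n")
  cat("  positives:", nPositive(object),
      " negatives:", nNegative(object),
      " hypothetical:", sum(object@provenance == "hypothetical"), "\n")
})

#' Residue-level benchmark
#'
#' A `SummarizedExperiment` of per-residue feature blocks: the `features`
#' assay holds the 140-component wavelet feature block per residue (features x
#' residues), and `colData` carries `protein`, `position`, `residue`,
#' `surface`, `label` (TRUE = interface/binding site) and `provenance`.
#' The `benchmarkMode` is `"surface"` (surface residues only) or `"all"`.
#'
#' @slot mode `"surface"` or `"all"`.
#' @export
setClass("ResidueBenchmark", contains = "SummarizedExperiment",
         representation(mode = "character"))

setValidity("ResidueBenchmark", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("protein", "position", "residue", "surface", "label", "provenance")
  if (!all(need %in% names(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  if (!object@mode %in% c("surface", "all"))
    return("mode must be 'surface' or 'all'")
  if (object@mode == "surface" && !all(cd$surface))
    return("surface-mode benchmark contains non-surface residues")
  if (any(cd$label & !cd$surface))
    return("interface residues must be surface residues")
  TRUE
})

#' @describeIn ResidueBenchmark-class benchmark mode accessor
#' @param x a `ResidueBenchmark`
#' @export
benchmarkMode <- function(x) x@mode

#' @describeIn ResidueBenchmark-class count of positive (interface) residues
#' @export
nPosBenchmark <- function(x) sum(SummarizedExperiment::colData(x)$label)

#' @describeIn ResidueBenchmark-class count of negative residues
#' @export
nNegBenchmark <- function(x) sum(!SummarizedExperiment::colData(x)$label)

setMethod("show", "ResidueBenchmark", function(object) {
  cat("ResidueBenchmark (", object@mode, " mode): ", ncol(object),
      " residues, ", nPosBenchmark(object), " positive / ",
      nNegBenchmark(object), " negative\n", sep = "")
  cat("  proteins:",
      length(unique(SummarizedExperiment::colData(object)$protein)), "\n")
})

#' Convert a benchmark to a TrainingSet
#'
#' @param benchmark a [ResidueBenchmark-class].
#' @return a [TrainingSet-class] with +1 for interface residues.
#' @export
asTrainingSet <- function(benchmark) {
  cd <- SummarizedExperiment::colData(benchmark)
  TrainingSet(featureMatrix(benchmark), cd$label,
              as.character(cd$provenance))
}

#' Ensemble binding-site predictor
#'
#' Seven per-property random-forest classifiers fused by voting.  Each
#' predictor sees only the 20 feature components derived from its own
#' physicochemical scale.
#'
#' @slot predictors list of 7 trained forests, named by property.
#' @slot config the [pipelineConfig()] used for training.
#' @slot trainingInfo list with sample counts and seed.
#' @export
setClass("PPBSEnsemble",
         representation(predictors = "list", config = "list",
                        trainingInfo = "list"))

setValidity("PPBSEnsemble", function(object) {
  if (!identical(sort(names(object@predictors)), sort(.PROPERTY_IDS)))
    return("ensemble must hold exactly one predictor per property")
  TRUE
})

setMethod("show", "PPBSEnsemble", function(object) {
  cat("PPBSEnsemble: 7 per-property random forests (",
      object@config$nTrees, " trees each)\n", sep = "")
  ti <- object@trainingInfo
  if (length(ti))
    cat("  trained on", ti$nPos, "positive /", ti$nNeg,
        "negative samples (seed", ti$seed, ")\n")
})
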