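#' Starting neighbour count for negative cleaning
#'
#' Imbalance-ratio heuristic for the cleaning parameter K: the integer part of
#' the negative-to-positive sample ratio.
#'
#' @param nPos,nNeg class sizes (`nPos >= 1`).
#' @return integer `K0`.
#' @examples
#' initialK(2828, 10943)  # 3, surface-residue benchmark
#' initialK(2828, 24614)  # 8, all-residue benchmark
#' @export
initialK <- function(nPos, nNeg) {
  if (nPos < 1) stop("need at least one positive sample")
  as.integer(nNeg %/% nPos)
}

#' K-nearest-neighbour cleaning of the negative subset
#'
#' Removes every negative sample that has at least one positive among its `k`
#' nearest neighbours (Euclidean distance on the full feature block,
#' neighbours searched among all other samples of the original set, self
#' excluded).  Removal decisions are taken on the original set in a single
#' pass; positives are never touched.  `k = 0` disables cleaning.
#'
#' @param training a [TrainingSet-class].
#' @param k neighbour count (non-negative integer).
#' @return the cleaned [TrainingSet-class].
#' @export
knncFilter <- function(training, k) {
  stopifnot(is(training, "TrainingSet"), k >= 0)
  if (k == 0L) return(training)
  X <- training@features
  neg <- which(training@label == -1L)
  if (length(neg) == 0L || nrow(X) < 2L) return(training)
  kk <- min(as.integer(k) + 1L, nrow(X))  # +1 so self can be dropped
  nn <- FNN::get.knnx(X, X[neg, , drop = FALSE], k = kk)
  drop <- logical(length(neg))
  for (i in seq_along(neg)) {
    nbr <- nn$nn.index[i, ]
    nbr <- nbr[nbr != neg[i]]
    nbr <- nbr[seq_len(min(k, length(nbr)))]
    drop[i] <- any(training@label[nbr] == 1L)
  }
  keep <- setdiff(seq_len(nrow(X)), neg[drop])
  new("TrainingSet", features = X[keep, , drop = FALSE],
      label = training@label[keep], provenance = training@provenance[keep])
}

#' Insert hypothetical training samples (SMOTE-style)
#'
#' Augments the smaller class with interpolated samples until both classes
#' have exactly the same size: repeatedly pick a random member `x` of the
#' minority class and one of its 5 nearest same-class neighbours `x'`, and
#' emit `x + lambda * (x' - x)` with `lambda` uniform on (0, 1).  Inserted
#' samples are flagged `"hypothetical"`; they exist only as feature vectors,
#' not as real peptide segments.
#'
#' @param training a [TrainingSet-class].
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param nNeighbors neighbour pool for interpolation (default 5, reduced if
#'   the class is smaller).
#' @return the exactly balanced [TrainingSet-class].
#' @export
ihtsAugment <- function(training, seed = NULL, nNeighbors = 5L) {
  stopifnot(is(training, "TrainingSet"))
  np <- nPositive(training); nn <- nNegative(training)
  if (np == nn) return(training)
  if (!is.null(seed)) set.seed(seed)
  minLab <- if (np < nn) 1L else -1L
  deficit <- abs(np - nn)
  small <- which(training@label == minLab)
  if (length(small) < 2L)
    stop("cannot augment a class with fewer than 2 members")
  Xs <- training@features[small, , drop = FALSE]
  kk <- min(nNeighbors, nrow(Xs) - 1L)
  nn.idx <- FNN::get.knn(Xs, k = kk)$nn.index
  base <- sample.int(nrow(Xs), deficit, replace = TRUE)
  pick <- nn.idx[cbind(base, sample.int(kk, deficit, replace = TRUE))]
  lambda <- stats::runif(deficit)
  synth <- Xs[base, , drop = FALSE] +
    lambda * (Xs[pick, , drop = FALSE] - Xs[base, , drop = FALSE])
  new("TrainingSet",
      features = rbind(training@features, synth),
      label = c(training@label, rep(minLab, deficit)),
      provenance = c(training@provenance, rep("hypothetical", deficit)))
}

#' Optimize an imbalanced training set
#'
#' The two-step treatment that turns a highly skewed training set into an
#' exactly balanced one: K-nearest-neighbour cleaning of the negative subset
#' ([knncFilter()]) followed by insertion of hypothetical minority samples to
#' exact balance ([ihtsAugment()]).  If cleaning leaves the negatives as the
#' smaller class, augmentation fills up the negatives instead (the contract is
#' exact balance, whichever side is short).
#'
#' @param training a [TrainingSet-class].
#' @param k cleaning neighbour count; `NA` uses [initialK()] on the input
#'   class sizes.
#' @param seed RNG seed for the augmentation step.
#' @return balanced [TrainingSet-class]; all inserted samples carry
#'   provenance `"hypothetical"`.
#' @export
optimizeTrainingSet <- function(training, k = NA, seed = NULL) {
  if (is.na(k)) k <- initialK(nPositive(training), nNegative(training))
  ihtsAugment(knncFilter(training, k), seed = seed)
}
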