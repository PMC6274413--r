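## Independent oracles and small fixture builders shared by the tests.
## These re-derive expected values by brute force / direct linear algebra and
## deliberately share no code with the package internals they check.

## --- Haar stationary wavelet oracle --------------------------------------
## Direct convolution-matrix implementation: the padded signal (half-sample
## right reflection to the next multiple of 16) is multiplied by explicit
## N x N circulant filter matrices at each level; padded positions are then
## dropped.  Returns list(A4, D4, D3, D2, D1) plus all per-level
## approximations for the reconstruction check.
oracleHaarSWT <- function(x, levels = 4L) {
  len <- length(x)
  block <- 2L^levels
  N <- as.integer(ceiling(len / block) * block)
  if (N > len) {
    refl <- c(seq(len, 1L), seq_len(len))
    pad <- refl[((seq_len(N - len) - 1L) %% (2L * len)) + 1L]
    x <- c(x, x[pad])
  }
  circulant <- function(shift, sign) {
    M <- matrix(0, N, N)
    for (n in seq_len(N)) {
      M[n, n] <- M[n, n] + 1 / sqrt(2)
      j <- ((n - 1L + shift) %% N) + 1L
      M[n, j] <- M[n, j] + sign / sqrt(2)
    }
    M
  }
  a <- x
  approx <- list()
  details <- list()
  for (j in seq_len(levels)) {
    s <- 2L^(j - 1L)
    details[[j]] <- as.vector(circulant(s, -1) %*% a)
    a <- as.vector(circulant(s, +1) %*% a)
    approx[[j]] <- a
  }
  keep <- seq_len(len)
  out <- c(list(a[keep]), lapply(rev(details), function(d) d[keep]))
  names(out) <- c(paste0("A", levels), paste0("D", seq(levels, 1L)))
  attr(out, "padded") <- x
  attr(out, "approxFull") <- approx
  attr(out, "detailFull") <- details
  out
}

## --- exhaustive KNN-cleaning oracle --------------------------------------
## O(n^2) pairwise distances; a negative is removed iff any of its k nearest
## other samples (both classes, self excluded) is positive.
oracleKnnc <- function(X, label, k) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  drop <- rep(FALSE, n)
  for (i in which(label == -1L)) {
    nbr <- order(D[i, ])[seq_len(min(k, n - 1L))]
    drop[i] <- any(label[nbr] == 1L)
  }
  which(drop)
}

## --- random training-set builder -----------------------------------------
## Two Gaussian clouds in feature space, padded to `p` columns.
makeTrainingSet <- function(nPos, nNeg, p = 140L, sep = 0, seed = 1L,
                            informative = 4L) {
  set.seed(seed)
  X <- matrix(rnorm((nPos + nNeg) * p), nPos + nNeg, p)
  X[seq_len(nPos), seq_len(informative)] <-
    X[seq_len(nPos), seq_len(informative)] + sep
  colnames(X) <- paste0("f", seq_len(p))
  TrainingSet(X, c(rep(1L, nPos), rep(-1L, nNeg)))
}

## Small synthetic benchmark shared by the slower tests.
smallFixtureBenchmark <- function(seed = 11L, nProteins = 8L) {
  simulateBenchmark(fixtureSpec(nProteins = nProteins,
                                lengthRange = c(60L, 80L), seed = seed))
}
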