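## Stationary (undecimated) Haar wavelet machinery.
##
## A window series of length 15 is padded on the right by mirror reflection to
## length 16 (the next multiple of 2^4) and decomposed with a 4-level a-trous
## Haar transform using periodic wrap on the padded signal:
##   a_j[n] = (a_{j-1}[n] + a_{j-1}[(n + s) mod N]) / sqrt(2)
##   d_j[n] = (a_{j-1}[n] - a_{j-1}[(n + s) mod N]) / sqrt(2),  s = 2^(j-1).
## Every band keeps the input length; padded positions are dropped before
## returning, so all 5 sub-bands (A4, D4, D3, D2, D1) have the original length.

.SWT_LEVELS <- 4L

## Half-sample symmetric right-extension indices for padding length m:
## len, len-1, ..., 1, 1, 2, ... (reflects back and forth for tiny inputs).
.reflectIndices <- function(len, m) {
  if (m == 0L) return(integer())
  cycle <- c(seq(len, 1L), seq_len(len))
  cycle[((seq_len(m) - 1L) %% (2L * len)) + 1L]
}

## Core transform on a matrix of series (rows = windows).  Returns a list of
## 5 matrices: A4, D4, D3, D2, D1, each n x len.
.swtMatrix <- function(X, levels = .SWT_LEVELS) {
  len <- ncol(X)
  if (len < 2L)
    stop("series must have length >= 2 for wavelet decomposition")
  block <- 2L^levels
  N <- as.integer(ceiling(len / block) * block)
  if (N > len)
    X <- cbind(X, X[, .reflectIndices(len, N - len), drop = FALSE])
  A <- X
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    s <- 2L^(j - 1L)
    idx <- ((seq_len(N) - 1L + s) %% N) + 1L
    shifted <- A[, idx, drop = FALSE]
    details[[j]] <- (A - shifted) / sqrt(2)
    A <- (A + shifted) / sqrt(2)
  }
  keep <- seq_len(len)
  out <- c(list(A[, keep, drop = FALSE]),
           lapply(rev(details), function(d) d[, keep, drop = FALSE]))
  names(out) <- c(paste0("A", levels), paste0("D", seq(levels, 1L)))
  out
}

#' Stationary Haar wavelet sub-bands of a property series
#'
#' Decomposes one encoded window series with a 4-level stationary wavelet
#' transform (Db1/Haar filters), yielding 5 sub-bands: the deepest
#' approximation `A4` and the details `D4`, `D3`, `D2`, `D1`.  Being
#' undecimated, every sub-band has the same length as the input series; the
#' internal right mirror-padding used to reach a dyadic length is dropped
#' before returning.
#'
#' @param series numeric vector (length `2 * xi + 1`, i.e. 15 by default;
#'   any length `>= 2` is accepted).
#' @return named list of 5 numeric vectors (`A4`, `D4`, `D3`, `D2`, `D1`),
#'   each the length of `series`.
#' @examples
#' b <- swtSubbands(encodeSegment("ACDEFGHIKLMNPQR", propertyTables(), "H1"))
#' lengths(b)
#' @export
swtSubbands <- function(series) {
  lapply(.swtMatrix(matrix(series, nrow = 1L)), drop)
}

#' Per-sub-band summary statistics
#'
#' Condenses 5 sub-bands into the 20-component feature vector: per band the
#' maximum (`alpha`), mean (`beta`), minimum (`gamma`) and population standard
#' deviation (`delta`) of the wavelet coefficients, ordered
#' `alpha1..alpha5, beta1..beta5, gamma1..gamma5, delta1..delta5`.
#'
#' @param bands list of 5 numeric vectors as returned by [swtSubbands()].
#' @return named numeric vector of length 20.
#' @export
subbandStatistics <- function(bands) {
  if (length(bands) != 5L)
    stop("expected exactly 5 sub-bands")
  alpha <- vapply(bands, max, 0)
  beta <- vapply(bands, mean, 0)
  gamma <- vapply(bands, min, 0)
  delta <- vapply(bands, function(b) sqrt(mean((b - mean(b))^2)), 0)
  out <- c(alpha, beta, gamma, delta)
  names(out) <- paste0(rep(c("alpha", "beta", "gamma", "delta"), each = 5L),
                       rep(1:5, 4L))
  out
}

## Band statistics for a matrix of series: returns n x 20.
.subbandStatisticsMatrix <- function(bands) {
  stat1 <- function(f) do.call(cbind, lapply(bands, f))
  alpha <- stat1(function(b) apply(b, 1L, max))
  beta <- stat1(rowMeans)
  gamma <- stat1(function(b) apply(b, 1L, min))
  delta <- stat1(function(b) sqrt(pmax(rowMeans(b^2) - rowMeans(b)^2, 0)))
  sqrtfix <- cbind(alpha, beta, gamma, delta)
  colnames(sqrtfix) <- paste0(rep(c("alpha", "beta", "gamma", "delta"),
                                  each = 5L), rep(1:5, 4L))
  sqrtfix
}

#' Feature block of one peptide segment
#'
#' Full feature construction for a single window: the segment is encoded under
#' each of the 7 standardized property scales, each series is decomposed into
#' 5 stationary-wavelet sub-bands, and each sub-band contributes its
#' max/mean/min/SD — a 7 x 20 = 140-component block, property-major
#' (all 20 `H1` components, then `H2`, ...).
#'
#' @param segment window string of length `2 * xi + 1`.
#' @param tables standardized property matrix from [propertyTables()].
#' @return named numeric vector of length 140.
#' @examples
#' length(featurizeSegment(strrep("A", 15)))
#' @export
featurizeSegment <- function(segment, tables = propertyTables()) {
  featurizeWindows(segment, tables)[1L, ]
}

#' Feature blocks of many windows
#'
#' Vectorized [featurizeSegment()] over a collection of windows; rows keep the
#' input order.
#'
#' @param windows character vector of equal-length window strings.
#' @param tables standardized property matrix from [propertyTables()].
#' @return numeric `length(windows)` x 140 matrix, columns named
#'   `<property>.<stat><band>`.
#' @export
featurizeWindows <- function(windows, tables = propertyTables()) {
  if (is.null(attr(tables, "standardized")) ||
      !isTRUE(attr(tables, "standardized")))
    stop("property tables must be standardized")
  if (length(windows) == 0L) {
    out <- matrix(numeric(), 0L, 140L)
    colnames(out) <- .featureNames()
    return(out)
  }
  cm <- .windowMatrix(windows)
  blocks <- lapply(.PROPERTY_IDS, function(p) {
    series <- .encodeMatrix(cm, tables, p)
    st <- .subbandStatisticsMatrix(.swtMatrix(series))
    colnames(st) <- paste0(p, ".", colnames(st))
    st
  })
  do.call(cbind, blocks)
}

.featureNames <- function() {
  as.vector(vapply(.PROPERTY_IDS, function(p)
    paste0(p, ".", paste0(rep(c("alpha", "beta", "gamma", "delta"), each = 5L),
                          rep(1:5, 4L))), character(20L)))
}

## Column indices of one property's 20-component slice in the 140-wide block.
.propertySlice <- function(property) {
  k <- match(property, .PROPERTY_IDS)
  if (is.na(k)) stop("unknown property: ", property)
  (k - 1L) * 20L + seq_len(20L)
}

#' Write a feature table to TSV
#'
#' Writes `protein`, `position`, `label` and the 140 feature columns
#' (`f001`..`f140`, property-major order) for downstream tools.
#'
#' @param features numeric n x 140 matrix.
#' @param meta data.frame with columns `protein`, `position`, `label`
#'   (one row per feature row).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTSV <- function(features, meta, path) {
  stopifnot(nrow(features) == nrow(meta))
  df <- cbind(meta[, c("protein", "position", "label")],
              as.data.frame(features))
  names(df)[-(1:3)] <- sprintf("f%03d", seq_len(ncol(features)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
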