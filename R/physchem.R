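#' @useDynLib wavePPBS, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

## Seven amino-acid physicochemical scales, raw (unstandardized) values:
## H1 hydrophobicity, H2 hydrophilicity, V side-chain volume, P1 polarity,
## P2 polarizability, SASA solvent-accessible surface area, NCI side-chain
## net charge index.  Row order is the 20 standard one-letter codes.
.PROPERTY_IDS <- c("H1", "H2", "V", "P1", "P2", "SASA", "NCI")

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.PROPERTY_RAW <- matrix(c(
  #   H1,    H2,     V,   P1,    P2,  SASA,       NCI
   0.62,  -0.5,  27.5,  8.1, 0.046, 1.181,  0.007187,  # A
   0.29,  -1.0,  44.6,  5.5, 0.128, 1.461, -0.036610,  # C
  -0.90,   3.0,  40.0, 13.0, 0.105, 1.587, -0.023820,  # D
  -0.74,   3.0,  62.0, 12.3, 0.151, 1.862,  0.006802,  # E
   1.19,  -2.5, 115.5,  5.2, 0.290, 2.228,  0.037552,  # F
   0.48,   0.0,   0.0,  9.0, 0.000, 0.881,  0.179052,  # G
  -0.40,  -0.5,  79.0, 10.4, 0.230, 2.025, -0.010690,  # H
   1.38,  -1.8,  93.5,  5.2, 0.186, 1.810,  0.021631,  # I
  -1.50,   3.0, 100.0, 11.3, 0.219, 2.258,  0.017708,  # K
   1.06,  -1.8,  93.5,  4.9, 0.186, 1.931,  0.051672,  # L
   0.64,  -1.3,  94.1,  5.7, 0.221, 2.034,  0.002683,  # M
  -0.78,   2.0,  58.7, 11.6, 0.134, 1.655,  0.005392,  # N
   0.12,   0.0,  41.9,  8.0, 0.131, 1.468,  0.239531,  # P
  -0.85,   0.2,  80.7, 10.5, 0.180, 1.932,  0.049211,  # Q
  -2.53,   3.0, 105.0, 10.5, 0.291, 2.560,  0.043587,  # R
  -0.18,   0.3,  29.3,  9.2, 0.062, 1.298,  0.004627,  # S
  -0.05,  -0.4,  51.3,  8.6, 0.108, 1.525,  0.003352,  # T
   1.08,  -1.5,  71.5,  5.9, 0.140, 1.645,  0.057004,  # V
   0.81,  -3.4, 145.5,  5.4, 0.409, 2.663,  0.037977,  # W
   0.26,  -2.3, 117.3,  6.2, 0.298, 2.368,  0.023599), # Y
  nrow = 20, byrow = TRUE,
  dimnames = list(.AA20, .PROPERTY_IDS))

## Maximum accessible surface area (A^2) of the free residue; the denominator
## of the surface-residue ratio.  B (D/N), Z (E/Q) and X (undetermined) carry
## their own entries so labeling accepts them.
.MAX_ASA <- c(A = 106, B = 160, C = 135, D = 163, E = 194, F = 197, G = 84,
              H = 184, I = 169, K = 205, L = 164, M = 188, N = 157, P = 136,
              Q = 198, R = 248, S = 130, T = 142, V = 142, W = 227, X = 180,
              Y = 222, Z = 196)

#' Amino-acid physicochemical property tables
#'
#' Returns the values of the seven physicochemical scales used to encode
#' peptide segments: hydrophobicity (`H1`), hydrophilicity (`H2`), side-chain
#' volume (`V`), polarity (`P1`), polarizability (`P2`), solvent-accessible
#' surface area (`SASA`) and side-chain net charge index (`NCI`).
#'
#' With `standardized = TRUE` (the default, and what the feature pipeline
#' requires) each column is centred and scaled to zero mean and unit standard
#' deviation over the 20 standard amino acids, so the scales are mutually
#' comparable and re-standardizing is a no-op.
#'
#' @param standardized logical; return standardized values?
#' @param file optional TSV overriding the built-in values; columns
#'   `aa`, `H1`, `H2`, `V`, `P1`, `P2`, `SASA`, `NCI`, one row per amino acid.
#' @return numeric 20 x 7 matrix, rows the one-letter amino-acid codes, columns
#'   the property identifiers, with attribute `standardized`.
#' @examples
#' tab <- propertyTables()
#' colMeans(tab)          # ~0 in every column
#' apply(tab, 2, sd)      # 1 in every column
#' @export
propertyTables <- function(standardized = TRUE, file = NULL) {
  tab <- .PROPERTY_RAW
  if (!is.null(file)) {
    ov <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("aa", .PROPERTY_IDS)
    if (!all(need %in% names(ov)))
      stop("property override file must have columns: ",
           paste(need, collapse = ", "))
    ov <- ov[match(.AA20, ov$aa), ]
    if (anyNA(ov$aa))
      stop("property override file must cover all 20 standard amino acids")
    tab <- as.matrix(ov[, .PROPERTY_IDS])
    rownames(tab) <- .AA20
  }
  if (standardized)
    tab <- apply(tab, 2, standardizeProperty)
  structure(tab, standardized = standardized)
}

#' Standardize one property scale
#'
#' Centres and scales a 20-value amino-acid property vector to zero mean and
#' unit standard deviation over the 20 amino-acid types.  The conversion is
#' idempotent: applying it to an already standardized scale returns the same
#' values.
#'
#' @param values named numeric vector of length 20 (one value per standard
#'   amino acid).
#' @return standardized numeric vector, same names and order.
#' @examples
#' h1 <- propertyTables(standardized = FALSE)[, "H1"]
#' z <- standardizeProperty(h1)
#' all.equal(z, standardizeProperty(z))
#' @export
standardizeProperty <- function(values) {
  if (length(values) != 20L)
    stop("a property table must have exactly 20 amino-acid values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("degenerate property table: standard deviation is zero")
  (values - mean(values)) / s
}

#' Maximum accessible surface area table
#'
#' ASA of each free amino acid (squared Angstroms), used as the denominator of
#' the surface-residue exposure ratio.  Covers the 20 standard codes plus the
#' ambiguity codes B (D or N), Z (E or Q) and X (undetermined).
#'
#' @return named numeric vector of length 23.
#' @export
maxASATable <- function() .MAX_ASA

## Map ambiguity codes to encodable residues: B -> D, Z -> E; X stays X and
## contributes the standardized mean (0).  Unknown codes are an error.
.encodeAlphabet <- function() c(.AA20, "B", "Z", "X")

#' Encode a peptide segment under one property scale
#'
#' Replaces each residue of a window by its standardized property value,
#' yielding the numeric series that the wavelet stage decomposes.  Ambiguous
#' residues fall back as B to D and Z to E; X contributes 0, the standardized
#' property mean (the least informative value).
#'
#' @param segment character scalar (e.g. `"ACDEFGHIKLMNPQR"`) or character
#'   vector of single-letter residues.
#' @param table standardized property matrix from [propertyTables()].
#' @param property one of `"H1"`, `"H2"`, `"V"`, `"P1"`, `"P2"`, `"SASA"`,
#'   `"NCI"`.
#' @return numeric vector, one standardized value per residue.
#' @examples
#' encodeSegment(strrep("A", 15), propertyTables(), "H1")
#' @export
encodeSegment <- function(segment, table = propertyTables(), property = "H1") {
  if (is.null(attr(table, "standardized")) || !isTRUE(attr(table, "standardized")))
    stop("property table must be standardized before encoding")
  property <- match.arg(property, .PROPERTY_IDS)
  res <- if (length(segment) == 1L && nchar(segment) > 1L)
    strsplit(segment, "")[[1]] else as.character(segment)
  res[res == "B"] <- "D"
  res[res == "Z"] <- "E"
  out <- numeric(length(res))
  isx <- res == "X"
  idx <- match(res[!isx], rownames(table))
  if (anyNA(idx))
    stop("cannot encode residue(s): ",
         paste(unique(res[!isx][is.na(idx)]), collapse = ", "))
  out[!isx] <- table[idx, property]
  out
}

## Vectorized residue -> value lookup on a character matrix of residues
## (rows = windows); returns a numeric matrix of the same shape.
.encodeMatrix <- function(charmat, table, property) {
  charmat[charmat == "B"] <- "D"
  charmat[charmat == "Z"] <- "E"
  vals <- c(table[, property], X = 0)
  idx <- match(charmat, names(vals))
  if (anyNA(idx))
    stop("cannot encode residue(s): ",
         paste(unique(charmat[is.na(idx)]), collapse = ", "))
  matrix(vals[idx], nrow = nrow(charmat))
}
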