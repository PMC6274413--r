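#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that upper-cases the
#' sequences and validates the residue alphabet (20 standard codes plus
#' B, X, Z).
#'
#' @param path FASTA file (multi-record allowed).
#' @return named character vector of sequences (names are the first
#'   whitespace-delimited token of each FASTA header).
#' @export
readProteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  bad <- grepl(sprintf("[^%s]", paste(.encodeAlphabet(), collapse = "")), seqs)
  if (any(bad))
    stop("non-amino-acid characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Mirror-extend a protein chain
#'
#' Prepends the reversed first `xi` residues and appends the reversed last
#' `xi` residues, so that full-length windows exist for residues within `xi`
#' of either terminus.  The extension reflects the chain at each terminus as
#' in a mirror: for `"ACDE"` with `xi = 2` the extended chain is `"CAACDEED"`.
#'
#' @param sequence character scalar protein sequence of length `L >= xi`.
#' @param xi window half-width (non-negative integer).
#' @return the extended sequence, `L + 2 * xi` characters.
#' @examples
#' mirrorExtend("ACDE", 2)
#' @export
mirrorExtend <- function(sequence, xi = 7L) {
  stopifnot(length(sequence) == 1L, xi >= 0)
  L <- nchar(sequence)
  if (L < xi)
    stop("sequence too short to mirror-extend: length ", L, " < xi = ", xi)
  if (xi == 0L) return(sequence)
  ch <- strsplit(sequence, "")[[1]]
  paste(c(rev(ch[seq_len(xi)]), ch, rev(ch[seq(L - xi + 1L, L)])),
        collapse = "")
}

#' Extract the working segment centred on one residue
#'
#' Returns the `(2 * xi + 1)`-residue window of the mirror-extended chain
#' centred on residue `center` of the original chain.  Interior centres reduce
#' to a plain substring of the sequence; centres within `xi` of a terminus use
#' the mirrored extension.
#'
#' @param sequence protein sequence, length `L >= xi`.
#' @param center 1-based residue position in the original chain.
#' @param xi window half-width.
#' @return character scalar of `2 * xi + 1` residues.
#' @examples
#' extractWindow("ACDEFGHIKLMNPQRSTVWY", center = 1, xi = 7)
#' @export
extractWindow <- function(sequence, center, xi = 7L) {
  L <- nchar(sequence)
  if (center < 1L || center > L)
    stop("center ", center, " out of range [1, ", L, "]")
  ext <- mirrorExtend(sequence, xi)
  substr(ext, center, center + 2L * xi)
}

#' Extract all windows of a protein
#'
#' One window per residue, in sequence order; every window has length
#' `2 * xi + 1` (terminal windows via mirror extension).
#'
#' @inheritParams extractWindow
#' @return character vector of length `L`, element `i` the window centred on
#'   residue `i`.
#' @export
extractAllWindows <- function(sequence, xi = 7L) {
  L <- nchar(sequence)
  ext <- mirrorExtend(sequence, xi)
  substring(ext, seq_len(L), seq_len(L) + 2L * xi)
}

## Windows as a character matrix (rows = windows, 2*xi+1 columns), the form
## the vectorized featurizer consumes.
.windowMatrix <- function(windows) {
  n <- length(windows)
  if (n == 0L) return(matrix(character(), 0L, 0L))
  w <- nchar(windows[1L])
  matrix(unlist(strsplit(windows, ""), use.names = FALSE),
         nrow = n, ncol = w, byrow = TRUE)
}
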