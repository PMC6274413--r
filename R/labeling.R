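#' Surface-residue rule
#'
#' A residue is a surface residue when its accessible surface area in the
#' monomer exceeds 25% of the maximum ASA of the free residue (strict
#' inequality).
#'
#' @param residue one-letter code(s); the 20 standard codes plus B, X, Z.
#' @param asaMonomer ASA of the residue within the monomeric protein (A^2).
#' @param maxAsa maximum-ASA lookup, default [maxASATable()].
#' @return logical vector.
#' @examples
#' isSurfaceResidue("A", 53)    # ratio 0.5 -> TRUE
#' isSurfaceResidue("A", 26.5)  # ratio exactly 0.25 -> FALSE (strict)
#' @export
isSurfaceResidue <- function(residue, asaMonomer, maxAsa = maxASATable()) {
  denom <- maxAsa[residue]
  if (anyNA(denom))
    stop("no maximum-ASA value for residue(s): ",
         paste(unique(residue[is.na(denom)]), collapse = ", "))
  unname(asaMonomer / denom > 0.25)
}

#' Interface-residue rule
#'
#' A surface residue is an interface (binding-site) residue when complex
#' formation buries more than 1 A^2 of its accessible surface area (strict
#' inequality).  Non-surface residues are never interface residues.
#'
#' @param surface logical; is the residue a surface residue?
#' @param asaMonomer ASA within the monomer (A^2).
#' @param asaComplex ASA within the protein-protein complex (A^2).
#' @return logical vector.
#' @export
isInterfaceResidue <- function(surface, asaMonomer, asaComplex) {
  surface & (asaMonomer - asaComplex > 1.0)
}

#' Label residues from an ASA table
#'
#' Applies the surface and interface rules to per-residue accessible surface
#' areas measured in the monomer and in the complex.
#'
#' @param asa data.frame with columns `protein`, `position`, `residue`,
#'   `asa_monomer`, `asa_complex` (A^2; both non-negative).
#' @return data.frame of labeled residues: `protein`, `position`, `residue`,
#'   `surface`, `interface`, `provenance` (always `"experimental"`).
#' @export
labelResidues <- function(asa) {
  need <- c("protein", "position", "residue", "asa_monomer", "asa_complex")
  if (!all(need %in% names(asa)))
    stop("ASA table must have columns: ", paste(need, collapse = ", "))
  if (any(asa$asa_monomer < 0 | asa$asa_complex < 0))
    stop("ASA values must be non-negative")
  surf <- isSurfaceResidue(asa$residue, asa$asa_monomer)
  data.frame(protein = asa$protein, position = asa$position,
             residue = asa$residue, surface = surf,
             interface = isInterfaceResidue(surf, asa$asa_monomer,
                                            asa$asa_complex),
             provenance = "experimental", stringsAsFactors = FALSE)
}

#' Read a per-residue ASA table (TSV)
#'
#' @param path TSV with header `protein`, `position`, `residue`,
#'   `asa_monomer`, `asa_complex`.
#' @return the parsed data.frame.
#' @export
readAsaTable <- function(path) {
  asa <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "position", "residue", "asa_monomer", "asa_complex")
  if (!all(need %in% names(asa)))
    stop("ASA table must have columns: ", paste(need, collapse = ", "))
  asa
}

#' Read a residue-attribution benchmark table
#'
#' Imports a whitespace- or TAB-delimited per-residue table of the layout used
#' by the published 99-chain heterocomplex benchmark: one row per residue
#' carrying the chain id, position, residue code, an experimental flag, a
#' surface flag and an interface flag.  Column positions and the tokens
#' counted as TRUE are configurable because distributed copies of such tables
#' vary.
#'
#' @param path input file.
#' @param columns named integer vector mapping fields to 1-based column
#'   indices; must name `protein`, `position`, `residue`, `experimental`,
#'   `surface`, `interface`.
#' @param trueValues tokens interpreted as a TRUE flag.
#' @param header logical; does the file start with a header line?
#' @return data.frame of labeled residues (`protein`, `position`, `residue`,
#'   `surface`, `interface`, `provenance`).  Rows violating the
#'   interface-implies-surface invariant raise an error naming the offending
#'   lines.
#' @export
readS1Dataset <- function(path,
                          columns = c(protein = 1L, position = 2L,
                                      residue = 3L, experimental = 4L,
                                      surface = 5L, interface = 6L),
                          trueValues = c("1", "+", "Y", "T", "TRUE", "S", "I"),
                          header = FALSE) {
  need <- c("protein", "position", "residue", "experimental", "surface",
            "interface")
  if (!all(need %in% names(columns)))
    stop("columns must name: ", paste(need, collapse = ", "))
  raw <- tryCatch(
    utils::read.table(path, header = header, stringsAsFactors = FALSE,
                      comment.char = "#"),
    error = function(e) stop("cannot parse residue table '", path, "': ",
                             conditionMessage(e)))
  if (ncol(raw) < max(columns))
    stop("residue table has ", ncol(raw), " columns; need at least ",
         max(columns))
  flag <- function(x) as.character(x) %in% trueValues
  pos <- suppressWarnings(as.integer(raw[[columns["position"]]]))
  if (anyNA(pos))
    stop("non-integer position at line(s): ",
         paste(which(is.na(pos)) + as.integer(header), collapse = ", "))
  out <- data.frame(protein = as.character(raw[[columns["protein"]]]),
                    position = pos,
                    residue = toupper(as.character(raw[[columns["residue"]]])),
                    surface = flag(raw[[columns["surface"]]]),
                    interface = flag(raw[[columns["interface"]]]),
                    provenance = ifelse(flag(raw[[columns["experimental"]]]),
                                        "experimental", "hypothetical"),
                    stringsAsFactors = FALSE)
  bad <- which(out$interface & !out$surface)
  if (length(bad))
    stop("interface residue marked non-surface at line(s): ",
         paste(bad + as.integer(header), collapse = ", "))
  out
}

#' Assemble a residue benchmark
#'
#' Extracts the window of every eligible residue (`mode = "surface"`: surface
#' residues only; `mode = "all"`: every labeled residue), computes its 140-
#' component wavelet feature block, and packages features plus labels into a
#' [ResidueBenchmark-class].  A residue is a positive sample iff it is an
#' interface residue.
#'
#' @param labeled data.frame from [labelResidues()] or [readS1Dataset()].
#' @param sequences named character vector of protein sequences covering every
#'   labeled protein.
#' @param mode `"surface"` or `"all"`.
#' @param tables standardized property matrix.
#' @param xi window half-width.
#' @return a [ResidueBenchmark-class].
#' @export
buildBenchmark <- function(labeled, sequences, mode = c("surface", "all"),
                           tables = propertyTables(), xi = 7L) {
  mode <- match.arg(mode)
  missing <- setdiff(unique(labeled$protein), names(sequences))
  if (length(missing))
    stop("no sequence for protein(s): ", paste(missing, collapse = ", "))
  keep <- if (mode == "surface") labeled$surface else rep(TRUE, nrow(labeled))
  lab <- labeled[keep, , drop = FALSE]
  lens <- nchar(sequences)[lab$protein]
  if (any(lab$position < 1L | lab$position > lens))
    stop("residue position out of sequence range for protein(s): ",
         paste(unique(lab$protein[lab$position < 1L | lab$position > lens]),
               collapse = ", "))
  windows <- character(nrow(lab))
  for (p in unique(lab$protein)) {
    rows <- which(lab$protein == p)
    allw <- extractAllWindows(sequences[[p]], xi)
    windows[rows] <- allw[lab$position[rows]]
  }
  feats <- featurizeWindows(windows, tables)
  cd <- S4Vectors::DataFrame(protein = lab$protein, position = lab$position,
                             residue = lab$residue, surface = lab$surface,
                             label = lab$interface,
                             provenance = lab$provenance)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(feats)), colData = cd)
  colnames(se) <- paste0(lab$protein, ":", lab$position)
  new("ResidueBenchmark", se, mode = mode)
}
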