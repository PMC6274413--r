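#' Specification for a synthetic benchmark
#'
#' Describes the stated world of the synthetic generator: proteins with
#' contiguous binding-site patches whose residues are drawn from a
#' property-biased amino-acid distribution, so the learnability of the
#' benchmark is tunable through `effectSize`.
#'
#' @param nProteins number of chains to simulate.
#' @param lengthRange inclusive range of chain lengths (each at least
#'   `2 * xi + 1`).
#' @param positiveFraction target fraction of interface residues among all
#'   residues (0.167 reproduces the 1:5 all-residue imbalance).
#' @param patchLength length of each contiguous interface patch (residues);
#'   patches are separated by at least one window width so labels stay
#'   unambiguous.
#' @param effectSize softmax inverse-temperature of the composition bias:
#'   interface residues are drawn with probability proportional to
#'   `exp(effectSize * z)` where `z` is the mean standardized value of the
#'   designated properties.  0 = no signal.
#' @param noiseSd label-noise control: each interface residue is drawn from
#'   the biased distribution with probability `1 / (1 + noiseSd)` and
#'   uniformly otherwise.
#' @param properties designated property id(s) carrying the signal.
#' @param surfaceFraction probability that a non-interface residue is a
#'   surface residue (interface residues are always surface).
#' @param xi window half-width.
#' @param seed RNG seed; the full fixture is a deterministic function of the
#'   spec.
#' @return named list of class `"ppbsFixtureSpec"`.
#' @export
fixtureSpec <- function(nProteins = 30L, lengthRange = c(80L, 120L),
                        positiveFraction = 1 / 6, patchLength = 8L,
                        effectSize = 2.0, noiseSd = 0.5,
                        properties = "H1", surfaceFraction = 0.8,
                        xi = 7L, seed = 1L) {
  stopifnot(positiveFraction >= 0, positiveFraction <= 1,
            min(lengthRange) >= 2L * xi + 1L, patchLength >= 1L,
            all(properties %in% .PROPERTY_IDS))
  structure(list(nProteins = as.integer(nProteins),
                 lengthRange = as.integer(lengthRange),
                 positiveFraction = positiveFraction,
                 patchLength = as.integer(patchLength),
                 effectSize = effectSize, noiseSd = noiseSd,
                 properties = properties,
                 surfaceFraction = surfaceFraction,
                 xi = as.integer(xi), seed = as.integer(seed)),
            class = "ppbsFixtureSpec")
}

## Biased amino-acid sampling weights: softmax of the mean standardized value
## of the designated properties.
.biasWeights <- function(spec, tables = propertyTables()) {
  z <- rowMeans(tables[, spec$properties, drop = FALSE])
  w <- exp(spec$effectSize * z)
  w / sum(w)
}

## Place non-overlapping patches of `len` consecutive positions in 1..L,
## separated by at least `gap`, aiming for `target` positive residues.
.placePatches <- function(L, len, gap, target) {
  pos <- integer()
  starts <- sample(seq_len(max(L - len + 1L, 1L)))
  taken <- rep(FALSE, L)
  for (s in starts) {
    if (length(pos) >= target) break
    span <- seq(max(1L, s - gap), min(L, s + len - 1L + gap))
    if (any(taken[span])) next
    patch <- seq(s, s + len - 1L)
    taken[span] <- TRUE
    pos <- c(pos, patch)
  }
  sort(pos)
}

#' Generate labeled synthetic proteins
#'
#' Draws seeded protein chains in which contiguous interface patches carry a
#' composition bias toward amino acids with high values of the designated
#' properties; all other residues are uniform over the 20 amino acids.
#' Interface residues are always surface residues; the remaining residues are
#' surface with probability `surfaceFraction`.
#'
#' @param spec a [fixtureSpec()].
#' @param tables standardized property matrix.
#' @return list with `sequences` (named character vector) and `labeled`
#'   (data.frame: `protein`, `position`, `residue`, `surface`, `interface`,
#'   `provenance`).
#' @export
generateLabeledProteins <- function(spec, tables = propertyTables()) {
  stopifnot(inherits(spec, "ppbsFixtureSpec"))
  set.seed(spec$seed)
  wBias <- .biasWeights(spec, tables)
  pBias <- 1 / (1 + spec$noiseSd)
  gap <- 2L * spec$xi + 1L
  seqs <- character(spec$nProteins)
  labs <- vector("list", spec$nProteins)
  ids <- sprintf("SYN%03d", seq_len(spec$nProteins))
  for (i in seq_len(spec$nProteins)) {
    L <- if (spec$lengthRange[1] == spec$lengthRange[2]) spec$lengthRange[1]
         else sample(seq(spec$lengthRange[1], spec$lengthRange[2]), 1L)
    target <- round(spec$positiveFraction * L)
    posPos <- if (target > 0L)
      .placePatches(L, spec$patchLength, gap, target) else integer()
    interface <- seq_len(L) %in% posPos
    res <- sample(.AA20, L, replace = TRUE)
    if (any(interface)) {
      useBias <- interface & (stats::runif(L) < pBias)
      res[useBias] <- sample(.AA20, sum(useBias), replace = TRUE,
                             prob = wBias)
    }
    surface <- interface | (stats::runif(L) < spec$surfaceFraction)
    seqs[i] <- paste(res, collapse = "")
    labs[[i]] <- data.frame(protein = ids[i], position = seq_len(L),
                            residue = res, surface = surface,
                            interface = interface,
                            provenance = "experimental",
                            stringsAsFactors = FALSE)
  }
  names(seqs) <- ids
  list(sequences = seqs, labeled = do.call(rbind, labs))
}

#' Generate ASA records consistent with labels
#'
#' Emits monomer/complex accessible-surface-area pairs that round-trip
#' exactly through the labeling rules: surface residues get an exposure ratio
#' above 25%, buried residues at most 25%, and interface residues
#' additionally lose more than 1 A^2 of ASA upon complex formation.
#'
#' @param labeled data.frame with `protein`, `position`, `residue`,
#'   `surface`, `interface`.
#' @param seed RNG seed.
#' @return data.frame: `protein`, `position`, `residue`, `asa_monomer`,
#'   `asa_complex`.
#' @export
generateAsaRecords <- function(labeled, seed = 1L) {
  set.seed(seed)
  n <- nrow(labeled)
  mx <- maxASATable()[labeled$residue]
  ratio <- ifelse(labeled$surface, stats::runif(n, 0.30, 0.90),
                  stats::runif(n, 0.02, 0.24))
  mono <- ratio * mx
  buried <- ifelse(labeled$interface,
                   stats::runif(n, 1.5, pmax(2, 0.5 * mono)),
                   stats::runif(n, 0.0, 0.9))
  data.frame(protein = labeled$protein, position = labeled$position,
             residue = labeled$residue, asa_monomer = mono,
             asa_complex = pmax(mono - buried, 0),
             stringsAsFactors = FALSE)
}

#' Simulate a full residue benchmark
#'
#' Convenience wrapper: generates labeled proteins from `spec` and assembles
#' the featurized benchmark in the requested mode.
#'
#' @param spec a [fixtureSpec()].
#' @param mode `"surface"` or `"all"`.
#' @param tables standardized property matrix.
#' @return a [ResidueBenchmark-class].
#' @export
simulateBenchmark <- function(spec, mode = c("all", "surface"),
                              tables = propertyTables()) {
  mode <- match.arg(mode)
  gen <- generateLabeledProteins(spec, tables)
  buildBenchmark(gen$labeled, gen$sequences, mode = mode, tables = tables,
                 xi = spec$xi)
}

#' Write fixture files to disk
#'
#' Writes the FASTA, residue-attribution TSV and ASA TSV dialects the import
#' functions read, for round-trip testing and command-line demos.
#'
#' @param gen output of [generateLabeledProteins()].
#' @param dir output directory (created if needed).
#' @param seed seed for the ASA record generation.
#' @return named list of the three file paths, invisibly.
#' @export
writeFixtureFiles <- function(gen, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "proteins.fasta")
  writeLines(paste0(">", names(gen$sequences), "\n", gen$sequences), fasta)
  labels <- file.path(dir, "residues.tsv")
  lab <- gen$labeled
  utils::write.table(
    data.frame(lab$protein, lab$position, lab$residue,
               as.integer(lab$provenance == "experimental"),
               as.integer(lab$surface), as.integer(lab$interface)),
    labels, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  asa <- file.path(dir, "asa.tsv")
  utils::write.table(generateAsaRecords(lab, seed), asa, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, labels = labels, asa = asa))
}
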