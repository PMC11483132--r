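#' @import methods
NULL

.RESIDUE_CATEGORIES <- c("protein", "nucleic", "ligand", "metal", "water")

.ATOM_COLUMNS <- c("chain", "resno", "insert", "resid", "category",
                   "elety", "elesy", "x", "y", "z", "o", "b",
                   "alt", "hydrogen")

#' Uniform in-memory model of a macromolecular structure
#'
#' A \code{StructureModel} holds one coordinate model of a structure parsed
#' from a PDB or mmCIF file: a flat atom table plus provenance.  Each atom
#' row carries its parent residue identity (chain, author residue number,
#' insertion code, three-letter component id) and the residue-level category
#' (\code{protein}, \code{nucleic}, \code{ligand}, \code{metal} or
#' \code{water}).  For predicted models the \code{b} column carries pLDDT
#' (0--100); for experimental structures it is the B-factor.
#'
#' @slot structureId character(1), an identifier for the structure (defaults
#'   to the file stem).
#' @slot source either \code{"experimental"} or \code{"predicted"}.
#' @slot modelNumber integer(1), the coordinate model retained (always the
#'   first; multi-model files are truncated with a message).
#' @slot atoms data.frame with one row per atom and columns
#'   \code{chain, resno, insert, resid, category, elety, elesy, x, y, z, o,
#'   b, alt, hydrogen}.
#'
#' @seealso [parseStructure()], [residueRecords()], [observedSequence()]
#' @export
setClass("StructureModel",
  representation(
    structureId = "character",
    source      = "character",
    modelNumber = "integer",
    atoms       = "data.frame"
  )
)

setValidity("StructureModel", function(object) {
  msg <- character()
  a <- object@atoms
  if (!all(.ATOM_COLUMNS %in% names(a)))
    msg <- c(msg, paste("atom table must have columns:",
                        paste(setdiff(.ATOM_COLUMNS, names(a)), collapse = ", ")))
  if (length(object@source) != 1L ||
      !object@source %in% c("experimental", "predicted"))
    msg <- c(msg, "source must be 'experimental' or 'predicted'")
  if (nrow(a) > 0L && all(.ATOM_COLUMNS %in% names(a))) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msg <- c(msg, "atom coordinates must be finite")
    if (!all(a$category %in% .RESIDUE_CATEGORIES))
      msg <- c(msg, "unknown residue category")
    if (any(a$o < 0 | a$o > 1, na.rm = TRUE))
      msg <- c(msg, "occupancy outside [0, 1]")
    if (any(!nzchar(a$elesy)))
      msg <- c(msg, "every atom needs a non-empty element symbol")
    ## one comp_id per (chain, resno, insert)
    key <- paste(a$chain, a$resno, a$insert, sep = "\r")
    if (anyDuplicated(unique(paste(key, a$resid, sep = "\r"))) ||
        length(unique(paste(key, a$resid, sep = "\r"))) != length(unique(key)))
      msg <- c(msg, "(chain, resno, insert) must identify a unique residue")
  }
  if (length(msg)) msg else TRUE
})

#' Residue-identifier to UniProt-position map for one chain
#'
#' Produced by [buildResidueMap()].  \code{entries} has one row per
#' structure residue that aligned to a (non-gap) reference column, with the
#' 1-based UniProt position, the observed and reference amino acids and a
#' mismatch flag.  The map is injective: no two structure residues share a
#' UniProt position.
#'
#' @slot structureId character(1).
#' @slot chainId character(1).
#' @slot entries data.frame with columns \code{resno, insert, uniprotPos,
#'   observedAa, referenceAa, mismatch}.
#' @slot identityFraction numeric(1) in [0, 1], identical aligned pairs over
#'   aligned pairs.
#' @slot nMismatches integer(1).
#' @slot referenceLength integer(1).
#' @export
setClass("ResidueMap",
  representation(
    structureId      = "character",
    chainId          = "character",
    entries          = "data.frame",
    identityFraction = "numeric",
    nMismatches      = "integer",
    referenceLength  = "integer"
  )
)

setValidity("ResidueMap", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("resno", "insert", "uniprotPos", "observedAa", "referenceAa",
            "mismatch")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$uniprotPos))
    msg <- c(msg, "map must be injective: duplicated uniprotPos")
  if (nrow(e) > 0L &&
      (min(e$uniprotPos) < 1L || max(e$uniprotPos) > object@referenceLength))
    msg <- c(msg, "uniprotPos outside [1, reference length]")
  if (object@identityFraction < 0 || object@identityFraction > 1)
    msg <- c(msg, "identityFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Pairwise semi-global alignment result
#'
#' @slot alignedQuery gapped query string.
#' @slot alignedReference gapped reference string of equal length.
#' @slot score alignment score.
#' @slot identityFraction identical aligned pairs over aligned (non-gap)
#'   pairs.
#' @export
setClass("AlignmentResult",
  representation(
    alignedQuery     = "character",
    alignedReference = "character",
    score            = "numeric",
    identityFraction = "numeric"
  )
)

setValidity("AlignmentResult", function(object) {
  if (nchar(object@alignedQuery) != nchar(object@alignedReference))
    return("aligned strings must have equal length")
  TRUE
})

#' Solvent-accessible surface area result
#'
#' Produced by [shrakeRupley()].  Areas are absolute, in square Angstroms;
#' \code{residueTable$relative} is filled in by [relativeSasa()] as a
#' percentage of the residue type's maximum accessible area (NA until then,
#' and NA for residue types missing from the normalisation table).
#'
#' @slot atomTable data.frame, one row per scored (non-hydrogen, non-water)
#'   atom: \code{chain, resno, insert, resid, elety, area}.
#' @slot residueTable data.frame, one row per scored residue:
#'   \code{chain, resno, insert, resid, area, relative}.
#' @slot probeRadius numeric(1), Angstrom.
#' @slot nSpherePoints integer(1), quadrature points per atom.
#' @export
setClass("SasaResult",
  representation(
    atomTable     = "data.frame",
    residueTable  = "data.frame",
    probeRadius   = "numeric",
    nSpherePoints = "integer"
  )
)

setValidity("SasaResult", function(object) {
  msg <- character()
  if (any(object@atomTable$area < 0)) msg <- c(msg, "negative atom area")
  if (nrow(object@residueTable) > 0L) {
    key <- paste(object@atomTable$chain, object@atomTable$resno,
                 object@atomTable$insert, sep = "\r")
    sums <- tapply(object@atomTable$area, key, sum)
    rkey <- paste(object@residueTable$chain, object@residueTable$resno,
                  object@residueTable$insert, sep = "\r")
    if (max(abs(object@residueTable$area - as.numeric(sums[rkey]))) > 1e-9)
      msg <- c(msg, "residue areas must equal the sum of their atom areas")
  }
  if (length(msg)) msg else TRUE
})

#' Structural coverage of a reference sequence
#'
#' @slot length reference length.
#' @slot counts integer vector of length \code{length}; number of distinct
#'   structures covering each position.
#' @slot coveredFraction fraction of positions with count > 0.
#' @slot uncoveredSegments data.frame(start, end) of maximal zero-count
#'   runs, 1-based closed intervals, sorted and disjoint.
#' @export
setClass("CoverageProfile",
  representation(
    length            = "integer",
    counts            = "integer",
    coveredFraction   = "numeric",
    uncoveredSegments = "data.frame"
  )
)

setValidity("CoverageProfile", function(object) {
  msg <- character()
  if (length(object@counts) != object@length)
    msg <- c(msg, "counts must have one entry per reference position")
  cf <- sum(object@counts > 0L) / object@length
  if (abs(cf - object@coveredFraction) > 1e-12)
    msg <- c(msg, "coveredFraction inconsistent with counts")
  if (length(msg)) msg else TRUE
})

#' Intrinsic-disorder profile from predicted-model confidence
#'
#' Positions whose residue-mean pLDDT falls below \code{threshold} are
#' called disordered.
#'
#' @slot length reference length.
#' @slot positions sorted integer vector of disordered 1-based positions.
#' @slot fraction |positions| / length.
#' @slot threshold pLDDT threshold used.
#' @slot method always \code{"plddt_threshold"}.
#' @export
setClass("DisorderProfile",
  representation(
    length    = "integer",
    positions = "integer",
    fraction  = "numeric",
    threshold = "numeric",
    method    = "character"
  )
)

setValidity("DisorderProfile", function(object) {
  msg <- character()
  if (length(object@positions) &&
      (min(object@positions) < 1L || max(object@positions) > object@length))
    msg <- c(msg, "disordered positions outside [1, length]")
  if (abs(object@fraction - length(object@positions) / object@length) > 1e-12)
    msg <- c(msg, "fraction inconsistent with positions")
  if (length(msg)) msg else TRUE
})
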