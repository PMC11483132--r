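## Structural coverage of the reference sequence and intrinsic disorder
## from predicted-model confidence (pLDDT).

#' Structural coverage of the reference sequence
#'
#' Counts, for every reference position, the number of distinct structures
#' whose residue maps cover it.  A structure contributes at most one count
#' per position regardless of how many of its chains (e.g. homodimer
#' copies) map there.
#'
#' @param maps list of [ResidueMap-class] objects (across all structures
#'   and chains).
#' @param length reference length.
#' @return a [CoverageProfile-class].
#' @export
computeCoverage <- function(maps, length) {
  stopifnot(length >= 1L)
  length <- as.integer(length)
  counts <- integer(length)
  perStructure <- split(maps, vapply(maps, function(m) m@structureId,
                                     character(1)))
  for (ms in perStructure) {
    pos <- sort(unique(unlist(lapply(ms, function(m) m@entries$uniprotPos))))
    if (length(pos) && (min(pos) < 1L || max(pos) > length))
      stop("mapped position outside [1, reference length]: bad residue map")
    counts[pos] <- counts[pos] + 1L
  }
  covered <- counts > 0L
  segs <- data.frame(start = integer(), end = integer())
  if (any(!covered)) {
    r <- rle(!covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- data.frame(start = starts[r$values], end = ends[r$values])
  }
  new("CoverageProfile", length = length, counts = counts,
      coveredFraction = sum(covered) / length, uncoveredSegments = segs)
}

#' Intrinsic disorder from a predicted model's pLDDT
#'
#' A reference position is disordered when the mean atomic pLDDT of its
#' mapped residue falls below \code{threshold} (default 50; a stricter 70
#' is sometimes used and can be passed instead).  Only positions covered by
#' the predicted model are assessable; uncovered positions are not called.
#'
#' @param model a predicted [StructureModel-class] (pLDDT in the B-factor
#'   column).
#' @param map the model's [ResidueMap-class] against the reference.
#' @param threshold pLDDT threshold in [0, 100].
#' @return a [DisorderProfile-class].
#' @export
computeDisorder <- function(model, map, threshold = 50) {
  if (model@source != "predicted")
    stop("disorder calls require a predicted model (pLDDT in B-factor)")
  a <- model@atoms
  a <- a[a$category == "protein" & !a$hydrogen, , drop = FALSE]
  key <- .residueKey(a$chain, a$resno, a$insert)
  meanPlddt <- tapply(a$b, key, mean)
  e <- map@entries
  ekey <- .residueKey(map@chainId, e$resno, e$insert)
  plddt <- as.numeric(meanPlddt[ekey])
  pos <- e$uniprotPos[!is.na(plddt) & plddt < threshold]
  new("DisorderProfile", length = map@referenceLength,
      positions = sort(as.integer(pos)),
      fraction = length(pos) / map@referenceLength,
      threshold = threshold, method = "plddt_threshold")
}

#' Fraction of unique mutations in disordered regions
#'
#' Counts unique mutation records whose position is disordered and reports
#' the percentage of all unique records, rounded half-up to one decimal.
#'
#' @param records deduplicated mutation records
#'   (from [aggregateMutations()]).
#' @param disorder a [DisorderProfile-class].
#' @return list with \code{nInDisorder} and \code{pctOfUnique}.
#' @export
#' @examples
#' prof <- new("DisorderProfile", length = 800L, positions = 1:134,
#'             fraction = 134 / 800, threshold = 50,
#'             method = "plddt_threshold")
#' recs <- data.frame(position = 1:752)
#' mutationsInDisorder(recs, prof)  # 134 of 752 = 17.8%
mutationsInDisorder <- function(records, disorder) {
  if (nrow(records) == 0L)
    stop("percentage undefined for an empty record list")
  n <- sum(records$position %in% disorder@positions)
  list(nInDisorder = as.integer(n),
       pctOfUnique = roundHalfUp(100 * n / nrow(records), 1L))
}
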