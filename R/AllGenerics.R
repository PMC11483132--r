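#' @rdname StructureModel-class
#' @param object,x a \code{StructureModel}.
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname StructureModel-class
#' @export
setGeneric("structureSource", function(x) standardGeneric("structureSource"))

#' @rdname StructureModel-class
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' @rdname StructureModel-class
#' @export
setGeneric("residueRecords", function(x) standardGeneric("residueRecords"))

#' @rdname StructureModel-class
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname ResidueMap-class
#' @param x a \code{ResidueMap}.
#' @export
setGeneric("mapEntries", function(x) standardGeneric("mapEntries"))

#' @rdname ResidueMap-class
#' @export
setGeneric("identityFraction", function(x) standardGeneric("identityFraction"))

#' @rdname SasaResult-class
#' @param x a \code{SasaResult}.
#' @export
setGeneric("atomAreas", function(x) standardGeneric("atomAreas"))

#' @rdname SasaResult-class
#' @export
setGeneric("residueAreas", function(x) standardGeneric("residueAreas"))

#' @rdname CoverageProfile-class
#' @param x a \code{CoverageProfile} or \code{DisorderProfile}.
#' @export
setGeneric("coveredFraction", function(x) standardGeneric("coveredFraction"))

#' @rdname CoverageProfile-class
#' @export
setGeneric("uncoveredSegments", function(x) standardGeneric("uncoveredSegments"))

#' @rdname DisorderProfile-class
#' @param x a \code{DisorderProfile}.
#' @export
setGeneric("disorderedPositions",
           function(x) standardGeneric("disorderedPositions"))

#' @rdname DisorderProfile-class
#' @export
setGeneric("disorderFraction", function(x) standardGeneric("disorderFraction"))

## ---- accessors -----------------------------------------------------------

#' @rdname StructureModel-class
#' @export
setMethod("structureId", "StructureModel", function(x) x@structureId)

#' @rdname StructureModel-class
#' @export
setMethod("structureSource", "StructureModel", function(x) x@source)

#' @rdname StructureModel-class
#' @export
setMethod("atomRecords", "StructureModel", function(x) x@atoms)

#' Residue-level view of a structure
#'
#' One row per residue, in file order, with its category and atom count.
#'
#' @rdname StructureModel-class
#' @export
setMethod("residueRecords", "StructureModel", function(x) {
  a <- x@atoms
  if (nrow(a) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      category = character(), nAtoms = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  out <- a[first, c("chain", "resno", "insert", "resid", "category")]
  out$nAtoms <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
})

#' @rdname StructureModel-class
#' @export
setMethod("chainIds", "StructureModel",
          function(x) unique(x@atoms$chain))

#' @rdname ResidueMap-class
#' @export
setMethod("mapEntries", "ResidueMap", function(x) x@entries)

#' @rdname ResidueMap-class
#' @export
setMethod("identityFraction", "ResidueMap", function(x) x@identityFraction)

#' @rdname SasaResult-class
#' @export
setMethod("atomAreas", "SasaResult", function(x) x@atomTable)

#' @rdname SasaResult-class
#' @export
setMethod("residueAreas", "SasaResult", function(x) x@residueTable)

#' @rdname CoverageProfile-class
#' @export
setMethod("coveredFraction", "CoverageProfile", function(x) x@coveredFraction)

#' @rdname CoverageProfile-class
#' @export
setMethod("uncoveredSegments", "CoverageProfile",
          function(x) x@uncoveredSegments)

#' @rdname DisorderProfile-class
#' @export
setMethod("disorderedPositions", "DisorderProfile", function(x) x@positions)

#' @rdname DisorderProfile-class
#' @export
setMethod("disorderFraction", "DisorderProfile", function(x) x@fraction)

## ---- show methods --------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  rr <- residueRecords(object)
  cat("StructureModel '", object@structureId, "' (", object@source, ")\n",
      sep = "")
  cat("  ", nrow(object@atoms), " atoms, ", nrow(rr), " residues, ",
      length(unique(rr$chain)), " chain(s)\n", sep = "")
  if (nrow(rr)) {
    tab <- table(rr$category)
    cat("  residues by category:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "ResidueMap", function(object) {
  cat("ResidueMap: structure '", object@structureId, "' chain '",
      object@chainId, "' -> UniProt 1..", object@referenceLength, "\n",
      sep = "")
  cat(sprintf("  %d mapped residues, identity %.3f, %d mismatch(es)\n",
              nrow(object@entries), object@identityFraction,
              object@nMismatches))
  invisible(NULL)
})

setMethod("show", "SasaResult", function(object) {
  cat(sprintf(
    "SasaResult: %d atoms, %d residues (probe %.2f A, %d points/atom)\n",
    nrow(object@atomTable), nrow(object@residueTable),
    object@probeRadius, object@nSpherePoints))
  cat(sprintf("  total area %.1f A^2\n", sum(object@atomTable$area)))
  invisible(NULL)
})

setMethod("show", "CoverageProfile", function(object) {
  cat(sprintf("CoverageProfile: length %d, covered %.1f%%, %d gap segment(s)\n",
              object@length, 100 * object@coveredFraction,
              nrow(object@uncoveredSegments)))
  invisible(NULL)
})

setMethod("show", "DisorderProfile", function(object) {
  cat(sprintf(
    "DisorderProfile: %d/%d positions disordered (%.1f%%), pLDDT < %g\n",
    length(object@positions), object@length, 100 * object@fraction,
    object@threshold))
  invisible(NULL)
})
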