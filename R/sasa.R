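## Shrake-Rupley solvent-accessible surface area.
##
## Test points are spread over each atom's probe-expanded sphere by a
## deterministic golden-section spiral; a point is accessible when it lies
## outside every neighbouring atom's expanded sphere.  The per-atom area is
## (accessible points / total points) * 4*pi*(r_atom + r_probe)^2.

.readKeyValueTable <- function(path, keyCol = 1L, valueCol = 2L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vals <- vapply(parts, function(p) as.numeric(p[valueCol]), numeric(1))
  names(vals) <- vapply(parts, function(p) p[keyCol], character(1))
  vals
}

#' Bundled van der Waals radii and maximum-accessibility tables
#'
#' \code{defaultVdwRadii()} returns the bundled element-keyed van der Waals
#' radii (Bondi/Mantina single-element set, Angstrom).
#' \code{defaultMaxAcc()} returns the bundled theoretical maximum accessible
#' areas per residue type (Tien et al. 2013 Gly-X-Gly values), keyed by
#' one-letter code.  Both are read from plain-text files under
#' \code{inst/extdata} and can be overridden by passing your own named
#' vector to [shrakeRupley()] / [relativeSasa()].
#'
#' @return named numeric vector.
#' @export
defaultVdwRadii <- function() {
  .readKeyValueTable(system.file("extdata", "vdw_radii.txt",
                                 package = "MutStruct", mustWork = TRUE))
}

#' @rdname defaultVdwRadii
#' @export
defaultMaxAcc <- function() {
  .readKeyValueTable(system.file("extdata", "max_acc_tien2013.txt",
                                 package = "MutStruct", mustWork = TRUE),
                     keyCol = 2L, valueCol = 3L)
}

#' Deterministic golden-section spiral points on the unit sphere
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  th <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom and per-residue SASA over all non-hydrogen,
#' non-water atoms of the model (hydrogens and waters are excluded both as
#' scored atoms and as occluders; configurable).  The structure is scored
#' as given in the file, so dimer partners, nucleic chains, ligands and
#' ions occlude protein residues.
#'
#' @param model a [StructureModel-class].
#' @param probeRadius probe radius in Angstrom (water = 1.4).
#' @param nPoints quadrature points per atom (>= 32; default 960).
#' @param radii named numeric vector of van der Waals radii keyed by
#'   element symbol; defaults to the bundled table.
#' @param defaultRadius radius used for elements missing from \code{radii};
#'   when \code{NULL} (default) an unknown element is an error.
#' @param excludeWaters,excludeHydrogens drop waters / hydrogens from both
#'   the scored set and the occluders (defaults TRUE).
#' @return a [SasaResult-class]; residue areas are sums of atom areas, the
#'   \code{relative} column is NA until [relativeSasa()] is applied.
#' @export
#' @examples
#' m <- makeHelix("AAAAA")
#' res <- shrakeRupley(m, nPoints = 240)
#' residueAreas(res)
shrakeRupley <- function(model, probeRadius = 1.4, nPoints = 960L,
                         radii = defaultVdwRadii(), defaultRadius = NULL,
                         excludeWaters = TRUE, excludeHydrogens = TRUE) {
  stopifnot(nPoints >= 32L, probeRadius >= 0)
  a <- model@atoms
  if (excludeHydrogens) a <- a[!a$hydrogen, , drop = FALSE]
  if (excludeWaters) a <- a[a$category != "water", , drop = FALSE]
  if (nrow(a) == 0L) stop("no scorable atoms in model")

  r <- unname(radii[a$elesy])
  if (anyNA(r)) {
    if (is.null(defaultRadius))
      stop("no van der Waals radius for element(s): ",
           paste(sort(unique(a$elesy[is.na(r)])), collapse = ", "))
    r[is.na(r)] <- defaultRadius
  }
  re <- r + probeRadius                 # expanded radii
  X <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(X)
  pts <- spherePoints(nPoints)

  d2 <- .crossDist2(X, X)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (re[i] + re)^2)
    nb <- nb[nb != i]
    if (!length(nb)) {
      area[i] <- 4 * pi * re[i]^2
      next
    }
    p <- sweep(pts * re[i], 2, X[i, ], "+")
    ## nearest occluders first: kills points sooner
    nb <- nb[order(d2[i, nb])]
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      idx <- which(free)
      if (!length(idx)) break
      dx <- p[idx, 1] - X[j, 1]
      dy <- p[idx, 2] - X[j, 2]
      dz <- p[idx, 3] - X[j, 3]
      free[idx] <- (dx * dx + dy * dy + dz * dz) > re[j]^2
    }
    area[i] <- sum(free) / nPoints * 4 * pi * re[i]^2
  }

  atomTable <- data.frame(chain = a$chain, resno = a$resno,
                          insert = a$insert, resid = a$resid,
                          elety = a$elety, area = area,
                          stringsAsFactors = FALSE)
  key <- .residueKey(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  sums <- tapply(area, key, sum)
  residueTable <- data.frame(chain = a$chain[first], resno = a$resno[first],
                             insert = a$insert[first], resid = a$resid[first],
                             area = as.numeric(sums[key[first]]),
                             relative = NA_real_, stringsAsFactors = FALSE)
  rownames(atomTable) <- rownames(residueTable) <- NULL
  new("SasaResult", atomTable = atomTable, residueTable = residueTable,
      probeRadius = probeRadius, nSpherePoints = as.integer(nPoints))
}

#' Relative (percent) solvent accessibility
#'
#' Normalises per-residue absolute areas by each residue type's maximum
#' accessible area: \code{relative = 100 * area / max_area}.  Residue types
#' missing from the table (including unknown 'X' residues) get \code{NA},
#' never a silent zero; their identities are recorded in the
#' \code{"flaggedResidues"} attribute of the residue table.
#'
#' @param result a [SasaResult-class] from [shrakeRupley()].
#' @param maxAcc named numeric vector of maximum areas keyed by one-letter
#'   residue code; defaults to the bundled Tien et al. table.
#' @return the updated [SasaResult-class].
#' @export
relativeSasa <- function(result, maxAcc = defaultMaxAcc()) {
  rt <- result@residueTable
  one <- aaThreeToOne(rt$resid)
  one[rt$resid == "UNK" | !rt$resid %in% names(.AA_THREE_TO_ONE)] <- "X"
  mx <- unname(maxAcc[one])
  rt$relative <- ifelse(is.na(mx), NA_real_, 100 * rt$area / mx)
  flagged <- unique(rt$resid[is.na(mx)])
  attr(rt, "flaggedResidues") <- flagged
  result@residueTable <- rt
  result
}

#' Classify residue burial from relative accessibility
#'
#' Relative accessibility below 25 percent marks a core residue; values
#' between 25 and 80 (inclusive) are noninterface; values above 80 are
#' exposed (often called "interface residues" in solvent-accessibility
#' nomenclature, a label this package avoids because its interface
#' annotations are distance-based).  Missing values classify as
#' \code{"unscored"}.
#'
#' @param relativePct numeric vector of relative accessibilities (percent),
#'   NA allowed.
#' @return character vector: \code{"core"}, \code{"noninterface"},
#'   \code{"exposed"} or \code{"unscored"}.
#' @export
#' @examples
#' classifyBurial(c(10, 50, 90, NA))
classifyBurial <- function(relativePct) {
  if (any(relativePct < 0, na.rm = TRUE))
    stop("relative accessibility cannot be negative")
  ifelse(is.na(relativePct), "unscored",
  ifelse(relativePct < 25, "core",
  ifelse(relativePct <= 80, "noninterface", "exposed")))
}
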