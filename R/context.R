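## Distance-cutoff structural context annotation: ligand-binding sites
## (6 A), dimer interfaces, protein-DNA interfaces and zinc sites (5 A).
## All distances are heavy-atom to heavy-atom minimums; hydrogens and
## waters never participate.  The engine is a uniform spatial grid with
## cell size = cutoff and a 27-cell neighbourhood scan, contractually
## identical to exhaustive all-pairs search.

#' Residue pairs within a distance cutoff
#'
#' Finds every (source residue, target residue) pair with at least one atom
#' pair at Euclidean distance <= cutoff, together with the minimal atom-pair
#' distance.  Atom sets are given as row indices into
#' \code{atomRecords(model)}; pairs of an atom with itself are ignored, and
#' pairs of atoms within the same residue are not reported.
#'
#' @param model a [StructureModel-class].
#' @param sourceIdx,targetIdx integer row indices into the atom table.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return data.frame with columns \code{sourceChain, sourceResno,
#'   sourceInsert, targetChain, targetResno, targetInsert, minDist}.
#' @export
findNeighbors <- function(model, sourceIdx, targetIdx, cutoff) {
  stopifnot(cutoff > 0, length(sourceIdx) > 0, length(targetIdx) > 0)
  a <- model@atoms
  S <- as.matrix(a[sourceIdx, c("x", "y", "z")])
  TG <- as.matrix(a[targetIdx, c("x", "y", "z")])

  cellOf <- function(M) {
    cbind(floor(M[, 1] / cutoff), floor(M[, 2] / cutoff),
          floor(M[, 3] / cutoff))
  }
  keyOf <- function(cells) paste(cells[, 1], cells[, 2], cells[, 3],
                                 sep = ",")
  tCells <- cellOf(TG)
  tIndex <- split(seq_along(targetIdx), keyOf(tCells))
  sCells <- cellOf(S)

  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  pairsS <- integer(0); pairsT <- integer(0); pairsD <- numeric(0)
  sKey <- keyOf(sCells)
  for (cellKey in unique(sKey)) {
    sHere <- which(sKey == cellKey)
    base <- sCells[sHere[1], ]
    nbKeys <- paste(base[1] + off[, 1], base[2] + off[, 2],
                    base[3] + off[, 3], sep = ",")
    cand <- unlist(tIndex[nbKeys], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    d2 <- .crossDist2(S[sHere, , drop = FALSE], TG[cand, , drop = FALSE])
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (!nrow(hit)) next
    pairsS <- c(pairsS, sHere[hit[, 1]])
    pairsT <- c(pairsT, cand[hit[, 2]])
    pairsD <- c(pairsD, sqrt(d2[hit]))
  }
  empty <- data.frame(sourceChain = character(), sourceResno = integer(),
                      sourceInsert = character(), targetChain = character(),
                      targetResno = integer(), targetInsert = character(),
                      minDist = numeric(), stringsAsFactors = FALSE)
  if (!length(pairsS)) return(empty)

  si <- sourceIdx[pairsS]; ti <- targetIdx[pairsT]
  keep <- si != ti &
    .residueKey(a$chain[si], a$resno[si], a$insert[si]) !=
    .residueKey(a$chain[ti], a$resno[ti], a$insert[ti])
  if (!any(keep)) return(empty)
  si <- si[keep]; ti <- ti[keep]; d <- pairsD[keep]

  pk <- paste(.residueKey(a$chain[si], a$resno[si], a$insert[si]),
              .residueKey(a$chain[ti], a$resno[ti], a$insert[ti]),
              sep = "\n")
  mind <- tapply(d, pk, min)
  first <- !duplicated(pk)
  out <- data.frame(
    sourceChain = a$chain[si][first], sourceResno = a$resno[si][first],
    sourceInsert = a$insert[si][first],
    targetChain = a$chain[ti][first], targetResno = a$resno[ti][first],
    targetInsert = a$insert[ti][first],
    minDist = as.numeric(mind[pk[first]]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$sourceChain, out$sourceResno, out$sourceInsert,
                   out$targetChain, out$targetResno, out$targetInsert), ]
  rownames(out) <- NULL
  out
}

## scaffold: all protein residues of the model with FALSE flags
.proteinResidueFrame <- function(model) {
  rr <- residueRecords(model)
  rr <- rr[rr$category == "protein", c("chain", "resno", "insert", "resid")]
  rownames(rr) <- NULL
  rr
}

.heavyIdx <- function(a) which(!a$hydrogen & a$category != "water")

## shared flag builder: protein residues vs a target atom set
.annotateVs <- function(model, targetSel, cutoff, flagName, idField = NULL) {
  a <- model@atoms
  out <- .proteinResidueFrame(model)
  out[[flagName]] <- FALSE
  if (!is.null(idField)) out[[idField]] <- ""
  out[[paste0(flagName, "_min_dist")]] <- NA_real_
  srcIdx <- which(!a$hydrogen & a$category == "protein")
  tgtIdx <- intersect(.heavyIdx(a), which(targetSel))
  if (!length(tgtIdx) || !length(srcIdx)) return(out)

  nb <- findNeighbors(model, srcIdx, tgtIdx, cutoff)
  if (!nrow(nb)) return(out)
  skey <- .residueKey(nb$sourceChain, nb$sourceResno, nb$sourceInsert)
  okey <- .residueKey(out$chain, out$resno, out$insert)
  for (k in unique(skey)) {
    r <- which(okey == k)
    sel <- skey == k
    out[[flagName]][r] <- TRUE
    out[[paste0(flagName, "_min_dist")]][r] <- min(nb$minDist[sel])
    if (!is.null(idField)) {
      tk <- .residueKey(nb$targetChain[sel], nb$targetResno[sel],
                        nb$targetInsert[sel])
      ids <- a$resid[match(tk, .residueKey(a$chain, a$resno, a$insert))]
      if (idField == "partner_chains") ids <- nb$targetChain[sel]
      out[[idField]][r] <- paste(sort(unique(ids)), collapse = ",")
    }
  }
  out
}

#' Annotate ligand-binding-site residues
#'
#' Protein residues with any heavy atom within \code{cutoff} (default 6
#' Angstrom) of any heavy atom of a ligand-category residue are flagged.
#' Waters and monoatomic ions are never ligands (ions carry the metal
#' category; see [parseStructure()]).
#'
#' @param model a [StructureModel-class].
#' @param cutoff Angstrom.
#' @return data.frame over all protein residues: \code{chain, resno,
#'   insert, resid, ligand_site, ligand_ids, ligand_site_min_dist}.
#' @export
annotateLigandSites <- function(model, cutoff = 6) {
  .annotateVs(model, model@atoms$category == "ligand", cutoff,
              "ligand_site", "ligand_ids")
}

#' Annotate dimer-interface residues
#'
#' A protein residue is at a chain-chain interface when any of its heavy
#' atoms lies within \code{cutoff} (default 5 Angstrom) of a heavy atom of
#' a protein residue in a different chain.  Partner chain ids are recorded.
#'
#' @inheritParams annotateLigandSites
#' @return data.frame with \code{dimer_interface, partner_chains,
#'   dimer_interface_min_dist}.
#' @export
annotateDimerInterface <- function(model, cutoff = 5) {
  a <- model@atoms
  out <- .proteinResidueFrame(model)
  out$dimer_interface <- FALSE
  out$partner_chains <- ""
  out$dimer_interface_min_dist <- NA_real_
  protIdx <- which(!a$hydrogen & a$category == "protein")
  if (length(unique(a$chain[protIdx])) < 2L) return(out)

  nb <- findNeighbors(model, protIdx, protIdx, cutoff)
  nb <- nb[nb$sourceChain != nb$targetChain, , drop = FALSE]
  if (!nrow(nb)) return(out)
  skey <- .residueKey(nb$sourceChain, nb$sourceResno, nb$sourceInsert)
  okey <- .residueKey(out$chain, out$resno, out$insert)
  for (k in unique(skey)) {
    r <- which(okey == k)
    sel <- skey == k
    out$dimer_interface[r] <- TRUE
    out$dimer_interface_min_dist[r] <- min(nb$minDist[sel])
    out$partner_chains[r] <- paste(sort(unique(nb$targetChain[sel])),
                                   collapse = ",")
  }
  out
}

#' Annotate protein-DNA (nucleic) interface residues
#'
#' Protein residues with any heavy atom within \code{cutoff} (default 5
#' Angstrom) of any heavy atom of a nucleic-category residue.  RNA chains
#' are treated under the same rule.
#'
#' @inheritParams annotateLigandSites
#' @return data.frame with \code{dna_interface, dna_interface_min_dist}.
#' @export
annotateDnaInterface <- function(model, cutoff = 5) {
  .annotateVs(model, model@atoms$category == "nucleic", cutoff,
              "dna_interface")
}

#' Annotate zinc-site residues
#'
#' Protein residues with any heavy atom within \code{cutoff} (default 5
#' Angstrom) of a zinc ion.
#'
#' @inheritParams annotateLigandSites
#' @return data.frame with \code{zinc_site, zinc_site_min_dist}.
#' @export
annotateZincSites <- function(model, cutoff = 5) {
  .annotateVs(model,
              model@atoms$category == "metal" & model@atoms$resid == "ZN",
              cutoff, "zinc_site")
}

#' All four context annotations in one table
#'
#' Contexts are independent flags, not exclusive categories: a residue can
#' simultaneously sit at a DNA interface and a zinc site.
#'
#' @param model a [StructureModel-class].
#' @param ligandCutoff Angstrom, ligand-binding-site cutoff (default 6).
#' @param interfaceCutoff Angstrom, dimer/DNA/zinc cutoff (default 5).
#' @return data.frame over all protein residues with the columns of the
#'   four annotators.
#' @export
annotateContexts <- function(model, ligandCutoff = 6, interfaceCutoff = 5) {
  lig <- annotateLigandSites(model, ligandCutoff)
  dim <- annotateDimerInterface(model, interfaceCutoff)
  dna <- annotateDnaInterface(model, interfaceCutoff)
  zn <- annotateZincSites(model, interfaceCutoff)
  out <- lig
  for (extra in list(dim, dna, zn)) {
    stopifnot(identical(extra$resno, out$resno),
              identical(extra$chain, out$chain))
    out <- cbind(out, extra[, setdiff(names(extra),
                                      c("chain", "resno", "insert",
                                        "resid")), drop = FALSE])
  }
  out
}
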