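## Synthetic, fully ground-truthed inputs: idealised helical proteins,
## B-DNA-like duplexes, zinc ions, small ligands, COSMIC-shaped mutation
## tables.  Geometry is planted at controlled minimal distances and verified
## post-generation by an exhaustive distance check that is independent of
## the package's neighbor-search code.

.ELEMENT_OF_ATOM <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C",
                      CG = "C", P = "P", "C1'" = "C", N1 = "N",
                      ZN = "ZN", C1 = "C", C2 = "C", C3 = "C")

.newAtoms <- function(chain, resno, insert, resid, elety, xyz, b = 30,
                      nucleicCodes = .DEFAULT_NUCLEIC_CODES) {
  elesy <- unname(.ELEMENT_OF_ATOM[elety])
  stopifnot(!anyNA(elesy))
  data.frame(
    chain = chain, resno = as.integer(resno), insert = insert,
    resid = resid, category = .categorizeResidues(resid, nucleicCodes),
    elety = elety, elesy = elesy,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = b, alt = "", hydrogen = FALSE,
    stringsAsFactors = FALSE
  )[, .ATOM_COLUMNS]
}

## ideal alpha-helix coordinates: rise 1.5 A / residue, twist 100 deg,
## C-alpha radius 2.3 A; side chains are stubs (CB radially out 1.53 A,
## plus one CG placeholder for residues larger than Ala)
.helixAtoms <- function(sequence, resnos, chainId, bfactors = NULL,
                        translate = c(0, 0, 0)) {
  letters1 <- strsplit(sequence, "")[[1]]
  n <- length(letters1)
  stopifnot(length(resnos) == n, all(letters1 %in% .AA_ONE))
  if (is.null(bfactors)) bfactors <- rep(30, n)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    th <- (i - 1) * 100 * pi / 180
    z <- (i - 1) * 1.5
    pos <- function(r, dth, dz) c(r * cos(th + dth), r * sin(th + dth), z + dz)
    aa <- letters1[i]
    names3 <- c("N", "CA", "C", "O")
    coords <- rbind(pos(1.6, -0.5, -0.9),
                    pos(2.3, 0.0, 0.0),
                    pos(1.7, 0.5, 0.9),
                    pos(1.9, 0.5, 2.1))
    if (aa != "G") {
      names3 <- c(names3, "CB")
      coords <- rbind(coords, pos(2.3 + 1.53, 0, 0))
    }
    if (!aa %in% c("G", "A")) {
      names3 <- c(names3, "CG")
      coords <- rbind(coords, pos(2.3 + 1.53 + 1.52, 0, 0))
    }
    res[[i]] <- .newAtoms(chainId, resnos[i], "",
                          unname(.AA_ONE_TO_THREE[aa]), names3,
                          sweep(coords, 2, translate, "+"), b = bfactors[i])
  }
  do.call(rbind, res)
}

#' Generate an ideal alpha-helical structure
#'
#' Builds a single-chain poly-peptide on ideal helix geometry (rise 1.5
#' Angstrom, twist 100 degrees per residue) with minimal side-chain stubs,
#' suitable as a fully ground-truthed test structure.
#'
#' @param sequence one-letter amino-acid string.
#' @param startResno author numbering of the first residue.
#' @param chainId chain identifier.
#' @param bfactors per-residue B-factor (or pLDDT for predicted models);
#'   recycled scalar allowed.
#' @param source \code{"experimental"} or \code{"predicted"}.
#' @param structureId identifier.
#' @return a [StructureModel-class].
#' @export
#' @examples
#' m <- makeHelix("AAAAAAAAAA")
#' residueRecords(m)
makeHelix <- function(sequence, startResno = 1L, chainId = "A",
                      bfactors = NULL, source = "experimental",
                      structureId = "helix") {
  if (!grepl("^[A-Z]+$", sequence) ||
      !all(strsplit(sequence, "")[[1]] %in% .AA_ONE))
    stop("invalid one-letter sequence")
  n <- nchar(sequence)
  if (!is.null(bfactors) && length(bfactors) == 1L)
    bfactors <- rep(bfactors, n)
  atoms <- .helixAtoms(sequence, seq(startResno, length.out = n), chainId,
                       bfactors)
  new("StructureModel", structureId = structureId, source = source,
      modelNumber = 1L, atoms = atoms)
}

## idealised double helix with 3 pseudo-atoms per nucleotide
## (rise 3.4 A, twist 36 deg per base pair)
.duplexAtoms <- function(nBp, chainIds = c("E", "F")) {
  strand <- function(chain, angle0, comps, resnos) {
    res <- vector("list", nBp)
    for (j in seq_len(nBp)) {
      th <- angle0 + (j - 1) * 36 * pi / 180
      z <- (j - 1) * 3.4
      coords <- rbind(
        c(8.9 * cos(th - 0.35), 8.9 * sin(th - 0.35), z),
        c(5.9 * cos(th), 5.9 * sin(th), z),
        c(3.5 * cos(th), 3.5 * sin(th), z))
      res[[j]] <- .newAtoms(chain, resnos[j], "", comps[j],
                            c("P", "C1'", "N1"), coords, b = 30)
    }
    do.call(rbind, res)
  }
  comps1 <- rep(c("DA", "DG"), length.out = nBp)
  comps2 <- rep(c("DT", "DC"), length.out = nBp)
  rbind(strand(chainIds[1], 0, comps1, seq_len(nBp)),
        strand(chainIds[2], 154 * pi / 180, comps2, rev(seq_len(nBp))))
}

## translate 'mobile' along the closest-pair direction until the minimal
## heavy-atom distance to 'fixed' equals target (exact by construction)
.nudgeToMinDistance <- function(fixed, mobile, target, maxIter = 200L) {
  F <- as.matrix(fixed); M <- as.matrix(mobile)
  for (it in seq_len(maxIter)) {
    d2 <- .crossDist2(F, M)
    i <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    d <- sqrt(d2[i[1], i[2]])
    if (abs(d - target) < 1e-9) return(M)
    u <- (F[i[1], ] - M[i[2], ])
    u <- u / sqrt(sum(u^2))
    M <- sweep(M, 2, u * (d - target), "+")
  }
  stop("could not realise the requested minimal distance (", target, " A)")
}

.minDistTo <- function(A, B) sqrt(min(.crossDist2(as.matrix(A), as.matrix(B))))

## exhaustive context flags, written independently of findNeighbors():
## plain distance matrices over heavy, non-water atoms
.bruteforceContexts <- function(atoms, ligandCutoff = 6, interfaceCutoff = 5) {
  heavy <- !atoms$hydrogen & atoms$category != "water"
  prot <- atoms[heavy & atoms$category == "protein", , drop = FALSE]
  rk <- .residueKey(prot$chain, prot$resno, prot$insert)
  first <- !duplicated(rk)
  out <- data.frame(chain = prot$chain[first], resno = prot$resno[first],
                    insert = prot$insert[first], resid = prot$resid[first],
                    stringsAsFactors = FALSE)
  okey <- .residueKey(out$chain, out$resno, out$insert)
  P <- as.matrix(prot[, c("x", "y", "z")])

  flagVs <- function(targetAtoms, cutoff) {
    flag <- rep(FALSE, nrow(out)); mind <- rep(NA_real_, nrow(out))
    ids <- rep("", nrow(out))
    if (nrow(targetAtoms) == 0L)
      return(list(flag = flag, mind = mind, ids = ids))
    D <- sqrt(.crossDist2(P, as.matrix(targetAtoms[, c("x", "y", "z")])))
    for (r in seq_len(nrow(out))) {
      rows <- rk == okey[r]
      dsub <- D[rows, , drop = FALSE]
      m <- min(dsub)
      if (m <= cutoff) {
        flag[r] <- TRUE; mind[r] <- m
        hit <- apply(dsub <= cutoff, 2, any)
        ids[r] <- paste(sort(unique(targetAtoms$resid[hit])), collapse = ",")
      }
    }
    list(flag = flag, mind = mind, ids = ids)
  }

  lig <- flagVs(atoms[heavy & atoms$category == "ligand", , drop = FALSE],
                ligandCutoff)
  dna <- flagVs(atoms[heavy & atoms$category == "nucleic", , drop = FALSE],
                interfaceCutoff)
  zn <- flagVs(atoms[heavy & atoms$category == "metal" &
                       atoms$resid == "ZN", , drop = FALSE], interfaceCutoff)

  ## dimer: per residue, nearest heavy atom in any *other* protein chain
  dimFlag <- rep(FALSE, nrow(out)); dimMin <- rep(NA_real_, nrow(out))
  partners <- rep("", nrow(out))
  if (length(unique(prot$chain)) > 1L) {
    Dpp <- sqrt(.crossDist2(P, P))
    for (r in seq_len(nrow(out))) {
      rows <- rk == okey[r]
      other <- prot$chain != out$chain[r]
      if (!any(other)) next
      dsub <- Dpp[rows, other, drop = FALSE]
      m <- min(dsub)
      if (m <= interfaceCutoff) {
        dimFlag[r] <- TRUE; dimMin[r] <- m
        hit <- apply(dsub <= interfaceCutoff, 2, any)
        partners[r] <- paste(sort(unique(prot$chain[other][hit])),
                             collapse = ",")
      }
    }
  }

  out$ligand_site <- lig$flag; out$ligand_ids <- lig$ids
  out$ligand_min_dist <- lig$mind
  out$dimer_interface <- dimFlag; out$partner_chains <- partners
  out$dimer_min_dist <- dimMin
  out$dna_interface <- dna$flag; out$dna_min_dist <- dna$mind
  out$zinc_site <- zn$flag; out$zinc_min_dist <- zn$mind
  rownames(out) <- NULL
  out
}

#' Generate a ground-truthed multi-chain complex
#'
#' Assembles one or two idealised helical protein chains and, optionally, a
#' B-DNA-like duplex, a zinc ion and a small three-atom ligand, each placed
#' at an exact requested minimal heavy-atom distance from the protein (the
#' duplex/ion/ligand is translated along the closest-pair direction until
#' the minimum matches the request).  The returned ground truth is computed
#' by an exhaustive distance check independent of the package's
#' neighbor-search implementation.
#'
#' @param reference full reference amino-acid sequence (one-letter).
#' @param chains list of chain descriptors, each a list with \code{chainId},
#'   \code{span} (c(first, last) reference positions), optional
#'   \code{offset} (author numbering = position + offset, default 0) and
#'   optional \code{deleted} (vector of reference positions omitted from the
#'   chain).
#' @param dimerDistance minimal heavy-atom distance between chains 1 and 2
#'   when two chains are requested.
#' @param dna \code{NULL} or list(nBp, anchorChain, anchorPos, distance).
#' @param zinc \code{NULL} or list(anchorChain, anchorPos, distance).
#' @param ligand \code{NULL} or list(anchorChain, anchorPos, distance,
#'   compId).
#' @param plddt optional numeric vector over reference positions; when given
#'   the model is marked predicted and B-factors carry these values.
#' @param structureId identifier.
#' @param ligandCutoff,interfaceCutoff cutoffs used for the ground-truth
#'   context table (defaults 6 and 5 Angstrom).
#' @return list with \code{model} (a [StructureModel-class]),
#'   \code{contexts} (ground-truth per-residue flag table),
#'   \code{numbering} (per chain, data.frame(resno, uniprotPos)) and
#'   \code{reference}.
#' @export
makeComplex <- function(reference,
                        chains = list(list(chainId = "A",
                                           span = c(1, nchar(reference)))),
                        dimerDistance = 4.5,
                        dna = NULL, zinc = NULL, ligand = NULL,
                        plddt = NULL,
                        structureId = "complex",
                        ligandCutoff = 6, interfaceCutoff = 5) {
  refLetters <- strsplit(reference, "")[[1]]
  chainAtoms <- list(); numbering <- list()
  for (k in seq_along(chains)) {
    ch <- chains[[k]]
    offset <- if (is.null(ch$offset)) 0L else as.integer(ch$offset)
    pos <- seq(ch$span[1], ch$span[2])
    if (!is.null(ch$deleted)) pos <- setdiff(pos, ch$deleted)
    if (max(pos) > nchar(reference)) stop("chain span beyond reference")
    seqk <- paste(refLetters[pos], collapse = "")
    bf <- if (is.null(plddt)) rep(30, length(pos)) else plddt[pos]
    at <- .helixAtoms(seqk, pos + offset, ch$chainId, bfactors = bf,
                      translate = c(0, 0, 0))
    chainAtoms[[k]] <- at
    numbering[[ch$chainId]] <- data.frame(resno = pos + offset,
                                          uniprotPos = pos)
  }
  ## place chain 2 parallel to chain 1 at the requested closest approach
  if (length(chainAtoms) >= 2L) {
    xyz1 <- chainAtoms[[1]][, c("x", "y", "z")]
    for (k in 2:length(chainAtoms)) {
      M <- as.matrix(chainAtoms[[k]][, c("x", "y", "z")])
      M <- sweep(M, 2, c(14 + 10 * (k - 2), 0, 0), "+")
      M <- .nudgeToMinDistance(xyz1, M, dimerDistance)
      chainAtoms[[k]][, c("x", "y", "z")] <- M
    }
  }
  atoms <- do.call(rbind, chainAtoms)

  anchorCoord <- function(anchorChain, anchorPos) {
    num <- numbering[[anchorChain]]
    resno <- num$resno[num$uniprotPos == anchorPos]
    if (!length(resno)) stop("anchor position not present in chain")
    sel <- atoms$chain == anchorChain & atoms$resno == resno &
      atoms$elety %in% c("CB", "CA")
    a <- atoms[sel, , drop = FALSE]
    a <- a[order(match(a$elety, c("CB", "CA"))), ][1, ]
    c(a$x, a$y, a$z)
  }
  ## outward direction: away from the chain's helical axis
  outwardDir <- function(anchorChain, coord) {
    ax <- colMeans(atoms[atoms$chain == anchorChain, c("x", "y")])
    u <- c(coord[1] - ax[1], coord[2] - ax[2], 0)
    u / sqrt(sum(u^2))
  }
  protXyz <- function() atoms[atoms$category == "protein", c("x", "y", "z")]

  placePiece <- function(piece, anchorChain, anchorPos, distance, cutoff) {
    coord <- anchorCoord(anchorChain, anchorPos)
    u0 <- outwardDir(anchorChain, coord)
    num <- numbering[[anchorChain]]
    resno <- num$resno[num$uniprotPos == anchorPos]
    anchorAtoms <- atoms[atoms$chain == anchorChain & atoms$resno == resno,
                         c("x", "y", "z")]
    others <- atoms[atoms$category != "protein", c("x", "y", "z")]
    M0 <- as.matrix(piece[, c("x", "y", "z")])
    ## the outward radial direction can point into a partner chain or an
    ## already-placed piece; scan rotations of it (deterministic order)
    ## until the nudged placement keeps the anchor residue inside the
    ## cutoff and clashes with nothing
    for (rot in seq(0, 330, by = 30) * pi / 180) {
      u <- c(cos(rot) * u0[1] - sin(rot) * u0[2],
             sin(rot) * u0[1] + cos(rot) * u0[2], 0)
      M <- sweep(M0, 2, coord + u * (distance + 4) - colMeans(M0), "+")
      M <- tryCatch(.nudgeToMinDistance(protXyz(), M, distance),
                    error = function(e) NULL)
      if (is.null(M)) next
      if (.minDistTo(anchorAtoms, M) > cutoff) next
      if (nrow(others) && .minDistTo(others, M) < 2.5) next
      piece[, c("x", "y", "z")] <- M
      return(piece)
    }
    stop("unrealisable fixture: anchor residue outside cutoff")
  }

  if (!is.null(dna)) {
    duplex <- .duplexAtoms(dna$nBp %||% 6L)
    duplex <- placePiece(duplex, dna$anchorChain, dna$anchorPos,
                         dna$distance, interfaceCutoff)
    atoms <- rbind(atoms, duplex)
  }
  if (!is.null(zinc)) {
    znAtom <- .newAtoms("Z", 1L, "", "ZN", "ZN",
                        matrix(c(0, 0, 0), 1), b = 30)
    znAtom <- placePiece(znAtom, zinc$anchorChain, zinc$anchorPos,
                         zinc$distance, interfaceCutoff)
    atoms <- rbind(atoms, znAtom)
  }
  if (!is.null(ligand)) {
    compId <- ligand$compId %||% "LIG"
    lg <- .newAtoms("L", 1L, "", compId, c("C1", "C2", "C3"),
                    rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0, 0)), b = 30)
    lg <- placePiece(lg, ligand$anchorChain, ligand$anchorPos,
                     ligand$distance, ligandCutoff)
    atoms <- rbind(atoms, lg)
  }

  rownames(atoms) <- NULL
  model <- new("StructureModel", structureId = structureId,
               source = if (is.null(plddt)) "experimental" else "predicted",
               modelNumber = 1L, atoms = atoms)
  truth <- .bruteforceContexts(atoms, ligandCutoff, interfaceCutoff)
  ## attach true UniProt positions
  truth$uniprotPos <- NA_integer_
  for (cid in names(numbering)) {
    num <- numbering[[cid]]
    sel <- truth$chain == cid
    truth$uniprotPos[sel] <- num$uniprotPos[match(truth$resno[sel],
                                                  num$resno)]
  }
  list(model = model, contexts = truth, numbering = numbering,
       reference = reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a StructureModel as a PDB file
#'
#' Protein and nucleic residues are written as ATOM records, everything
#' else as HETATM (via \pkg{bio3d}).
#'
#' @param model a [StructureModel-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStructurePdb <- function(model, path) {
  a <- model@atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$category %in% c("protein", "nucleic"), "ATOM", "HETATM"),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = ifelse(nzchar(a$chain), a$chain, " "),
    insert = ifelse(nzchar(a$insert), a$insert, ""),
    alt = ifelse(nzchar(a$alt), a$alt, ""),
    o = a$o, b = a$b, elesy = a$elesy, end = TRUE
  )
  invisible(path)
}

#' Write a StructureModel as a minimal mmCIF file
#'
#' Emits a single atom_site loop sufficient for round-trip parsing of the
#' synthetic fixtures (this package never writes mmCIF for real data).
#'
#' @inheritParams writeStructurePdb
#' @export
writeStructureCif <- function(model, path) {
  a <- model@atoms
  hdr <- c(
    paste0("data_", model@structureId),
    "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num"))
  )
  q <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'),
                          paste0("'", x, "'"))
  rows <- paste(
    ifelse(a$category %in% c("protein", "nucleic"), "ATOM", "HETATM"),
    seq_len(nrow(a)), a$elesy, q(a$elety),
    ifelse(nzchar(a$alt), a$alt, "."),
    a$resid, a$chain, 1, a$resno,
    ifelse(nzchar(a$insert), a$insert, "?"),
    sprintf("%.3f", a$x), sprintf("%.3f", a$y), sprintf("%.3f", a$z),
    sprintf("%.2f", a$o), sprintf("%.2f", a$b),
    a$resno, a$resid, a$chain, q(a$elety), 1)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows, "#"), con)
  invisible(path)
}

#' Write a COSMIC-shaped mutation table with known multiplicities
#'
#' Emits a tab-delimited table with columns \code{Gene name},
#' \code{Mutation AA} and \code{Sample name}: one row per sample
#' observation, each mutation repeated according to its requested
#' multiplicity, rows shuffled deterministically by \code{seed}.
#'
#' @param mutations named integer vector, names are protein-change
#'   notations (e.g. \code{c(R248Q = 3, G245S = 1)}).
#' @param path output path.
#' @param gene gene symbol for every row.
#' @param seed shuffle seed.
#' @param extraNotations character vector of additional (e.g. rejectable)
#'   notations appended with multiplicity 1.
#' @return invisibly, a list with \code{path} and \code{expected}, the
#'   expected unique records (position, ref, alt, count, frequency) in the
#'   deterministic output order of [aggregateMutations()].
#' @export
makeMutationTable <- function(mutations, path, gene = "GENE1", seed = 1L,
                              extraNotations = character()) {
  stopifnot(length(mutations) > 0L, all(mutations >= 1L))
  notations <- c(rep(names(mutations), times = mutations), extraNotations)
  rows <- data.frame(
    `Gene name` = gene,
    `Mutation AA` = paste0("p.", notations),
    `Sample name` = sprintf("S%04d", seq_along(notations)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  rows <- .withSeed(seed, rows[sample(nrow(rows)), , drop = FALSE])
  con <- file(path, open = "wb")
  writeLines(paste(names(rows), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(rows), sep = "\t")), con)
  close(con)

  parsed <- do.call(rbind, lapply(names(mutations), function(nt) {
    p <- parseProteinChange(nt)
    data.frame(position = p$position, ref_aa = p$ref, alt_aa = p$alt,
               count = unname(mutations[nt]), stringsAsFactors = FALSE)
  }))
  total <- sum(parsed$count)
  parsed$frequency <- parsed$count / total
  parsed <- parsed[order(-parsed$count, parsed$position, parsed$alt_aa), ]
  rownames(parsed) <- NULL
  invisible(list(path = path, expected = parsed))
}

## independent Monte-Carlo SASA (random sphere points, fixed seed) used only
## to establish ground-truth burial classes for planted fixture positions
.monteCarloSasa <- function(model, nPoints = 2500L, probe = 1.4,
                            seed = 99L) {
  radii <- defaultVdwRadii()
  a <- model@atoms
  a <- a[!a$hydrogen & a$category != "water", , drop = FALSE]
  X <- as.matrix(a[, c("x", "y", "z")])
  r <- unname(radii[a$elesy]) + probe
  if (anyNA(r)) stop("element without radius in Monte-Carlo oracle")
  pts <- .withSeed(seed, {
    m <- matrix(stats::rnorm(nPoints * 3L), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  d2 <- .crossDist2(X, X)
  n <- nrow(X)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, X[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      free <- free & (rowSums(sweep(p, 2, X[j, ])^2) > r[j]^2)
      if (!any(free)) break
    }
    area[i] <- sum(free) / nPoints * 4 * pi * r[i]^2
  }
  key <- .residueKey(a$chain, a$resno, a$insert)
  resArea <- tapply(area, key, sum)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resid = a$resid[first],
                    stringsAsFactors = FALSE)
  out$area <- as.numeric(resArea[key[first]])
  maxacc <- defaultMaxAcc()
  out$relative <- 100 * out$area / unname(maxacc[aaThreeToOne(out$resid)])
  out
}

#' Build the complete end-to-end fixture scenario
#'
#' Generates, under \code{dir}, every input the pipeline needs: a reference
#' FASTA (300 residues), an experimental homodimer complex (chains A and B
#' covering positions 94--292, chain B renumbered with an offset) with a
#' docked DNA duplex, a zinc ion and a small ligand at planted distances; a
#' predicted full-length model whose pLDDT marks positions 1--93 and
#' 294--300 as disordered; and a COSMIC-shaped mutation table containing 20
#' unique substitutions (including the six TP53-style hotspot notations
#' R248Q, R248W, R273H, R273C, R282W, G245S) plus rejectable rows.  All
#' expected outcomes are returned as machine-readable ground truth.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed controlling the reference sequence, mutation
#'   multiplicities and row shuffling.
#' @return list with input paths (\code{complexPdb}, \code{complexCif},
#'   \code{predictedPdb}, \code{referenceFasta}, \code{mutationTable}) and
#'   ground truth (\code{reference}, \code{contexts}, \code{numbering},
#'   \code{expectedRecords}, \code{nSkipped}, \code{disorderPositions},
#'   \code{coveredRange}, \code{burialTruth}, \code{plantedContexts}).
#' @export
caseStudyFixture <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refLen <- 300L
  letters1 <- .withSeed(seed, sample(.AA_ONE, refLen, replace = TRUE))
  hot <- c(`245` = "G", `248` = "R", `273` = "R", `282` = "R")
  letters1[as.integer(names(hot))] <- unname(hot)
  ## anchor residues need full side-chain stubs to sit nearest the planted
  ## piece; cysteine at the zinc site mirrors real zinc coordination
  letters1[237] <- "C"
  letters1[150] <- "L"
  reference <- paste(letters1, collapse = "")

  span <- c(94L, 292L)
  cx <- makeComplex(
    reference,
    chains = list(list(chainId = "A", span = span, offset = 0L),
                  list(chainId = "B", span = span, offset = -93L)),
    dimerDistance = 4.5,
    dna = list(nBp = 6L, anchorChain = "A", anchorPos = 248L,
               distance = 4.0),
    zinc = list(anchorChain = "A", anchorPos = 237L, distance = 4.8),
    ligand = list(anchorChain = "A", anchorPos = 150L, distance = 4.0,
                  compId = "LIG"),
    structureId = "complex1"
  )
  plddt <- rep(90, refLen)
  disorderPositions <- c(1:93, 294:300)
  plddt[disorderPositions] <- 30
  predicted <- makeHelix(reference, startResno = 1L, chainId = "A",
                         bfactors = plddt, source = "predicted",
                         structureId = "predicted1")

  ## choose 20 unique mutation positions from the planted geometry
  ctxA <- cx$contexts[cx$contexts$chain == "A", ]
  pickFrom <- function(flag, n, exclude) {
    cand <- sort(ctxA$uniprotPos[ctxA[[flag]]])
    cand <- setdiff(cand, exclude)
    utils::head(cand, n)
  }
  hotspotPos <- c(245L, 248L, 273L, 282L)
  dimerPos <- pickFrom("dimer_interface", 2L, hotspotPos)
  dnaPos <- pickFrom("dna_interface", 1L, c(hotspotPos, dimerPos))
  zincPos <- pickFrom("zinc_site", 2L, c(hotspotPos, dimerPos, dnaPos))
  ligandPos <- pickFrom("ligand_site", 1L,
                        c(hotspotPos, dimerPos, dnaPos, zincPos))
  disorderMutPos <- c(20L, 50L)
  used <- c(hotspotPos, dimerPos, dnaPos, zincPos, ligandPos,
            disorderMutPos)
  filler <- .withSeed(seed + 1L,
                      sample(setdiff(seq(span[1], span[2]), used),
                             20L - 6L - length(setdiff(used, hotspotPos))))
  positions <- c(dimerPos, dnaPos, zincPos, ligandPos, disorderMutPos,
                 filler)
  altFor <- function(ref, shift) {
    pool <- setdiff(.AA_ONE, ref)
    pool[(shift %% length(pool)) + 1L]
  }
  notations <- c("R248Q", "R248W", "R273H", "R273C", "R282W", "G245S",
                 vapply(seq_along(positions), function(i) {
                   p <- positions[i]
                   paste0(letters1[p], p, altFor(letters1[p], seed + i))
                 }, character(1)))
  stopifnot(length(unique(notations)) == 20L)
  mult <- .withSeed(seed + 2L,
                    c(sample(25:40, 6), sample(1:15, length(positions),
                                               replace = TRUE)))
  names(mult) <- notations
  syn <- paste0("p.", .AA_ONE_TO_THREE[letters1[125]], "125",
                .AA_ONE_TO_THREE[letters1[125]])
  ## strip the added "p." later: makeMutationTable prefixes p. itself
  synBare <- sub("^p\\.", "", syn)
  mutTablePath <- file.path(dir, "mutations.tsv")
  mt <- makeMutationTable(mult, mutTablePath, gene = "GENE1", seed = seed,
                          extraNotations = c(synBare, "Gly10fs", "Val20del"))

  paths <- list(
    complexPdb = file.path(dir, "complex1.pdb"),
    complexCif = file.path(dir, "complex1.cif"),
    predictedPdb = file.path(dir, "predicted1.pdb"),
    referenceFasta = file.path(dir, "reference.fasta"),
    mutationTable = mutTablePath
  )
  writeStructurePdb(cx$model, paths$complexPdb)
  writeStructureCif(cx$model, paths$complexCif)
  writeStructurePdb(predicted, paths$predictedPdb)
  con <- file(paths$referenceFasta, "wb")
  writeLines(c(">REF0001 synthetic reference", reference), con)
  close(con)

  ## ground-truth burial for the planted (structure-covered) positions,
  ## from an independent Monte-Carlo SASA; classes within 3 percentage
  ## points of a 25/80 boundary are left NA (not asserted)
  mc <- .monteCarloSasa(cx$model)
  mutPos <- sort(unique(c(hotspotPos, positions)))
  covered <- mutPos[mutPos >= span[1] & mutPos <= span[2]]
  bt <- do.call(rbind, lapply(covered, function(p) {
    sel <- mc[(mc$chain == "A" & mc$resno == p) |
                (mc$chain == "B" & mc$resno == p - 93L), ]
    sel$uniprotPos <- p
    sel
  }))
  safe <- abs(bt$relative - 25) > 3 & abs(bt$relative - 80) > 3
  bt$burial <- ifelse(!safe, NA_character_,
               ifelse(bt$relative < 25, "core",
               ifelse(bt$relative > 80, "exposed", "noninterface")))

  planted <- list(ligand_site = c(150L, ligandPos),
                  dimer_interface = dimerPos,
                  dna_interface = c(248L, dnaPos),
                  zinc_site = c(237L, zincPos))

  c(paths, list(
    seed = seed,
    reference = reference,
    contexts = cx$contexts,
    numbering = cx$numbering,
    expectedRecords = mt$expected,
    nSkipped = 3L,
    disorderPositions = disorderPositions,
    coveredRange = span,
    burialTruth = bt,
    plantedContexts = planted
  ))
}
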