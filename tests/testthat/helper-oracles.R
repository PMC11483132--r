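## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: neighbor search is a plain distance matrix,
## the alignment score is an exhaustive enumeration over aligned-column
## subsets, SASA cross-validation calls an external implementation.

## build a StructureModel directly from coordinates (bypasses the parser)
cloudModel <- function(coords, elements = "C", resid = "LIG",
                       chain = "X", oneResiduePerAtom = TRUE,
                       category = NULL) {
  n <- nrow(coords)
  elements <- rep_len(elements, n)
  resid <- rep_len(resid, n)
  chain <- rep_len(chain, n)
  resno <- if (oneResiduePerAtom) seq_len(n) else rep(1L, n)
  atoms <- data.frame(
    chain = chain, resno = resno, insert = "", resid = resid,
    category = if (is.null(category)) "ligand" else rep_len(category, n),
    elety = elements, elesy = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    o = 1, b = 0, alt = "", hydrogen = FALSE,
    stringsAsFactors = FALSE
  )
  new("StructureModel", structureId = "cloud", source = "experimental",
      modelNumber = 1L, atoms = atoms)
}

## exhaustive O(N^2) neighbor oracle: residue pairs with min distance <=
## cutoff, written with a plain double loop over residues
bruteNeighborPairs <- function(model, sourceSel, targetSel, cutoff) {
  a <- atomRecords(model)
  S <- a[sourceSel, , drop = FALSE]
  TG <- a[targetSel, , drop = FALSE]
  d <- sqrt(outer(S$x, TG$x, "-")^2 + outer(S$y, TG$y, "-")^2 +
              outer(S$z, TG$z, "-")^2)
  skey <- paste(S$chain, S$resno, S$insert, sep = "|")
  tkey <- paste(TG$chain, TG$resno, TG$insert, sep = "|")
  rows <- list()
  for (sk in unique(skey)) {
    for (tk in unique(tkey)) {
      if (sk == tk) next
      m <- min(d[skey == sk, tkey == tk])
      if (m <= cutoff) rows[[length(rows) + 1L]] <-
          data.frame(source = sk, target = tk, minDist = m,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(source = character(), target = character(),
                      minDist = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$source, out$target), ]
}

## normalise findNeighbors() output to the oracle's shape
neighborsAsKeys <- function(nb) {
  if (nrow(nb) == 0L)
    return(data.frame(source = character(), target = character(),
                      minDist = numeric()))
  out <- data.frame(
    source = paste(nb$sourceChain, nb$sourceResno, nb$sourceInsert,
                   sep = "|"),
    target = paste(nb$targetChain, nb$targetResno, nb$targetInsert,
                   sep = "|"),
    minDist = nb$minDist, stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target), ]
  rownames(out) <- NULL
  out
}

## exhaustive semi-global alignment score: enumerate every set of aligned
## columns (increasing index subsets of query and reference), score matches
## by BLOSUM62 and charge each maximal gap run open + ext * length; leading
## and trailing reference overhangs are free (free end gaps on the query),
## unaligned query letters always pay.
bruteAlignScore <- function(query, reference, open = 10, ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- get("BLOSUM62", envir = environment())
  q <- strsplit(query, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  nq <- length(q); nr <- length(r)
  gapCost <- function(len) if (len > 0) open + ext * len else 0
  best <- -Inf
  for (k in seq_len(min(nq, nr))) {
    qi <- utils::combn(nq, k, simplify = FALSE)
    ri <- utils::combn(nr, k, simplify = FALSE)
    for (a in qi) {
      for (b in ri) {
        sc <- sum(S[cbind(q[a], r[b])])
        ## query letters skipped before/between/after aligned columns
        qskips <- diff(c(0L, a, nq + 1L)) - 1L
        sc <- sc - sum(vapply(qskips, gapCost, numeric(1)))
        ## reference letters skipped between aligned columns (internal
        ## only; overhangs are free)
        if (k > 1L) {
          rskips <- diff(b) - 1L
          sc <- sc - sum(vapply(rskips, gapCost, numeric(1)))
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}
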