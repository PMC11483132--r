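## Structure-to-UniProt residue renumbering via semi-global alignment of a
## chain's observed sequence against the reference sequence.  Replaces the
## external renumbering step usually delegated to a dedicated tool:
## consistent numbering is what makes a mutation's stated position land on
## the right structure residue.

#' Semi-global pairwise alignment of an observed chain sequence
#'
#' Aligns \code{query} (the structure-observed sequence) against
#' \code{reference} with free end gaps on the query side (the query may
#' start and end anywhere inside the reference without penalty), BLOSUM62
#' scoring and affine gap penalties.  A gap of length L costs
#' \code{gapOpening + gapExtension * L}.  Letters outside the BLOSUM62
#' alphabet (U, O) are scored as X.
#'
#' @param query,reference non-empty uppercase one-letter sequences
#'   ('X' allowed).
#' @param gapOpening,gapExtension positive gap costs (defaults 10 and 0.5).
#' @return an [AlignmentResult-class]: equal-length gapped strings covering
#'   the full reference and full query, the alignment score, and the
#'   identity fraction over aligned (both non-gap) columns.
#' @export
#' @examples
#' globalAlign("CDE", "ACDEF")
globalAlign <- function(query, reference, gapOpening = 10,
                        gapExtension = 0.5) {
  if (!nzchar(query) || !nzchar(reference))
    stop("sequences must be non-empty")
  if (grepl("[^A-Z]", query) || grepl("[^A-Z]", reference))
    stop("sequences must be uppercase one-letter codes")
  q <- chartr("UOBJZ", "XXXXX", query)
  r <- chartr("UOBJZ", "XXXXX", reference)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(q),
    subject = Biostrings::AAString(r),
    type = "global-local",
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = gapOpening, gapExtension = gapExtension
  )
  gq <- as.character(Biostrings::alignedPattern(pa))
  gr <- as.character(Biostrings::alignedSubject(pa))
  ## reinstate unaligned reference flanks as free end gaps on the query
  s <- Biostrings::start(Biostrings::subject(pa))
  e <- Biostrings::end(Biostrings::subject(pa))
  pre <- substr(reference, 1L, s - 1L)
  post <- substr(reference, e + 1L, nchar(reference))
  alignedRef <- paste0(pre, gr, post)
  alignedQry <- paste0(strrep("-", nchar(pre)), gq,
                       strrep("-", nchar(post)))
  ## restore original (pre-substitution) letters
  alignedRef <- .regap(reference, alignedRef)
  alignedQry <- .regap(query, alignedQry)

  cq <- strsplit(alignedQry, "")[[1]]
  cr <- strsplit(alignedRef, "")[[1]]
  both <- cq != "-" & cr != "-"
  idf <- if (any(both)) sum(cq[both] == cr[both]) / sum(both) else 0

  new("AlignmentResult", alignedQuery = alignedQry,
      alignedReference = alignedRef,
      score = Biostrings::score(pa), identityFraction = idf)
}

## overlay the original letters of `seq` onto the non-gap columns of `gapped`
.regap <- function(seq, gapped) {
  g <- strsplit(gapped, "")[[1]]
  g[g != "-"] <- strsplit(seq, "")[[1]]
  paste(g, collapse = "")
}

#' Map a protein chain's residues to UniProt positions
#'
#' Aligns the chain's observed sequence to the reference and records, for
#' every structure residue aligned to a non-gap reference column, the
#' 1-based reference position.  Mismatched (non-identical) aligned pairs are
#' mapped but counted: engineered substitutions in crystal constructs are
#' exactly the positions mutation mapping cares about.  Residues aligned to
#' a query gap column (insertions relative to the reference) receive no
#' entry.  An identity fraction below \code{identityFloor} means the chain
#' likely belongs to a different protein and is an error.
#'
#' @param model a [StructureModel-class].
#' @param chainId protein chain to map.
#' @param reference reference amino-acid sequence (1-based positions).
#' @param identityFloor minimum identity fraction over aligned columns
#'   (default 0.30).
#' @param gapOpening,gapExtension passed to [globalAlign()].
#' @return a [ResidueMap-class].
#' @export
buildResidueMap <- function(model, chainId, reference,
                            identityFloor = 0.30,
                            gapOpening = 10, gapExtension = 0.5) {
  if (!nzchar(reference)) stop("reference must be non-empty")
  obs <- observedSequence(model, chainId)   # errors on non-protein chain
  al <- globalAlign(obs$sequence, reference,
                    gapOpening = gapOpening, gapExtension = gapExtension)
  if (al@identityFraction < identityFloor)
    stop(sprintf(
      "chain '%s' does not match reference (identity %.2f < floor %.2f)",
      chainId, al@identityFraction, identityFloor))

  cq <- strsplit(al@alignedQuery, "")[[1]]
  cr <- strsplit(al@alignedReference, "")[[1]]
  qi <- cumsum(cq != "-")                  # query residue index per column
  ri <- cumsum(cr != "-")                  # reference position per column
  both <- cq != "-" & cr != "-"
  entries <- data.frame(
    resno  = obs$numbering$resno[qi[both]],
    insert = obs$numbering$insert[qi[both]],
    uniprotPos  = ri[both],
    observedAa  = cq[both],
    referenceAa = cr[both],
    stringsAsFactors = FALSE
  )
  entries$mismatch <- entries$observedAa != entries$referenceAa
  new("ResidueMap", structureId = model@structureId, chainId = chainId,
      entries = entries, identityFraction = al@identityFraction,
      nMismatches = sum(entries$mismatch),
      referenceLength = nchar(reference))
}

#' Renumber mapped residues to UniProt positions
#'
#' Returns a copy of the model in which every residue covered by one of the
#' maps carries \code{resno = uniprotPos} and an empty insertion code;
#' unmapped residues and non-protein chains are unchanged.
#'
#' @param model a [StructureModel-class].
#' @param maps list of [ResidueMap-class] objects for chains of this model.
#' @return a renumbered [StructureModel-class].
#' @export
renumberStructure <- function(model, maps) {
  if (!length(maps)) stop("need at least one residue map")
  a <- model@atoms
  key <- .residueKey(a$chain, a$resno, a$insert)
  newResno <- a$resno
  newInsert <- a$insert
  for (m in maps) {
    e <- m@entries
    mkey <- .residueKey(m@chainId, e$resno, e$insert)
    hit <- match(key, mkey)
    sel <- !is.na(hit)
    newResno[sel] <- e$uniprotPos[hit[sel]]
    newInsert[sel] <- ""
  }
  a$resno <- as.integer(newResno)
  a$insert <- newInsert
  out <- model
  out@atoms <- a
  validObject(out)
  out
}

#' Read a reference sequence from FASTA
#'
#' Uses the first record; multi-record files require an explicit
#' \code{accession} naming which record to use (matched against the first
#' whitespace-delimited token of each header).
#'
#' @param path FASTA file.
#' @param accession optional record identifier for multi-record files.
#' @return list with \code{accession} and \code{sequence}.
#' @export
readReferenceFasta <- function(path, accession = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (length(set) > 1L && is.null(accession))
    stop("multi-record FASTA: pass `accession` to pick a sequence (found: ",
         paste(ids, collapse = ", "), ")")
  i <- if (is.null(accession)) 1L else match(accession, ids)
  if (is.na(i)) stop("accession '", accession, "' not found in ", path)
  list(accession = ids[i], sequence = as.character(set[[i]]))
}
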