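## Residue-code tables ------------------------------------------------------

## standard amino acids plus common modified residues seen in depositions;
## anything here is categorised as protein and contributes to the observed
## sequence (unknown protein-like codes become 'X' via UNK handling below).
.AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  ## modified / non-standard
  MSE = "M", SEC = "U", PYL = "O", HYP = "P", CSO = "C",
  CME = "C", OCS = "C", SEP = "S", TPO = "T", PTR = "Y",
  MLY = "K", KCX = "K", LLP = "K", M3L = "K", CSD = "C",
  UNK = "X"
)

.AA_ONE <- unname(.AA_THREE_TO_ONE[1:20])
.AA_ONE_TO_THREE <- structure(names(.AA_THREE_TO_ONE)[1:20],
                              names = unname(.AA_THREE_TO_ONE[1:20]))

.DEFAULT_NUCLEIC_CODES <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "U")

.WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

## single-element ion component ids (element == comp_id); these take the
## 'metal' category and are never treated as ligands
.ION_CODES <- c("ZN", "NA", "K", "MG", "CA", "MN", "FE", "CU", "CO", "NI",
                "CD", "HG", "CL", "BR", "IOD", "F", "LI", "RB", "CS", "SR",
                "BA", "AL")

.TWO_LETTER_ELEMENTS <- c("ZN", "NA", "MG", "CL", "CA", "MN", "FE", "CU",
                          "SE", "BR", "NI", "CD", "CO", "HG", "LI", "RB",
                          "CS", "SR", "BA", "AL")

#' Translate three-letter residue codes to one-letter codes
#'
#' Standard and common modified amino acids are translated; anything else
#' becomes \code{"X"}.
#'
#' @param codes character vector of three-letter component ids.
#' @return character vector of one-letter codes.
#' @export
#' @examples
#' aaThreeToOne(c("ALA", "MSE", "XYZ"))
aaThreeToOne <- function(codes) {
  out <- unname(.AA_THREE_TO_ONE[toupper(codes)])
  out[is.na(out)] <- "X"
  out
}

## infer an element symbol from an atom name when the element column is blank
.inferElement <- function(elety, resid) {
  elety <- toupper(trimws(elety))
  resid <- toupper(trimws(resid))
  ## monoatomic ions: the atom name is the element
  ifelse(resid %in% .ION_CODES & elety == resid & resid != "IOD",
         elety,
  ifelse(resid == "IOD", "I", {
    nm <- gsub("[0-9'\"*]", "", elety)
    two <- substr(nm, 1, 2)
    ifelse(two == "SE" & resid == "MSE", "SE",
           ifelse(two %in% .TWO_LETTER_ELEMENTS & !substr(nm, 1, 1) %in%
                    c("C", "N", "O", "H", "S", "P"),
                  two, substr(nm, 1, 1)))
  }))
}

.categorizeResidues <- function(resid, nucleicCodes) {
  resid <- toupper(resid)
  ifelse(resid %in% .WATER_CODES, "water",
  ifelse(resid %in% .ION_CODES, "metal",
  ifelse(resid %in% nucleicCodes, "nucleic",
  ifelse(resid %in% names(.AA_THREE_TO_ONE), "protein",
         "ligand"))))
}

.guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  ## content sniff: mmCIF files start with 'data_'
  head <- tryCatch(readLines(path, n = 5L, warn = FALSE),
                   error = function(e) character())
  if (any(startsWith(head, "data_")) || any(grepl("^_atom_site\\.", head)))
    "mmcif" else "pdb"
}

#' Parse a PDB or mmCIF file into a StructureModel
#'
#' Reads a coordinate file (via \pkg{bio3d}), keeps the first coordinate
#' model, resolves alternate locations to the highest-occupancy conformer
#' (ties broken by altloc letter order), flags hydrogens, infers missing
#' element symbols from atom names, clamps out-of-range occupancies, and
#' categorises every residue as protein, nucleic, ligand, metal or water.
#' Waters are retained but flagged by their category.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format \code{"auto"} (default; inferred from extension, then
#'   content), \code{"pdb"} or \code{"mmcif"}.
#' @param source \code{"experimental"} or \code{"predicted"}.  For
#'   predicted models the B-factor column is interpreted as pLDDT.
#' @param structureId identifier; defaults to the file stem.
#' @param nucleicCodes component ids categorised as nucleic.
#' @return a [StructureModel-class] object.
#' @export
parseStructure <- function(path,
                           format = c("auto", "pdb", "mmcif"),
                           source = c("experimental", "predicted"),
                           structureId = NULL,
                           nucleicCodes = .DEFAULT_NUCLEIC_CODES) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path))
    stop("cannot read structure file: ", path)
  if (format == "auto") format <- .guessFormat(path)
  if (is.null(structureId))
    structureId <- sub("\\.(pdb|ent|cif|mmcif)$", "",
                       basename(path), ignore.case = TRUE)

  pdb <- if (format == "pdb") {
    nModels <- sum(startsWith(readLines(path, warn = FALSE), "MODEL "))
    if (nModels > 1L)
      message("multi-model file '", basename(path),
              "': keeping model 1 of ", nModels)
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  } else {
    withCallingHandlers(
      bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
      warning = function(w) {
        if (grepl("beta version|helix/sheet", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }

  a <- pdb$atom
  atoms <- data.frame(
    chain  = as.character(a$chain),
    resno  = as.integer(a$resno),
    insert = ifelse(is.na(a$insert) | a$insert == "?", "",
                    as.character(a$insert)),
    resid  = toupper(as.character(a$resid)),
    elety  = as.character(a$elety),
    elesy  = ifelse(is.na(a$elesy), "", toupper(trimws(as.character(a$elesy)))),
    x = as.numeric(a$x), y = as.numeric(a$y), z = as.numeric(a$z),
    o = ifelse(is.na(a$o), 1, as.numeric(a$o)),
    b = ifelse(is.na(a$b), 0, as.numeric(a$b)),
    alt = ifelse(is.na(a$alt) | a$alt == ".", "", as.character(a$alt)),
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- ""

  if (any(atoms$o < 0 | atoms$o > 1)) {
    warning("occupancies outside [0, 1] clamped for ",
            sum(atoms$o < 0 | atoms$o > 1), " atom(s)")
    atoms$o <- pmin(pmax(atoms$o, 0), 1)
  }

  blank <- !nzchar(atoms$elesy)
  if (any(blank)) {
    atoms$elesy[blank] <- .inferElement(atoms$elety[blank],
                                        atoms$resid[blank])
    warning("element symbol inferred from atom name for ",
            sum(blank), " atom(s)")
  }
  atoms$hydrogen <- atoms$elesy %in% c("H", "D")

  ## altloc resolution: highest occupancy wins, ties by altloc letter order;
  ## operates per (residue, atom name) so residue count is never changed
  if (any(nzchar(atoms$alt))) {
    akey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
                  sep = "\r")
    ord <- order(akey, -atoms$o, atoms$alt)
    atoms <- atoms[ord, ]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                     atoms$elety, sep = "\r")), ]
    ## restore file order
    atoms <- atoms[order(as.integer(rownames(atoms))), ]
  }

  atoms$category <- .categorizeResidues(atoms$resid, toupper(nucleicCodes))
  ## component ids outside every table are usable but logged
  ligandish <- unique(atoms$resid[atoms$category == "ligand"])
  if (length(ligandish))
    message("non-polymer component(s) categorised as ligand: ",
            paste(sort(ligandish), collapse = ", "))

  if (!any(atoms$category == "protein"))
    stop("no protein content in '", path, "'")

  atoms <- atoms[, .ATOM_COLUMNS]
  rownames(atoms) <- NULL
  new("StructureModel", structureId = structureId, source = source,
      modelNumber = 1L, atoms = atoms)
}

#' Observed one-letter sequence of a protein chain
#'
#' Returns the chain's amino-acid sequence in file order together with the
#' parallel author numbering.  Non-standard residues translate through the
#' bundled modified-residue table (e.g. MSE to M) or to \code{"X"}.
#'
#' @param model a [StructureModel-class].
#' @param chainId chain identifier.
#' @return list with \code{sequence} (one-letter string) and
#'   \code{numbering} (data.frame with \code{resno}, \code{insert}, one row
#'   per sequence position).
#' @export
observedSequence <- function(model, chainId) {
  rr <- residueRecords(model)
  rr <- rr[rr$chain == chainId, , drop = FALSE]
  if (nrow(rr) == 0L)
    stop("no such chain: '", chainId, "'")
  rr <- rr[rr$category == "protein", , drop = FALSE]
  if (nrow(rr) == 0L)
    stop("chain '", chainId, "' has no protein residues")
  list(
    sequence  = paste(aaThreeToOne(rr$resid), collapse = ""),
    numbering = data.frame(resno = rr$resno, insert = rr$insert,
                           stringsAsFactors = FALSE)
  )
}

## fixed, documented column order of the annotated-mutation table
.ANNOTATION_COLUMNS <- c(
  "structure_id", "chain_id", "position", "ref_aa", "alt_aa", "count",
  "frequency", "raw_notation", "observed_aa", "ref_match", "burial_class",
  "relative_sasa", "ligand_site", "ligand_ids", "dimer_interface",
  "partner_chains", "dna_interface", "zinc_site", "in_disorder", "mapped_via"
)

.emptyAnnotationTable <- function() {
  out <- data.frame(
    structure_id = character(), chain_id = character(), position = integer(),
    ref_aa = character(), alt_aa = character(), count = integer(),
    frequency = numeric(), raw_notation = character(),
    observed_aa = character(), ref_match = logical(),
    burial_class = character(), relative_sasa = numeric(),
    ligand_site = logical(), ligand_ids = character(),
    dimer_interface = logical(), partner_chains = character(),
    dna_interface = logical(), zinc_site = logical(),
    in_disorder = logical(), mapped_via = character(),
    stringsAsFactors = FALSE
  )
  out
}

#' Write / read the annotated-mutation table
#'
#' The TSV has the fixed header
#' \code{structure_id, chain_id, position, ref_aa, alt_aa, count, frequency,
#' raw_notation, observed_aa, ref_match, burial_class, relative_sasa,
#' ligand_site, ligand_ids, dimer_interface, partner_chains, dna_interface,
#' zinc_site, in_disorder, mapped_via}; JSON output is an array of objects
#' with the same fields.  Both round-trip losslessly through
#' [readAnnotationTable()].
#'
#' @param rows data.frame of annotated mutations (possibly empty).
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return invisibly, the path.
#' @export
writeAnnotationTable <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (nrow(rows) == 0L) rows <- .emptyAnnotationTable()
  missing <- setdiff(.ANNOTATION_COLUMNS, names(rows))
  if (length(missing))
    stop("annotation rows lack column(s): ", paste(missing, collapse = ", "))
  rows <- rows[, .ANNOTATION_COLUMNS]
  if (format == "tsv") {
    con <- file(path, open = "wb")  # binary mode: byte-identical on rerun
    on.exit(close(con))
    writeLines(paste(.ANNOTATION_COLUMNS, collapse = "\t"), con)
    if (nrow(rows)) {
      fmt <- vapply(seq_len(nrow(rows)), function(i) {
        paste(vapply(.ANNOTATION_COLUMNS, function(cn) {
          v <- rows[[cn]][i]
          if (is.numeric(v) && !is.integer(v))
            { if (is.na(v)) "NA" else format(v, digits = 15) }
          else if (is.logical(v)) as.character(v)
          else as.character(v)
        }, character(1)), collapse = "\t")
      }, character(1))
      writeLines(fmt, con)
    }
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = FALSE)
  }
  invisible(path)
}

#' @rdname writeAnnotationTable
#' @export
readAnnotationTable <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- utils::read.delim(path, sep = "\t", header = TRUE,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    if (nrow(out)) {
      out$position <- as.integer(out$position)
      out$count <- as.integer(out$count)
      out$frequency <- as.numeric(out$frequency)
      out$relative_sasa <- as.numeric(out$relative_sasa)
      for (cn in c("ref_match", "ligand_site", "dimer_interface",
                   "dna_interface", "zinc_site", "in_disorder"))
        out[[cn]] <- as.logical(out[[cn]])
      for (cn in c("ligand_ids", "partner_chains"))
        out[[cn]][is.na(out[[cn]])] <- ""
    } else {
      out <- .emptyAnnotationTable()
    }
  } else {
    out <- jsonlite::fromJSON(path)
    if (!is.data.frame(out) || nrow(out) == 0L) out <- .emptyAnnotationTable()
    out$position <- as.integer(out$position)
    out$count <- as.integer(out$count)
  }
  out[, .ANNOTATION_COLUMNS]
}
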