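## COSMIC-style mutation tables: HGVS protein-change parsing, per-sample
## deduplication, aggregation into unique substitutions and occurrence
## frequencies.

.THREE_LETTER_AA <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  SEC = "U", PYL = "O", TER = "*", XAA = "X"
)

#' Parse a protein-change notation
#'
#' Accepts bare one-letter (\code{"R248Q"}), HGVS one-letter
#' (\code{"p.R248Q"}) and HGVS three-letter (\code{"p.Arg248Gln"},
#' case-insensitive) substitutions, including nonsense changes
#' (\code{"R306*"}, \code{"p.Arg306Ter"}, alt \code{"*"}).  Synonymous,
#' frameshift, deletion/insertion/duplication/indel and splice-like
#' notations are rejected with a typed reason rather than an error so that
#' callers can tally skips.
#'
#' @param notation a single protein-change string.
#' @return list with \code{accepted} (logical); when accepted: \code{ref},
#'   \code{position}, \code{alt}; when rejected: \code{reason}, one of
#'   \code{"synonymous"}, \code{"frameshift"}, \code{"deletion"},
#'   \code{"insertion"}, \code{"duplication"}, \code{"indel"},
#'   \code{"splice"}, \code{"unparseable"}.
#' @export
#' @examples
#' parseProteinChange("R248Q")
#' parseProteinChange("p.Arg282Trp")
#' parseProteinChange("p.Thr125Thr")
parseProteinChange <- function(notation) {
  if (length(notation) != 1L || is.na(notation) || !nzchar(trimws(notation)))
    stop("notation must be a single non-empty string")
  s <- trimws(notation)
  s <- sub("^p\\.", "", s)
  s <- sub("^\\((.*)\\)$", "\\1", s)     # p.(R248Q)

  reject <- function(reason) list(accepted = FALSE, reason = reason,
                                  raw = notation)
  accept <- function(ref, pos, alt) {
    if (ref == alt) return(reject("synonymous"))
    list(accepted = TRUE, ref = ref, position = as.integer(pos), alt = alt,
         raw = notation)
  }

  low <- tolower(s)
  if (grepl("fs", low)) return(reject("frameshift"))
  if (grepl("delins", low)) return(reject("indel"))
  if (grepl("del", low)) return(reject("deletion"))
  if (grepl("ins", low)) return(reject("insertion"))
  if (grepl("dup", low)) return(reject("duplication"))
  if (grepl("^c\\.", low) || grepl("[+>]", s) || low %in% c("?", "p.?"))
    return(reject("splice"))

  ## synonymous shorthand: Thr125= / T125=
  m <- regmatches(s, regexec("^([A-Za-z]{1,3})([0-9]+)=$", s))[[1]]
  if (length(m)) return(reject("synonymous"))

  ## three-letter form
  m <- regmatches(s, regexec(
    "^([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|\\*)$", s))[[1]]
  if (length(m)) {
    ref <- unname(.THREE_LETTER_AA[toupper(m[2])])
    alt <- if (m[4] == "*") "*" else unname(.THREE_LETTER_AA[toupper(m[4])])
    if (is.na(ref) || is.na(alt)) return(reject("unparseable"))
    return(accept(ref, m[3], alt))
  }

  ## one-letter form
  m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z*])$", s))[[1]]
  if (length(m)) {
    if (as.integer(m[3]) < 1L) return(reject("unparseable"))
    return(accept(m[2], m[3], m[4]))
  }
  reject("unparseable")
}

#' Format a substitution back to one-letter notation
#'
#' Inverse of [parseProteinChange()] for accepted substitutions.
#'
#' @param ref,alt one-letter codes (alt may be \code{"*"}).
#' @param position 1-based integer position.
#' @return character notation such as \code{"R248Q"}.
#' @export
formatProteinChange <- function(ref, position, alt) {
  paste0(ref, position, alt)
}

#' Read a COSMIC-style mutation table
#'
#' Delimited text with one row per sample observation.  The separator is
#' auto-detected from the header line (tab if it contains a tab, otherwise
#' comma).  Column names default to the COSMIC targeted-screen export
#' headers and are configurable.
#'
#' @param path file path.
#' @param aaColumn column holding the protein-change notation
#'   (default \code{"Mutation AA"}).
#' @param sampleColumn column holding sample identifiers (default
#'   \code{"Sample name"}); set to \code{NULL} if absent.
#' @param geneColumn column holding the gene symbol (default
#'   \code{"Gene name"}); set to \code{NULL} if absent.
#' @param gene optional gene symbol filter.
#' @return data.frame with columns \code{notation}, \code{sample} (NA when
#'   no sample column), \code{gene} (NA when no gene column).
#' @export
readMutationTable <- function(path, aaColumn = "Mutation AA",
                              sampleColumn = "Sample name",
                              geneColumn = "Gene name", gene = NULL) {
  if (!file.exists(path)) stop("cannot read mutation table: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"")
  if (!aaColumn %in% names(tab))
    stop("column '", aaColumn, "' not found in ", path)
  out <- data.frame(notation = as.character(tab[[aaColumn]]),
                    stringsAsFactors = FALSE)
  out$sample <- if (!is.null(sampleColumn) && sampleColumn %in% names(tab))
    as.character(tab[[sampleColumn]]) else NA_character_
  out$gene <- if (!is.null(geneColumn) && geneColumn %in% names(tab))
    as.character(tab[[geneColumn]]) else NA_character_
  if (!is.null(gene)) out <- out[!is.na(out$gene) & out$gene == gene, ,
                                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate parsed rows into unique mutation records
#'
#' Parses every row's notation, drops rejected rows into a skip table,
#' deduplicates observations per (sample, mutation) pair when sample
#' identifiers are present (COSMIC rows can repeat a sample across
#' studies), and collapses the rest into unique (position, ref, alt)
#' records with occurrence counts.  Frequency is count divided by the total
#' number of accepted observations for the gene, so frequencies over unique
#' records sum to one.  Output order is deterministic: descending count,
#' then position, then alternate residue.
#'
#' @param rows data.frame as returned by [readMutationTable()] (columns
#'   \code{notation} and optionally \code{sample}), or a character vector
#'   of notations.
#' @return list with \code{records} (data.frame: position, ref_aa, alt_aa,
#'   count, frequency, raw_notation), \code{skipped} (data.frame: notation,
#'   reason) and \code{nAccepted} (total accepted observations, the
#'   frequency denominator).
#' @export
#' @examples
#' aggregateMutations(c("R248Q", "R248Q", "R248Q", "G245S"))$records
aggregateMutations <- function(rows) {
  if (is.character(rows)) {
    if (!length(rows)) stop("no mutation rows to aggregate")
    rows <- data.frame(notation = rows, sample = NA_character_,
                       stringsAsFactors = FALSE)
  }
  if (nrow(rows) == 0L) stop("no mutation rows to aggregate")
  if (!"sample" %in% names(rows)) rows$sample <- NA_character_

  parsed <- lapply(rows$notation, parseProteinChange)
  ok <- vapply(parsed, `[[`, logical(1), "accepted")
  skipped <- data.frame(
    notation = rows$notation[!ok],
    reason = vapply(parsed[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  if (!any(ok)) stop("zero accepted mutation rows")

  acc <- data.frame(
    position = vapply(parsed[ok], `[[`, integer(1), "position"),
    ref_aa = vapply(parsed[ok], `[[`, character(1), "ref"),
    alt_aa = vapply(parsed[ok], `[[`, character(1), "alt"),
    raw_notation = rows$notation[ok],
    sample = rows$sample[ok],
    stringsAsFactors = FALSE
  )
  mutKey <- paste(acc$position, acc$ref_aa, acc$alt_aa, sep = "\r")
  ## one observation per (sample, mutation) when samples are known
  hasSample <- !is.na(acc$sample)
  keep <- rep(TRUE, nrow(acc))
  keep[hasSample] <- !duplicated(paste(mutKey, acc$sample,
                                       sep = "\r")[hasSample])
  acc <- acc[keep, , drop = FALSE]
  mutKey <- mutKey[keep]

  counts <- table(mutKey)
  first <- !duplicated(mutKey)
  records <- data.frame(
    position = acc$position[first],
    ref_aa = acc$ref_aa[first],
    alt_aa = acc$alt_aa[first],
    count = as.integer(counts[mutKey[first]]),
    stringsAsFactors = FALSE
  )
  records$frequency <- records$count / sum(records$count)
  records$raw_notation <- formatProteinChange(records$ref_aa,
                                              records$position,
                                              records$alt_aa)
  ord <- order(-records$count, records$position, records$alt_aa)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, skipped = skipped, nAccepted = sum(records$count))
}

#' Check mutation records against the reference sequence
#'
#' A record is consistent when the reference letter at its position equals
#' its stated reference residue.  Mismatches and out-of-range positions are
#' flagged, never dropped.
#'
#' @param records data.frame from [aggregateMutations()].
#' @param reference reference amino-acid sequence.
#' @return the records with an added \code{status} column:
#'   \code{"consistent"}, \code{"mismatched"} or \code{"out_of_range"}.
#' @export
validateAgainstReference <- function(records, reference) {
  if (!nzchar(reference)) stop("reference must be non-empty")
  letters1 <- strsplit(reference, "")[[1]]
  n <- length(letters1)
  inRange <- records$position >= 1L & records$position <= n
  refAt <- rep(NA_character_, nrow(records))
  refAt[inRange] <- letters1[records$position[inRange]]
  records$status <- ifelse(!inRange, "out_of_range",
                    ifelse(refAt == records$ref_aa, "consistent",
                           "mismatched"))
  records
}
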