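## End-to-end orchestration: parse structures, renumber chains to UniProt
## positions, compute SASA and context annotations, aggregate the mutation
## table, map every unique mutation onto every covering structure chain
## (falling back to the predicted model for positions no experimental
## structure covers), and emit per-structure tables plus a summary report.

#' Validated pipeline configuration
#'
#' @param structures character vector of experimental structure paths (PDB
#'   or mmCIF).
#' @param referenceFasta reference sequence FASTA path.
#' @param mutationTable COSMIC-style mutation table path.
#' @param outputDir output directory (created if needed).
#' @param predictedModel optional predicted-model PDB/mmCIF path (pLDDT in
#'   the B-factor column); enables disorder statistics and fallback mapping.
#' @param formats structure formats, recycled over \code{structures}
#'   (\code{"auto"}, \code{"pdb"} or \code{"mmcif"}).
#' @param referenceAccession record to use from a multi-record FASTA.
#' @param aaColumn,sampleColumn,geneColumn,gene mutation-table column
#'   mapping, see [readMutationTable()].
#' @param ligandCutoff,interfaceCutoff context cutoffs in Angstrom
#'   (defaults 6 and 5).
#' @param probeRadius,sasaPoints SASA parameters (defaults 1.4 Angstrom,
#'   960 points).
#' @param plddtThreshold disorder threshold (default 50).
#' @param identityFloor minimum chain-to-reference identity (default 0.30).
#' @return a validated config (list of class \code{"MutStructConfig"}).
#' @export
runConfig <- function(structures, referenceFasta, mutationTable, outputDir,
                      predictedModel = NULL, formats = "auto",
                      referenceAccession = NULL,
                      aaColumn = "Mutation AA",
                      sampleColumn = "Sample name",
                      geneColumn = "Gene name", gene = NULL,
                      ligandCutoff = 6, interfaceCutoff = 5,
                      probeRadius = 1.4, sasaPoints = 960L,
                      plddtThreshold = 50, identityFloor = 0.30) {
  stopifnot(length(structures) >= 1L,
            ligandCutoff > 0, interfaceCutoff > 0, probeRadius >= 0,
            sasaPoints >= 32L)
  for (p in c(structures, referenceFasta, mutationTable, predictedModel))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  cfg <- list(structures = structures,
              formats = rep_len(formats, length(structures)),
              predictedModel = predictedModel,
              referenceFasta = referenceFasta,
              referenceAccession = referenceAccession,
              mutationTable = mutationTable,
              aaColumn = aaColumn, sampleColumn = sampleColumn,
              geneColumn = geneColumn, gene = gene,
              ligandCutoff = ligandCutoff,
              interfaceCutoff = interfaceCutoff,
              probeRadius = probeRadius,
              sasaPoints = as.integer(sasaPoints),
              plddtThreshold = plddtThreshold,
              identityFloor = identityFloor,
              outputDir = outputDir)
  class(cfg) <- "MutStructConfig"
  cfg
}

#' Map one mutation record onto one annotated structure chain
#'
#' Looks up the structure residue whose mapped UniProt position equals the
#' record's position and attaches burial class and context flags.  When the
#' observed residue differs from the record's stated reference residue the
#' row is still emitted, with \code{ref_match = FALSE}.
#'
#' @param record one-row slice of the records from [aggregateMutations()].
#' @param model a [StructureModel-class] (used for its id).
#' @param map the chain's [ResidueMap-class].
#' @param sasa the model's [SasaResult-class], after [relativeSasa()].
#' @param contexts the model's table from [annotateContexts()].
#' @param disorderPositions integer vector of disordered positions.
#' @param mappedVia \code{"experimental"} or \code{"predicted"}.
#' @return a one-row data.frame, or \code{NULL} when the chain does not
#'   cover the position.
#' @export
mapMutation <- function(record, model, map, sasa, contexts,
                        disorderPositions = integer(),
                        mappedVia = "experimental") {
  e <- map@entries
  i <- match(record$position, e$uniprotPos)
  if (is.na(i)) return(NULL)
  rkey <- .residueKey(map@chainId, e$resno[i], e$insert[i])

  rt <- sasa@residueTable
  j <- match(rkey, .residueKey(rt$chain, rt$resno, rt$insert))
  relative <- if (is.na(j)) NA_real_ else rt$relative[j]

  k <- match(rkey, .residueKey(contexts$chain, contexts$resno,
                               contexts$insert))
  ctx <- if (is.na(k)) NULL else contexts[k, ]
  flag <- function(col, default) if (is.null(ctx)) default else ctx[[col]]

  data.frame(
    structure_id = model@structureId, chain_id = map@chainId,
    position = record$position, ref_aa = record$ref_aa,
    alt_aa = record$alt_aa, count = record$count,
    frequency = record$frequency, raw_notation = record$raw_notation,
    observed_aa = e$observedAa[i],
    ref_match = e$observedAa[i] == record$ref_aa,
    burial_class = classifyBurial(relative),
    relative_sasa = relative,
    ligand_site = flag("ligand_site", FALSE),
    ligand_ids = flag("ligand_ids", ""),
    dimer_interface = flag("dimer_interface", FALSE),
    partner_chains = flag("partner_chains", ""),
    dna_interface = flag("dna_interface", FALSE),
    zinc_site = flag("zinc_site", FALSE),
    in_disorder = record$position %in% disorderPositions,
    mapped_via = mappedVia,
    stringsAsFactors = FALSE
  )
}

## parse + renumber + score one structure; returns NULL when no chain maps
.prepareStructure <- function(path, format, reference, cfg, source) {
  model <- parseStructure(path, format = format, source = source)
  protChains <- unique(model@atoms$chain[model@atoms$category == "protein"])
  maps <- list()
  for (ch in protChains) {
    m <- tryCatch(buildResidueMap(model, ch, reference,
                                  identityFloor = cfg$identityFloor),
                  error = function(e) {
                    message("structure '", model@structureId, "' chain '",
                            ch, "' skipped: ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(m)) maps[[ch]] <- m
  }
  if (!length(maps)) {
    message("structure '", model@structureId,
            "' skipped: no chain maps to the reference")
    return(NULL)
  }
  sasa <- relativeSasa(shrakeRupley(model, probeRadius = cfg$probeRadius,
                                    nPoints = cfg$sasaPoints))
  contexts <- annotateContexts(model, ligandCutoff = cfg$ligandCutoff,
                               interfaceCutoff = cfg$interfaceCutoff)
  list(model = model, maps = maps, sasa = sasa, contexts = contexts)
}

#' Run the full mutation-mapping pipeline
#'
#' Executes every stage on the configured inputs and writes, under
#' \code{outputDir}: one \code{<structure_id>_annotated.tsv} per structure
#' (fixed header, see [writeAnnotationTable()]), \code{summary.json} and
#' \code{skipped.tsv} (rejected mutation rows with typed reasons).  The run
#' is deterministic: identical inputs give byte-identical outputs.
#'
#' @param config a config from [runConfig()].
#' @return invisibly, a list: \code{summary} (named list as written to
#'   JSON), \code{rows} (all annotated-mutation rows), \code{records},
#'   \code{skipped}, \code{coverage} ([CoverageProfile-class]),
#'   \code{disorder} ([DisorderProfile-class] or NULL) and \code{maps}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "MutStructConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)

  ref <- readReferenceFasta(config$referenceFasta,
                            config$referenceAccession)
  refLen <- nchar(ref$sequence)

  rows <- readMutationTable(config$mutationTable,
                            aaColumn = config$aaColumn,
                            sampleColumn = config$sampleColumn,
                            geneColumn = config$geneColumn,
                            gene = config$gene)
  agg <- aggregateMutations(rows)
  records <- validateAgainstReference(agg$records, ref$sequence)
  message("mutation table: ", nrow(rows), " rows, ", agg$nAccepted,
          " accepted observations, ", nrow(records), " unique mutations, ",
          nrow(agg$skipped), " skipped")

  prepared <- list()
  for (i in seq_along(config$structures)) {
    p <- .prepareStructure(config$structures[i], config$formats[i],
                           ref$sequence, config, "experimental")
    if (!is.null(p)) prepared[[p$model@structureId]] <- p
  }
  if (!length(prepared)) stop("no usable experimental structures")

  expMaps <- unlist(lapply(prepared, `[[`, "maps"), use.names = FALSE)
  coverage <- computeCoverage(expMaps, refLen)
  message("coverage: ", sprintf("%.1f%%", 100 * coverage@coveredFraction),
          " of ", refLen, " positions, from ", length(prepared),
          " structure(s)")

  predicted <- NULL
  disorder <- NULL
  if (!is.null(config$predictedModel)) {
    predicted <- .prepareStructure(config$predictedModel, "auto",
                                   ref$sequence, config, "predicted")
    if (is.null(predicted)) stop("predicted model does not map to reference")
    predMap <- predicted$maps[[1]]
    disorder <- computeDisorder(predicted$model, predMap,
                                threshold = config$plddtThreshold)
    message(sprintf("disorder: %.1f%% of positions (pLDDT < %g)",
                    100 * disorder@fraction, disorder@threshold))
  }
  disorderPositions <- if (is.null(disorder)) integer()
                       else disorder@positions

  ## map every unique mutation onto every covering structure chain
  allRows <- list()
  nCovered <- 0L
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    coveredHere <- FALSE
    for (sid in names(prepared)) {
      p <- prepared[[sid]]
      for (ch in names(p$maps)) {
        row <- mapMutation(rec, p$model, p$maps[[ch]], p$sasa, p$contexts,
                           disorderPositions, "experimental")
        if (!is.null(row)) {
          allRows[[length(allRows) + 1L]] <- row
          coveredHere <- TRUE
        }
      }
    }
    if (coveredHere) {
      nCovered <- nCovered + 1L
    } else if (!is.null(predicted)) {
      for (ch in names(predicted$maps)) {
        row <- mapMutation(rec, predicted$model, predicted$maps[[ch]],
                           predicted$sasa, predicted$contexts,
                           disorderPositions, "predicted")
        if (!is.null(row)) allRows[[length(allRows) + 1L]] <- row
      }
    }
  }
  annotated <- if (length(allRows)) do.call(rbind, allRows)
               else .emptyAnnotationTable()
  annotated <- annotated[order(annotated$structure_id, annotated$chain_id,
                               annotated$position, annotated$alt_aa), ,
                         drop = FALSE]
  rownames(annotated) <- NULL
  message("mapped: ", nCovered, " of ", nrow(records),
          " unique mutations covered by experimental structures; ",
          nrow(records) - nCovered, " fell back to the predicted model")

  ## per-structure outputs and per-context counts
  perStructure <- list()
  sids <- unique(annotated$structure_id)
  for (sid in sort(sids)) {
    sub <- annotated[annotated$structure_id == sid, , drop = FALSE]
    writeAnnotationTable(sub, file.path(config$outputDir,
                                        paste0(sid, "_annotated.tsv")))
    uniqueCount <- function(flagCol) {
      length(unique(paste(sub$position, sub$alt_aa)[sub[[flagCol]]]))
    }
    perChain <- lapply(split(sub, sub$chain_id), function(cs) {
      list(n_mutations = nrow(cs),
           n_ligand_site = sum(cs$ligand_site),
           n_dimer_interface = sum(cs$dimer_interface),
           n_dna_interface = sum(cs$dna_interface),
           n_zinc_site = sum(cs$zinc_site))
    })
    perStructure[[sid]] <- list(
      n_rows = nrow(sub),
      n_unique_mutations = length(unique(paste(sub$position, sub$alt_aa))),
      n_ligand_site = uniqueCount("ligand_site"),
      n_dimer_interface = uniqueCount("dimer_interface"),
      n_dna_interface = uniqueCount("dna_interface"),
      n_zinc_site = uniqueCount("zinc_site"),
      per_chain = perChain
    )
  }

  disorderStats <- if (!is.null(disorder))
    mutationsInDisorder(records, disorder) else NULL

  summary <- list(
    reference_accession = ref$accession,
    reference_length = refLen,
    n_structures = length(prepared),
    covered_fraction = coverage@coveredFraction,
    uncovered_segments = coverage@uncoveredSegments,
    disorder_fraction = if (is.null(disorder)) NULL else disorder@fraction,
    n_input_rows = nrow(rows),
    n_accepted_observations = agg$nAccepted,
    n_skipped_rows = nrow(agg$skipped),
    n_unique_mutations = nrow(records),
    n_covered_mutations = nCovered,
    n_uncovered_mutations = nrow(records) - nCovered,
    n_mutations_in_disorder =
      if (is.null(disorderStats)) NULL else disorderStats$nInDisorder,
    pct_mutations_in_disorder =
      if (is.null(disorderStats)) NULL else disorderStats$pctOfUnique,
    structures = perStructure
  )
  jsonlite::write_json(summary, file.path(config$outputDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")

  skpPath <- file.path(config$outputDir, "skipped.tsv")
  con <- file(skpPath, "wb")
  writeLines(c("notation\treason",
               if (nrow(agg$skipped))
                 paste(agg$skipped$notation, agg$skipped$reason,
                       sep = "\t")), con)
  close(con)

  invisible(list(summary = summary, rows = annotated, records = records,
                 skipped = agg$skipped, coverage = coverage,
                 disorder = disorder,
                 maps = lapply(prepared, `[[`, "maps")))
}
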