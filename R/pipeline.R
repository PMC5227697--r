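#' Run the full metabarcoding pipeline
#'
#' Orchestrates QC, dereplication, negative-control sequence removal,
#' taxonomic assignment, OTU clustering and curation, cut-off derivation and
#' the detection matrix, then the community statistics. Every stochastic
#' step (only the Mantel permutations) is seeded from the configuration.
#'
#' @param sampleSheet sample-sheet data.frame or CSV path.
#' @param fastqDir directory with per-sample FASTQ files.
#' @param reference reference data.frame or FASTA path.
#' @param checklist checklist data.frame or TSV path; NULL derives an
#'   all-local checklist from the reference.
#' @param config a [PipelineConfig-class].
#' @param primers primer set ([mifishPrimerSet()]).
#' @param outDir optional run directory; when given, the QC report, OTU
#'   table, detection matrix, statistics and a JSON run report are written.
#' @return list with \code{detectionMatrix}, \code{report} (stage tallies and
#'   the four-row assignment summary inputs), \code{otus}, \code{cutoff},
#'   \code{stats} (replicate accumulation, Chao1, layer partition, station
#'   group counts, Mantel correlogram).
#' @export
runPipeline <- function(sampleSheet, fastqDir, reference, checklist = NULL,
                        config = PipelineConfig(),
                        primers = mifishPrimerSet(), outDir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(sampleSheet)) sampleSheet <- readSampleSheet(sampleSheet)
  if (is.character(reference)) reference <- readReferenceFasta(reference)
  if (is.null(checklist))
    checklist <- checklistFromReference(reference)
  else if (is.character(checklist)) checklist <- readChecklist(checklist)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  timing <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timing[[name]] <<- t1 - t0
    t0 <<- t1
  }

  qc <- runQc(sampleSheet, fastqDir, config@qc, primers,
              outDir = if (is.null(outDir)) NULL else file.path(outDir, "qc"))
  tick("qc")

  uniq <- dereplicate(qc$inserts, minCount = config@minUniqueCount)
  qcPassedReads <- sum(lengths(qc$inserts))
  clusteredReads <- sum(uniq$uniques$total)
  clusteredUniques <- nrow(uniq$uniques)
  negIds <- sampleSheet$sample_id[sampleSheet$is_negative]
  readsInNegatives <- sum(uniq$counts$count[uniq$counts$sample_id %in% negIds])
  uniqClean <- removeNegativeSequences(uniq, negIds)
  tick("dereplicate")

  assign <- searchReference(uniqClean, reference,
                            identityThreshold = config@identityThreshold,
                            minAlignedLength = config@minAlignedLength)
  assign <- classifyConfidence(assign, reference,
                               identityThreshold = config@identityThreshold,
                               confidenceMargin = config@confidenceMargin)
  otusRaw <- clusterOtus(assign, uniqClean, reference)
  otus <- curateOtus(otusRaw, checklist)
  tick("taxonomy")

  cutoff <- if (config@cutoffMode == "derive")
    deriveCutoff(readsInNegatives, length(negIds), nrow(sampleSheet),
                 clusteredReads)
  else config@fixedCutoff
  dm <- applyCutoff(otus, cutoff, sampleSheet)
  tick("decontam")

  totals <- setNames(uniqClean$uniques$total, uniqClean$uniques$seq_id)
  assignedReads <- sum(totals[assign$seq_id[assign$assigned]])
  unassignedReads <- sum(totals[assign$seq_id[!assign$assigned]])
  report <- list(
    tallies = qc$tallies,
    qcPassedReads = qcPassedReads,
    singletonReads = uniq$discarded$nReads,
    singletonUniques = uniq$discarded$nSequences,
    clusteredReads = clusteredReads,
    clusteredUniques = clusteredUniques,
    readsInNegatives = readsInNegatives,
    negativeRemovedReads = uniqClean$removed$nReads,
    negativeRemovedUniques = uniqClean$removed$nSequences,
    assignedReads = assignedReads,
    assignedUniques = sum(assign$assigned),
    unassignedReads = unassignedReads,
    unassignedUniques = sum(!assign$assigned),
    otusBeforeCuration = nrow(otusRaw$otus),
    otusAfterCuration = nrow(otus$otus),
    otusDetected = sum(rowSums(detections(dm)) > 0))

  set.seed(deriveSeed(config@seed, 11L))
  comm <- stationCommunity(dm)
  stats <- list(
    replicateAccumulation = list(
      surface = replicateAccumulation(dm, "surface"),
      bottom = replicateAccumulation(dm, "bottom")),
    chao1 = chao1Richness(dm, corrected = config@chao1Corrected),
    partition = partitionByLayer(dm),
    stationGroups = stationGroupCounts(dm),
    correlogram = if (nrow(comm) >= 4)
      mantelCorrelogram(comm, attr(comm, "coords"),
                        nClasses = if (is.na(config@nDistanceClasses)) NA
                                   else config@nDistanceClasses,
                        nPerm = config@nPermutations,
                        seed = deriveSeed(config@seed, 12L))
      else NULL)
  tick("stats")
  report$timing <- timing

  if (!is.null(outDir)) {
    writeOtuTable(otus, file.path(outDir, "otu_table.tsv"))
    writeDetectionMatrix(dm, file.path(outDir, "detection_matrix.tsv"))
    if (!is.null(stats$correlogram))
      write.table(correlogramTable(stats$correlogram),
                  file.path(outDir, "correlogram.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    write.table(stats$chao1, file.path(outDir, "chao1.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write_json(report[setdiff(names(report), "tallies")],
               file.path(outDir, "report.json"), auto_unbox = TRUE,
               pretty = TRUE, digits = NA)
  }
  list(detectionMatrix = dm, report = report, otus = otus, cutoff = cutoff,
       stats = stats)
}

#' All-local checklist derived from a reference database
#'
#' @param reference reference data.frame.
#' @return checklist data.frame (\code{species, genus, local,
#'   substitute_for}).
#' @export
checklistFromReference <- function(reference) {
  data.frame(species = reference$species, genus = reference$genus,
             local = reference$local, substitute_for = NA_character_,
             stringsAsFactors = FALSE)
}

#' Four-row assignment summary
#'
#' Read and unique-sequence totals for assigned / not assigned / discarded
#' singletons, with percentages of the quality-passed totals rounded half-up
#' to one decimal.
#'
#' @param report either a pipeline report (from [runPipeline()]) or a list
#'   with \code{assignedReads, unassignedReads, singletonReads} and
#'   optionally the corresponding \code{*Uniques} counts.
#' @return data.frame rows \code{assigned, not_assigned, discarded_singleton,
#'   total} with \code{reads, reads_pct, uniques, uniques_pct}.
#' @export
summarizeTable1 <- function(report) {
  reads <- c(assigned = report$assignedReads,
             not_assigned = report$unassignedReads,
             discarded_singleton = report$singletonReads)
  uniq <- c(assigned = report$assignedUniques %||% NA_real_,
            not_assigned = report$unassignedUniques %||% NA_real_,
            discarded_singleton = report$singletonUniques %||% NA_real_)
  totR <- sum(reads); totU <- sum(uniq)
  if (totR == 0) {
    warning("no reads to summarize")
    return(data.frame(category = character(), reads = numeric(),
                      reads_pct = numeric(), uniques = numeric(),
                      uniques_pct = numeric()))
  }
  data.frame(
    category = c(names(reads), "total"),
    reads = c(reads, totR),
    reads_pct = c(roundHalfUp(100 * reads / totR, 1), NA),
    uniques = c(uniq, totU),
    uniques_pct = c(roundHalfUp(100 * uniq / totU, 1), NA),
    row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
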