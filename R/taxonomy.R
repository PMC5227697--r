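#' Dereplicate QC-passed inserts
#'
#' Groups exactly identical sequences across all samples, keeping per-sample
#' read counts. Sequences whose run-wide total falls below
#' \code{minCount} (default 2: singletons) are discarded and tallied
#' separately. The count threshold is applied across the run, not per
#' sample.
#'
#' @param inserts named list of per-sample insert character vectors (as from
#'   [runQc()]).
#' @param minCount minimum run-wide total read count retained.
#' @return list (class \code{UniqueSet}): \code{uniques} (data.frame
#'   \code{seq_id, sequence, total}), \code{counts} (long data.frame
#'   \code{seq_id, sample_id, count}) and \code{discarded}
#'   (\code{nSequences}, \code{nReads} below the threshold).
#' @export
dereplicate <- function(inserts, minCount = 2L) {
  sampleIds <- names(inserts)
  allSeq <- unlist(inserts, use.names = FALSE)
  allSamp <- rep(sampleIds, lengths(inserts))
  if (length(allSeq) == 0) {
    return(structure(list(
      uniques = data.frame(seq_id = character(), sequence = character(),
                           total = integer()),
      counts = data.frame(seq_id = character(), sample_id = character(),
                          count = integer()),
      discarded = list(nSequences = 0L, nReads = 0L)), class = "UniqueSet"))
  }
  seqF <- factor(allSeq)
  sampF <- factor(allSamp, levels = sampleIds)
  nS <- nlevels(sampF)
  code <- (as.integer(seqF) - 1L) * nS + as.integer(sampF)
  tab <- table(code)
  codeVals <- as.integer(names(tab))
  seqIdx <- (codeVals - 1L) %/% nS + 1L
  sampIdx <- (codeVals - 1L) %% nS + 1L
  totals <- tabulate(as.integer(seqF), nbins = nlevels(seqF))

  keepSeq <- totals >= minCount
  ord <- order(-totals[keepSeq], levels(seqF)[keepSeq])
  keptLevels <- which(keepSeq)[ord]
  ids <- sprintf("U%06d", seq_along(keptLevels))
  idOf <- rep(NA_character_, nlevels(seqF))
  idOf[keptLevels] <- ids

  keepRow <- keepSeq[seqIdx]
  counts <- data.frame(seq_id = idOf[seqIdx[keepRow]],
                       sample_id = sampleIds[sampIdx[keepRow]],
                       count = as.integer(tab)[keepRow],
                       stringsAsFactors = FALSE)
  counts <- counts[order(counts$seq_id, counts$sample_id), , drop = FALSE]
  rownames(counts) <- NULL
  uniques <- data.frame(seq_id = ids,
                        sequence = levels(seqF)[keptLevels],
                        total = totals[keptLevels], stringsAsFactors = FALSE)
  structure(list(uniques = uniques, counts = counts,
                 discarded = list(nSequences = sum(!keepSeq),
                                  nReads = sum(totals[!keepSeq]))),
            class = "UniqueSet")
}

#' Assign unique sequences against the reference database
#'
#' Ranks references by ungapped identity over the full query (matching bases
#' at offset zero over the aligned length, divided by the query length). A
#' query is assigned when the top hit reaches \code{identityThreshold} and
#' the aligned length is at least \code{minAlignedLength} bp -- the latter
#' standing in for a BLAST E-value bound, which cannot bind for ~170 bp
#' amplicons at 99\% identity. The best and the runner-up species (best
#' identity among species other than the top hit) are both recorded.
#'
#' @param uniqueSet a \code{UniqueSet} from [dereplicate()].
#' @param reference reference data.frame ([readReferenceFasta()]).
#' @param identityThreshold minimum top identity (\%) for assignment.
#' @param minAlignedLength minimum aligned length (bp).
#' @param wordSize queries shorter than this are unassigned with a note.
#' @return data.frame of assignments: \code{seq_id, top_species,
#'   top_identity, aligned_length, second_species, second_identity, assigned,
#'   note}.
#' @export
searchReference <- function(uniqueSet, reference, identityThreshold = 99,
                            minAlignedLength = 100L, wordSize = 11L) {
  if (nrow(reference) == 0) stop("reference database is empty")
  u <- uniqueSet$uniques
  spLevels <- unique(reference$species)
  spIdx <- match(reference$species, spLevels)
  res <- cpp_top2_search(u$sequence, reference$sequence, spIdx,
                         length(spLevels))
  out <- data.frame(seq_id = u$seq_id,
                    top_species = spLevels[res$top_species],
                    top_identity = res$top_identity,
                    aligned_length = res$aligned_length,
                    second_species = ifelse(is.na(res$second_species), NA,
                                            spLevels[res$second_species]),
                    second_identity = res$second_identity,
                    stringsAsFactors = FALSE)
  tooShort <- nchar(u$sequence) < wordSize
  out$assigned <- !tooShort & out$top_identity >= identityThreshold &
    out$aligned_length >= minAlignedLength
  out$note <- ifelse(tooShort, "query shorter than word size", "")
  out[tooShort, c("top_species", "second_species")] <- NA
  out
}

#' Classify assignment confidence
#'
#' LOW when the runner-up species also reaches the identity threshold (the
#' assignment cannot be distinguished from the second candidate); MODERATE
#' when the runner-up is below the threshold but within
#' \code{confidenceMargin} percentage points of the top hit; HIGH otherwise.
#' Exact ties between the top and runner-up identities are additionally
#' flagged, and noted as cross-genus when the two species' genera differ.
#'
#' @param assignments data.frame from [searchReference()].
#' @param reference reference data.frame (for genus lookup on ties).
#' @param identityThreshold identity threshold (\%).
#' @param confidenceMargin MODERATE/HIGH boundary (percentage points).
#' @return the assignments with \code{confidence} and \code{tie_across_genera}
#'   columns (NA for unassigned rows).
#' @export
classifyConfidence <- function(assignments, reference,
                               identityThreshold = 99, confidenceMargin = 1) {
  conf <- rep(NA_character_, nrow(assignments))
  a <- assignments$assigned
  sec <- assignments$second_identity
  topI <- assignments$top_identity
  conf[a] <- ifelse(!is.na(sec[a]) & sec[a] >= identityThreshold, "LOW",
             ifelse(!is.na(sec[a]) & sec[a] >= topI[a] - confidenceMargin,
                    "MODERATE", "HIGH"))
  genusOf <- setNames(reference$genus, reference$species)
  tie <- a & !is.na(sec) & sec == topI
  assignments$confidence <- conf
  assignments$tie_across_genera <- tie &
    genusOf[assignments$top_species] != genusOf[assignments$second_species]
  assignments$tie_across_genera[is.na(assignments$tie_across_genera)] <- FALSE
  assignments
}

confidenceRank <- c(LOW = 1L, MODERATE = 2L, HIGH = 3L)

#' Cluster assigned sequences into species-level OTUs
#'
#' One OTU per assigned species; member read counts are summed per sample
#' and the OTU confidence is the worst member confidence
#' (LOW < MODERATE < HIGH).
#'
#' @param assignments classified assignments ([classifyConfidence()]).
#' @param uniqueSet the \code{UniqueSet} the assignments refer to.
#' @param reference reference data.frame (taxon metadata).
#' @return list (class \code{OtuSet}): \code{otus} (data.frame
#'   \code{otu_id, taxon, rank, confidence, genus, family, habitat, local,
#'   fishery, note}) and \code{counts} (long data.frame
#'   \code{otu_id, sample_id, reads}).
#' @export
clusterOtus <- function(assignments, uniqueSet, reference) {
  a <- assignments[assignments$assigned, , drop = FALSE]
  if (nrow(a) == 0) {
    return(structure(list(
      otus = data.frame(otu_id = character(), taxon = character(),
                        rank = character(), confidence = character(),
                        genus = character(), family = character(),
                        habitat = character(), local = logical(),
                        fishery = logical(), note = character()),
      counts = data.frame(otu_id = character(), sample_id = character(),
                          reads = integer())), class = "OtuSet"))
  }
  spp <- sort(unique(a$top_species))
  refRow <- reference[match(spp, reference$species), , drop = FALSE]
  conf <- vapply(spp, function(s) {
    cl <- a$confidence[a$top_species == s]
    names(confidenceRank)[min(confidenceRank[cl])]
  }, character(1))
  tie <- vapply(spp, function(s) any(a$tie_across_genera[a$top_species == s]),
                logical(1))
  otus <- data.frame(otu_id = sprintf("OTU%04d", seq_along(spp)),
                     taxon = spp, rank = "species", confidence = conf,
                     genus = refRow$genus, family = refRow$family,
                     habitat = refRow$habitat, local = refRow$local,
                     fishery = refRow$fishery,
                     tie_across_genera = tie,
                     note = "", stringsAsFactors = FALSE)
  cnt <- uniqueSet$counts[uniqueSet$counts$seq_id %in% a$seq_id, , drop = FALSE]
  cnt$otu_id <- otus$otu_id[match(a$top_species[match(cnt$seq_id, a$seq_id)],
                                  otus$taxon)]
  counts <- stats::aggregate(count ~ otu_id + sample_id, data = cnt, FUN = sum)
  names(counts)[names(counts) == "count"] <- "reads"
  counts <- counts[order(counts$otu_id, counts$sample_id),
                   c("otu_id", "sample_id", "reads")]
  rownames(counts) <- NULL
  structure(list(otus = otus, counts = counts), class = "OtuSet")
}

#' Curate OTUs against a local checklist
#'
#' Applies two rules. (1) LOW-confidence OTUs are demoted to genus rank
#' (\code{"Genus sp."}) unless the checklist lists exactly one local species
#' in that genus, in which case that species is adopted at species rank; a
#' LOW OTU whose identity tie spans genera is demoted to family rank
#' instead. (2) OTUs assigned to a species absent from the local checklist
#' are renamed through the checklist's substitution map when an entry
#' exists (a checklist species with \code{substitute_for} naming the
#' assigned species), otherwise retained with a \code{"non-local"} note.
#' OTUs that converge on the same taxon after curation are merged (counts
#' summed, worst confidence kept). The result does not depend on OTU order.
#'
#' @param otuSet an \code{OtuSet} from [clusterOtus()].
#' @param checklist checklist data.frame ([readChecklist()]).
#' @return curated \code{OtuSet}; every change is recorded in \code{note}.
#' @export
curateOtus <- function(otuSet, checklist) {
  otus <- otuSet$otus
  counts <- otuSet$counts
  if (nrow(otus) == 0) return(otuSet)
  localSpecies <- checklist$species[checklist$local]
  subsMap <- checklist[!is.na(checklist$substitute_for),
                       c("species", "substitute_for"), drop = FALSE]
  if (nrow(subsMap) && !all(subsMap$species %in% localSpecies))
    stop("substitution map points outside the local checklist")

  for (i in seq_len(nrow(otus))) {
    if (identical(otus$confidence[i], "LOW")) {
      if (isTRUE(otus$tie_across_genera[i])) {
        otus$taxon[i] <- otus$family[i]
        otus$rank[i] <- "higher"
        otus$note[i] <- "rule1: identity tie across genera, family rank"
        next
      }
      genusLocal <- localSpecies[checklist$genus[checklist$local] == otus$genus[i]]
      if (length(genusLocal) == 1L) {
        otus$note[i] <- sprintf("rule1: LOW, single local congener (%s -> %s)",
                                otus$taxon[i], genusLocal)
        otus$taxon[i] <- genusLocal
      } else {
        otus$taxon[i] <- paste(otus$genus[i], "sp.")
        otus$rank[i] <- "genus"
        otus$note[i] <- "rule1: LOW, demoted to genus"
      }
    } else if (!otus$taxon[i] %in% localSpecies) {
      j <- match(otus$taxon[i], subsMap$substitute_for)
      if (!is.na(j)) {
        otus$note[i] <- sprintf("rule2: non-local %s -> local %s",
                                otus$taxon[i], subsMap$species[j])
        otus$taxon[i] <- subsMap$species[j]
      } else {
        otus$note[i] <- "non-local"
      }
    }
  }

  # merge OTUs that converged on one taxon
  key <- otus$taxon
  if (anyDuplicated(key)) {
    counts$taxon <- otus$taxon[match(counts$otu_id, otus$otu_id)]
    merged <- lapply(split(seq_len(nrow(otus)), key), function(rows) {
      o <- otus[rows, , drop = FALSE]
      o1 <- o[1, , drop = FALSE]
      o1$confidence <- names(confidenceRank)[min(confidenceRank[o$confidence])]
      o1$note <- paste(unique(o$note[nzchar(o$note)]), collapse = "; ")
      o1
    })
    otus <- do.call(rbind, merged)
    cAgg <- stats::aggregate(reads ~ taxon + sample_id, data = counts, FUN = sum)
    otus <- otus[order(otus$taxon), , drop = FALSE]
    otus$otu_id <- sprintf("OTU%04d", seq_len(nrow(otus)))
    cAgg$otu_id <- otus$otu_id[match(cAgg$taxon, otus$taxon)]
    counts <- cAgg[order(cAgg$otu_id, cAgg$sample_id),
                   c("otu_id", "sample_id", "reads")]
    rownames(counts) <- NULL
  } else {
    ord <- order(otus$taxon)
    relabel <- setNames(sprintf("OTU%04d", order(ord)), otus$otu_id)
    otus <- otus[ord, , drop = FALSE]
    otus$otu_id <- sprintf("OTU%04d", seq_len(nrow(otus)))
    counts$otu_id <- unname(relabel[counts$otu_id])
    counts <- counts[order(counts$otu_id, counts$sample_id), , drop = FALSE]
    rownames(counts) <- NULL
  }
  rownames(otus) <- NULL
  structure(list(otus = otus, counts = counts), class = "OtuSet")
}

#' Write an OTU table as TSV
#'
#' Long format: \code{otu_id, taxon, rank, confidence, sample_id, reads}.
#'
#' @param otuSet an \code{OtuSet}.
#' @param path output path.
#' @export
writeOtuTable <- function(otuSet, path) {
  m <- match(otuSet$counts$otu_id, otuSet$otus$otu_id)
  long <- data.frame(otu_id = otuSet$counts$otu_id,
                     taxon = otuSet$otus$taxon[m],
                     rank = otuSet$otus$rank[m],
                     confidence = otuSet$otus$confidence[m],
                     sample_id = otuSet$counts$sample_id,
                     reads = otuSet$counts$reads)
  write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
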