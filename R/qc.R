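#' Trim low-quality 3' tails
#'
#' Removes bases from the 3' end, one at a time, while the terminal base's
#' Phred score is below \code{phredFloor}. A read can come back empty; it is
#' then discarded at the merge step, where it cannot satisfy the minimum
#' overlap.
#'
#' @param seqs character vector of read sequences.
#' @param quals character vector of phred+33 quality strings (same lengths).
#' @param phredFloor minimum terminal quality retained.
#' @return list with trimmed \code{seq} and \code{qual} vectors.
#' @export
trimTails <- function(seqs, quals, phredFloor = 20L) {
  stopifnot(length(seqs) == length(quals),
            all(nchar(seqs) == nchar(quals)))
  cpp_trim_tails(seqs, quals, as.integer(phredFloor))
}

#' Merge read pairs by overlap
#'
#' Reverse-complements each R2, then scans all overlap offsets of at least
#' \code{minOverlap} bases, choosing the one with the most matching bases
#' among offsets whose mismatch fraction does not exceed
#' \code{maxOverlapMismatchFrac} (ties go to the larger overlap). Overlap
#' disagreements keep the higher-quality base (tie: the R1 base); agreements
#' get the larger of the two qualities. Pairs with no admissible offset are
#' rejected, not erred.
#'
#' @param s1,q1 R1 sequences and phred+33 qualities.
#' @param s2,q2 R2 sequences and qualities (raw orientation).
#' @param config a [QcConfig-class].
#' @return list with \code{seq}, \code{qual}, logical \code{accepted} and the
#'   chosen \code{overlap} (NA when rejected).
#' @export
mergePairs <- function(s1, q1, s2, q2, config = QcConfig()) {
  stopifnot(length(s1) == length(s2))
  s2rc <- as.character(reverseComplement(DNAStringSet(s2)))
  q2r <- as.character(reverse(BStringSet(q2)))
  cpp_merge_pairs(s1, q1, s2rc, q2r, config@minOverlap,
                  config@maxOverlapMismatchFrac)
}

#' Ambiguity filter
#'
#' @param seqs character vector of merged reads.
#' @return logical; TRUE for reads free of N bases.
#' @export
filterAmbiguous <- function(seqs) {
  !grepl("N", seqs, fixed = TRUE)
}

#' Merged-length filter
#'
#' @param seqs character vector of merged reads.
#' @param config a [QcConfig-class]; bounds are inclusive.
#' @return logical keep vector.
#' @export
filterLength <- function(seqs, config = QcConfig()) {
  n <- nchar(seqs)
  n >= config@lengthMin & n <= config@lengthMax
}

#' Flag bimeric chimeras among a sample's distinct sequences
#'
#' De novo, abundance-aware bimera rule: a sequence is flagged when some
#' breakpoint at least \code{chimeraMargin} bases from both ends splits it
#' into a prefix matching one parent and a suffix matching another, each side
#' with at most \code{chimeraMaxMmPerSide} mismatches, where both parents are
#' unflagged sequences at least \code{chimeraMinFold} times as abundant,
#' differ from each other by at least \code{chimeraMinParentDiv} bases and
#' from the candidate by at least \code{chimeraMinCandidateDiv} bases.
#'
#' @param seqs distinct merged sequences of one sample.
#' @param counts their per-sample abundances.
#' @param config a [QcConfig-class].
#' @return logical; TRUE for flagged (chimeric) sequences.
#' @export
flagBimeras <- function(seqs, counts, config = QcConfig()) {
  stopifnot(length(seqs) == length(counts), !anyDuplicated(seqs))
  cpp_flag_bimeras(seqs, as.integer(counts), config@chimeraMinFold,
                   config@chimeraMaxMmPerSide, config@chimeraMargin,
                   config@chimeraMinParentDiv, config@chimeraMinCandidateDiv)
}

#' Locate and strip primers from merged reads
#'
#' Matches every forward-primer variant against the 5' end and the reverse
#' complement of every reverse-primer variant against the 3' end, each
#' tolerating at most \code{maxPrimerMismatches} mismatches. Reads missing a
#' match at either terminus are rejected. Matched primers are stripped and
#' the best-matching forward variant reported.
#'
#' @param seqs character vector of merged reads.
#' @param primers primer set as from [mifishPrimerSet()]: list with named
#'   \code{forward} and \code{reverse} character vectors.
#' @param config a [QcConfig-class].
#' @return list with \code{insert} (NA when rejected), \code{variant} and
#'   logical \code{accepted}.
#' @export
stripPrimers <- function(seqs, primers = mifishPrimerSet(),
                         config = QcConfig()) {
  fwd <- primers$forward
  revRc <- vapply(as.list(primers$reverse), revComp, character(1))
  mmF <- cpp_anchored_mismatches(seqs, fwd, TRUE)
  mmR <- cpp_anchored_mismatches(seqs, revRc, FALSE)
  mmF[is.na(mmF)] <- .Machine$integer.max
  mmR[is.na(mmR)] <- .Machine$integer.max
  bf <- max.col(-mmF, ties.method = "first")
  br <- max.col(-mmR, ties.method = "first")
  idx <- seq_along(seqs)
  okF <- mmF[cbind(idx, bf)] <= config@maxPrimerMismatches
  okR <- mmR[cbind(idx, br)] <= config@maxPrimerMismatches
  accepted <- okF & okR
  insert <- rep(NA_character_, length(seqs))
  nf <- nchar(fwd)[bf]
  nr <- nchar(revRc)[br]
  insert[accepted] <- substr(seqs[accepted], nf[accepted] + 1L,
                             nchar(seqs[accepted]) - nr[accepted])
  variant <- ifelse(accepted, names(fwd)[bf], NA_character_)
  list(insert = insert, variant = variant, accepted = accepted)
}

#' Run the full QC stage over all samples
#'
#' Per sample: 3' tail trimming, pair merging, ambiguity filter, merged
#' length filter, per-sample bimera removal, primer location/stripping; in
#' that order. Stage read tallies are recorded so that counts are exactly
#' conserved: pairs in = merged + merge-rejected, and each later stage's
#' input equals the previous stage's output.
#'
#' @param sampleSheet sample-sheet data.frame ([readSampleSheet()]).
#' @param fastqDir directory holding \code{<sample_id>_R1.fastq} /
#'   \code{_R2.fastq}.
#' @param config a [QcConfig-class].
#' @param primers primer set as from [mifishPrimerSet()].
#' @param outDir optional; when given, surviving inserts are written as one
#'   FASTA per sample plus a \code{qc_report.tsv} stage-count table.
#' @return list with \code{inserts} (named list of per-sample insert
#'   character vectors) and \code{tallies} (data.frame
#'   \code{sample_id, stage, reads_in, reads_out}).
#' @export
runQc <- function(sampleSheet, fastqDir, config = QcConfig(),
                  primers = mifishPrimerSet(), outDir = NULL) {
  inserts <- list()
  tallies <- list()
  for (sid in sampleSheet$sample_id) {
    f1 <- file.path(fastqDir, paste0(sid, "_R1.fastq"))
    f2 <- file.path(fastqDir, paste0(sid, "_R2.fastq"))
    if (!file.exists(f1) || !file.exists(f2))
      stop("missing FASTQ for sample ", sid)
    x1 <- readDNAStringSet(f1, format = "fastq", with.qualities = TRUE)
    x2 <- readDNAStringSet(f2, format = "fastq", with.qualities = TRUE)
    if (length(x1) != length(x2))
      stop("R1/R2 read counts differ for sample ", sid)
    nIn <- length(x1)
    stage <- function(name, n_in, n_out)
      data.frame(sample_id = sid, stage = name, reads_in = n_in,
                 reads_out = n_out, stringsAsFactors = FALSE)

    t1 <- cpp_trim_tails(as.character(x1),
                         as.character(S4Vectors::mcols(x1)$qualities),
                         config@phredFloor)
    t2 <- cpp_trim_tails(as.character(x2),
                         as.character(S4Vectors::mcols(x2)$qualities),
                         config@phredFloor)
    rows <- list(stage("trim", nIn, nIn))

    if (nIn > 0) {
      s2rc <- as.character(reverseComplement(DNAStringSet(t2$seq)))
      q2r <- as.character(reverse(BStringSet(t2$qual)))
      m <- cpp_merge_pairs(t1$seq, t1$qual, s2rc, q2r, config@minOverlap,
                           config@maxOverlapMismatchFrac)
      merged <- m$seq[m$accepted]
    } else merged <- character(0)
    rows <- c(rows, list(stage("merge", nIn, length(merged))))

    keep <- filterAmbiguous(merged)
    noN <- merged[keep]
    rows <- c(rows, list(stage("ambiguous", length(merged), length(noN))))

    keep <- filterLength(noN, config)
    inLen <- noN[keep]
    rows <- c(rows, list(stage("length", length(noN), length(inLen))))

    if (length(inLen)) {
      tab <- table(inLen)
      flags <- flagBimeras(names(tab), as.integer(tab), config)
      bad <- names(tab)[flags]
      noChim <- inLen[!inLen %in% bad]
    } else noChim <- character(0)
    rows <- c(rows, list(stage("chimera", length(inLen), length(noChim))))

    if (length(noChim)) {
      sp <- stripPrimers(noChim, primers, config)
      ins <- sp$insert[sp$accepted]
    } else ins <- character(0)
    rows <- c(rows, list(stage("primer", length(noChim), length(ins))))

    inserts[[sid]] <- ins
    tallies[[sid]] <- do.call(rbind, rows)
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      x <- DNAStringSet(ins)
      if (length(x)) names(x) <- sprintf("%s_insert%05d", sid, seq_along(x))
      writeXStringSet(x, file.path(outDir, paste0(sid, "_inserts.fasta")))
    }
  }
  tallies <- do.call(rbind, c(tallies, list(make.row.names = FALSE)))
  if (!is.null(outDir))
    write.table(tallies, file.path(outDir, "qc_report.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  list(inserts = inserts, tallies = tallies)
}
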