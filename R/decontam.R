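#' Remove sequences that occur in negative controls
#'
#' Any unique sequence with at least one read in any negative control is
#' removed from every sample (the blank read indexes contamination that may
#' have touched all samples). The removal is tallied.
#'
#' @param uniqueSet a \code{UniqueSet} from [dereplicate()].
#' @param negativeSampleIds sample_ids of the negative controls.
#' @return the filtered \code{UniqueSet}, with a \code{removed} element
#'   (\code{nSequences}, \code{nReads}, \code{seq_ids}).
#' @export
removeNegativeSequences <- function(uniqueSet, negativeSampleIds) {
  cnt <- uniqueSet$counts
  bad <- unique(cnt$seq_id[cnt$sample_id %in% negativeSampleIds & cnt$count > 0])
  keepU <- !uniqueSet$uniques$seq_id %in% bad
  keepC <- !cnt$seq_id %in% bad
  out <- uniqueSet
  out$removed <- list(nSequences = length(bad),
                      nReads = sum(uniqueSet$uniques$total[!keepU]),
                      seq_ids = bad)
  out$uniques <- uniqueSet$uniques[keepU, , drop = FALSE]
  out$counts <- cnt[keepC, , drop = FALSE]
  rownames(out$uniques) <- rownames(out$counts) <- NULL
  out
}

#' Derive the per-sample read-fraction cut-off from negative controls
#'
#' Projects the blank contamination background onto the whole run:
#' \code{C = floor(R_neg / N_neg * N_tot)} possible contaminant reads, and
#' \code{p = round(C / R_tot, 3)} as the per-sample cut-off fraction (a
#' fraction of each sample's total reads below which an OTU is considered
#' absent from that sample).
#'
#' @param readsInNegatives total clustered reads in the negative controls.
#' @param nNegatives number of negative controls (must be > 0).
#' @param nTotalSamples total PCR samples, field samples plus blanks.
#' @param totalClusteredReads total clustered (non-singleton) reads.
#' @return a [CutoffDerivation-class].
#' @examples
#' deriveCutoff(3778, 30, 312, 2557862)  # C = 39291, p = 1.5%
#' @export
deriveCutoff <- function(readsInNegatives, nNegatives, nTotalSamples,
                         totalClusteredReads) {
  if (nNegatives <= 0)
    stop("cannot derive a cut-off without negative controls; ",
         "supply a fixed cut-off instead")
  if (totalClusteredReads <= 0) stop("totalClusteredReads must be positive")
  C <- floor(readsInNegatives / nNegatives * nTotalSamples)
  p <- round(C / totalClusteredReads, 3)
  new("CutoffDerivation", readsInNegatives = as.numeric(readsInNegatives),
      nNegatives = as.numeric(nNegatives),
      nTotalSamples = as.numeric(nTotalSamples),
      totalClusteredReads = as.numeric(totalClusteredReads),
      projectedContaminantReads = C, cutoffFraction = p)
}

#' Apply the read-fraction cut-off and build the detection matrix
#'
#' Per sample, an OTU is detected iff its reads amount to at least fraction
#' \code{p} of the sample's total OTU reads (an OTU with less than that is
#' considered absent, so a count exactly on the boundary is present) and the
#' count is positive. Sample totals are computed over the supplied
#' (post-negative-removal) OTU counts. Sub-threshold counts are zeroed only
#' in the incidence layer; the raw counts remain in the \code{counts} assay
#' for audit.
#'
#' @param otuSet curated \code{OtuSet} ([curateOtus()]).
#' @param cutoff either a [CutoffDerivation-class] or a plain fraction in
#'   [0, 1].
#' @param sampleSheet sample-sheet data.frame; negative controls are excluded
#'   from the matrix columns.
#' @return a [DetectionMatrix-class] (taxa x field PCR samples).
#' @export
applyCutoff <- function(otuSet, cutoff, sampleSheet) {
  p <- if (is(cutoff, "CutoffDerivation")) cutoff@cutoffFraction else cutoff
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  sheet <- sampleSheet[!sampleSheet$is_negative, , drop = FALSE]
  otus <- otuSet$otus
  cnt <- matrix(0L, nrow = nrow(otus), ncol = nrow(sheet),
                dimnames = list(otus$otu_id, sheet$sample_id))
  cc <- otuSet$counts[otuSet$counts$sample_id %in% sheet$sample_id, , drop = FALSE]
  cnt[cbind(match(cc$otu_id, otus$otu_id),
            match(cc$sample_id, sheet$sample_id))] <- cc$reads
  totals <- colSums(cnt)
  if (any(totals == 0) && nrow(otus) > 0)
    warning(sum(totals == 0), " sample(s) with zero OTU reads; ",
            "all taxa absent there")
  det <- sweep(cnt, 2, p * totals, ">=") & cnt > 0
  rd <- DataFrame(otus[, setdiff(names(otus), "otu_id"), drop = FALSE],
                  row.names = otus$otu_id)
  cd <- DataFrame(sheet, row.names = sheet$sample_id)
  se <- SummarizedExperiment(assays = list(counts = cnt, detected = det),
                             rowData = rd, colData = cd)
  new("DetectionMatrix", se, cutoff = p)
}
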