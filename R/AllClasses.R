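#' Simulation configuration for a synthetic eDNA metabarcoding survey
#'
#' Holds every knob of the synthetic-data generator. The defaults emulate a
#' bay-wide survey: 47 stations sampled at surface and bottom with three PCR
#' replicates each (282 PCR samples) plus 30 negative controls, ~170 bp
#' 12S inserts flanked by two fish-universal primer-pair variants, declining
#' 3' base quality, substitution sequencing errors, bimeric chimeras and
#' low-level cross-contamination.
#'
#' @slot seed integer RNG seed; every stochastic step derives from it.
#' @slot nSpecies number of reference species (including one designated
#'   blank-contaminant species and one non-local species kept out of the
#'   simulated communities).
#' @slot nStations,nLayers,nReplicates,nNegativeControls survey design.
#' @slot readsPerSample read pairs generated per field PCR sample.
#' @slot readLength length of each mate in bp.
#' @slot insertLengthMean,insertLengthSd insert length distribution (bp);
#'   truncated to \code{insertWindow} so insert + both primers stays inside
#'   the downstream merged-length filter.
#' @slot insertWindow allowed insert length range (bp).
#' @slot substitutionErrorRate per-base substitution probability per read.
#' @slot chimeraRate fraction of sample reads emitted as two-parent bimeras.
#' @slot contaminantRate blank read depth as a fraction of
#'   \code{readsPerSample}; each negative control receives
#'   \code{round(contaminantRate * readsPerSample)} contaminant reads.
#' @slot crossContaminationRate fraction of field-sample reads replaced by
#'   the contaminant species.
#' @slot rangeScale Gaussian occupancy-kernel width of species ranges (m).
#' @slot bayExtent numeric length-2, bay width and height (m).
#' @slot congenericPairDivergence sequence divergence of the designated
#'   congeneric species pair (fraction; default 0.005 so the pair cannot be
#'   separated at a 99\% identity threshold).
#' @slot logseriesTheta parameter of the log-series rank-abundance model.
#' @slot freshwaterFraction fraction of community species flagged freshwater.
#' @slot primerMixture fraction of reads carrying the U primer variant.
#' @slot presenceThreshold expected relative abundance above which a species
#'   belongs to a station/layer ground-truth set.
#' @export
setClass("SimulationConfig", representation(
  seed = "integer", nSpecies = "integer", nStations = "integer",
  nLayers = "integer", nReplicates = "integer", nNegativeControls = "integer",
  readsPerSample = "integer", readLength = "integer",
  insertLengthMean = "numeric", insertLengthSd = "numeric",
  insertWindow = "numeric", substitutionErrorRate = "numeric",
  chimeraRate = "numeric", contaminantRate = "numeric",
  crossContaminationRate = "numeric", rangeScale = "numeric",
  bayExtent = "numeric", congenericPairDivergence = "numeric",
  logseriesTheta = "numeric", freshwaterFraction = "numeric",
  primerMixture = "numeric", presenceThreshold = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  rates <- c(substitutionErrorRate = object@substitutionErrorRate,
             chimeraRate = object@chimeraRate,
             contaminantRate = object@contaminantRate,
             crossContaminationRate = object@crossContaminationRate,
             congenericPairDivergence = object@congenericPairDivergence,
             primerMixture = object@primerMixture,
             freshwaterFraction = object@freshwaterFraction)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    msg <- c(msg, paste("rates outside [0,1]:", paste(names(rates)[bad], collapse = ", ")))
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@nSpecies < 2L) msg <- c(msg, "nSpecies must be >= 2")
  if (length(object@insertWindow) != 2L || object@insertWindow[1] > object@insertWindow[2])
    msg <- c(msg, "insertWindow must be an increasing length-2 range")
  if (length(object@bayExtent) != 2L || any(object@bayExtent <= 0))
    msg <- c(msg, "bayExtent must be two positive lengths")
  if (object@rangeScale <= 0) msg <- c(msg, "rangeScale must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig Constructor with survey-design defaults.
#' @param seed,nSpecies,nStations,nLayers,nReplicates,nNegativeControls,
#'   readsPerSample,readLength,insertLengthMean,insertLengthSd,insertWindow,
#'   substitutionErrorRate,chimeraRate,contaminantRate,crossContaminationRate,
#'   rangeScale,bayExtent,congenericPairDivergence,logseriesTheta,
#'   freshwaterFraction,primerMixture,presenceThreshold see slots.
#' @export
SimulationConfig <- function(seed = 1L, nSpecies = 50L, nStations = 47L,
    nLayers = 2L, nReplicates = 3L, nNegativeControls = 30L,
    readsPerSample = 1000L, readLength = 170L,
    insertLengthMean = 170, insertLengthSd = 8, insertWindow = c(145, 195),
    substitutionErrorRate = 0.003, chimeraRate = 0.03,
    contaminantRate = 0.005, crossContaminationRate = 0.001,
    rangeScale = 800, bayExtent = c(4000, 3000),
    congenericPairDivergence = 0.005, logseriesTheta = 0.95,
    freshwaterFraction = 0.15, primerMixture = 0.5,
    presenceThreshold = 1e-3) {
  new("SimulationConfig", seed = as.integer(seed),
      nSpecies = as.integer(nSpecies), nStations = as.integer(nStations),
      nLayers = as.integer(nLayers), nReplicates = as.integer(nReplicates),
      nNegativeControls = as.integer(nNegativeControls),
      readsPerSample = as.integer(readsPerSample),
      readLength = as.integer(readLength),
      insertLengthMean = insertLengthMean, insertLengthSd = insertLengthSd,
      insertWindow = insertWindow,
      substitutionErrorRate = substitutionErrorRate, chimeraRate = chimeraRate,
      contaminantRate = contaminantRate,
      crossContaminationRate = crossContaminationRate,
      rangeScale = rangeScale, bayExtent = bayExtent,
      congenericPairDivergence = congenericPairDivergence,
      logseriesTheta = logseriesTheta, freshwaterFraction = freshwaterFraction,
      primerMixture = primerMixture, presenceThreshold = presenceThreshold)
}

#' Quality-control configuration
#'
#' Thresholds of the read QC stage. Defaults follow common MiSeq amplicon
#' practice for ~300 bp fish 12S amplicons: 3' bases trimmed until the last
#' base reaches Phred 20, pairs merged when they overlap by more than 9 bp,
#' merged reads kept when 272--322 bp long, primers matched with at most 3
#' mismatches.
#'
#' @slot phredFloor minimum terminal base quality retained by tail trimming.
#' @slot minOverlap smallest admissible pair overlap in bp (10 means ">9 bp").
#' @slot maxOverlapMismatchFrac largest tolerated mismatch fraction inside
#'   the chosen overlap.
#' @slot lengthMin,lengthMax inclusive merged-length window (bp).
#' @slot maxPrimerMismatches largest primer mismatch count accepted per
#'   terminus (3 means "fewer than 4").
#' @slot chimeraMinFold parent/candidate abundance ratio required of bimera
#'   parents.
#' @slot chimeraMaxMmPerSide mismatches tolerated on each side of a bimera
#'   breakpoint.
#' @slot chimeraMargin minimum breakpoint distance from either end (bp). The
#'   default exceeds both primer lengths so that admissible breakpoints lie
#'   within the insert: a bimera whose breakpoint falls inside the shared
#'   primer region is indistinguishable from a pure parent amplicon, and
#'   allowing such breakpoints lets primer-variant structure masquerade as
#'   chimeric.
#' @slot chimeraMinParentDiv minimum divergence between the two parents (bases).
#' @slot chimeraMinCandidateDiv minimum divergence between candidate and each
#'   parent (bases); guards against flagging 1-substitution error variants of
#'   an abundant template, which otherwise always decompose into (parent,
#'   anything) because amplicons share identical primer termini.
#' @export
setClass("QcConfig", representation(
  phredFloor = "integer", minOverlap = "integer",
  maxOverlapMismatchFrac = "numeric", lengthMin = "integer",
  lengthMax = "integer", maxPrimerMismatches = "integer",
  chimeraMinFold = "numeric", chimeraMaxMmPerSide = "integer",
  chimeraMargin = "integer", chimeraMinParentDiv = "integer",
  chimeraMinCandidateDiv = "integer"))

setValidity("QcConfig", function(object) {
  msg <- character()
  if (object@lengthMin > object@lengthMax) msg <- c(msg, "lengthMin > lengthMax")
  if (object@minOverlap < 1L) msg <- c(msg, "minOverlap must be >= 1")
  if (object@maxOverlapMismatchFrac < 0 || object@maxOverlapMismatchFrac > 1)
    msg <- c(msg, "maxOverlapMismatchFrac outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn QcConfig Constructor.
#' @param phredFloor,minOverlap,maxOverlapMismatchFrac,lengthMin,lengthMax,
#'   maxPrimerMismatches,chimeraMinFold,chimeraMaxMmPerSide,chimeraMargin,
#'   chimeraMinParentDiv,chimeraMinCandidateDiv see slots.
#' @export
QcConfig <- function(phredFloor = 20L, minOverlap = 10L,
    maxOverlapMismatchFrac = 0.25, lengthMin = 272L, lengthMax = 322L,
    maxPrimerMismatches = 3L, chimeraMinFold = 2, chimeraMaxMmPerSide = 1L,
    chimeraMargin = 75L, chimeraMinParentDiv = 3L,
    chimeraMinCandidateDiv = 2L) {
  new("QcConfig", phredFloor = as.integer(phredFloor),
      minOverlap = as.integer(minOverlap),
      maxOverlapMismatchFrac = maxOverlapMismatchFrac,
      lengthMin = as.integer(lengthMin), lengthMax = as.integer(lengthMax),
      maxPrimerMismatches = as.integer(maxPrimerMismatches),
      chimeraMinFold = chimeraMinFold,
      chimeraMaxMmPerSide = as.integer(chimeraMaxMmPerSide),
      chimeraMargin = as.integer(chimeraMargin),
      chimeraMinParentDiv = as.integer(chimeraMinParentDiv),
      chimeraMinCandidateDiv = as.integer(chimeraMinCandidateDiv))
}

#' Pipeline configuration
#'
#' Bundles the QC thresholds with taxonomy, decontamination and statistics
#' options for [runPipeline()].
#'
#' @slot qc a [QcConfig-class].
#' @slot identityThreshold minimum top-hit identity (\%) for assignment.
#' @slot minAlignedLength minimum aligned length (bp) for assignment; stands
#'   in for a BLAST E-value bound, which cannot bind for ~170 bp amplicons at
#'   99\% identity.
#' @slot minUniqueCount dereplicated sequences below this total read count are
#'   discarded (2 discards singletons).
#' @slot confidenceMargin MODERATE/HIGH boundary: MODERATE when the runner-up
#'   identity is within this many percentage points of the top hit.
#' @slot cutoffMode "derive" (from negative controls) or "fixed".
#' @slot fixedCutoff per-sample read-fraction cut-off used when
#'   \code{cutoffMode == "fixed"}.
#' @slot nPermutations Mantel correlogram permutations.
#' @slot nDistanceClasses number of correlogram distance classes (NA = Sturges).
#' @slot chao1Corrected use the bias-corrected Chao1 form.
#' @slot seed RNG seed for the statistics stage.
#' @export
setClass("PipelineConfig", representation(
  qc = "QcConfig", identityThreshold = "numeric", minAlignedLength = "integer",
  minUniqueCount = "integer", confidenceMargin = "numeric",
  cutoffMode = "character", fixedCutoff = "numeric",
  nPermutations = "integer", nDistanceClasses = "integer",
  chao1Corrected = "logical", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!object@cutoffMode %in% c("derive", "fixed"))
    msg <- c(msg, "cutoffMode must be 'derive' or 'fixed'")
  if (object@identityThreshold < 0 || object@identityThreshold > 100)
    msg <- c(msg, "identityThreshold outside [0,100]")
  if (object@fixedCutoff < 0 || object@fixedCutoff > 1)
    msg <- c(msg, "fixedCutoff outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn PipelineConfig Constructor.
#' @param qc,identityThreshold,minAlignedLength,minUniqueCount,
#'   confidenceMargin,cutoffMode,fixedCutoff,nPermutations,nDistanceClasses,
#'   chao1Corrected,seed see slots.
#' @export
PipelineConfig <- function(qc = QcConfig(), identityThreshold = 99,
    minAlignedLength = 100L, minUniqueCount = 2L, confidenceMargin = 1,
    cutoffMode = "derive", fixedCutoff = 0, nPermutations = 999L,
    nDistanceClasses = NA_integer_, chao1Corrected = TRUE, seed = 1L) {
  new("PipelineConfig", qc = qc, identityThreshold = identityThreshold,
      minAlignedLength = as.integer(minAlignedLength),
      minUniqueCount = as.integer(minUniqueCount),
      confidenceMargin = confidenceMargin, cutoffMode = cutoffMode,
      fixedCutoff = fixedCutoff, nPermutations = as.integer(nPermutations),
      nDistanceClasses = as.integer(nDistanceClasses),
      chao1Corrected = chao1Corrected, seed = as.integer(seed))
}

#' Negative-control read cut-off derivation
#'
#' Projects the contamination background measured in the negative controls
#' onto the whole run and expresses it as a per-sample read fraction:
#' \code{C = floor(R_neg / N_neg * N_tot)} possible contaminant reads, and
#' \code{p = round(C / R_tot, 3)} as the per-sample cut-off fraction.
#'
#' @slot readsInNegatives total clustered reads observed in negative controls.
#' @slot nNegatives number of negative controls.
#' @slot nTotalSamples total PCR samples (field samples + negative controls).
#' @slot totalClusteredReads total clustered (non-singleton) reads in the run.
#' @slot projectedContaminantReads the projected count \code{C}.
#' @slot cutoffFraction the per-sample fraction \code{p}.
#' @export
setClass("CutoffDerivation", representation(
  readsInNegatives = "numeric", nNegatives = "numeric",
  nTotalSamples = "numeric", totalClusteredReads = "numeric",
  projectedContaminantReads = "numeric", cutoffFraction = "numeric"))

setValidity("CutoffDerivation", function(object) {
  C <- floor(object@readsInNegatives / object@nNegatives * object@nTotalSamples)
  p <- round(C / object@totalClusteredReads, 3)
  if (!isTRUE(all.equal(C, object@projectedContaminantReads)))
    return("projectedContaminantReads does not satisfy C = floor(R_neg/N_neg * N_tot)")
  if (!isTRUE(all.equal(p, object@cutoffFraction)))
    return("cutoffFraction does not satisfy p = round(C/R_tot, 3)")
  TRUE
})

#' Detection matrix of an eDNA metabarcoding run
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with taxa as rows and
#' PCR samples as columns, two assays (\code{counts}: raw post-curation read
#' counts, audit layer; \code{detected}: incidence after the read-fraction
#' cut-off), per-taxon metadata in \code{rowData} (taxon, rank, confidence,
#' habitat and flags) and the sample sheet in \code{colData}.
#'
#' @slot cutoff the per-sample read-fraction cut-off that produced the
#'   \code{detected} assay.
#' @export
setClass("DetectionMatrix", contains = "SummarizedExperiment",
         representation(cutoff = "numeric"))

setValidity("DetectionMatrix", function(object) {
  msg <- character()
  a <- assays(object)
  if (!all(c("counts", "detected") %in% names(a)))
    msg <- c(msg, "assays must contain 'counts' and 'detected'")
  else {
    cnt <- a$counts; det <- a$detected
    if (any(det & cnt <= 0)) msg <- c(msg, "detected cells must have reads > 0")
    if (any(cnt < 0)) msg <- c(msg, "negative read counts")
  }
  need <- c("sample_id", "station_id", "layer", "replicate")
  if (!all(need %in% colnames(colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Mantel correlogram result
#'
#' One row per distance class: class bounds and midpoint (m), member pair
#' count, Mantel statistic (positive = positive spatial autocorrelation,
#' i.e. communities within the class are more similar than average),
#' one-tailed permutation p value in the direction of the statistic's sign,
#' progressively Holm-corrected p, and a significance flag at alpha = 0.05.
#'
#' @slot table per-class data.frame.
#' @slot nPermutations permutations used (0 = none, p values NA).
#' @slot exact TRUE when p values come from full enumeration of all station
#'   permutations.
#' @export
setClass("CorrelogramResult", representation(
  table = "data.frame", nPermutations = "integer", exact = "logical"))

setValidity("CorrelogramResult", function(object) {
  need <- c("class", "d_lower", "d_upper", "midpoint", "n_pairs", "mantel_r",
            "p_value", "p_corrected", "significant")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  TRUE
})
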