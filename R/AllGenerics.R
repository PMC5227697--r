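#' @name accessors
#' @title Accessors for pipeline result classes
#' @param object,x a result object
#' @param ... ignored
NULL

#' @rdname accessors
#' @export
setGeneric("readCounts", function(x, ...) standardGeneric("readCounts"))

#' @rdname accessors
#' @export
setGeneric("detections", function(x, ...) standardGeneric("detections"))

#' @rdname accessors
#' @export
setGeneric("cutoffFraction", function(x, ...) standardGeneric("cutoffFraction"))

#' @rdname accessors
#' @export
setGeneric("projectedContaminantReads",
           function(x, ...) standardGeneric("projectedContaminantReads"))

#' @rdname accessors
#' @export
setGeneric("correlogramTable", function(x, ...) standardGeneric("correlogramTable"))

#' @describeIn DetectionMatrix raw read-count assay (taxa x samples).
#' @param x,... see generic.
#' @export
setMethod("readCounts", "DetectionMatrix", function(x, ...)
  assays(x)$counts)

#' @describeIn DetectionMatrix logical incidence assay after the cut-off.
#' @export
setMethod("detections", "DetectionMatrix", function(x, ...)
  assays(x)$detected)

#' @describeIn DetectionMatrix the per-sample read-fraction cut-off applied.
#' @export
setMethod("cutoffFraction", "DetectionMatrix", function(x, ...) x@cutoff)

#' @describeIn CutoffDerivation projected contaminant read count C.
#' @export
setMethod("projectedContaminantReads", "CutoffDerivation", function(x, ...)
  x@projectedContaminantReads)

#' @describeIn CutoffDerivation the per-sample cut-off fraction p.
#' @export
setMethod("cutoffFraction", "CutoffDerivation", function(x, ...)
  x@cutoffFraction)

#' @describeIn CorrelogramResult the per-distance-class table.
#' @export
setMethod("correlogramTable", "CorrelogramResult", function(x, ...) x@table)

setMethod("show", "CutoffDerivation", function(object) {
  cat("Negative-control cut-off derivation\n")
  cat(sprintf("  %s reads in %d negative controls; %d PCR samples in total\n",
              format(object@readsInNegatives, big.mark = ","),
              object@nNegatives, object@nTotalSamples))
  cat(sprintf("  projected contaminant reads C = %s\n",
              format(object@projectedContaminantReads, big.mark = ",")))
  cat(sprintf("  per-sample cut-off p = %.1f%% of %s clustered reads\n",
              100 * object@cutoffFraction,
              format(object@totalClusteredReads, big.mark = ",")))
})

setMethod("show", "DetectionMatrix", function(object) {
  callNextMethod()
  cat(sprintf("cutoff: %.3f%% of sample-total reads; %d detections\n",
              100 * object@cutoff, sum(assays(object)$detected)))
})

setMethod("show", "CorrelogramResult", function(object) {
  cat(sprintf("Mantel correlogram (%s)\n",
              if (object@exact) "exact permutation distribution"
              else sprintf("%d permutations", object@nPermutations)))
  print(object@table, row.names = FALSE, digits = 4)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d species, %d stations x %d layers",
                     " x %d replicates + %d blanks, %d pairs/sample\n"),
              object@nSpecies, object@nStations, object@nLayers,
              object@nReplicates, object@nNegativeControls,
              object@readsPerSample))
  cat(sprintf("  error %.4f/bp, chimera %.3f, blank depth %.3f, seed %d\n",
              object@substitutionErrorRate, object@chimeraRate,
              object@contaminantRate, object@seed))
})
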