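#' @name accessors
#' @title Accessors for acpfa data objects
#' @description Small accessor generics so downstream code never reaches into
#'   slots directly.
#' @param object An acpfa S4 object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("spacingMm", function(object) standardGeneric("spacingMm"))
#' @rdname accessors
#' @export
setMethod("spacingMm", "ScenarioGrid", function(object) object@spacingMm)

#' @rdname accessors
#' @export
setGeneric("voxelLabels", function(object) standardGeneric("voxelLabels"))
#' @rdname accessors
#' @export
setMethod("voxelLabels", "ScenarioGrid", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("voxelLabels", "SegmentationVolume", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("electrodeGroups", function(object) standardGeneric("electrodeGroups"))
#' @rdname accessors
#' @export
setMethod("electrodeGroups", "ScenarioGrid", function(object)
  list(groups = object@groups, polarity = object@groupPolarity))

#' @rdname accessors
#' @export
setGeneric("gridMaterials", function(object) standardGeneric("gridMaterials"))
#' @rdname accessors
#' @export
setMethod("gridMaterials", "ScenarioGrid", function(object) object@materials)

#' @rdname accessors
#' @export
setGeneric("potentialV", function(object) standardGeneric("potentialV"))
#' @rdname accessors
#' @export
setMethod("potentialV", "FieldSolution", function(object) object@potential)

#' @rdname accessors
#' @export
setGeneric("fieldVcm", function(object) standardGeneric("fieldVcm"))
#' @rdname accessors
#' @export
setMethod("fieldVcm", "FieldSolution", function(object) object@eMag)

#' @rdname accessors
#' @export
setGeneric("currentDensityKAm2", function(object) standardGeneric("currentDensityKAm2"))
#' @rdname accessors
#' @export
setMethod("currentDensityKAm2", "FieldSolution", function(object) object@jMag)

#' @rdname accessors
#' @export
setGeneric("probeSeries", function(object) standardGeneric("probeSeries"))
#' @rdname accessors
#' @export
setMethod("probeSeries", "ThermalTrace", function(object)
  data.frame(time_s = object@timeS, object@probesC, check.names = FALSE))

#' @rdname accessors
#' @export
setGeneric("peakMapC", function(object) standardGeneric("peakMapC"))
#' @rdname accessors
#' @export
setMethod("peakMapC", "ThermalTrace", function(object) object@peakMapC)

#' @rdname accessors
#' @export
setGeneric("finalMapC", function(object) standardGeneric("finalMapC"))
#' @rdname accessors
#' @export
setMethod("finalMapC", "ThermalTrace", function(object) object@finalC)

#' @rdname accessors
#' @export
setGeneric("burstTimes", function(object) standardGeneric("burstTimes"))
#' @rdname accessors
#' @export
setMethod("burstTimes", "GatingSchedule", function(object) object@burstTimesS)

setMethod("show", "BurstSpec", function(object) {
  ncyc <- object@durationUs * object@internalFreqKhz / 1000
  cat(sprintf(
    "BurstSpec: %g V, %g us @ %g kHz (%d oscillations), duty %.2f, %d bursts\n",
    object@amplitudeVolts, object@durationUs, object@internalFreqKhz,
    as.integer(round(ncyc)), object@duty, object@nBursts))
})

setMethod("show", "GatingSchedule", function(object) {
  cat(sprintf(
    "GatingSchedule: %d bursts, delay %g ms, mean inter-burst %.3f s\n",
    length(object@burstTimesS), object@delayMs, object@meanInterburstS))
})

setMethod("show", "ScenarioGrid", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels, levels = .LBL, labels = names(.LBL)))
  cat(sprintf("ScenarioGrid '%s': %d x %d x %d voxels @ %g mm\n",
              object@kind, d[1], d[2], d[3], object@spacingMm))
  cat("  voxels:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  cat(sprintf("  electrode groups: %d (%s)\n", length(object@groupPolarity),
              paste(substr(object@groupPolarity, 1, 1), collapse = "")))
  if (length(object@materials))
    cat("  materials: attached\n")
})

setMethod("show", "FieldSolution", function(object) {
  cat(sprintf(
    "FieldSolution: %g V applied, I = %.3f A, residual %.2e, balance %.2e\n",
    object@appliedVolts, object@totalCurrentA, object@residual,
    object@currentBalance))
})

setMethod("show", "ThermalTrace", function(object) {
  cat(sprintf(
    "ThermalTrace: %d steps over %.4g s, baseline %g C, domain peak %.2f C\n",
    length(object@timeS), max(object@timeS), object@baselineC,
    max(object@probesC[, "domain_max"])))
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit: A = %.3f C, tau = %.3f ms, baseline = %.2f C, R2 = %.4f\n",
              object@amplitudeC, object@tauMs, object@baselineC, object@r2))
})

setMethod("show", "SegmentationVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf(
    "SegmentationVolume: %d x %d x %d @ %g mm (slices %g mm), %d specimen voxels\n",
    d[1], d[2], d[3], object@voxelMm, object@sliceMm,
    sum(object@labels > 0L)))
})
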