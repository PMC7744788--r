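#' @import methods
#' @importFrom stats coef complete.cases kruskal.test lm median nls.control
#'   pnorm pt qnorm residuals rnorm runif sd setNames t.test var
NULL

## Integer label codes shared by all voxelized scenario grids.
.LBL <- c(
  blood             = 1L,
  myocardium        = 2L,
  electrode_line    = 3L,
  electrode_neutral = 4L,
  insulator         = 5L
)

#' Voxel label codes used in scenario grids
#'
#' Scenario grids store tissue/electrode categories as integers. This helper
#' returns the named code table so external tools (and NIfTI round trips) can
#' interpret the label volume.
#'
#' @return Named integer vector mapping category names to label codes.
#' @export
#' @examples
#' scenarioLabelCodes()
scenarioLabelCodes <- function() .LBL

#' AC burst waveform parameters
#'
#' Describes one charge-balanced AC burst: a square bipolar oscillation at
#' \code{internalFreqKhz} sustained for \code{durationUs}, delivered at
#' \code{amplitudeVolts}. \code{duty} is the on-time fraction of each
#' half-cycle, so the time-averaged squared voltage (the Joule duty factor)
#' equals \code{duty}. The default 100 us at 100 kHz gives ten full bipolar
#' oscillations per burst.
#'
#' @slot amplitudeVolts Applied voltage (V), positive.
#' @slot durationUs Burst duration (microseconds).
#' @slot internalFreqKhz Internal oscillation frequency (kHz).
#' @slot duty On-time fraction per half-cycle, in (0, 1].
#' @slot nBursts Number of bursts in the train (60 atrial, 120 septal).
#' @slot generatorMaxVolts Configured generator voltage ceiling (V).
#' @export
setClass("BurstSpec",
  representation(
    amplitudeVolts    = "numeric",
    durationUs        = "numeric",
    internalFreqKhz   = "numeric",
    duty              = "numeric",
    nBursts           = "integer",
    generatorMaxVolts = "numeric"
  )
)

setValidity("BurstSpec", function(object) {
  msg <- character()
  if (length(object@amplitudeVolts) != 1L || !is.finite(object@amplitudeVolts) ||
      object@amplitudeVolts <= 0)
    msg <- c(msg, "amplitudeVolts must be a single positive number")
  if (length(object@generatorMaxVolts) == 1L &&
      is.finite(object@generatorMaxVolts) &&
      length(object@amplitudeVolts) == 1L &&
      object@amplitudeVolts > object@generatorMaxVolts)
    msg <- c(msg, sprintf("amplitudeVolts (%g V) exceeds generator maximum (%g V)",
                          object@amplitudeVolts, object@generatorMaxVolts))
  if (object@durationUs <= 0) msg <- c(msg, "durationUs must be positive")
  if (object@internalFreqKhz <= 0) msg <- c(msg, "internalFreqKhz must be positive")
  ncyc <- object@durationUs * object@internalFreqKhz / 1000
  if (!isTRUE(abs(ncyc - round(ncyc)) < 1e-9) || round(ncyc) < 1)
    msg <- c(msg, sprintf(
      "durationUs * internalFreqKhz / 1000 = %g must be a positive integer (whole cycles per burst)",
      ncyc))
  if (object@duty <= 0 || object@duty > 1)
    msg <- c(msg, "duty must lie in (0, 1]")
  if (object@nBursts < 1L) msg <- c(msg, "nBursts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a BurstSpec
#'
#' @param amplitudeVolts Applied voltage (V).
#' @param durationUs Burst duration in microseconds (default 100).
#' @param internalFreqKhz Internal frequency in kHz (default 100).
#' @param duty On-time fraction per half-cycle in (0, 1] (default 0.5).
#' @param nBursts Number of bursts in the train (default 60, the atrial
#'   protocol; use 120 for the septal one).
#' @param generatorMaxVolts Generator compliance ceiling (default 1500 V).
#' @return A \linkS4class{BurstSpec} object.
#' @export
#' @examples
#' BurstSpec(900)                      # atrial burst
#' BurstSpec(1500, nBursts = 120)      # septal burst
BurstSpec <- function(amplitudeVolts, durationUs = 100, internalFreqKhz = 100,
                      duty = 0.5, nBursts = 60L, generatorMaxVolts = 1500) {
  new("BurstSpec",
      amplitudeVolts = as.numeric(amplitudeVolts),
      durationUs = as.numeric(durationUs),
      internalFreqKhz = as.numeric(internalFreqKhz),
      duty = as.numeric(duty),
      nBursts = as.integer(nBursts),
      generatorMaxVolts = as.numeric(generatorMaxVolts))
}

#' ECG-gated burst-train schedule
#'
#' One burst is delivered per detected R peak, a fixed delay after it, so the
#' pulse lands in the ventricular effective refractory period. The delay is
#' restricted to the 50-75 ms safety window.
#'
#' @slot rPeakTimesS R-peak times used for gating (s), ordered.
#' @slot delayMs Gating delay after each R peak (ms), in [50, 75].
#' @slot burstTimesS Scheduled burst times (s), strictly increasing.
#' @slot meanInterburstS Mean interval between consecutive bursts (s).
#' @export
setClass("GatingSchedule",
  representation(
    rPeakTimesS     = "numeric",
    delayMs         = "numeric",
    burstTimesS     = "numeric",
    meanInterburstS = "numeric"
  )
)

setValidity("GatingSchedule", function(object) {
  msg <- character()
  if (length(object@burstTimesS) != length(object@rPeakTimesS))
    msg <- c(msg, "one burst per gated beat required")
  if (object@delayMs < 50 || object@delayMs > 75)
    msg <- c(msg, "delayMs outside the [50, 75] ms safety window")
  if (is.unsorted(object@burstTimesS, strictly = TRUE))
    msg <- c(msg, "burstTimesS must be strictly increasing")
  if (any(abs(object@burstTimesS - object@rPeakTimesS - object@delayMs / 1000) > 1e-9))
    msg <- c(msg, "burstTimesS must equal rPeakTimesS + delayMs/1000")
  if (length(msg)) msg else TRUE
})

#' Voxelized labeled scenario geometry
#'
#' A regular voxel grid labelling each cell as blood, myocardium, line
#' electrode, neutral electrode or insulator (see
#' \code{\link{scenarioLabelCodes}}). Electrode voxels act as perfect
#' conductors held at Dirichlet voltages. \code{groups} assigns each
#' electrode voxel to a physical electrode (for polarity and gap metrics);
#' \code{materials} holds per-voxel property arrays once
#' \code{\link{assignMaterials}} has run. Coordinates are cell-centred, in mm,
#' 0-based half-open extents.
#'
#' @slot spacingMm Isotropic voxel edge length (mm).
#' @slot labels 3D integer array of label codes.
#' @slot groups 3D integer array; 0 outside electrodes, else electrode index.
#' @slot groupPolarity Character vector, per electrode group, "line"/"neutral".
#' @slot electrodeVoltage Named numeric: Dirichlet voltage per polarity.
#' @slot kind Scenario kind ("pv_ostium", "atrial_wall", "septal", "custom").
#' @slot materials List of per-voxel property arrays (sigma, k, rho, cp) plus
#'   baselineC, filled by \code{\link{assignMaterials}}.
#' @slot meta List of construction metadata (lumen radius, axis, ...).
#' @export
setClass("ScenarioGrid",
  representation(
    spacingMm        = "numeric",
    labels           = "array",
    groups           = "array",
    groupPolarity    = "character",
    electrodeVoltage = "numeric",
    kind             = "character",
    materials        = "list",
    meta             = "list"
  )
)

## line/neutral electrode voxels must never touch face-on (dead short at grid
## resolution)
.electrodesAdjacent <- function(lab) {
  a <- lab == .LBL[["electrode_line"]]
  b <- lab == .LBL[["electrode_neutral"]]
  if (!any(a) || !any(b)) return(FALSE)
  d <- dim(lab)
  shift_pairs <- function(m1, m2, ax) {
    n <- d[ax]
    if (n < 2L) return(FALSE)
    idx1 <- lapply(seq_along(d), function(i) seq_len(d[i]))
    idx2 <- idx1
    idx1[[ax]] <- 1:(n - 1L); idx2[[ax]] <- 2:n
    any(do.call(`[`, c(list(m1), idx1)) & do.call(`[`, c(list(m2), idx2))) ||
      any(do.call(`[`, c(list(m2), idx1)) & do.call(`[`, c(list(m1), idx2)))
  }
  any(vapply(1:3, function(ax) shift_pairs(a, b, ax), logical(1)))
}

setValidity("ScenarioGrid", function(object) {
  msg <- character()
  lab <- object@labels
  if (length(dim(lab)) != 3L) msg <- c(msg, "labels must be a 3D array")
  if (!(length(object@spacingMm) == 1L && object@spacingMm > 0))
    msg <- c(msg, "spacingMm must be a single positive number")
  if (!all(lab %in% .LBL))
    msg <- c(msg, "labels contain codes outside the allowed set")
  if (!any(lab == .LBL[["electrode_line"]]))
    msg <- c(msg, "no electrode_line voxels")
  if (!any(lab == .LBL[["electrode_neutral"]]))
    msg <- c(msg, "no electrode_neutral voxels")
  if (length(msg) == 0L && .electrodesAdjacent(lab))
    msg <- c(msg, "line and neutral electrodes are face-adjacent (short circuit)")
  if (length(msg)) msg else TRUE
})

#' Per-label material property table
#'
#' Electrical conductivity sigma (S/m), thermal conductivity k (W/m/K),
#' density rho (kg/m^3) and specific heat cp (J/kg/K) for each voxel
#' category, plus the baseline temperature.
#'
#' @slot values data.frame with one row per label (rownames = label names)
#'   and columns sigma, k, rho, cp.
#' @slot baselineC Baseline temperature (deg C), default 37.
#' @export
setClass("MaterialTable",
  representation(values = "data.frame", baselineC = "numeric"))

setValidity("MaterialTable", function(object) {
  msg <- character()
  v <- object@values
  need <- c("sigma", "k", "rho", "cp")
  if (!all(need %in% colnames(v)))
    msg <- c(msg, "values must have columns sigma, k, rho, cp")
  for (lbl in intersect(c("blood", "myocardium"), rownames(v)))
    if (any(v[lbl, need] <= 0))
      msg <- c(msg, sprintf("all properties of %s must be positive", lbl))
  if ("insulator" %in% rownames(v) && v["insulator", "sigma"] > 1e-6)
    msg <- c(msg, "insulator sigma must be <= 1e-6 S/m")
  if (length(msg)) msg else TRUE
})

#' Quasi-static conduction solution on a scenario grid
#'
#' @slot potential 3D array of electric potential (V).
#' @slot eMag 3D array of electric field magnitude (V/cm).
#' @slot jMag 3D array of current density magnitude (kA/m^2).
#' @slot totalCurrentA Total current through the line electrodes (A).
#' @slot appliedVolts Applied line-electrode voltage (V).
#' @slot residual Final relative residual of the iterative solve.
#' @slot currentBalance Relative mismatch between line and neutral currents.
#' @export
setClass("FieldSolution",
  representation(
    potential      = "array",
    eMag           = "array",
    jMag           = "array",
    totalCurrentA  = "numeric",
    appliedVolts   = "numeric",
    residual       = "numeric",
    currentBalance = "numeric"
  )
)

#' Static laminar blood-velocity field
#'
#' Velocity is nonzero only in blood voxels, with a no-slip zero layer in
#' blood voxels face-adjacent to tissue or electrodes.
#'
#' @slot vx,vy,vz 3D arrays of velocity components (m/s).
#' @slot peakVelocityMs Peak velocity (m/s).
#' @slot profile "plug" or "poiseuille".
#' @export
setClass("FlowField",
  representation(
    vx = "array", vy = "array", vz = "array",
    peakVelocityMs = "numeric", profile = "character"
  )
)

#' Temperature transient of one gated burst
#'
#' @slot timeS Time points (s).
#' @slot probesC Matrix of probe temperatures (deg C), one column per probe
#'   ("tissue_interface", "blood", "domain_max").
#' @slot peakMapC 3D array of the running temperature maximum (deg C).
#' @slot finalC 3D array of the temperature at the last time point (deg C).
#' @slot baselineC Baseline temperature (deg C).
#' @slot meta List (dt used, burst/relax durations, stability bound).
#' @export
setClass("ThermalTrace",
  representation(
    timeS     = "numeric",
    probesC   = "matrix",
    peakMapC  = "array",
    finalC    = "array",
    baselineC = "numeric",
    meta      = "list"
  )
)

#' Exponential temperature-decay fit
#'
#' Parameters of T(t) = baseline + A * exp(-t / tau) fitted to a post-burst
#' probe series.
#'
#' @slot amplitudeC Fitted amplitude A (deg C).
#' @slot tauMs Fitted decay constant tau (ms).
#' @slot baselineC Fitted baseline (deg C).
#' @slot r2 Goodness of fit.
#' @export
setClass("DecayFit",
  representation(amplitudeC = "numeric", tauMs = "numeric",
                 baselineC = "numeric", r2 = "numeric"))

setValidity("DecayFit", function(object) {
  msg <- character()
  if (object@tauMs <= 0) msg <- c(msg, "tauMs must be positive")
  if (object@amplitudeC < 0) msg <- c(msg, "amplitudeC must be >= 0")
  if (object@r2 > 1) msg <- c(msg, "r2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' Labeled MRI-like segmentation volume
#'
#' Integer label volume in the documented dialect: 0 = background,
#' 1 = myocardium, 2 = non-myocardial tissue. In-plane voxel size and slice
#' thickness are stored separately (slices along the third axis).
#'
#' @slot labels 3D integer array (0/1/2).
#' @slot voxelMm In-plane voxel edge (mm).
#' @slot sliceMm Slice thickness (mm), default 1.
#' @slot truth List of generator ground truth (empty for real data).
#' @export
setClass("SegmentationVolume",
  representation(labels = "array", voxelMm = "numeric",
                 sliceMm = "numeric", truth = "list"))

setValidity("SegmentationVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be 3D")
  if (!all(object@labels %in% 0:2))
    msg <- c(msg, "labels must be 0 (background), 1 (myocardium) or 2 (non-myocardial)")
  if (!any(object@labels == 1L)) msg <- c(msg, "at least one myocardium voxel required")
  if (object@voxelMm <= 0 || object@sliceMm <= 0)
    msg <- c(msg, "voxelMm and sliceMm must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn SegmentationVolume-class Constructor.
#' @param labels 3D integer array (0/1/2).
#' @param voxelMm In-plane voxel edge (mm).
#' @param sliceMm Slice thickness (mm).
#' @param truth Optional generator ground-truth list.
#' @export
SegmentationVolume <- function(labels, voxelMm, sliceMm = 1, truth = list()) {
  storage.mode(labels) <- "integer"
  new("SegmentationVolume", labels = labels, voxelMm = as.numeric(voxelMm),
      sliceMm = as.numeric(sliceMm), truth = truth)
}
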