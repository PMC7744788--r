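## Orchestration: YAML run configuration, scenario -> solve -> thermal ->
## lesion report, study-metrics reports, and file I/O (CSV traces, NIfTI
## volumes, JSON reports). All physical keys carry unit suffixes (_mm, _v,
## _ms, ...) to prevent unit drift; every report embeds the seed and a hash
## of the configuration that produced it.

#' Read a run configuration
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  yaml::read_yaml(path)
}

.configHash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), tf)
  unname(tools::md5sum(tf))
}

.require_keys <- function(config, keys) {
  miss <- setdiff(keys, names(config))
  if (length(miss))
    stop(sprintf("config is missing block(s): %s",
                 paste(miss, collapse = ", ")))
}

.buildFromConfig <- function(sc) {
  kind <- sc$kind
  if (is.null(kind)) stop("config is missing key: scenario.kind")
  sp <- sc$spacing_mm %||% 0.5
  switch(kind,
    pv_ostium = buildPVOstium(
      diameterMm = sc$diameter_mm %||% 13,
      wallMm = sc$wall_mm %||% 5.85, spacingMm = sp),
    atrial_wall = buildAtrialWall(
      wallMm = sc$wall_mm %||% 5.85,
      loopDiameterMm = sc$loop_diameter_mm %||% 20, spacingMm = sp),
    septal = buildSeptal(
      septumMm = sc$septum_mm %||% 15,
      offsetMm = sc$offset_mm %||% 0,
      tiltDeg = sc$tilt_deg %||% 0, spacingMm = sp),
    stop(sprintf("unknown scenario.kind '%s'", kind)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.materialsFromConfig <- function(mats) {
  ov <- lapply(mats, function(x) unlist(x))
  ov <- ov[!vapply(ov, is.null, logical(1))]
  defaultMaterialTable(overrides = ov)
}

#' Run one ablation scenario end to end
#'
#' Builds the configured geometry, attaches materials, solves the
#' quasi-static field at the burst voltage, integrates the thermal
#' transient of one gated burst for each velocity in the sweep, fits the
#' post-burst tissue decay, and assembles the lesion report.
#'
#' @param config Configuration list (see the package vignette) or a YAML
#'   path. Required blocks: \code{scenario}, \code{burst},
#'   \code{materials}.
#' @param outDir Optional output directory; writes \code{report.json} (and
#'   \code{trace_v<velocity>.csv} per sweep velocity) when given.
#' @param thermal If FALSE, skip the transient (field metrics only).
#' @return List: the lesion report, per-velocity peak blood temperatures,
#'   the decay fit, solver diagnostics, seed and config hash.
#' @export
runScenario <- function(config, outDir = NULL, thermal = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  .require_keys(config, c("scenario", "burst", "materials"))
  seed <- config$seed %||% 0L
  hash <- .configHash(config)
  t0 <- proc.time()["elapsed"]
  grid <- .buildFromConfig(config$scenario)
  grid <- assignMaterials(grid, .materialsFromConfig(config$materials))
  spec <- BurstSpec(
    amplitudeVolts = config$burst$amplitude_v %||%
      stop("config is missing key: burst.amplitude_v"),
    durationUs = config$burst$duration_us %||% 100,
    internalFreqKhz = config$burst$freq_khz %||% 100,
    duty = config$burst$duty %||% 0.5,
    nBursts = config$burst$n %||% 60)
  tol <- config$solver$tol %||% 1e-8
  sol <- solvePotential(grid, spec@amplitudeVolts, tol = tol)
  tSolve <- proc.time()["elapsed"] - t0
  message(sprintf("[solve] residual %.2e, current %.3f A (%.1f s)",
                  sol@residual, sol@totalCurrentA, tSolve))
  comp <- totalCurrent(sol, grid,
                       complianceA = config$solver$compliance_a %||% 12)
  if (comp$exceedsCompliance)
    warning(sprintf("delivered current %.2f A exceeds generator compliance",
                    comp$currentA))

  sweep <- config$velocity_sweep %||% 0
  traces <- list()
  decay <- NULL
  if (thermal) {
    q <- jouleSource(sol, grid, dutyPowerFactor(spec))
    th <- config$thermal %||% list()
    for (v in sweep) {
      flow <- if (v > 0) makeFlowField(grid, v,
                                       th$profile %||% "poiseuille") else NULL
      tr <- simulateTransient(grid, q, flow,
        burstS = spec@durationUs * 1e-6,
        relaxS = th$relax_s %||% 0.8,
        dtBurstS = th$dt_burst_s %||% 1e-6,
        dtRelaxS = th$dt_relax_s %||% 1e-3)
      traces[[as.character(v)]] <- tr
      message(sprintf("[thermal v=%g] peak blood %.2f C, peak interface %.2f C",
                      v, max(tr@probesC[, "blood"]),
                      max(tr@probesC[, "tissue_interface"])))
    }
    tr0 <- traces[[1]]
    iPk <- which.max(tr0@probesC[, "tissue_interface"])
    decay <- tryCatch(
      fitExponentialDecay(tr0@timeS, tr0@probesC[, "tissue_interface"],
                          window = c(tr0@timeS[iPk], max(tr0@timeS))),
      error = function(e) NULL)
  }
  rep <- lesionReport(grid, sol,
                      trace = if (length(traces)) traces[[1]] else NULL,
                      decay = decay,
                      thresholdVcm = config$threshold_v_per_cm %||% 400)
  out <- list(
    report = rep,
    peakBloodC = vapply(traces, function(tr)
      max(tr@probesC[, "blood"]), numeric(1)),
    velocitySweepMs = sweep,
    decay = rep$decay,
    solver = list(residual = sol@residual,
                  currentBalance = sol@currentBalance,
                  exceedsCompliance = comp$exceedsCompliance),
    seed = seed, configHash = hash)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeReportJson(out, file.path(outDir, "report.json"))
    for (v in names(traces))
      writeTraceCsv(traces[[v]],
                    file.path(outDir, sprintf("trace_v%s.csv", v)))
  }
  out
}

#' Run the study outcome metrics
#'
#' Volumetrics on a treated/control segmentation pair (non-myocardial
#' percentages, control-subtracted ablated percentage, extruded-cylinder
#' reference ratio), paired pre/post electrogram statistics, and/or a
#' summary-statistics one-sample t test.
#'
#' @param seg Treated \linkS4class{SegmentationVolume} or NIfTI path
#'   (labels 0 background, 1 myocardium, 2 non-myocardial).
#' @param control Control \linkS4class{SegmentationVolume} or NIfTI path.
#' @param egm EGM cohort: data.frame in the wide layout of
#'   \code{\link{genEgmCohort}}, a long data.frame with columns id, metric,
#'   pre, post, or a CSV path of either.
#' @param summary Optional list(mean, sd, n, mu0) for a summary-statistics
#'   one-sample t test.
#' @param loopDiameterMm Loop catheter diameter for the reference cylinder.
#' @param outDir Optional output directory for \code{metrics.json}.
#' @param seed Seed to embed in the report.
#' @return List of computed metrics.
#' @export
runStudyMetrics <- function(seg = NULL, control = NULL, egm = NULL,
                            summary = NULL, loopDiameterMm = 20,
                            outDir = NULL, seed = 0L) {
  out <- list(seed = seed)
  if (!is.null(seg)) {
    seg <- .asSegmentation(seg)
    vf <- volumeFractions(seg)
    out$treated <- list(nonmyoPct = vf$nonmyoPct, vPct = vf$vPct,
                        vtotMm3 = vf$vtotMm3)
    if (!is.null(control)) {
      control <- .asSegmentation(control)
      vc <- volumeFractions(control)
      out$control <- list(nonmyoPct = vc$nonmyoPct, vPct = vc$vPct)
      out$ablatedPct <- ablatedFraction(vf$nonmyoPct, vc$nonmyoPct,
                                        digits = 2)
      ablVol <- out$ablatedPct / 100 * vf$vtotMm3
      er <- extrusionReferenceRatio(seg, ablVol, loopDiameterMm)
      out$extrusionRatio <- er$ratio
      out$maxWallMm <- er$maxWallMm
    }
  }
  if (!is.null(egm)) {
    egm <- .asEgmWide(egm)
    out$egm <- lapply(c("amplitude", "duration", "impedance"), function(m) {
      res <- tryCatch(pairedChangeStats(egm, m), error = function(e) NULL)
      if (!is.null(res)) c(metric = m, res)
    })
    out$egm <- Filter(Negate(is.null), out$egm)
  }
  if (!is.null(summary))
    out$oneSampleT <- oneSampleTSummary(summary$mean, summary$sd,
                                        summary$n, summary$mu0)
  if (is.null(out$treated) && is.null(out$egm) && is.null(out$oneSampleT))
    stop("no inputs: provide seg, egm and/or summary")
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeReportJson(out, file.path(outDir, "metrics.json"))
  }
  out
}

.asSegmentation <- function(x) {
  if (is(x, "SegmentationVolume")) return(x)
  if (is.character(x)) return(readSegmentationNifti(x))
  stop("expected a SegmentationVolume or a NIfTI path")
}

.asEgmWide <- function(x) {
  if (is.character(x)) {
    x <- utils::read.csv(x)
    if (nrow(x) == 0L) stop("empty EGM table")
  }
  if (all(c("id", "metric", "pre", "post") %in% colnames(x))) {
    units <- c(amplitude = "mv", duration = "ms", impedance = "ohm")
    ids <- sort(unique(x$id))
    wide <- data.frame(id = ids)
    for (m in unique(x$metric)) {
      sub <- x[x$metric == m, ]
      u <- units[[m]] %||% "x"
      wide[[paste0(m, "_pre_", u)]] <- sub$pre[match(ids, sub$id)]
      wide[[paste0(m, "_post_", u)]] <- sub$post[match(ids, sub$id)]
    }
    return(wide)
  }
  if (nrow(x) == 0L) stop("empty EGM table")
  x
}

#' Write a report list as JSON
#'
#' @param x Report list.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeReportJson <- function(x, path) {
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           pretty = TRUE, null = "null",
                                           na = "null")), path)
  invisible(path)
}

#' Write a thermal trace as CSV
#'
#' Columns: time_s plus one column per probe.
#'
#' @param trace A \linkS4class{ThermalTrace}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTraceCsv <- function(trace, path) {
  utils::write.csv(probeSeries(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a scenario grid as NIfTI + JSON sidecar
#'
#' The label volume goes to \code{<path>.nii.gz}-style NIfTI with the voxel
#' spacing in its header; electrode voltages, group polarity and the label
#' code table go to \code{<path>.json}.
#'
#' @param grid A \linkS4class{ScenarioGrid}.
#' @param path Output path (".nii" appended if absent).
#' @return Invisibly, the NIfTI path.
#' @export
writeScenarioNifti <- function(grid, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii")
  img <- RNifti::asNifti(grid@labels)
  RNifti::pixdim(img) <- rep(grid@spacingMm, 3)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  writeReportJson(list(kind = grid@kind, spacing_mm = grid@spacingMm,
                       label_codes = as.list(scenarioLabelCodes()),
                       electrode_voltage = as.list(grid@electrodeVoltage),
                       group_polarity = grid@groupPolarity,
                       meta = grid@meta), side)
  invisible(path)
}

#' Write a field solution as NIfTI float volumes
#'
#' Writes \code{<stem>_potential.nii}, \code{<stem>_emag.nii} and
#' \code{<stem>_jmag.nii}.
#'
#' @param sol A \linkS4class{FieldSolution}.
#' @param grid The corresponding grid (for voxel spacing).
#' @param stem Output path stem.
#' @return Invisibly, the paths.
#' @export
writeFieldNifti <- function(sol, grid, stem) {
  w <- function(arr, suffix) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(grid@spacingMm, 3)
    p <- sprintf("%s_%s.nii", stem, suffix)
    RNifti::writeNifti(img, p)
    p
  }
  invisible(c(w(sol@potential, "potential"), w(sol@eMag, "emag"),
              w(sol@jMag, "jmag")))
}

#' Write a segmentation volume as NIfTI
#'
#' @param seg A \linkS4class{SegmentationVolume}.
#' @param path Output path (".nii" appended if absent).
#' @return Invisibly, the path.
#' @export
writeSegmentationNifti <- function(seg, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii")
  img <- RNifti::asNifti(seg@labels)
  RNifti::pixdim(img) <- c(seg@voxelMm, seg@voxelMm, seg@sliceMm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a segmentation volume from NIfTI
#'
#' Expects the documented label dialect (0 background, 1 myocardium,
#' 2 non-myocardial); anything else is rejected.
#'
#' @param path NIfTI path.
#' @return A \linkS4class{SegmentationVolume}.
#' @export
readSegmentationNifti <- function(path) {
  img <- RNifti::readNifti(path)
  lab <- array(as.integer(round(img)), dim(img)[1:3])
  if (!all(lab %in% 0:2))
    stop("label dialect violation: expected labels 0/1/2 ",
         "(background/myocardium/non-myocardial)")
  pd <- RNifti::pixdim(img)
  SegmentationVolume(lab, voxelMm = pd[1], sliceMm = pd[3])
}
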