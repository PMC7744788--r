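## Scenario geometry builders: voxelized labeled grids for the three
## simulated ablation settings, plus material attachment.
##
## Coordinate convention: 0-based half-open extents in mm, cell-centred voxel
## coordinates ((i - 0.5) * spacing), isotropic spacing.

.cellCenters <- function(dims, h)
  lapply(1:3, function(ax) (seq_len(dims[ax]) - 0.5) * h)

#' Construct a ScenarioGrid from a label array
#'
#' Low-level constructor for custom geometries (bench tests, analytic
#' verification grids). The shipped builders
#' (\code{\link{buildPVOstium}}, \code{\link{buildAtrialWall}},
#' \code{\link{buildSeptal}}) call this internally.
#'
#' @param labels 3D integer array of codes from
#'   \code{\link{scenarioLabelCodes}}.
#' @param spacingMm Isotropic voxel spacing (mm).
#' @param groups Optional 3D integer array assigning electrode voxels to
#'   groups (0 elsewhere). If NULL, one group per polarity is assumed.
#' @param groupPolarity Character vector, per group, "line" or "neutral".
#' @param kind Scenario kind string.
#' @param meta Construction metadata list.
#' @return A validated \linkS4class{ScenarioGrid}.
#' @export
ScenarioGrid <- function(labels, spacingMm, groups = NULL,
                         groupPolarity = NULL, kind = "custom",
                         meta = list()) {
  storage.mode(labels) <- "integer"
  if (is.null(groups)) {
    groups <- array(0L, dim(labels))
    groups[labels == .LBL[["electrode_line"]]] <- 1L
    groups[labels == .LBL[["electrode_neutral"]]] <- 2L
    groupPolarity <- c("line", "neutral")
  }
  storage.mode(groups) <- "integer"
  new("ScenarioGrid", spacingMm = as.numeric(spacingMm), labels = labels,
      groups = groups, groupPolarity = groupPolarity,
      electrodeVoltage = c(electrode_line = 1, electrode_neutral = 0),
      kind = kind, materials = list(), meta = meta)
}

#' Default material property table
#'
#' Literature-range defaults: myocardium sigma 0.381 S/m, k 0.56 W/m/K,
#' rho 1081 kg/m^3, cp 3686 J/kg/K; blood 0.70 S/m, 0.52 W/m/K,
#' 1050 kg/m^3, 3617 J/kg/K; platinum electrodes and a nylon insulator
#' shaft. All values are overridable.
#'
#' @param overrides Named list of named numeric vectors, e.g.
#'   \code{list(myocardium = c(sigma = 0.5))}.
#' @param baselineC Baseline temperature (deg C), default 37.
#' @return A \linkS4class{MaterialTable}.
#' @export
#' @examples
#' defaultMaterialTable(list(myocardium = c(sigma = 0.45)))
defaultMaterialTable <- function(overrides = list(), baselineC = 37) {
  v <- data.frame(
    sigma = c(blood = 0.70, myocardium = 0.381,
              electrode_line = 9.4e6, electrode_neutral = 9.4e6,
              insulator = 1e-10),
    k     = c(0.52, 0.56, 71.6, 71.6, 0.26),
    rho   = c(1050, 1081, 21450, 21450, 1150),
    cp    = c(3617, 3686, 133, 133, 1700))
  for (lbl in names(overrides)) {
    if (!lbl %in% rownames(v))
      stop(sprintf("unknown material label '%s'", lbl))
    for (prop in names(overrides[[lbl]])) {
      if (!prop %in% colnames(v))
        stop(sprintf("unknown material property '%s'", prop))
      v[lbl, prop] <- overrides[[lbl]][[prop]]
    }
  }
  new("MaterialTable", values = v, baselineC = baselineC)
}

## place n alternating electrode groups of arc length segMm on the circle of
## radius radMm around (cx, cy) at slice zIdx; returns modified labels/groups
.placeRing <- function(lab, grp, h, n, radMm, cx, cy, zIdx, segMm) {
  d <- dim(lab)
  xs <- (seq_len(d[1]) - 0.5) * h
  ys <- (seq_len(d[2]) - 0.5) * h
  ang <- 2 * pi * (seq_len(n) - 1) / n
  gx <- cx + radMm * cos(ang)
  gy <- cy + radMm * sin(ang)
  pol <- ifelse(seq_len(n) %% 2L == 1L, "line", "neutral")
  code <- ifelse(pol == "line", .LBL[["electrode_line"]],
                 .LBL[["electrode_neutral"]])
  for (g in seq_len(n)) {
    dx <- outer(xs - gx[g], rep(1, d[2]))
    dy <- outer(rep(1, d[1]), ys - gy[g])
    d2 <- dx * dx + dy * dy
    hit <- which(d2 <= (segMm / 2)^2, arr.ind = TRUE)
    if (nrow(hit) == 0L)   # coarse grids: snap to the nearest voxel centre
      hit <- which(d2 == min(d2), arr.ind = TRUE)[1, , drop = FALSE]
    for (r in seq_len(nrow(hit))) {
      lab[hit[r, 1], hit[r, 2], zIdx] <- code[g]
      grp[hit[r, 1], hit[r, 2], zIdx] <- g
    }
  }
  list(lab = lab, grp = grp, polarity = pol)
}

#' Build the pulmonary-vein-ostium ablation scenario
#'
#' A cylindrical vein lumen (blood) runs through a myocardial wall; a ring
#' of 10 electrode groups rests on the lumen rim at the endocardial face,
#' with alternating line/neutral polarity (odd groups on the line pole,
#' even on the neutral), mirroring a decapolar circular catheter at the
#' ostium.
#'
#' @param diameterMm Lumen diameter (mm); ostia of 12-14 mm are typical and
#'   values outside that range warn.
#' @param wallMm Myocardial wall thickness (mm), default 5.85.
#' @param spacingMm Voxel spacing (mm), default 0.5.
#' @param padMm Lateral blood padding beyond the lumen (mm).
#' @param bloodMm Blood depth above and below the wall (mm).
#' @param electrodeMm Arc length of each electrode segment (mm), default 1.
#' @return A \linkS4class{ScenarioGrid} of kind "pv_ostium".
#' @export
#' @examples
#' g <- buildPVOstium(13, spacingMm = 0.5)
#' g
buildPVOstium <- function(diameterMm = 13, wallMm = 5.85, spacingMm = 0.5,
                          padMm = 6, bloodMm = 6, electrodeMm = 1) {
  if (diameterMm <= 0) stop("diameterMm must be positive")
  if (diameterMm < 12 || diameterMm > 14)
    warning("diameterMm outside the typical 12-14 mm ostium range")
  if (spacingMm > electrodeMm)
    stop("spacing too coarse to resolve electrode segments")
  h <- spacingMm
  L <- diameterMm + 2 * padMm
  H <- wallMm + 2 * bloodMm
  d <- c(round(L / h), round(L / h), round(H / h))
  cc <- .cellCenters(d, h)
  cx <- d[1] * h / 2; cy <- d[2] * h / 2
  lab <- array(.LBL[["blood"]], d)
  inSlab <- cc[[3]] >= bloodMm & cc[[3]] <= bloodMm + wallMm
  r2 <- outer((cc[[1]] - cx)^2, (cc[[2]] - cy)^2, `+`)
  wallMask <- r2 > (diameterMm / 2)^2
  for (k in which(inSlab)) {
    sl <- lab[, , k]
    sl[wallMask] <- .LBL[["myocardium"]]
    lab[, , k] <- sl
  }
  grp <- array(0L, d)
  zTop <- max(which(inSlab)) + 1L   # first blood layer above the wall
  ring <- .placeRing(lab, grp, h, 10L, diameterMm / 2, cx, cy, zTop,
                     electrodeMm)
  ScenarioGrid(ring$lab, h, ring$grp, ring$polarity, kind = "pv_ostium",
               meta = list(diameterMm = diameterMm, wallMm = wallMm,
                           centerMm = c(cx, cy), lumenAxis = 3L,
                           slabZIdx = range(which(inSlab)),
                           electrodeZIdx = zTop))
}

#' Build the atrial-wall ablation scenario
#'
#' A flat, trabecula-free myocardial slab under a blood pool, with a
#' 10-electrode loop of the stated diameter resting on the endocardial face
#' (alternating line/neutral polarity around the loop).
#'
#' @param wallMm Wall thickness (mm), default 5.85 (a typical atrial mean).
#' @param loopDiameterMm Loop catheter diameter (mm), default 20.
#' @param spacingMm Voxel spacing (mm), default 0.5.
#' @param padMm Lateral blood padding beyond the loop (mm).
#' @param bloodMm Blood pool height above the wall (mm).
#' @param electrodeMm Arc length of each electrode segment (mm), default 1.
#' @param lateralMm Optional fixed lateral domain size (mm); rejects a loop
#'   that does not fit.
#' @return A \linkS4class{ScenarioGrid} of kind "atrial_wall".
#' @export
buildAtrialWall <- function(wallMm = 5.85, loopDiameterMm = 20,
                            spacingMm = 0.5, padMm = 5, bloodMm = 10,
                            electrodeMm = 1, lateralMm = NULL) {
  if (wallMm <= 0) stop("wallMm must be positive")
  if (spacingMm > electrodeMm)
    stop("spacing too coarse to resolve electrode segments")
  h <- spacingMm
  L <- if (is.null(lateralMm)) loopDiameterMm + 2 * padMm else lateralMm
  if (loopDiameterMm + 2 * h > L)
    stop("loop larger than the domain")
  H <- wallMm + bloodMm
  d <- c(round(L / h), round(L / h), round(H / h))
  cc <- .cellCenters(d, h)
  lab <- array(.LBL[["blood"]], d)
  inSlab <- cc[[3]] <= wallMm
  lab[, , which(inSlab)] <- .LBL[["myocardium"]]
  grp <- array(0L, d)
  zTop <- max(which(inSlab)) + 1L
  ring <- .placeRing(lab, grp, h, 10L, loopDiameterMm / 2,
                     d[1] * h / 2, d[2] * h / 2, zTop, electrodeMm)
  ScenarioGrid(ring$lab, h, ring$grp, ring$polarity, kind = "atrial_wall",
               meta = list(wallMm = wallMm, loopDiameterMm = loopDiameterMm,
                           slabZIdx = range(which(inSlab)),
                           electrodeZIdx = zTop))
}

## voxelize a capsule (segment p0 -> p0 + len*dir with radius r) into `code`
.placeCapsule <- function(lab, grp, h, p0, dir, len, radius, code, gid) {
  d <- dim(lab)
  cc <- .cellCenters(d, h)
  p1 <- p0 + len * dir
  ## bounding box to keep the scan cheap
  lo <- pmin(p0, p1) - radius - h
  hi <- pmax(p0, p1) + radius + h
  ix <- which(cc[[1]] >= lo[1] & cc[[1]] <= hi[1])
  iy <- which(cc[[2]] >= lo[2] & cc[[2]] <= hi[2])
  iz <- which(cc[[3]] >= lo[3] & cc[[3]] <= hi[3])
  for (k in iz) for (j in iy) {
    px <- cc[[1]][ix]; py <- cc[[2]][j]; pz <- cc[[3]][k]
    ## distance from points to the segment
    vx <- px - p0[1]; vy <- py - p0[2]; vz <- pz - p0[3]
    t <- (vx * dir[1] + vy * dir[2] + vz * dir[3])
    t <- pmin(pmax(t, 0), len)
    dx <- vx - t * dir[1]; dy <- vy - t * dir[2]; dz <- vz - t * dir[3]
    hit <- ix[dx * dx + dy * dy + dz * dz <= radius^2]
    if (length(hit)) {
      lab[cbind(hit, j, k)] <- code
      grp[cbind(hit, j, k)] <- gid
    }
  }
  list(lab = lab, grp = grp)
}

#' Build the interventricular-septum ablation scenario
#'
#' A myocardial slab of stated thickness with blood pools on both faces.
#' One tip electrode (line pole, ablation-catheter-sized) touches one face;
#' a second (neutral pole, diagnostic-catheter-sized) touches the opposite
#' face, displaced laterally by \code{offsetMm} and tilted by
#' \code{tiltDeg}. Electrodes are modelled as capsules whose lowest point
#' touches the tissue face, so they can never penetrate the slab.
#'
#' @param septumMm Septal wall thickness (mm), default 15.
#' @param offsetMm Lateral misalignment between the two tips (mm).
#' @param tiltDeg Tilt of the line-electrode axis from the face normal
#'   (degrees, 0 <= tilt < 90).
#' @param spacingMm Voxel spacing (mm), default 0.5.
#' @param tipLenMm Electrode tip lengths (mm): named c(line=, neutral=),
#'   defaults 4 and 2.
#' @param tipDiamMm Tip diameter (mm), default 2.33 (7F).
#' @param padMm Lateral blood padding (mm).
#' @param bloodMm Blood depth beyond each face (mm).
#' @return A \linkS4class{ScenarioGrid} of kind "septal".
#' @export
#' @examples
#' g <- buildSeptal(15, offsetMm = 10, tiltDeg = 45)
#' g
buildSeptal <- function(septumMm = 15, offsetMm = 0, tiltDeg = 0,
                        spacingMm = 0.5,
                        tipLenMm = c(line = 4, neutral = 2),
                        tipDiamMm = 2.33, padMm = 8, bloodMm = 8) {
  if (septumMm <= 0) stop("septumMm must be positive")
  if (offsetMm < 0) stop("offsetMm must be >= 0")
  if (tiltDeg < 0 || tiltDeg >= 90) stop("tiltDeg must lie in [0, 90)")
  h <- spacingMm
  r <- tipDiamMm / 2
  tilt <- tiltDeg * pi / 180
  Lx <- offsetMm + 2 * padMm + tipDiamMm +
    max(tipLenMm) * sin(tilt) + 2 * h
  Ly <- 2 * padMm + tipDiamMm
  bloodNeed <- max(tipLenMm) * cos(tilt) + 2 * r + 2 * h
  Hb <- max(bloodMm, bloodNeed)
  H <- septumMm + 2 * Hb
  d <- c(round(Lx / h), round(Ly / h), round(H / h))
  cc <- .cellCenters(d, h)
  lab <- array(.LBL[["blood"]], d)
  inSlab <- cc[[3]] >= Hb & cc[[3]] <= Hb + septumMm
  lab[, , which(inSlab)] <- .LBL[["myocardium"]]
  grp <- array(0L, d)
  zTopMm <- max(cc[[3]][inSlab]) + h / 2    # face positions
  zBotMm <- min(cc[[3]][inSlab]) - h / 2
  cy <- d[2] * h / 2
  cxLine <- d[1] * h / 2 - offsetMm / 2
  cxNeut <- d[1] * h / 2 + offsetMm / 2
  dirUp <- c(sin(tilt), 0, cos(tilt))
  res <- .placeCapsule(lab, grp, h, c(cxLine, cy, zTopMm + r), dirUp,
                       tipLenMm[["line"]], r, .LBL[["electrode_line"]], 1L)
  res <- .placeCapsule(res$lab, res$grp, h, c(cxNeut, cy, zBotMm - r),
                       c(0, 0, -1), tipLenMm[["neutral"]], r,
                       .LBL[["electrode_neutral"]], 2L)
  lab <- res$lab; grp <- res$grp
  ## an electrode voxel replacing myocardium means the capsule dipped into
  ## the wall
  slabIdx <- which(inSlab)
  if (any(lab[, , slabIdx] %in% .LBL[c("electrode_line", "electrode_neutral")]))
    stop("electrode overlaps the tissue interior")
  ScenarioGrid(lab, h, grp, c("line", "neutral"), kind = "septal",
               meta = list(septumMm = septumMm, offsetMm = offsetMm,
                           tiltDeg = tiltDeg,
                           slabZIdx = range(slabIdx),
                           axisXMm = c(cxLine, cxNeut), axisYMm = cy))
}

#' Attach material properties to a scenario grid
#'
#' Populates per-voxel sigma, k, rho and cp arrays from a per-label table.
#'
#' @param grid A \linkS4class{ScenarioGrid}.
#' @param table A \linkS4class{MaterialTable}; default
#'   \code{\link{defaultMaterialTable}()}.
#' @return The grid with \code{gridMaterials(grid)} populated.
#' @export
#' @examples
#' g <- assignMaterials(buildAtrialWall(spacingMm = 1))
#' names(gridMaterials(g))
assignMaterials <- function(grid, table = defaultMaterialTable()) {
  stopifnot(is(grid, "ScenarioGrid"), is(table, "MaterialTable"))
  validObject(table)
  lab <- grid@labels
  present <- names(.LBL)[.LBL %in% unique(as.vector(lab))]
  missing <- setdiff(present, rownames(table@values))
  if (length(missing))
    stop(sprintf("material table lacks label(s): %s",
                 paste(missing, collapse = ", ")))
  idx <- match(as.vector(lab), .LBL[rownames(table@values)])
  mk <- function(prop) array(table@values[[prop]][idx], dim(lab))
  grid@materials <- list(sigma = mk("sigma"), k = mk("k"),
                         rho = mk("rho"), cp = mk("cp"),
                         baselineC = table@baselineC)
  grid
}
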