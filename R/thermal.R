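## Bioheat transient of one gated AC burst: conduction (finite-volume,
## harmonic-mean face conductivities), optional convective transport by a
## static laminar blood-velocity field (first-order upwind), Joule source
## active during the burst only. Diffusion is integrated implicitly
## (backward Euler, unconditionally stable across the Pt/tissue/blood
## property contrast), advection explicitly with a CFL check; an explicit
## diffusion mode with a hard stability bound is selectable.

#' Build a static laminar blood-velocity field
#'
#' Analytic laminar profiles standing in for a static flow solve. For the
#' pulmonary-vein scenario the flow runs along the lumen axis:
#' "poiseuille" gives v(r) = peak * (1 - r^2/R^2), "plug" a uniform core.
#' For wall-type scenarios the flow runs parallel to the wall: "poiseuille"
#' gives a shear profile rising from 0 at the endocardial surface to peak
#' at the top of the blood pool, "plug" a uniform pool. In all cases
#' velocity is zero outside blood and in blood voxels face-adjacent to
#' tissue or electrodes (no-slip).
#'
#' @param grid A \linkS4class{ScenarioGrid}.
#' @param peakVelocityMs Peak velocity (m/s), >= 0.
#' @param profile "poiseuille" or "plug".
#' @return A \linkS4class{FlowField}.
#' @export
#' @examples
#' g <- buildPVOstium(13, spacingMm = 1)
#' f <- makeFlowField(g, 0.16, "poiseuille")
makeFlowField <- function(grid, peakVelocityMs,
                          profile = c("poiseuille", "plug")) {
  stopifnot(is(grid, "ScenarioGrid"), peakVelocityMs >= 0)
  profile <- match.arg(profile)
  lab <- grid@labels
  d <- dim(lab)
  h <- grid@spacingMm
  blood <- lab == .LBL[["blood"]]
  if (!any(blood)) stop("grid has no blood voxels")
  vx <- vy <- vz <- array(0, d)
  cc <- .cellCenters(d, h)
  if (grid@kind == "pv_ostium") {
    ctr <- grid@meta$centerMm
    R <- grid@meta$diameterMm / 2
    r2 <- outer((cc[[1]] - ctr[1])^2, (cc[[2]] - ctr[2])^2, `+`)
    for (k in seq_len(d[3])) {
      sl <- array(0, d[1:2])
      inLum <- r2 < R^2
      sl[inLum] <- if (profile == "poiseuille")
        peakVelocityMs * (1 - r2[inLum] / R^2)
      else peakVelocityMs
      sl[!blood[, , k]] <- 0
      vz[, , k] <- sl
    }
  } else {
    ## wall-type scenario: flow along +x above the endocardial surface
    slabTop <- if (!is.null(grid@meta$slabZIdx))
      max(grid@meta$slabZIdx) else 0L
    zTopMm <- d[3] * h
    z0Mm <- slabTop * h
    Hc <- max(zTopMm - z0Mm, h)
    for (k in seq_len(d[3])) {
      zrel <- cc[[3]][k] - z0Mm
      if (zrel <= 0) next
      v <- if (profile == "poiseuille")
        peakVelocityMs * (1 - ((Hc - zrel) / Hc)^2)
      else peakVelocityMs
      sl <- array(v, d[1:2])
      sl[!blood[, , k]] <- 0
      vx[, , k] <- sl
    }
  }
  ## no-slip: zero any blood voxel face-adjacent to a non-blood voxel
  noslip <- .adjacentToNonBlood(blood)
  vx[noslip] <- 0; vy[noslip] <- 0; vz[noslip] <- 0
  new("FlowField", vx = vx, vy = vy, vz = vz,
      peakVelocityMs = peakVelocityMs, profile = profile)
}

.adjacentToNonBlood <- function(blood) {
  d <- dim(blood)
  out <- array(FALSE, d)
  nonblood <- !blood
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    s1 <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    s2 <- s1
    s1[[ax]] <- seq_len(n - 1L); s2[[ax]] <- 2:n
    a <- do.call(`[`, c(list(blood), s1, list(drop = FALSE))) &
      do.call(`[`, c(list(nonblood), s2, list(drop = FALSE)))
    b <- do.call(`[`, c(list(blood), s2, list(drop = FALSE))) &
      do.call(`[`, c(list(nonblood), s1, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), s1,
      list(do.call(`[`, c(list(out), s1, list(drop = FALSE))) | a)))
    out <- do.call(`[<-`, c(list(out), s2,
      list(do.call(`[`, c(list(out), s2, list(drop = FALSE))) | b)))
  }
  out
}

#' Joule heating source from a field solution
#'
#' q = dutyFactor * sigma * |E|^2 per voxel (W/m^3): the plateau resistive
#' heating scaled by the burst on-time fraction. The source is zero in
#' insulator and electrode voxels (perfect conductors carry no interior
#' field).
#'
#' @param sol A solved \linkS4class{FieldSolution}.
#' @param grid The corresponding \linkS4class{ScenarioGrid} (materials
#'   attached).
#' @param dutyFactor Burst on-time fraction in [0, 1]; see
#'   \code{\link{dutyPowerFactor}}.
#' @return 3D array of power density (W/m^3).
#' @export
jouleSource <- function(sol, grid, dutyFactor) {
  stopifnot(is(sol, "FieldSolution"), is(grid, "ScenarioGrid"),
            dutyFactor >= 0, dutyFactor <= 1)
  if (length(grid@materials) == 0L) grid <- assignMaterials(grid)
  eVm <- sol@eMag * 100          # V/cm -> V/m
  q <- dutyFactor * grid@materials$sigma * eVm^2
  q[grid@labels %in% .LBL[c("insulator", "electrode_line",
                            "electrode_neutral")]] <- 0
  q
}

## assemble the conduction operator: A (W/K, (A T)_i = sum_f g_f (T_i - T_j))
## and the heat capacity diagonal M = rho * cp * Vcell (J/K)
.thermalOperator <- function(grid) {
  mat <- grid@materials
  d <- dim(grid@labels)
  hM <- grid@spacingMm * 1e-3
  kv <- as.vector(mat$k)
  ti <- tj <- integer(0); tx <- numeric(0)
  for (ax in 1:3) {
    f <- .faceIndex(d, ax)
    g <- 2 * kv[f$p] * kv[f$q] / (kv[f$p] + kv[f$q]) * hM
    ti <- c(ti, f$p, f$q, f$p, f$q)
    tj <- c(tj, f$q, f$p, f$p, f$q)
    tx <- c(tx, -g, -g, g, g)
  }
  N <- prod(d)
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(N, N))
  M <- as.vector(mat$rho * mat$cp) * hM^3
  list(A = A, M = M)
}

## first-order upwind advection operator: (U T)_i approximates (u . grad T)_i
.advectionOperator <- function(flow, d, hM) {
  N <- prod(d)
  ti <- tj <- integer(0); tx <- numeric(0)
  vcomp <- list(as.vector(flow@vx), as.vector(flow@vy), as.vector(flow@vz))
  idx <- array(seq_len(N), d)
  for (ax in 1:3) {
    v <- vcomp[[ax]]
    act <- which(v != 0)
    if (!length(act)) next
    ijk <- arrayInd(act, d)
    up <- ijk
    up[, ax] <- up[, ax] - as.integer(sign(v[act]))
    ok <- up[, ax] >= 1L & up[, ax] <= d[ax]
    act <- act[ok]; up <- up[ok, , drop = FALSE]
    upLin <- idx[up]
    c0 <- abs(v[act]) / hM
    ti <- c(ti, act, act)
    tj <- c(tj, act, upLin)
    tx <- c(tx, c0, -c0)
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(N, N))
}

.boundaryShell <- function(d) {
  m <- array(FALSE, d)
  m[c(1, d[1]), , ] <- TRUE
  m[, c(1, d[2]), ] <- TRUE
  m[, , c(1, d[3])] <- TRUE
  m
}

#' Simulate the temperature transient of one gated burst
#'
#' Integrates rho*c dT/dt = div(k grad T) - rho_b c_b (u . grad T) + q with
#' the Joule source active only during \code{burstS}, then relaxes for
#' \code{relaxS}. Records probe series ("tissue_interface": hottest
#' myocardial voxel face-adjacent to an electrode; "blood": hottest blood
#' voxel; "domain_max") and the running peak-temperature map.
#'
#' @param grid A \linkS4class{ScenarioGrid} with materials attached.
#' @param source Per-voxel power density (W/m^3), see
#'   \code{\link{jouleSource}}; NULL for no source.
#' @param flow Optional \linkS4class{FlowField}.
#' @param burstS Burst duration (s), default 1e-4 (one 100 us burst).
#' @param relaxS Relaxation horizon (s), default 0.8 (one R-R interval at
#'   75 bpm).
#' @param dtBurstS Time step during the burst (s), default 1e-6.
#' @param dtRelaxS Time step during relaxation (s), default 1e-3.
#' @param scheme "implicit" (backward-Euler diffusion, unconditionally
#'   stable) or "explicit" (rejected with the stability bound if dt is too
#'   large).
#' @param boundary "baseline" (outer boundary held at baseline) or
#'   "adiabatic".
#' @param initialC Optional initial temperature array (deg C); defaults to
#'   uniform baseline.
#' @param perfusionW Volumetric blood-perfusion rate (1/s) applied in
#'   myocardium as a heat sink toward baseline; default 0 (single-burst,
#'   sub-second horizon).
#' @param tol Relative tolerance of the implicit conjugate-gradient solves.
#' @return A \linkS4class{ThermalTrace}.
#' @export
simulateTransient <- function(grid, source = NULL, flow = NULL,
                              burstS = 1e-4, relaxS = 0.8,
                              dtBurstS = 1e-6, dtRelaxS = 1e-3,
                              scheme = c("implicit", "explicit"),
                              boundary = c("baseline", "adiabatic"),
                              initialC = NULL, perfusionW = 0,
                              tol = 1e-8) {
  stopifnot(is(grid, "ScenarioGrid"))
  scheme <- match.arg(scheme)
  boundary <- match.arg(boundary)
  if (length(grid@materials) == 0L) grid <- assignMaterials(grid)
  mat <- grid@materials
  lab <- grid@labels
  d <- dim(lab)
  N <- prod(d)
  hM <- grid@spacingMm * 1e-3
  base <- mat$baselineC
  op <- .thermalOperator(grid)
  A <- op$A; M <- op$M
  U <- if (!is.null(flow)) .advectionOperator(flow, d, hM) else NULL
  qV <- if (!is.null(source)) as.vector(source) * hM^3 else NULL  # W per cell

  ## stability bounds
  dtDiffMax <- min(M / Matrix::diag(A))
  dtAdvMax <- if (!is.null(U)) {
    mx <- max(abs(flow@vx) + abs(flow@vy) + abs(flow@vz))
    if (mx > 0) hM / mx else Inf
  } else Inf
  for (dt in c(dtBurstS, dtRelaxS)) {
    if (scheme == "explicit" && dt > dtDiffMax)
      stop(sprintf("explicit diffusion unstable: dt = %g s exceeds bound %.3e s",
                   dt, dtDiffMax))
    if (dt > dtAdvMax)
      stop(sprintf("advection CFL violated: dt = %g s exceeds bound %.3e s",
                   dt, dtAdvMax))
  }

  Tv <- if (is.null(initialC)) rep(base, N) else as.vector(initialC)
  shell <- as.vector(.boundaryShell(d))
  if (boundary == "baseline") Tv[shell] <- base

  ## probe masks
  elec <- lab %in% .LBL[c("electrode_line", "electrode_neutral")]
  elecArr <- array(elec, d)
  iface <- as.vector(.adjacentToNonBlood(!elecArr) & lab == .LBL[["myocardium"]])
  ## (.adjacentToNonBlood on !elec marks non-electrode voxels adjacent to
  ## electrodes)
  if (!any(iface)) iface <- as.vector(lab == .LBL[["myocardium"]])
  bloodM <- as.vector(lab == .LBL[["blood"]])
  perf <- if (perfusionW > 0)
    perfusionW * 1050 * 3617 * as.numeric(as.vector(lab) == .LBL[["myocardium"]])
  else NULL

  nB <- max(0L, as.integer(round(burstS / dtBurstS)))
  nR <- max(0L, as.integer(round(relaxS / dtRelaxS)))
  nT <- nB + nR + 1L
  timeS <- numeric(nT)
  probes <- matrix(NA_real_, nT, 3,
                   dimnames = list(NULL, c("tissue_interface", "blood",
                                           "domain_max")))
  peak <- Tv
  rec <- function(i, t) {
    timeS[i] <<- t
    probes[i, ] <<- c(if (any(iface)) max(Tv[iface]) else NA_real_,
                      if (any(bloodM)) max(Tv[bloodM]) else NA_real_,
                      max(Tv))
  }
  rec(1L, 0)

  step <- function(dt, withSource) {
    rhs <- numeric(N)
    if (withSource && !is.null(qV)) rhs <- rhs + qV
    if (!is.null(perf)) rhs <- rhs - perf * (Tv - base) * hM^3
    if (!is.null(U)) rhs <- rhs - M * as.numeric(U %*% Tv)
    if (scheme == "implicit") {
      ## (M + dt A) T_new = M T + dt rhs
      b <- M * Tv + dt * rhs
      Tv <<- .pcgSolveShifted(A, M, dt, b, Tv, tol)
    } else {
      Tv <<- Tv + dt * (-as.numeric(A %*% Tv) + rhs) / M
    }
    if (boundary == "baseline") Tv[shell] <<- base
    if (anyNA(Tv) || any(!is.finite(Tv)))
      stop("thermal integration produced non-finite temperatures")
    peak <<- pmax(peak, Tv)
  }

  t <- 0
  i <- 1L
  if (nB > 0) for (s in seq_len(nB)) {
    step(dtBurstS, withSource = TRUE)
    t <- t + dtBurstS; i <- i + 1L
    rec(i, t)
  }
  if (nR > 0) for (s in seq_len(nR)) {
    step(dtRelaxS, withSource = FALSE)
    t <- t + dtRelaxS; i <- i + 1L
    rec(i, t)
  }
  new("ThermalTrace", timeS = timeS, probesC = probes,
      peakMapC = array(peak, d), finalC = array(Tv, d), baselineC = base,
      meta = list(burstS = burstS, relaxS = relaxS, dtBurstS = dtBurstS,
                  dtRelaxS = dtRelaxS, scheme = scheme, boundary = boundary,
                  dtDiffMax = dtDiffMax, dtAdvMax = dtAdvMax,
                  peakVelocityMs = if (!is.null(flow)) flow@peakVelocityMs
                  else 0))
}

## PCG for (M + dt A) x = b with Jacobi preconditioner, warm start x0
.pcgSolveShifted <- function(A, M, dt, b, x0, tol = 1e-8, maxIter = 2000L) {
  mv <- function(x) M * x + dt * as.numeric(A %*% x)
  x <- x0
  r <- b - mv(x)
  nb <- sqrt(sum(b * b))
  if (nb == 0) nb <- 1
  dinv <- 1 / (M + dt * Matrix::diag(A))
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  if (sqrt(sum(r * r)) / nb <= tol) return(x)
  for (it in seq_len(maxIter)) {
    Ap <- mv(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) / nb <= tol) return(x)
    z <- dinv * r
    rzn <- sum(r * z)
    p <- z + (rzn / rz) * p
    rz <- rzn
  }
  stop("implicit thermal solve did not converge")
}
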