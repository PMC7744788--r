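## Quasi-static conduction solver.
##
## Solves div(sigma grad phi) = 0 on the voxel grid with Dirichlet voltages
## on electrode voxels and zero-flux outer boundaries, by a 7-point
## finite-volume discretization with harmonic-mean face conductivities
## (flux-continuous across material interfaces) and a Jacobi-preconditioned
## conjugate-gradient solve. The solve is DC-equivalent at the burst plateau
## voltage: no 100 kHz dispersion or skin effect, which is consistent with
## reporting per-burst fields with static conductivities.

## face lists along one axis: linear indices of the two cells sharing each
## interior face
.faceIndex <- function(d, ax) {
  n <- d[ax]
  idx <- array(seq_len(prod(d)), d)
  take <- function(rng) {
    sel <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    sel[[ax]] <- rng
    as.vector(do.call(`[`, c(list(idx), sel)))
  }
  list(p = take(seq_len(n - 1L)), q = take(2:n))
}

#' Solve the quasi-static potential on a scenario grid
#'
#' Imposes \code{appliedVolts} on line-electrode voxels, 0 V on neutral
#' ones, zero normal flux on the outer boundary, and solves
#' div(sigma grad phi) = 0 over all remaining voxels. The field magnitude
#' is obtained by central differences (one-sided at boundaries), the
#' current density as sigma * E, and the total current by integrating the
#' conduction flux over the line-electrode surface.
#'
#' @param grid A \linkS4class{ScenarioGrid}; materials are attached with
#'   \code{\link{defaultMaterialTable}} defaults if absent.
#' @param appliedVolts Line-electrode voltage (V), >= 0.
#' @param tol Relative residual tolerance of the conjugate-gradient solve.
#' @param maxIter Iteration cap; exceeding it raises an error reporting the
#'   residual.
#' @return A \linkS4class{FieldSolution}.
#' @export
#' @examples
#' g <- buildSeptal(15, spacingMm = 1)
#' sol <- solvePotential(g, 1500)
#' sol
solvePotential <- function(grid, appliedVolts, tol = 1e-8, maxIter = 20000L) {
  stopifnot(is(grid, "ScenarioGrid"))
  if (appliedVolts < 0) stop("appliedVolts must be >= 0")
  if (length(grid@materials) == 0L)
    grid <- assignMaterials(grid)
  lab <- grid@labels
  d <- dim(lab)
  N <- prod(d)
  hM <- grid@spacingMm * 1e-3
  sigma <- grid@materials$sigma
  isLine <- lab == .LBL[["electrode_line"]]
  isNeut <- lab == .LBL[["electrode_neutral"]]
  dirich <- isLine | isNeut
  phiD <- numeric(N)
  phiD[isLine] <- appliedVolts
  unknown <- !dirich
  uId <- integer(N)
  uId[unknown] <- seq_len(sum(unknown))
  nU <- sum(unknown)

  ti <- tj <- integer(0); tx <- numeric(0)
  rhs <- numeric(nU)
  sv <- as.vector(sigma)
  for (ax in 1:3) {
    f <- .faceIndex(d, ax)
    keep <- unknown[f$p] | unknown[f$q]
    p <- f$p[keep]; q <- f$q[keep]
    g <- 2 * sv[p] * sv[q] / (sv[p] + sv[q]) * hM  # face conductance (S)
    pu <- unknown[p]; qu <- unknown[q]
    both <- pu & qu
    ## off-diagonal + diagonal couplings between two unknowns
    if (any(both)) {
      iP <- uId[p[both]]; iQ <- uId[q[both]]; gb <- g[both]
      ti <- c(ti, iP, iQ, iP, iQ)
      tj <- c(tj, iQ, iP, iP, iQ)
      tx <- c(tx, -gb, -gb, gb, gb)
    }
    ## unknown-Dirichlet faces: diagonal + RHS
    ud <- pu & !qu
    if (any(ud)) {
      iP <- uId[p[ud]]
      ti <- c(ti, iP); tj <- c(tj, iP); tx <- c(tx, g[ud])
      add <- rowsum(g[ud] * phiD[q[ud]], iP)
      rhs[as.integer(rownames(add))] <- rhs[as.integer(rownames(add))] + add[, 1]
    }
    du <- !pu & qu
    if (any(du)) {
      iQ <- uId[q[du]]
      ti <- c(ti, iQ); tj <- c(tj, iQ); tx <- c(tx, g[du])
      add <- rowsum(g[du] * phiD[p[du]], iQ)
      rhs[as.integer(rownames(add))] <- rhs[as.integer(rownames(add))] + add[, 1]
    }
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(nU, nU))
  rm(ti, tj, tx)

  x <- .pcgSolve(A, rhs, tol = tol, maxIter = maxIter)
  phi <- phiD
  phi[unknown] <- x$x
  phi <- array(phi, d)

  grad <- .centralGradient(phi, hM)               # V/m per component
  eMagVm <- sqrt(grad[[1]]^2 + grad[[2]]^2 + grad[[3]]^2)
  eMag <- eMagVm / 100                            # V/cm
  jMag <- sigma * eMagVm / 1000                   # kA/m^2

  cur <- .electrodeCurrents(phi, sv, unknown, isLine, isNeut, d, hM)
  new("FieldSolution", potential = phi, eMag = eMag, jMag = jMag,
      totalCurrentA = cur$line, appliedVolts = appliedVolts,
      residual = x$residual,
      currentBalance = cur$balance)
}

## Jacobi-preconditioned conjugate gradients for the SPD finite-volume system
.pcgSolve <- function(A, b, tol = 1e-8, maxIter = 20000L) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = numeric(length(b)), residual = 0))
  dinv <- 1 / Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxIter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / nb
    if (res <= tol)
      return(list(x = x, residual = res, iterations = it))
    z <- dinv * r
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  stop(sprintf("conduction solve did not converge: relative residual %.3e after %d iterations",
               res, maxIter))
}

.centralGradient <- function(phi, hM) {
  d <- dim(phi)
  lapply(1:3, function(ax) {
    n <- d[ax]
    sel <- function(rng) {
      s <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      s[[ax]] <- rng
      do.call(`[`, c(list(phi), s, list(drop = FALSE)))
    }
    g <- array(0, d)
    if (n >= 3) {
      mid <- (sel(3:n) - sel(seq_len(n - 2L))) / (2 * hM)
      s <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      s[[ax]] <- 2:(n - 1L)
      g <- do.call(`[<-`, c(list(g), s, list(mid)))
    }
    if (n >= 2) {
      s1 <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])); s1[[ax]] <- 1L
      g <- do.call(`[<-`, c(list(g), s1,
                            list((sel(2L) - sel(1L)) / hM)))
      sn <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])); sn[[ax]] <- n
      g <- do.call(`[<-`, c(list(g), sn,
                            list((sel(n) - sel(n - 1L)) / hM)))
    }
    g
  })
}

## conduction currents through electrode surfaces (A); positive out of the
## line electrodes, into the neutral ones
.electrodeCurrents <- function(phi, sv, unknown, isLine, isNeut, d, hM) {
  pv <- as.vector(phi)
  lineV <- as.vector(isLine); neutV <- as.vector(isNeut)
  iLine <- 0; iNeut <- 0
  for (ax in 1:3) {
    f <- .faceIndex(d, ax)
    g <- 2 * sv[f$p] * sv[f$q] / (sv[f$p] + sv[f$q]) * hM
    ## line -> non-electrode neighbours
    m <- lineV[f$p] & unknown[f$q]
    iLine <- iLine + sum(g[m] * (pv[f$p[m]] - pv[f$q[m]]))
    m <- lineV[f$q] & unknown[f$p]
    iLine <- iLine + sum(g[m] * (pv[f$q[m]] - pv[f$p[m]]))
    m <- neutV[f$p] & unknown[f$q]
    iNeut <- iNeut + sum(g[m] * (pv[f$q[m]] - pv[f$p[m]]))
    m <- neutV[f$q] & unknown[f$p]
    iNeut <- iNeut + sum(g[m] * (pv[f$p[m]] - pv[f$q[m]]))
  }
  bal <- if (max(abs(iLine), abs(iNeut)) > 0)
    abs(iLine - iNeut) / max(abs(iLine), abs(iNeut)) else 0
  list(line = iLine, neutral = iNeut, balance = bal)
}

#' Total delivered current and generator-compliance flag
#'
#' @param sol A solved \linkS4class{FieldSolution}.
#' @param grid The \linkS4class{ScenarioGrid} it was solved on (unused
#'   beyond interface symmetry; the current is integrated during the solve).
#' @param complianceA Generator current compliance (A), default 12.
#' @return List with \code{currentA} and \code{exceedsCompliance}.
#' @export
totalCurrent <- function(sol, grid, complianceA = 12) {
  stopifnot(is(sol, "FieldSolution"))
  list(currentA = sol@totalCurrentA,
       exceedsCompliance = sol@totalCurrentA > complianceA)
}

#' Field and current-density summary over a labeled region
#'
#' Masked statistics in the units a simulation summary table reports:
#' electric field max in kV/cm and mean in V/cm (both also returned in the
#' other unit), current density mean and max in kA/m^2.
#'
#' @param sol A solved \linkS4class{FieldSolution}.
#' @param grid The corresponding \linkS4class{ScenarioGrid}.
#' @param region Label name, e.g. "myocardium" or "blood".
#' @return List: \code{eMaxKVcm}, \code{eMaxVcm}, \code{eMeanVcm},
#'   \code{eMeanKVcm}, \code{jMeanKAm2}, \code{jMaxKAm2}, \code{nVoxels}.
#' @export
fieldMetrics <- function(sol, grid, region = "myocardium") {
  stopifnot(is(sol, "FieldSolution"), is(grid, "ScenarioGrid"))
  if (!region %in% names(.LBL)) stop(sprintf("unknown region '%s'", region))
  mask <- grid@labels == .LBL[[region]]
  if (!any(mask)) stop(sprintf("region '%s' is empty", region))
  e <- sol@eMag[mask]
  j <- sol@jMag[mask]
  list(eMaxKVcm = max(e) / 1000, eMaxVcm = max(e),
       eMeanVcm = mean(e), eMeanKVcm = mean(e) / 1000,
       jMeanKAm2 = mean(j), jMaxKAm2 = max(j),
       nVoxels = sum(mask))
}
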