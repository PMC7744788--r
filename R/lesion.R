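## Lesion-relevant derived metrics: temperature-decay fitting, field
## threshold extent (irreversible-electroporation radius), untreated gap
## between opposing electrodes, and misalignment sensitivity.

#' Fit an exponential decay to a post-burst temperature series
#'
#' Least-squares fit of T(t) = baseline + A * exp(-t/tau) on the stated
#' window (times are re-zeroed at the window start, which must contain the
#' peak). Nonlinear LS with a log-linear start.
#'
#' @param timeS Sample times (s).
#' @param tempC Temperatures (deg C).
#' @param window Optional c(t0, t1) fit window (s); default the full range.
#' @return A \linkS4class{DecayFit} (tau reported in ms).
#' @export
#' @examples
#' d <- genDecaySeries(noiseFrac = 0)
#' fitExponentialDecay(d$series$time_s, d$series$temp_c)
fitExponentialDecay <- function(timeS, tempC, window = NULL) {
  stopifnot(length(timeS) == length(tempC))
  if (!is.null(window)) {
    keep <- timeS >= window[1] & timeS <= window[2]
    timeS <- timeS[keep]; tempC <- tempC[keep]
  }
  if (length(timeS) < 10) stop("need >= 10 samples in the fit window")
  if (sd(tempC) < .Machine$double.eps^0.5 * max(1, abs(mean(tempC))))
    stop("constant series: tau is unidentifiable")
  o <- order(timeS)
  t <- timeS[o] - timeS[o][1]
  y <- tempC[o]
  nHead <- max(3L, ceiling(length(y) * 0.1))
  nTail <- max(3L, ceiling(length(y) * 0.1))
  if (mean(y[seq_len(nHead)]) <= mean(y[seq(length(y) - nTail + 1, length(y))]))
    stop("series does not decay: exponential-decay model rejected")
  b0 <- min(y)
  a0 <- max(y[1] - b0, .Machine$double.eps)
  pos <- y - b0 > a0 * 1e-3
  lf <- lm(log(y[pos] - b0 + a0 * 1e-6) ~ t[pos])
  tau0 <- unname(-1 / coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 3
  fit <- minpack.lm::nlsLM(
    y ~ b + A * exp(-t / tau),
    start = list(b = b0, A = a0, tau = tau0),
    lower = c(-Inf, 0, .Machine$double.eps),
    control = nls.control(maxiter = 200))
  cf <- coef(fit)
  ss <- sum(residuals(fit)^2)
  r2 <- 1 - ss / sum((y - mean(y))^2)
  new("DecayFit", amplitudeC = unname(cf["A"]), tauMs = unname(cf["tau"]) * 1000,
      baselineC = unname(cf["b"]), r2 = r2)
}

## coordinates (mm) of TRUE voxels in a mask
.maskCoordsMm <- function(mask, h) {
  idx <- which(mask, arr.ind = TRUE)
  (idx - 0.5) * h
}

## for each row of x, min Euclidean distance to rows of y (chunked)
.minDistMm <- function(x, y, chunk = 2048L) {
  n <- nrow(x)
  out <- numeric(n)
  y2 <- rowSums(y^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    xs <- x[s:e, , drop = FALSE]
    d2 <- outer(rowSums(xs^2), y2, `+`) - 2 * xs %*% t(y)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Effective irreversible-electroporation field radius
#'
#' Extent of the super-threshold tissue region. In "electrode_surface" mode
#' this is the maximum distance from the nearest electrode-surface voxel
#' over all myocardial voxels whose field exceeds the threshold (a discrete
#' distance-transform measure). In "inter_electrode" mode it is the
#' half-width of the super-threshold mask on the mid-plane between the two
#' closest opposite-polarity electrode groups.
#'
#' @param sol A solved \linkS4class{FieldSolution}.
#' @param grid The corresponding \linkS4class{ScenarioGrid}.
#' @param thresholdVcm Field threshold (V/cm), default 400 (muscle
#'   irreversible-electroporation threshold).
#' @param reference "electrode_surface" or "inter_electrode".
#' @return Radius (mm); 0 for an empty super-threshold mask.
#' @export
effectiveFieldRadius <- function(sol, grid, thresholdVcm = 400,
                                 reference = c("electrode_surface",
                                               "inter_electrode")) {
  stopifnot(is(sol, "FieldSolution"), is(grid, "ScenarioGrid"),
            thresholdVcm > 0)
  reference <- match.arg(reference)
  h <- grid@spacingMm
  lab <- grid@labels
  mask <- lab == .LBL[["myocardium"]] & sol@eMag >= thresholdVcm
  if (!any(mask)) return(0)
  elec <- lab %in% .LBL[c("electrode_line", "electrode_neutral")]
  elecArr <- array(elec, dim(lab))
  if (reference == "electrode_surface") {
    ## only electrode voxels on the electrode surface matter
    surf <- elecArr & .adjacentToNonBlood(elecArr)
    if (!any(surf)) surf <- elecArr
    max(.minDistMm(.maskCoordsMm(mask, h), .maskCoordsMm(surf, h)))
  } else {
    gi <- grid@groups
    cents <- lapply(sort(unique(gi[gi > 0L])), function(g)
      colMeans(.maskCoordsMm(gi == g, h)))
    pol <- grid@groupPolarity
    pairs <- expand.grid(a = seq_along(cents), b = seq_along(cents))
    pairs <- pairs[pol[pairs$a] == "line" & pol[pairs$b] == "neutral", ]
    if (nrow(pairs) == 0L) stop("no line/neutral electrode pair found")
    dd <- vapply(seq_len(nrow(pairs)), function(r)
      sqrt(sum((cents[[pairs$a[r]]] - cents[[pairs$b[r]]])^2)), numeric(1))
    best <- pairs[which.min(dd), ]
    c1 <- cents[[best$a]]; c2 <- cents[[best$b]]
    u <- (c2 - c1) / sqrt(sum((c2 - c1)^2))
    m <- (c1 + c2) / 2
    xm <- .maskCoordsMm(mask, h)
    s <- as.numeric((xm - matrix(m, nrow(xm), 3, byrow = TRUE)) %*% u)
    onPlane <- abs(s) <= h / 2
    if (!any(onPlane)) return(0)
    xp <- xm[onPlane, , drop = FALSE]
    dv <- xp - matrix(m, nrow(xp), 3, byrow = TRUE)
    max(sqrt(rowSums(dv^2) - s[onPlane]^2))
  }
}

#' Longest untreated myocardial span between opposing electrodes
#'
#' Samples the inter-electrode axis (line-electrode centroid to
#' neutral-electrode centroid by default) and returns the longest
#' contiguous run of myocardial samples whose field stays below the
#' threshold, in mm.
#'
#' @param sol A solved \linkS4class{FieldSolution}.
#' @param grid A septal-style two-electrode \linkS4class{ScenarioGrid}.
#' @param thresholdVcm Field threshold (V/cm), default 400.
#' @param axis Optional list(p0, p1) of segment endpoints (mm) overriding
#'   the electrode centroids.
#' @return Gap length (mm); 0 when the whole span is treated.
#' @export
untreatedGap <- function(sol, grid, thresholdVcm = 400, axis = NULL) {
  stopifnot(is(sol, "FieldSolution"), is(grid, "ScenarioGrid"))
  h <- grid@spacingMm
  lab <- grid@labels
  if (is.null(axis)) {
    gi <- grid@groups
    pol <- grid@groupPolarity
    lineIds <- which(pol == "line"); neutIds <- which(pol == "neutral")
    if (!length(lineIds) || !length(neutIds))
      stop("grid lacks a line/neutral electrode pair")
    p0 <- colMeans(.maskCoordsMm(gi == lineIds[1], h))
    p1 <- colMeans(.maskCoordsMm(gi == neutIds[1], h))
  } else {
    p0 <- axis$p0; p1 <- axis$p1
  }
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) stop("degenerate axis")
  stepMm <- h / 2
  tt <- seq(0, 1, by = stepMm / L)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]),
               p0[2] + tt * (p1[2] - p0[2]),
               p0[3] + tt * (p1[3] - p0[3]))
  d <- dim(lab)
  ijk <- pmin(pmax(ceiling(pts / h), 1L),
              matrix(d, nrow(pts), 3, byrow = TRUE))
  lin <- cbind(ijk[, 1], ijk[, 2], ijk[, 3])
  labAt <- lab[lin]
  eAt <- sol@eMag[lin]
  inMyo <- labAt == .LBL[["myocardium"]]
  if (!any(inMyo)) stop("axis misses the myocardium")
  sub <- inMyo & (eAt < thresholdVcm)
  r <- rle(sub)
  if (!any(r$values)) return(0)
  max(r$lengths[r$values]) * stepMm
}

#' Coefficient of variation of lesion radii across alignments
#'
#' Sample SD divided by the mean, in percent: the sensitivity of the
#' effective radius (or any scalar lesion metric) to catheter misalignment.
#'
#' @param values Numeric vector (>= 2 values).
#' @return CV in percent.
#' @export
#' @examples
#' alignmentSensitivity(c(5.0, 5.5, 4.5, 5.0))  # ~8.16
alignmentSensitivity <- function(values) {
  if (length(values) < 2) stop("need >= 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero: CV undefined")
  sd(values) / m * 100
}

#' Assemble a lesion report for one solved scenario
#'
#' Bundles the summary-table fields (applied voltage, field and
#' current-density statistics, peak interface temperature) with the
#' effective radius, the untreated gap (septal grids) and an optional decay
#' fit.
#'
#' @param grid A \linkS4class{ScenarioGrid}.
#' @param sol A solved \linkS4class{FieldSolution}.
#' @param trace Optional \linkS4class{ThermalTrace}.
#' @param decay Optional \linkS4class{DecayFit}.
#' @param thresholdVcm Field threshold (V/cm), default 400.
#' @return List of metrics (class "lesionReport").
#' @export
lesionReport <- function(grid, sol, trace = NULL, decay = NULL,
                         thresholdVcm = 400) {
  stopifnot(is(grid, "ScenarioGrid"), is(sol, "FieldSolution"))
  conductive <- grid@labels %in% .LBL[c("blood", "myocardium")]
  e <- sol@eMag[conductive]; j <- sol@jMag[conductive]
  rep <- list(
    scenario = grid@kind,
    voltageAppliedV = sol@appliedVolts,
    eFieldMaxKVcm = max(e) / 1000,
    eFieldMeanVcm = mean(e),
    jMeanKAm2 = mean(j),
    jMaxKAm2 = max(j),
    tInterfaceMaxC = if (!is.null(trace))
      max(trace@probesC[, "tissue_interface"]) else NA_real_,
    effectiveRadiusMm = effectiveFieldRadius(sol, grid, thresholdVcm),
    untreatedGapMm = if (grid@kind == "septal")
      untreatedGap(sol, grid, thresholdVcm) else NA_real_,
    thresholdVcm = thresholdVcm,
    totalCurrentA = sol@totalCurrentA,
    decay = if (!is.null(decay))
      list(amplitudeC = decay@amplitudeC, tauMs = decay@tauMs,
           baselineC = decay@baselineC, r2 = decay@r2) else NULL)
  class(rep) <- c("lesionReport", "list")
  rep
}
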