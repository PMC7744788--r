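## Study outcome estimators: segmentation volumetrics, the ablated-fraction
## subtraction estimator, the extruded-cylinder reference ratio, and the
## electrophysiology statistics.

#' Round half away from zero
#'
#' Fixed-digit rounding with ties going away from zero (the convention used
#' for printed-value comparison), unlike \code{round()}'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric.
#' @export
#' @examples
#' roundHalfAway(11.025, 2)  # 11.03
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Myocardial / non-myocardial volume fractions of a segmentation
#'
#' Computes the myocardial volume percentage
#' v = (Vtot - Vnonmyo) / Vtot * 100 of a labeled specimen, where Vtot is
#' the full specimen volume (myocardium + non-myocardial tissue; background
#' excluded) and Vnonmyo the non-myocardial part, plus its complement
#' nonmyo = 100 - v, globally and per axial slice.
#'
#' @param seg A \linkS4class{SegmentationVolume}.
#' @return List with \code{vPct} (myocardial %), \code{nonmyoPct}
#'   (non-myocardial %), \code{vtotMm3}, \code{vnonmyoMm3}, and
#'   \code{perSlice} (data.frame: slice, v_pct, nonmyo_pct; NA for empty
#'   slices).
#' @export
#' @examples
#' seg <- genSegmentation(dims = c(32, 32, 20), lesionFraction = 0.11, seed = 1)
#' volumeFractions(seg)$nonmyoPct
volumeFractions <- function(seg) {
  stopifnot(is(seg, "SegmentationVolume"))
  validObject(seg)
  lab <- seg@labels
  voxMm3 <- seg@voxelMm^2 * seg@sliceMm
  nTot <- sum(lab > 0L)
  if (nTot == 0L) stop("zero specimen volume")
  nNon <- sum(lab == 2L)
  vPct <- (nTot - nNon) / nTot * 100
  nSl <- dim(lab)[3]
  sliceTot <- vapply(seq_len(nSl), function(k) sum(lab[, , k] > 0L), numeric(1))
  sliceNon <- vapply(seq_len(nSl), function(k) sum(lab[, , k] == 2L), numeric(1))
  sliceV <- ifelse(sliceTot > 0, (sliceTot - sliceNon) / sliceTot * 100, NA_real_)
  list(vPct = vPct, nonmyoPct = 100 - vPct,
       vtotMm3 = nTot * voxMm3, vnonmyoMm3 = nNon * voxMm3,
       perSlice = data.frame(slice = seq_len(nSl), v_pct = sliceV,
                             nonmyo_pct = 100 - sliceV))
}

#' Ablated volume percentage by control subtraction
#'
#' Subtracts the non-myocardial percentage of an age-matched non-ablated
#' control from that of a treated specimen, leaving the ablation-derived
#' part. A negative result (control above treated) is possible and flagged
#' with a warning.
#'
#' @param nonmyoPct Treated-specimen non-myocardial percentage.
#' @param controlNonmyoPct Control non-myocardial percentage.
#' @param digits If non-NULL, round half away from zero to this many digits.
#' @return Ablated volume percentage.
#' @export
#' @examples
#' ablatedFraction(20.25, 9.225, digits = 2)  # 11.03
ablatedFraction <- function(nonmyoPct, controlNonmyoPct, digits = NULL) {
  stopifnot(nonmyoPct >= 0, nonmyoPct <= 100,
            controlNonmyoPct >= 0, controlNonmyoPct <= 100)
  out <- nonmyoPct - controlNonmyoPct
  if (out < 0)
    warning("ablated fraction is negative (control exceeds treated)")
  if (!is.null(digits)) out <- roundHalfAway(out, digits)
  out
}

## in-plane maximal inscribed width (mm) of the specimen in one slice:
## 2 * max distance from a specimen voxel center to the nearest background
## voxel center (volume edges count as background), minus one voxel
.sliceThicknessMm <- function(sliceLab, voxelMm) {
  spec <- which(sliceLab > 0L, arr.ind = TRUE)
  if (nrow(spec) == 0L) return(NA_real_)
  d <- dim(sliceLab)
  bg <- which(sliceLab == 0L, arr.ind = TRUE)
  ## virtual background ring one voxel outside the slice
  edge <- rbind(
    cbind(0L, 0:(d[2] + 1L)), cbind(d[1] + 1L, 0:(d[2] + 1L)),
    cbind(1:d[1], 0L), cbind(1:d[1], d[2] + 1L))
  bg <- rbind(bg, edge)
  dmin <- vapply(seq_len(nrow(spec)), function(i) {
    dx <- bg[, 1] - spec[i, 1]
    dy <- bg[, 2] - spec[i, 2]
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1))
  (2 * max(dmin) - 1) * voxelMm
}

#' Ablated volume relative to the extruded loop-catheter cylinder
#'
#' Individual-specific reference: the cylinder obtained by extruding the
#' loop catheter footprint, pi * (d/2)^2, along the thickest section of the
#' wall (the maximum per-slice inscribed wall width). The ratio is the
#' ablated volume divided by this reference cylinder.
#'
#' @param seg A \linkS4class{SegmentationVolume} (provides wall thickness).
#' @param ablatedVolumeMm3 Ablated volume (mm^3).
#' @param loopDiameterMm Loop catheter diameter (mm).
#' @return List with \code{ratio}, \code{referenceMm3} and
#'   \code{maxWallMm}.
#' @export
extrusionReferenceRatio <- function(seg, ablatedVolumeMm3, loopDiameterMm) {
  stopifnot(is(seg, "SegmentationVolume"), loopDiameterMm > 0,
            ablatedVolumeMm3 >= 0)
  lab <- seg@labels
  th <- vapply(seq_len(dim(lab)[3]),
               function(k) .sliceThicknessMm(lab[, , k], seg@voxelMm),
               numeric(1))
  maxWall <- suppressWarnings(max(th, na.rm = TRUE))
  if (!is.finite(maxWall) || maxWall <= 0)
    stop("zero wall thickness: specimen has no measurable wall")
  ref <- pi * (loopDiameterMm / 2)^2 * maxWall
  list(ratio = ablatedVolumeMm3 / ref, referenceMm3 = ref, maxWallMm = maxWall)
}

#' One-sample t test from summary statistics
#'
#' t = (mean - mu0) / (sd / sqrt(n)) with two-sided p from the t
#' distribution on n - 1 degrees of freedom, for use when only printed
#' summary statistics are available.
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation.
#' @param n Sample size (>= 2).
#' @param mu0 Null value.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
#' @examples
#' oneSampleTSummary(20.25, 4.40, 5, 9.225)$p  # ~0.005
oneSampleTSummary <- function(mean, sd, n, mu0) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) {
    if (mean == mu0) return(list(t = 0, df = n - 1, p = 1))
    warning("sd = 0 with mean != mu0: p set to 0 by convention")
    return(list(t = sign(mean - mu0) * Inf, df = n - 1, p = 0))
  }
  tstat <- (mean - mu0) / (sd / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), df = n - 1))
}

#' Paired pre/post change statistics for an electrogram cohort
#'
#' Per-pair deltas (post - pre) with a two-sided paired t test; a Welch
#' (unequal-variance, unpaired) variant is selectable for cohorts where
#' pairing is broken.
#'
#' @param samples data.frame as produced by \code{\link{genEgmCohort}} (or a
#'   CSV read into the same columns): \code{<metric>_pre_*} and
#'   \code{<metric>_post_*}.
#' @param metric One of "amplitude", "duration", "impedance".
#' @param welch If TRUE use Welch's unpaired unequal-variance test instead
#'   of the paired test.
#' @return List with \code{meanDelta}, \code{sdDelta}, \code{n}, \code{p},
#'   \code{method}.
#' @export
#' @examples
#' cohort <- genEgmCohort(30, seed = 1)
#' pairedChangeStats(cohort$samples, "amplitude")$p
pairedChangeStats <- function(samples, metric = c("amplitude", "duration",
                                                  "impedance"),
                              welch = FALSE) {
  metric <- match.arg(metric)
  cols <- grep(paste0("^", metric, "_(pre|post)_"), colnames(samples),
               value = TRUE)
  pre <- samples[[grep("_pre_", cols, value = TRUE)]]
  post <- samples[[grep("_post_", cols, value = TRUE)]]
  if (is.null(pre) || is.null(post))
    stop(sprintf("columns for metric '%s' not found", metric))
  keep <- complete.cases(pre, post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 2) stop("need at least 2 paired records")
  delta <- post - pre
  if (all(delta == 0)) {
    p <- 1
    method <- "paired t (degenerate: all deltas zero)"
  } else if (welch) {
    p <- t.test(post, pre, var.equal = FALSE)$p.value
    method <- "Welch two-sample t"
  } else {
    p <- t.test(post, pre, paired = TRUE)$p.value
    method <- "paired t"
  }
  list(meanDelta = mean(delta), sdDelta = sd(delta), n = n, p = p,
       method = method)
}

#' Kruskal-Wallis omnibus with Dunn's post hoc comparisons
#'
#' Rank-based omnibus test across >= 3 groups (tie-corrected H via
#' \code{kruskal.test}) followed by Dunn's pairwise z tests on mean ranks
#' with tie correction and Bonferroni adjustment over all pairs.
#'
#' @param groups Named (or unnamed) list of numeric vectors, each of length
#'   >= 2.
#' @return List with \code{H}, \code{omnibusP} and \code{pairs} (data.frame:
#'   group1, group2, z, p, pAdjusted).
#' @export
#' @examples
#' g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(12, 13, 14, 15))
#' kruskalDunn(g)$omnibusP
kruskalDunn <- function(groups) {
  if (length(groups) < 3) stop("need >= 3 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  N <- length(x)
  if (length(unique(x)) == 1L) {
    pairsIdx <- utils::combn(names(groups), 2)
    return(list(H = 0, omnibusP = 1,
                pairs = data.frame(group1 = pairsIdx[1, ],
                                   group2 = pairsIdx[2, ],
                                   z = 0, p = 1, pAdjusted = 1)))
  }
  kw <- kruskal.test(x, g)
  rk <- rank(x)
  meanRank <- tapply(rk, g, mean)
  ni <- tapply(rk, g, length)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairsIdx <- utils::combn(names(groups), 2)
  m <- ncol(pairsIdx)
  z <- p <- numeric(m)
  for (k in seq_len(m)) {
    i <- pairsIdx[1, k]; j <- pairsIdx[2, k]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ni[[i]] + 1 / ni[[j]]))
    z[k] <- (meanRank[[i]] - meanRank[[j]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  list(H = unname(kw$statistic), omnibusP = kw$p.value,
       pairs = data.frame(group1 = pairsIdx[1, ], group2 = pairsIdx[2, ],
                          z = z, p = p, pAdjusted = pmin(1, p * m)))
}
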