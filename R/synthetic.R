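## Synthetic-data generators: every downstream stage has a generator that
## produces a valid input with known ground truth, so the whole pipeline is
## testable without external data. All generators are seed-deterministic.

#' Generate a synthetic gated-ablation ECG trace
#'
#' Minimal lead-III-like trace for gating work: Gaussian R spikes at a fixed
#' sinus rate plus additive Gaussian noise. Morphology is deliberately
#' minimal (gating only needs R peaks); an optional T-wave bump supports
#' gating-failure experiments. The first beat falls half an R-R interval
#' into the trace.
#'
#' @param bpm Sinus rate (beats/min); default 69, a typical anesthetized
#'   porcine rate.
#' @param durationS Trace duration (s).
#' @param noiseSdMv Additive noise SD (mV).
#' @param seed Integer seed (NULL to leave the RNG alone).
#' @param sampleRateHz Sampling rate (Hz), default 1000.
#' @param rAmplitudeMv R-spike amplitude (mV), default 1.
#' @param rWidthS Gaussian R-spike SD (s), default 0.01.
#' @param tWaveAmplitudeMv Optional T-wave bump amplitude (mV), default 0.
#' @return List with \code{trace} (data.frame \code{time_s}, \code{ecg_mv}),
#'   \code{peaksS} (true R-peak times), and the generating parameters.
#' @export
#' @examples
#' e <- genEcg(bpm = 75, durationS = 8, noiseSdMv = 0, seed = 1)
#' length(e$peaksS)  # 10 beats in 8 s at 75 bpm
genEcg <- function(bpm = 69, durationS = 10, noiseSdMv = 0, seed = NULL,
                   sampleRateHz = 1000, rAmplitudeMv = 1, rWidthS = 0.01,
                   tWaveAmplitudeMv = 0) {
  stopifnot(bpm > 0, durationS > 0, sampleRateHz > 0)
  if (!is.null(seed)) set.seed(seed)
  rr <- 60 / bpm
  t <- seq(0, durationS - 1 / sampleRateHz, by = 1 / sampleRateHz)
  peaks <- seq(rr / 2, durationS, by = rr)
  peaks <- peaks[peaks <= durationS - rr / 4]
  v <- numeric(length(t))
  for (pk in peaks)
    v <- v + rAmplitudeMv * exp(-(t - pk)^2 / (2 * rWidthS^2))
  if (tWaveAmplitudeMv > 0)
    for (pk in peaks)
      v <- v + tWaveAmplitudeMv * exp(-(t - pk - 0.3)^2 / (2 * 0.05^2))
  if (noiseSdMv > 0)
    v <- v + rnorm(length(t), 0, noiseSdMv)
  list(trace = data.frame(time_s = t, ecg_mv = v),
       peaksS = peaks, bpm = bpm, durationS = durationS,
       noiseSdMv = noiseSdMv, sampleRateHz = sampleRateHz, seed = seed)
}

## sample `count` distinct entries from a logical mask, growing contiguous
## patches by face-neighbor accretion
.growPatch <- function(allowed, dims, start, count) {
  nb <- function(i) {
    ijk <- arrayInd(i, dims)
    out <- integer(0)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      p <- ijk
      p[ax] <- p[ax] + s
      if (p[ax] >= 1L && p[ax] <= dims[ax])
        out <- c(out, p[1] + (p[2] - 1L) * dims[1] +
                   (p[3] - 1L) * dims[1] * dims[2])
    }
    out
  }
  patch <- logical(prod(dims))
  patch[start] <- TRUE
  frontier <- setdiff(nb(start), start)
  frontier <- frontier[allowed[frontier]]
  got <- 1L
  while (got < count && length(frontier)) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    frontier <- frontier[frontier != pick]
    if (!patch[pick]) {
      patch[pick] <- TRUE
      got <- got + 1L
      cand <- nb(pick)
      cand <- cand[allowed[cand] & !patch[cand]]
      frontier <- c(frontier, cand)
    }
  }
  which(patch)
}

#' Generate a labeled atrial-wall-like segmentation volume
#'
#' Builds a shell-shaped myocardial specimen (a spherical-shell section of
#' stated wall thickness) and injects two kinds of non-myocardial tissue:
#' contiguous lesion-like patches grown by seeded region accretion
#' (transmural-scar-like), totalling fraction \code{lesionFraction} of the
#' specimen, and dispersed native non-myocardium (connective-lining-like)
#' totalling \code{nativeFraction}. Ground truth is recorded on the object.
#'
#' @param dims Volume dimensions (voxels), slices along the third axis.
#' @param wallMm Wall thickness (mm); default 5.85, a typical porcine atrial
#'   mean.
#' @param voxelMm In-plane voxel size (mm).
#' @param sliceMm Slice thickness (mm), default 1.
#' @param lesionFraction Fraction of specimen voxels converted to contiguous
#'   lesion patches.
#' @param nativeFraction Fraction converted to dispersed native
#'   non-myocardium; default 0.09225, a typical healthy-control level.
#' @param nPatches Number of lesion patches, default 3.
#' @param shape "shell" (curved spherical-shell section, the default) or
#'   "slab" (an opened-flat wall: an in-plane band of the stated thickness,
#'   convenient when exact per-slice thickness matters).
#' @param seed Integer seed.
#' @return A \linkS4class{SegmentationVolume}; \code{object@truth} holds the
#'   injected fractions.
#' @export
#' @examples
#' seg <- genSegmentation(dims = c(32, 32, 20), lesionFraction = 0.11, seed = 7)
#' volumeFractions(seg)$nonmyoPct
genSegmentation <- function(dims = c(48, 48, 30), wallMm = 5.85,
                            voxelMm = 0.5, sliceMm = 1,
                            lesionFraction = 0, nativeFraction = 0.09225,
                            nPatches = 3L, shape = c("shell", "slab"),
                            seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(dims) == 3, all(dims > 3), wallMm > 0,
            lesionFraction >= 0, nativeFraction >= 0)
  if (lesionFraction + nativeFraction >= 1)
    stop("lesionFraction + nativeFraction must be < 1")
  if (!is.null(seed)) set.seed(seed)
  sp <- c(voxelMm, voxelMm, sliceMm)
  ext <- dims * sp
  ctr <- ext / 2
  x <- (seq_len(dims[1]) - 0.5) * sp[1]
  lab <- array(0L, dims)
  if (shape == "shell") {
    halfmin <- min(ext) / 2
    r0 <- halfmin - wallMm - 2 * max(sp)
    if (r0 <= 2 * max(sp))
      stop("volume too small for the requested wall thickness")
    y <- (seq_len(dims[2]) - 0.5) * sp[2]
    z <- (seq_len(dims[3]) - 0.5) * sp[3]
    r <- sqrt(outer(outer((x - ctr[1])^2, (y - ctr[2])^2, `+`),
                    (z - ctr[3])^2, `+`))
    lab[r >= r0 & r <= r0 + wallMm] <- 1L
  } else {
    if (wallMm >= ext[1] - 2 * voxelMm)
      stop("volume too small for the requested wall thickness")
    band <- abs(x - ctr[1]) <= wallMm / 2
    lab[band, , ] <- 1L
  }
  specimen <- which(lab == 1L)
  n <- length(specimen)
  if (n == 0L) stop("degenerate shell: no specimen voxels")
  allowed <- lab == 1L
  nLesion <- round(lesionFraction * n)
  if (nLesion > 0) {
    per <- diff(round(seq(0, nLesion, length.out = nPatches + 1L)))
    for (k in seq_len(nPatches)) {
      if (per[k] == 0) next
      open <- which(allowed & lab != 2L)
      start <- open[sample.int(length(open), 1L)]
      idx <- .growPatch(allowed & lab != 2L, dims, start, per[k])
      lab[idx] <- 2L
    }
  }
  nNative <- round(nativeFraction * n)
  if (nNative > 0) {
    open <- which(lab == 1L)
    lab[open[sample.int(length(open), nNative)]] <- 2L
  }
  SegmentationVolume(lab, voxelMm = voxelMm, sliceMm = sliceMm,
    truth = list(lesionFraction = lesionFraction,
                 nativeFraction = nativeFraction,
                 nonmyoFraction = (nLesion + nNative) / n,
                 wallMm = wallMm, nSpecimen = n, seed = seed))
}

#' Generate a paired pre/post electrogram cohort
#'
#' Draws paired electrogram records with stated means and SDs for amplitude,
#' duration and impedance, truncated at zero. Defaults follow typical
#' left-atrial AC-PFA effect sizes: amplitude 2.20 +/- 0.84 mV falling to
#' 0.61 +/- 0.18 mV, duration 45.29 +/- 8.1 ms lengthening to
#' 58.38 +/- 12.61 ms, and an impedance drop of 31.75 +/- 13.92 Ohm at
#' 100 Hz from a nominal 110 +/- 15 Ohm baseline.
#'
#' @param n Cohort size (>= 2).
#' @param params List of c(mean, sd) pairs: \code{amplitudePre/Post} (mV),
#'   \code{durationPre/Post} (ms), \code{impedancePre} (Ohm) and
#'   \code{impedanceDelta} (Ohm, applied additively to pre).
#' @param seed Integer seed.
#' @return List with \code{samples} (data.frame, one row per subject, pre
#'   and post columns per metric) and \code{truth} (the parameters used).
#' @export
#' @examples
#' cohort <- genEgmCohort(10, seed = 42)
#' head(cohort$samples)
genEgmCohort <- function(n,
                         params = list(
                           amplitudePre  = c(2.20, 0.84),
                           amplitudePost = c(0.61, 0.18),
                           durationPre   = c(45.29, 8.1),
                           durationPost  = c(58.38, 12.61),
                           impedancePre  = c(110, 15),
                           impedanceDelta = c(-31.75, 13.92)),
                         seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  rtrunc <- function(n, ms) {   # positive-truncated normal by rejection
    out <- rnorm(n, ms[1], ms[2])
    bad <- which(out <= 0)
    while (length(bad)) {
      out[bad] <- rnorm(length(bad), ms[1], ms[2])
      bad <- bad[out[bad] <= 0]
    }
    out
  }
  pre_imp <- rtrunc(n, params$impedancePre)
  samples <- data.frame(
    id = seq_len(n),
    amplitude_pre_mv  = rtrunc(n, params$amplitudePre),
    amplitude_post_mv = rtrunc(n, params$amplitudePost),
    duration_pre_ms   = rtrunc(n, params$durationPre),
    duration_post_ms  = rtrunc(n, params$durationPost),
    impedance_pre_ohm  = pre_imp,
    impedance_post_ohm = pre_imp +
      rnorm(n, params$impedanceDelta[1], params$impedanceDelta[2]))
  list(samples = samples, truth = params, seed = seed)
}

#' Generate a noisy exponential temperature-decay series
#'
#' T(t) = baseline + A * exp(-t/tau) * (1 + eps), eps ~ N(0, noiseFrac).
#' Defaults reproduce a tissue-probe relaxation after one AC burst
#' (A = 7.6 C, tau = 9.22 ms).
#'
#' @param amplitudeC Peak temperature excess A (deg C).
#' @param tauMs Decay constant (ms).
#' @param baselineC Baseline temperature (deg C), default 37.
#' @param noiseFrac Multiplicative noise SD on the decaying term.
#' @param dtMs Sample interval (ms), default 0.1.
#' @param durationMs Series length (ms); default 5 * tau.
#' @param seed Integer seed.
#' @return List with \code{series} (data.frame \code{time_s},
#'   \code{temp_c}) and \code{truth}.
#' @export
#' @examples
#' d <- genDecaySeries(seed = 1)
#' head(d$series)
genDecaySeries <- function(amplitudeC = 7.6, tauMs = 9.22, baselineC = 37,
                           noiseFrac = 0, dtMs = 0.1, durationMs = 5 * tauMs,
                           seed = NULL) {
  stopifnot(tauMs > 0, dtMs > 0, amplitudeC >= 0)
  if (!is.null(seed)) set.seed(seed)
  tMs <- seq(0, durationMs, by = dtMs)
  decay <- amplitudeC * exp(-tMs / tauMs)
  if (noiseFrac > 0)
    decay <- decay * (1 + rnorm(length(tMs), 0, noiseFrac))
  list(series = data.frame(time_s = tMs / 1000, temp_c = baselineC + decay),
       truth = list(amplitudeC = amplitudeC, tauMs = tauMs,
                    baselineC = baselineC, noiseFrac = noiseFrac,
                    seed = seed))
}
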