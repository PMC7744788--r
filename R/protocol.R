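## Protocol layer: AC burst waveform synthesis and ECG-gated scheduling.

#' Synthesize the sampled AC burst waveform
#'
#' Builds the bipolar square burst described by a \linkS4class{BurstSpec}.
#' Each oscillation period is laid out as: +V for \code{duty}/2 of the
#' period, off, -V for \code{duty}/2, off. With \code{duty = 1} the burst is
#' a continuous bipolar square wave; with the default \code{duty = 0.5} the
#' voltage is applied half of the time, so \code{duty} is a true power
#' fraction. Samples are taken at cell-centred times, which makes the
#' discrete time-integral of the waveform exactly zero (charge balance).
#'
#' @param spec A \linkS4class{BurstSpec}.
#' @param sampleRateHz Sampling rate (Hz); must be at least 20x the internal
#'   frequency so each on-phase holds at least two samples.
#' @return A data.frame with columns \code{time_s} and \code{voltage_v};
#'   \code{nrow = durationUs * 1e-6 * sampleRateHz}.
#' @export
#' @examples
#' w <- synthesizeBurst(BurstSpec(900), sampleRateHz = 1e7)
#' nrow(w)            # 1000 samples for 100 us at 10 MHz
#' range(w$voltage_v) # -900 .. 900
#' sum(w$voltage_v)   # 0: charge balanced
synthesizeBurst <- function(spec, sampleRateHz) {
  stopifnot(is(spec, "BurstSpec"))
  validObject(spec)
  fHz <- spec@internalFreqKhz * 1000
  if (sampleRateHz < 20 * fHz)
    stop("sampleRateHz must be >= 20x the internal frequency (undersampled)")
  durS <- spec@durationUs * 1e-6
  n <- durS * sampleRateHz
  if (abs(n - round(n)) > 1e-6)
    stop("burst duration must hold a whole number of samples at this rate")
  n <- as.integer(round(n))
  t <- (seq_len(n) - 0.5) / sampleRateHz
  phase <- (t * fHz) %% 1
  d2 <- spec@duty / 2
  v <- numeric(n)
  v[phase < d2] <- spec@amplitudeVolts
  v[phase >= 0.5 & phase < 0.5 + d2] <- -spec@amplitudeVolts
  data.frame(time_s = t, voltage_v = v)
}

#' Time-averaged Joule scaling of the burst waveform
#'
#' Mean of (v(t)/V)^2 over one burst: the factor by which the plateau Joule
#' power density sigma*|E|^2 must be scaled to obtain the burst-averaged
#' heating. For the square on/off waveform this equals the duty fraction.
#'
#' @param spec A \linkS4class{BurstSpec}.
#' @return Dimensionless fraction in (0, 1].
#' @export
#' @examples
#' dutyPowerFactor(BurstSpec(900, duty = 0.5))  # 0.5
dutyPowerFactor <- function(spec) {
  stopifnot(is(spec, "BurstSpec"))
  validObject(spec)
  spec@duty
}

#' Detect R peaks on an ECG trace
#'
#' Threshold detector mirroring a hardware QRS gating circuit: each
#' contiguous over-threshold excursion yields one peak (the local maximum of
#' the excursion), and a refractory lockout suppresses further detections
#' within \code{refractoryS} of an accepted peak.
#'
#' @param timeS Sample times (s), uniformly spaced.
#' @param signal Sampled ECG amplitudes (mV), same length as \code{timeS}.
#' @param thresholdMv Detection threshold (mV), positive.
#' @param refractoryS Lockout after an accepted peak (s); default 0.2, below
#'   the minimum physiological R-R interval at sinus rates.
#' @param debounceS Excursions separated by less than this gap (s) are
#'   merged into one event before peak picking, so noise dips within a QRS
#'   complex do not split it; default 0.05, longer than any QRS.
#' @return Numeric vector of peak times (s); empty for a flat/sub-threshold
#'   trace.
#' @export
#' @examples
#' ecg <- genEcg(bpm = 75, durationS = 10, noiseSdMv = 0, seed = 1)
#' detectRPeaks(ecg$trace$time_s, ecg$trace$ecg_mv, thresholdMv = 0.5)
detectRPeaks <- function(timeS, signal, thresholdMv, refractoryS = 0.2,
                         debounceS = 0.05) {
  stopifnot(length(timeS) == length(signal), thresholdMv > 0)
  if (length(signal) == 0L) return(numeric(0))
  over <- signal > thresholdMv
  if (!any(over)) return(numeric(0))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  ## debounce: merge excursions whose gap is shorter than debounceS
  mStart <- starts[1]; mEnd <- ends[1]
  cand <- numeric(0)
  flush <- function(s, e) {
    i <- s:e
    timeS[i[which.max(signal[i])]]
  }
  if (length(starts) > 1L) for (k in 2:length(starts)) {
    if (timeS[starts[k]] - timeS[mEnd] < debounceS) {
      mEnd <- ends[k]
    } else {
      cand <- c(cand, flush(mStart, mEnd))
      mStart <- starts[k]; mEnd <- ends[k]
    }
  }
  cand <- c(cand, flush(mStart, mEnd))
  cand <- sort(as.numeric(cand))
  out <- numeric(0)
  last <- -Inf
  for (tt in cand) {
    if (tt - last >= refractoryS) {
      out <- c(out, tt)
      last <- tt
    }
  }
  out
}

#' Schedule an ECG-gated burst train
#'
#' Assigns one burst per detected beat at a fixed delay after the R peak, so
#' delivery falls within the effective refractory period. Delays outside the
#' observed 50-75 ms safety window are rejected.
#'
#' @param rPeaksS Ordered R-peak times (s).
#' @param delayMs Delay after each R peak (ms), in [50, 75].
#' @param nBursts Number of bursts to schedule; requires at least this many
#'   beats.
#' @return A \linkS4class{GatingSchedule}.
#' @export
#' @examples
#' sched <- scheduleBursts(seq(0, 10, by = 0.8), delayMs = 50, nBursts = 10)
#' burstTimes(sched)[1:3]
scheduleBursts <- function(rPeaksS, delayMs, nBursts) {
  if (delayMs < 50 || delayMs > 75)
    stop("delayMs outside the [50, 75] ms safety window")
  nBursts <- as.integer(nBursts)
  if (nBursts < 1L) stop("nBursts must be >= 1")
  if (length(rPeaksS) < nBursts)
    stop(sprintf("too few beats: %d R peaks for %d bursts",
                 length(rPeaksS), nBursts))
  if (is.unsorted(rPeaksS, strictly = TRUE))
    stop("rPeaksS must be strictly increasing")
  used <- rPeaksS[seq_len(nBursts)]
  bt <- used + delayMs / 1000
  mib <- if (nBursts > 1L) mean(diff(bt)) else NA_real_
  new("GatingSchedule", rPeakTimesS = used, delayMs = delayMs,
      burstTimesS = bt, meanInterburstS = mib)
}
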