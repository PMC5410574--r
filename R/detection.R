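#' @include AllClasses.R
NULL

#' Detection parameters
#'
#' Parameters governing event detection and window preprocessing.
#'
#' @param windowMs event window duration T_w in milliseconds (default 100).
#' @param smoothCutoffHz low-pass cutoff used only to localize peaks
#'   (default 70; the stored raw windows are never filtered).
#' @param minAmplitudeMv candidate threshold on the baseline-subtracted
#'   smoothed peak amplitude.
#' @param baselineFraction fraction of initial window samples averaged for
#'   offset removal (strictly between 0 and 0.5).
#' @param targetRateHz resampling rate of the processed windows (default
#'   1600, reducing a 100 ms window from 1000 to 160 samples).
#' @return a validated list of class \code{"DetectionParams"}.
#' @export
detectionParams <- function(windowMs = 100, smoothCutoffHz = 70,
                            minAmplitudeMv = 0.1, baselineFraction = 0.1,
                            targetRateHz = 1600) {
  if (baselineFraction <= 0 || baselineFraction >= 0.5)
    stop("invalid argument: baselineFraction must be in (0, 0.5)")
  if (windowMs <= 0 || smoothCutoffHz <= 0 || targetRateHz <= 0)
    stop("invalid argument: durations and rates must be positive")
  structure(list(windowMs = windowMs, smoothCutoffHz = smoothCutoffHz,
                 minAmplitudeMv = minAmplitudeMv,
                 baselineFraction = baselineFraction,
                 targetRateHz = targetRateHz),
            class = "DetectionParams")
}

#' Zero-phase low-pass smoothing
#'
#' Forward-backward (zero-phase) application of a 4th-order Butterworth
#' low-pass filter. Used only to localize event peaks so that the time-stamp
#' is unbiased; stored raw windows are never filtered.
#'
#' @param trace numeric voltage series.
#' @param rateHz sampling rate (Hz).
#' @param cutoffHz cutoff frequency, strictly below the Nyquist rate.
#' @return filtered copy of \code{trace}, same length.
#' @export
lowpassSmooth <- function(trace, rateHz, cutoffHz) {
  if (cutoffHz >= rateHz / 2)
    stop("invalid argument: cutoffHz must be below the Nyquist frequency")
  flt <- signal::butter(4, cutoffHz / (rateHz / 2), type = "low")
  n <- length(trace)
  if (n < 3) return(as.numeric(trace))
  # mean removal + mirror padding suppress the filter's edge transients
  # (filtfilt assumes zeros outside the signal)
  m <- mean(trace)
  p <- min(n - 1, 1000)
  x <- trace - m
  xe <- c(rev(x[seq_len(p)]), x, rev(x[(n - p + 1):n]))
  as.numeric(signal::filtfilt(flt, xe))[(p + 1):(p + n)] + m
}

# indices of strict local maxima (plateau-tolerant on the right)
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect CDP-like events in a recording
#'
#' Peaks of the smoothed trace become event candidates when (i) the full
#' window around the peak lies inside the recording, (ii) the
#' baseline-subtracted smoothed amplitude reaches \code{minAmplitudeMv},
#' (iii) no second smoothed local maximum inside the window exceeds 80\% of
#' the central peak (single-dominant-peak shape constraint), and (iv) the
#' peak survives greedy overlap resolution: when two candidate windows
#' overlap by more than half a window the larger peak is kept.
#'
#' @param recording a \code{\link{CdpRecording}}.
#' @param params a \code{\link{detectionParams}} list.
#' @return a \code{\link{CdpEventSet}} with raw windows filled, sorted by
#'   peak index. An empty trace yields an empty event set.
#' @export
detectEvents <- function(recording, params = detectionParams()) {
  stopifnot(is(recording, "CdpRecording"), inherits(params, "DetectionParams"))
  rate <- recording@rateHz
  x <- recording@samples
  wn <- round(params$windowMs / 1000 * rate)
  half <- wn %/% 2
  nb <- max(1L, round(params$baselineFraction * wn))
  empty <- new("CdpEventSet", peakIndex = integer(),
               rawWindows = matrix(0, 0, wn), processedWindows = matrix(0, 0, 0),
               rateHz = rate, windowMs = params$windowMs,
               segmentId = recording@segmentId, stepId = recording@stepId,
               maneuver = recording@maneuver)
  if (length(x) <= wn) return(empty)
  s <- lowpassSmooth(x, rate, params$smoothCutoffHz)
  peaks <- .localMaxima(s)
  peaks <- peaks[peaks - half >= 1 & peaks - half + wn - 1 <= length(x)]
  if (!length(peaks)) return(empty)

  start <- peaks - half
  base <- vapply(seq_along(peaks), function(i)
    mean(s[start[i]:(start[i] + nb - 1)]), 0)
  amp <- s[peaks] - base
  keep <- amp >= params$minAmplitudeMv
  peaks <- peaks[keep]; start <- start[keep]; amp <- amp[keep]; base <- base[keep]
  if (!length(peaks)) return(empty)

  allMax <- .localMaxima(s)
  dominant <- vapply(seq_along(peaks), function(i) {
    inWin <- allMax[allMax >= start[i] & allMax <= start[i] + wn - 1 &
                      allMax != peaks[i]]
    !any(s[inWin] - base[i] > 0.8 * amp[i])
  }, TRUE)
  peaks <- peaks[dominant]; start <- start[dominant]; amp <- amp[dominant]
  if (!length(peaks)) return(empty)

  # greedy overlap resolution: larger peaks first, suppress peaks closer
  # than half a window to an accepted one
  ord <- order(-amp)
  accepted <- integer()
  for (i in ord)
    if (!any(abs(peaks[accepted] - peaks[i]) < half))
      accepted <- c(accepted, i)
  accepted <- sort(peaks[accepted])

  raw <- t(vapply(accepted, function(p) x[(p - half):(p - half + wn - 1)],
                  numeric(wn)))
  new("CdpEventSet", peakIndex = as.integer(accepted), rawWindows = raw,
      processedWindows = matrix(0, 0, 0), rateHz = rate,
      windowMs = params$windowMs, segmentId = recording@segmentId,
      stepId = recording@stepId, maneuver = recording@maneuver)
}

#' Resample and baseline-align event windows
#'
#' Each raw window is resampled from the native rate to
#' \code{params$targetRateHz} (polyphase FIR resampling) and the average of
#' its first \code{baselineFraction} samples is subtracted, so windows are
#' dimensionality-reduced and baseline-aligned for clustering. The operation
#' is idempotent: re-removing the baseline changes nothing.
#'
#' @param events a \code{\link{CdpEventSet}} with raw windows.
#' @param params the \code{\link{detectionParams}} used at detection.
#' @return the event set with \code{processedWindows} filled
#'   (\code{windowMs * targetRateHz / 1000} samples per window; 160 at
#'   defaults).
#' @export
preprocessEvents <- function(events, params = detectionParams()) {
  stopifnot(is(events, "CdpEventSet"), inherits(params, "DetectionParams"))
  wn <- round(params$windowMs / 1000 * events@rateHz)
  if (length(events) > 0 && ncol(events@rawWindows) != wn)
    stop("invalid argument: window length does not match params")
  g <- .gcd(round(params$targetRateHz), round(events@rateHz))
  p <- round(params$targetRateHz) / g
  q <- round(events@rateHz) / g
  outLen <- round(params$windowMs / 1000 * params$targetRateHz)
  nb <- max(1L, round(params$baselineFraction * outLen))
  proc <- matrix(0, length(events), outLen)
  for (i in seq_len(length(events))) {
    y <- .resampleWindow(events@rawWindows[i, ], p, q, outLen)
    proc[i, ] <- y - mean(y[seq_len(nb)])
  }
  events@processedWindows <- proc
  events@targetRateHz <- params$targetRateHz
  validObject(events)
  events
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# polyphase FIR resampling with mean removal and mirror padding so that the
# filter's zero-padding assumption cannot distort the window edges
.resampleWindow <- function(x, p, q, outLen) {
  n <- length(x)
  pad <- min(n, 200)
  m <- mean(x)
  xe <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1):n])) - m
  y <- as.numeric(signal::resample(xe, p, q)) + m
  start <- floor(pad * p / q) + 1
  y[start:(start + outLen - 1)]
}

#' Baseline alignment of processed windows
#'
#' Subtracts from each row the mean of its first \code{baselineFraction}
#' samples. Exposed separately because template waveforms must be pushed
#' through the same alignment when compared with learned prototypes.
#'
#' @param windows numeric matrix, one window per row.
#' @param baselineFraction fraction of initial samples averaged.
#' @return matrix with aligned rows.
#' @export
alignBaseline <- function(windows, baselineFraction = 0.1) {
  windows <- rbind(windows)
  nb <- max(1L, round(baselineFraction * ncol(windows)))
  windows - rowMeans(windows[, seq_len(nb), drop = FALSE])
}
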