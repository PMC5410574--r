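#' @include AllGenerics.R
NULL

#' Construct a CdpRecording
#'
#' @param samples numeric voltage trace (mV).
#' @param rateHz sampling frequency (Hz).
#' @param segmentId,stepId,maneuver provenance labels.
#' @return a \code{\link{CdpRecording}}.
#' @export
CdpRecording <- function(samples, rateHz, segmentId = NA_character_,
                         stepId = NA_character_, maneuver = NA_character_) {
  new("CdpRecording", samples = as.numeric(samples), rateHz = rateHz,
      segmentId = as.character(segmentId), stepId = as.character(stepId),
      maneuver = as.character(maneuver))
}

#' Construct a SymbolSequence
#'
#' @param tokens character tokens over the shape alphabet plus \code{"$"}.
#' @param eventTimes strictly increasing times (s) for non-pause tokens
#'   (may be omitted when unknown).
#' @param segmentId,stepId,maneuver provenance labels.
#' @param pauseDuration pause duration in seconds (NA when unknown).
#' @return a \code{\link{SymbolSequence}}.
#' @export
SymbolSequence <- function(tokens, eventTimes = numeric(),
                           segmentId = NA_character_, stepId = NA_character_,
                           maneuver = NA_character_,
                           pauseDuration = NA_real_) {
  new("SymbolSequence", tokens = as.character(tokens),
      eventTimes = as.numeric(eventTimes),
      segmentId = as.character(segmentId), stepId = as.character(stepId),
      maneuver = as.character(maneuver),
      pauseDuration = as.numeric(pauseDuration))
}

# Gaussian bump mixture on the unit window, zero-tapered at the edges.
.bumpWaveform <- function(nSamples, centers, widths, amps) {
  t <- (seq_len(nSamples) - 0.5) / nSamples
  w <- rep(0, nSamples)
  for (b in seq_along(centers))
    w <- w + amps[b] * exp(-(t - centers[b])^2 / (2 * widths[b]^2))
  taper <- rep(1, nSamples)
  nt <- max(2L, round(0.15 * nSamples))
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nt)))
  taper[seq_len(nt)] <- ramp
  taper[nSamples + 1 - seq_len(nt)] <- ramp
  w * taper
}

#' Generate ground-truth CDP shape templates
#'
#' Each template is a sum of 2--4 Gaussian bumps (a dominant positive one
#' near the window center plus satellites confined to the central region)
#' low-pass filtered at 60 Hz, so it is smooth, CDP-like and safely inside
#' the 70 Hz detection band. Templates are redrawn until pairwise Euclidean
#' distances exceed a floor well above five times
#' \code{\link{defaultNoiseSd}} and every absolute maximum falls in the
#' central fifth of the window.
#'
#' @param nShapes number of shape classes (1--26).
#' @param windowMs event window duration in milliseconds.
#' @param rateHz sampling rate in Hz.
#' @param seed integer seed (optional); results are deterministic given the
#'   seed.
#' @return a \code{\link{ShapeTemplates}} object with labels "A", "B", ...
#' @examples
#' tpl <- makeTemplates(4, seed = 1)
#' tpl
#' @export
makeTemplates <- function(nShapes, windowMs = 100, rateHz = 10000,
                          seed = NULL) {
  if (!is.numeric(nShapes) || nShapes < 1)
    stop("invalid argument: nShapes must be >= 1")
  if (nShapes > 26) stop("invalid argument: at most 26 single-letter shapes")
  if (windowMs <= 0) stop("invalid argument: windowMs must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- round(windowMs / 1000 * rateHz)
  lp <- signal::butter(4, min(0.99, 60 / (rateHz / 2)), type = "low")

  drawOne <- function() {
    nb <- sample(2:4, 1)
    # satellites stay in the central window region with modest widths so the
    # template carries no secondary peak near the window edges (which would
    # spawn spurious double detections)
    centers <- c(runif(1, 0.45, 0.55), runif(nb - 1, 0.3, 0.7))
    widths <- c(runif(1, 0.05, 0.10), runif(nb - 1, 0.03, 0.08))
    # dominant bump positive: events are time-stamped at the positive peak
    # (recordings are stored with the main CDP deflection plotted upward)
    amps <- c(runif(1, 0.8, 1.4),
              sample(c(-1, 1), nb - 1, replace = TRUE) * runif(nb - 1, 0.15, 0.5))
    w <- .bumpWaveform(n, centers, widths, amps)
    as.numeric(signal::filtfilt(lp, w))
  }

  centerOk <- function(w) {
    pk <- which.max(abs(w))
    pk == which.max(w) && pk >= 0.4 * n && pk <= 0.6 * n
  }

  waves <- matrix(0, nShapes, n)
  # distinctness floor: well above the 5-sigma noise bound so prototypes stay
  # separable after resampling and PCA denoising
  minDist <- max(5 * defaultNoiseSd, 2.5)
  for (i in seq_len(nShapes)) {
    for (try in seq_len(200)) {
      w <- drawOne()
      ok <- centerOk(w)
      if (ok && i > 1) {
        d <- sqrt(rowSums(sweep(waves[seq_len(i - 1), , drop = FALSE], 2, w)^2))
        ok <- min(d) > minDist
      }
      if (ok) break
    }
    if (!ok) stop("could not draw a distinct, center-peaked template")
    waves[i, ] <- w
  }
  labels <- LETTERS[seq_len(nShapes)]
  rownames(waves) <- labels
  new("ShapeTemplates", waveforms = waves, labels = labels, rateHz = rateHz,
      windowMs = windowMs)
}

#' Templates in processed-window space
#'
#' Pushes each template through the same transformation the detector applies
#' to real events: the window is re-centred at the template's (positive)
#' peak, resampled to the target rate and baseline-aligned. The result is
#' directly comparable with learned \code{\link{ShapeDictionary}} prototypes.
#'
#' @param templates a \code{\link{ShapeTemplates}} object.
#' @param params \code{\link{detectionParams}} (window, rates, baseline).
#' @return shapes-by-samples matrix in processed-window space.
#' @export
processedTemplates <- function(templates, params = detectionParams()) {
  w <- templates@waveforms
  n <- ncol(w)
  half <- n %/% 2
  g <- .gcd(round(params$targetRateHz), round(templates@rateHz))
  p <- round(params$targetRateHz) / g
  q <- round(templates@rateHz) / g
  outLen <- round(params$windowMs / 1000 * params$targetRateHz)
  out <- matrix(0, nrow(w), outLen)
  for (i in seq_len(nrow(w))) {
    padded <- c(rep(0, n), w[i, ], rep(0, n))
    # centre where the detector puts its time-stamp: the smoothed maximum
    sm <- lowpassSmooth(padded, templates@rateHz, params$smoothCutoffHz)
    pk <- which.max(sm)
    win <- padded[(pk - half):(pk - half + n - 1)]
    out[i, ] <- .resampleWindow(win, p, q, outLen)
  }
  rownames(out) <- templates@labels
  alignBaseline(out, params$baselineFraction)
}

.checkStochastic <- function(P, tol = 1e-6) {
  if (is.null(rownames(P)) || is.null(colnames(P)) ||
      !identical(rownames(P), colnames(P)))
    stop("invalid model: transition matrix needs matching row/column names")
  if (any(P < 0)) stop("invalid model: negative transition probability")
  if (any(abs(rowSums(P) - 1) > tol))
    stop("invalid model: rows must sum to 1")
  invisible(P)
}

#' Stationary distribution of a first-order chain
#'
#' @param P row-stochastic transition matrix with symbol dimnames.
#' @return named probability vector solving p = p P.
#' @export
stationaryDistribution <- function(P) {
  .checkStochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  setNames(v / sum(v), rownames(P))
}

#' Sample a token sequence from a first-order Markov chain
#'
#' @param transitionMatrix row-stochastic matrix with symbol dimnames
#'   (rows must sum to 1 within 1e-6).
#' @param length number of tokens to draw (>= 1).
#' @param startDistribution optional probability vector for the first token;
#'   defaults to the stationary distribution of the chain.
#' @param seed optional integer seed.
#' @return character vector of tokens.
#' @examples
#' P <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' sampleMarkovSequence(P, 6, startDistribution = c(1, 0), seed = 1)
#' @export
sampleMarkovSequence <- function(transitionMatrix, length,
                                 startDistribution = NULL, seed = NULL) {
  .checkStochastic(transitionMatrix)
  if (length < 1) stop("invalid argument: length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  syms <- rownames(transitionMatrix)
  if (is.null(startDistribution))
    startDistribution <- stationaryDistribution(transitionMatrix)
  start <- sample.int(length(syms), 1, prob = startDistribution)
  cumP <- t(apply(transitionMatrix, 1, cumsum))
  idx <- .sampleChainC(cumP, as.integer(length), as.integer(start))
  syms[idx]
}

#' Random row-stochastic matrix
#'
#' Rows drawn independently from a symmetric Dirichlet distribution.
#'
#' @param alphabet character symbols naming the rows/columns.
#' @param concentration Dirichlet concentration parameter.
#' @param seed optional integer seed.
#' @return a row-stochastic matrix.
#' @export
randomStochasticMatrix <- function(alphabet, concentration = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(alphabet)
  g <- matrix(stats::rgamma(m * m, shape = concentration), m, m)
  P <- g / rowSums(g)
  dimnames(P) <- list(alphabet, alphabet)
  P
}

#' Maneuver-specific generating matrices with guaranteed separation
#'
#' Builds one transition matrix per maneuver over the shape alphabet plus the
#' pause symbol. All maneuvers share a common random background; each adds
#' probability mass \code{separation} on a maneuver-specific target symbol
#' per row (targets rotate with the maneuver index), so the per-row total
#' variation distance between any two maneuvers is
#' \code{(1 - pauseProb) * separation}.
#'
#' @param shapes character vector of shape labels (no pause).
#' @param maneuvers character vector of maneuver labels.
#' @param separation mass moved to the maneuver-specific target (default 0.45
#'   gives a per-row TV separation of about 0.34 at the default pauseProb).
#' @param pauseProb probability of a pause after any token.
#' @param seed optional integer seed.
#' @return named list of row-stochastic matrices, one per maneuver.
#' @export
maneuverMatrices <- function(shapes, maneuvers, separation = 0.45,
                             pauseProb = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(shapes) >= 2, length(maneuvers) >= 1)
  alpha <- c(shapes, PAUSE)
  m <- length(alpha)
  k <- length(shapes)
  base <- randomStochasticMatrix(shapes, concentration = 2)
  out <- list()
  for (d in seq_along(maneuvers)) {
    P <- matrix(0, m, m, dimnames = list(alpha, alpha))
    for (i in seq_len(m)) {
      target <- shapes[((i - 1) + (d - 1) * max(1L, k %/% length(maneuvers))) %% k + 1]
      shapeRow <- (1 - separation) * base[min(i, k), ] +
        separation * (shapes == target)
      P[i, shapes] <- (1 - pauseProb) * shapeRow
      P[i, PAUSE] <- pauseProb
    }
    out[[maneuvers[d]]] <- P
  }
  out
}

#' State specification for the synthetic generator
#'
#' @param maneuver maneuver label (e.g. "ctrl", "capsa", "esp").
#' @param transitionMatrix row-stochastic generating matrix over the shape
#'   alphabet plus "$" (rows must sum to 1 within 1e-9 of tolerance 1e-6).
#' @param nSteps number of 10-minute-analogue time steps (>= 1).
#' @param symbolsPerStep tokens generated per step (at most 6000, the typical
#'   sequence length of a 10-minute recording).
#' @return a validated list of class \code{"StateSpec"}.
#' @export
stateSpec <- function(maneuver, transitionMatrix, nSteps = 1,
                      symbolsPerStep = 6000) {
  .checkStochastic(transitionMatrix)
  if (nSteps < 1) stop("invalid argument: nSteps must be >= 1")
  if (symbolsPerStep < 1 || symbolsPerStep > 6000)
    stop("invalid argument: symbolsPerStep must be in [1, 6000]")
  structure(list(maneuver = as.character(maneuver),
                 transitionMatrix = transitionMatrix,
                 nSteps = as.integer(nSteps),
                 symbolsPerStep = as.integer(symbolsPerStep)),
            class = "StateSpec")
}

#' Render a symbol sequence as a noisy voltage recording
#'
#' Events are placed sequentially: the interval between consecutive events
#' equals \code{pauseDurationS * (k + 0.92)} for \code{k} intervening pause
#' tokens, plus Gaussian jitter truncated to 0.07 pause periods, so the
#' floor-rule discretization recovers exactly \code{k} pauses in the
#' noiseless limit and adjacent 100 ms event windows are always disjoint
#' (the smallest possible peak gap is 0.85 pause periods, 102 ms at the
#' default pause). Each non-pause
#' token adds its template waveform centred at the event time; i.i.d.
#' Gaussian noise of standard deviation \code{noiseSd} is added throughout.
#'
#' @param symbols character token sequence over the template labels plus "$".
#' @param templates a \code{\link{ShapeTemplates}} object.
#' @param pauseDurationS pause duration in seconds (> 0).
#' @param jitterSdS jitter standard deviation in seconds (default 4\% of the
#'   pause duration; truncated at \code{0.07 * pauseDurationS}).
#' @param noiseSd background noise standard deviation in mV.
#' @param seed optional integer seed.
#' @param segmentId,stepId,maneuver provenance labels for the recording.
#' @return list with elements \code{recording} (a \code{\link{CdpRecording}})
#'   and \code{truthTimes} (planted peak times in seconds, one per non-pause
#'   token, strictly increasing).
#' @export
renderRecording <- function(symbols, templates, pauseDurationS = 0.12,
                            jitterSdS = NULL, noiseSd = defaultNoiseSd,
                            seed = NULL, segmentId = NA, stepId = NA,
                            maneuver = NA) {
  if (pauseDurationS <= 0) stop("invalid argument: pauseDurationS must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(jitterSdS)) jitterSdS <- 0.04 * pauseDurationS
  lab <- templates@labels
  unknown <- setdiff(unique(symbols), c(lab, PAUSE))
  if (length(unknown))
    stop("invalid symbol: no template for ", paste(unknown, collapse = ", "))
  rate <- templates@rateHz
  n <- ncol(templates@waveforms)
  events <- symbols[symbols != PAUSE]
  # count pauses preceding each event
  evPos <- which(symbols != PAUSE)
  nPause <- diff(c(0L, evPos)) - 1L
  jitMax <- 0.07 * pauseDurationS
  t0 <- n / rate / 2 + pauseDurationS
  times <- numeric(length(events))
  cur <- t0
  for (i in seq_along(events)) {
    if (i > 1) {
      jit <- max(-jitMax, min(jitMax, rnorm(1, 0, jitterSdS)))
      cur <- cur + pauseDurationS * (nPause[i] + 0.92) + jit
    }
    times[i] <- cur
  }
  tailPause <- length(symbols) - if (length(evPos)) max(evPos) else 0L
  total <- (if (length(times)) max(times) else t0) +
    n / rate / 2 + (tailPause + 1) * pauseDurationS
  N <- ceiling(total * rate)
  trace <- rnorm(N, 0, noiseSd)
  # truth time = where the detector's time-stamp lands for an isolated,
  # noiseless event: the argmax of the 70 Hz-smoothed template
  smPeak <- vapply(seq_len(nrow(templates@waveforms)), function(i) {
    padded <- c(rep(0, n), templates@waveforms[i, ], rep(0, n))
    which.max(lowpassSmooth(padded, rate, 70)) - n
  }, 0)
  truth <- numeric(length(events))
  for (i in seq_along(events)) {
    j <- match(events[i], lab)
    w <- templates@waveforms[j, ]
    # place the waveform so its smoothed peak (the detector's time-stamp)
    # lands exactly at the scheduled time: inter-event gaps then follow the
    # spacing rule regardless of where each template peaks in its window
    s0 <- round(times[i] * rate) - smPeak[j] + 2
    idx <- s0:(s0 + n - 1)
    trace[idx] <- trace[idx] + w
    truth[i] <- (s0 + smPeak[j] - 2) / rate
  }
  rec <- CdpRecording(trace, rate, segmentId, stepId, maneuver)
  list(recording = rec, truthTimes = truth)
}

#' Generate a ground-truthed multichannel synthetic experiment
#'
#' One symbol sequence (and optionally a rendered recording) is produced per
#' (segment, step). All steps of a state share that state's generating
#' matrix; per-segment matrices are perturbed by convex mixing with a random
#' stochastic matrix (weight \code{perturbWeight}) to emulate inter-segment
#' variation. Everything is reproducible from \code{seed}.
#'
#' @param states non-empty list of \code{\link{stateSpec}} objects.
#' @param nSegments number of parallel recording channels (>= 1).
#' @param templates \code{\link{ShapeTemplates}} whose labels match the
#'   non-pause alphabet of the state matrices (only needed when rendering).
#' @param seed integer seed.
#' @param perturbWeight convex weight of the random per-segment perturbation.
#' @param render logical; render voltage recordings (slow for long
#'   sequences) or generate symbol sequences only.
#' @param pauseDurationS,jitterSdS,noiseSd rendering parameters, see
#'   \code{\link{renderRecording}}.
#' @return a \code{\link{SyntheticExperiment}}.
#' @examples
#' P <- maneuverMatrices(LETTERS[1:3], c("ctrl", "capsa"), seed = 1)
#' st <- list(stateSpec("ctrl", P$ctrl, 2, 200),
#'            stateSpec("capsa", P$capsa, 2, 200))
#' ex <- makeExperiment(st, nSegments = 2, seed = 1, render = FALSE)
#' ex
#' @export
makeExperiment <- function(states, nSegments = 1, templates = NULL, seed = 1,
                           perturbWeight = 0.1, render = TRUE,
                           pauseDurationS = 0.12, jitterSdS = NULL,
                           noiseSd = defaultNoiseSd) {
  if (!length(states)) stop("invalid argument: states must be non-empty")
  if (nSegments < 1) stop("invalid argument: nSegments must be >= 1")
  if (!all(vapply(states, inherits, TRUE, "StateSpec")))
    stop("invalid argument: states must be stateSpec() objects")
  if (render && is.null(templates))
    stop("invalid argument: templates required when render = TRUE")
  set.seed(seed)
  alpha <- rownames(states[[1]]$transitionMatrix)
  stepIds <- character()
  stepMan <- character()
  for (st in states) {
    ids <- paste0(st$maneuver, "_", seq_len(st$nSteps))
    stepIds <- c(stepIds, ids)
    stepMan <- c(stepMan, rep(st$maneuver, st$nSteps))
  }
  segIds <- sprintf("seg%02d", seq_len(nSegments))

  recordings <- list()
  truthSymbols <- list()
  truthMatrices <- list()
  for (s in seq_len(nSegments)) {
    segMat <- list()
    for (st in states) {
      R <- randomStochasticMatrix(alpha)
      segMat[[st$maneuver]] <-
        (1 - perturbWeight) * st$transitionMatrix + perturbWeight * R
    }
    truthMatrices[[segIds[s]]] <- segMat
    for (st in states) {
      for (j in seq_len(st$nSteps)) {
        sid <- paste0(st$maneuver, "_", j)
        key <- paste(segIds[s], sid, sep = ".")
        tok <- sampleMarkovSequence(segMat[[st$maneuver]], st$symbolsPerStep)
        if (render) {
          r <- renderRecording(tok, templates, pauseDurationS, jitterSdS,
                               noiseSd, segmentId = segIds[s], stepId = sid,
                               maneuver = st$maneuver)
          recordings[[key]] <- r$recording
          tt <- r$truthTimes
        } else {
          # jitter-free placement times following the rendering spacing rule
          ev <- which(tok != PAUSE)
          tt <- if (length(ev))
            pauseDurationS * (ev[1] + cumsum(c(0, (diff(ev) - 1) + 0.92)))
          else numeric()
        }
        truthSymbols[[key]] <- SymbolSequence(tok, tt, segIds[s], sid,
                                              st$maneuver, pauseDurationS)
      }
    }
  }
  new("SyntheticExperiment", recordings = recordings,
      truthSymbols = truthSymbols, truthMatrices = truthMatrices,
      templates = templates,
      stepTable = data.frame(stepId = stepIds, maneuver = stepMan,
                             stringsAsFactors = FALSE),
      seed = as.integer(seed))
}
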