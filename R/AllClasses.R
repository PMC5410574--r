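#' @include cdpMarkov-package.R
NULL

PAUSE <- "$"

#' Single-channel voltage recording
#'
#' One channel's voltage trace (millivolts) together with its sampling rate
#' and provenance: the recording site ("segment", e.g. \code{"L6rL"}), the
#' time-step label within the experiment, and the experimental maneuver the
#' step belongs to (control, capsaicin or spinalization analogue).
#'
#' @slot samples numeric vector, voltage in mV.
#' @slot rateHz sampling frequency in Hz (nominally 10000).
#' @slot segmentId,stepId,maneuver character provenance labels (may be NA).
#' @export
setClass("CdpRecording",
  representation(samples = "numeric", rateHz = "numeric",
                 segmentId = "character", stepId = "character",
                 maneuver = "character"),
  prototype(segmentId = NA_character_, stepId = NA_character_,
            maneuver = NA_character_))

setValidity("CdpRecording", function(object) {
  msg <- character()
  if (length(object@rateHz) != 1L || !is.finite(object@rateHz) ||
      object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Detected CDP events of one recording
#'
#' Container for the events detected in a single recording: the sample index
#' of each smoothed-trace peak (the event time-stamp), the raw event windows
#' at the native rate (one row per event) and, after preprocessing, the
#' resampled baseline-aligned windows used for clustering and labeling.
#'
#' @slot peakIndex integer vector of 1-based peak sample indices; peak time in
#'   seconds is \code{(peakIndex - 1) / rateHz}.
#' @slot rawWindows events-by-samples matrix at the native rate.
#' @slot processedWindows events-by-samples matrix at \code{targetRateHz}
#'   (0-column until \code{\link{preprocessEvents}} is applied).
#' @slot rateHz,targetRateHz,windowMs acquisition and window geometry.
#' @slot segmentId,stepId,maneuver provenance labels.
#' @export
setClass("CdpEventSet",
  representation(peakIndex = "integer", rawWindows = "matrix",
                 processedWindows = "matrix", rateHz = "numeric",
                 targetRateHz = "numeric", windowMs = "numeric",
                 segmentId = "character", stepId = "character",
                 maneuver = "character"),
  prototype(targetRateHz = NA_real_, segmentId = NA_character_,
            stepId = NA_character_, maneuver = NA_character_))

setValidity("CdpEventSet", function(object) {
  msg <- character()
  if (nrow(object@rawWindows) != length(object@peakIndex))
    msg <- c(msg, "rawWindows must have one row per event")
  if (nrow(object@processedWindows) > 0 &&
      nrow(object@processedWindows) != length(object@peakIndex))
    msg <- c(msg, "processedWindows must have one row per event")
  if (is.unsorted(object@peakIndex, strictly = TRUE) &&
      length(object@peakIndex) > 1)
    msg <- c(msg, "peakIndex must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Synthetic CDP shape templates
#'
#' A set of smooth, band-limited (below 70 Hz) waveforms used by the
#' synthetic generator as the ground-truth shape classes. Each template's
#' absolute maximum lies in the central fifth of the event window so the
#' detector's center-peak rule can fire, and templates are pairwise separated
#' by more than five times \code{\link{defaultNoiseSd}}.
#'
#' @slot waveforms shapes-by-samples matrix (mV), row names are the labels.
#' @slot labels character labels ("A", "B", ...).
#' @slot rateHz sampling rate of the waveforms.
#' @slot windowMs window duration in milliseconds.
#' @export
setClass("ShapeTemplates",
  representation(waveforms = "matrix", labels = "character",
                 rateHz = "numeric", windowMs = "numeric"))

setValidity("ShapeTemplates", function(object) {
  msg <- character()
  if (nrow(object@waveforms) != length(object@labels))
    msg <- c(msg, "one label per waveform required")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Principal-component basis for event windows
#'
#' The minimal set of leading principal components whose cumulative explained
#' variance reaches the requested target (0.98 by default in the pipeline).
#'
#' @slot components samples-by-nSelected matrix of orthonormal directions.
#' @slot center numeric, per-sample mean removed before projection.
#' @slot explainedRatios full non-increasing vector of variance fractions.
#' @slot nSelected number of retained components.
#' @slot varianceTarget the requested cumulative variance fraction.
#' @export
setClass("PcaBasis",
  representation(components = "matrix", center = "numeric",
                 explainedRatios = "numeric", nSelected = "integer",
                 varianceTarget = "numeric"))

setValidity("PcaBasis", function(object) {
  msg <- character()
  r <- object@explainedRatios
  if (any(diff(r) > 1e-8)) msg <- c(msg, "explainedRatios must be non-increasing")
  n <- object@nSelected
  if (n < 1L || n > length(r)) msg <- c(msg, "nSelected out of range")
  else {
    cum <- cumsum(r)
    if (cum[n] < object@varianceTarget - 1e-9)
      msg <- c(msg, "selected components do not reach the variance target")
    if (n > 1L && cum[n - 1L] >= object@varianceTarget - 1e-12)
      msg <- c(msg, "nSelected is not minimal")
  }
  if (ncol(object@components) != n)
    msg <- c(msg, "components must hold exactly nSelected columns")
  if (length(msg)) msg else TRUE
})

#' Dictionary of CDP shape classes
#'
#' k-means prototype waveforms (in processed-window space) with per-cluster
#' dispersion, used to label each detected event with the symbol of its
#' nearest prototype (Euclidean distance).
#'
#' @slot prototypes k-by-samples matrix of cluster centroids.
#' @slot labels character symbol labels "A", "B", ...
#' @slot dispersions k-by-samples matrix of per-cluster, per-sample standard
#'   deviations.
#' @slot pca the \code{\link{PcaBasis}} used to denoise the training windows,
#'   or NULL when the dictionary was fit on raw windows.
#' @export
setClass("ShapeDictionary",
  representation(prototypes = "matrix", labels = "character",
                 dispersions = "matrix", pca = "ANY"),
  prototype(pca = NULL))

setValidity("ShapeDictionary", function(object) {
  msg <- character()
  if (nrow(object@prototypes) < 1L) msg <- c(msg, "at least one prototype required")
  if (nrow(object@prototypes) != length(object@labels))
    msg <- c(msg, "one label per prototype required")
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
  if (!identical(dim(object@prototypes), dim(object@dispersions)))
    msg <- c(msg, "dispersions must match prototypes in shape")
  if (length(msg)) msg else TRUE
})

#' Discrete symbol sequence with pause tokens
#'
#' Ordered tokens over the shape alphabet plus the pause symbol \code{"$"}.
#' Event times (seconds) are carried for non-pause tokens only; pauses stand
#' for whole inter-event intervals in which no event was identified.
#'
#' @slot tokens character vector over the alphabet plus "$".
#' @slot eventTimes strictly increasing times (s) of the non-pause tokens;
#'   may be empty when times are unknown (e.g. plain token files).
#' @slot segmentId,stepId,maneuver provenance labels.
#' @slot pauseDuration estimated/nominal pause duration in seconds (NA when
#'   unknown).
#' @export
setClass("SymbolSequence",
  representation(tokens = "character", eventTimes = "numeric",
                 segmentId = "character", stepId = "character",
                 maneuver = "character", pauseDuration = "numeric"),
  prototype(eventTimes = numeric(), segmentId = NA_character_,
            stepId = NA_character_, maneuver = NA_character_,
            pauseDuration = NA_real_))

setValidity("SymbolSequence", function(object) {
  msg <- character()
  nEvents <- sum(object@tokens != PAUSE)
  if (length(object@eventTimes) > 0 && length(object@eventTimes) != nEvents)
    msg <- c(msg, "eventTimes must have one entry per non-pause token")
  if (length(object@eventTimes) > 1 &&
      any(diff(object@eventTimes) <= 0))
    msg <- c(msg, "eventTimes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' First-order transition model over the symbol alphabet
#'
#' Pair counts and (optionally additively smoothed) row-stochastic transition
#' probabilities over the full alphabet including the pause symbol. Rows with
#' no outgoing pairs and no smoothing are flagged unsupported and left at
#' zero.
#'
#' @slot alphabet ordered symbols, pause (if present) last.
#' @slot counts integer pair-count matrix (entry i,j = times j follows i).
#' @slot probs row-stochastic matrix; unsupported rows are all zero.
#' @slot supported logical per-row support flags.
#' @slot alpha additive-smoothing pseudo-count used (0 = maximum likelihood).
#' @slot segmentId,stepId,maneuver provenance labels.
#' @slot trainedOn number of tokens in the training sequence.
#' @export
setClass("TransitionModel",
  representation(alphabet = "character", counts = "matrix", probs = "matrix",
                 supported = "logical", alpha = "numeric",
                 segmentId = "character", stepId = "character",
                 maneuver = "character", trainedOn = "integer"),
  prototype(alpha = 0, segmentId = NA_character_, stepId = NA_character_,
            maneuver = NA_character_, trainedOn = NA_integer_))

setValidity("TransitionModel", function(object) {
  msg <- character()
  m <- length(object@alphabet)
  if (!identical(dim(object@counts), c(m, m)) ||
      !identical(dim(object@probs), c(m, m)))
    msg <- c(msg, "counts and probs must be m x m for alphabet size m")
  if (length(object@supported) != m)
    msg <- c(msg, "supported must have one flag per alphabet symbol")
  rs <- rowSums(object@probs)
  if (any(abs(rs[object@supported] - 1) > 1e-9))
    msg <- c(msg, "supported rows must sum to 1")
  if (any(object@probs < -1e-12) || any(object@probs > 1 + 1e-12))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Result of a Markov-order hypothesis test
#'
#' @slot method "chi2-order1", "permutation-order1" or "whittle-order2".
#' @slot statistic observed divergence value.
#' @slot df chi-squared degrees of freedom (NA for surrogate tests).
#' @slot pValue p-value in (0, 1]; surrogate tests use the
#'   (1 + exceedances) / (1 + draws) convention so p is never zero.
#' @slot nSurrogates number of surrogate draws (0 for the chi-squared test).
#' @slot nullStats surrogate null statistics (empty for chi-squared).
#' @slot alphabet symbols the test was computed over.
#' @export
setClass("OrderTestResult",
  representation(method = "character", statistic = "numeric", df = "numeric",
                 pValue = "numeric", nSurrogates = "integer",
                 nullStats = "numeric", alphabet = "character"),
  prototype(df = NA_real_, nSurrogates = 0L, nullStats = numeric()))

setValidity("OrderTestResult", function(object) {
  msg <- character()
  if (object@statistic < 0) msg <- c(msg, "statistic must be non-negative")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground-truthed synthetic experiment
#'
#' Bundle produced by \code{\link{makeExperiment}}: one generating symbol
#' sequence (with planted event peak times) per (segment, step), the
#' per-segment generating transition matrices, the shape templates, and the
#' rendered recordings when rendering was requested.
#'
#' @slot recordings named list of \code{\link{CdpRecording}} keyed
#'   "segment.step" (empty when \code{render = FALSE}).
#' @slot truthSymbols named list of \code{\link{SymbolSequence}} with the
#'   generating tokens and planted peak times.
#' @slot truthMatrices per-segment named list of per-maneuver generating
#'   transition matrices.
#' @slot templates the \code{\link{ShapeTemplates}} used for rendering.
#' @slot stepTable data.frame (stepId, maneuver) describing the design.
#' @slot seed integer seed the experiment was generated from.
#' @export
setClass("SyntheticExperiment",
  representation(recordings = "list", truthSymbols = "list",
                 truthMatrices = "list", templates = "ANY",
                 stepTable = "data.frame", seed = "integer"))

setValidity("SyntheticExperiment", function(object) {
  msg <- character()
  for (nm in names(object@truthSymbols)) {
    ss <- object@truthSymbols[[nm]]
    if (!is(ss, "SymbolSequence")) { msg <- c(msg, "truthSymbols must hold SymbolSequence objects"); break }
    if (length(ss@eventTimes) != sum(ss@tokens != PAUSE)) {
      msg <- c(msg, sprintf("sequence %s: one truth time per non-pause token required", nm))
      break
    }
  }
  if (length(msg)) msg else TRUE
})
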