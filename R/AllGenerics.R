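#' @include AllClasses.R
NULL

#' Accessors for cdpMarkov containers
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{tokens} and \code{eventTimes} for \code{\link{SymbolSequence}},
#' \code{samples} and \code{sampleRate} for \code{\link{CdpRecording}},
#' \code{prototypes} for \code{\link{ShapeDictionary}} /
#' \code{\link{ShapeTemplates}}, \code{alphabet} / \code{transitionCounts} /
#' \code{probs} for \code{\link{TransitionModel}}, \code{pValue} /
#' \code{statistic} for \code{\link{OrderTestResult}}, and the provenance
#' accessors \code{segmentId}, \code{stepId}, \code{maneuver}.
#'
#' @param x an object of the documented classes.
#' @return the corresponding slot value.
#' @name accessors
#' @rdname accessors
#' @examples
#' s <- SymbolSequence(c("A", "$", "B"), eventTimes = c(0, 0.25))
#' tokens(s)
#' eventTimes(s)
NULL

#' @rdname accessors
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))
#' @rdname accessors
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("segmentId", function(x) standardGeneric("segmentId"))
#' @rdname accessors
#' @export
setGeneric("stepId", function(x) standardGeneric("stepId"))
#' @rdname accessors
#' @export
setGeneric("maneuver", function(x) standardGeneric("maneuver"))
#' @rdname accessors
#' @export
setGeneric("prototypes", function(x) standardGeneric("prototypes"))
#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))
#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))
#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setGeneric("processedWindows", function(x) standardGeneric("processedWindows"))
#' @rdname accessors
#' @export
setGeneric("peakTimes", function(x) standardGeneric("peakTimes"))

#' @rdname accessors
#' @export
setMethod("tokens", "SymbolSequence", function(x) x@tokens)
#' @rdname accessors
#' @export
setMethod("eventTimes", "SymbolSequence", function(x) x@eventTimes)
#' @rdname accessors
#' @export
setMethod("samples", "CdpRecording", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("sampleRate", "CdpRecording", function(x) x@rateHz)
#' @rdname accessors
#' @export
setMethod("sampleRate", "CdpEventSet", function(x) x@rateHz)

for (cls in c("CdpRecording", "CdpEventSet", "SymbolSequence",
              "TransitionModel")) {
  setMethod("segmentId", cls, function(x) x@segmentId)
  setMethod("stepId", cls, function(x) x@stepId)
  setMethod("maneuver", cls, function(x) x@maneuver)
}

#' @rdname accessors
#' @export
setMethod("prototypes", "ShapeDictionary", function(x) x@prototypes)
#' @rdname accessors
#' @export
setMethod("prototypes", "ShapeTemplates", function(x) x@waveforms)
#' @rdname accessors
#' @export
setMethod("alphabet", "TransitionModel", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("alphabet", "ShapeDictionary", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("transitionCounts", "TransitionModel", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("probs", "TransitionModel", function(x) x@probs)
#' @rdname accessors
#' @export
setMethod("pValue", "OrderTestResult", function(x) x@pValue)
#' @rdname accessors
#' @export
setMethod("statistic", "OrderTestResult", function(x) x@statistic)
#' @rdname accessors
#' @export
setMethod("processedWindows", "CdpEventSet", function(x) x@processedWindows)
#' @rdname accessors
#' @export
setMethod("peakTimes", "CdpEventSet", function(x) (x@peakIndex - 1) / x@rateHz)

#' @describeIn accessors number of detected events
#' @export
setMethod("length", "CdpEventSet", function(x) length(x@peakIndex))
#' @describeIn accessors number of tokens (pauses included)
#' @export
setMethod("length", "SymbolSequence", function(x) length(x@tokens))

setMethod("show", "CdpRecording", function(object) {
  cat(sprintf("CdpRecording: %s / %s (%s)\n  %d samples at %g Hz (%.1f s)\n",
              object@segmentId, object@stepId, object@maneuver,
              length(object@samples), object@rateHz,
              length(object@samples) / object@rateHz))
})

setMethod("show", "CdpEventSet", function(object) {
  cat(sprintf("CdpEventSet: %d events from %s / %s\n", length(object),
              object@segmentId, object@stepId))
  cat(sprintf("  raw windows: %d x %d at %g Hz; processed: %s\n",
              nrow(object@rawWindows), ncol(object@rawWindows), object@rateHz,
              if (ncol(object@processedWindows) > 0)
                sprintf("%d x %d at %g Hz", nrow(object@processedWindows),
                        ncol(object@processedWindows), object@targetRateHz)
              else "not yet computed"))
})

setMethod("show", "ShapeTemplates", function(object) {
  cat(sprintf("ShapeTemplates: %d shapes (%s), %g ms at %g Hz\n",
              nrow(object@waveforms),
              paste(object@labels, collapse = ""), object@windowMs,
              object@rateHz))
})

setMethod("show", "ShapeDictionary", function(object) {
  cat(sprintf("ShapeDictionary: k = %d prototypes (%s), %d samples each\n",
              nrow(object@prototypes), paste(object@labels, collapse = ""),
              ncol(object@prototypes)))
  if (!is.null(object@pca))
    cat(sprintf("  PCA basis: %d components (%.1f%% variance)\n",
                object@pca@nSelected,
                100 * sum(object@pca@explainedRatios[seq_len(object@pca@nSelected)])))
})

setMethod("show", "SymbolSequence", function(object) {
  n <- length(object@tokens)
  shown <- paste(head(object@tokens, 20), collapse = " ")
  if (n > 20) shown <- paste(shown, "...")
  cat(sprintf("SymbolSequence: %d tokens (%d events, %d pauses) [%s / %s / %s]\n  %s\n",
              n, sum(object@tokens != PAUSE), sum(object@tokens == PAUSE),
              object@segmentId, object@stepId, object@maneuver, shown))
})

setMethod("show", "TransitionModel", function(object) {
  cat(sprintf("TransitionModel over {%s} (alpha = %g)\n",
              paste(object@alphabet, collapse = ", "), object@alpha))
  if (!is.na(object@trainedOn))
    cat(sprintf("  trained on %d tokens [%s / %s / %s]\n", object@trainedOn,
                object@segmentId, object@stepId, object@maneuver))
  if (any(!object@supported))
    cat(sprintf("  unsupported rows: %s\n",
                paste(object@alphabet[!object@supported], collapse = ", ")))
})

setMethod("show", "OrderTestResult", function(object) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g", object@method,
              object@statistic, object@pValue))
  if (!is.na(object@df)) cat(sprintf(" (df = %g)", object@df))
  if (object@nSurrogates > 0)
    cat(sprintf(" (%d surrogates)", object@nSurrogates))
  cat("\n")
})

setMethod("show", "SyntheticExperiment", function(object) {
  cat(sprintf("SyntheticExperiment: %d sequences, %d recordings, seed %d\n",
              length(object@truthSymbols), length(object@recordings),
              object@seed))
  print(object@stepTable)
})
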