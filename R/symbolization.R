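#' @include AllClasses.R
NULL

#' Estimate the pause duration from inter-event intervals
#'
#' The pause duration is the arithmetic mean of the intervals between
#' consecutive event times: the mean of the inter-event interval
#' distribution is taken as the duration of one pause period.
#'
#' @param eventTimes strictly increasing event times in seconds (>= 2).
#' @return the pause duration in seconds.
#' @examples
#' estimatePauseDuration(c(0, 0.1, 0.3))  # 0.15
#' @export
estimatePauseDuration <- function(eventTimes) {
  if (length(eventTimes) < 2)
    stop("insufficient data: at least 2 event times required")
  if (any(diff(eventTimes) <= 0))
    stop("invalid argument: event times must be strictly increasing")
  mean(diff(eventTimes))
}

#' Discretize labeled events into a symbol sequence with pauses
#'
#' Between consecutive events separated by a gap \code{g},
#' \code{floor(g / pauseDurationS)} pause tokens are inserted (a gap shorter
#' than one pause period inserts none). Event tokens keep their order and
#' times. A tiny relative tolerance guards the floor against floating-point
#' representation of exact multiples.
#'
#' @param labels character symbol per event.
#' @param eventTimes strictly increasing event times (s), aligned with
#'   \code{labels}.
#' @param pauseDurationS pause duration in seconds (> 0), e.g. from
#'   \code{\link{estimatePauseDuration}}; the fixed 100 ms reading can be
#'   emulated by passing 0.1.
#' @param segmentId,stepId,maneuver provenance labels.
#' @return a \code{\link{SymbolSequence}}.
#' @examples
#' tokens(discretize(c("A", "B"), c(0, 0.25), 0.12))  # "A" "$" "$" "B"
#' @export
discretize <- function(labels, eventTimes, pauseDurationS,
                       segmentId = NA, stepId = NA, maneuver = NA) {
  if (length(labels) != length(eventTimes))
    stop("invalid argument: labels and eventTimes must be aligned")
  if (length(eventTimes) > 1 && any(diff(eventTimes) <= 0))
    stop("invalid argument: event times must be strictly increasing")
  if (pauseDurationS <= 0)
    stop("invalid argument: pauseDurationS must be > 0")
  toks <- character()
  for (i in seq_along(labels)) {
    if (i > 1) {
      g <- eventTimes[i] - eventTimes[i - 1]
      nP <- floor(g / pauseDurationS + 1e-9)
      if (nP > 0) toks <- c(toks, rep(PAUSE, nP))
    }
    toks <- c(toks, labels[i])
  }
  SymbolSequence(toks, eventTimes, segmentId, stepId, maneuver,
                 pauseDurationS)
}

#' Per-step symbol occurrence probabilities
#'
#' For each time step, the relative frequency of each non-pause symbol among
#' the non-pause tokens of that step's sequences (the per-step occurrence
#' histograms of the shape classes). Steps without any event get a zero row
#' and are flagged in the \code{"flagged"} attribute with a warning.
#'
#' @param sequences list of \code{\link{SymbolSequence}} objects; rows are
#'   grouped by \code{stepId}.
#' @param alphabet optional symbol order for the columns (non-pause).
#' @return steps-by-symbols matrix whose supported rows sum to 1, with
#'   attribute \code{"flagged"} naming event-free steps.
#' @export
symbolFrequencies <- function(sequences, alphabet = NULL) {
  if (!length(sequences)) stop("invalid argument: sequences must be non-empty")
  if (is(sequences, "SymbolSequence")) sequences <- list(sequences)
  steps <- vapply(sequences, function(s) s@stepId, "")
  if (is.null(alphabet)) {
    alphabet <- sort(unique(setdiff(unlist(lapply(sequences, tokens)), PAUSE)))
  }
  uSteps <- unique(steps)
  out <- matrix(0, length(uSteps), length(alphabet),
                dimnames = list(uSteps, alphabet))
  flagged <- character()
  for (st in uSteps) {
    tok <- unlist(lapply(sequences[steps == st], tokens))
    tok <- tok[tok != PAUSE]
    if (!length(tok)) {
      flagged <- c(flagged, st)
      next
    }
    tab <- table(factor(tok, levels = alphabet))
    out[st, ] <- as.numeric(tab) / length(tok)
  }
  if (length(flagged))
    warning("steps with no events: ", paste(flagged, collapse = ", "))
  attr(out, "flagged") <- flagged
  out
}

#' Write a symbol sequence to plain-text files
#'
#' The main file holds '#'-prefixed header lines (segment, step, maneuver,
#' pause_duration_s) followed by one line of whitespace-separated tokens
#' with \code{"$"} for pauses. Event times, when present, go to a companion
#' two-column CSV \code{<path>_times.csv} (time_s, label).
#'
#' @param x a \code{\link{SymbolSequence}}.
#' @param path output file path for the token file.
#' @return \code{path}, invisibly.
#' @export
writeSymbolSequence <- function(x, path) {
  stopifnot(is(x, "SymbolSequence"))
  hdr <- c(paste("# segment:", x@segmentId),
           paste("# step:", x@stepId),
           paste("# maneuver:", x@maneuver),
           paste("# pause_duration_s:", format(x@pauseDuration, digits = 17)))
  writeLines(c(hdr, paste(x@tokens, collapse = " ")), path)
  if (length(x@eventTimes)) {
    tf <- paste0(tools::file_path_sans_ext(path), "_times.csv")
    write.csv(data.frame(time_s = format(x@eventTimes, digits = 17),
                         label = x@tokens[x@tokens != PAUSE]),
              tf, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a symbol sequence written by \code{\link{writeSymbolSequence}}
#'
#' @param path token file path; the companion \code{<path>_times.csv} is
#'   read when present.
#' @return a \code{\link{SymbolSequence}}. Malformed tokens raise a parse
#'   error naming the offending line.
#' @export
readSymbolSequence <- function(path) {
  lines <- readLines(path)
  meta <- list(segment = NA, step = NA, maneuver = NA, pause_duration_s = NA)
  tokens <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*([a-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(m) == 3 && m[2] %in% names(meta)) meta[[m[2]]] <- m[3]
      next
    }
    toks <- strsplit(ln, "\\s+")[[1]]
    bad <- !grepl("^([A-Za-z]|\\$)$", toks)
    if (any(bad))
      stop(sprintf("parse error at line %d of %s: unknown token '%s'",
                   i, path, toks[which(bad)[1]]))
    tokens <- c(tokens, toks)
  }
  times <- numeric()
  tf <- paste0(tools::file_path_sans_ext(path), "_times.csv")
  if (file.exists(tf)) times <- read.csv(tf)$time_s
  asNa <- function(v) if (identical(v, "NA") || is.na(v)) NA_character_ else v
  SymbolSequence(tokens, times, asNa(meta$segment), asNa(meta$step),
                 asNa(meta$maneuver),
                 suppressWarnings(as.numeric(meta$pause_duration_s)))
}

#' Detect, label and discretize a recording in one call
#'
#' Chains \code{\link{detectEvents}}, \code{\link{preprocessEvents}},
#' \code{\link{labelEvents}} and \code{\link{discretize}}.
#'
#' @param recording a \code{\link{CdpRecording}}.
#' @param dictionary a \code{\link{ShapeDictionary}}.
#' @param params \code{\link{detectionParams}}.
#' @param pauseDurationS pause duration; when NULL it is estimated from the
#'   detected event times with \code{\link{estimatePauseDuration}}.
#' @return a \code{\link{SymbolSequence}}.
#' @export
symbolizeRecording <- function(recording, dictionary,
                               params = detectionParams(),
                               pauseDurationS = NULL) {
  ev <- preprocessEvents(detectEvents(recording, params), params)
  if (length(ev) == 0)
    return(SymbolSequence(character(), numeric(), recording@segmentId,
                          recording@stepId, recording@maneuver,
                          pauseDurationS %||% NA_real_))
  lab <- labelEvents(ev@processedWindows, dictionary)
  tms <- peakTimes(ev)
  if (is.null(pauseDurationS)) pauseDurationS <- estimatePauseDuration(tms)
  discretize(lab, tms, pauseDurationS, recording@segmentId,
             recording@stepId, recording@maneuver)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
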