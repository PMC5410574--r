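#' @include AllClasses.R
NULL

#' Plot a shape dictionary
#'
#' One panel per prototype showing the centroid waveform with a +/- 1
#' standard-deviation band, in the style of a per-segment shape-dictionary
#' figure.
#'
#' @param dictionary a \code{\link{ShapeDictionary}}.
#' @param rateHz sampling rate of the prototypes (for the ms axis).
#' @return invisibly, the dictionary.
#' @export
plotDictionary <- function(dictionary, rateHz = 1600) {
  stopifnot(is(dictionary, "ShapeDictionary"))
  k <- nrow(dictionary@prototypes)
  nc <- ceiling(sqrt(k))
  old <- graphics::par(mfrow = c(ceiling(k / nc), nc),
                       mar = c(2.5, 2.5, 1.5, 0.5))
  on.exit(graphics::par(old))
  t <- (seq_len(ncol(dictionary@prototypes)) - 1) / rateHz * 1000
  for (i in seq_len(k)) {
    p <- dictionary@prototypes[i, ]
    s <- dictionary@dispersions[i, ]
    graphics::plot(t, p, type = "n", ylim = range(p - s, p + s),
                   xlab = "ms", ylab = "mV", main = dictionary@labels[i])
    graphics::polygon(c(t, rev(t)), c(p + s, rev(p - s)),
                      col = "grey85", border = NA)
    graphics::lines(t, p, lwd = 2)
  }
  invisible(dictionary)
}

#' Heatmap of a transition matrix
#'
#' @param model a \code{\link{TransitionModel}} (or plain matrix with
#'   dimnames).
#' @param main plot title.
#' @return invisibly, the probability matrix.
#' @export
plotTransitionMatrix <- function(model, main = "Transition probabilities") {
  P <- if (is(model, "TransitionModel")) {
    M <- probs(model)
    dimnames(M) <- list(alphabet(model), alphabet(model))
    M
  } else as.matrix(model)
  m <- nrow(P)
  graphics::image(seq_len(m), seq_len(m), t(P[m:1, ]), axes = FALSE,
                  xlab = "to", ylab = "from", main = main,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  graphics::axis(1, seq_len(m), colnames(P), las = 2)
  graphics::axis(2, seq_len(m), rev(rownames(P)), las = 2)
  invisible(P)
}
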