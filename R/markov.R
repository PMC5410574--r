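#' @include AllClasses.R
NULL

# tokens of x as a character vector
.asTokens <- function(x) {
  if (is(x, "SymbolSequence")) x@tokens else as.character(x)
}

# canonical alphabet: shape symbols sorted, pause last
.defaultAlphabet <- function(tokens) {
  syms <- unique(tokens)
  c(sort(setdiff(syms, PAUSE)), if (PAUSE %in% syms) PAUSE)
}

.tokenIndex <- function(tokens, alphabet) {
  idx <- match(tokens, alphabet)
  if (anyNA(idx))
    stop("invalid symbol: ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "),
         " not in the alphabet")
  as.integer(idx)
}

#' Pair counts of consecutive symbols
#'
#' Counts, over all adjacent positions of the sequence, how often symbol j
#' immediately follows symbol i. Pauses are counted as ordinary symbols and
#' occupy their own row and column. The total count equals the sequence
#' length minus one.
#'
#' @param x a \code{\link{SymbolSequence}} or character token vector of
#'   length >= 2.
#' @param alphabet optional symbol order; defaults to the sorted symbols of
#'   the sequence with the pause last.
#' @return integer matrix with symbol dimnames.
#' @examples
#' pairCounts(c("A", "B", "A", "B"))
#' @export
pairCounts <- function(x, alphabet = NULL) {
  tok <- .asTokens(x)
  if (length(tok) < 2) stop("insufficient data: need at least 2 tokens")
  if (is.null(alphabet)) alphabet <- .defaultAlphabet(tok)
  idx <- .tokenIndex(tok, alphabet)
  N <- .pairCountsC(idx, length(alphabet))
  dimnames(N) <- list(alphabet, alphabet)
  N
}

#' Maximum-likelihood transition probabilities from pair counts
#'
#' Each row of the pair-count matrix is divided by its sum; rows without any
#' outgoing pair are flagged unsupported and left at zero.
#'
#' @param counts square pair-count matrix with symbol dimnames, e.g. from
#'   \code{\link{pairCounts}}.
#' @return a \code{\link{TransitionModel}} with \code{alpha = 0}.
#' @export
transitionProbs <- function(counts) {
  if (sum(counts) < 1) stop("insufficient data: no pairs counted")
  rs <- rowSums(counts)
  supported <- rs > 0
  P <- counts * 0
  P[supported, ] <- counts[supported, , drop = FALSE] / rs[supported]
  new("TransitionModel", alphabet = rownames(counts),
      counts = unname(matrix(as.integer(counts), nrow(counts))) ,
      probs = unname(as.matrix(P)), supported = unname(supported),
      alpha = 0, trainedOn = as.integer(sum(counts) + 1L))
}

#' Expected pair counts under symbol independence
#'
#' The order-0 null expectation E[i, j] = n P(i) P(j), with marginal symbol
#' frequencies taken over the whole sequence and n the number of adjacent
#' pairs (sequence length minus one), so observed and expected totals match.
#'
#' @inheritParams pairCounts
#' @return numeric matrix of expected counts with symbol dimnames.
#' @export
independenceExpected <- function(x, alphabet = NULL) {
  tok <- .asTokens(x)
  if (length(tok) < 2) stop("insufficient data: need at least 2 tokens")
  if (is.null(alphabet)) alphabet <- .defaultAlphabet(tok)
  .tokenIndex(tok, alphabet)
  p <- as.numeric(table(factor(tok, levels = alphabet))) / length(tok)
  E <- (length(tok) - 1) * outer(p, p)
  dimnames(E) <- list(alphabet, alphabet)
  E
}

#' Chi-squared-style divergence between observed and expected counts
#'
#' Sum over cells with positive expectation of (O - E)^2 / E. Cells with
#' E = 0 and O = 0 contribute zero; E = 0 with O > 0 cannot arise when both
#' matrices come from the same sequence and is treated as an error.
#'
#' @param observed observed count matrix.
#' @param expected expected count matrix of the same shape.
#' @return the non-negative divergence; zero iff O = E on supported cells.
#' @export
chi2Divergence <- function(observed, expected) {
  if (!identical(dim(observed), dim(expected)))
    stop("invalid argument: observed and expected shapes differ")
  if (any(observed > 0 & expected == 0))
    stop("undefined cell: observed count with zero expectation")
  ok <- expected > 0
  sum((observed[ok] - expected[ok])^2 / expected[ok])
}

#' Pearson chi-squared test of Markov order one vs independence
#'
#' Tests the null that the sequence is a renewal process (each symbol
#' independent of its predecessor) by comparing observed pair counts with
#' the independence expectation; the statistic follows a chi-squared
#' distribution with m(m - 1) degrees of freedom for an alphabet of m
#' symbols (pause included).
#'
#' @inheritParams pairCounts
#' @return an \code{\link{OrderTestResult}}.
#' @export
chi2TestOrder1 <- function(x, alphabet = NULL) {
  tok <- .asTokens(x)
  if (is.null(alphabet)) alphabet <- .defaultAlphabet(tok)
  O <- pairCounts(tok, alphabet)
  E <- independenceExpected(tok, alphabet)
  stat <- chi2Divergence(O, E)
  m <- length(alphabet)
  df <- m * (m - 1)
  p <- pchisq(stat, df, lower.tail = FALSE)
  p <- min(1, max(p, .Machine$double.xmin))
  new("OrderTestResult", method = "chi2-order1", statistic = stat,
      df = as.numeric(df), pValue = p, alphabet = alphabet)
}

#' Permutation surrogate test of Markov order one
#'
#' Generates uniform random permutations of the sequence (each preserves the
#' symbol histogram exactly but destroys any sequential structure), computes
#' for each the same independence divergence as for the original, and
#' reports p = (1 + exceedances) / (1 + draws), so the smallest attainable
#' p with 10,000 surrogates is below 1/10,000.
#'
#' @inheritParams pairCounts
#' @param nSurrogates number of random permutations (default 10000).
#' @param seed optional integer seed.
#' @return an \code{\link{OrderTestResult}} carrying the null statistics.
#' @export
permutationTestOrder1 <- function(x, nSurrogates = 10000, seed = NULL,
                                  alphabet = NULL) {
  if (nSurrogates < 1) stop("invalid argument: nSurrogates must be >= 1")
  tok <- .asTokens(x)
  if (length(tok) < 3) stop("insufficient data: need at least 3 tokens")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(alphabet)) alphabet <- .defaultAlphabet(tok)
  idx <- .tokenIndex(tok, alphabet)
  m <- length(alphabet)
  obs <- .indepChi2C(idx, m)
  null <- .permNullC(idx, m, as.integer(nSurrogates))
  p <- (1 + sum(null >= obs)) / (nSurrogates + 1)
  new("OrderTestResult", method = "permutation-order1", statistic = obs,
      pValue = p, nSurrogates = as.integer(nSurrogates), nullStats = null,
      alphabet = alphabet)
}

#' Pair-count-preserving Whittle surrogate
#'
#' Draws a sequence uniformly at random among all sequences with exactly the
#' input's pair counts (hence the same first and last symbols, which fixing
#' all pair counts forces). The draw is realized as a uniform random
#' Eulerian trail of the pair-count multigraph: a last-exit arborescence
#' toward the final symbol is sampled by Wilson's loop-erased random walk
#' with edge weights equal to the pair counts, and all remaining out-edges
#' are shuffled uniformly.
#'
#' @inheritParams pairCounts
#' @param seed optional integer seed.
#' @return a character token vector (or \code{\link{SymbolSequence}} tokens
#'   if \code{x} was one) with identical pair counts to the input.
#' @export
whittleSurrogate <- function(x, seed = NULL, alphabet = NULL) {
  tok <- .asTokens(x)
  if (length(tok) < 3) return(tok)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(alphabet)) alphabet <- .defaultAlphabet(tok)
  idx <- .tokenIndex(tok, alphabet)
  alphabet[.whittleC(idx, length(alphabet))]
}

#' Triplet counts of consecutive symbol triples
#'
#' @inheritParams pairCounts
#' @return m x m x m integer array with symbol dimnames; for the 13-symbol
#'   alphabet (12 shapes plus pause) the structure has 2197 entries.
#' @export
tripletCounts <- function(x, alphabet = NULL) {
  tok <- .asTokens(x)
  if (length(tok) < 3) stop("insufficient data: need at least 3 tokens")
  if (is.null(alphabet)) alphabet <- .defaultAlphabet(tok)
  idx <- .tokenIndex(tok, alphabet)
  m <- length(alphabet)
  arr <- array(0L, c(m, m, m), dimnames = list(alphabet, alphabet, alphabet))
  for (t in seq_len(length(idx) - 2))
    arr[idx[t], idx[t + 1], idx[t + 2]] <-
      arr[idx[t], idx[t + 1], idx[t + 2]] + 1L
  arr
}

#' Whittle-surrogate test of Markov order two
#'
#' The statistic is the chi-squared-style divergence of observed triplet
#' counts N(i, j, k) from their order-one expectation N(i, j) P(k | j). The
#' null distribution comes from Whittle surrogates, which keep all pair
#' counts (the order-one sufficient statistic) while destroying any
#' second-order dependence; p uses the (1 + exceedances) / (1 + draws)
#' convention, so 1,000 surrogates resolve p down to about 0.001.
#'
#' @inheritParams pairCounts
#' @param nSurrogates number of Whittle surrogates (default 1000).
#' @param seed optional integer seed.
#' @return an \code{\link{OrderTestResult}}.
#' @export
surrogateTestOrder2 <- function(x, nSurrogates = 1000, seed = NULL,
                                alphabet = NULL) {
  if (nSurrogates < 1) stop("invalid argument: nSurrogates must be >= 1")
  tok <- .asTokens(x)
  if (length(tok) < 4) stop("insufficient data: need at least 4 tokens")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(alphabet)) alphabet <- .defaultAlphabet(tok)
  idx <- .tokenIndex(tok, alphabet)
  m <- length(alphabet)
  obs <- .tripletStatC(idx, m)
  null <- .order2NullC(idx, m, as.integer(nSurrogates))
  p <- (1 + sum(null >= obs)) / (nSurrogates + 1)
  new("OrderTestResult", method = "whittle-order2", statistic = obs,
      pValue = p, nSurrogates = as.integer(nSurrogates), nullStats = null,
      alphabet = alphabet)
}
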