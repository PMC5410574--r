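# Independent oracles and small simulation helpers used across tests.

# Exhaustively enumerate every token sequence sharing the pair counts of
# `tok` (depth-first over the remaining pair multiset). Oracle for the
# Whittle surrogate sampler; only usable for tiny sequences.
enumFeasibleSequences <- function(tok) {
  alpha <- unique(tok)
  m <- length(alpha)
  idx <- match(tok, alpha)
  N <- matrix(0L, m, m)
  for (t in seq_len(length(idx) - 1))
    N[idx[t], idx[t + 1]] <- N[idx[t], idx[t + 1]] + 1L
  res <- character()
  recurse <- function(cur, counts, path) {
    if (all(counts == 0L)) {
      res[[length(res) + 1]] <<- paste(alpha[path], collapse = " ")
      return(invisible())
    }
    for (nxt in seq_len(m)) {
      if (counts[cur, nxt] > 0L) {
        counts[cur, nxt] <- counts[cur, nxt] - 1L
        recurse(nxt, counts, c(path, nxt))
        counts[cur, nxt] <- counts[cur, nxt] + 1L
      }
    }
  }
  recurse(idx[1], N, idx[1])
  sort(unique(res))
}

# Pauses before the first and after the last event are unobservable to the
# floor-rule discretization (no bounding events), so round trips are exact
# on the planted sequence between its first and last event.
trimBoundaryPauses <- function(tok) {
  ev <- which(tok != "$")
  if (!length(ev)) return(character())
  tok[ev[1]:ev[length(ev)]]
}

# Second-order Markov sampler: with probability 1 - eps the next symbol is a
# deterministic function of the last two, otherwise uniform. Strongly
# order-2, with near-uniform pair structure.
sampleOrder2Chain <- function(n, alphabet, eps = 0.4) {
  m <- length(alphabet)
  s <- integer(n)
  s[1] <- 1L
  s[2] <- 2L
  u <- runif(n)
  for (t in 3:n) {
    s[t] <- if (u[t] > eps) (s[t - 2] + s[t - 1]) %% m + 1L
            else sample.int(m, 1)
  }
  alphabet[s]
}

# Strongly first-order chain over `alphabet`: mass `rho` on a cyclic
# successor, remainder spread uniformly.
cyclicDominantMatrix <- function(alphabet, rho = 0.6) {
  m <- length(alphabet)
  P <- matrix((1 - rho) / m, m, m, dimnames = list(alphabet, alphabet))
  for (i in seq_len(m)) P[i, i %% m + 1] <- P[i, i %% m + 1] + rho
  P
}

# Best greedy matching of learned labels to planted labels by prototype
# proximity; returns the fraction of events whose matched label agrees.
labelAgreement <- function(assigned, truth) {
  tab <- table(assigned, truth)
  total <- 0
  while (nrow(tab) > 0 && ncol(tab) > 0) {
    i <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    total <- total + tab[i[1], i[2]]
    tab <- tab[-i[1], -i[2], drop = FALSE]
  }
  total / length(assigned)
}

# e130221-style three-maneuver synthetic experiment on symbol sequences only
makeE130221Experiment <- function(seed, symbolsPerStep = 3000, nSegments = 11,
                                  separation = 0.45, perturbWeight = 0.1) {
  shapes <- LETTERS[1:12]
  mats <- maneuverMatrices(shapes, c("ctrl", "esp", "capsa"),
                           separation = separation, seed = seed)
  states <- list(stateSpec("ctrl", mats$ctrl, 2, symbolsPerStep),
                 stateSpec("esp", mats$esp, 2, symbolsPerStep),
                 stateSpec("capsa", mats$capsa, 4, symbolsPerStep))
  makeExperiment(states, nSegments = nSegments, seed = seed, render = FALSE,
                 perturbWeight = perturbWeight)
}
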