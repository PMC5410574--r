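---
title: "Markovian analysis of cord dorsum potential sequences: models, choices and limits"
author: "cdpMarkov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markovian analysis of CDP sequences: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdpMarkov)
```

## The scientific problem

Spontaneous cord dorsum potentials (CDPs) are voltage deflections recorded
from the dorsal surface of the spinal cord, generated by synchronized
ensembles of dorsal horn neurons. Multichannel recordings from the lumbar
segments of anesthetized preparations show a repertoire of recurring CDP
waveform classes whose occurrence statistics change across experimental
maneuvers: control periods, acute nociceptive stimulation (intradermic
capsaicin), and spinalization (cord transection removing supraspinal
influence).

This package implements the full analysis chain for asking two questions of
such recordings:

1. **Is the sequence of CDP classes memoryless?** If the next CDP class is
   independent of its predecessor, the sequence is a renewal process; if it
   depends on exactly the previous class it is a first-order Markov chain.
2. **Does each maneuver leave a transition signature?** If so, a short
   held-out stretch of recording can be attributed to its originating
   functional state by likelihood.

Because the original cat recordings are not publicly deposited, the package
ships a first-class synthetic generator that produces ground-truthed
multichannel experiments with the statistical structure the analysis
assumes. Every stage of the pipeline is validated end to end against that
ground truth.

## Pipeline overview

```
voltage trace --> detectEvents --> preprocessEvents --> buildDictionary
     --> labelEvents --> discretize --> { chi2TestOrder1,
         permutationTestOrder1, surrogateTestOrder2 }
     --> fitModel / evaluateExperiment (state identification)
```

## Event detection

Detection assumes CDPs are smooth (band-limited below 70 Hz), appear as
peaks, and ride on stationary, essentially Gaussian background noise.

* **Smoothing.** A 4th-order Butterworth low-pass at 70 Hz applied
  forward-backward (zero phase), used *only* to localize peaks; stored raw
  windows are never filtered. Zero-phase filtering keeps the time-stamp
  unbiased. The trace mean is removed and the ends mirror-padded before
  filtering, because the filter otherwise assumes zeros outside the signal
  and distorts the first and last tens of milliseconds.
* **Candidate rule.** A candidate is a local maximum of the smoothed trace
  whose full 100 ms window lies inside the recording and whose
  baseline-subtracted smoothed amplitude reaches `minAmplitudeMv` (default
  0.1 mV, i.e. five times the nominal noise standard deviation of
  0.02 mV). The published description requires unspecified "shape
  constraints"; here these are made concrete and testable as a
  *single-dominant-peak* rule: no second smoothed maximum inside the window
  may exceed 80% of the central peak. This rejects double events.
* **Overlap resolution.** Remaining candidates closer than half a window
  are resolved greedily, keeping the larger peak. The underlying method
  description is silent on colliding candidates; greedy-by-amplitude is the
  simplest deterministic rule.
* **Coordinates.** Peak indices are stored 1-based (R convention); peak
  time in seconds is `(index - 1) / rate`, so the first sample is time 0.

## Window preprocessing

Windows of 100 ms at the native 10 kHz are resampled to 1.6 kHz (1000 to
160 samples) by polyphase FIR resampling, then offset-aligned by
subtracting the mean of the first 10% of samples. Resampling uses the same
mirror-padding-and-mean-removal guard as the smoother: without it a
constant window would come back distorted at the edges. Baseline removal is
idempotent, which the tests assert.

## Shape dictionary

* **Denoising.** PCA retains the minimal number of leading components whose
  cumulative explained variance reaches 98%, and windows are reconstructed
  from those components only. Clustering and labeling both operate on this
  reconstructed representation (the source describes reconstructing each
  CDP from the selected dimensions; operating on the same representation
  throughout is the consistent reading).
* **Number of classes.** Two internal validity indices vote over the
  candidate range: average silhouette width and the Calinski-Harabasz
  criterion. The consensus is the modal vote, ties resolved toward the
  smaller k (parsimony). If even the best silhouette stays below 0.25 — the
  conventional "no substantial structure" threshold — the minimum candidate
  is returned and a message emitted.
* **k-means.** Because well-separated clusters of very unequal sizes
  routinely trap randomly initialized k-means in poor local optima, each
  fit runs once from a Ward-linkage tree cut and ten times from random
  starts, keeping the best inertia. Cluster labels are assigned
  deterministically (decreasing size, then centroid energy) so a fixed
  seed yields a byte-identical dictionary.
* **Labeling.** Each event takes the label of the Euclidean-closest
  prototype; exact ties go to the lowest-index label.

A caveat established during validation: rare classes (few events) are
imperfectly spanned by the 98% PCA basis, so their prototypes can sit
visibly away from the true class mean even when clustering is perfect.
This is a property of denoised-space prototypes, not an implementation
fault; the dictionary-recovery tests therefore use balanced class
frequencies to isolate what they are meant to measure.

## Symbolization and the pause token

Events become tokens; the special pause symbol `$` stands for an
inter-event interval in which no event was identified. The pause duration
is the arithmetic mean of consecutive inter-event intervals, and between
events separated by a gap `g` the discretization inserts
`floor(g / pause)` pauses, so gaps shorter than one pause period insert
nothing. A relative tolerance of 1e-9 inside the floor guards exact
multiples against floating-point representation.

The source material describes the pause both as the mean inter-event
interval and, elsewhere, as a fixed 100 ms ("no other detectable CDP within
100 ms"). The mean-interval rule is taken as normative; the fixed reading
can be emulated by passing `pauseDurationS = 0.1` explicitly.

Pauses before the first and after the last detected event have no bounding
events, so no discretization rule can recover them; round-trip exactness
is therefore stated for the planted sequence between its first and last
event.

## Markov analysis

With alphabet size m (pause included), pair counts $O_{ij}$ count how often
symbol $j$ immediately follows $i$; the maximum-likelihood transition
matrix is the row-normalized count matrix, $\hat P(j\mid i) = O_{ij} /
\sum_k O_{ik}$.

* **Independence expectation.** Under the renewal null,
  $E_{ij} = n\,\hat p_i\,\hat p_j$ with marginals taken over the whole
  sequence. The number $n$ is taken as the number of *adjacent pairs*
  (length − 1) rather than the number of tokens, so that
  $\sum O = \sum E$ exactly; the two readings differ by one count.
* **Divergence.** $X^2 = \sum_{E_{ij}>0} (O_{ij}-E_{ij})^2/E_{ij}$. Cells
  with $E = 0$ and $O = 0$ contribute zero; $E = 0$ with $O > 0$ cannot
  occur when both matrices come from the same sequence and is trapped as an
  error.
* **χ² test.** The statistic is referred to a χ² distribution with
  $m(m-1)$ degrees of freedom — the formula printed in the methodology this
  package reproduces, with the pause counted in m (12 shapes + pause = 13
  symbols, df = 156). The classical degrees of freedom for an order-0
  versus order-1 Pearson comparison would be $(m-1)^2$; with the larger
  printed value the test is *conservative* on independent data (empirical
  type-I rate well below the nominal level). The package keeps the printed
  formula and documents the consequence rather than silently correcting
  it; the permutation test below is exact by construction and is the
  recommended variant.
* **Permutation test.** Surrogates are uniform random permutations of the
  sequence — the symbol histogram is preserved exactly while all
  sequential structure is destroyed — and each surrogate's divergence is
  computed exactly as the original's. The p-value convention is
  $(1 + \#\{X^2_{sur} \ge X^2_{obs}\}) / (1 + N)$, so p is never zero and
  10,000 surrogates can resolve "less than 1 in 10,000".
* **Whittle surrogates.** For the order-2 test, surrogates must preserve
  the full pair-count matrix (the order-1 sufficient statistic). A
  surrogate is drawn uniformly among all sequences with exactly the
  original's pair counts — equivalently, uniform random Eulerian trails of
  the pair-count multigraph. The sampler draws the "last-exit"
  arborescence toward the final symbol by Wilson's loop-erased random walk
  with edge weights equal to the pair counts, then shuffles each vertex's
  remaining out-edge instances uniformly. Uniformity over instance-level
  trails implies uniformity over token sequences because every sequence
  corresponds to the same number of instance orderings. Fixing all pair
  counts forces the surrogate's first and last symbols to equal the
  original's. The tests verify, by exhaustive enumeration on small
  alphabets, that the sampler hits exactly the feasible set and does so
  uniformly.
* **Order-2 statistic.** The methodology being reproduced never prints its
  second-order statistic. The natural second-order analogue of the pair
  divergence is used: observed triplet counts $N(i,j,k)$ against their
  order-1 expectation $N_2(i,j)\,\hat P(k \mid j)$, summed over cells with
  positive expectation. Conditional on the pair counts all sequences are
  equally likely under the order-1 null, so the Whittle-surrogate null
  distribution is exact. With 1,000 surrogates the smallest attainable
  p-value is about 0.001; the calibration tests run at 199 surrogates,
  which resolves 0.005 and keeps runtimes short.

## State identification

Each (segment, step) pair yields a transition model; the model set for a
segment is used to attribute a held-out test sequence to a step by the
log-likelihood $\sum_t \log P(c_{t+1} \mid c_t; m_{l,s})$.

* **Smoothing.** Held-out sequences can contain transitions unseen in
  training, for which the maximum-likelihood model assigns probability
  zero and the log-likelihood diverges. The protocol therefore smooths
  additively: $P(j \mid i) = (N_{ij} + \alpha)/(N_{i\cdot} + \alpha m)$,
  default $\alpha = 0.5$ (the Jeffreys pseudo-count). $\alpha = 0$
  reproduces the unsmoothed estimator exactly, and as $\alpha \to 0^+$ the
  ranking converges to the unsmoothed ranking whenever all test
  transitions were seen in training.
* **Hold-out.** "The last 100 CDPs" counts non-pause tokens; the pauses
  interleaved among them travel with the test suffix, because pauses
  participate in the likelihood through the `$` row and column. At the
  typical event rate 100 events span roughly 12 s.
* **Success criterion.** A prediction succeeds when the top-ranked step
  belongs to the true *maneuver* (per the protocol's worked example, a
  control test sequence attributed to the other control step is a
  success). Exact-step accuracy is reported secondarily. Ties rank toward
  the earlier step; the consensus across segments is the modal predicted
  maneuver, ties broken by summed log-likelihood.
* **Random baseline.** Under step-uniform truth and prediction, the
  success probability is $\sum_t (n_t/N)^2$ over maneuver types. The
  Monte-Carlo estimator draws the predicted step per trial and uses the
  exact success probability given that prediction (a Rao-Blackwellized
  indicator): still an unbiased 10,000-trial Monte-Carlo estimate, but
  with error far below the 0.1-percentage-point resolution at which such
  baselines are conventionally printed, where a raw 0/1 indicator would
  carry a ~0.5-point standard error.

## The synthetic generator

The generator emulates exactly the statistical structure the analysis
assumes, with ground truth for every intermediate quantity.

* **Templates.** Each shape class is a sum of 2–4 Gaussian bumps — a
  dominant positive bump near the window center plus satellites confined
  to the central region — low-pass filtered at 60 Hz, edge-tapered, and
  redrawn until pairwise Euclidean distances exceed a floor well above
  five noise standard deviations. Confining satellites keeps templates
  from carrying secondary peaks near the window edges, which would spawn
  spurious double detections; the distinctness floor keeps
  nearest-prototype labeling well posed.
* **Event timing.** The published material gives no timing model beyond
  "roughly 12 s per 100 CDPs", so the generator defines one: consecutive
  events with k intervening pauses are separated by
  `pause * (k + 0.92)` plus Gaussian jitter truncated at `0.07 * pause`.
  Two properties motivate the constants: the gap always lies strictly
  inside `(k*pause, (k+1)*pause)`, so the floor-rule discretization
  recovers exactly k pauses even at full jitter; and the smallest possible
  peak separation is 0.85 pauses = 102 ms at the default 120 ms pause,
  so adjacent 100 ms windows never overlap and event windows stay
  uncontaminated by neighbors. Waveforms are placed so the *smoothed* peak
  (the detector's time-stamp) lands exactly at the scheduled time.
* **Multichannel experiments.** Maneuver-specific generating matrices
  share a random background and concentrate extra mass
  (`separation`, default 0.45) on maneuver-specific target symbols, giving
  a guaranteed per-row total-variation separation of
  `(1 - pauseProb) * separation` (about 0.34 at defaults). Pauses occur
  with probability 0.25 after any token, matching an event rate near the
  quoted 100 CDPs per ~12 s. Per-segment variation mixes each state
  matrix with a random stochastic matrix (weight 0.1), mirroring the
  per-segment variability of real multichannel predictions. Sequences are
  at most 6,000 symbols per step, the stated upper bound for a 10-minute
  recording.
* **What it does not emulate.** Real CDP waveform morphology beyond
  "smooth and distinct"; nonstationary or non-Gaussian noise; line or
  movement artifacts; drifting event rates; inter-channel synchronization
  (explicitly out of scope). Passing tests therefore demonstrate that the
  *analysis machinery* is correct and calibrated under its own
  assumptions — not that those assumptions hold for any particular real
  recording.

## Numerical and reproducibility choices

* All stochastic functions accept a `seed`; identical seeds give
  bit-identical outputs (chains and surrogate loops run in C++ on R's own
  RNG stream).
* p-values are clamped to at least the smallest positive double (the χ²
  tail underflows near machine zero for extreme statistics).
* `floor(g/p + 1e-9)` guards pause counting at exact multiples.
* Degenerate inputs: empty traces detect to empty event sets; a step with
  only pauses yields a zero frequency row with a flag; single-symbol
  sequences give divergence 0 and p = 1 under permutation; `k = 1`
  dictionaries are allowed but flagged as degenerate in the sweep.

## Problem sizes used by the test-suite

The suite exercises the protocol at sizes chosen to make its statistical
assertions meaningful while keeping a full run in minutes on one core:
type-I calibration uses 500 iid replicates of length 6,000 (permutation
nulls at 999 surrogates; 10,000 for the strong-chain significance check);
order-2 calibration uses 200 first-order chains of length 6,000 at 199
surrogates; classifier experiments use the 2+2+4-step, 11-segment design
with 3,000 symbols per step over 10 seeds; rendered end-to-end checks use
sequences of 120–700 tokens at the native 10 kHz. The acceptance script
reports each quantity with the problem size it used.

## Known limitations

* The χ² variant inherits the printed, conservative degrees of freedom
  (see above); use the permutation test when exact level matters.
* Dictionary-size selection is reliable for well-separated classes but can
  merge near-duplicate shapes or split classes under heavy contamination;
  the robustness sweep (`robustnessSweep`) exists precisely because the
  downstream Markov conclusions should not hinge on the exact k.
* Prototypes live in the 98%-variance PCA space; rare classes are
  represented slightly off their true mean (see the dictionary section).
* The similarity index between time steps mentioned as future work in the
  source material has no published formula and is not implemented.
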