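---
title: "Phase-locking energy landscapes: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking energy landscapes: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eplsa)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic generators do and do not emulate,
and the numerical choices made where the underlying method is silent.

## From BOLD signals to binary activity patterns

The pipeline assumes its input is a preprocessed, band-limited BOLD table
(frames × regions); all denoising, filtering and atlas work is upstream of
this package. Region series are optionally averaged into networks
(`aggregate_networks()`, unweighted mean of member regions — region
volumes are deliberately not used as weights, since the method operates on
network-representative signals, not on volume-integrated activity).

`hilbert_phase()` demeans each column and forms its analytic signal
$z(t) = s(t) + i\,H[s](t)$ with the discrete Hilbert transform computed in
the frequency domain (one-sided spectrum doubling). The instantaneous
phase is the quadrant-aware angle $\arg z(t) \in (-\pi, \pi]$ — not a
naive $\arctan(H[s]/s)$, which would lose the quadrant. Finite-length
transforms are least reliable at the series ends, so a configurable
number of frames (`trim`, default 1 per end) is excluded from the valid
range; the default is minimal because the phase estimate recovers quickly
and band-limited inputs have little energy at the disruptive frequencies.
A constant column has no phase and raises an error rather than a warning.

At each frame the dynamic phase-locking matrix
$\mathrm{dPL}(i,j,t) = \cos(\varphi_i(t) - \varphi_j(t))$ is symmetric,
unit-diagonal and bounded in $[-1, 1]$. Its leading eigenvector summarizes
the dominant synchronization mode; the sign pattern of its components
splits networks into two phase communities.

**Eigenvector sign convention.** An eigenvector is defined only up to
global sign, so binarization needs a fixed orientation. `fix_eig_sign()`
orients the vector so that non-positive components are in the strict
majority (zeros count as negative); on an exact tie the largest-magnitude
component is made negative. This matches the community-splitting
convention used in the leading-eigenvector clustering literature and makes
the downstream binarization deterministic. When the leading eigenvalue is
degenerate (e.g. a perfectly uncorrelated frame), the deterministic
symmetric eigensolver output in canonical network order is sign-fixed and
used as-is; reproducibility is preferred over any attempt to pick a
"better" basis vector.

**Binarization.** Components strictly above zero map to active ($+1$),
all others to inactive ($-1$). The threshold is structurally zero — the
bipartition is carried by the eigenvector's signs — so no free parameter
is introduced. Patterns are encoded as integers with network 1 in the
most significant bit and $+1 \mapsto 1$, which makes the code a stable key
across every module.

## The pairwise maximum-entropy model

Over the $2^N$ binary patterns the package fits the Boltzmann distribution

$$P(\sigma \mid h, J) \propto e^{-E(\sigma)}, \qquad
E(\sigma) = -\sum_i h_i \sigma_i - \tfrac12 \sum_{i \neq j} J_{ij} \sigma_i \sigma_j,$$

the maximum-entropy distribution consistent with the empirical first and
second moments. Fitting is by exact-gradient ascent: model moments are
computed by full enumeration (practical for $N \le 20$; the intended
working range is roughly 6–15 units, and the canonical analysis uses
$N = 7$ networks, i.e. 128 patterns), and

$$h \leftarrow h + \eta(\langle\sigma_i\rangle_{\mathrm{emp}} - \langle\sigma_i\rangle_{\mathrm{mod}}), \qquad
J \leftarrow J + \eta(\langle\sigma_i\sigma_j\rangle_{\mathrm{emp}} - \langle\sigma_i\sigma_j\rangle_{\mathrm{mod}}).$$

Because the log-likelihood is concave in $(h, J)$ and the gradient is the
moment gap, the iteration converges monotonically for sufficiently small
$\eta$. Defaults: $\eta = 0.2$, tolerance $10^{-6}$ on the largest
absolute moment discrepancy, at most 50 000 iterations, parameters
initialized at zero. At $N = 7$ with generic data this converges in a few
hundred iterations (well under a second).

Two practical notes:

* *Zero-frequency patterns are fine.* The empirical distribution is not
  smoothed; only its moments enter the fit, and the model distribution is
  strictly positive regardless.
* *Near-deterministic distributions need a gentler step.* When the data
  concentrate on very few patterns, some empirical moments sit at or near
  $\pm 1$ and the maximum-likelihood parameters lie at (or diverge toward)
  the boundary. With the default $\eta = 0.2$ the ascent can overshoot and
  oscillate; the fitter detects a moment gap that grows for 100
  consecutive iterations and aborts with advice to reduce the learning
  rate. For such inputs (e.g. low-noise simulations) $\eta = 0.05$ with a
  looser tolerance is the recommended setting; the landscape's minima are
  insensitive to the exact stopping point because they are determined by
  the ordering of energies, not their precise values.

`fit_mem()` returns a `mem_fit` with broom-style `tidy()` (one row per
$h_i$ and upper-triangle $J_{ij}$) and `glance()` (iterations, moment gap,
log-likelihood). Group-level fits pool pattern series frame-wise across
scans before computing the empirical distribution (`eplsa_run()`);
per-scan fits are available by fitting each series separately.

## Energy landscape construction

A pattern is a **local minimum** when its energy is strictly below all $N$
single-flip neighbours. Under the Boltzmann form this is equivalent to
being locally most probable, which is what makes the minima interpretable
as recurrent brain states.

**Basins** are assigned by steepest descent: from any pattern, repeatedly
move to the strictly lowest-energy neighbour until a minimum is reached.
Two deterministic tie rules close the definition where continuous fitted
energies never tie but hand-built or degenerate landscapes might: among
equally low neighbours the smallest pattern code wins, and a pattern with
no strictly lower neighbour but an equal-energy one moves to the
smallest-code equal neighbour (flagged as a degenerate landscape). A
cycle guard caps walks at $2^N$ steps; it cannot fire under strict
descent and exists to surface corrupted inputs.

**Barriers and the disconnectivity graph.** The construction lowers a
threshold through the sorted distinct energy values, removing patterns at
or above it from the hypercube graph; the barrier between two minima is
the lowest level at which they remain connected. The package computes
this with an equivalent union-find sweep that activates patterns in
ascending energy order and records the activation energy at which two
minima's components first merge. That energy is exactly the minimax
(bottleneck) path cost — the smallest, over all hypercube paths between
the minima, of the maximum energy along the path — which is what the
test suite verifies against an independent Dijkstra-style widest-path
oracle (exact equality on hundreds of random landscapes). Barriers form
an ultrametric, so the merge structure is a tree; it is exported as
Newick with branch lengths equal to merge height minus child height, so
leaf depths reproduce minima energies and internal nodes sit at barrier
heights. `autoplot()` draws the conventional disconnectivity diagram.

## State dynamics

`label_states()` maps each frame's pattern to its basin; run-length
encoding then yields:

* **fractional occupancy** — share of frames per state;
* **dwell time** — mean contiguous run length × TR, in seconds (frames
  are available by dividing by TR; seconds are the default so values are
  comparable across acquisitions);
* **occurrence frequency** — runs per second of scan;
* **transition matrix** — by default self-transitions are excluded and
  rows are normalized over observed exits, which is the natural reading
  of inter-state transition probabilities; `include_self = TRUE` gives
  the row-stochastic Markov form instead. Rows of unvisited states are
  `NA`, never silently zero.

**Major versus minor states.** The method's downstream analyses contrast
dominant ("primary") and rare ("secondary") states but no single
classification rule is canonical, so three are exposed and the applied
rule is recorded in the result: the default calls a state major when its
basin size exceeds the uniform share $1/n_{\text{states}}$ (scale-free and
parameter-free); `top-k` keeps the $k$ largest basins; `explicit` takes a
user list. Note that basin size (share of the $2^N$ pattern space) and
fractional occupancy (share of observed frames) can disagree — a weakly
magnetized landscape gives spin-flip partner minima large basins that are
rarely visited — which is precisely why the explicit rule exists. If a
rule produces an empty major set (e.g. exactly equal basins), the largest
basin is promoted and a message is emitted.

**Direct versus indirect transitions.** The state sequence is collapsed
to runs; each excursion between consecutive major-state runs is direct
(adjacent runs) or indirect (all intervening runs minor). The reported
probability normalizes over all such excursions, and the counts are
returned so per-pair normalizations can be computed if preferred.

## Baselines

* **Leading-eigenvector clustering (LEiDA).** `leida_fit()` runs k-means
  with Euclidean distance on the sign-fixed eigenvectors (`n_init`
  restarts, default 20, from a mandatory seed; best inertia kept). On
  unit-norm vectors Euclidean distance is monotone in cosine distance, so
  the choice is conventional rather than consequential; sign-fixing
  before clustering avoids splitting a state across antipodal vectors.
  `cluster_quality()` reports the Dunn index (minimum inter-cluster
  point distance over maximum intra-cluster diameter; `Inf` flags
  zero-diameter degeneracies) and distortion (k-means inertia) for
  choosing $k$.
* **Amplitude binarization (conventional energy-landscape input).**
  `ela_binarize()` z-scores each network column and thresholds at zero,
  the classical amplitude-based front end; it emits the same
  `pattern_series` type, so everything downstream of binarization is
  shared and method comparisons isolate the front end.

## Evaluation statistics

**MNR discriminability.** For every ordered within-subject measurement
pair $(i, j)$, with all of $i$'s same-subject distances excluded from the
comparison pool,

$$r_{i,j} = 1 - \frac{\#\{D_{i,\cdot} < D_{i,j}\} + 0.5\,\#\{D_{i,\cdot} = D_{i,j}\}}{N - S},$$

where $N$ is the total measurement count and $S$ the size of $i$'s
subject group; the index is the mean over pairs. It is 1 when every
repeat of a subject is closer to its other repeats than to anyone else's
measurements, and 0.5 under exchangeability. Exclusion is implemented by
masking rather than literal infinite distances, and the tie term makes
the index invariant to strictly monotone transforms of the distances
(rank-based), which the suite tests directly.

**Symmetrized KL divergence.** $0.5[\sum P \ln(P/Q) + \sum Q \ln(Q/P)]$
between occupancy distributions. Zero occupancies occur whenever a state
is unvisited in one condition; additive smoothing with
$\varepsilon = 10^{-10}$ followed by renormalization is applied only when
zeros are present, leaving exact closed-form cases untouched (the
$(0.8, 0.2)$ vs $(0.2, 0.8)$ pair evaluates to $0.6 \ln 4$ to machine
precision).

`occupancy_features()` exports one feature row per scan over a zero-filled
union of states (occurrence frequency by default, occupancy optionally),
with subject/session/condition metadata — the exact table an external
classifier consumes, so classification benchmarks can be reproduced with
any standard learner without this package taking a dependency on one.

## Synthetic generators: what they emulate, and what they do not

All generator randomness flows from one integer master seed through named
sub-streams (`split_seed()`), so multi-subject designs are bitwise
reproducible and sub-components can be regenerated independently.

* `sample_ising()` draws i.i.d. patterns from the fully enumerated
  Boltzmann distribution by inverse-CDF sampling — exact, no MCMC, no
  autocorrelation. It validates the fitting direction (parameter recovery
  at $10^5$ samples is accurate to a few times $10^{-2}$ for parameters
  drawn uniformly from $[-0.5, 0.5]$ at $N = 7$).
* `gen_oscillator_bold()` draws a latent path from a Markov chain and
  emits $\sin(2\pi f t + \theta_{s}(j))$ per network plus Gaussian noise.
  Defaults — $f = 0.05$ Hz, TR $= 0.72$ s, noise sd 0.1 against unit
  amplitude, switching probability 0.05 per frame (mean dwell ≈ 14 s) —
  sit inside the conventional BOLD band and dwell-time range, keeping the
  Hilbert phase well-defined without any filtering step.
* `gen_reliability_set()` produces multi-subject, multi-session feature
  tables in two modes: subject-specific two-state Markov chains
  (stay-probabilities drawn once per subject on the logit scale; sessions
  are fresh realizations; features are occupancies) and a Gaussian
  random-effects mode (subject mean + session noise) that gives direct,
  independent control of between- and within-subject dispersion — the
  two endpoints of the discriminability index (within-dispersion zero
  gives MNR $= 1$ exactly; between-dispersion zero gives exchangeability,
  MNR $\approx 0.5$).

What these generators deliberately do **not** emulate: hemodynamic
response convolution, $1/f$ and physiological noise spectra, scanner
drift, head motion, spatial correlation of noise across networks, and
amplitude–phase coupling. Passing tests therefore demonstrate that the
algorithms recover the structure they model — phase-locking communities,
Boltzmann statistics, Markov state dynamics — not that real BOLD data
satisfy those models; conclusions about real data rest on the method's
published applications, not on this suite.

## Validation problem sizes

The test suite and the acceptance script exercise the package at the
scales the method targets: $N = 7$ networks (128 patterns) for model
fitting and recovery from $10^5$ exact samples; random landscapes at
$N = 4$–$6$ (16–64 patterns), 100 at a time, for exact agreement of
barriers and basins with brute-force oracles; $10^4$-frame oscillator
simulations for dynamics recovery (occupancy to a few parts per thousand,
transition probabilities to better than 0.015); 200 replicates for the
exchangeability endpoint of the discriminability index. These sizes are
the package's own validation design; all complete in seconds on one core.

## Known limitations

* Exact enumeration bounds the unit count: practical fitting at
  $N \lesssim 15$, hard cap at 20. Pseudo-likelihood or MCMC fitting for
  larger $N$ is out of scope.
* Only the leading eigenvector is retained per frame; secondary
  synchronization modes are discarded by design.
* The maximum-likelihood parameters of (near-)deterministic pattern
  distributions are unbounded; fits there should use a reduced learning
  rate and a moment-gap tolerance appropriate to the question, as
  described above.
* Group-level fits pool frames across subjects, weighting subjects by
  scan length; a per-subject fit followed by comparison of parameters or
  metrics is the alternative when scan lengths differ substantially.
* ROI-level (non-aggregated) phase-locking landscapes are intentionally
  unsupported: at hundreds of regions the state space is astronomically
  larger than any scan, and the fitted model would be meaningless.
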