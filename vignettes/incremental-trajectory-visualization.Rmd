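---
title: "Incrementally learned visualization of longitudinal trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incrementally learned visualization of longitudinal trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilvis)
```

## The problem

Longitudinal experiments -- for example multi-electrode-array (MEA)
recordings of maturing brain organoids -- produce a batch of high-dimensional
observations at each sampling timepoint. The scientific question is usually
about the *progression*: is the system drifting steadily away from its
initial state, is a treated culture following a different path than an
untreated one, and do two treatments produce similar paths?

Static embeddings (t-SNE, UMAP) answer none of these questions well for an
*ongoing* experiment, because refitting them after every new batch produces a
fresh, arbitrarily oriented map: the picture at month 3 cannot be compared to
the picture at month 1. `ilvis` instead maintains a single *parametric* model
that is fine-tuned as increments arrive, so consecutive visualizations evolve
smoothly and remain mutually comparable.

## The model

The embedding state is $\theta = \{C, E, Y\}$:

* $C = \{c_j \in \mathbb{R}^D\}$ -- *coding vectors*, a compact codebook
  quantizing the input space;
* $E$ -- a symmetric non-negative weight matrix; $G = (C, E)$ is a topology
  graph whose heavy edges span dense data regions;
* $Y = \{y_j \in \mathbb{R}^2\}$ -- one 2D layout position per coding vector
  (a bijection with $C$).

Each training session runs three steps over the accumulated data:

1. **Vector quantization with growth.** Inputs are assigned to their nearest
   coding vector (ties broken by lowest index). The winner moves toward the
   input with a linearly decaying learning rate, and its graph neighbors
   follow at a fraction of that rate (winner-take-most). An input farther
   than a growth threshold $\theta_g$ from every coding vector spawns a new
   coding vector at its position. $\theta_g$ is derived per session as
   $\max(0.15\,\mathrm{RMS}, 1.5\,\mathrm{NN})$, where RMS is the root mean
   square distance of the session data to its centroid and NN the median
   nearest-neighbor spacing (estimated from at most 400 rows). The RMS term
   sets the codebook resolution relative to the data's extent; the NN floor
   matters in noisy high-dimensional data, where pairwise distances
   concentrate and a purely extent-based threshold would memorize every
   observation instead of letting winners average the noise out.
2. **Self-organization.** After each assignment the edge between the winner
   and the runner-up is reinforced by 1 while the winner's other edges decay
   by a factor 0.99 -- so edges that span dense regions accumulate weight.
   Reinforcement is gated: it happens only when the runner-up is at most
   `edge_ratio` (default 3) times farther from the input than the winner,
   i.e. when the input genuinely lies *between* the two neighborhoods. The
   gate prevents far-apart clusters from being welded together by points deep
   inside one of them. Edges below $10^{-3}$ of the maximum weight are pruned
   at the end of the session.
3. **Cross-entropy layout.** $Y$ is optimized by stochastic gradient descent
   on the cross entropy between the graph weights (log-compressed to $[0,1]$,
   because Hebbian counts span orders of magnitude) and the low-dimensional
   kernel $q_{jk} = 1/(1 + \lVert y_j - y_k \rVert^2)$: attraction along
   edges, repulsion against negative samples (5 per edge endpoint per epoch),
   updates clamped at 4 per coordinate, learning rate decaying linearly from
   0.05 over 150 epochs.

**Layout placement.** Newly grown coding vectors initially sit at their
parent's layout position. Before the SGD step, the session computes a
classical MDS solution of the codebook distance matrix and aligns it to the
carried-over layout with a similarity Procrustes fit (rotation/reflection,
isotropic scale, translation); the aligned solution seeds the layout that SGD
then polishes. At the very first session, where there is nothing to align
to, the MDS solution is used directly. Euclidean codebook distances are the
default placement metric because they preserve *global* relations --
distances between different trajectories' medians are exactly what the
downstream similarity ranking consumes. A geodesic variant (shortest paths
over the topology graph augmented with nearest-neighbor shortcuts) is
available via `song_config(placement_metric = "geodesic")` for data on
strongly curved manifolds, at the cost of stretching global distances.

**Incremental training.** At session $i$ the model is fine-tuned on
$D_i = \bigcup_{k \le i} I_k$, the union of all increments so far (full
replay). Replaying everything is the package's anti-forgetting mechanism;
a rehearsal strategy that subsamples old increments is a known alternative
but is deliberately not implemented -- at the intended scale (a few thousand
segments) full replay is cheap and exact. The orientation continuity that
carry-over buys can be measured with `orientation_qc()`; reinitializing
instead of carrying over (`run_session(..., reset_params = TRUE)`) is
provided only as an ablation and demonstrably loses orientation.

**Projection.** `song_transform()` maps an input to the inverse-squared-
distance weighted average of the layout positions of its 3 nearest coding
vectors; an input coinciding with a coding vector maps exactly to that
vector's position. Inputs far outside the codebook's support are thereby
pulled to the nearest cell -- a deliberate, conservative extrapolation.

**Median tracing and distances.** Each increment's 2D points are summarized
by their coordinate-wise median (robust to outlying segments), and medians
are connected chronologically to give the progression trajectory $T^L$. Two
trajectories with medians $a_i, b_i$, $i = 1..n$, are compared by

$$D(A,B) = \frac{1}{n} \sum_{i=1}^{n}
  \left[(a_i^x - b_i^x)^2 + (a_i^y - b_i^y)^2\right]^{1/2},$$

the mean Euclidean distance between corresponding medians, reported in
embedding units. Unequal increment counts are refused unless truncation to
the common prefix is explicitly requested, since the metric is defined only
for matched $n$.

## The trajectory simulator

The simulator provides ground truth for validating the pipeline. A line in
$\mathbb{R}^D$ with intercepts $p \sim U(-1,1)$ and gradients
$d \sim U(0, 0.01)$ is evaluated at integer pseudo-times $t$ and bent by
squaring a random half of its dimensions:
component $i$ at time $t$ is $(d_i t + p_i)^{a_i}$ with $a_i \in \{1, 2\}$.
The coefficient ranges are package choices (the generating recipe prescribes
random coefficients without ranges): with $t$ up to 499 and squaring, they
keep components of order $10$--$10^2$, a visualizable scale, and non-negative
gradients give the steady outward drift that maturing cultures show. The
fraction of squared dimensions (0.5) is likewise a package default; both are
configurable.

Secondary trajectories are convex combinations of two principals,
$T_3 = \alpha T_1 + (1-\alpha) T_2$ and $T_4 = (1-\alpha) T_1 + \alpha T_2$,
combined *after* exponentiation. The similarity factor $\alpha$ controls how
close a secondary is to its principal: at $\alpha = 1$ they coincide, at
$\alpha = 0.5$ both secondaries coincide with each other.

Increment $i$ holds one point per integer
$t \in [100(i-1),\, 100 i - \delta)$, i.e. $100 - \delta$ points; the
sampling gap $\delta \in [0, 99]$ models unobserved stretches between
recordings. Observation noise adds $\lambda \phi$ per dimension,
$\phi \sim N(0, SD_d^2)$, where $SD_d$ is the per-dimension standard
deviation of the noiseless trajectory over the full pseudo-time span -- so
$\lambda = 0.2$ means "20% noise" in every dimension regardless of its
magnitude (the noise recipe leaves the SD source open; this scale-free
choice is the package's). At $\delta = 99$ an increment holds a single
point, which is replicated into 100 copies with $N(0, 0.001^2)$ jitter --
replication, deliberately not interpolation between sampled times.

## MEA featurization and the spike baseline

Raw recordings (electrodes x samples, 25 kHz in the target hardware) are
high-pass filtered with a third-order Butterworth at 300 Hz -- applied
forward-backward by default, so spike shapes are not phase-distorted (a
single causal pass is available) -- segmented into non-overlapping 4 s
windows anchored at the first sample (trailing partial windows discarded),
and transformed with the FFT. Only the first half of each channel's
amplitude spectrum is kept (conjugate symmetry of real signals; DC bin
included). The per-channel half-spectra are concatenated -- preserving
per-electrode information -- and reduced to exactly `k = 1000` features by
averaging adjacent bins, a deterministic, data-independent reduction that
preserves spectral ordering (truncation and max-pooling are selectable).
Whether the 1000 features should be per electrode or in total is not fixed
by the recipe; this implementation reads it as the total per segment.
Segments of timepoint $i$ form increment $I_i$; labels with missing
timepoints get consecutively renumbered increments so that differently
sampled organoids can still be modeled jointly.

The conventional baseline, `detect_spikes()`, subtracts the reference
channel if one is declared, band-passes 300--1000 Hz, and detects
negative-going crossings of $-4 \cdot MS$ where $MS$ is the median of the
filtered signal's absolute values (taken literally; the 0.6745-scaled MAD
variant is available). Crossings within a 1 ms refractory window collapse
into one event -- a standard dead time at 25 kHz. Note that for Gaussian
background noise $-4 \cdot MS \approx -2.7\sigma$, which yields a nonzero
noise-crossing rate; detector quality statements in the tests are therefore
recall-based (matched to injected ground truth) rather than raw counts.

## The surrogate MEA generator

`generate_surrogate()` emulates a longitudinal MEA experiment: each channel
is Gaussian noise plus Poisson-timed biphasic spike waveforms (about 1 ms,
negative main lobe with a smaller rebound -- the shape extracellular spikes
present to a negative threshold), with a per-timepoint firing-rate schedule
as the longitudinal drift. The default sampling rate is 5 kHz rather than
25 kHz; the waveform timescale is unchanged, so filtering and detection
behave the same while runs stay fast. What the surrogate does *not* model:
bursting dynamics, synchrony between electrodes, cross-talk,
non-stationary noise, electrode drift. Tests passing on surrogates therefore
demonstrate pipeline mechanics (featurization, incremental embedding, trend
recovery), not biological realism.

## Numerical choices and degenerate inputs

* Nearest-coding-vector ties break to the lowest index; the layout and
  transform are then fully deterministic given $\theta$.
* All stochastic steps -- codebook initialization (4 coding vectors drawn
  from the first batch), shuffling, growth jitter, negative sampling -- draw
  from R's RNG, so a single `set.seed()` makes entire runs bit-reproducible,
  and a run resumed from a checkpoint equals an unbroken one.
* An empty batch is a no-op; an empty increment in median tracing is skipped
  with a warning; an all-zero spike channel yields threshold 0 and no
  events; a recording shorter than one window yields no segments and a
  warning.
* Checkpoints use RDS for exact round-trips; a JSON export (full precision)
  is provided for interoperability.
* `max_nodes` (default 1000) caps codebook growth; at the intended problem
  sizes the cap is never approached.

## Problem sizes

The package's own validation runs use the simulator at $D = 100$, $n = 5$
increments, 100 points per increment, noise $\lambda \in \{0, 0.2\}$, gaps
$\delta \in \{0, 25, 50, 99\}$, similarity $\alpha \in \{0.6, 0.7, 0.8,
0.9\}$, with 10 seeded replicates for every stochastic claim; surrogate MEA
runs use 9 electrodes at 5 kHz, 40--120 s per timepoint, 5 timepoints.
These sizes make the full suite run in a couple of minutes on one CPU while
matching the simulated study conditions exactly.

## A worked run

```{r example, eval = FALSE}
set.seed(1)
trajectory <- make_trajectory(make_line(100), square_fraction = 0.5)
increments <- add_noise(form_increments(trajectory, n = 5, delta = 0,
                                        label = "T1"), lambda = 0.2)
result <- joint_model(list(T1 = increments))
projection <- result$projections$T1
projection            # 2D medians, chronologically ordered
trend_score(projection)

# similarity ranking of composed trajectories
set.seed(2)
T1 <- make_trajectory(make_line(100), 0.5)
T2 <- make_trajectory(make_line(100), 0.5)
sec <- compose_secondary(T1, T2, alpha = 0.8)
streams <- list(T1 = form_increments(T1, 5, 0, "T1"),
                T2 = form_increments(T2, 5, 0, "T2"),
                T3 = form_increments(sec$T3, 5, 0, "T3"),
                T4 = form_increments(sec$T4, 5, 0, "T4"))
pr <- joint_model(streams)$projections
rank_distances(pr$T1, pr[c("T2", "T3", "T4")])
```

## Known limitations

* The 2D layout is a similarity-preserving *visualization*, not an isometry:
  distances are meaningful relatively (rankings, trends), not absolutely.
* Trajectories embedded in separate models are not comparable -- joint
  modeling is the supported route, and `rank_distances()` assumes it.
* The default Euclidean placement favors global metric fidelity; data on
  strongly curved low-dimensional manifolds may prefer the geodesic
  placement option.
* Full replay stores all increments; for experiments with orders of
  magnitude more segments a rehearsal scheme would be needed.
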