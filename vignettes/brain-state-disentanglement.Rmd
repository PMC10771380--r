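---
title: "Disentangling transient brain states from resting-state MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling transient brain states from resting-state MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megstates)
```

## The problem

Resting-state MEG and EEG recordings are believed to alternate between a
small number of transient, quasi-stable spatiotemporal patterns — brain
states — each a burst of band-limited oscillatory activity generated by a
circumscribed cortical region and lasting tens to hundreds of
milliseconds.  In focal epilepsy the interest is clinical: among the
states expressed by a patient's resting recording, one may reflect the
epileptogenic network, and localizing its cortical generator from
noninvasive data can guide intracranial electrode placement.  `megstates`
implements the full analysis chain: segmentation of the multichannel
recording into states, per-state source localization, per-state directed
connectivity, and a graph-theoretic score that flags the most likely
pathological state.  A Monte-Carlo simulator with a known ground truth
closes the loop and quantifies every step.

## The model

### Time-delay embedding and ICA reduction

A state is characterized not by an instantaneous field map alone but by
the joint spatio-spectral content of a short window.  The recording
$y_t \in \mathbb{R}^{C}$ (here $C = 102$ magnetometers) is therefore
embedded: the vectors $(y_t, y_{t-1}, \dots, y_{t-L+1})$ are stacked into
columns of a $(C\,L) \times (T-L+1)$ matrix, with the window length fixed
at 100 ms ($L = 25$ at 250 Hz).  The embedded matrix is centered, reduced
by PCA whitening to $N$ dimensions, and rotated by symmetric fixed-point
ICA (tanh contrast), giving components $IC_i$ (patterns over channels and
lags) and activations $Y_i(t)$ with
$\mathrm{Signal} \approx \sum_{i=1}^{N} Y_i \times IC_i$ on the retained
subspace.  The package verifies this reconstruction identity to
$10^{-6}$ relative error in its test suite.

By default $N$ is the smallest count explaining 95% of embedded variance,
capped at 40.  At the simulator's 10 dB SNR the cap binds: white sensor
noise spreads the residual variance over thousands of embedded
dimensions, so chasing the literal 95% would retain noise, while the
oscillatory signal itself is low-rank and sits comfortably inside the
leading 40 components.

### The embedded hidden Markov model

The activations are modeled with a $K$-state hidden Markov model with
multivariate Gaussian emissions $\mathcal{N}(\mu_k, \Sigma_k)$, initial
distribution $\pi$, and transition matrix $A$.  Inference is variational
Bayes with the conjugate prior family — Dirichlet (concentration 1) over
$\pi$ and each row of $A$, unit-information Normal–Wishart over
$(\mu_k, \Sigma_k)$ with the prior precision matched to the overall
activation covariance.  The E-step runs forward–backward on expected
log-parameters; the M-step updates the variational factors; the free
energy (negative evidence lower bound) is computed every iteration and is
non-increasing, a property the test suite asserts for every restart.
Iterations stop when the relative free-energy change drops below
$10^{-6}$ or after 500 iterations.

Because the free-energy surface is multimodal, fitting restarts from
multiple initializations and keeps the solution with the lowest free
energy.  Restarts alternate two families: k-means++ clustering of the
activations concatenated with their smoothed log-power envelopes
(oscillatory states are near zero-mean and separate by envelope;
mean-shifted states by the raw block), and random contiguous-chunk
labelings.  Each restart runs a short exploratory phase (12 iterations by
default) and only the best is polished to convergence — the schedule used
by the established embedded-HMM toolboxes, and necessary on one CPU at
$T \approx 30{,}000$ embedded samples; `init_iter = Inf` restores
full-convergence restarts.

The most probable state path is decoded by log-domain Viterbi (ties
toward the lower state index).  Runs of identical states become events; a
smoothing step splits events longer than 200 ms into sub-events (which
contribute no transition counts, since self-transitions are neglected)
and merges sub-2-sample flickers.  The empirical transition matrix is
$\bar a_{ij} = N_{i \to j} / \sum_k N_{i \to k}$ over consecutive
differing events.

### Back-projection, localization, connectivity, scoring

Each decoded state receives: a component weighting (its posterior-weighted
RMS activation per component, normalized to sum to one); sensor-space
segments cut from the original recording at the Viterbi intervals; a
topography — the first left singular vector of the centered segment data,
i.e. the dominant field pattern of exactly the data that feed the
beamformer; and a representative time at the global-field-power maximum.

Localization is a unit-gain LCMV beamformer with fixed source
orientation: with segment covariance $C$ and 5% mean-eigenvalue diagonal
loading, $w_v = (C_r^{-1} g_v)/(g_v^\top C_r^{-1} g_v)$, activation
$w_v^\top C\, w_v \ge 0$, and the peak vertex is the argmax.  Source time
courses averaged within each of 68 ROIs (34 per hemisphere) feed a
least-squares MVAR model (order by BIC over 1..10), from which partial
directed coherence
$\pi_{ij}(f) = |\bar A_{ij}(f)| / \sqrt{\sum_k |\bar A_{kj}(f)|^2}$
is averaged over 1–50 Hz in 1 Hz steps.  The top 20% of directed
off-diagonal flows (ties at the cutoff kept) are symmetrized by the
maximum of the two directions into a weighted undirected graph.  Two
global features summarize it: ACC, the mean Onnela (geometric-mean)
weighted clustering coefficient on max-normalized weights, and BCD, the
absolute difference of mean betweenness centrality (distances
$1/\mathrm{weight}$, normalized) between hemispheres.  The graph feature
index $\mathrm{GFI} = (1-\mathrm{ACC}) \cdot \mathrm{BCD}$ rises for
centralized, lateralized — putatively pathological — networks; states are
ranked by GFI with ties broken by BCD then state id.  Across recording
segments, states can be grouped by hierarchical clustering (average
linkage, correlation distance on vectorized connectivity; cluster count
by maximal mean silhouette).

## The simulator

The generator draws $K \in [4,7]$ states, each a cortical vertex (all
pairwise distances > 5 cm) and a frequency uniform on 2–20 Hz.  A
transition matrix with flat-Dirichlet rows drives an event chain; raw
event durations are uniform on 20–200 ms.  Self-transitions are allowed
and merged: a state that repeats across consecutive raw events forms one
longer epoch, and the tapered-cosine (Tukey, taper 0.5) amplitude window
— which mimics the transition edge effect — spans the merged epoch, not
each raw event.  During an epoch only that state's vertex is active, with
a unit sinusoid at the state frequency (phase 0 at epoch onset).  Sensor
data are the leadfield projection plus white Gaussian noise scaled so the
whole-array broadband power ratio equals the requested SNR exactly.  The
realized transition matrix — the zero-diagonal event-level empirical
matrix of the generated chain — is stored separately from the generator,
and evaluation compares against the realized one.

The epoch-merging choice matters beyond realism.  When every 20–200 ms
event is independently tapered and states are forced to switch at every
event, most 100 ms embedding windows straddle an event boundary; the
free-energy-optimal HMM then prefers dedicating a state to the
boundary-window regime (and splitting high-occupancy states by
instantaneous amplitude) over representing a weak state — we verified
that a truth-initialized fit has *higher* free energy than that
degenerate optimum across component counts 8–40, so no amount of
restarting recovers the truth.  With self-transitions merged into longer
tapered epochs (and with events at least as long as the window), the
truth basin is stable and recovery is clean.

The forward model is an analytic single-sphere magnetometer model:
vertices quasi-uniform (Fibonacci lattice) on an 8 cm sphere, 102 radial
magnetometers on an 11 cm sphere, and the closed-form field of a
tangential unit dipole in a conducting sphere.  Radial dipoles are
magnetically silent in spherical geometry, so source moments are
tangential unit vectors; the test suite asserts both the silence and the
rotation invariance of the gain.  ROI labels come from spatial k-means
(34 clusters per hemisphere; hemisphere by sign of x, ties left).  Any
externally computed leadfield can be loaded from a dense gain matrix plus
a geometry table instead.

What the simulator does *not* emulate: colored/physiological 1/f
background, multiple simultaneously active sources, amplitude and phase
variability within a state, realistic cortical geometry, gradiometers,
head movement, and artifacts.  Passing the simulation study therefore
shows the chain recovers states generated under its own assumptions
through a known forward model; it does not certify performance on
clinical recordings.

## Evaluation

Extracted and simulated states are matched greedily: the difference
between an extracted topography and a simulated state's noiseless gain
column is $1 - |r|$ (Pearson); the globally smallest pair is fixed first
and selection repeats on the remainder.  Three per-trial metrics follow:
mean Euclidean distance (mm) from each matched state's LCMV peak to its
simulated source; mean absolute difference between the channel-power-
summed FFT peak of each state's concatenated segments (zero-padded to at
least 1 s) and the simulated frequency; and the Pearson correlation
(negatives floored at 0) between the relabeled event transition matrix
and the realized one.

For slow states the FFT-peak metric has an intrinsic bias worth knowing
about: a 2–4 Hz oscillation restarted at epoch onset rarely completes a
cycle inside a 20–200 ms event, so even a perfectly segmented slow state
has its spectral peak displaced upward by the event-length envelope.  The
~1 Hz average frequency error of the simulation study is dominated by
this effect, not by segmentation failures.

`run_simulation_study()` executes the full chain per trial —
simulate, embed, ICA, VB-HMM at the true $K$, Viterbi, smoothing,
back-projection, localization, matching, metrics — with per-trial seeds
drawn from the study seed, failures recorded rather than dropped, and a
`glance()` method for condition-level means and standard errors.

### Problem sizes

The package's own validation runs at desk scale, chosen once: the
headline study uses 20 trials of 2-minute 102-channel recordings at
250 Hz through a 2000-vertex spherical model with 10 VB restarts; the
ordinal-trend study (SNR 0/5/10 dB; $K = 4\ldots7$) uses 20 trials per
condition of 20 s at 125 Hz through a 400-vertex model with 3 restarts
and 12 components.  The sampling rate default of 250 Hz satisfies Nyquist
for the fastest 20 Hz state while keeping the 100 ms embedding at 25
lags.

## Numerical choices and degenerate inputs

* Oscillation amplitude 1 and phase 0 at epoch onset; SNR defined as the
  whole-array broadband power ratio, with the realized noise rescaled so
  the ratio is exact by construction.
* PCA uses a seeded randomized range-finder SVD (oversampling 10, one
  power iteration) when the embedded matrix is large, exact `svd()`
  otherwise; component signs are fixed by making each component's
  largest-magnitude mixing entry positive.
* FastICA tolerance $10^{-4}$ (the convention of the widely used
  implementations), 200 iterations; non-convergence returns the best
  rotation with a warning, never silently.
* Emission means are estimated freely (the states of interest are
  oscillatory and near zero-mean, but event-locked phase can shift
  means, and the degenerate case costs nothing).
* Covariance collapse is prevented by the Normal–Wishart prior; the LCMV
  solver adds stronger diagonal loading with a warning when a state's
  segments are shorter than the channel count, and an all-zero covariance
  falls back to identity loading (zero data produce zero time courses
  rather than an error).
* Viterbi ties break toward the lower state index; matching ties break
  by row then column; ranking ties by larger BCD then lower state id;
  zero-variance topographies take difference 1; never-visited states are
  flagged and excluded from frequency averages.
* An isolated graph node has clustering coefficient and betweenness 0,
  not `NaN`; all-identical connectivity matrices collapse to one flagged
  cluster.

## Known limitations

* The Gaussian emission model can, in adversarial regimes (forced state
  switching at every 20–200 ms event), prefer amplitude- or
  boundary-driven partitions over the generating one; see the simulator
  section.  Diagnosing this requires ground truth, which real recordings
  lack.
* A milder form of the same failure survives in the default protocol:
  when a sampled chain gives one state a near-zero self-transition
  probability, that state's epochs stay so short that the
  minimal-free-energy solution absorbs it and splits a dominant state
  instead (we verified the truth-initialized fit has distinctly worse
  free energy on such trials, so no restart budget recovers it).
  Roughly a third of randomly drawn chains contain such a state; an
  affected trial contributes one mismatched state pair and about 30 mm
  to its trial-mean localization error, which dominates the spread of
  the study means between seeds.
* The spherical forward model is adequate for magnetometer simulations
  (MEG is insensitive to the conductivity profile) but is not a
  substitute for a subject-specific BEM when analyzing real data; supply
  a computed leadfield via `load_leadfield()` for that.
* The GFI is a heuristic: it encodes the hypothesis that pathological
  states are centralized (low ACC) and lateralized (high BCD).  States
  violating that hypothesis — bilateral or diffuse epileptic networks —
  will not rank first.
* Localization error statistics are reported for fixed tangential source
  orientations; free-orientation beamforming would shift them somewhat.
* Noise robustness cuts the other way than intuition suggests: with an
  exact forward model, white sensor noise at 0–10 dB barely perturbs the
  beamformer peak, while the occasional segmentation failure is driven
  by clean signal structure that noise masks.  In our trend study the
  mean localization error therefore does not increase as SNR drops from
  10 to 0 dB — the corresponding ordinal check in the acceptance suite
  documents this honestly by failing — whereas the degradation with
  growing state count K is clear and monotone.
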