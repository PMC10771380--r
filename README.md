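# megstates

Disentangling transient brain states from resting-state MEG/EEG, and
scoring them for epileptogenic character.

Resting-state electrophysiological recordings alternate between brief
(tens to hundreds of milliseconds) quasi-stable activity patterns —
brain states.  In drug-resistant focal epilepsy, one of those states may
express the epileptic network, and localizing its cortical generator
noninvasively can help guide presurgical evaluation.  `megstates`
implements a complete analysis chain for this problem:

1. **Time-delay embedding + ICA** — a 100 ms window of the multichannel
   recording is embedded, PCA-whitened and rotated by FastICA, so that a
   state captures joint spatio-spectral structure
   (`time_embed()`, `ica_decompose()`).
2. **Embedded hidden Markov model** — a K-state Gaussian-emission HMM on
   the IC activations, fitted by variational Bayes with conjugate priors,
   multiple restarts and free-energy model selection; Viterbi decoding,
   event smoothing, and transition-matrix estimation
   (`vb_fit()`, `viterbi_decode()`, `smooth_path()`,
   `estimate_transition_matrix()`).
3. **Per-state source imaging** — unit-gain LCMV beamforming of each
   state's sensor segments onto a source space; peak localization and
   68-ROI source time courses (`lcmv_filters()`, `localize_state()`,
   `roi_timecourses()`).
4. **Per-state networks** — MVAR + partial directed coherence
   (`pi_ij(f) = |A̅_ij(f)| / sqrt(Σ_k |A̅_kj(f)|²)`, averaged 1–50 Hz),
   top-20% thresholding into a weighted undirected graph, and the graph
   feature index **GFI = (1 − ACC) × BCD** (ACC: mean Onnela weighted
   clustering coefficient; BCD: hemispheric difference of mean
   betweenness centrality).  The state with the highest GFI is flagged
   as the putative pathological state (`fit_mvar()`, `compute_pdc()`,
   `build_state_graph()`, `graph_features()`, `rank_states()`,
   `cluster_states()`).
5. **Monte-Carlo validation** — a simulator plays a Markov chain of
   oscillatory cortical states (2–20 Hz, 20–200 ms events, sources
   > 5 cm apart, Tukey-tapered epochs) through an analytic single-sphere
   magnetometer leadfield at chosen SNR, and the evaluation module
   measures localization error, frequency error, and transition-matrix
   correlation against the known ground truth
   (`build_spherical_leadfield()`, `sample_markov_model()`,
   `synthesize_trial()`, `match_states()`, `run_simulation_study()`).

## Worked example

```r
library(megstates)

lf    <- build_spherical_leadfield(500, 102, seed = 1)
model <- sample_markov_model(4, lf, seed = 7)
trial <- synthesize_trial(model, lf, duration_s = 60, sfreq = 250,
                          snr_db = 10, seed = 7)

emb    <- time_embed(trial, window_ms = 100)
ica    <- ica_decompose(emb, seed = 7)
fit    <- vb_fit(ica, K = 4, n_restarts = 10, seed = 7)
states <- backproject_states(ica, fit$gamma, fit$viterbi_path, trial)

glance(fit)
#> # A tibble: 1 x 6
#>       K free_energy iterations converged n_restarts best_restart
#>   <dbl>       <dbl>      <int> <lgl>          <dbl>        <int>
#> 1     4     437398.         58 TRUE              10            8

sources  <- lapply(states, localize_state, leadfield = lf)
matching <- match_states(states, model, lf)
localization_error(matching, sources, model, lf)$trial_mean
#> [1] 0
frequency_difference(matching, states, model, sfreq = 250)$trial_mean
#> [1] 1.444664
```

The fitted HMM converged after 58 variational iterations (restart 8 of
10 had the lowest free energy).  Every decoded state's beamformer peak
lands on its simulated source vertex (0 mm mean localization error), and
the FFT peaks of the decoded state segments sit 1.4 Hz from the
simulated oscillation frequencies on average (dominated by the slowest
state, whose sub-cycle events displace the spectral peak upward).

For a state ranked by network character:

```r
tc    <- roi_timecourses(states[[1]], lf)
conn  <- compute_pdc(fit_mvar(tc), sfreq = 250)
graph_features(build_state_graph(conn))
#> # A tibble: 1 x 3
#>      acc     bcd     gfi
#>    <dbl>   <dbl>   <dbl>
#> 1 0.0875 0.00990 0.00903
```

A command-line front end over the same functions is installed at
`inst/cli/megstates.R` (subcommands `simulate`, `fit`, `evaluate`,
`rank`).

The methods vignette (`vignettes/brain-state-disentanglement.Rmd`)
documents the model, priors, numerical choices, simulator assumptions,
and limitations.

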