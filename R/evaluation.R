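# The simulation evaluation metrics (localization error, FFT-peak
# frequency difference, transition-matrix correlation), the greedy
# state-matching procedure, and the Monte-Carlo study orchestrator.

#' Greedy one-to-one matching of extracted and simulated states
#'
#' The difference between an extracted state and a simulated state is
#' `1 - |r|`, the absolute-Pearson-correlation distance between the
#' extracted sensor topography and the simulated state's noiseless dipole
#' topography (its leadfield column).  The pair with the smallest
#' difference is selected first, both states are removed, and selection
#' repeats until every extracted state (or simulated state, whichever is
#' fewer) is matched.
#'
#' @param estimated list of `megstates_brain_state`, or a channels x K
#'   matrix of topographies.
#' @param simulated a `megstates_markov_model`.
#' @param leadfield a `megstates_leadfield`.
#' @return tibble `estimated_state`, `simulated_state`, `difference`,
#'   in greedy pick order.
#' @export
match_states <- function(estimated, simulated, leadfield) {
  topo_est <- if (is.list(estimated))
    vapply(estimated, `[[`, numeric(n_channels(leadfield)), "topography")
  else estimated
  topo_sim <- leadfield$gain[, simulated$state_vertex, drop = FALSE]
  diff_mat <- greedy_difference_matrix(topo_est, topo_sim)
  greedy_match(diff_mat)
}

# difference = 1 - |cor|; degenerate zero-variance topographies get 1
greedy_difference_matrix <- function(topo_est, topo_sim) {
  n_e <- ncol(topo_est); n_s <- ncol(topo_sim)
  d <- matrix(1, n_e, n_s)
  for (i in seq_len(n_e)) {
    if (sd(topo_est[, i]) == 0) next
    for (j in seq_len(n_s)) {
      if (sd(topo_sim[, j]) == 0) next
      d[i, j] <- 1 - abs(cor(topo_est[, i], topo_sim[, j]))
    }
  }
  d
}

# sequential global-minimum selection on a difference matrix; ties break
# by lower row index then lower column index
greedy_match <- function(diff_mat) {
  n_pairs <- min(nrow(diff_mat), ncol(diff_mat))
  est <- integer(n_pairs); sim <- integer(n_pairs); dv <- numeric(n_pairs)
  d <- diff_mat
  for (p in seq_len(n_pairs)) {
    idx <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    est[p] <- idx[1]; sim[p] <- idx[2]; dv[p] <- d[idx[1], idx[2]]
    d[idx[1], ] <- NA; d[, idx[2]] <- NA
  }
  tibble::tibble(estimated_state = est, simulated_state = sim,
                 difference = dv)
}

#' Per-trial localization error
#'
#' Euclidean distance (mm) from each matched extracted state's peak
#' beamformer vertex to the matched simulated state's source vertex,
#' averaged over pairs.
#'
#' @param matching tibble from [match_states()].
#' @param source_estimates list of `megstates_source_estimate`, indexed by
#'   extracted state id (entries may be NULL for empty states).
#' @param simulated a `megstates_markov_model`.
#' @param leadfield a `megstates_leadfield`.
#' @return list with `per_pair` (mm per matched pair, NA when no source
#'   estimate exists) and `trial_mean`.
#' @export
localization_error <- function(matching, source_estimates, simulated,
                               leadfield) {
  pos <- leadfield$source_space$pos
  per_pair <- vapply(seq_len(nrow(matching)), function(p) {
    se <- source_estimates[[matching$estimated_state[p]]]
    if (is.null(se)) return(NA_real_)
    true_v <- simulated$state_vertex[matching$simulated_state[p]]
    sqrt(sum((pos[se$peak_vertex, ] - pos[true_v, ])^2)) * 1000
  }, numeric(1))
  list(per_pair = per_pair, trial_mean = mean(per_pair, na.rm = TRUE))
}

# FFT peak frequency of a channels x time segment: per-channel spectra,
# power summed over channels, peak over positive frequencies.  Data
# shorter than min_duration_s are zero-padded to that length.
fft_peak_frequency <- function(dat, sfreq, min_duration_s = 1) {
  n_min <- ceiling(min_duration_s * sfreq)
  if (ncol(dat) < n_min)
    dat <- cbind(dat, matrix(0, nrow(dat), n_min - ncol(dat)))
  n_t <- ncol(dat)
  spec <- Mod(t(mvfft(t(dat))))^2
  power <- colSums(spec)
  freqs <- (seq_len(n_t) - 1) * sfreq / n_t
  keep <- freqs > 0 & freqs <= sfreq / 2
  freqs[keep][which.max(power[keep])]
}

#' Per-trial FFT-peak frequency difference
#'
#' For each matched pair, the peak frequency of the extracted state's
#' concatenated segments (channel-power-summed FFT) is compared with the
#' simulated state's oscillation frequency; absolute differences are
#' averaged over matched states.  States with empty segments are excluded
#' and flagged.
#'
#' @param matching tibble from [match_states()].
#' @param states list of `megstates_brain_state` indexed by extracted id.
#' @param simulated a `megstates_markov_model`.
#' @param sfreq sampling rate in Hz.
#' @return list with `per_pair` (Hz), `trial_mean`, `excluded` (extracted
#'   state ids with empty segments).
#' @export
frequency_difference <- function(matching, states, simulated, sfreq) {
  per_pair <- rep(NA_real_, nrow(matching))
  excluded <- integer(0)
  for (p in seq_len(nrow(matching))) {
    st <- states[[matching$estimated_state[p]]]
    if (st$empty || ncol(st$data) == 0) {
      excluded <- c(excluded, st$state_id)
      next
    }
    f_est <- fft_peak_frequency(st$data, sfreq)
    per_pair[p] <- abs(f_est -
                         simulated$state_frequency[matching$simulated_state[p]])
  }
  list(per_pair = per_pair, trial_mean = mean(per_pair, na.rm = TRUE),
       excluded = excluded)
}

#' Transition-matrix correlation
#'
#' Pearson correlation over off-diagonal entries between the estimated
#' event transition matrix (relabeled into simulated-state space through
#' the matching) and the trial's realized transition matrix.  Negative
#' correlations are floored at 0; undefined correlations (constant
#' entries) are reported as 0 with a flag.
#'
#' @param estimated a `megstates_transition` (in extracted-state labels).
#' @param realized_A K x K realized transition matrix of the trial.
#' @param matching tibble from [match_states()]; NULL if labels already
#'   agree.
#' @return list with `correlation` in \[0, 1\], `raw_correlation`,
#'   `degenerate` flag.
#' @export
transition_correlation <- function(estimated, realized_A, matching = NULL) {
  a_est <- estimated$A_bar
  K <- nrow(realized_A)
  if (!is.null(matching)) {
    relabeled <- matrix(0, K, K)
    for (p in seq_len(nrow(matching))) for (q in seq_len(nrow(matching))) {
      relabeled[matching$simulated_state[p], matching$simulated_state[q]] <-
        a_est[matching$estimated_state[p], matching$estimated_state[q]]
    }
    a_est <- relabeled
  }
  off <- row(realized_A) != col(realized_A)
  x <- a_est[off]; y <- realized_A[off]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(correlation = 0, raw_correlation = NA_real_,
                degenerate = TRUE))
  r <- cor(x, y)
  list(correlation = max(0, r), raw_correlation = r, degenerate = FALSE)
}

#' Run the full pipeline on one synthetic trial
#'
#' simulate -> embed -> ICA -> VB-HMM (true K) -> Viterbi -> smooth ->
#' back-project -> LCMV localize -> greedy match -> metrics.
#'
#' @param leadfield a `megstates_leadfield`.
#' @param K number of simulated (and fitted) states.
#' @param snr_db sensor SNR in dB.
#' @param duration_s trial length (s).
#' @param sfreq sampling rate (Hz).
#' @param n_restarts VB restarts.
#' @param seed integer seed.
#' @param window_ms embedding window (ms).
#' @param n_components ICA components (`"auto"` or integer).
#' @param reg_fraction LCMV diagonal loading.
#' @return one-row tibble with `le_mm`, `freq_diff_hz`, `trans_corr` and
#'   condition metadata; the fitted objects as an attribute `detail`.
#' @export
run_trial <- function(leadfield, K, snr_db, duration_s = 120, sfreq = 250,
                      n_restarts = 10, seed = 1, window_ms = 100,
                      n_components = "auto", reg_fraction = 0.05) {
  model <- sample_markov_model(K, leadfield, seed = seed)
  trial <- synthesize_trial(model, leadfield, duration_s, sfreq,
                            snr_db = snr_db, seed = seed + 1L)
  emb <- time_embed(trial$recording, window_ms, sfreq)
  ica <- ica_decompose(emb, n_components = n_components, seed = seed + 2L)
  rm(emb)
  fit <- vb_fit(ica$activations, K, n_restarts = n_restarts,
                seed = seed + 3L)
  states <- backproject_states(ica, fit$gamma, fit$viterbi_path,
                               trial$recording)
  events <- smooth_path(fit$viterbi_path, max_event_ms = 200, sfreq = sfreq)
  trans_est <- estimate_transition_matrix(events, K = K)
  sources <- lapply(states, function(st)
    if (st$empty) NULL else localize_state(st, leadfield, reg_fraction))
  matching <- match_states(states, model, leadfield)
  le <- localization_error(matching, sources, model, leadfield)
  fd <- frequency_difference(matching, states, model, sfreq)
  tc <- transition_correlation(trans_est, trial$realized_A, matching)
  out <- tibble::tibble(K = K, snr_db = snr_db, seed = seed,
                        le_mm = le$trial_mean,
                        freq_diff_hz = fd$trial_mean,
                        trans_corr = tc$correlation,
                        n_empty_states = sum(vapply(states, `[[`,
                                                    logical(1), "empty")),
                        error = NA_character_)
  attr(out, "detail") <- list(model = model, trial = trial, fit = fit,
                              states = states, sources = sources,
                              matching = matching, le = le, fd = fd, tc = tc)
  out
}

#' Run the Monte-Carlo simulation study
#'
#' Executes [run_trial()] for every combination of `K_values` and
#' `snr_values`, `n_trials` trials each, with per-trial seeds derived from
#' `seed`.  Failures are recorded per trial (row kept, metrics NA) and the
#' study continues.
#'
#' @param leadfield a `megstates_leadfield`.
#' @param K_values integer vector of state counts.
#' @param snr_values numeric vector of SNRs (dB).
#' @param n_trials trials per condition.
#' @param seed study seed.
#' @param ... further arguments to [run_trial()].
#' @return a `megstates_report`: tibble of per-trial rows with condition
#'   columns; summary via [glance()][generics::glance].
#' @export
run_simulation_study <- function(leadfield, K_values = 4, snr_values = 10,
                                 n_trials = 20, seed = 1, ...) {
  conds <- expand.grid(K = K_values, snr_db = snr_values)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    trial_seeds <- sample.int(.Machine$integer.max - 10L, n_trials)
    for (tr in seq_len(n_trials)) {
      row <- tryCatch(
        run_trial(leadfield, K = conds$K[ci], snr_db = conds$snr_db[ci],
                  seed = trial_seeds[tr], ...),
        error = function(e)
          tibble::tibble(K = conds$K[ci], snr_db = conds$snr_db[ci],
                         seed = trial_seeds[tr], le_mm = NA_real_,
                         freq_diff_hz = NA_real_, trans_corr = NA_real_,
                         n_empty_states = NA_integer_,
                         error = conditionMessage(e)))
      attr(row, "detail") <- NULL
      row$trial <- tr
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("megstates_report", class(out))
  attr(out, "seed") <- as.integer(seed)
  out
}
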