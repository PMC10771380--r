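# Monte-Carlo simulator: a Markov chain of transient oscillatory cortical
# states played through the forward model, plus additive white sensor noise.

#' Tapered-cosine (Tukey) window
#'
#' @param n window length in samples.
#' @param taper total taper fraction in \[0, 1\] (0 = rectangular,
#'   1 = Hann); default 0.5.
#' @return numeric vector of length `n` in \[0, 1\].
#' @export
tukey_window <- function(n, taper = 0.5) {
  stopifnot(n >= 1, taper >= 0, taper <= 1)
  if (n == 1) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- taper / 2
  lo <- x < edge
  hi <- x > 1 - edge
  if (taper > 0) {
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / taper - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / taper - 2 / taper + 1)))
  }
  w
}

#' Sample a Markov model of oscillatory brain states
#'
#' Draws K cortical states: a transition matrix with flat-Dirichlet rows
#' (self-transitions allowed — a state may repeat across consecutive
#' events, which lengthens its effective epochs), uniform initial
#' probabilities, one source vertex per state with all pairwise source
#' distances above `min_separation`, and one oscillation frequency per
#' state drawn uniformly from `freq_range`.
#'
#' @param K number of states, typically 4..7.
#' @param leadfield a `megstates_leadfield` supplying candidate vertices.
#' @param seed integer seed.
#' @param freq_range oscillation frequency range in Hz.
#' @param min_separation minimum pairwise source distance in meters.
#' @return a `megstates_markov_model`.
#' @export
sample_markov_model <- function(K, leadfield, seed = 1,
                                freq_range = c(2, 20),
                                min_separation = 0.05) {
  stopifnot(K >= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  pos <- leadfield$source_space$pos
  vertices <- NULL
  for (attempt in seq_len(10000)) {
    cand <- sample.int(nrow(pos), K)
    d <- as.matrix(dist(pos[cand, , drop = FALSE]))
    if (K == 1 || min(d[upper.tri(d)]) > min_separation) { vertices <- cand; break }
  }
  if (is.null(vertices))
    stop("could not place ", K, " sources separated by > ",
         min_separation, " m after 10000 attempts")
  A <- matrix(rgamma(K * K, 1), K, K)      # flat Dirichlet rows
  A <- A / rowSums(A)
  structure(list(K = K, pi = rep(1 / K, K), A = A,
                 state_frequency = runif(K, freq_range[1], freq_range[2]),
                 state_vertex = vertices, seed = as.integer(seed)),
            class = "megstates_markov_model")
}

#' @export
print.megstates_markov_model <- function(x, ...) {
  cat("<megstates_markov_model> K =", x$K, "states;",
      "frequencies", paste(sprintf("%.1f", x$state_frequency), collapse = "/"),
      "Hz\n")
  invisible(x)
}

#' Simulate a state event sequence from a Markov model
#'
#' The first event's state is drawn from the initial distribution; each
#' following state from the transition matrix.  Raw event durations are
#' uniform on `duration_range` seconds, quantized to samples; events tile
#' the trial and the last one is truncated at `duration_s`.  A state may
#' self-transition and so persist across consecutive raw events; such runs
#' are merged into one epoch (self-transitions are neglected downstream),
#' so consecutive returned epochs always differ in state while epoch
#' durations can exceed the raw event range.
#'
#' @param model a `megstates_markov_model`.
#' @param duration_s trial length in seconds.
#' @param sfreq sampling rate in Hz.
#' @param seed integer seed.
#' @param duration_range raw event duration range in seconds
#'   (default 20-200 ms).
#' @return tibble with columns `state`, `onset`, `offset` (0-based
#'   half-open sample intervals) of the merged epochs; the unmerged raw
#'   events are kept in attribute `raw_events`.
#' @export
simulate_state_sequence <- function(model, duration_s, sfreq, seed = 1,
                                    duration_range = c(0.02, 0.2)) {
  stopifnot(duration_s > 0)
  if (round(duration_range[1] * sfreq) < 2)
    stop("sfreq too low: the shortest event (", duration_range[1] * 1000,
         " ms) spans fewer than 2 samples")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  n_total <- round(duration_s * sfreq)
  states <- integer(0); onsets <- integer(0); offsets <- integer(0)
  t0 <- 0L
  s <- sample.int(model$K, 1, prob = model$pi)
  while (t0 < n_total) {
    len <- round(runif(1, duration_range[1], duration_range[2]) * sfreq)
    len <- min(len, n_total - t0)
    states <- c(states, s); onsets <- c(onsets, t0); offsets <- c(offsets, t0 + len)
    t0 <- t0 + len
    s <- sample.int(model$K, 1, prob = model$A[s, ])
  }
  raw <- tibble::tibble(state = as.integer(states), onset = as.integer(onsets),
                        offset = as.integer(offsets))
  # merge runs of self-transitioning events into single epochs
  grp <- cumsum(c(1L, as.integer(diff(raw$state) != 0)))
  merged <- tibble::tibble(
    state = raw$state[!duplicated(grp)],
    onset = raw$onset[!duplicated(grp)],
    offset = raw$offset[rev(!duplicated(rev(grp)))])
  attr(merged, "raw_events") <- raw
  merged
}

# Empirical transition matrix of an event sequence: count consecutive event
# pairs with differing states, normalize rows; zero-count rows stay zero.
event_transition_matrix <- function(event_states, K) {
  counts <- matrix(0, K, K)
  if (length(event_states) >= 2) {
    from <- event_states[-length(event_states)]
    to <- event_states[-1]
    keep <- from != to
    for (i in which(keep)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  rs <- rowSums(counts)
  A_bar <- counts
  nz <- rs > 0
  A_bar[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  list(counts = counts, A_bar = A_bar)
}

#' Synthesize one sensor-space MEG trial
#'
#' Each event activates only its state's source vertex with a unit-amplitude
#' sinusoid at the state's frequency (phase 0 at event onset), shaped by a
#' Tukey window over the event; all other vertices stay silent.  Sensor data
#' are `gain %*% source` plus white Gaussian noise scaled so that the
#' whole-array broadband power ratio matches `snr_db` exactly
#' (`10*log10(P_signal/P_noise) = snr_db`).
#'
#' @param model a `megstates_markov_model`.
#' @param leadfield a `megstates_leadfield`.
#' @param duration_s trial length in seconds (default 120).
#' @param sfreq sampling rate in Hz (default 250).
#' @param snr_db signal-to-noise ratio in dB; `Inf` means no noise.
#' @param seed integer seed.
#' @param taper Tukey taper fraction per event.
#' @return a `megstates_trial` with elements `recording` (channels x time,
#'   with attribute `sfreq`), `clean_recording`, `events` (tibble),
#'   `realized_A`, `model`.
#' @export
synthesize_trial <- function(model, leadfield, duration_s = 120, sfreq = 250,
                             snr_db = 10, seed = 1, taper = 0.5) {
  if (!is.finite(snr_db) && !identical(snr_db, Inf))
    stop("snr_db must be finite (or Inf for noiseless)")
  if (sfreq <= 2 * max(model$state_frequency))
    stop("sfreq must exceed twice the fastest state frequency")
  events <- simulate_state_sequence(model, duration_s, sfreq, seed = seed)
  n_total <- round(duration_s * sfreq)
  n_ch <- n_channels(leadfield)
  clean <- matrix(0, n_ch, n_total)
  for (e in seq_len(nrow(events))) {
    on <- events$onset[e]; off <- events$offset[e]
    len <- off - on
    if (len < 1) next
    tt <- seq_len(len) - 1
    osc <- sin(2 * pi * model$state_frequency[events$state[e]] * tt / sfreq) *
      tukey_window(len, taper)
    g <- leadfield$gain[, model$state_vertex[events$state[e]]]
    clean[, (on + 1):off] <- clean[, (on + 1):off] + outer(g, osc)
  }
  p_signal <- mean(clean^2)
  if (is.finite(snr_db)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed) + 1L)
    noise <- matrix(rnorm(n_ch * n_total), n_ch, n_total)
    p_target <- p_signal / 10^(snr_db / 10)
    noise <- noise * sqrt(p_target / mean(noise^2))
    rec <- clean + noise
  } else rec <- clean
  attr(rec, "sfreq") <- sfreq
  attr(clean, "sfreq") <- sfreq
  structure(list(recording = rec, clean_recording = clean, events = events,
                 realized_A = event_transition_matrix(events$state, model$K)$A_bar,
                 model = model, sfreq = sfreq, snr_db = snr_db,
                 seed = as.integer(seed)),
            class = "megstates_trial")
}

#' @export
print.megstates_trial <- function(x, ...) {
  cat("<megstates_trial> ", nrow(x$recording), " channels x ",
      ncol(x$recording), " samples @ ", x$sfreq, " Hz, K = ", x$model$K,
      ", SNR = ", x$snr_db, " dB, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}
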