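# Variational-Bayes Gaussian-emission HMM on IC activations, Viterbi
# decoding, event smoothing and transition-matrix estimation.

#' Fit a Gaussian-emission HMM by variational Bayes
#'
#' Conjugate model: Dirichlet priors (concentration 1) over the initial
#' distribution and each transition-matrix row, and a unit-information
#' Normal-Wishart prior over each state's mean and precision.  The E-step
#' runs forward-backward on expected log-parameters, the M-step updates the
#' variational factors, and iterations stop when the relative free-energy
#' change falls below `tol` (or at `max_iter`).  The fit is restarted
#' `n_restarts` times from perturbed k-means initializations; each restart
#' runs a short exploratory phase of `init_iter` iterations, and the
#' restart with the lowest free energy at that point is continued to full
#' convergence (set `init_iter = Inf` to converge every restart).
#'
#' @param activations component x time matrix (finite entries).
#' @param K number of states (1 <= K <= T).
#' @param n_restarts number of restarts (default 50).
#' @param seed integer seed.
#' @param tol relative free-energy convergence tolerance.
#' @param max_iter maximum VB iterations per restart.
#' @param init_iter exploratory iterations per restart before the best
#'   restart is polished to convergence (default 12).
#' @return a `megstates_hmm` with point parameters (`pi`, `A`, `mu`,
#'   `Sigma`), posteriors `gamma`, `free_energy_trace` (best restart),
#'   `restart_energies`, `viterbi_path`, and the variational
#'   hyperparameters.
#' @export
vb_fit <- function(activations, K, n_restarts = 50, seed = 1,
                   tol = 1e-6, max_iter = 500, init_iter = 12) {
  if (inherits(activations, "megstates_ica")) activations <- activations$activations
  x <- as.matrix(activations)
  if (any(!is.finite(x))) stop("activations contain non-finite values")
  n <- nrow(x); t_len <- ncol(x)
  if (K < 1 || K > t_len) stop("K must be between 1 and T")
  # unit-information Normal-Wishart prior matched to the data scale
  m0 <- rowMeans(x)
  s_data <- tcrossprod(x - m0) / t_len
  s_data <- s_data + diag(1e-6 * mean(diag(s_data)) + 1e-12, n)
  nu0 <- n + 2
  w0inv <- s_data * nu0       # prior E[Lambda] = inv(s_data)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  run_one <- function(r, iters) {
    set.seed(as.integer(seed) + r - 1L)
    # alternate init families across restarts for optimizer diversity
    gamma0 <- init_responsibilities(x, K,
                                    type = if (r %% 2 == 1) "kmeans" else "chunks")
    vb_hmm_cpp(x, gamma0, alpha0_pi = 1, alpha0_A = 1,
               beta0 = 1, nu0 = nu0, W0inv = w0inv, m0 = m0,
               tol = tol, max_iter = iters)
  }
  phase_iter <- if (is.finite(init_iter)) min(init_iter, max_iter) else max_iter
  best <- NULL
  energies <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    fit <- run_one(r, phase_iter)
    energies[r] <- tail(fit$free_energy_trace, 1)
    if (is.null(best) || energies[r] < tail(best$free_energy_trace, 1)) {
      best <- fit
      best$restart <- r
    }
  }
  if (is.finite(init_iter) && !isTRUE(as.logical(best$converged))) {
    best_r <- best$restart
    best <- run_one(best_r, max_iter)   # polish the winning restart
    best$restart <- best_r
    energies[best_r] <- tail(best$free_energy_trace, 1)
  }
  pi_hat <- as.vector(best$alpha_pi) / sum(best$alpha_pi)
  A_hat <- best$alpha_A / rowSums(best$alpha_A)
  Sigma <- lapply(seq_len(K), function(k)
    best$Winv[, , k] / (best$nu[k] - n - 1))
  out <- structure(list(
    K = K, pi = pi_hat, A = A_hat,
    mu = best$m, Sigma = Sigma,
    gamma = best$gamma,
    free_energy_trace = as.vector(best$free_energy_trace),
    free_energy = tail(best$free_energy_trace, 1),
    restart_energies = energies,
    best_restart = best$restart,
    n_restarts = n_restarts,
    converged = as.logical(best$converged),
    iterations = best$iterations,
    hyper = best[c("alpha_pi", "alpha_A", "beta", "nu", "m", "Winv")],
    seed = as.integer(seed)),
    class = "megstates_hmm")
  out$viterbi_path <- viterbi_decode(out, x)
  out
}

# Initialization of responsibilities, softened so no state starts with
# zero mass anywhere; the per-restart seed perturbs the start.
# "kmeans": clusters standardized raw samples concatenated with smoothed
# log-power envelopes (oscillatory states are zero-mean and separate by
# envelope, mean-shifted states by the raw block).
# "chunks": random contiguous segments assigned random states.
init_responsibilities <- function(x, K, soften = 0.1, env_smooth = 13,
                                  type = c("kmeans", "chunks")) {
  t_len <- ncol(x)
  if (K == 1) return(matrix(1, 1, t_len))
  type <- match.arg(type)
  if (type == "kmeans") {
    feats <- rbind(x, log_envelope(x, env_smooth))
    feats <- feats / pmax(apply(feats, 1, sd), 1e-12)
    # cluster a column subsample, then assign every column to the nearest
    # center; same initialization quality at a fraction of the cost
    sub <- if (t_len > 8000) seq(1, t_len, by = 4) else seq_len(t_len)
    centers <- kmeanspp_centers(t(feats[, sub, drop = FALSE]), K)
    km <- suppressWarnings(
      kmeans(t(feats[, sub, drop = FALSE]), centers = centers,
             iter.max = 20, algorithm = "Lloyd"))
    d2 <- crossprod(feats, t(km$centers))            # T x K inner products
    d2 <- sweep(-2 * d2, 2, rowSums(km$centers^2), `+`)
    cl <- max.col(-d2, ties.method = "first")
  } else {
    cl <- integer(t_len)
    t0 <- 1
    while (t0 <= t_len) {
      len <- sample(25:250, 1)
      cl[t0:min(t_len, t0 + len - 1)] <- sample.int(K, 1)
      t0 <- t0 + len
    }
  }
  g <- matrix(soften / K, K, t_len)
  g[cbind(cl, seq_len(t_len))] <- g[cbind(cl, seq_len(t_len))] + (1 - soften)
  g / rep(colSums(g), each = K)
}

# kmeans++ seeding: points sampled with probability proportional to the
# squared distance from the nearest chosen center
kmeanspp_centers <- function(pts, K) {
  n <- nrow(pts)
  idx <- sample.int(n, 1)
  d2 <- rowSums(sweep(pts, 2, pts[idx, ])^2)
  for (k in seq_len(K - 1)) {
    idx <- c(idx, sample.int(n, 1, prob = pmax(d2, 1e-300)))
    d2 <- pmin(d2, rowSums(sweep(pts, 2, pts[tail(idx, 1), ])^2))
  }
  pts[idx, , drop = FALSE]
}

# centered moving-average power per row, on a log scale
log_envelope <- function(x, k) {
  k <- max(1L, min(as.integer(k), ncol(x)))
  cs <- cbind(0, t(apply(x^2, 1, cumsum)))
  env <- (cs[, (k + 1):ncol(cs), drop = FALSE] -
            cs[, 1:(ncol(cs) - k), drop = FALSE]) / k
  lead <- (k - 1) %/% 2
  out <- cbind(matrix(env[, 1], nrow(x), lead), env,
               matrix(env[, ncol(env)], nrow(x), k - 1 - lead))
  log(out + 1e-12)
}

#' Select the number of states by minimal free energy
#'
#' Fits the VB-HMM for every candidate K and returns the fit with the
#' lowest final free energy, with the full comparison table attached.
#' Intended for real recordings where the state count is unknown;
#' simulation studies use the generating K directly.
#'
#' @inheritParams vb_fit
#' @param K_range candidate state counts (default 2:8).
#' @return the best `megstates_hmm`; the comparison tibble
#'   (`K`, `free_energy`, `converged`) is in attribute `selection`.
#' @export
select_k <- function(activations, K_range = 2:8, n_restarts = 10, seed = 1,
                     ...) {
  fits <- lapply(K_range, function(k)
    vb_fit(activations, k, n_restarts = n_restarts, seed = seed, ...))
  fe <- vapply(fits, `[[`, numeric(1), "free_energy")
  best <- fits[[which.min(fe)]]
  attr(best, "selection") <- tibble::tibble(
    K = K_range, free_energy = fe,
    converged = vapply(fits, `[[`, logical(1), "converged"))
  best
}

#' @export
print.megstates_hmm <- function(x, ...) {
  cat("<megstates_hmm> K = ", x$K, ", ", nrow(x$mu), " dims, ",
      ncol(x$gamma), " samples; free energy ",
      format(x$free_energy, digits = 8), " (restart ", x$best_restart,
      "/", x$n_restarts, ")\n", sep = "")
  invisible(x)
}

# Gaussian log-densities for all states: K x T matrix.
gaussian_log_emissions <- function(mu, Sigma, x) {
  K <- ncol(mu); n <- nrow(mu)
  out <- matrix(0, K, ncol(x))
  for (k in seq_len(K)) {
    ch <- chol(Sigma[[k]])
    xc <- backsolve(ch, x - mu[, k], transpose = TRUE)
    out[k, ] <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          colSums(xc^2))
  }
  out
}

#' Viterbi decoding of the most probable state path
#'
#' Maximum a posteriori state sequence under the fitted point parameters,
#' by log-domain dynamic programming; ties break toward the lower state
#' index.
#'
#' @param params a `megstates_hmm`, or a list with `pi`, `A`, `mu`
#'   (dims x K), `Sigma` (list of dims x dims).
#' @param activations component x time matrix.
#' @return integer vector of states (1..K) per sample.
#' @export
viterbi_decode <- function(params, activations) {
  x <- as.matrix(activations)
  log_b <- gaussian_log_emissions(params$mu, params$Sigma, x)
  as.integer(viterbi_cpp(log(params$pi), log(params$A), log_b))
}

#' Smooth a decoded state path into an event list
#'
#' Runs of identical states become events.  Events shorter than 2 samples
#' are merged into the preceding event (the first event, if short, into the
#' following one); events longer than `max_event_ms` are split into
#' consecutive sub-events of at most that length.  Sub-events sharing a
#' state contribute no transitions downstream.
#'
#' @param path integer state per sample.
#' @param max_event_ms maximum event duration in ms (default 200).
#' @param sfreq sampling rate in Hz.
#' @return tibble `state`, `onset`, `offset` (0-based half-open intervals).
#' @export
smooth_path <- function(path, max_event_ms = 200, sfreq = 250) {
  stopifnot(length(path) >= 1)
  runs <- path_runs(path)
  # merge events shorter than 2 samples into the preceding event
  state <- integer(0); onset <- integer(0); offset <- integer(0)
  for (i in seq_len(nrow(runs))) {
    len <- runs$offset[i] - runs$onset[i]
    if (len < 2 && length(state) > 0) {
      offset[length(state)] <- runs$offset[i]
    } else if (len < 2 && nrow(runs) > 1) {
      # leading short event: absorbed by the following one
      next_state <- runs$state[which(runs$offset - runs$onset >= 2)[1]]
      if (is.na(next_state)) next_state <- runs$state[i]
      state <- c(state, next_state); onset <- c(onset, runs$onset[i])
      offset <- c(offset, runs$offset[i])
    } else {
      state <- c(state, runs$state[i]); onset <- c(onset, runs$onset[i])
      offset <- c(offset, runs$offset[i])
    }
  }
  # collapse adjacent events that now share a state
  keep_s <- integer(0); keep_on <- integer(0); keep_off <- integer(0)
  for (i in seq_along(state)) {
    if (length(keep_s) > 0 && keep_s[length(keep_s)] == state[i] &&
        keep_off[length(keep_s)] == onset[i]) {
      keep_off[length(keep_s)] <- offset[i]
    } else {
      keep_s <- c(keep_s, state[i]); keep_on <- c(keep_on, onset[i])
      keep_off <- c(keep_off, offset[i])
    }
  }
  # split events longer than max_event_ms
  max_len <- max(1L, round(max_event_ms * sfreq / 1000))
  state <- integer(0); onset <- integer(0); offset <- integer(0)
  for (i in seq_along(keep_s)) {
    starts <- seq(keep_on[i], keep_off[i] - 1L, by = max_len)
    ends <- pmin(starts + max_len, keep_off[i])
    state <- c(state, rep(keep_s[i], length(starts)))
    onset <- c(onset, starts); offset <- c(offset, ends)
  }
  tibble::tibble(state = as.integer(state), onset = as.integer(onset),
                 offset = as.integer(offset))
}

#' Estimate the transition matrix from an event list
#'
#' Counts transitions between consecutive events with differing states
#' (self-transitions, e.g. from splitting long events, are neglected) and
#' row-normalizes.  Rows with no outgoing transitions are left all-zero and
#' flagged.
#'
#' @param event_list tibble with a `state` column (from [smooth_path()] or
#'   [simulate_state_sequence()]).
#' @param K number of states; default the largest state id present.
#' @return a `megstates_transition`: list with `counts`, `A_bar`,
#'   `zero_rows`.
#' @export
estimate_transition_matrix <- function(event_list, K = max(event_list$state)) {
  states <- event_list$state
  tm <- event_transition_matrix(states, K)
  structure(list(counts = tm$counts, A_bar = tm$A_bar,
                 zero_rows = which(rowSums(tm$counts) == 0),
                 single_event = length(states) < 2),
            class = "megstates_transition")
}

#' @export
print.megstates_transition <- function(x, ...) {
  cat("<megstates_transition> ", nrow(x$A_bar), " states, ",
      sum(x$counts), " transitions",
      if (length(x$zero_rows)) paste0(" (zero rows: ",
                                      paste(x$zero_rows, collapse = ","), ")"),
      "\n", sep = "")
  invisible(x)
}
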