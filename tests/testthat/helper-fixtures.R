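# Shared small fixtures, built once per test run.

small_leadfield <- local({
  lf <- NULL
  function() {
    if (is.null(lf)) lf <<- build_spherical_leadfield(300, 64, seed = 7)
    lf
  }
})

# toy leadfield with orthogonal columns: channels = vertices, gain = I-ish,
# geometry on a sphere so ROI labels stay valid
identity_leadfield <- function(n = 136) {
  lf <- build_spherical_leadfield(n, n, seed = 3)
  lf$gain <- diag(n)
  lf
}

# deterministic 2-state scalar HMM sampler for parameter-recovery tests
sample_scalar_hmm <- function(t_len, mu = c(-3, 3), stay = 0.95, seed = 1) {
  set.seed(seed)
  s <- integer(t_len)
  s[1] <- sample(2, 1)
  for (t in 2:t_len)
    s[t] <- if (runif(1) < stay) s[t - 1] else 3 - s[t - 1]
  y <- rnorm(t_len, mu[s], 1)
  list(states = s, y = matrix(y, 1))
}

# stable 3-channel order-2 MVAR generator
sample_mvar2 <- function(t_len, seed = 1) {
  set.seed(seed)
  a1 <- matrix(c(0.5, 0.2, 0, 0, 0.4, 0.3, 0, 0, 0.5), 3, 3, byrow = TRUE)
  a2 <- matrix(c(-0.2, 0, 0, 0.1, -0.3, 0, 0, 0.2, -0.2), 3, 3, byrow = TRUE)
  y <- matrix(0, 3, t_len + 100)
  for (t in 3:(t_len + 100))
    y[, t] <- a1 %*% y[, t - 1] + a2 %*% y[, t - 2] + rnorm(3, sd = 1)
  list(y = y[, 101:(t_len + 100)], A = list(a1, a2))
}

# Brute-force HMM path oracle: enumerate all K^T state sequences.
brute_force_viterbi <- function(log_pi, log_A, log_B) {
  K <- nrow(log_B); t_len <- ncol(log_B)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), t_len)))
  best <- -Inf; best_path <- NULL
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    lp <- log_pi[p[1]] + log_B[p[1], 1]
    for (t in 2:t_len) lp <- lp + log_A[p[t - 1], p[t]] + log_B[p[t], t]
    if (lp > best + 1e-12) { best <- lp; best_path <- p }
  }
  unname(best_path)
}

# exhaustive oracle for the greedy sequential-minimum matching
brute_greedy <- function(d) {
  n <- min(nrow(d), ncol(d))
  est <- integer(0); sim <- integer(0)
  for (p in seq_len(n)) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(nrow(d))) for (j in seq_len(ncol(d))) {
      if (i %in% est || j %in% sim) next
      if (d[i, j] < best) { best <- d[i, j]; bi <- i; bj <- j }
    }
    est <- c(est, bi); sim <- c(sim, bj)
  }
  cbind(est, sim)
}
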