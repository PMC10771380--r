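test_that("Viterbi equals exhaustive path search on small problems", {
  set.seed(1)
  for (rep in 1:5) {
    K <- sample(2:3, 1); t_len <- sample(5:8, 1)
    pi0 <- rgamma(K, 1); pi0 <- pi0 / sum(pi0)
    A <- matrix(rgamma(K * K, 1), K); A <- A / rowSums(A)
    log_B <- matrix(rnorm(K * t_len), K)
    got <- as.integer(megstates:::viterbi_cpp(log(pi0), log(A), log_B))
    want <- brute_force_viterbi(log(pi0), log(A), log_B)
    expect_equal(got, want)
  }
})

test_that("Viterbi limits: emission-dominated and transition-dominated", {
  # uniform transitions, one dominant emission per sample
  log_B <- log(matrix(c(0.9, 0.05, 0.05,
                        0.1, 0.8, 0.1,
                        0.2, 0.1, 0.7), 3)[, c(1, 2, 3, 2, 1)])
  path <- as.integer(megstates:::viterbi_cpp(log(rep(1 / 3, 3)),
                                             log(matrix(1 / 3, 3, 3)), log_B))
  expect_equal(path, apply(log_B, 2, which.max))
  # deterministic cyclic transitions override emissions
  A <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  log_B2 <- matrix(log(runif(3 * 6)), 3)
  path2 <- as.integer(megstates:::viterbi_cpp(log(c(1, 0, 0) + 1e-300),
                                              log(A + 1e-300), log_B2))
  expect_equal(path2, rep(1:3, 2))
})

test_that("forward-backward posteriors are proper distributions", {
  set.seed(2)
  K <- 3; t_len <- 200
  pi0 <- rep(1 / 3, 3)
  A <- matrix(c(0.8, 0.1, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1, 0.8), 3, byrow = TRUE)
  log_B <- matrix(rnorm(K * t_len, sd = 2), K)
  fb <- megstates:::forward_backward_cpp(log(pi0), log(A), log_B)
  expect_equal(colSums(fb$gamma), rep(1, t_len), tolerance = 1e-9)
  expect_true(all(fb$gamma >= 0))
})

test_that("VB recovers a well-separated 2-state scalar HMM over 10 seeds", {
  errs <- vapply(1:10, function(s) {
    sim <- sample_scalar_hmm(1500, mu = c(-3, 3), stay = 0.95, seed = s)
    fit <- vb_fit(sim$y, K = 2, n_restarts = 5, seed = s + 100)
    mu_hat <- sort(as.vector(fit$mu))
    max(abs(mu_hat - c(-3, 3)))
  }, numeric(1))
  expect_lt(max(errs), 0.2)
})

test_that("free energy is non-increasing for every restart", {
  set.seed(3)
  sim <- sample_scalar_hmm(800, seed = 11)
  x <- rbind(sim$y, sim$y * 0.5 + rnorm(800, sd = 0.3))
  for (r in 1:6) {
    set.seed(500 + r)
    g0 <- megstates:::init_responsibilities(x, 2,
                                            type = if (r %% 2) "kmeans" else "chunks")
    m0 <- rowMeans(x)
    sdat <- tcrossprod(x - m0) / ncol(x) + diag(1e-6, 2)
    f <- megstates:::vb_hmm_cpp(x, g0, 1, 1, 1, 4, sdat * 4, m0, 1e-10, 200)
    fe <- f$free_energy_trace
    expect_true(all(diff(fe) <= 1e-8 * pmax(abs(fe[-1]), 1)))
  }
})

test_that("the returned restart has the lowest evaluated free energy", {
  sim <- sample_scalar_hmm(600, seed = 21)
  fit <- vb_fit(sim$y, K = 2, n_restarts = 6, seed = 22)
  expect_lte(fit$free_energy, min(fit$restart_energies) + 1e-9)
})

test_that("K = 1 degenerates to the empirical mean with unit posteriors", {
  set.seed(4)
  x <- matrix(rnorm(3 * 400, mean = 2), 3)
  fit <- vb_fit(x, K = 1, n_restarts = 1, seed = 5)
  expect_true(all(fit$gamma == 1))
  expect_equal(as.vector(fit$mu), rowMeans(x), tolerance = 1e-8)
})

test_that("invalid K is rejected", {
  x <- matrix(rnorm(100), 1)
  expect_error(vb_fit(x, K = 0), "between 1 and T")
  expect_error(vb_fit(x, K = 101), "between 1 and T")
  expect_error(vb_fit(matrix(c(1, NA), 1), K = 1), "finite")
})

test_that("fitted model beats a time-shuffled control in held-out likelihood", {
  wins <- vapply(1:10, function(s) {
    sim <- sample_scalar_hmm(1000, mu = c(-2, 2), stay = 0.9, seed = s + 30)
    train <- sim$y[, 1:700, drop = FALSE]
    test <- sim$y[, 701:1000, drop = FALSE]
    fit <- vb_fit(train, K = 2, n_restarts = 3, seed = s)
    loglik <- function(y, fit) {
      lb <- megstates:::gaussian_log_emissions(fit$mu, fit$Sigma, y)
      megstates:::forward_backward_cpp(log(fit$pi), log(fit$A), lb)$loglik
    }
    set.seed(s)
    shuffled <- test[, sample(ncol(test)), drop = FALSE]
    loglik(test, fit) > loglik(shuffled, fit)
  }, logical(1))
  expect_true(all(wins))
})

test_that("smooth_path merges sub-2-sample events and splits long ones", {
  # 100 samples of one state at 250 Hz with 200 ms cap -> two 50-sample
  # events, no transitions
  ev <- smooth_path(rep(1L, 100), max_event_ms = 200, sfreq = 250)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$offset - ev$onset, c(50, 50))
  tm <- estimate_transition_matrix(ev, K = 2)
  expect_equal(sum(tm$counts), 0)
  # explicit run structure
  ev2 <- smooth_path(c(1, 1, 2, 2, 1, 1), max_event_ms = 1000, sfreq = 250)
  expect_equal(ev2$state, c(1L, 2L, 1L))
  tm2 <- estimate_transition_matrix(ev2, K = 2)
  expect_equal(tm2$counts[1, 2], 1)
  expect_equal(tm2$counts[2, 1], 1)
  # alternating path collapses through the merge rule; samples conserved
  alt <- rep(c(1L, 2L), 40)
  ev3 <- smooth_path(alt, max_event_ms = 200, sfreq = 250)
  expect_equal(sum(ev3$offset - ev3$onset), 80)
  expect_true(all(ev3$offset - ev3$onset >= 1))
})

test_that("transition estimates count consecutive differing events", {
  ev <- tibble::tibble(state = c(1L, 2L, 1L, 3L),
                       onset = c(0L, 10L, 20L, 30L),
                       offset = c(10L, 20L, 30L, 40L))
  tm <- estimate_transition_matrix(ev, K = 3)
  expect_equal(tm$A_bar[1, 2], 0.5)
  expect_equal(tm$A_bar[1, 3], 0.5)
  expect_equal(tm$A_bar[2, 1], 1)
  expect_equal(diag(tm$counts), rep(0, 3))
  expect_equal(tm$zero_rows, 3L)   # state 3 has no outgoing transition
  # single event: all-zero flagged estimate
  tm1 <- estimate_transition_matrix(ev[1, ], K = 2)
  expect_true(tm1$single_event)
  expect_equal(sum(tm1$A_bar), 0)
})

test_that("free-energy K selection returns the minimizing fit and table", {
  sim <- sample_scalar_hmm(900, mu = c(-3, 3), stay = 0.95, seed = 51)
  x <- rbind(sim$y, 0.5 * sim$y + rnorm(900, sd = 0.4))
  best <- select_k(x, K_range = 1:3, n_restarts = 3, seed = 52)
  sel <- attr(best, "selection")
  expect_equal(nrow(sel), 3)
  expect_equal(best$K, sel$K[which.min(sel$free_energy)])
  expect_equal(best$free_energy, min(sel$free_energy))
  # strongly bimodal two-state data must not collapse to a single state
  expect_gte(best$K, 2)
})
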