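test_that("greedy matching equals the sequential-minimum oracle", {
  set.seed(1)
  for (rep in 1:20) {
    d <- matrix(runif(25), 5, 5)
    got <- megstates:::greedy_match(d)
    want <- brute_greedy(d)
    expect_equal(got$estimated_state, unname(want[, "est"]))
    expect_equal(got$simulated_state, unname(want[, "sim"]))
  }
})

test_that("identical topographies match to themselves with zero difference", {
  lf <- small_leadfield()
  m <- sample_markov_model(4, lf, seed = 2)
  topo <- lf$gain[, m$state_vertex]
  mt <- match_states(topo, m, lf)
  expect_equal(mt$estimated_state, mt$simulated_state)
  expect_equal(mt$difference, rep(0, 4), tolerance = 1e-12)
})

test_that("zero-variance topographies get difference 1", {
  lf <- small_leadfield()
  m <- sample_markov_model(3, lf, seed = 3)
  topo <- lf$gain[, m$state_vertex]
  topo[, 2] <- 0
  d <- megstates:::greedy_difference_matrix(topo, lf$gain[, m$state_vertex])
  expect_equal(d[2, ], rep(1, 3))
})

test_that("localization error is the mean pairwise peak-to-source distance", {
  lf <- small_leadfield()
  m <- sample_markov_model(3, lf, seed = 4)
  matching <- tibble::tibble(estimated_state = 1:3, simulated_state = 1:3,
                             difference = 0)
  # source estimates peaked at the true vertices: zero error
  ses <- lapply(m$state_vertex, function(v)
    structure(list(peak_vertex = v), class = "megstates_source_estimate"))
  le <- localization_error(matching, ses, m, lf)
  expect_equal(le$per_pair, rep(0, 3))
  expect_equal(le$trial_mean, 0)
  # known displacements average like plain distances
  pos <- lf$source_space$pos
  other <- which.max(sqrt(rowSums((pos - pos[m$state_vertex[1], ])^2)))
  ses2 <- ses; ses2[[1]]$peak_vertex <- other
  d1 <- sqrt(sum((pos[other, ] - pos[m$state_vertex[1], ])^2)) * 1000
  le2 <- localization_error(matching, ses2, m, lf)
  expect_equal(le2$per_pair[1], d1)
  expect_equal(le2$trial_mean, mean(c(d1, 0, 0)))
})

test_that("frequency differences compare FFT peaks to simulated frequencies", {
  lf <- small_leadfield()
  m <- sample_markov_model(2, lf, seed = 5)
  m$state_frequency <- c(10, 12)
  sfreq <- 250
  mk_state <- function(id, f_hz) {
    dat <- outer(lf$gain[, m$state_vertex[id]],
                 sin(2 * pi * f_hz * (0:2499) / sfreq))
    structure(list(state_id = id, data = dat, empty = FALSE),
              class = "megstates_brain_state")
  }
  matching <- tibble::tibble(estimated_state = 1:2, simulated_state = 1:2,
                             difference = 0)
  fd <- frequency_difference(matching, list(mk_state(1, 10), mk_state(2, 10)),
                             m, sfreq)
  expect_equal(fd$per_pair[1], 0, tolerance = 0.11)
  expect_equal(fd$per_pair[2], 2, tolerance = 0.11)
  # empty state excluded with a flag
  empty <- structure(list(state_id = 2, data = matrix(0, 64, 0), empty = TRUE),
                     class = "megstates_brain_state")
  fd2 <- frequency_difference(matching, list(mk_state(1, 10), empty), m, sfreq)
  expect_equal(fd2$excluded, 2L)
  expect_equal(fd2$trial_mean, fd2$per_pair[1])
})

test_that("FFT peak resolution matches the bin width", {
  lf <- small_leadfield()
  sfreq <- 250
  # 120 s of signal: bin width 1/120 Hz
  f_true <- 10.3371
  dat <- outer(lf$gain[, 10], sin(2 * pi * f_true * (0:(120 * sfreq - 1)) / sfreq))
  pk <- megstates:::fft_peak_frequency(dat, sfreq)
  expect_lt(abs(pk - f_true), 1 / 120 + 1e-9)
})

test_that("transition correlation handles relabeling, clipping, degeneracy", {
  a <- rbind(c(0, 0.7, 0.3), c(0.2, 0, 0.8), c(0.6, 0.4, 0))
  est <- structure(list(A_bar = a), class = "megstates_transition")
  expect_equal(transition_correlation(est, a)$correlation, 1)
  # rows/cols permuted through the matching relabel back to 1
  perm <- c(2, 3, 1)   # estimated state i corresponds to simulated perm[i]
  a_perm <- a
  a_perm[perm, perm] <- a
  est2 <- structure(list(A_bar = a_perm), class = "megstates_transition")
  matching <- tibble::tibble(estimated_state = perm, simulated_state = 1:3,
                             difference = 0)
  expect_equal(transition_correlation(est2, a, matching)$correlation, 1)
  # constant matrices are degenerate -> 0 with flag
  cst <- structure(list(A_bar = matrix(0.5, 3, 3)),
                   class = "megstates_transition")
  tc <- transition_correlation(cst, a)
  expect_equal(tc$correlation, 0)
  expect_true(tc$degenerate)
})

test_that("independent random transition matrices correlate near zero", {
  set.seed(6)
  vals <- vapply(1:1000, function(i) {
    a1 <- matrix(rgamma(25, 1), 5); diag(a1) <- 0; a1 <- a1 / rowSums(a1)
    a2 <- matrix(rgamma(25, 1), 5); diag(a2) <- 0; a2 <- a2 / rowSums(a2)
    est <- structure(list(A_bar = a1), class = "megstates_transition")
    transition_correlation(est, a2)$raw_correlation
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("a small simulation study is reproducible and conserves trials", {
  lf <- small_leadfield()
  r1 <- suppressWarnings(
    run_simulation_study(lf, K_values = 3, snr_values = 10, n_trials = 2,
                         seed = 5, duration_s = 8, sfreq = 250,
                         n_restarts = 2, n_components = 12))
  r2 <- suppressWarnings(
    run_simulation_study(lf, K_values = 3, snr_values = 10, n_trials = 2,
                         seed = 5, duration_s = 8, sfreq = 250,
                         n_restarts = 2, n_components = 12))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 2)
  expect_true(all(r1$K == 3 & r1$snr_db == 10))
  g <- glance(r1)
  expect_equal(g$n, 2)
  expect_true(all(c("le_mm", "freq_diff_hz", "trans_corr") %in% names(g)))
})

test_that("preprocessing band-passes, regresses artifacts, and segments", {
  sfreq <- 250
  tt <- 0:(10 * sfreq - 1) / sfreq
  clean <- rbind(sin(2 * pi * 10 * tt), cos(2 * pi * 8 * tt))
  drift <- sin(2 * pi * 0.1 * tt)          # below the 1 Hz edge
  eog <- sin(2 * pi * 3 * tt + 0.5)
  rec <- clean + 3 * rep(1, 2) %o% drift + rbind(2 * eog, -1.5 * eog)
  segs <- preprocess_recording(rec, sfreq, band = c(1, 50),
                               artifact = matrix(eog, 1), segment_s = 4)
  expect_equal(length(segs), 3)            # 4 + 4 + 2 s remainder
  expect_equal(ncol(segs[[3]]), 2 * sfreq)
  x <- do.call(cbind, segs)
  # drift and EOG mostly removed; oscillations preserved
  expect_gt(abs(cor(x[1, ], clean[1, ])), 0.95)
  expect_lt(abs(cor(x[1, 100:2400], eog[100:2400])), 0.1)
  expect_lt(abs(cor(x[1, 100:2400], drift[100:2400])), 0.25)
})

test_that("cluster values average within clusters", {
  set.seed(8)
  t1 <- matrix(runif(100), 10); diag(t1) <- 0
  t2 <- matrix(runif(100), 10); diag(t2) <- 0
  cl <- cluster_states(list(t1, t1, t2, t2), n_clusters = 2,
                       state_values = c(10, 20, 1, 3))
  a <- cl$assignment$cluster
  expect_equal(sort(cl$cluster_values), c(2, 15))
  expect_equal(cl$cluster_values[a[1]], 15)
})
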