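test_that("MVAR least squares recovers known order-2 coefficients", {
  sim <- sample_mvar2(5000, seed = 1)
  fit <- fit_mvar(sim$y, order = 2)
  rmse <- sqrt(mean((unlist(fit$A) - unlist(sim$A))^2))
  expect_lt(rmse, 0.05)
})

test_that("independent white noise yields near-zero cross coefficients", {
  set.seed(2)
  y <- matrix(rnorm(4 * 4000), 4)
  fit <- fit_mvar(y, order = 1)
  a <- fit$A[[1]]
  se <- 1 / sqrt(4000)          # ~SE of an AR coefficient on white noise
  expect_true(all(abs(a[row(a) != col(a)]) < 3.5 * se))
})

test_that("BIC selects the true order 2 in at least 8 of 10 seeds", {
  hits <- vapply(1:10, function(s) {
    sim <- sample_mvar2(3000, seed = s + 10)
    fit_mvar(sim$y, order = "auto", max_order = 5)$order == 2
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("PDC columns are normalized at every frequency", {
  sim <- sample_mvar2(3000, seed = 31)
  fit <- fit_mvar(sim$y, order = 2)
  conn <- compute_pdc(fit, sfreq = 250)
  for (fi in seq_along(conn$frequencies)) {
    expect_equal(colSums(conn$pdc_f[, , fi]^2), rep(1, 3), tolerance = 1e-9)
  }
  expect_true(all(conn$pdc >= 0 & conn$pdc <= 1))
})

test_that("decoupled channels give near-zero off-diagonal PDC", {
  fit <- structure(list(A = list(diag(c(0.5, 0.3, -0.4))), order = 1,
                        n_channels = 3), class = "megstates_mvar")
  conn <- compute_pdc(fit, sfreq = 250)
  off <- conn$pdc[row(conn$pdc) != col(conn$pdc)]
  expect_lt(max(off), 0.02)
})

test_that("unidirectional coupling dominates the reverse direction at all frequencies", {
  # x drives y: y_t = 0.9 x_{t-1} + ...
  a1 <- rbind(c(0.5, 0), c(0.9, 0.2))
  fit <- structure(list(A = list(a1), order = 1, n_channels = 2),
                   class = "megstates_mvar")
  conn <- compute_pdc(fit, sfreq = 250)
  # flow x->y sits in entry (2,1); y->x in (1,2)
  expect_true(all(conn$pdc_f[2, 1, ] > conn$pdc_f[1, 2, ]))
})

test_that("unstable MVAR models are rejected with the spectral radius", {
  fit <- structure(list(A = list(diag(c(1.05, 0.2))), order = 1,
                        n_channels = 2), class = "megstates_mvar")
  expect_error(compute_pdc(fit, 250), "spectral radius")
})

test_that("top-20% thresholding retains 912 directed values on 68 nodes", {
  set.seed(4)
  m <- matrix(runif(68 * 68), 68)
  diag(m) <- 0
  g <- build_state_graph(m, keep_fraction = 0.2)
  expect_equal(g$n_directed_kept, ceiling(0.2 * 68 * 67))  # 912
  expect_equal(g$n_directed_kept, 912)
  expect_true(igraph::ecount(g$graph) <= 912)
  expect_true(all(diag(g$adjacency) == 0))
  # keep_fraction = 1 keeps every nonzero flow
  g1 <- build_state_graph(m, keep_fraction = 1)
  expect_equal(igraph::ecount(g1$graph), 68 * 67 / 2)
  # all-equal matrix: every value tied at the cutoff, all retained
  me <- matrix(1, 10, 10); diag(me) <- 0
  ge <- build_state_graph(me, keep_fraction = 0.2)
  expect_equal(ge$n_directed_kept, 90)
})

test_that("graph features match closed forms on canonical graphs", {
  # unweighted complete graph: ACC 1, all BC 0, GFI 0
  n <- 10
  cm <- matrix(1, n, n); diag(cm) <- 0
  g <- build_state_graph(cm, keep_fraction = 1)
  hemi <- rep(c("left", "right"), each = 5)
  feats <- graph_features(g, hemi)
  expect_equal(feats$acc, 1, tolerance = 1e-12)
  expect_equal(feats$bcd, 0, tolerance = 1e-12)
  expect_equal(feats$gfi, 0, tolerance = 1e-12)
  # star centered on a left node: center CC 0, BCD > 0, GFI > 0
  sm <- matrix(0, n, n)
  sm[1, 2:n] <- 1; sm[2:n, 1] <- 1
  gs <- build_state_graph(sm, keep_fraction = 1)
  fs <- graph_features(gs, hemi)
  cc <- attr(fs, "clustering")
  bc <- attr(fs, "betweenness")
  expect_equal(cc[1], 0)
  expect_equal(bc[1], 1)                      # normalized star center
  expect_gt(fs$bcd, 0)
  expect_gt(fs$gfi, 0)
  expect_equal(fs$gfi, (1 - fs$acc) * fs$bcd) # exact identity
})

test_that("GFI is invariant to uniform edge-weight scaling", {
  set.seed(5)
  m <- matrix(runif(16 * 16), 16); diag(m) <- 0
  hemi <- rep(c("left", "right"), each = 8)
  f1 <- graph_features(build_state_graph(m, 0.3), hemi)
  f2 <- graph_features(build_state_graph(m * 7.3, 0.3), hemi)
  expect_equal(f1$gfi, f2$gfi, tolerance = 1e-12)
  expect_equal(f1$acc, f2$acc, tolerance = 1e-12)
})

test_that("hierarchical clustering groups connectivity patterns correctly", {
  set.seed(6)
  t1 <- matrix(runif(12 * 12), 12); diag(t1) <- 0
  t2 <- matrix(runif(12 * 12), 12); diag(t2) <- 0
  # two copies each of two distinct matrices
  cl <- cluster_states(list(t1, t1, t2, t2), n_clusters = 2)
  expect_equal(cl$n_clusters, 2L)
  a <- cl$assignment$cluster
  expect_equal(a[1], a[2]); expect_equal(a[3], a[4])
  expect_true(a[1] != a[3])
  # cluster mean of identical members equals any member
  expect_equal(cl$mean_connectivity[[a[1]]], t1)
  # all-identical matrices: single flagged cluster
  cid <- cluster_states(list(t1, t1, t1))
  expect_equal(cid$n_clusters, 1L)
  expect_true(cid$identical)
})

test_that("noisy template perturbations cluster with >= 14/15 accuracy", {
  set.seed(7)
  templates <- lapply(1:3, function(i) {
    m <- matrix(runif(12 * 12), 12); diag(m) <- 0; m
  })
  mats <- list(); truth <- integer(0)
  for (i in 1:3) for (r in 1:5) {
    m <- templates[[i]] + matrix(rnorm(144, sd = 0.02), 12)
    diag(m) <- 0
    mats[[length(mats) + 1]] <- m
    truth <- c(truth, i)
  }
  cl <- cluster_states(mats, n_clusters = "auto")
  expect_equal(cl$n_clusters, 3L)
  tab <- table(truth, cl$assignment$cluster)
  expect_gte(sum(apply(tab, 1, max)), 14)
})

test_that("state ranking is by GFI with BCD and id tie-breaks", {
  feats <- tibble::tibble(gfi = c(0.001, 0.028, 0.010),
                          bcd = c(0.1, 0.2, 0.3))
  rk <- rank_states(feats)
  expect_equal(rk$state[1], 2)
  expect_true(rk$pathological[1])
  expect_false(any(rk$pathological[-1]))
  # single state ranks itself
  expect_equal(rank_states(tibble::tibble(gfi = 0.5, bcd = 0.1))$state, 1)
  # full tie chain: equal GFI -> larger BCD, then lower id
  tie <- tibble::tibble(gfi = c(0.2, 0.2, 0.2), bcd = c(0.1, 0.3, 0.3))
  rk2 <- rank_states(tie)
  expect_equal(rk2$state, c(2, 3, 1))
})

test_that("a hub-driven state attains the top GFI more often than chance", {
  # two "states": one hub-driven MVAR network (one left-hemisphere node
  # drives many others), one balanced network; 10 dB observation noise
  hits <- vapply(1:20, function(s) {
    set.seed(s + 200)
    n <- 68
    hub <- sample(1:34, 1)              # left-hemisphere driver
    a_hub <- diag(0.3, n)
    targets <- sample(setdiff(1:n, hub), 20)
    a_hub[targets, hub] <- 0.5
    a_bal <- diag(0.3, n)
    ring <- cbind(1:n, c(2:n, 1))
    a_bal[ring] <- 0.25                  # balanced nearest-neighbor flow
    gen <- function(a) {
      y <- matrix(0, n, 1300)
      for (t in 2:1300) y[, t] <- a %*% y[, t - 1] + rnorm(n)
      y <- y[, 101:1300]
      y + matrix(rnorm(n * 1200), n) * sqrt(mean(y^2) / 10 / 1)
    }
    feats <- lapply(list(a_hub, a_bal), function(a) {
      fit <- fit_mvar(gen(a), order = 1)
      graph_features(build_state_graph(compute_pdc(fit, 250), 0.2))
    })
    feats[[1]]$gfi > feats[[2]]$gfi
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})
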