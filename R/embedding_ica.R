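# Time-delay embedding and ICA reduction of the sensor recording, and the
# back-projection of decoded states into sensor space.

#' Time-delay embed a multichannel recording
#'
#' Stacks lagged copies of the recording: row block `b` (lags 0..L-1, L =
#' `round(window_ms * sfreq / 1000)`) holds the recording delayed by `b`
#' samples.  Columns are indexed by the latest sample of the window, so
#' column `j` covers original samples `j .. j+L-1` and the lag-0 block
#' equals the last `T - L + 1` columns of the input.
#'
#' @param recording channels x time matrix with attribute `sfreq`, or a
#'   `megstates_trial`.
#' @param window_ms embedding window length in milliseconds (default 100).
#' @param sfreq sampling rate; taken from the recording attribute if absent.
#' @return a `megstates_embedded`: matrix of dimension
#'   `(channels*L) x (T-L+1)` with fields `lag_samples`, `n_channels`,
#'   `window_ms`, `sfreq`.
#' @export
time_embed <- function(recording, window_ms = 100, sfreq = NULL) {
  if (inherits(recording, "megstates_trial")) recording <- recording$recording
  if (is.null(sfreq)) sfreq <- attr(recording, "sfreq")
  if (is.null(sfreq)) stop("sfreq not given and not an attribute of the recording")
  L <- round(window_ms * sfreq / 1000)
  if (L < 2) stop("embedding window must span at least 2 samples")
  n_ch <- nrow(recording); n_t <- ncol(recording)
  if (L > n_t) stop("embedding window (", L, " samples) longer than the recording")
  n_col <- n_t - L + 1
  emb <- matrix(0, n_ch * L, n_col)
  for (b in 0:(L - 1)) {
    emb[(b * n_ch + 1):((b + 1) * n_ch), ] <- recording[, (L - b):(n_t - b)]
  }
  structure(list(matrix = emb, lag_samples = L, n_channels = n_ch,
                 window_ms = window_ms, sfreq = sfreq),
            class = "megstates_embedded")
}

# Randomized-range-finder SVD for the leading k left singular vectors of a
# wide matrix; two power iterations are ample for low-rank-plus-noise data.
# Exact svd() is used when the problem is small.
partial_svd <- function(x, k, seed = 1, oversample = 10, power_iter = 1) {
  m <- nrow(x); n <- ncol(x)
  k <- min(k, m, n)
  if (m <= 300 || m * n <= 5e6) {
    s <- svd(x, nu = k, nv = 0)
    return(list(u = s$u[, seq_len(k), drop = FALSE], d = s$d[seq_len(k)]))
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  l <- min(k + oversample, m, n)
  om <- matrix(rnorm(n * l), n, l)
  y <- x %*% om
  for (i in seq_len(power_iter)) {
    y <- qr.Q(qr(y))
    y <- x %*% crossprod(x, y)
  }
  q <- qr.Q(qr(y))
  b <- crossprod(q, x)           # l x n
  sb <- svd(b, nu = l, nv = 0)
  list(u = (q %*% sb$u)[, seq_len(k), drop = FALSE], d = sb$d[seq_len(k)])
}

# Symmetric fixed-point FastICA rotation (tanh contrast) on whitened data
# z (comp x time, identity covariance).  Returns the orthonormal unmixing
# rotation and a convergence flag.
fastica_rotation <- function(z, seed = 1, max_iter = 200, tol = 1e-4, alpha = 1) {
  n <- nrow(z); t_len <- ncol(z)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  w <- matrix(rnorm(n * n), n, n)
  sym_orth <- function(w) {
    s <- svd(w)
    s$u %*% t(s$v)
  }
  w <- sym_orth(w)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    wx <- w %*% z
    g <- tanh(alpha * wx)
    g_prime_mean <- alpha * rowMeans(1 - g^2)
    w_new <- tcrossprod(g, z) / t_len - diag(g_prime_mean, n) %*% w
    w_new <- sym_orth(w_new)
    delta <- max(abs(abs(rowSums(w_new * w)) - 1))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(rotation = w, converged = converged, iterations = iter)
}

#' ICA decomposition of embedded data
#'
#' Centers the embedded matrix, reduces it by PCA whitening to
#' `n_components` dimensions (`"auto"`: the smallest count explaining at
#' least 95% of variance, capped at 40), then rotates with symmetric
#' fixed-point FastICA.  The mixing map reconstructs the retained-variance
#' projection of the embedded data from the activations.  Component signs
#' are fixed by making each component's largest-magnitude mixing entry
#' positive.
#'
#' @param embedded a `megstates_embedded` (or bare matrix).
#' @param n_components integer, or `"auto"`.
#' @param seed integer seed.
#' @param var_explained variance fraction for `"auto"` (default 0.95).
#' @param max_components cap for `"auto"` (default 40).
#' @return a `megstates_ica` with `activations` (N x T), `mixing`
#'   (embedded_dim x N), `unmixing` (N x embedded_dim), `center`,
#'   `converged`, and the embedding metadata.
#' @export
ica_decompose <- function(embedded, n_components = "auto", seed = 1,
                          var_explained = 0.95, max_components = 40) {
  meta <- if (inherits(embedded, "megstates_embedded")) embedded else
    list(matrix = embedded, lag_samples = 1L, n_channels = nrow(embedded),
         window_ms = NA_real_, sfreq = NA_real_)
  x <- meta$matrix
  center <- rowMeans(x)
  xc <- x - center
  t_len <- ncol(xc)
  k_max <- if (identical(n_components, "auto")) min(max_components, nrow(xc), t_len)
           else n_components
  if (!identical(n_components, "auto") && n_components > min(dim(xc)))
    stop("n_components exceeds the rank bound of the embedded matrix")
  sv <- partial_svd(xc, k_max, seed = seed)
  if (identical(n_components, "auto")) {
    total_var <- sum(xc^2)
    cum <- cumsum(sv$d^2) / total_var
    n_comp <- which(cum >= var_explained)[1]
    if (is.na(n_comp)) n_comp <- k_max
  } else n_comp <- n_components
  u <- sv$u[, seq_len(n_comp), drop = FALSE]
  d <- sv$d[seq_len(n_comp)]
  d[d < .Machine$double.eps * max(d)] <- .Machine$double.eps * max(d)
  scores <- crossprod(u, xc)                    # n_comp x T
  z <- scores / (d / sqrt(t_len))               # whitened (unit variance rows)
  fi <- fastica_rotation(z, seed = seed)
  if (!fi$converged)
    warning("FastICA did not converge in ", fi$iterations,
            " iterations; returning the best rotation found")
  activations <- fi$rotation %*% z              # N x T
  mixing <- u %*% (t(fi$rotation) * (d / sqrt(t_len)))  # embedded_dim x N
  # sign convention: largest |mixing| entry positive per component
  flip <- apply(mixing, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  mixing <- sweep(mixing, 2, flip, `*`)
  activations <- activations * flip
  unmixing <- (t(u) / (d / sqrt(t_len)))
  unmixing <- (fi$rotation %*% unmixing) * flip
  structure(list(activations = activations, mixing = mixing,
                 unmixing = unmixing, center = center,
                 pca_basis = u, pca_singular_values = d,
                 n_components = n_comp, singular_values = sv$d,
                 converged = fi$converged, seed = as.integer(seed),
                 lag_samples = meta$lag_samples, n_channels = meta$n_channels,
                 window_ms = meta$window_ms, sfreq = meta$sfreq),
            class = "megstates_ica")
}

#' @export
print.megstates_ica <- function(x, ...) {
  cat("<megstates_ica> ", x$n_components, " components x ",
      ncol(x$activations), " samples (embedded dim ",
      nrow(x$mixing), ")\n", sep = "")
  invisible(x)
}

#' Reconstruct the embedded-space data from an ICA decomposition
#'
#' Returns `mixing %*% activations + center`, i.e. the retained-variance
#' projection of the embedded matrix.
#'
#' @param decomposition a `megstates_ica`.
#' @return embedded_dim x T matrix.
#' @export
ica_reconstruct <- function(decomposition) {
  decomposition$mixing %*% decomposition$activations + decomposition$center
}

#' Back-project decoded states to sensor space
#'
#' For each state j, the component weighting `S[j, ]` is the
#' posterior-weighted root-mean-square activation of each component under
#' that state, normalized to sum to one (nonnegative, sums to 1).  The
#' state's sensor topography is the dominant field pattern of its assigned
#' segments (first left singular vector of the centered segment data) —
#' the same data that drive the beamformer — because a nonnegative
#' component weighting cannot express the signed interference between
#' components that shapes a dipolar field map.  A state the Viterbi path
#' never visits falls back to the lag-0 block of the component sum
#' weighted by the leading eigenvector of its posterior-weighted
#' activation covariance.  Segments are cut from the original recording at
#' the Viterbi intervals, and the representative time is the sample of
#' maximal global field power within those segments.
#'
#' @param decomposition a `megstates_ica`.
#' @param posteriors K x T state posterior matrix (columns sum to 1).
#' @param viterbi_path integer state per embedded sample (length T).
#' @param recording the original channels x time recording the embedding
#'   was computed from.
#' @return list of `megstates_brain_state` (one per state), each with
#'   `state_id`, `weighting`, `topography`, `segments` (tibble of 0-based
#'   half-open sample intervals in the original recording), `data`
#'   (concatenated segment data), `representative_time`, `empty`.
#' @export
backproject_states <- function(decomposition, posteriors, viterbi_path,
                               recording) {
  if (inherits(recording, "megstates_trial")) recording <- recording$recording
  K <- nrow(posteriors)
  t_len <- ncol(posteriors)
  stopifnot(length(viterbi_path) == t_len,
            ncol(decomposition$activations) == t_len)
  colsum <- colSums(posteriors)
  if (max(abs(colsum - 1)) > 1e-6)
    stop("posterior columns must sum to 1")
  act2 <- decomposition$activations^2
  L <- decomposition$lag_samples
  n_ch <- decomposition$n_channels
  # posterior-weighted mean-square activation of each component per state
  tot <- rowSums(posteriors)
  p2 <- act2 %*% t(posteriors)
  p2 <- sweep(p2, 2, pmax(tot, .Machine$double.eps), `/`)   # N x K
  acts <- decomposition$activations
  lapply(seq_len(K), function(j) {
    if (tot[j] > 0) {
      s_j <- sqrt(p2[, j])                             # RMS under state j
      if (sum(s_j) > 0) s_j <- s_j / sum(s_j) else s_j <- rep(0, length(s_j))
      # dominant component pattern: leading eigenvector of the
      # state-conditional activation covariance
      w_t <- posteriors[j, ]
      mu_j <- as.vector(acts %*% w_t) / tot[j]
      xc <- acts - mu_j
      cov_j <- (xc * rep(w_t, each = nrow(xc))) %*% t(xc) / tot[j]
      e_j <- eigen(cov_j, symmetric = TRUE)$vectors[, 1]
    } else {
      s_j <- rep(0, decomposition$n_components)
      e_j <- rep(0, decomposition$n_components)
    }
    topo_emb <- as.vector(decomposition$mixing %*% e_j)
    topography <- topo_emb[seq_len(n_ch)]              # lag-0 sensor block
    runs <- path_runs(viterbi_path)
    runs_j <- runs[runs$state == j, , drop = FALSE]
    if (nrow(runs_j) > 0) {
      # a decoded column's state reflects the whole L-sample window, so a
      # run of columns [on, off) is mapped to the window-centered original
      # samples [on + L/2, off + L/2) (0-based); segments stay disjoint
      shift <- L %/% 2
      seg <- tibble::tibble(onset = runs_j$onset + shift,
                            offset = pmin(runs_j$offset + shift, ncol(recording)))
      dat <- do.call(cbind, lapply(seq_len(nrow(seg)), function(i)
        recording[, (seg$onset[i] + 1):seg$offset[i], drop = FALSE]))
      topography <- svd(dat - rowMeans(dat), nu = 1, nv = 0)$u[, 1]
      cm <- colMeans(dat)
      gfp <- sqrt(pmax(0, colMeans(dat^2) - cm^2))     # spatial sd per sample
      all_idx <- unlist(lapply(seq_len(nrow(seg)), function(i)
        (seg$onset[i] + 1):seg$offset[i]))
      rep_time <- all_idx[which.max(gfp)] - 1L
      empty <- FALSE
    } else {
      seg <- tibble::tibble(onset = integer(0), offset = integer(0))
      dat <- matrix(0, n_ch, 0); rep_time <- NA_integer_; empty <- TRUE
    }
    structure(list(state_id = j, weighting = s_j, topography = topography,
                   segments = seg, data = dat, representative_time = rep_time,
                   empty = empty),
              class = "megstates_brain_state")
  })
}

# Runs of identical values in an integer path; 0-based half-open intervals.
path_runs <- function(path) {
  r <- rle(path)
  off <- cumsum(r$lengths)
  tibble::tibble(state = r$values,
                 onset = as.integer(off - r$lengths),
                 offset = as.integer(off))
}

#' @export
print.megstates_brain_state <- function(x, ...) {
  cat("<megstates_brain_state> state ", x$state_id, ": ",
      nrow(x$segments), " segments, ", ncol(x$data), " samples",
      if (x$empty) " (never visited)", "\n", sep = "")
  invisible(x)
}
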