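# Per-state connectivity: MVAR fit, partial directed coherence, network
# thresholding, weighted graph metrics, the graph feature index, and
# hierarchical clustering of states by connectivity pattern.

#' Fit a multivariate autoregressive (MVAR) model
#'
#' Least-squares multichannel AR fit; with `order = "auto"` the lag order
#' is chosen by BIC over 1..`max_order`.  An ill-conditioned regression
#' falls back to a small ridge with a warning.
#'
#' @param roi_tc a `megstates_roi_tc` or channels x time matrix.
#' @param order integer lag order, or `"auto"`.
#' @param max_order order range searched by `"auto"` (default 10).
#' @return a `megstates_mvar`: `A` (list of n x n coefficient matrices),
#'   `order`, `resid_cov`, `bic` (when selected), `n_channels`.
#' @export
fit_mvar <- function(roi_tc, order = "auto", max_order = 10) {
  y <- if (inherits(roi_tc, "megstates_roi_tc")) roi_tc$data else roi_tc
  n <- nrow(y); t_len <- ncol(y)
  orders <- if (identical(order, "auto")) seq_len(max_order) else order
  if (t_len <= n * max(orders) * 3)
    stop("need more than 3 * channels * order samples to fit the MVAR")
  fit_one <- function(p) {
    t_eff <- t_len - p
    x <- matrix(0, t_eff, n * p)
    for (r in seq_len(p))
      x[, ((r - 1) * n + 1):(r * n)] <- t(y[, (p - r + 1):(t_len - r), drop = FALSE])
    yy <- t(y[, (p + 1):t_len, drop = FALSE])
    qr_x <- qr(x)
    coef <- if (qr_x$rank < ncol(x)) {
      warning("ill-conditioned MVAR regression; using ridge fallback")
      xtx <- crossprod(x)
      solve(xtx + diag(1e-8 * mean(diag(xtx)), ncol(x)), crossprod(x, yy))
    } else qr.coef(qr_x, yy)
    resid <- yy - x %*% coef
    resid_cov <- crossprod(resid) / t_eff
    # BIC with n^2 * p free coefficients
    ld <- determinant(resid_cov, logarithm = TRUE)$modulus
    bic <- t_eff * as.numeric(ld) + log(t_eff) * n^2 * p
    a_list <- lapply(seq_len(p), function(r)
      t(coef[((r - 1) * n + 1):(r * n), , drop = FALSE]))
    list(A = a_list, order = p, resid_cov = resid_cov, bic = bic)
  }
  fits <- lapply(orders, fit_one)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  structure(c(best, list(n_channels = n,
                         bic_table = tibble::tibble(
                           order = orders,
                           bic = vapply(fits, `[[`, numeric(1), "bic")))),
            class = "megstates_mvar")
}

# Spectral radius of the MVAR companion matrix.
mvar_spectral_radius <- function(mvar) {
  n <- mvar$n_channels; p <- mvar$order
  comp <- matrix(0, n * p, n * p)
  for (r in seq_len(p)) comp[1:n, ((r - 1) * n + 1):(r * n)] <- mvar$A[[r]]
  if (p > 1) comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Partial directed coherence of a fitted MVAR model
#'
#' Column-normalized PDC (Baccala-Sameshima):
#' `pi_ij(f) = |Abar_ij(f)| / sqrt(sum_k |Abar_kj(f)|^2)` with
#' `Abar(f) = I - sum_r A_r exp(-i 2 pi f r / sfreq)`; entry (i, j) is the
#' flow j -> i.  The returned matrix is the mean over an evenly spaced
#' frequency grid covering `band` (1 Hz steps by default).
#'
#' @param mvar a `megstates_mvar`.
#' @param sfreq sampling rate in Hz.
#' @param band frequency band in Hz (default c(1, 50)).
#' @param freq_step grid step in Hz (default 1).
#' @return a `megstates_connectivity`: `pdc` (n x n band-averaged),
#'   `pdc_f` (n x n x F), `frequencies`, `order`.
#' @export
compute_pdc <- function(mvar, sfreq, band = c(1, 50), freq_step = 1) {
  rho <- mvar_spectral_radius(mvar)
  if (rho >= 1)
    stop("unstable MVAR model (companion spectral radius ",
         format(rho, digits = 4), " >= 1)")
  freqs <- seq(band[1], band[2], by = freq_step)
  n <- mvar$n_channels
  pdc_f <- array(0, c(n, n, length(freqs)))
  for (fi in seq_along(freqs)) {
    a_bar <- diag(n) + 0i
    for (r in seq_along(mvar$A))
      a_bar <- a_bar - mvar$A[[r]] * exp(-2i * pi * freqs[fi] * r / sfreq)
    denom <- sqrt(colSums(Mod(a_bar)^2))
    pdc_f[, , fi] <- sweep(Mod(a_bar), 2, denom, `/`)
  }
  structure(list(pdc = apply(pdc_f, c(1, 2), mean), pdc_f = pdc_f,
                 frequencies = freqs, order = mvar$order),
            class = "megstates_connectivity")
}

#' Threshold a connectivity matrix into a weighted undirected graph
#'
#' Ranks all off-diagonal directed values, keeps the top `keep_fraction`
#' (ties at the cutoff are all kept), symmetrizes retained flows by the
#' maximum of the two directions, and builds a weighted undirected igraph
#' graph with no self-loops.
#'
#' @param conn a `megstates_connectivity` or bare square matrix.
#' @param keep_fraction fraction of directed values retained (default 0.2).
#' @return a `megstates_state_graph`: `graph` (igraph), `adjacency`,
#'   `n_directed_kept`, `cutoff`.
#' @export
build_state_graph <- function(conn, keep_fraction = 0.2) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  m <- if (inherits(conn, "megstates_connectivity")) conn$pdc else conn
  n <- nrow(m)
  off <- m; diag(off) <- NA
  vals <- off[!is.na(off)]
  n_keep <- ceiling(keep_fraction * length(vals))
  cutoff <- sort(vals, decreasing = TRUE)[n_keep]
  keep <- !is.na(off) & off >= cutoff
  adj <- matrix(0, n, n)
  adj[keep] <- m[keep]
  adj_sym <- pmax(adj, t(adj))                    # max of the two directions
  g <- igraph::graph_from_adjacency_matrix(adj_sym, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  structure(list(graph = g, adjacency = adj_sym,
                 n_directed_kept = sum(keep), cutoff = cutoff),
            class = "megstates_state_graph")
}

# Onnela geometric-mean weighted clustering coefficient per node, on
# weights max-normalized to [0, 1]; nodes with degree < 2 get 0.
onnela_clustering <- function(adj) {
  w <- adj / max(adj, na.rm = TRUE)
  if (!is.finite(max(adj)) || max(adj) == 0) return(rep(0, nrow(adj)))
  w3 <- w^(1 / 3)
  num <- diag(w3 %*% w3 %*% w3)
  k <- rowSums(adj > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  pmax(pmin(cc, 1), 0)
}

#' Graph features of a state network
#'
#' ACC is the mean Onnela weighted clustering coefficient over all nodes
#' (weights max-normalized); betweenness centrality uses edge distances
#' `1/weight`, normalized by `(n-1)(n-2)/2`; BCD is the absolute difference
#' of the hemispheric BC means, and `GFI = (1 - ACC) * BCD`.  Higher GFI
#' flags a more pathological (centralized, lateralized) state.
#'
#' @param g a `megstates_state_graph`.
#' @param hemisphere_map character vector (`"left"`/`"right"`) per node;
#'   default 34 left then 34 right (the spherical-model ROI order).
#' @return tibble with `acc`, `bcd`, `gfi` and the per-node vectors as
#'   attributes.
#' @export
graph_features <- function(g, hemisphere_map = NULL) {
  adj <- g$adjacency
  n <- nrow(adj)
  if (is.null(hemisphere_map))
    hemisphere_map <- rep(c("left", "right"), each = n / 2)
  stopifnot(length(hemisphere_map) == n)
  cc <- onnela_clustering(adj)
  acc <- mean(cc)
  graph <- g$graph
  ew <- igraph::E(graph)$weight
  bc <- rep(0, n)
  if (length(ew) > 0) {
    bc_raw <- igraph::betweenness(graph, directed = FALSE, weights = 1 / ew,
                                  normalized = TRUE)
    bc[as.integer(igraph::V(graph))] <- bc_raw
  }
  bcd <- abs(mean(bc[hemisphere_map == "left"]) -
               mean(bc[hemisphere_map == "right"]))
  out <- tibble::tibble(acc = acc, bcd = bcd, gfi = (1 - acc) * bcd)
  attr(out, "clustering") <- cc
  attr(out, "betweenness") <- bc
  out
}

#' Hierarchically cluster states by connectivity pattern
#'
#' Vectorizes each state's off-diagonal PDC entries, clusters with average
#' linkage on correlation distance, and picks the cluster count with the
#' largest mean silhouette over 2..(n-1) (or uses `n_clusters`).  Each
#' cluster's connectivity is the element-wise mean over members.
#'
#' @param connectivities list of `megstates_connectivity` (or matrices).
#' @param n_clusters integer, or `"auto"`.
#' @param state_values optional numeric per-state values (e.g. a
#'   localization error per state) averaged within each cluster.
#' @return a `megstates_state_clusters`: `assignment` tibble
#'   (`state`, `cluster`), `mean_connectivity` (list per cluster),
#'   `n_clusters`, `identical` flag, and `cluster_values` when
#'   `state_values` is given.
#' @export
cluster_states <- function(connectivities, n_clusters = "auto",
                           state_values = NULL) {
  stopifnot(length(connectivities) >= 2)
  mats <- lapply(connectivities, function(x)
    if (inherits(x, "megstates_connectivity")) x$pdc else x)
  n <- nrow(mats[[1]])
  vecs <- t(vapply(mats, function(m) m[row(m) != col(m)],
                   numeric(n * (n - 1))))
  n_states <- nrow(vecs)
  if (all(apply(vecs, 2, function(col) max(col) - min(col)) <
          1e-12 * max(abs(vecs), 1e-300))) {
    assignment <- tibble::tibble(state = seq_len(n_states), cluster = 1L)
    return(structure(list(assignment = assignment,
                          mean_connectivity = list(Reduce(`+`, mats) / length(mats)),
                          n_clusters = 1L, identical = TRUE,
                          cluster_values = if (!is.null(state_values))
                            mean(state_values)),
                     class = "megstates_state_clusters"))
  }
  d <- as.dist(1 - cor(t(vecs)))
  d[!is.finite(d)] <- 1
  hc <- hclust(d, method = "average")
  if (identical(n_clusters, "auto")) {
    ks <- 2:max(2, n_states - 1)
    sil <- vapply(ks, function(k) {
      cl <- cutree(hc, k)
      if (length(unique(cl)) < 2) return(-Inf)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k_best <- ks[which.max(sil)]
  } else k_best <- n_clusters
  cl <- cutree(hc, k_best)
  mean_conn <- lapply(sort(unique(cl)), function(k) {
    members <- mats[cl == k]
    Reduce(`+`, members) / length(members)
  })
  structure(list(assignment = tibble::tibble(state = seq_len(n_states),
                                             cluster = as.integer(cl)),
                 mean_connectivity = mean_conn,
                 n_clusters = as.integer(k_best), identical = FALSE,
                 cluster_values = if (!is.null(state_values))
                   as.vector(tapply(state_values, cl, mean))),
            class = "megstates_state_clusters")
}

#' Rank states by graph feature index
#'
#' Descending GFI; ties break by larger BCD, then lower state id.  The
#' top-ranked state is flagged as the putative pathological state.
#'
#' @param features data frame with columns `gfi`, `bcd` (one row per
#'   state), e.g. from row-binding [graph_features()] results.
#' @return tibble with `state`, `gfi`, `bcd`, `rank`, `pathological`.
#' @export
rank_states <- function(features) {
  stopifnot(nrow(features) >= 1)
  df <- tibble::as_tibble(features)
  if (!"state" %in% names(df)) df$state <- seq_len(nrow(df))
  ord <- order(-df$gfi, -df$bcd, df$state)
  df <- df[ord, c("state", "gfi", "bcd",
                  setdiff(names(df), c("state", "gfi", "bcd")))]
  df$rank <- seq_len(nrow(df))
  df$pathological <- df$rank == 1
  df
}

#' Write a connectivity matrix / edge list to CSV
#' @param conn a `megstates_connectivity` or matrix.
#' @param file output path.
#' @return invisibly, the written data frame.
#' @export
write_connectivity_csv <- function(conn, file) {
  m <- if (inherits(conn, "megstates_connectivity")) conn$pdc else conn
  rownames(m) <- colnames(m) <- paste0("roi", seq_len(nrow(m)))
  write.csv(m, file)
  invisible(as.data.frame(m))
}
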