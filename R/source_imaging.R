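# LCMV beamforming of brain states onto the source space, peak
# localization, and 68-ROI source time-course extraction.

#' LCMV spatial filters for every vertex
#'
#' Unit-gain linearly-constrained minimum-variance filters under fixed
#' source orientation: with `C_reg = C + reg_fraction * mean(eig(C)) * I`,
#' the filter for leadfield column g is
#' `w = (C_reg^-1 g) / (g' C_reg^-1 g)`.
#'
#' @param leadfield a `megstates_leadfield`.
#' @param data_cov channels x channels symmetric data covariance.
#' @param reg_fraction diagonal-loading fraction of the mean eigenvalue
#'   (default 0.05).
#' @return n_vertices x n_channels matrix of filters (one row per vertex).
#' @export
lcmv_filters <- function(leadfield, data_cov, reg_fraction = 0.05) {
  stopifnot(reg_fraction >= 0)
  if (max(abs(data_cov - t(data_cov))) > 1e-8 * max(abs(data_cov)))
    stop("data_cov must be symmetric")
  n_ch <- nrow(data_cov)
  ridge <- reg_fraction * mean(diag(data_cov))
  if (ridge <= 0 && reg_fraction > 0) ridge <- 1   # zero covariance: any scale
  c_reg <- data_cov + diag(ridge, n_ch)
  ci_g <- tryCatch(solve(c_reg, leadfield$gain),
                   error = function(e)
                     stop("regularized covariance is singular; ",
                          "increase reg_fraction"))
  denom <- colSums(leadfield$gain * ci_g)
  t(ci_g) / denom
}

#' Localize a brain state with an LCMV beamformer
#'
#' Estimates the channel covariance from the state's concatenated segments,
#' computes per-vertex filters, and returns each vertex's output variance
#' as the activation map; the peak vertex is the argmax (lowest index on
#' ties).
#'
#' @param state a `megstates_brain_state` with nonempty segments, or a bare
#'   channels x time matrix.
#' @param leadfield a `megstates_leadfield`.
#' @param reg_fraction diagonal loading passed to [lcmv_filters()].
#' @return a `megstates_source_estimate`: `activation` (per vertex, >= 0),
#'   `peak_vertex`, `peak_coord_mm`, `weights`.
#' @export
localize_state <- function(state, leadfield, reg_fraction = 0.05) {
  dat <- if (inherits(state, "megstates_brain_state")) state$data else state
  if (is.null(dat) || ncol(dat) == 0) stop("state has no segments to localize")
  if (ncol(dat) < nrow(dat)) {
    warning("fewer segment samples than channels; adding stronger ",
            "regularization")
    reg_fraction <- max(reg_fraction, 0.5)
  }
  c_seg <- tcrossprod(dat - rowMeans(dat)) / ncol(dat)
  w <- lcmv_filters(leadfield, c_seg, reg_fraction)
  activation <- rowSums((w %*% c_seg) * w)       # w' C w per vertex
  activation <- pmax(activation, 0)
  peak <- which.max(activation)                  # lowest index on ties
  structure(list(activation = activation, peak_vertex = peak,
                 peak_coord_mm = leadfield$source_space$pos[peak, ] * 1000,
                 weights = w),
            class = "megstates_source_estimate")
}

#' @export
print.megstates_source_estimate <- function(x, ...) {
  cat("<megstates_source_estimate> peak vertex ", x$peak_vertex,
      " at (", paste(sprintf("%.1f", x$peak_coord_mm), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

#' 68-ROI source time courses of a brain state
#'
#' Beamforms the state's concatenated segments to every vertex and averages
#' the source time series within each ROI (rows ordered by ROI id 1..68).
#' Averaging filtered series equals filtering with the ROI-mean filter, so
#' the ROI filters are averaged first.
#'
#' @inheritParams localize_state
#' @return a `megstates_roi_tc`: `data` (68 x samples), `sfreq` if known.
#' @export
roi_timecourses <- function(state, leadfield, reg_fraction = 0.05) {
  dat <- if (inherits(state, "megstates_brain_state")) state$data else state
  if (is.null(dat) || ncol(dat) == 0) stop("state has no segments")
  c_seg <- tcrossprod(dat - rowMeans(dat)) / ncol(dat)
  w <- lcmv_filters(leadfield, c_seg, reg_fraction)
  roi <- leadfield$source_space$roi
  w_roi <- rowsum(w, roi) / as.vector(table(roi))
  structure(list(data = w_roi %*% dat, roi = sort(unique(roi))),
            class = "megstates_roi_tc")
}
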