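# Sensor-space preprocessing for real recordings: band-pass filtering,
# artifact-channel regression, and segmentation into analysis epochs.

#' Preprocess a sensor recording
#'
#' Zero-phase band-pass filters every channel (4th-order Butterworth,
#' forward-backward), regresses out artifact reference channels (e.g. EOG
#' or ECG) by least squares, and optionally splits the recording into
#' fixed-length segments for separate state-space fits.
#'
#' @param recording channels x time matrix with attribute `sfreq`, or a
#'   `megstates_trial`.
#' @param sfreq sampling rate in Hz (taken from the attribute if absent).
#' @param band band-pass edges in Hz (default `c(1, 50)`); `NULL` skips
#'   filtering.
#' @param artifact data of the artifact reference channels
#'   (n_artifact x time), or `NULL`.
#' @param segment_s segment length in seconds; `NULL` returns one segment.
#' @return list of channels x time matrices (segments, each with `sfreq`
#'   attribute); a trailing remainder shorter than `segment_s` is kept.
#' @export
preprocess_recording <- function(recording, sfreq = NULL, band = c(1, 50),
                                 artifact = NULL, segment_s = NULL) {
  if (inherits(recording, "megstates_trial")) recording <- recording$recording
  if (is.null(sfreq)) sfreq <- attr(recording, "sfreq")
  if (is.null(sfreq)) stop("sfreq not given and not an attribute of the recording")
  x <- recording
  if (!is.null(band)) {
    ny <- sfreq / 2
    bf <- signal::butter(4, c(band[1] / ny, band[2] / ny), type = "pass")
    x <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  }
  if (!is.null(artifact)) {
    a <- rbind(artifact)
    if (!is.null(band)) {
      ny <- sfreq / 2
      bf <- signal::butter(4, c(band[1] / ny, band[2] / ny), type = "pass")
      a <- t(apply(a, 1, function(ch) signal::filtfilt(bf, ch)))
    }
    beta <- t(solve(tcrossprod(a) + diag(1e-12 * mean(a^2) + 1e-300, nrow(a)),
                    tcrossprod(a, x)))
    x <- x - beta %*% a
  }
  n_t <- ncol(x)
  cuts <- if (is.null(segment_s)) c(0L, n_t) else
    unique(c(seq(0L, n_t, by = round(segment_s * sfreq)), n_t))
  lapply(seq_len(length(cuts) - 1), function(i) {
    seg <- x[, (cuts[i] + 1):cuts[i + 1], drop = FALSE]
    attr(seg, "sfreq") <- sfreq
    seg
  })
}
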