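# broom-style tidiers and ggplot2 figures.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted HMM: one row per state
#'
#' @param x a `megstates_hmm`.
#' @param ... unused.
#' @return tibble with `state`, `occupancy` (mean posterior), `pi`,
#'   `self_transition`, `mean_norm`.
#' @method tidy megstates_hmm
#' @export
tidy.megstates_hmm <- function(x, ...) {
  tibble::tibble(
    state = seq_len(x$K),
    occupancy = rowMeans(x$gamma),
    pi = x$pi,
    self_transition = diag(x$A),
    mean_norm = sqrt(colSums(x$mu^2)))
}

#' One-row summary of a fitted HMM
#' @inheritParams tidy.megstates_hmm
#' @return tibble with `K`, `free_energy`, `iterations`, `converged`,
#'   `n_restarts`, `best_restart`.
#' @method glance megstates_hmm
#' @export
glance.megstates_hmm <- function(x, ...) {
  tibble::tibble(K = x$K, free_energy = x$free_energy,
                 iterations = x$iterations, converged = x$converged,
                 n_restarts = x$n_restarts, best_restart = x$best_restart)
}

#' Condition-level summary of a simulation report
#'
#' @param x a `megstates_report`.
#' @param ... unused.
#' @return tibble with per-condition means and standard errors of the
#'   three evaluation metrics.
#' @method glance megstates_report
#' @export
glance.megstates_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$K, .data$snr_db),
    n = dplyr::n(),
    n_failed = sum(!is.na(.data$error)),
    le_mm_se = sd_se(.data$le_mm),
    le_mm = mean(.data$le_mm, na.rm = TRUE),
    freq_diff_hz_se = sd_se(.data$freq_diff_hz),
    freq_diff_hz = mean(.data$freq_diff_hz, na.rm = TRUE),
    trans_corr_se = sd_se(.data$trans_corr),
    trans_corr = mean(.data$trans_corr, na.rm = TRUE),
    .groups = "drop")
}

sd_se <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 2) return(NA_real_)
  sd(v) / sqrt(length(v))
}

#' @importFrom rlang .data
NULL

#' Plot free-energy convergence of a fitted HMM
#' @param object a `megstates_hmm`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot megstates_hmm
#' @export
autoplot.megstates_hmm <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$free_energy_trace),
                       free_energy = object$free_energy_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "VB iteration", y = "free energy",
                  title = "Variational free energy (best restart)")
}

#' Plot evaluation metrics by condition
#' @param object a `megstates_report`.
#' @param ... unused.
#' @return a ggplot (localization error by SNR and K).
#' @method autoplot megstates_report
#' @export
autoplot.megstates_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$snr_db), .data$le_mm,
                                   fill = factor(.data$K))) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "SNR (dB)", y = "localization error (mm)",
                  fill = "states K")
}

#' Plot a state's sensor topography as a flat sensor map
#' @param state a `megstates_brain_state`.
#' @param leadfield the leadfield carrying sensor positions.
#' @return a ggplot (azimuthal projection of sensor amplitudes).
#' @export
plot_topography <- function(state, leadfield) {
  pos <- leadfield$sensor_pos
  if (is.null(pos)) stop("leadfield carries no sensor positions")
  df <- tibble::tibble(x = pos[, 1], y = pos[, 2],
                       amplitude = state$topography)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   color = .data$amplitude)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::scale_color_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("State", state$state_id, "topography"))
}
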