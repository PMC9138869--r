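#' Detection configuration
#'
#' Collects every tunable of the burst-detection pipeline in one validated
#' object. Defaults follow the standard SKNA processing conventions: a
#' 500--1000 Hz analysis band, iSKNA threshold multiplier rho = 3, envelope
#' threshold multiplier lambda = 1, a 2 ms envelope window (the minimum
#' duration of a nerve action potential), an integral window of half the
#' envelope window, a 2 ms minimum burst duration, and an RC integration time
#' constant of 0.1 s.
#'
#' @param band_low_hz,band_high_hz band-pass edges in Hz.
#' @param rho iSKNA threshold multiplier (threshold = mu + rho * sigma).
#' @param lambda envelope threshold multiplier (eth = lambda * max baseline envelope).
#' @param n_env_ms envelope (sliding-maximum) window in ms.
#' @param dt_ms integral (moving-average) window in ms; default half of
#'   \code{n_env_ms}.
#' @param ts_ms minimum burst duration in ms; shorter detections are
#'   relabelled artifact.
#' @param rc_tau_s RC integrator time constant in seconds.
#' @param baseline_interval optional \code{c(start_s, end_s)} of a quiet epoch
#'   used to estimate the maximum baseline envelope; \code{NULL} selects the
#'   lowest-envelope windows automatically (see \code{\link{envelope_threshold}}).
#' @param invert_qrs_width_rule logical; if TRUE the ECG-artifact width test uses the
#'   inequality Wqrs < L instead of the default L < Wqrs (see
#'   \code{\link{reject_ecg_artifacts}}).
#' @param energy_basis signal whose squared samples enter the SKNAER energy
#'   sums: \code{"filtered"} (default) or \code{"tke"}.
#' @param normalize_by_duration logical; if TRUE SKNAER uses mean power per
#'   label instead of total energy.
#' @return A validated list of class \code{skna_config}.
#' @export
skna_config <- function(band_low_hz = 500, band_high_hz = 1000,
                        rho = 3, lambda = 1,
                        n_env_ms = 2, dt_ms = n_env_ms / 2, ts_ms = 2,
                        rc_tau_s = 0.1, baseline_interval = NULL,
                        invert_qrs_width_rule = FALSE,
                        energy_basis = c("filtered", "tke"),
                        normalize_by_duration = FALSE) {
  energy_basis <- match.arg(energy_basis)
  stopifnot(band_low_hz > 0, band_high_hz > band_low_hz,
            rho > 0, lambda > 0, n_env_ms > 0, dt_ms > 0, ts_ms > 0,
            rc_tau_s > 0)
  if (!is.null(baseline_interval)) {
    if (length(baseline_interval) != 2L || baseline_interval[2] <= baseline_interval[1]) {
      stop("'baseline_interval' must be c(start_s, end_s) with end > start")
    }
  }
  structure(list(
    band_low_hz = band_low_hz, band_high_hz = band_high_hz,
    rho = rho, lambda = lambda,
    n_env_ms = n_env_ms, dt_ms = dt_ms, ts_ms = ts_ms,
    rc_tau_s = rc_tau_s, baseline_interval = baseline_interval,
    invert_qrs_width_rule = invert_qrs_width_rule, energy_basis = energy_basis,
    normalize_by_duration = normalize_by_duration
  ), class = "skna_config")
}

#' @export
print.skna_config <- function(x, ...) {
  cat("<skna_config>\n")
  cat(sprintf("  band: %g-%g Hz | rho: %g | lambda: %g\n",
              x$band_low_hz, x$band_high_hz, x$rho, x$lambda))
  cat(sprintf("  envelope: %g ms | integral: %g ms | Ts: %g ms | tau: %g s\n",
              x$n_env_ms, x$dt_ms, x$ts_ms, x$rc_tau_s))
  bl <- if (is.null(x$baseline_interval)) "auto" else
    sprintf("%g-%g s", x$baseline_interval[1], x$baseline_interval[2])
  cat(sprintf("  baseline interval: %s | energy basis: %s\n", bl, x$energy_basis))
  invisible(x)
}

# ms -> samples, at least 1
ms_to_samples <- function(ms, fs) max(1L, as.integer(round(ms * fs / 1000)))
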