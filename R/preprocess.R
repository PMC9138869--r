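#' Band-pass filter a raw channel into the SKNA band
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase), so burst timing is not skewed by filter group delay. The
#' default band is 500--1000 Hz, above the bulk of ECG/EMG energy and below
#' the Nyquist limit of high-rate surface recordings.
#'
#' @param x numeric vector, raw channel (uV).
#' @param fs sampling rate in Hz.
#' @param band \code{c(low, high)} in Hz; requires \code{fs > 2 * high}.
#' @param order filter order of each Butterworth prototype (default 4).
#' @return numeric vector of the same length, the filtered signal (uV).
#' @export
bandpass <- function(x, fs, band = c(500, 1000), order = 4L) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    stop("'band' must be c(low, high) with 0 < low < high")
  }
  if (fs <= 2 * band[2]) stop("band infeasible: fs must exceed twice the upper edge")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Full-wave rectification
#' @param x numeric vector.
#' @return \code{abs(x)}.
#' @export
rectify <- function(x) abs(x)

#' First-order RC integration (iSKNA stage)
#'
#' Discrete first-order low-pass emulating a resistance-capacitance
#' integrating network: y(n) = alpha * y(n-1) + (1 - alpha) * x(n) with
#' alpha = exp(-1 / (fs * tau)) and y(-1) = 0. Applied to the rectified
#' band-passed signal this yields the integrated SKNA (iSKNA) envelope.
#'
#' @param x non-negative numeric vector (rectified signal, uV).
#' @param fs sampling rate in Hz.
#' @param tau_s RC time constant in seconds (default 0.1).
#' @return numeric vector, the iSKNA signal (uV).
#' @export
rc_integrate <- function(x, fs, tau_s = 0.1) {
  if (tau_s <= 0) stop("'tau_s' must be positive")
  alpha <- exp(-1 / (fs * tau_s))
  as.numeric(stats::filter((1 - alpha) * x, alpha, method = "recursive"))
}

#' iSKNA burst threshold
#'
#' The classical threshold mu + rho * sigma on the iSKNA signal, with sigma
#' the population standard deviation over the analysed window. rho = 3 is the
#' conventional default; lower rho increases sensitivity, higher rho
#' specificity.
#'
#' @param iskna numeric vector, the iSKNA signal.
#' @param rho threshold multiplier.
#' @param exclude optional logical vector marking samples (e.g. filter
#'   warm-up) excluded from the statistics.
#' @return list with \code{mu}, \code{sigma}, \code{rho}, \code{value}.
#' @export
iskna_threshold <- function(iskna, rho = 3, exclude = NULL) {
  if (!length(iskna)) stop("empty iSKNA signal")
  v <- if (is.null(exclude)) iskna else iskna[!exclude]
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  list(mu = mu, sigma = sigma, rho = rho, value = mu + rho * sigma)
}

#' Threshold burst detector on the iSKNA signal
#'
#' Maximal runs with iSKNA >= threshold are labelled \code{burst}; the
#' complement is \code{baseline}. Together the segments tile the analysed
#' interval \code{[0, N)} (0-based half-open sample indices).
#'
#' @param iskna numeric vector.
#' @param threshold scalar threshold, or the list from
#'   \code{\link{iskna_threshold}}.
#' @return data.frame of segments with columns \code{sp}, \code{ep},
#'   \code{label}, \code{source}.
#' @export
iskna_burst_detect <- function(iskna, threshold) {
  if (is.list(threshold)) threshold <- threshold$value
  above <- iskna >= threshold
  r <- rle(above)
  ep <- cumsum(r$lengths)
  sp <- ep - r$lengths
  data.frame(sp = as.integer(sp), ep = as.integer(ep),
             label = ifelse(r$values, "burst", "baseline"),
             source = "iskna_threshold", stringsAsFactors = FALSE)
}

# Number of warm-up samples whose filter/integrator transients are excluded
# from threshold statistics: 5 RC time constants.
warmup_samples <- function(fs, tau_s = 0.1) as.integer(ceiling(5 * tau_s * fs))
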