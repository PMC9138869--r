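#' RR interval series from R-peak indices
#'
#' @param r_indices 0-based R-peak sample indices (>= 2 peaks).
#' @param fs sampling rate in Hz.
#' @return list of class \code{rr_series}: \code{rr} in ms and \code{times},
#'   the interval end-times in seconds.
#' @export
rr_from_rpeaks <- function(r_indices, fs) {
  if (length(r_indices) < 2L) stop("need at least 2 R peaks")
  r_indices <- sort(r_indices)
  rr <- diff(r_indices) / fs * 1000
  structure(list(rr = rr, times = r_indices[-1L] / fs), class = "rr_series")
}

#' SDNN: standard deviation of NN intervals
#' @param rr numeric vector of RR intervals in ms, or an \code{rr_series}.
#' @return SDNN in ms (sample standard deviation).
#' @export
sdnn <- function(rr) {
  if (inherits(rr, "rr_series")) rr <- rr$rr
  if (length(rr) < 2L) stop("need at least 2 intervals")
  stats::sd(rr)
}

# Classical Lomb periodogram of an unevenly sampled, mean-centred series.
# Returns power per frequency; units follow y^2 (ms^2 for RR input).
lomb_power <- function(t, y, freqs) {
  y <- y - mean(y)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Frequency-domain HRV features
#'
#' Band powers of the RR series computed with a Lomb periodogram on the
#' uneven beat times (no resampling, hence no interpolation bias), integrated
#' over the conventional short-term bands: vLF 0.0033--0.04 Hz, LF
#' 0.04--0.15 Hz, HF 0.15--0.4 Hz. LF/HF is the usual sympathovagal balance
#' index. vLF needs at least 5 min of data and is reported missing on shorter
#' records.
#'
#' @param rr_series an \code{rr_series} from \code{\link{rr_from_rpeaks}}, or
#'   a list with \code{rr} (ms) and \code{times} (s).
#' @return list with \code{vlf}, \code{lf}, \code{hf} (ms^2) and
#'   \code{lf_hf}.
#' @export
frequency_features <- function(rr_series) {
  t <- rr_series$times; y <- rr_series$rr
  if (length(y) < 8L) stop("too few intervals for spectral analysis")
  span <- diff(range(t))
  df <- 1 / (4 * span)
  freqs <- seq(max(df, 0.002), 0.4, by = df)
  p <- lomb_power(t, y, freqs)
  band_power <- function(lo, hi) {
    sel <- freqs >= lo & freqs < hi
    if (!any(sel)) return(0)
    sum(p[sel]) * df * 2   # two-sided -> one-sided band power
  }
  vlf <- if (span < 300) NA_real_ else band_power(0.0033, 0.04)
  lf <- band_power(0.04, 0.15)
  hf <- band_power(0.15, 0.4)
  list(vlf = vlf, lf = lf, hf = hf,
       lf_hf = if (hf > 0) lf / hf else NA_real_)
}
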