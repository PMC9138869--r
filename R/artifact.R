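#' R-peak detection on the co-recorded ECG
#'
#' An integrated-derivative detector: the raw channel is band-pass filtered
#' to 5--15 Hz, differentiated, squared, and integrated over a 150 ms moving
#' window; peaks of the integrated signal above an adaptive threshold mark
#' beats, subject to a 200 ms refractory period. Each fiducial is then
#' refined to the local absolute maximum of the raw channel within +/- 50 ms,
#' so inverted-polarity leads yield the same beats.
#'
#' @param ecg numeric vector, raw channel containing mV-scale QRS complexes.
#' @param fs sampling rate in Hz.
#' @return integer vector of R-peak sample indices (0-based), possibly empty.
#' @export
detect_qrs <- function(ecg, fs) {
  n <- length(ecg)
  if (n < fs) return(integer(0))
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  f <- as.numeric(signal::filtfilt(bf, ecg))
  d <- c(0, diff(f))
  sq <- d^2
  mwi <- moving_mean(sq, floor(ms_to_samples(150, fs) / 2))
  peak_level <- stats::quantile(mwi, 0.99, names = FALSE)
  if (peak_level <= 0) return(integer(0))
  noise_level <- stats::median(mwi)
  if (noise_level > 0 && peak_level < 5 * noise_level) {
    return(integer(0))  # no beat-scale structure above background
  }
  thr <- noise_level + 0.25 * (peak_level - noise_level)
  refractory <- ms_to_samples(200, fs)
  above <- mwi >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  fiducials <- vapply(runs, function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(mwi[seg])]
  }, integer(1))
  # enforce refractory on fiducials
  keep <- integer(0)
  for (fi in fiducials) {
    if (!length(keep) || fi - keep[length(keep)] >= refractory) keep <- c(keep, fi)
  }
  half <- ms_to_samples(50, fs)
  r_idx <- vapply(keep, function(fi) {
    lo <- max(1L, fi - half); hi <- min(n, fi + half)
    seg <- lo:hi
    seg[which.max(abs(ecg[seg]))]
  }, integer(1))
  as.integer(sort(unique(r_idx)) - 1L)
}

#' QRS onset/offset delineation via the curve-length transform
#'
#' The raw channel is first low-passed to 40 Hz (the QRS morphology band) so
#' the curve length is driven by the complex rather than broadband noise,
#' then the per-sample curve-length increment sqrt(1 + (delta ecg)^2) - 1 is
#' accumulated over short windows: a backward-looking window for the onset
#' (it stays at baseline until the window starts entering the complex) and a
#' forward-looking window for the offset. The onset is the last index before
#' the R peak where the backward curve length is below theta_frac times the
#' full curve length of the beat; the offset is the first index after the R
#' peak where the forward curve length falls below it. Widths are clipped to
#' the physiological 40--200 ms range; beats too close to the record edge
#' are dropped.
#'
#' @param ecg numeric vector, raw channel.
#' @param fs sampling rate in Hz.
#' @param r_indices 0-based R-peak sample indices.
#' @param theta_frac threshold fraction of the beat curve length.
#' @param window_ms curve-length accumulation window in ms.
#' @return list of class \code{qrs_info}: \code{r_indices}, \code{onsets},
#'   \code{offsets}, \code{widths} (all 0-based samples; widths in samples).
#' @export
delineate_qrs <- function(ecg, fs, r_indices, theta_frac = 0.01, window_ms = 80) {
  n <- length(ecg)
  bf <- signal::butter(4, 40 / (fs / 2), type = "low")
  lp <- as.numeric(signal::filtfilt(bf, ecg))
  w <- ms_to_samples(window_ms, fs)
  dl <- c(0, sqrt(1 + diff(lp)^2) - 1)
  cs <- cumsum(dl)
  l_back <- cs - cs[pmax(seq_len(n) - w, 1L)]
  l_fwd <- cs[pmin(seq_len(n) + w, n)] - cs
  search <- ms_to_samples(250, fs)
  min_w <- ms_to_samples(40, fs); max_w <- ms_to_samples(200, fs)
  on <- integer(0); off <- integer(0); rk <- integer(0)
  for (r0 in r_indices) {
    r <- r0 + 1L  # 1-based
    if (r - search < 1L || r + search > n) next
    beat_len <- cs[min(n, r + search)] - cs[max(1L, r - search)]
    thr <- theta_frac * beat_len
    if (!is.finite(thr) || thr <= 0) next
    below_pre <- which(l_back[(r - search):r] < thr)
    below_post <- which(l_fwd[r:(r + search)] < thr)
    if (!length(below_pre) || !length(below_post)) next
    onset <- (r - search) + max(below_pre) - 1L
    offset <- r + min(below_post) - 1L
    width <- offset - onset
    if (width < min_w) { pad <- min_w - width; onset <- onset - ceiling(pad / 2); offset <- offset + floor(pad / 2) }
    if (offset - onset > max_w) {
      onset <- max(onset, r - max_w %/% 2); offset <- min(offset, r + max_w %/% 2)
    }
    on <- c(on, onset - 1L); off <- c(off, offset - 1L); rk <- c(rk, r0)
  }
  if (length(rk) < length(r_indices)) {
    message(sprintf("delineate_qrs: dropped %d beat(s) near record edges or with flat morphology",
                    length(r_indices) - length(rk)))
  }
  structure(list(r_indices = rk, onsets = on, offsets = off,
                 widths = off - on), class = "qrs_info")
}

#' Relabel ECG-induced false bursts
#'
#' A detected burst that contains an R-peak index and is narrower than the
#' QRS complex of that beat is attributed to residual high-frequency QRS
#' energy rather than nerve activity and relabelled \code{artifact}. When a
#' burst contains several R peaks it is tested against the widest contained
#' QRS. Segments are only relabelled -- never created, merged or moved. With
#' \code{qrs = NULL} (no ECG available) the input is returned unchanged.
#'
#' @param segments data.frame of labelled segments (\code{sp}, \code{ep},
#'   \code{label}, \code{source}).
#' @param qrs a \code{qrs_info} object, or NULL to skip the rule.
#' @param invert_qrs_width_rule logical; if TRUE use the inverted width test
#'   (artifact iff Wqrs < L) for comparison purposes.
#' @return the segments with ECG artifacts relabelled.
#' @export
reject_ecg_artifacts <- function(segments, qrs, invert_qrs_width_rule = FALSE) {
  if (is.null(qrs) || !length(qrs$r_indices)) {
    if (is.null(qrs)) message("reject_ecg_artifacts: no ECG channel; QRS width rule skipped")
    return(segments)
  }
  is_burst <- segments$label == "burst"
  for (i in which(is_burst)) {
    sp <- segments$sp[i]; ep <- segments$ep[i]
    contained <- qrs$r_indices > sp & qrs$r_indices < ep
    if (!any(contained)) next
    w_qrs <- max(qrs$widths[contained])
    L <- ep - sp
    hit <- if (invert_qrs_width_rule) w_qrs < L else L < w_qrs
    if (hit) {
      segments$label[i] <- "artifact"
      segments$source[i] <- "qrs_width"
    }
  }
  segments
}

#' Relabel too-short bursts
#'
#' Bursts shorter than the minimum nerve-action-potential duration Ts
#' (default 2 ms) are relabelled \code{artifact}; bursts of exactly Ts are
#' kept. When the burst boundaries come from a sliding-maximum envelope of
#' window n, every suprathreshold event is dilated by n - 1 samples (a single
#' above-threshold sample already yields a segment of the full window
#' length); \code{dilation_samples} subtracts that widening so the duration
#' compared against Ts is that of the underlying event, not of its dilated
#' footprint.
#'
#' @param segments data.frame of labelled segments.
#' @param fs sampling rate in Hz.
#' @param ts_ms minimum duration in ms.
#' @param dilation_samples envelope dilation to subtract from each burst
#'   length before the comparison (default 0).
#' @return the segments with short bursts relabelled.
#' @export
reject_short_bursts <- function(segments, fs, ts_ms = 2, dilation_samples = 0L) {
  ts <- ms_to_samples(ts_ms, fs)
  len <- segments$ep - segments$sp - dilation_samples
  short <- segments$label == "burst" & len < ts
  segments$label[short] <- "artifact"
  segments$source[short] <- "min_duration"
  segments
}

#' Close sub-threshold gaps between bursts
#'
#' Consecutive burst boundaries (an end and the following start) closer than
#' Ts are removed, concatenating the two bursts: no two distinct sympathetic
#' discharges can be separated by less than the duration of a single nerve
#' action potential, so such a gap is a threshold-crossing artifact of the
#' stochastic burst carrier, not a real pause.
#'
#' @param bursts data.frame of disjoint, sorted burst intervals (\code{sp},
#'   \code{ep}, 0-based half-open).
#' @param fs sampling rate in Hz.
#' @param ts_ms maximum gap to close, in ms (default 2).
#' @return the merged burst intervals.
#' @export
merge_close_bursts <- function(bursts, fs, ts_ms = 2) {
  if (nrow(bursts) < 2L) return(bursts)
  ts <- ms_to_samples(ts_ms, fs)
  keep <- bursts[1L, , drop = FALSE]
  for (i in 2L:nrow(bursts)) {
    last <- nrow(keep)
    if (bursts$sp[i] - keep$ep[last] < ts) {
      keep$ep[last] <- bursts$ep[i]
    } else {
      keep <- rbind(keep, bursts[i, , drop = FALSE])
    }
  }
  rownames(keep) <- NULL
  keep
}
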