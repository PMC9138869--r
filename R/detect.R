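#' Detect SKNA bursts in a recording
#'
#' The main entry point. For the default \code{method = "tke"} the pipeline
#' is: band-pass (500--1000 Hz, zero phase) -> Teager--Kaiser energy
#' enhancement with full-wave rectification -> sliding-maximum envelope ->
#' threshold candidates at eth = lambda * (baseline envelope maximum) ->
#' boundary refinement on the short-window integral signal -> relabelling of
#' ECG-induced bursts (narrower than the containing QRS complex) and of
#' bursts shorter than Ts as artifacts. \code{method = "iskna"} runs the
#' classical comparator instead: rectified band-passed signal integrated by a
#' first-order RC stage and thresholded at mu + rho * sigma.
#'
#' The returned segments tile the whole recording: every sample is labelled
#' \code{burst}, \code{baseline} or \code{artifact}, with the rule that
#' assigned the label recorded in \code{source}.
#'
#' @param rec an \code{skna_recording} (or a numeric vector, in which case
#'   \code{fs} must be given).
#' @param config an \code{\link{skna_config}}.
#' @param channel channel index/label carrying the SKNA signal.
#' @param ecg_channel channel for QRS detection; defaults to the same lead
#'   (SKNA and ECG are recorded from the same surface electrodes). Set to
#'   \code{NA} to disable the ECG-artifact rule.
#' @param method \code{"tke"} (proposed pipeline) or \code{"iskna"}
#'   (threshold comparator).
#' @param fs sampling rate, only when \code{rec} is a bare vector.
#' @param r_indices optional precomputed 0-based R-peak indices (bypasses the
#'   built-in detector).
#' @return An object of class \code{skna_detect} with components
#'   \code{segments} (tiling data.frame: sp, ep, label, source),
#'   \code{filtered}, \code{iskna}, \code{thresholds}, \code{qrs},
#'   \code{config}, \code{fs}, \code{n}, \code{method}, \code{rejections}.
#' @examples
#' spec <- sim_spec(duration_s = 20, burst_rate_per_min = 12, seed = 7)
#' sim <- skna_simulate(spec)
#' fit <- skna_detect(sim$recording, skna_config())
#' summary(fit)
#' @export
skna_detect <- function(rec, config = skna_config(), channel = 1L,
                        ecg_channel = channel, method = c("tke", "iskna"),
                        fs = NULL, r_indices = NULL) {
  method <- match.arg(method)
  if (is.numeric(rec) && is.null(dim(rec))) {
    if (is.null(fs)) stop("'fs' required when 'rec' is a numeric vector")
    rec <- skna_recording(rec, fs)
  }
  stopifnot(inherits(rec, "skna_recording"), inherits(config, "skna_config"))
  fs <- rec$fs
  x <- channel(rec, channel)
  n <- length(x)
  band <- c(config$band_low_hz, config$band_high_hz)
  filtered <- bandpass(x, fs, band)
  rect <- rectify(filtered)
  iskna <- rc_integrate(rect, fs, config$rc_tau_s)
  warm <- warmup_samples(fs, config$rc_tau_s)
  exclude <- rep(FALSE, n)
  if (2L * warm < n) {
    exclude[seq_len(warm)] <- TRUE
    exclude[(n - warm + 1L):n] <- TRUE
  }

  thresholds <- list()
  rejections <- c(qrs_width = 0L, min_duration = 0L)
  qrs <- NULL

  if (method == "iskna") {
    thr <- iskna_threshold(iskna, config$rho, exclude = exclude)
    segments <- iskna_burst_detect(iskna, thr)
    thresholds <- thr
    phi <- NULL
  } else {
    phi <- tke(filtered, rectified = TRUE)
    env <- envelope(phi, fs, config$n_env_ms)
    eth <- envelope_threshold(env, fs, config$baseline_interval, config$lambda)
    cands <- detect_candidates(env, eth$eth)
    integ <- integral_signal(phi, fs, config$dt_ms)
    cands <- refine_boundaries(cands, integ)
    cands <- merge_close_bursts(cands, fs, config$ts_ms)
    bursts <- data.frame(sp = cands$sp, ep = cands$ep, label = "burst",
                         source = ifelse(cands$refined, "envelope+integral", "envelope"),
                         stringsAsFactors = FALSE)
    segments <- tile_segments(bursts, n)
    if (!is.na(ecg_channel)) {
      ecg <- channel(rec, ecg_channel)
      if (is.null(r_indices)) r_indices <- detect_qrs(ecg, fs)
      if (length(r_indices)) qrs <- delineate_qrs(ecg, fs, r_indices)
      before <- sum(segments$label == "burst")
      segments <- reject_ecg_artifacts(segments, qrs, config$invert_qrs_width_rule)
      rejections["qrs_width"] <- before - sum(segments$label == "burst")
    } else {
      message("skna_detect: no ECG channel; QRS-artifact discrimination skipped")
    }
    before <- sum(segments$label == "burst")
    dil <- ms_to_samples(config$n_env_ms, fs) - 1L  # sliding-max widening
    segments <- reject_short_bursts(segments, fs, config$ts_ms,
                                    dilation_samples = dil)
    rejections["min_duration"] <- before - sum(segments$label == "burst")
    thresholds <- list(skna_max = eth$skna_max, lambda = eth$lambda, eth = eth$eth)
  }

  structure(list(
    segments = segments, filtered = filtered, iskna = iskna, phi = phi,
    thresholds = thresholds, qrs = qrs, config = config,
    fs = fs, n = n, method = method, rejections = rejections,
    call = match.call()
  ), class = "skna_detect")
}

#' Extract burst-labelled segments from a detection
#' @param fit an \code{skna_detect} object.
#' @return data.frame of burst segments (sp, ep, label, source).
#' @export
bursts <- function(fit) {
  stopifnot(inherits(fit, "skna_detect"))
  out <- fit$segments[fit$segments$label == "burst", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert detected burst segments to an annotation set (seconds)
#' @param fit an \code{skna_detect} object.
#' @return an \code{skna_annotations} object.
#' @export
as_annotations <- function(fit) {
  b <- bursts(fit)
  skna_annotations(b$sp / fit$fs, b$ep / fit$fs, "burst")
}

#' @export
print.skna_detect <- function(x, ...) {
  nb <- sum(x$segments$label == "burst")
  na <- sum(x$segments$label == "artifact")
  cat(sprintf("<skna_detect> method = %s | %d samples @ %g Hz\n",
              x$method, x$n, x$fs))
  cat(sprintf("  %d burst(s), %d artifact segment(s)\n", nb, na))
  invisible(x)
}

#' @export
summary.skna_detect <- function(object, ...) {
  seg <- object$segments
  dur <- (seg$ep - seg$sp) / object$fs
  tab <- tapply(dur, seg$label, sum)
  cnt <- table(seg$label)
  out <- list(method = object$method, fs = object$fs,
              total_s = object$n / object$fs,
              counts = cnt, durations_s = tab,
              thresholds = object$thresholds,
              rejections = object$rejections,
              n_beats = if (is.null(object$qrs)) 0L else length(object$qrs$r_indices))
  class(out) <- "summary.skna_detect"
  out
}

#' @export
print.summary.skna_detect <- function(x, ...) {
  cat(sprintf("SKNA burst detection (method = %s), %.1f s @ %g Hz\n",
              x$method, x$total_s, x$fs))
  for (lab in names(x$counts)) {
    cat(sprintf("  %-9s %4d segment(s), %8.3f s total\n",
                lab, x$counts[[lab]], x$durations_s[[lab]]))
  }
  if (x$method == "tke") {
    cat(sprintf("  envelope threshold eth = %.4g (lambda = %g, baseline max = %.4g)\n",
                x$thresholds$eth, x$thresholds$lambda, x$thresholds$skna_max))
    cat(sprintf("  rejections: %d by QRS width, %d by minimum duration; %d beat(s)\n",
                x$rejections[["qrs_width"]], x$rejections[["min_duration"]], x$n_beats))
  } else {
    cat(sprintf("  iSKNA threshold = %.4g (mu = %.4g, sigma = %.4g, rho = %g)\n",
                x$thresholds$value, x$thresholds$mu, x$thresholds$sigma, x$thresholds$rho))
  }
  invisible(x)
}

#' Plot a detection over the filtered signal
#'
#' Draws the band-passed SKNA trace with detected segments shaded: bursts in
#' blue, artifacts in red; unshaded regions are baseline.
#'
#' @param x an \code{skna_detect} object.
#' @param xlim optional time range in seconds.
#' @param ... passed to \code{plot}.
#' @export
plot.skna_detect <- function(x, xlim = NULL, ...) {
  t <- seq_len(x$n) / x$fs
  if (is.null(xlim)) xlim <- range(t)
  graphics::plot(t, x$filtered, type = "l", col = "grey30",
                 xlab = "time (s)", ylab = "filtered SKNA (uV)", xlim = xlim, ...)
  shade <- function(seg, col) {
    if (!nrow(seg)) return(invisible())
    graphics::rect(seg$sp / x$fs, graphics::par("usr")[3],
                   seg$ep / x$fs, graphics::par("usr")[4],
                   col = col, border = NA)
  }
  seg <- x$segments
  shade(seg[seg$label == "burst", ], grDevices::adjustcolor("blue", 0.2))
  shade(seg[seg$label == "artifact", ], grDevices::adjustcolor("red", 0.2))
  graphics::lines(t, x$filtered, col = "grey30")
  invisible(x)
}
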