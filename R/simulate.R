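#' Specification of a synthetic SKNA recording
#'
#' Describes a single-lead body-surface recording of the kind the detector is
#' designed for: a mV-scale ECG, microvolt-scale nerve bursts confined to the
#' 500--1000 Hz band, broadband baseline noise, and optional power-line,
#' EMG-burst and step-artifact contamination. Defaults reflect standard
#' acquisition conditions: 8 kHz sampling, QRS amplitude ~1 mV and width
#' 80 ms, burst amplitudes spanning 0.5--80 uV, baseline noise of 1 uV RMS.
#' Real QRS complexes retain a small amount of energy above 500 Hz; the
#' template therefore carries a brief intra-QRS high-frequency component
#' (default 4 uV RMS at ~700 Hz) so band-passed recordings show the
#' characteristic ECG artifact.
#'
#' @param duration_s total duration in seconds.
#' @param fs sampling rate in Hz (default 8000).
#' @param heart_rate_bpm mean heart rate (default 75); RR intervals jitter
#'   uniformly by +/- 3 percent.
#' @param qrs_amplitude_uv R-wave amplitude in uV (default 1000; 0 disables
#'   the ECG).
#' @param qrs_width_ms nominal QRS duration in ms (default 80).
#' @param qrs_hf_uv RMS of the intra-QRS high-frequency residual in uV.
#' @param burst_rate_per_min expected nerve-burst rate (default 10).
#' @param burst_duration_ms \code{c(min, max)} burst duration range in ms.
#' @param burst_amplitude_uv \code{c(min, max)} burst RMS amplitude range in
#'   uV (default 0.5--80).
#' @param baseline_noise_uv_rms white baseline noise RMS in uV (default 1).
#' @param powerline_hz,powerline_uv optional mains interference frequency and
#'   amplitude (NULL disables).
#' @param emg_events number of broadband (20--450 Hz) EMG bursts to inject.
#' @param step_artifacts number of transient baseline level shifts to inject.
#' @param epochs optional data.frame \code{(start_s, end_s, rate_scale,
#'   amp_scale, label)} modulating burst rate/amplitude piecewise (used by
#'   \code{\link{skna_scenario}}).
#' @param seed RNG seed for reproducibility.
#' @return A validated list of class \code{sim_spec}.
#' @export
sim_spec <- function(duration_s = 60, fs = 8000, heart_rate_bpm = 75,
                     qrs_amplitude_uv = 1000, qrs_width_ms = 80,
                     qrs_hf_uv = 4,
                     burst_rate_per_min = 10,
                     burst_duration_ms = c(200, 600),
                     burst_amplitude_uv = c(0.5, 80),
                     baseline_noise_uv_rms = 1,
                     powerline_hz = NULL, powerline_uv = 5,
                     emg_events = 0L, step_artifacts = 0L,
                     epochs = NULL, seed = 1L) {
  stopifnot(duration_s > 0, fs > 2000, heart_rate_bpm > 0,
            qrs_amplitude_uv >= 0, qrs_width_ms > 0,
            burst_rate_per_min >= 0,
            length(burst_duration_ms) == 2L, all(burst_duration_ms > 0),
            burst_duration_ms[1] <= burst_duration_ms[2],
            length(burst_amplitude_uv) == 2L, all(burst_amplitude_uv > 0),
            baseline_noise_uv_rms >= 0)
  peak_rate <- burst_rate_per_min *
    (if (is.null(epochs)) 1 else max(epochs$rate_scale))
  if (peak_rate / 60 * mean(burst_duration_ms) / 1000 > 0.8) {
    stop("infeasible burst rate: expected burst time exceeds 80% of the recording")
  }
  structure(list(
    duration_s = duration_s, fs = fs, heart_rate_bpm = heart_rate_bpm,
    qrs_amplitude_uv = qrs_amplitude_uv, qrs_width_ms = qrs_width_ms,
    qrs_hf_uv = qrs_hf_uv, burst_rate_per_min = burst_rate_per_min,
    burst_duration_ms = burst_duration_ms,
    burst_amplitude_uv = burst_amplitude_uv,
    baseline_noise_uv_rms = baseline_noise_uv_rms,
    powerline_hz = powerline_hz, powerline_uv = powerline_uv,
    emg_events = emg_events, step_artifacts = step_artifacts,
    epochs = epochs, seed = seed
  ), class = "sim_spec")
}

# PQRST template sampled around the R peak; returns list(offsets, values)
ecg_template <- function(fs, amp, qrs_width_ms, hf_uv) {
  t <- seq(-0.4, 0.4, by = 1 / fs)
  g <- function(a, mu_ms, sd_ms) a * exp(-((t - mu_ms / 1000)^2) / (2 * (sd_ms / 1000)^2))
  sd_r <- qrs_width_ms / 7
  v <- g(0.08 * amp, -180, 22) +                              # P
       g(-0.10 * amp, -0.28 * qrs_width_ms, qrs_width_ms / 18) +  # Q
       g(amp, 0, sd_r) +                                      # R
       g(-0.18 * amp, 0.31 * qrs_width_ms, qrs_width_ms / 15) +   # S
       g(0.25 * amp, 220, 55)                                 # T
  if (hf_uv > 0) {
    sd_hf <- qrs_width_ms / 8 / 1000
    envl <- exp(-t^2 / (2 * sd_hf^2))
    carrier <- sin(2 * pi * 700 * t) * envl
    carrier <- carrier / sqrt(mean(carrier[envl > 0.1]^2)) * hf_uv
    v <- v + carrier
  }
  list(offsets = round(t * fs), values = v)
}

#' Simulate a recording with ground truth
#'
#' Generates one surface lead containing ECG, band-limited (500--1000 Hz)
#' SKNA bursts with Tukey-tapered edges and amplitudes drawn uniformly from
#' the configured range (the amplitude is the RMS of the injected burst),
#' white baseline noise, and any optional contaminants, together with the
#' exact injected event times. The same spec and seed reproduce the recording
#' bit for bit.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @return list with \code{recording} (an \code{skna_recording}) and
#'   \code{truth}: \code{bursts} (data.frame sp, ep; 0-based half-open),
#'   \code{r_indices}, \code{qrs_width} (samples), \code{artifacts}
#'   (data.frame sp, ep, type).
#' @export
skna_simulate <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  fs <- spec$fs
  n <- as.integer(round(spec$duration_s * fs))
  x <- stats::rnorm(n, sd = spec$baseline_noise_uv_rms)

  # --- ECG ---
  r_idx <- integer(0); qrs_w <- integer(0)
  if (spec$qrs_amplitude_uv > 0) {
    tmpl <- ecg_template(fs, spec$qrs_amplitude_uv, spec$qrs_width_ms, spec$qrs_hf_uv)
    rr <- 60 / spec$heart_rate_bpm
    beats <- numeric(0); tcur <- 0.5
    while (tcur < spec$duration_s - 0.5) {
      beats <- c(beats, tcur)
      tcur <- tcur + rr * stats::runif(1, 0.97, 1.03)
    }
    r_idx <- as.integer(round(beats * fs))
    for (r in r_idx) {
      pos <- r + tmpl$offsets + 1L
      ok <- pos >= 1L & pos <= n
      x[pos[ok]] <- x[pos[ok]] + tmpl$values[ok]
    }
    qrs_w <- rep(ms_to_samples(spec$qrs_width_ms, fs), length(r_idx))
    r_idx <- r_idx  # 0-based by construction (beats from t = 0)
  }

  # --- nerve bursts ---
  bursts <- data.frame(sp = integer(), ep = integer(), amp = numeric())
  epochs <- spec$epochs
  if (is.null(epochs)) {
    epochs <- data.frame(start_s = 0, end_s = spec$duration_s,
                         rate_scale = 1, amp_scale = 1, label = "all")
  }
  onsets <- numeric(0); durs <- numeric(0); amps <- numeric(0)
  for (k in seq_len(nrow(epochs))) {
    len <- epochs$end_s[k] - epochs$start_s[k]
    lam <- spec$burst_rate_per_min / 60 * epochs$rate_scale[k] * len
    m <- stats::rpois(1, lam)
    if (m > 0) {
      onsets <- c(onsets, sort(stats::runif(m, epochs$start_s[k], epochs$end_s[k])))
      durs <- c(durs, stats::runif(m, spec$burst_duration_ms[1],
                                   spec$burst_duration_ms[2]) / 1000)
      amps <- c(amps, stats::runif(m, spec$burst_amplitude_uv[1],
                                   spec$burst_amplitude_uv[2]) * epochs$amp_scale[k])
    }
  }
  if (length(onsets)) {
    ord <- order(onsets)
    onsets <- onsets[ord]; durs <- durs[ord]; amps <- amps[ord]
    gap <- 0.05
    keep <- logical(length(onsets)); last_end <- -Inf
    for (i in seq_along(onsets)) {
      if (onsets[i] >= last_end + gap &&
          onsets[i] + durs[i] < spec$duration_s) {
        keep[i] <- TRUE; last_end <- onsets[i] + durs[i]
      }
    }
    onsets <- onsets[keep]; durs <- durs[keep]; amps <- amps[keep]
    band <- c(500, 1000)
    for (i in seq_along(onsets)) {
      sp <- as.integer(round(onsets[i] * fs))
      L <- max(ms_to_samples(1000 * durs[i], fs), 32L)
      ep <- min(sp + L, n)
      L <- ep - sp
      pad <- 256L  # generate with padding so the band-pass transient is discarded
      carrier <- bandpass(stats::rnorm(L + 2L * pad), fs, band)[(pad + 1L):(pad + L)]
      carrier <- carrier * tukey_window(L, 0.25)
      carrier <- carrier / sqrt(mean(carrier^2)) * amps[i]
      x[(sp + 1L):ep] <- x[(sp + 1L):ep] + carrier
      bursts <- rbind(bursts, data.frame(sp = sp, ep = ep, amp = amps[i]))
    }
  }

  # --- optional contaminants ---
  artifacts <- data.frame(sp = integer(), ep = integer(), type = character())
  if (!is.null(spec$powerline_hz)) {
    tt <- seq_len(n) / fs
    x <- x + spec$powerline_uv * sin(2 * pi * spec$powerline_hz * tt)
  }
  if (spec$emg_events > 0) {
    bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
    for (i in seq_len(spec$emg_events)) {
      dur <- stats::runif(1, 0.5, 2)
      sp <- as.integer(round(stats::runif(1, 0, spec$duration_s - dur) * fs))
      L <- as.integer(round(dur * fs))
      amp <- stats::runif(1, 20, 100)
      e <- as.numeric(signal::filtfilt(bf, stats::rnorm(L)))
      e <- e * tukey_window(L, 0.5)
      e <- e / sqrt(mean(e^2)) * amp
      x[(sp + 1L):(sp + L)] <- x[(sp + 1L):(sp + L)] + e
      artifacts <- rbind(artifacts, data.frame(sp = sp, ep = sp + L, type = "emg"))
    }
  }
  if (spec$step_artifacts > 0) {
    for (i in seq_len(spec$step_artifacts)) {
      dur <- stats::runif(1, 1, 3)
      sp <- as.integer(round(stats::runif(1, 0, spec$duration_s - dur) * fs))
      L <- as.integer(round(dur * fs))
      x[(sp + 1L):(sp + L)] <- x[(sp + 1L):(sp + L)] +
        sample(c(-1, 1), 1) * stats::runif(1, 100, 500)
      artifacts <- rbind(artifacts, data.frame(sp = sp, ep = sp + L, type = "step"))
    }
  }

  rec <- skna_recording(x, fs, labels = "ch1")
  truth <- list(bursts = bursts, r_indices = r_idx, qrs_width = qrs_w,
                artifacts = artifacts, epochs = epochs)
  list(recording = rec, truth = truth)
}

# Tukey (tapered cosine) window of length n with taper fraction alpha
tukey_window <- function(n, alpha = 0.25) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Canned simulation scenarios
#'
#' \code{"stimulation"} mirrors a rest/activation protocol: 30 s quiet
#' baseline (sparse, small bursts), 60 s sympathetic activation (elevated
#' burst rate and amplitude), 30 s recovery. \code{"longterm"} is a
#' compressed monitoring run: eight 30 s periods with a piecewise burst-rate
#' profile (activity falling, rebounding mid-run, and rising at the end).
#'
#' @param name \code{"stimulation"} or \code{"longterm"}.
#' @param seed RNG seed passed through to the spec.
#' @return A \code{\link{sim_spec}} with an \code{epochs} table.
#' @export
skna_scenario <- function(name = c("stimulation", "longterm"), seed = 1L) {
  name <- match.arg(name)
  if (name == "stimulation") {
    epochs <- data.frame(
      start_s = c(0, 30, 90), end_s = c(30, 90, 120),
      rate_scale = c(0.2, 2.5, 0.5), amp_scale = c(0.4, 1.5, 0.6),
      label = c("baseline", "activation", "recovery"))
    sim_spec(duration_s = 120, burst_rate_per_min = 10,
             burst_amplitude_uv = c(10, 40), epochs = epochs, seed = seed)
  } else {
    starts <- seq(0, 210, by = 30)
    epochs <- data.frame(
      start_s = starts, end_s = starts + 30,
      rate_scale = c(1.4, 0.8, 0.7, 1.3, 1.0, 0.6, 0.7, 1.2),
      amp_scale = rep(1, 8),
      label = paste0("period", 1:8))
    sim_spec(duration_s = 240, burst_rate_per_min = 8,
             burst_amplitude_uv = c(5, 30), epochs = epochs, seed = seed)
  }
}
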