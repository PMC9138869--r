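#' Decimate an iSKNA signal to unit-time bins
#'
#' The average-SKNA feature is conventionally computed on iSKNA values taken
#' once per 0.1 s unit time. This reduces the full-rate RC output to one
#' value per bin (bin mean).
#'
#' @param iskna numeric vector, full-rate iSKNA (uV).
#' @param fs sampling rate in Hz.
#' @param unit_s unit time in seconds (default 0.1).
#' @return numeric vector of per-bin iSKNA values; a trailing partial bin is
#'   dropped.
#' @export
iskna_units <- function(iskna, fs, unit_s = 0.1) {
  bin <- max(1L, as.integer(round(unit_s * fs)))
  nb <- length(iskna) %/% bin
  if (nb < 1L) stop("signal shorter than one unit time")
  m <- matrix(iskna[seq_len(nb * bin)], nrow = bin)
  colMeans(m)
}

#' Average SKNA (aSKNA) over an analysis window
#'
#' The arithmetic mean of the 0.1 s iSKNA values inside the window; N such
#' values are averaged (N = 3000 for a 5 min window). Units are microvolts.
#' Being a plain amplitude average, aSKNA scales with any gain applied to
#' the recording and is sensitive to baseline and impulse noise.
#'
#' @param iskna full-rate iSKNA vector (uV).
#' @param fs sampling rate in Hz.
#' @param window \code{c(start_s, end_s)}; default the whole signal.
#' @param unit_s unit time of the decimation (default 0.1 s).
#' @return list with \code{askna} (uV) and \code{n_units} averaged.
#' @export
askna <- function(iskna, fs, window = NULL, unit_s = 0.1) {
  units <- iskna_units(iskna, fs, unit_s)
  if (is.null(window)) {
    sel <- seq_along(units)
  } else {
    lo <- floor(window[1] / unit_s) + 1L
    hi <- min(floor(window[2] / unit_s), length(units))
    if (lo > hi) stop("empty aSKNA window")
    sel <- lo:hi
  }
  list(askna = mean(units[sel]), n_units = length(sel))
}

#' SKNA energy ratio (SKNAER) over an analysis window
#'
#' SKNAER = 10 * log10(P_burst / P_baseline) in dB, where P_burst is the
#' total energy (sum of squared band-passed samples) over burst-labelled
#' samples in the window and P_baseline the same over baseline-labelled
#' samples. Artifact-labelled samples count towards neither sum. Because
#' recording gain cancels in the ratio, SKNAER is robust to sensor and
#' subject amplitude differences that make aSKNA unstable. A window that is
#' entirely burst or entirely baseline is flagged \code{abnormal} and the
#' ratio reported as missing (never +/- Inf).
#'
#' @param filtered numeric vector of band-passed samples (uV).
#' @param segments tiling data.frame of labelled segments (sp, ep, label).
#' @param window \code{c(start_s, end_s)}; default the whole signal.
#' @param fs sampling rate in Hz.
#' @param energy_basis kept for provenance; the vector passed as
#'   \code{filtered} is the energy basis.
#' @param normalize_by_duration if TRUE use mean power per label instead of
#'   total energy (a power-ratio variant).
#' @return one-row data.frame: \code{window_start_s}, \code{window_end_s},
#'   \code{sknaer_db}, \code{p_burst}, \code{p_baseline}, \code{abnormal}.
#' @export
sknaer <- function(filtered, segments, fs, window = NULL,
                   energy_basis = "filtered", normalize_by_duration = FALSE) {
  n <- length(filtered)
  if (is.null(window)) window <- c(0, n / fs)
  w_lo <- as.integer(round(window[1] * fs))      # 0-based half-open window
  w_hi <- min(as.integer(round(window[2] * fs)), n)
  if (w_hi <= w_lo) stop("empty SKNAER window")
  sums <- c(burst = 0, baseline = 0)
  counts <- c(burst = 0L, baseline = 0L)
  for (i in seq_len(nrow(segments))) {
    lab <- segments$label[i]
    if (!lab %in% names(sums)) next
    lo <- max(segments$sp[i], w_lo); hi <- min(segments$ep[i], w_hi)
    if (hi <= lo) next
    sums[lab] <- sums[lab] + sum(filtered[(lo + 1L):hi]^2)
    counts[lab] <- counts[lab] + (hi - lo)
  }
  abnormal <- counts[["burst"]] == 0L || counts[["baseline"]] == 0L
  p_burst <- sums[["burst"]]; p_baseline <- sums[["baseline"]]
  if (normalize_by_duration && !abnormal) {
    p_burst <- p_burst / counts[["burst"]]
    p_baseline <- p_baseline / counts[["baseline"]]
  }
  val <- if (abnormal || p_burst <= 0 || p_baseline <= 0) NA_real_ else
    10 * log10(p_burst / p_baseline)
  data.frame(window_start_s = window[1], window_end_s = window[2],
             sknaer_db = val, p_burst = p_burst, p_baseline = p_baseline,
             abnormal = abnormal || p_burst <= 0 || p_baseline <= 0)
}

#' Per-window feature table for a detection
#'
#' Splits the recording into consecutive analysis windows and computes aSKNA
#' and SKNAER per window. Default window lengths in practice: 60 s for
#' stimulation-style runs, 30 min for long-term monitoring.
#'
#' @param fit an \code{skna_detect} object.
#' @param window_s analysis window length in seconds.
#' @param abnormal_retry if TRUE, a window flagged abnormal is retried once
#'   with doubled length (centred on the same start).
#' @return data.frame with columns \code{window_start_s}, \code{window_end_s},
#'   \code{askna_uv}, \code{sknaer_db}, \code{abnormal}.
#' @export
skna_features <- function(fit, window_s = 60, abnormal_retry = FALSE) {
  stopifnot(inherits(fit, "skna_detect"))
  total_s <- fit$n / fit$fs
  basis <- if (fit$config$energy_basis == "tke" && !is.null(fit$phi))
    sqrt(fit$phi) else fit$filtered
  n_win <- max(1L, as.integer(ceiling(total_s / window_s - 1e-9)))
  starts <- (seq_len(n_win) - 1) * window_s
  rows <- lapply(starts, function(s) {
    e <- min(s + window_s, total_s)
    er <- sknaer(basis, fit$segments, fit$fs, c(s, e),
                 normalize_by_duration = fit$config$normalize_by_duration)
    if (er$abnormal && abnormal_retry) {
      e2 <- min(s + 2 * window_s, total_s)
      er <- sknaer(basis, fit$segments, fit$fs, c(s, e2),
                   normalize_by_duration = fit$config$normalize_by_duration)
    }
    a <- askna(fit$iskna, fit$fs, c(s, er$window_end_s))
    data.frame(window_start_s = s, window_end_s = er$window_end_s,
               askna_uv = a$askna, sknaer_db = er$sknaer_db,
               abnormal = er$abnormal)
  })
  do.call(rbind, rows)
}
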