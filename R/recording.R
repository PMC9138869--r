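#' Construct a multichannel biopotential recording
#'
#' A recording holds raw body-surface biopotential samples in microvolts,
#' one row per channel, together with the sampling rate. SKNA analysis
#' assumes a high sampling rate (>= 2 kHz; typically 8 kHz) so that the
#' 500--1000 Hz nerve band is resolvable.
#'
#' @param samples numeric matrix, channels in rows, samples in columns (uV),
#'   or a numeric vector for a single channel.
#' @param fs sampling rate in Hz (> 0).
#' @param labels optional character vector of channel names; defaults to
#'   \code{ch1, ch2, ...}.
#' @param start_time optional wall-clock origin (POSIXct), metadata only.
#' @return An object of class \code{skna_recording} with fields
#'   \code{samples}, \code{fs}, \code{labels}, \code{start_time}.
#' @export
skna_recording <- function(samples, fs, labels = NULL, start_time = NULL) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, nrow = 1L)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("'samples' must be a numeric matrix [channel x sample] or a vector")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)")
  }
  if (ncol(samples) < 2L) stop("a recording needs at least 2 samples")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  if (length(labels) != nrow(samples)) {
    stop("'labels' must have one entry per channel")
  }
  rownames(samples) <- labels
  structure(
    list(samples = samples, fs = as.numeric(fs), labels = as.character(labels),
         start_time = start_time),
    class = "skna_recording"
  )
}

#' @export
print.skna_recording <- function(x, ...) {
  cat(sprintf("<skna_recording> %d channel(s), %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param x an \code{skna_recording}.
#' @return integer sample count per channel.
#' @export
n_samples <- function(x) ncol(x$samples)

#' Extract one channel as a numeric vector
#' @param rec an \code{skna_recording}.
#' @param channel channel index or label.
#' @return numeric vector of samples (uV).
#' @export
channel <- function(rec, channel = 1L) {
  if (is.character(channel)) {
    idx <- match(channel, rec$labels)
    if (is.na(idx)) stop("unknown channel label: ", channel)
    channel <- idx
  }
  if (channel < 1L || channel > nrow(rec$samples)) stop("channel out of range")
  as.numeric(rec$samples[channel, ])
}

#' Read a recording from disk
#'
#' CSV is the supported interchange dialect: a header row of channel names and
#' one row per sample, values in microvolts. The sampling rate is not encoded
#' in CSV, so it must be given via \code{fs} or a JSON sidecar
#' (\code{<path>.meta.json} with an \code{fs} field).
#'
#' @param path file path.
#' @param format one of \code{"csv"}, \code{"wfdb"}, \code{"edf"}; only CSV
#'   has a reader in this package.
#' @param fs sampling rate in Hz (required for CSV unless a sidecar exists).
#' @return An \code{skna_recording}.
#' @export
read_recording <- function(path, format = c("csv", "wfdb", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (format != "csv") {
    stop(sprintf("format '%s' is not supported by this reader; convert to CSV (one column per channel, uV)", format))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(fs)) {
    sidecar <- paste0(path, ".meta.json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      fs <- meta$fs
    }
  }
  if (is.null(fs)) stop("sampling rate 'fs' is required for CSV input (argument or .meta.json sidecar)")
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) < 2L) stop("recording too short")
  m <- t(as.matrix(df))
  skna_recording(m, fs = fs, labels = colnames(df))
}

#' Write a recording to CSV
#'
#' One column per channel, header row of channel labels, values in uV. A JSON
#' sidecar \code{<path>.meta.json} carries the sampling rate so the file
#' round-trips through \code{\link{read_recording}}.
#'
#' @param rec an \code{skna_recording}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- as.data.frame(t(rec$samples))
  names(df) <- rec$labels
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct an annotation set of expert burst intervals
#'
#' Intervals are stored in seconds, sorted and validated: strictly positive
#' length, non-overlapping.
#'
#' @param onset_s,offset_s numeric vectors of interval bounds in seconds.
#' @param label character vector of labels (recycled), default "burst".
#' @return An object of class \code{skna_annotations}: a data.frame with
#'   columns \code{onset_s}, \code{offset_s}, \code{label}.
#' @export
skna_annotations <- function(onset_s = numeric(), offset_s = numeric(),
                             label = "burst") {
  if (length(onset_s) != length(offset_s)) stop("onset/offset length mismatch")
  df <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   label = rep_len(as.character(label), length(onset_s)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df)) {
    if (any(df$offset_s <= df$onset_s)) stop("annotations must have positive length")
    if (any(df$onset_s[-1L] < df$offset_s[-nrow(df)])) {
      stop("annotations must not overlap")
    }
  }
  class(df) <- c("skna_annotations", "data.frame")
  df
}

#' Read expert burst annotations from CSV
#' @param path CSV with columns \code{onset_s,offset_s,label}.
#' @return An \code{skna_annotations} object (sorted, validated).
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s")
  if (!all(need %in% names(df))) stop("annotation CSV needs columns onset_s, offset_s")
  if (is.null(df$label)) df$label <- "burst"
  skna_annotations(df$onset_s, df$offset_s, df$label)
}

#' Write annotations to CSV
#' @param ann an \code{skna_annotations} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE)
  invisible(path)
}

#' Convert annotations (seconds) to half-open sample intervals
#'
#' Internal representation of segments is 0-based half-open sample intervals
#' \code{[sp, ep)}, so lengths are \code{ep - sp} and consecutive segments
#' tile without gap or overlap.
#'
#' @param ann an \code{skna_annotations} object.
#' @param fs sampling rate of the target recording.
#' @return data.frame with integer columns \code{sp}, \code{ep} and \code{label}.
#' @export
annotations_to_samples <- function(ann, fs) {
  data.frame(sp = as.integer(round(ann$onset_s * fs)),
             ep = as.integer(round(ann$offset_s * fs)),
             label = ann$label, stringsAsFactors = FALSE)
}
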