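#' Match detected bursts against expert annotations
#'
#' Greedy one-to-one matching by descending overlap: candidate pairs with
#' positive overlap are sorted by overlap length and assigned while both
#' members are still free. Unmatched detected segments are false positives,
#' unmatched expert segments false negatives. A minimum overlap fraction of
#' the expert segment can be required to tighten the rule.
#'
#' @param detected data.frame of burst segments (0-based half-open
#'   \code{sp}, \code{ep} in samples).
#' @param expert data.frame of reference segments in the same units (e.g.
#'   from \code{\link{annotations_to_samples}}).
#' @param min_overlap_frac minimum overlap as a fraction of the expert
#'   segment length for a pair to count (default 0: any overlap).
#' @return list of class \code{skna_match}: \code{tp}, \code{fp}, \code{fn},
#'   \code{pairs} (data.frame detected/expert row indices + \code{co}),
#'   \code{co_mean}.
#' @export
match_segments <- function(detected, expert, min_overlap_frac = 0) {
  nd <- nrow(detected); ne <- nrow(expert)
  cand <- NULL
  if (nd && ne) {
    grid <- expand.grid(d = seq_len(nd), e = seq_len(ne))
    ov <- pmin(detected$ep[grid$d], expert$ep[grid$e]) -
          pmax(detected$sp[grid$d], expert$sp[grid$e])
    need <- min_overlap_frac * (expert$ep[grid$e] - expert$sp[grid$e])
    keep <- ov > 0 & ov >= need
    cand <- grid[keep, , drop = FALSE]
    cand$ov <- ov[keep]
    cand <- cand[order(-cand$ov), , drop = FALSE]
  }
  used_d <- logical(nd); used_e <- logical(ne)
  pairs <- list()
  for (i in seq_len(NROW(cand))) {
    d <- cand$d[i]; e <- cand$e[i]
    if (used_d[d] || used_e[e]) next
    used_d[d] <- TRUE; used_e[e] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      detected = d, expert = e,
      co = coincidence(c(detected$sp[d], detected$ep[d]),
                       c(expert$sp[e], expert$ep[e])))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(detected = integer(), expert = integer(), co = numeric())
  structure(list(tp = nrow(pairs), fp = nd - nrow(pairs), fn = ne - nrow(pairs),
                 pairs = pairs,
                 co_mean = if (nrow(pairs)) mean(pairs$co) else NA_real_),
            class = "skna_match")
}

#' @export
print.skna_match <- function(x, ...) {
  cat(sprintf("<skna_match> TP = %d, FP = %d, FN = %d | DR = %.1f%%, P+ = %.1f%%, mean CO = %.3f\n",
              x$tp, x$fp, x$fn, detection_rate(x$tp, x$fn),
              precision(x$tp, x$fp), x$co_mean))
  invisible(x)
}

#' Detection rate DR = TP / (TP + FN) * 100
#' @param tp,fn non-negative counts.
#' @return percent in [0, 100].
#' @export
detection_rate <- function(tp, fn) {
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn) * 100
}

#' Precision P+ = TP / (TP + FP) * 100
#' @param tp,fp non-negative counts.
#' @return percent in [0, 100].
#' @export
precision <- function(tp, fp) {
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp) * 100
}

#' Coincidence of a detected and an expert segment
#'
#' CO = (min(EPa, EPe) - max(SPa, SPe)) / (EPe - SPe): the overlap as a
#' fraction of the expert segment length. The raw value is negative for
#' disjoint pairs and exceeds 1 when the detected segment strictly contains
#' the expert segment; it is clamped to [0, 1] (the raw value is available
#' via \code{clamp = FALSE}).
#'
#' @param detected_pair,expert_pair numeric \code{c(sp, ep)} pairs.
#' @param clamp clamp the result to [0, 1] (default TRUE).
#' @return coincidence fraction.
#' @export
coincidence <- function(detected_pair, expert_pair, clamp = TRUE) {
  len <- expert_pair[2] - expert_pair[1]
  if (len <= 0) stop("expert segment must have positive length")
  co <- (min(detected_pair[2], expert_pair[2]) -
         max(detected_pair[1], expert_pair[1])) / len
  if (clamp) co <- min(1, max(0, co))
  co
}

#' Evaluate a detection against reference annotations
#'
#' Convenience wrapper: extracts burst segments from a detection, converts
#' the annotations to samples at the detection's rate, matches, and reports
#' DR, precision and mean coincidence.
#'
#' @param fit an \code{skna_detect} object.
#' @param annotations an \code{skna_annotations} object (seconds), or a
#'   data.frame of sample intervals with \code{sp}, \code{ep}.
#' @param min_overlap_frac see \code{\link{match_segments}}.
#' @return one-row data.frame: \code{tp,fp,fn,dr_pct,precision_pct,co_mean}.
#' @export
evaluate_detection <- function(fit, annotations, min_overlap_frac = 0) {
  det <- bursts(fit)
  ref <- if (inherits(annotations, "skna_annotations"))
    annotations_to_samples(annotations, fit$fs) else annotations
  m <- match_segments(det, ref, min_overlap_frac)
  data.frame(tp = m$tp, fp = m$fp, fn = m$fn,
             dr_pct = detection_rate(m$tp, m$fn),
             precision_pct = precision(m$tp, m$fp),
             co_mean = m$co_mean)
}
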