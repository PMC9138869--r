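#' Sliding-maximum envelope of the rectified TKE sequence
#'
#' The envelope at sample i is the maximum of the sequence over the centred
#' window \code{[i - floor(n/2), i + floor(n/2)]}, truncated at the array
#' edges. The window length n defaults to 2 ms worth of samples -- the
#' minimum duration of a nerve action potential -- so sub-burst fluctuations
#' are shielded while the overall trend is retained.
#'
#' @param phi non-negative numeric vector (rectified TKE sequence).
#' @param fs sampling rate in Hz.
#' @param n_env_ms window length in ms (default 2).
#' @return numeric vector, the envelope; same length as \code{phi}.
#' @export
envelope <- function(phi, fs, n_env_ms = 2) {
  n <- ms_to_samples(n_env_ms, fs)
  moving_max(phi, floor(n / 2))
}

# centred sliding maximum with half-width k, edges truncated
moving_max <- function(x, k) {
  n <- length(x)
  res <- x
  if (k < 1L || n < 2L) return(res)
  for (off in seq_len(min(k, n - 1L))) {
    head_idx <- seq_len(n - off)
    res[head_idx + off] <- pmax(res[head_idx + off], x[head_idx])
    res[head_idx] <- pmax(res[head_idx], x[head_idx + off])
  }
  res
}

# centred moving average with half-width k, edges truncated
moving_mean <- function(x, k) {
  n <- length(x)
  if (k < 1L) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Envelope threshold from a baseline epoch
#'
#' The threshold is eth = lambda * Sknamax, where Sknamax is the maximum
#' envelope value over a burst-free baseline epoch. With the default
#' lambda = 1 the baseline maximum itself is the threshold. If no epoch is
#' supplied, a quiet region is selected automatically: the recording is cut
#' into 1 s windows and every window whose envelope maximum is not a
#' burst-scale outlier (at most twice the median window maximum) serves as
#' baseline. Screening on the window maximum -- the statistic the threshold
#' is built from -- excludes windows clipped by the edge of a burst, whose
#' median would still look quiet; keeping all non-outlier windows (rather
#' than only the very quietest) avoids biasing the estimated baseline
#' maximum downward. The automatic rule assumes bursts occupy a minority of
#' the record; give an explicit interval otherwise.
#'
#' @param env numeric envelope vector.
#' @param fs sampling rate in Hz.
#' @param baseline_interval optional \code{c(start_s, end_s)} within the
#'   recording.
#' @param lambda threshold multiplier (default 1).
#' @return list with \code{skna_max}, \code{lambda}, \code{eth} and
#'   \code{baseline_samples} (the 1-based sample indices used).
#' @export
envelope_threshold <- function(env, fs, baseline_interval = NULL, lambda = 1) {
  n <- length(env)
  if (!is.null(baseline_interval)) {
    lo <- as.integer(floor(baseline_interval[1] * fs)) + 1L
    hi <- min(as.integer(ceiling(baseline_interval[2] * fs)), n)
    if (lo > hi || lo < 1L) stop("baseline interval empty or outside the recording")
    idx <- lo:hi
  } else {
    win <- max(1L, as.integer(fs))
    starts <- seq(1L, n, by = win)
    maxes <- vapply(starts, function(s) max(env[s:min(s + win - 1L, n)]),
                    numeric(1))
    keep <- starts[maxes <= 2 * stats::median(maxes)]
    if (!length(keep)) keep <- starts[which.min(maxes)]
    idx <- unlist(lapply(keep, function(s) s:min(s + win - 1L, n)))
  }
  skna_max <- max(env[idx])
  if (!is.finite(skna_max) || skna_max <= 0) {
    stop("degenerate baseline: envelope maximum is not positive")
  }
  list(skna_max = skna_max, lambda = lambda, eth = lambda * skna_max,
       baseline_samples = idx)
}

#' Candidate burst detection on the envelope
#'
#' A candidate opens at the first sample where the envelope is at or above
#' the threshold with a positive first difference (rising through the
#' threshold), and closes at the first later sample where the envelope is
#' below the threshold with a negative difference (falling away from it).
#' A candidate still open at the end of the signal closes at the last sample.
#'
#' @param env numeric envelope vector.
#' @param eth positive scalar threshold (or the list from
#'   \code{\link{envelope_threshold}}).
#' @return data.frame of disjoint, ordered candidates with 0-based half-open
#'   columns \code{sp}, \code{ep} and logical \code{refined} (FALSE here).
#' @export
detect_candidates <- function(env, eth) {
  if (is.list(eth)) eth <- eth$eth
  if (!is.finite(eth) || eth <= 0) stop("'eth' must be a positive number")
  n <- length(env)
  d <- c(0, diff(env))
  open_idx <- which(env >= eth & d > 0)
  close_idx <- which(env < eth & d < 0)
  sp <- integer(0); ep <- integer(0)
  pos <- 0L
  repeat {
    oi <- open_idx[findInterval(pos, open_idx) + 1L]
    if (is.na(oi)) break
    ci <- close_idx[findInterval(oi, close_idx) + 1L]
    sp <- c(sp, oi - 1L)                 # to 0-based
    ep <- c(ep, if (is.na(ci)) n else ci - 1L)
    if (is.na(ci)) break
    pos <- ci
  }
  data.frame(sp = as.integer(sp), ep = as.integer(ep),
             refined = logical(length(sp)))
}

#' Short-window integral of the rectified TKE sequence
#'
#' Centred moving average over a window of \code{dt_ms} (discretisation of
#' the unit-time integral area). It reflects local detail better than the
#' sliding-maximum envelope, so it drives the fine boundary adjustment.
#' The default window is half the envelope window.
#'
#' @param phi non-negative numeric vector (rectified TKE sequence).
#' @param fs sampling rate in Hz.
#' @param dt_ms window in ms (default 1).
#' @return numeric vector, same length as \code{phi}.
#' @export
integral_signal <- function(phi, fs, dt_ms = 1) {
  dt <- ms_to_samples(dt_ms, fs)
  moving_mean(phi, floor(dt / 2))
}

#' Refine candidate boundaries on the integral signal
#'
#' For each candidate of rough length L = ep - sp, the new start is the
#' position of the minimum of the integral signal within one tenth of L
#' around the old start, and likewise for the end. Argmin ties break to the
#' earliest index for the start and the latest for the end, widening
#' conservatively so burst energy is not truncated. A refinement that would
#' invert the interval is rejected and the candidate kept unrefined.
#' Candidates that overlap after refinement are merged.
#'
#' @param cands data.frame from \code{\link{detect_candidates}}.
#' @param integ numeric vector from \code{\link{integral_signal}}.
#' @return data.frame of refined, disjoint, ordered candidates.
#' @export
refine_boundaries <- function(cands, integ) {
  n <- length(integ)
  if (!nrow(cands)) return(cands)
  sp_new <- cands$sp; ep_new <- cands$ep; refined <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    sp <- cands$sp[i]; ep <- cands$ep[i]
    w <- floor((ep - sp) / 10)
    # start: search [sp - w, sp + w] (0-based sample indices), earliest argmin
    lo <- max(0L, sp - w); hi <- min(n - 1L, sp + w)
    win <- integ[(lo + 1L):(hi + 1L)]
    s_cand <- lo + which.min(win) - 1L
    # end: search around the boundary index ep, latest argmin
    lo2 <- max(0L, ep - w); hi2 <- min(n - 1L, ep + w)
    win2 <- integ[(lo2 + 1L):(hi2 + 1L)]
    e_cand <- lo2 + (length(win2) - which.min(rev(win2)))
    if (s_cand < e_cand) {
      sp_new[i] <- s_cand; ep_new[i] <- e_cand; refined[i] <- TRUE
    }
  }
  out <- data.frame(sp = as.integer(sp_new), ep = as.integer(ep_new),
                    refined = refined)
  out <- out[order(out$sp), , drop = FALSE]
  merge_candidates(out)
}

# concatenate candidates whose refined boundaries meet or overlap
merge_candidates <- function(cands) {
  if (nrow(cands) < 2L) { rownames(cands) <- NULL; return(cands) }
  keep <- cands[1L, , drop = FALSE]
  for (i in 2L:nrow(cands)) {
    last <- nrow(keep)
    if (cands$sp[i] <= keep$ep[last]) {
      keep$ep[last] <- max(keep$ep[last], cands$ep[i])
      keep$refined[last] <- keep$refined[last] || cands$refined[i]
    } else {
      keep <- rbind(keep, cands[i, , drop = FALSE])
    }
  }
  rownames(keep) <- NULL
  keep
}

#' Tile an interval with labelled segments
#'
#' Expands a set of disjoint burst/artifact intervals into a full tiling of
#' \code{[0, n)}: every sample not inside a listed segment is labelled
#' \code{baseline}. The result satisfies the partition invariant every
#' downstream energy feature relies on.
#'
#' @param segs data.frame with columns \code{sp}, \code{ep}, \code{label},
#'   \code{source} (0-based half-open, disjoint, sorted).
#' @param n total number of samples.
#' @return data.frame tiling \code{[0, n)}.
#' @export
tile_segments <- function(segs, n) {
  segs <- segs[order(segs$sp), , drop = FALSE]
  out <- list(); pos <- 0L
  add <- function(sp, ep, label, source) {
    data.frame(sp = as.integer(sp), ep = as.integer(ep), label = label,
               source = source, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(segs))) {
    if (segs$sp[i] > pos) out[[length(out) + 1L]] <- add(pos, segs$sp[i], "baseline", "gap")
    out[[length(out) + 1L]] <- segs[i, c("sp", "ep", "label", "source")]
    pos <- segs$ep[i]
  }
  if (pos < n) out[[length(out) + 1L]] <- add(pos, n, "baseline", "gap")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
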