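# Independent brute-force oracles used to check the vectorised implementations.

# windowed maximum over [i - k, i + k], truncated at edges
brute_moving_max <- function(x, k) {
  n <- length(x)
  vapply(seq_len(n), function(i) max(x[max(1, i - k):min(n, i + k)]), numeric(1))
}

# windowed mean over [i - k, i + k], truncated at edges
brute_moving_mean <- function(x, k) {
  n <- length(x)
  vapply(seq_len(n), function(i) mean(x[max(1, i - k):min(n, i + k)]), numeric(1))
}

# per-sample replay of the candidate open/close state machine
brute_candidates <- function(env, eth) {
  n <- length(env)
  d <- c(0, diff(env))
  sp <- integer(0); ep <- integer(0); open <- FALSE
  for (i in seq_len(n)) {
    if (!open && env[i] >= eth && d[i] > 0) {
      open <- TRUE; sp <- c(sp, i - 1L)
    } else if (open && env[i] < eth && d[i] < 0) {
      open <- FALSE; ep <- c(ep, i - 1L)
    }
  }
  if (open) ep <- c(ep, n)
  data.frame(sp = sp, ep = ep)
}

# run-length comparator for the iSKNA threshold detector
brute_runs <- function(x, thr) {
  lab <- ifelse(x >= thr, "burst", "baseline")
  ch <- c(TRUE, lab[-1] != lab[-length(lab)])
  sp <- which(ch) - 1L
  ep <- c(sp[-1], length(x))
  data.frame(sp = sp, ep = ep, label = lab[ch])
}

# exhaustive maximum-cardinality-then-overlap one-to-one matching for
# small instances (checks the greedy matcher's counts)
brute_match_counts <- function(det, exp) {
  nd <- nrow(det); ne <- nrow(exp)
  ov <- outer(seq_len(nd), seq_len(ne), function(i, j) {
    pmin(det$ep[i], exp$ep[j]) - pmax(det$sp[i], exp$sp[j])
  })
  best <- 0
  assign_rec <- function(i, used, score, count) {
    if (i > nd) {
      best <<- max(best, count)
      return(invisible())
    }
    assign_rec(i + 1L, used, score, count)          # leave detected i unmatched
    for (j in seq_len(ne)) {
      if (!used[j] && ov[i, j] > 0) {
        used[j] <- TRUE
        assign_rec(i + 1L, used, score + ov[i, j], count + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_rec(1L, rep(FALSE, ne), 0, 0L)
  best
}

# two-sum energy oracle for SKNAER on explicit label masks
brute_sknaer <- function(x, burst_mask, baseline_mask) {
  pb <- sum(x[burst_mask]^2); pn <- sum(x[baseline_mask]^2)
  10 * log10(pb / pn)
}

# fixture: a clean sinusoid recording wrapper
sine_at <- function(freq, fs, dur_s = 1, amp = 1) {
  amp * sin(2 * pi * freq * seq(0, dur_s, by = 1 / fs)[-1])
}
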