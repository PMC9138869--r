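fs <- 8000

test_that("envelope matches the brute-force sliding maximum", {
  set.seed(31)
  for (i in 1:10) {
    x <- abs(rnorm(400))
    k <- floor(ms_to_samples(2, fs) / 2)
    expect_equal(envelope(x, fs, 2), brute_moving_max(x, k))
    expect_equal(integral_signal(x, fs, 1),
                 brute_moving_mean(x, floor(ms_to_samples(1, fs) / 2)))
  }
  # window of one sample is the identity
  x <- abs(rnorm(50))
  expect_equal(moving_max(x, 0L), x)
  expect_equal(moving_mean(x, 0L), x)
})

test_that("envelope dominates the signal and is monotone in window size", {
  set.seed(32)
  x <- abs(rnorm(1000))
  e1 <- envelope(x, fs, 2)
  e2 <- envelope(x, fs, 4)
  expect_true(all(e1 >= x))
  expect_true(all(e2 >= e1))
})

test_that("envelope threshold honours an explicit baseline interval", {
  env <- c(rep(0.5, fs), rep(3, fs))      # quiet first second, active second
  thr <- envelope_threshold(env, fs, baseline_interval = c(0, 1), lambda = 1)
  expect_equal(thr$eth, 0.5)
  expect_equal(thr$skna_max, 0.5)
  thr2 <- envelope_threshold(env, fs, baseline_interval = c(0, 1), lambda = 2)
  expect_equal(thr2$eth, 1.0)
  expect_error(envelope_threshold(env, fs, baseline_interval = c(5, 6)),
               "baseline interval")
  expect_error(envelope_threshold(numeric(100) , fs, baseline_interval = c(0, 0.01)),
               "degenerate")
})

test_that("automatic baseline excludes burst-contaminated windows", {
  set.seed(33)
  env <- abs(rnorm(20 * fs, mean = 5))    # 20 one-second baseline windows
  burst <- (7 * fs + 1):(7 * fs + 3000)   # burst inside window 8
  env[burst] <- 500
  thr <- envelope_threshold(env, fs)
  # the burst window's samples are not used for the threshold
  expect_false(any(burst %in% thr$baseline_samples))
  # the other 19 windows all are: no downward selection bias
  expect_equal(length(thr$baseline_samples), 19 * fs)
  # and the threshold is the clean-region maximum, far below the burst level
  expect_equal(thr$eth, max(env[-(7 * fs + 1):-(8 * fs)]))
  expect_lt(thr$eth, 500)

  # a burst clipping the edge of a window excludes that window too
  env2 <- abs(rnorm(20 * fs, mean = 5))
  env2[(8 * fs - 100):(8 * fs + 3000)] <- 500   # straddles windows 8 and 9
  thr2 <- envelope_threshold(env2, fs)
  expect_equal(length(thr2$baseline_samples), 18 * fs)
  expect_lt(thr2$eth, 500)
})

test_that("candidate detection replays the open/close state machine", {
  # hand-built envelope: rise through threshold, fall below it
  env <- c(0.1, 0.2, 0.9, 1.5, 1.2, 0.8, 0.3, 0.1)
  cand <- detect_candidates(env, eth = 1.0)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$sp, 3L)               # first sample >= eth with d > 0
  expect_equal(cand$ep, 5L)               # first sample < eth with d < 0
  # candidate still open at end of signal closes at n
  env2 <- c(0.1, 0.5, 1.2, 1.4, 1.6)
  cand2 <- detect_candidates(env2, eth = 1.0)
  expect_equal(cand2$sp, 2L)
  expect_equal(cand2$ep, 5L)

  set.seed(34)
  for (i in 1:25) {
    env <- abs(cumsum(rnorm(300)))
    eth <- stats::quantile(env, 0.7)[[1]]
    if (eth <= 0) next
    got <- detect_candidates(env, eth)
    want <- brute_candidates(env, eth)
    expect_equal(got$sp, want$sp)
    expect_equal(got$ep, want$ep)
    # candidates are disjoint and ordered
    if (nrow(got) > 1) expect_true(all(got$sp[-1] > got$ep[-nrow(got)]))
    expect_true(all(got$ep > got$sp))
  }
  expect_error(detect_candidates(env, -1), "positive")
})

test_that("boundary refinement seeks integral minima with conservative ties", {
  # integral with clear minima just outside the rough boundaries
  integ <- rep(1, 100)
  integ[18] <- 0.1     # 0-based 17, within sp - L/10 of sp = 20 (L = 50)
  integ[76] <- 0.1     # 0-based 75, within ep + L/10 of ep = 70
  cand <- data.frame(sp = 20L, ep = 70L, refined = FALSE)
  ref <- refine_boundaries(cand, integ)
  expect_equal(ref$sp, 17L)
  expect_equal(ref$ep, 75L)
  expect_true(ref$refined)

  # ties: earliest for start, latest for end
  integ2 <- rep(1, 100); integ2[16:24] <- 0.2; integ2[66:76] <- 0.2
  ref2 <- refine_boundaries(cand, integ2)
  expect_equal(ref2$sp, 15L)   # earliest tie within [15, 25]
  expect_equal(ref2$ep, 75L)   # latest tie within [65, 75]

  # short candidates (L < 10) have a zero search radius and cannot move
  integ3 <- rep(1, 100); integ3[30] <- 0; integ3[25] <- 0
  cand3 <- data.frame(sp = 25L, ep = 28L, refined = FALSE)
  ref3 <- refine_boundaries(cand3, integ3)
  expect_equal(c(ref3$sp, ref3$ep), c(25L, 28L))

  # overlapping refinements merge into one candidate
  integ4 <- rep(1, 200); integ4[c(40, 121)] <- 0
  cands4 <- data.frame(sp = c(45L, 115L), ep = c(116L, 180L),
                       refined = c(FALSE, FALSE))
  ref4 <- refine_boundaries(cands4, integ4)
  expect_equal(nrow(ref4), 1L)
  expect_lte(ref4$sp, 45L)
  expect_gte(ref4$ep, 180L)
})

test_that("tiling covers [0, n) exactly with baseline gap fill", {
  segs <- data.frame(sp = c(100L, 400L), ep = c(200L, 500L),
                     label = "burst", source = "tke")
  t1 <- tile_segments(segs, 1000L)
  expect_equal(t1$sp[1], 0L)
  expect_equal(t1$ep[nrow(t1)], 1000L)
  expect_equal(t1$sp[-1], t1$ep[-nrow(t1)])
  expect_equal(sum(t1$ep - t1$sp), 1000L)
  expect_equal(t1$label, c("baseline", "burst", "baseline", "burst", "baseline"))

  # segments flush with the edges produce no gap rows there
  t2 <- tile_segments(data.frame(sp = 0L, ep = 1000L, label = "burst",
                                 source = "tke"), 1000L)
  expect_equal(nrow(t2), 1L)

  # empty input tiles to a single baseline run
  t3 <- tile_segments(segs[0, ], 1000L)
  expect_equal(nrow(t3), 1L)
  expect_equal(t3$label, "baseline")
})
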