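fs <- 8000

test_that("R-peak detection recovers simulated beat positions", {
  spec <- sim_spec(duration_s = 20, burst_rate_per_min = 0, seed = 41)
  sim <- skna_simulate(spec)
  ecg <- channel(sim$recording, 1)
  r <- detect_qrs(ecg, fs)
  expect_equal(length(r), length(sim$truth$r_indices))
  tol <- ms_to_samples(20, fs)
  expect_true(all(abs(r - sim$truth$r_indices) <= tol))
  # inverted lead polarity finds the same beats
  r_inv <- detect_qrs(-ecg, fs)
  expect_equal(r_inv, r)
})

test_that("R-peak detection returns empty on structureless input", {
  set.seed(42)
  expect_length(detect_qrs(rnorm(2 * fs), fs), 0L)
  expect_length(detect_qrs(numeric(2 * fs), fs), 0L)
  expect_length(detect_qrs(rnorm(100), fs), 0L)   # shorter than 1 s
})

test_that("delineated widths track the true QRS width and stay in range", {
  widths_for <- function(qw, seed) {
    spec <- sim_spec(duration_s = 20, burst_rate_per_min = 0,
                     qrs_width_ms = qw, seed = seed)
    sim <- skna_simulate(spec)
    ecg <- channel(sim$recording, 1)
    q <- delineate_qrs(ecg, fs, sim$truth$r_indices)
    expect_gt(length(q$widths), 0)
    expect_true(all(q$onsets < q$r_indices & q$r_indices < q$offsets))
    expect_true(all(q$widths >= ms_to_samples(40, fs)))
    expect_true(all(q$widths <= ms_to_samples(200, fs)))
    mean(q$widths) / fs * 1000
  }
  w80 <- suppressMessages(widths_for(80, 43))
  w120 <- suppressMessages(widths_for(120, 44))
  # threshold-based delineation under-covers the Gaussian tails slightly,
  # so the agreement check is loose; monotonicity is the hard requirement
  expect_equal(w80, 80, tolerance = 0.25)
  expect_equal(w120, 120, tolerance = 0.3)
  expect_gt(w120, w80)                       # monotone in true width
})

test_that("delineation drops beats at the record edges with a message", {
  spec <- sim_spec(duration_s = 10, burst_rate_per_min = 0, seed = 45)
  sim <- skna_simulate(spec)
  ecg <- channel(sim$recording, 1)
  r <- c(100L, sim$truth$r_indices)          # a beat inside the edge guard
  expect_message(q <- delineate_qrs(ecg, fs, r), "dropped")
  expect_false(100L %in% q$r_indices)
})

test_that("QRS-width rule relabels narrow bursts containing an R peak", {
  qrs <- structure(list(r_indices = c(1000L, 5000L),
                        onsets = c(800L, 4800L), offsets = c(1400L, 5400L),
                        widths = c(600L, 600L)), class = "qrs_info")
  segs <- data.frame(
    sp = c(0L, 900L, 1200L, 4500L, 5600L),
    ep = c(900L, 1200L, 4500L, 5500L, 8000L),
    label = c("baseline", "burst", "baseline", "burst", "baseline"),
    source = c("gap", "tke", "gap", "tke", "gap"))
  out <- reject_ecg_artifacts(segs, qrs)
  # burst [900, 1200) contains R = 1000 and L = 300 < Wqrs = 600 -> artifact
  expect_equal(out$label[2], "artifact")
  expect_equal(out$source[2], "qrs_width")
  # burst [4500, 5500) contains R = 5000 but L = 1000 >= 600 -> kept
  expect_equal(out$label[4], "burst")
  # geometry untouched: only labels change
  expect_equal(out$sp, segs$sp)
  expect_equal(out$ep, segs$ep)

  # a narrow burst with no contained R peak is untouched by this rule
  segs2 <- segs; segs2$sp[2] <- 2000L; segs2$ep[2] <- 2300L
  segs2 <- segs2[order(segs2$sp), ]
  out2 <- reject_ecg_artifacts(segs2, qrs)
  expect_false("artifact" %in% out2$label[out2$sp == 2000L])

  # literal inequality flips the rule
  out3 <- reject_ecg_artifacts(segs, qrs, invert_qrs_width_rule = TRUE)
  expect_equal(out3$label[2], "burst")
  expect_equal(out3$label[4], "artifact")

  # no ECG: identity with a message
  expect_message(out4 <- reject_ecg_artifacts(segs, NULL), "skipped")
  expect_identical(out4, segs)
})

test_that("minimum-duration rule with and without dilation correction", {
  ts <- ms_to_samples(2, fs)   # 16 samples
  segs <- data.frame(sp = c(0L, 100L, 200L),
                     ep = c(100L, 100L + ts, 200L + ts - 1L),
                     label = c("burst", "burst", "burst"),
                     source = "tke")
  out <- reject_short_bursts(segs, fs)
  expect_equal(out$label, c("burst", "burst", "artifact"))  # exactly Ts kept
  expect_equal(out$source[3], "min_duration")

  # with dilation n - 1: a burst of exactly Ts is now an artifact too
  out2 <- reject_short_bursts(segs, fs, dilation_samples = ts - 1L)
  expect_equal(out2$label, c("burst", "artifact", "artifact"))
  # baselines are never relabelled
  segs$label <- "baseline"
  expect_equal(reject_short_bursts(segs, fs)$label, rep("baseline", 3))
})

test_that("sub-Ts gaps between bursts are closed", {
  ts <- ms_to_samples(2, fs)
  b <- data.frame(sp = c(0L, 100L + ts - 1L, 1000L),
                  ep = c(100L, 500L, 1200L))
  m <- merge_close_bursts(b, fs)
  expect_equal(nrow(m), 2L)
  expect_equal(c(m$sp[1], m$ep[1]), c(0L, 500L))       # gap of ts - 1 closed
  expect_equal(c(m$sp[2], m$ep[2]), c(1000L, 1200L))   # wide gap kept

  # gap of exactly Ts is preserved
  b2 <- data.frame(sp = c(0L, 100L + ts), ep = c(100L, 500L))
  expect_equal(nrow(merge_close_bursts(b2, fs)), 2L)

  # chains merge transitively
  b3 <- data.frame(sp = c(0L, 105L, 210L), ep = c(100L, 205L, 300L))
  m3 <- merge_close_bursts(b3, fs)
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$sp, m3$ep), c(0L, 300L))

  expect_equal(merge_close_bursts(b[0, ], fs), b[0, ])
})
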