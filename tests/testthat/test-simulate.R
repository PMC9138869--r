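test_that("simulation is reproducible and leaves the RNG state alone", {
  spec <- sim_spec(duration_s = 5, seed = 9)
  a <- skna_simulate(spec)
  set.seed(999)
  before <- .Random.seed
  b <- skna_simulate(spec)
  expect_identical(before, .Random.seed)   # caller's RNG state restored
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$bursts, b$truth$bursts)
  # different seed, different recording
  c_ <- skna_simulate(sim_spec(duration_s = 5, seed = 10))
  expect_false(identical(a$recording$samples, c_$recording$samples))
})

test_that("spec validation rejects infeasible settings", {
  expect_error(sim_spec(duration_s = -1), "duration_s")
  expect_error(sim_spec(burst_amplitude_uv = c(0, 10)), "burst_amplitude_uv")
  expect_error(sim_spec(burst_duration_ms = c(600, 200)), "burst_duration_ms")
  expect_error(sim_spec(burst_rate_per_min = 400), "infeasible")
})

test_that("injected bursts have the requested geometry and amplitude", {
  spec <- sim_spec(duration_s = 60, qrs_amplitude_uv = 0,
                   baseline_noise_uv_rms = 0, burst_rate_per_min = 12,
                   burst_amplitude_uv = c(10, 20), seed = 91)
  sim <- skna_simulate(spec)
  tr <- sim$truth$bursts
  expect_gt(nrow(tr), 3)
  # durations within the configured range (allow rounding slack)
  dur_ms <- (tr$ep - tr$sp) / spec$fs * 1000
  expect_true(all(dur_ms >= 199 & dur_ms <= 601))
  # no overlap, 50 ms minimum separation
  expect_true(all(tr$sp[-1] - tr$ep[-nrow(tr)] >= 0.05 * spec$fs - 1))
  # with zero background the burst RMS is close to the drawn amplitude
  x <- channel(sim$recording, 1)
  for (i in seq_len(nrow(tr))) {
    seg <- x[(tr$sp[i] + 1L):tr$ep[i]]
    expect_equal(sqrt(mean(seg^2)), tr$amp[i], tolerance = 0.01)
    expect_true(tr$amp[i] >= 10 && tr$amp[i] <= 20)
  }
  # outside bursts the lead is silent
  mask <- rep(TRUE, length(x))
  for (i in seq_len(nrow(tr))) mask[(tr$sp[i] + 1L):tr$ep[i]] <- FALSE
  expect_equal(max(abs(x[mask])), 0)
})

test_that("burst energy is confined to the nerve band", {
  spec <- sim_spec(duration_s = 10, qrs_amplitude_uv = 0,
                   baseline_noise_uv_rms = 0, burst_rate_per_min = 30,
                   burst_amplitude_uv = c(20, 20), seed = 92)
  sim <- skna_simulate(spec)
  x <- channel(sim$recording, 1)
  pg <- stats::spec.pgram(stats::ts(x, frequency = spec$fs), plot = FALSE,
                          taper = 0)
  band_sum <- function(lo, hi) sum(pg$spec[pg$freq >= lo & pg$freq < hi])
  in_band <- band_sum(500, 1000)
  out_band <- band_sum(0, 450) + band_sum(1100, 4000)
  expect_gt(in_band, 20 * out_band)
})

test_that("ECG beats appear at the stated indices with mV-scale R waves", {
  spec <- sim_spec(duration_s = 20, burst_rate_per_min = 0,
                   baseline_noise_uv_rms = 0, seed = 93)
  sim <- skna_simulate(spec)
  x <- channel(sim$recording, 1)
  r <- sim$truth$r_indices
  expect_gt(length(r), 20)            # ~75 bpm over 19 s
  expect_equal(x[r + 1L], rep(max(x), length(r)), tolerance = 0.02)
  expect_equal(max(x), spec$qrs_amplitude_uv, tolerance = 0.02)
  # stated QRS width accompanies every beat
  expect_length(sim$truth$qrs_width, length(r))
  # rate check: mean RR within the 3% jitter of the nominal value
  rr <- diff(r) / spec$fs
  expect_equal(mean(rr), 60 / spec$heart_rate_bpm, tolerance = 0.02)
})

test_that("optional contaminants are injected and recorded", {
  spec <- sim_spec(duration_s = 10, powerline_hz = 50, powerline_uv = 8,
                   emg_events = 1L, step_artifacts = 1L, seed = 94)
  sim <- skna_simulate(spec)
  expect_equal(nrow(sim$truth$artifacts), 2L)
  expect_setequal(sim$truth$artifacts$type, c("emg", "step"))
  # 50 Hz line is present at the configured amplitude
  x <- channel(sim$recording, 1)
  tt <- seq_along(x) / spec$fs
  amp <- 2 * mean(x * sin(2 * pi * 50 * tt))   # quadrature projection
  expect_equal(amp, 8, tolerance = 0.1)
})

test_that("scenario specs modulate burst rate across epochs", {
  spec <- skna_scenario("stimulation", seed = 95)
  expect_s3_class(spec, "sim_spec")
  sim <- skna_simulate(spec)
  tr <- sim$truth$bursts
  mid_s <- (tr$sp + tr$ep) / 2 / spec$fs
  n_act <- sum(mid_s >= 30 & mid_s < 90)
  n_base <- sum(mid_s < 30)
  # activation epoch: 12.5x the baseline epoch rate over 2x the duration
  expect_gt(n_act, n_base)
  lt <- skna_scenario("longterm", seed = 95)
  expect_equal(lt$duration_s, 240)
  expect_equal(nrow(lt$epochs), 8L)
})
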