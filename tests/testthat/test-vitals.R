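test_that("peak_frequency reads known tones to sub-bin accuracy", {
  fs <- 20; tt <- (0:999) / fs   # 50 s record
  x15 <- slow_time_signal(sin(2 * pi * 1.5 * tt), Ts = 1 / fs)
  expect_lt(abs(peak_frequency(x15, c(0.8, 2.5)) - 1.5), 0.005)
  x267 <- slow_time_signal(sin(2 * pi * 0.267 * tt), Ts = 1 / fs)
  expect_lt(abs(peak_frequency(x267, c(0.1, 0.7)) - 0.267), 0.005)
  # noiseless-tone error bounded well below the native 0.02 Hz grid
  for (f0 in c(0.23, 1.07, 1.91)) {
    x <- sin(2 * pi * f0 * tt + 1.1)
    expect_lt(abs(peak_frequency(x, c(0.1, 2.5), fs = fs) - f0), 0.005)
  }
})

test_that("peak_frequency rejects empty bands and flat signals", {
  x <- slow_time_signal(rep(1, 100), Ts = 0.05)
  expect_error(peak_frequency(x, c(0.1, 0.7)), "no spectral peak")
  tone <- slow_time_signal(sin(2 * pi * 1.5 * (0:99) * 0.05), Ts = 0.05)
  expect_error(peak_frequency(tone, c(0.7, 0.1)), "band")
  expect_error(peak_frequency(tone, c(11, 12)), "band")
})

test_that("classify_modes separates heartbeat from respiratory harmonics", {
  # centres at 0, fr, 2fr, ~4fr, fh: the 1.01 Hz mode is the respiratory 4th
  # harmonic and must be rejected even though it sits in the heartbeat band
  res <- fake_vmd_result(c(0, 0.27, 0.53, 1.01, 1.5))
  cls <- classify_modes(res)
  expect_equal(cls$resp_mode_index, 2L)
  expect_equal(cls$heart_mode_index, 5L)
  expect_equal(cls$rejected_harmonics, 4L)
  expect_false(cls$fallback)
  # no harmonic conflicts
  res2 <- fake_vmd_result(c(0, 0.25, 1.2))
  cls2 <- classify_modes(res2)
  expect_equal(cls2$resp_mode_index, 2L)
  expect_equal(cls2$heart_mode_index, 3L)
  # no candidate in the heartbeat band
  expect_error(classify_modes(fake_vmd_result(c(0, 0.25, 0.5))),
               "heartbeat band .* empty")
  expect_error(classify_modes(fake_vmd_result(c(0, 0.9, 1.5))),
               "respiration band .* empty")
})

test_that("harmonic rejection keeps a non-harmonic candidate when one exists", {
  # both 1.06 (4x0.265) and 1.45 in band; only the harmonic is rejected
  res <- fake_vmd_result(c(0, 0.265, 1.06, 1.45), amps = c(1, 1, 5, 0.5))
  cls <- classify_modes(res)
  expect_equal(cls$heart_mode_index, 4L)
  expect_false(cls$fallback)
  # all candidates harmonic: fallback to the largest peak, flagged
  res2 <- fake_vmd_result(c(0, 0.265, 1.06), amps = c(1, 1, 2))
  cls2 <- classify_modes(res2)
  expect_true(cls2$fallback)
  expect_equal(cls2$heart_mode_index, 3L)
})

test_that("extract_vitals recovers clean rates without SSA", {
  rc <- quick_config(N = 1000L)
  mo <- chest_motion(d0 = 0.6, fr = 0.25, fh = 1.4)
  e <- synthesize_echo(rc, radar_scene(noise_sigma = 0), mo)
  gate <- select_max_gate(clutter_suppress(e))
  v <- extract_vitals(gate$signal, use_ssa = FALSE)
  expect_s3_class(v, "vitals_result")
  expect_equal(v$method_tag, "VMD")
  expect_lt(abs(v$fr_hat - 0.25), 0.01)
  expect_lt(abs(v$fh_hat - 1.4), 0.02)
  v2 <- extract_vitals(gate$signal, use_ssa = TRUE)
  expect_equal(v2$method_tag, "SSA-VMD")
  expect_lt(abs(v2$fh_hat - 1.4), 0.02)
})

test_that("error_report reproduces the published mean errors", {
  t3 <- heart_rate_table("0.6m")
  expect_equal(error_report(t3$standard_hr_hz, t3$ssa_vmd_hz, t3$object)$mae, 0.045)
  expect_equal(error_report(t3$standard_hr_hz, t3$vmd_hz, t3$object)$mae, 0.115)
  t4 <- heart_rate_table("1.2m")
  expect_equal(error_report(t4$standard_hr_hz, t4$ssa_vmd_hz)$mae, 0.041)
  expect_equal(error_report(t4$standard_hr_hz, t4$vmd_hz)$mae, 0.074)
  # identical inputs give zero error
  expect_equal(error_report(c(1.2, 1.5), c(1.2, 1.5))$mae, 0)
  expect_error(error_report(c(1, 2), c(1)), "equal length")
})

test_that("mae is invariant to ordering and global sign flip", {
  std <- c(1.4, 1.25, 1.15); est <- c(1.45, 1.2, 1.18)
  base <- error_report(std, est)$mae
  perm <- sample(3)
  expect_equal(error_report(std[perm], est[perm])$mae, base)
  flipped <- std - (est - std)   # errors negated
  expect_equal(error_report(std, flipped)$mae, base)
})
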