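test_that("chest_distance evaluates the dual-sinusoid motion model", {
  mo <- chest_motion(d0 = 0.6, Ar = 0.004, fr = 0.267, Ah = 3e-4, fh = 1.5)
  # t = 0: both sines vanish
  expect_equal(chest_distance(0, mo), 0.6)
  # quarter respiration period with no heartbeat: d0 + Ar
  mo0 <- chest_motion(d0 = 0.6, Ar = 0.004, fr = 0.267, Ah = 0, fh = 1.5)
  expect_equal(chest_distance(1 / (4 * 0.267), mo0), 0.604)
  # frozen independent scalar evaluation at t = 0.37 s
  expect_equal(chest_distance(0.37, mo), 0.6022248492161715, tolerance = 1e-12)
})

test_that("chest_motion and radar_config reject invalid parameters", {
  expect_error(chest_motion(d0 = 0.005, Ar = 0.004, Ah = 0.002), "smaller than d0")
  expect_error(chest_motion(d0 = -1), "d0")
  expect_error(radar_config(delta_T = 1 / 10e9, fc = 7.29e9), "Nyquist")
})

test_that("pulse waveform decays, integrates to zero, oscillates at fc", {
  rc <- radar_config()
  tau <- seq(-8, 8, length.out = 4096) * rc$pulse_sigma
  w <- pulse_waveform(tau, rc)
  peak <- max(abs(w))
  expect_lt(abs(pulse_waveform(6 * rc$pulse_sigma, rc)), 1e-6 * peak)
  expect_lt(abs(pulse_waveform(-6 * rc$pulse_sigma, rc)), 1e-6 * peak)
  # odd-symmetric derivative pulse integrates to ~0 over its support
  expect_lt(abs(sum(w) * (tau[2] - tau[1])), 1e-9 * peak * rc$pulse_sigma)
  # dominant oscillation: spacing of successive maxima near the centre = 1/fc
  tt <- seq(-3 * rc$pulse_sigma, 3 * rc$pulse_sigma, by = rc$delta_T / 4)
  ww <- pulse_waveform(tt, rc)
  pk <- which(diff(sign(diff(ww))) == -2) + 1
  spacing <- diff(tt[pk])
  # envelope modulation perturbs the outermost extrema; the typical spacing
  # is the carrier period
  expect_lt(abs(stats::median(spacing) - 1 / rc$fc), 0.1 / rc$fc)
  # spectral peak sits at fc plus the derivative-envelope skew 1/(2*pi*sigma),
  # i.e. within two unpadded bins of fc
  ts2 <- seq(-6 * rc$pulse_sigma, 6 * rc$pulse_sigma, by = rc$delta_T)
  ws <- pulse_waveform(ts2, rc)
  mag <- Mod(stats::fft(ws))[1:(length(ws) %/% 2)]
  fgrid <- (0:(length(ws) %/% 2 - 1)) / (length(ws) * rc$delta_T)
  bin <- fgrid[2] - fgrid[1]
  expect_lt(abs(fgrid[which.max(mag)] - rc$fc), 2 * bin)
})

test_that("synthesize_echo handles static and empty scenes", {
  rc <- quick_config(N = 50L)
  # frozen chest, no noise: every slow-time column identical
  mo <- chest_motion(d0 = 0.5, Ar = 0, fr = 0.25, Ah = 0, fh = 1.5)
  e <- synthesize_echo(rc, radar_scene(noise_sigma = 0), mo)
  expect_true(all(e$values == e$values[, 1]))
  # nothing reflecting: all-zero matrix
  e0 <- synthesize_echo(rc, radar_scene(av = 0, statics = list(),
                                        dc_offset = 0, noise_sigma = 0), mo)
  expect_true(all(e0$values == 0))
})

test_that("chest return is centred at the round-trip-delay row", {
  rc <- quick_config(N = 20L)
  mo <- chest_motion(d0 = 0.6)
  # 2 * 0.6 / c = 4.00 ns
  expect_equal(2 * 0.6 / C_LIGHT, 4.003e-9, tolerance = 1e-3)
  e <- chest_only_echo(rc, mo)
  col1 <- e$values[, 1]^2
  centroid <- sum(seq_along(col1) * col1) / sum(col1)
  expect_lt(abs(centroid - (2 * 0.6 / C_LIGHT / rc$delta_T + 1)), 2)
})

test_that("echo synthesis is reproducible and linear in the scene", {
  rc <- quick_config(N = 40L)
  mo <- chest_motion(fr = 0.3, fh = 1.2)
  sc <- radar_scene(noise_sigma = 0.05)
  e1 <- synthesize_echo(rc, sc, mo, seed = 11)
  e2 <- synthesize_echo(rc, sc, mo, seed = 11)
  expect_identical(e1$values, e2$values)
  e3 <- synthesize_echo(rc, sc, mo, seed = 12)
  expect_false(identical(e1$values, e3$values))
  # noiseless superposition: chest + statics == chest alone + statics alone
  sc_all <- radar_scene(av = 1, statics = list(c(0.2, 0.8), c(0.35, 1.1)),
                        dc_offset = 0, noise_sigma = 0)
  sc_chest <- radar_scene(av = 1, statics = list(), dc_offset = 0, noise_sigma = 0)
  sc_stat <- radar_scene(av = 0, statics = list(c(0.2, 0.8), c(0.35, 1.1)),
                         dc_offset = 0, noise_sigma = 0)
  both <- synthesize_echo(rc, sc_all, mo)$values
  parts <- synthesize_echo(rc, sc_chest, mo)$values +
    synthesize_echo(rc, sc_stat, mo)$values
  expect_equal(both, parts, tolerance = 1e-12)
})

test_that("scene ranges outside the fast-time window are rejected", {
  rc <- quick_config(N = 20L)  # window ~0.77 m
  expect_error(synthesize_echo(rc, radar_scene(statics = list(c(1.4, 1))),
                               chest_motion()), "exceeds")
  expect_error(synthesize_echo(rc, radar_scene(statics = list()),
                               chest_motion(d0 = 1.2)), "exceeds")
})

test_that("snr_to_noise_sigma scales with the requested SNR", {
  rc <- quick_config(N = 200L)
  mo <- chest_motion(fr = 0.25, fh = 1.4)
  s0 <- snr_to_noise_sigma(0, rc, mo)
  s10 <- snr_to_noise_sigma(10, rc, mo)
  expect_gt(s0, 0)
  expect_equal(s0 / s10, sqrt(10), tolerance = 1e-10)
  # 0 dB: noise power equals the mean-removed chest power at the liveliest gate
  chest <- chest_only_echo(rc, mo)$values
  ac <- chest - rowMeans(chest)
  expect_equal(s0^2, max(rowMeans(ac^2)), tolerance = 1e-12)
})

test_that("echo matrices round-trip through CSV + sidecar and RDS", {
  rc <- quick_config(N = 25L)
  mo <- chest_motion(fr = 0.3, fh = 1.3)
  e <- synthesize_echo(rc, radar_scene(noise_sigma = 0.02), mo, seed = 4)
  csv <- tempfile(fileext = ".csv")
  write_echo_csv(e, csv)
  back <- read_echo_csv(csv)
  expect_equal(back$values, e$values, tolerance = 1e-12)
  expect_equal(back$Ts, e$Ts)
  expect_equal(back$motion$fh, mo$fh)
  rds <- tempfile(fileext = ".rds")
  write_echo_rds(e, rds)
  expect_equal(read_echo_rds(rds)$values, e$values)
  unlink(c(csv, paste0(csv, ".json"), rds))
})

test_that("range_axis maps rows to one-way range", {
  rc <- quick_config(N = 20L)
  e <- chest_only_echo(rc, chest_motion(d0 = 0.5))
  ax <- range_axis(e)
  expect_equal(ax[1], 0)
  expect_equal(diff(ax)[1], rc$delta_T * C_LIGHT / 2)
  expect_length(ax, rc$M)
})
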