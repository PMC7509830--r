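test_that("default ground truths encode the intended tuning structure", {
  for (task in c("vernier", "letter")) {
    gt <- default_ground_truth(task, the_montage)
    expect_equal(sqrt(sum(gt$source1$topography^2)), 1)
    expect_equal(sqrt(sum(gt$source2$topography^2)), 1)
    # lag consistency: lag_ms = dphase / (360 * 3) * 1000
    dphase <- (gt$source2$phase_1f_deg - gt$source1$phase_1f_deg) %% 360
    expect_equal(dphase / (360 * 3) * 1000, gt$lag_ms)
    expect_true(all(gt$source1$amp_1f >= 0 & gt$source2$amp_1f >= 0))
  }
  gl <- default_ground_truth("letter", the_montage)
  # letter source 2 peaks at the level nearest 0.6 logMAR (level 3)
  expect_identical(which.max(gl$source2$amp_1f), 3L)
  expect_identical(which.min(abs(gl$levels - 0.6)), 3L)
  # letter source 1 saturating and monotone
  expect_true(all(diff(gl$source1$amp_1f) > 0))
  gv <- default_ground_truth("vernier", the_montage)
  expect_equal(gv$lag_ms, rep(90, 5))
  # letter source-1 topography peaks over left-lateral electrodes 65/66,
  # vernier source-1 over the occipital pole electrode 75
  expect_true(which.max(gl$source1$topography) %in% c(65L, 66L))
  expect_identical(which.max(gv$source1$topography), 75L)
  expect_error(default_ground_truth("audio"), "arg")
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- small_session(trial_s = 3, seed = 9,
                     noise = noise_spec(noise_rms_uv = 3, blink_rate_hz = 0.1))
  b <- small_session(trial_s = 3, seed = 9,
                     noise = noise_spec(noise_rms_uv = 3, blink_rate_hz = 0.1))
  expect_identical(a$data, b$data)
  expect_identical(a$blinks, b$blinks)
  c <- small_session(trial_s = 3, seed = 10,
                     noise = noise_spec(noise_rms_uv = 3, blink_rate_hz = 0.1))
  expect_false(identical(a$data, c$data))
})

test_that("noiseless simulation inverts exactly through the spectral stage", {
  raw <- small_session(trial_s = 3, noise = quiet_noise())
  gt <- list(vernier = default_ground_truth("vernier", the_montage),
             letter = default_ground_truth("letter", the_montage))
  ct <- raw$condition_table
  for (i in c(1, 4, 7)) {  # a few trials across tasks
    ev <- raw$events[i, ]
    cond <- ct[ct$condition == ev$condition, ]
    g <- gt[[cond$task]]
    lev <- cond$level
    idx <- ev$onset + seq_len(round(ev$duration_s * raw$fs))
    eps <- epoch_trial(raw$data[, idx], raw$fs)
    d <- dft_epoch(eps[[1]], raw$fs)
    for (h in 1:2) {
      ib <- which(abs(d$freqs - 3 * h) < 1e-9)
      z <- d$coeffs[, ib]
      amp <- if (h == 1) {
        list(g$source1$amp_1f[lev], g$source2$amp_1f[lev])
      } else {
        list(g$source1$amp_2f[lev], g$source2$amp_2f[lev])
      }
      ph <- if (h == 1) {
        list(g$source1$phase_1f_deg[lev], g$source2$phase_1f_deg[lev])
      } else {
        list(g$source1$phase_2f_deg[lev], g$source2$phase_2f_deg[lev])
      }
      expected <- g$source1$topography * amp[[1]] * exp(-1i * ph[[1]] * pi / 180) +
                  g$source2$topography * amp[[2]] * exp(-1i * ph[[2]] * pi / 180)
      expect_lt(max(Mod(z - expected)), 1e-10)
    }
    # leakage at non-harmonic bins below -100 dB on whole-cycle windows
    harm <- d$freqs %in% c(3, 6)
    off_amp <- max(Mod(d$coeffs[, !harm & d$freqs > 0]))
    peak <- max(Mod(d$coeffs[, harm]))
    expect_lt(20 * log10(off_amp / peak), -100)
  }
})

test_that("pink background noise has the configured 1/f slope", {
  raw <- small_session(trial_s = 6, seed = 21,
                       noise = noise_spec(noise_rms_uv = 5, blink_rate_hz = 0,
                                          amp_jitter = 0))
  # estimate the PSD slope from signal-free channels (frontal, far from
  # the posterior sources): average periodogram over channels 1..20
  n <- ncol(raw$data)
  freqs <- (seq_len(n %/% 2) - 1) * raw$fs / n
  keep <- freqs >= 1 & freqs <= 40
  psd <- rowMeans(vapply(1:20, function(ch) {
    p <- Mod(stats::fft(raw$data[ch, ]))^2 / n
    p[seq_len(n %/% 2)]
  }, numeric(n %/% 2)))
  fit <- stats::lm(log10(psd[keep]) ~ log10(freqs[keep]))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.15)
})

test_that("doubling noise RMS doubles the neighbor-bin noise estimate", {
  # per-channel RMS standardization makes the scaling exact per seed;
  # check across several seeds on the coherent-average noise floor
  ratios <- vapply(1:5, function(s) {
    r1 <- small_session(trial_s = 3, seed = s,
                        noise = noise_spec(noise_rms_uv = 2, blink_rate_hz = 0,
                                           amp_jitter = 0))
    r2 <- small_session(trial_s = 3, seed = s,
                        noise = noise_spec(noise_rms_uv = 4, blink_rate_hz = 0,
                                           amp_jitter = 0))
    f <- function(raw) {
      idx <- raw$events$onset[1] + seq_len(3 * raw$fs)
      d <- dft_epoch(epoch_trial(raw$data[, idx], raw$fs)[[1]], raw$fs)
      mean(Mod(d$coeffs[, which(abs(d$freqs - 2.5) < 1e-9)]))
    }
    f(r2) / f(r1)
  }, numeric(1))
  expect_equal(ratios, rep(2, 5), tolerance = 1e-6)
})

test_that("blinks are frontal-weighted transients recorded in the session", {
  raw <- small_session(trial_s = 3, seed = 33,
                       noise = noise_spec(noise_rms_uv = 0, blink_rate_hz = 0.3,
                                          amp_jitter = 0))
  expect_gt(nrow(raw$blinks), 0)
  # at a blink peak, frontal (nose +y) channels dominate posterior ones
  pos <- montage_positions(the_montage)
  b <- raw$blinks$onset[1] + round(0.2 * raw$fs)
  v <- raw$data[, b]
  expect_gt(mean(abs(v[pos[, 2] > 0.7])), 10 * mean(abs(v[pos[, 2] < -0.7])))
})
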