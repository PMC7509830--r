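config <- analysis_config()

test_that("resampling 500 -> 420 Hz preserves counts, events and sinusoids", {
  raw <- small_session(trial_s = 3, noise = quiet_noise())
  rs <- resample_session(raw, 420)
  expect_equal(rs$fs, 420)
  expect_identical(ncol(rs$data), as.integer(ncol(raw$data) * 420 / 500))
  expect_equal(rs$fs / 3, 140)  # samples per stimulus cycle
  expect_equal(rs$events$onset, round(raw$events$onset * 420 / 500))

  # analytic sinusoid oracle: amplitude preserved to well under 0.1%
  n <- 500 * 12
  x <- 2.5 * cos(2 * pi * 3 * (0:(n - 1)) / 500 - 0.4)
  sess <- raw_session(matrix(rep(x, each = 128), 128), 500,
                      raw$events[1, ], raw$condition_table)
  out <- resample_session(sess, 420)
  d <- dft_epoch(out$data[1, 1:840, drop = FALSE], 420)
  ib <- which(abs(d$freqs - 3) < 1e-9)
  expect_equal(Mod(d$coeffs[1, ib]), 2.5, tolerance = 1e-6)
  expect_equal(Arg(d$coeffs[1, ib]), -0.4, tolerance = 1e-6)

  # identity when already at the target rate
  same <- resample_session(raw, 500, stim_freq_hz = 2.5)
  expect_identical(same$data, raw$data)
  expect_error(resample_session(raw, 421), "samples per stimulus cycle")
})

test_that("band-pass is transparent at the harmonics and kills DC/stopband", {
  fs <- 420
  n <- fs * 20
  t <- (0:(n - 1)) / fs
  mk <- function(x) {
    ev <- tibble::tibble(trial = 1, block = 1, condition = 1, onset = 0,
                         duration_s = 2)
    ct <- tibble::tibble(condition = 1, task = "vernier", logmar = 0.15,
                         level = 1)
    s <- raw_session(matrix(rep(x, each = 128), 128), fs, ev, ct,
                     stages = "resample")
    bandpass_session(s)
  }
  mid <- (n %/% 4):(3 * n %/% 4)
  amp_mid <- function(y, f) {
    2 * Mod(sum(y[mid] * exp(-2i * pi * f * t[mid]))) / length(mid)
  }
  y3 <- mk(cos(2 * pi * 3 * t))$data[1, ]
  expect_gt(amp_mid(y3, 3), 0.99)
  expect_lt(amp_mid(y3, 3), 1.01)
  y6 <- mk(cos(2 * pi * 6 * t))$data[1, ]
  expect_gt(amp_mid(y6, 6), 0.99)
  y100 <- mk(cos(2 * pi * 100 * t))$data[1, ]
  expect_lt(amp_mid(y100, 100), 0.05)
  ydc <- mk(rep(10, n))$data[1, ]
  expect_lt(max(abs(ydc[mid])), 0.5)  # DC removed (high-pass)
  expect_error(mk_err <- bandpass_session(
    raw_session(matrix(0, 128, 100), 100,
                tibble::tibble(trial = 1, block = 1, condition = 1,
                               onset = 0, duration_s = 0.5),
                tibble::tibble(condition = 1, task = "letter", logmar = 0.2),
                stages = "resample"), lo = 60, hi = 45), "band edges")
})

test_that("bad channels are replaced by the mean of 6 nearest good sensors", {
  raw <- small_session(trial_s = 3, noise = noise_spec(noise_rms_uv = 5,
                                                       blink_rate_hz = 0))
  s <- resample_session(raw, 420)
  s <- bandpass_session(s)
  bad <- c(40L, 75L)
  out <- replace_bad_channels(s, bad, the_montage)
  expect_identical(out$report$replaced_channels, bad)
  for (ch in bad) {
    nb <- nearest_sensors(the_montage, ch, k = 6, exclude = bad)
    expect_equal(out$session$data[ch, ],
                 colMeans(s$data[nb, ]))  # direct row-mean oracle
  }
  # untouched channels identical; empty bad list is identity
  good <- setdiff(1:128, bad)
  expect_identical(out$session$data[good, ], s$data[good, ])
  expect_identical(replace_bad_channels(s, integer(0))$session$data, s$data)
  expect_error(replace_bad_channels(s, 1:40), "25%")
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  raw <- small_session(trial_s = 3, noise = noise_spec(noise_rms_uv = 5,
                                                       blink_rate_hz = 0))
  s <- preprocess_chain(raw)
  expect_lt(max(abs(colMeans(s$data))), 1e-10)
  # bipolar differences unchanged by re-referencing
  pre <- replace_bad_channels(bandpass_session(resample_session(raw, 420)),
                              integer(0))$session
  expect_equal(s$data[10, ] - s$data[90, ], pre$data[10, ] - pre$data[90, ])
  # idempotence
  s2 <- s
  s2$stages <- s2$stages[-4]
  expect_equal(rereference_average(s2)$data, s$data)
})

test_that("epoch rejection counts time samples where any channel exceeds threshold", {
  eps <- list(matrix(0, 128, 840), matrix(0, 128, 840))
  rep0 <- reject_epochs(eps, threshold_uv = 60)
  expect_length(rep0$rejected_epochs, 0)
  expect_identical(rep0$rejection_fraction, 0)

  # 500 uV blink on a few frontal channels spanning 20% of samples
  eps[[2]][1:10, 1:168] <- 500
  rep1 <- reject_epochs(eps, threshold_uv = 60, max_bad_fraction = 0.1)
  expect_identical(rep1$rejected_epochs, 2L)
  expect_identical(rep1$rejection_fraction, 0.5)
  expect_identical(rep1$threshold_uv, 60)

  # fraction counts samples, not channel-sample pairs: 8% of samples over
  # threshold on one channel must NOT reject at the 10% cutoff
  eps[[2]] <- matrix(0, 128, 840)
  eps[[2]][5, 1:67] <- 500
  expect_length(reject_epochs(eps, 60, max_bad_fraction = 0.1)$rejected_epochs, 0)
})

test_that("preprocessing stages out of order raise informative errors", {
  raw <- small_session(trial_s = 3, noise = quiet_noise())
  expect_error(bandpass_session(raw), "out of order")
  expect_error(rereference_average(raw), "out of order")
  s <- resample_session(raw, 420)
  expect_error(resample_session(s, 420), "already applied")
  expect_error(replace_bad_channels(s, integer(0)), "out of order")
  s <- bandpass_session(s)
  expect_error(rereference_average(s), "out of order")
  # spectra require the full chain
  expect_error(session_spectra(s), "preprocessed")
})

test_that("trial-level rejection drops whole trials overlapping blinks", {
  raw <- small_session(trial_s = 12, seed = 7,
                       noise = noise_spec(noise_rms_uv = 1, blink_rate_hz = 0.06))
  s <- preprocess_chain(raw)
  sp_trial <- session_spectra(s, reject = "trial")
  sp_epoch <- session_spectra(s, reject = "epoch")
  frac <- sp_trial$report$rejection_fraction
  expect_gt(frac, 0)
  expect_lt(frac, 0.5)
  # trial-level drops complete trials: surviving trials keep all 5 epochs
  kept <- table(sp_trial$epochs$trial)
  expect_true(all(kept == 5))
  # epoch-level rejections target epochs overlapping injected blinks
  rej <- sp_epoch$report$rejected_epochs
  expect_gt(nrow(rej), 0)
  blink_windows <- cbind(raw$blinks$onset * 420 / 500,
                         raw$blinks$onset * 420 / 500 +
                           raw$blinks$duration_s * 420)
  overlaps <- vapply(seq_len(nrow(rej)), function(i) {
    ev <- s$events[s$events$trial == rej$trial[i], ]
    a <- ev$onset + 420 + (rej$epoch_in_trial[i] - 1) * 840
    b <- a + 840
    any(blink_windows[, 2] > a & blink_windows[, 1] < b)
  }, logical(1))
  expect_gte(mean(overlaps), 0.9)
})
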