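# Shared fixtures: the montage is loaded once; small sessions and direct
# RCA inputs are built in code at test time.

the_montage <- load_montage()

# a small 10-condition session: 1 block x 1 trial/condition, short trials
small_session <- function(trial_s = 3, noise = noise_spec(),
                          seed = 42, fs = 500) {
  sched <- build_schedule(n_blocks = 1, per_block_per_cond = 1,
                          trial_s = trial_s, seed = seed)
  gt <- list(vernier = default_ground_truth("vernier", the_montage),
             letter = default_ground_truth("letter", the_montage))
  simulate_session(sched, gt, noise, fs = fs, seed = seed,
                   montage = the_montage)
}

quiet_noise <- function(...) {
  noise_spec(noise_rms_uv = 0, blink_rate_hz = 0, amp_jitter = 0, ...)
}

# run the enforced preprocessing chain without bad channels
preprocess_chain <- function(session, config = analysis_config()) {
  s <- resample_session(session, config$resample_hz, config$stim_freq_hz)
  s <- bandpass_session(s, config$bandpass_hz[1], config$bandpass_hz[2])
  s <- replace_bad_channels(s, integer(0), the_montage)$session
  rereference_average(s)
}

# direct RCA input: two fixed sources + white complex sensor noise,
# n_trials spread over 5 levels, eppt epochs per trial
make_direct_input <- function(noise_sd, n_trials = 80, eppt = 5,
                              task = "vernier", seed = 1,
                              single_source = FALSE) {
  gt <- default_ground_truth(task, the_montage)
  t1 <- gt$source1$topography
  t2 <- gt$source2$topography
  n_ep <- n_trials * eppt
  obs <- matrix(0, 2 * n_ep, 128)
  trial <- integer(2 * n_ep)
  condv <- integer(2 * n_ep)
  withr::with_seed(seed, {
    k <- 0
    for (tr in seq_len(n_trials)) {
      lev <- ((tr - 1) %% 5) + 1
      z_sig <- t1 * gt$source1$amp_1f[lev] *
        exp(-1i * gt$source1$phase_1f_deg[lev] * pi / 180)
      if (!single_source) {
        z_sig <- z_sig + t2 * gt$source2$amp_1f[lev] *
          exp(-1i * gt$source2$phase_1f_deg[lev] * pi / 180)
      }
      for (e in seq_len(eppt)) {
        z <- z_sig + complex(real = rnorm(128, 0, noise_sd),
                             imaginary = rnorm(128, 0, noise_sd))
        k <- k + 1
        obs[2 * k - 1, ] <- Re(z)
        obs[2 * k, ] <- Im(z)
        trial[2 * k - 1:0] <- tr
        condv[2 * k - 1:0] <- lev
      }
    }
  })
  as_rca_input(obs, trial, condition = condv,
               part = rep(c("re", "im"), n_ep))
}
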