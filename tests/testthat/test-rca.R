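test_that("cross-trial covariances match a brute-force pair sum (3 trials)", {
  withr::with_seed(4, {
    # 3 trials of one condition, 2 epochs each, 6 channels
    obs <- matrix(rnorm(3 * 2 * 2 * 6), ncol = 6)
    trial <- rep(1:3, each = 4)
    part <- rep(c("re", "im"), 6)
    inp <- as_rca_input(obs, trial, condition = rep(1, 12), part = part)
    cv <- cross_trial_covariances(inp)

    # oracle: center per part, collapse each trial x part to its mean,
    # then average the symmetrized cross-products over unordered pairs
    x <- obs
    for (p in c("re", "im")) {
      rows <- part == p
      x[rows, ] <- sweep(obs[rows, , drop = FALSE], 2,
                         colMeans(obs[rows, , drop = FALSE]))
    }
    tm <- function(tr) rbind(colMeans(x[trial == tr & part == "re", ]),
                             colMeans(x[trial == tr & part == "im", ]))
    pair <- function(i, j) {
      cij <- crossprod(tm(i), tm(j))
      (cij + t(cij)) / (2 * 2)
    }
    rb_oracle <- (pair(1, 2) + pair(1, 3) + pair(2, 3)) / 3
    expect_equal(cv$R_between, rb_oracle, tolerance = 1e-12)
    expect_equal(cv$R_within, crossprod(x) / nrow(x), tolerance = 1e-12)
    expect_identical(cv$n_pairs, 3L)
    expect_equal(cv$R_between, t(cv$R_between))
    expect_true(min(eigen(cv$R_within, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-12)
  })
})

test_that("identical trials give R_between = R_within; noise gives ~zero", {
  withr::with_seed(5, {
    base <- matrix(rnorm(10 * 16), ncol = 16)
    obs <- do.call(rbind, replicate(4, base, simplify = FALSE))
    inp <- as_rca_input(obs, rep(1:4, each = 10), condition = rep(1, 40))
    cv <- cross_trial_covariances(inp)
    # all trials identical: after grand-mean centering every trial mean is
    # zero, so the cross-trial covariance vanishes exactly (the reliable
    # structure lives entirely in the removed grand mean)
    expect_lt(max(abs(cv$R_between)), 1e-12)

    # two conditions with distinct identical-within-condition responses:
    # R_between equals the average outer product of the centered
    # condition-mean observations - the perfectly reliable structure
    base2 <- matrix(rnorm(10 * 16), ncol = 16)
    obs2 <- rbind(obs, do.call(rbind, replicate(4, base2, simplify = FALSE)))
    inp2 <- as_rca_input(obs2, rep(1:8, each = 10),
                         condition = rep(1:2, each = 40))
    cv2 <- cross_trial_covariances(inp2)
    grand <- colMeans(obs2)
    m1 <- colMeans(base) - grand
    m2 <- colMeans(base2) - grand
    expect_equal(cv2$R_between, (tcrossprod(m1) + tcrossprod(m2)) / 2,
                 tolerance = 1e-12)
    # independent white-noise trials: between-trial covariance vanishes
    obs_n <- matrix(rnorm(200 * 5 * 16), ncol = 16)
    inp_n <- as_rca_input(obs_n, rep(1:200, each = 5),
                          condition = rep(1, 1000))
    cv_n <- cross_trial_covariances(inp_n)
    expect_lt(norm(cv_n$R_between, "F") / norm(cv_n$R_within, "F"), 0.1)
  })
})

test_that("single-source input is recovered almost perfectly", {
  inp <- make_direct_input(noise_sd = 0.05, single_source = TRUE, seed = 2)
  fit <- fit_rca(inp, n_components = 2)
  gt <- default_ground_truth("vernier", the_montage)
  expect_gt(abs(stats::cor(fit$A[, 1], gt$source1$topography)), 0.99)
  expect_gt(fit$eigvals[1], 5 * fit$eigvals[2])
})

test_that("two orthogonal-topography sources are recovered after matching", {
  inp <- make_direct_input(noise_sd = 0.15, seed = 3)
  fit <- fit_rca(inp, n_components = 2)
  gt <- default_ground_truth("vernier", the_montage)
  mm <- match_components(fit, cbind(gt$source1$topography,
                                    gt$source2$topography))
  expect_identical(sort(mm$source), 1:2)
  expect_true(all(abs(mm$r) >= 0.95))
})

test_that("RCA is equivariant under channel permutation and scale invariant", {
  inp <- make_direct_input(noise_sd = 0.3, n_trials = 40, seed = 6)
  fit <- fit_rca(inp, 2)
  perm <- withr::with_seed(1, sample(128))
  inp_p <- inp
  inp_p$obs <- inp$obs[, perm]
  fit_p <- fit_rca(inp_p, 2)
  expect_equal(abs(fit_p$A), abs(fit$A[perm, ]), tolerance = 1e-6)
  # scale invariance: directions and reliability spectrum unchanged
  inp_s <- inp
  inp_s$obs <- inp$obs * 7.3
  fit_s <- fit_rca(inp_s, 2)
  expect_equal(fit_s$eigvals, fit$eigvals, tolerance = 1e-9)
  expect_equal(abs(stats::cor(fit_s$A[, 1], fit$A[, 1])), 1, tolerance = 1e-9)
  expect_equal(fit_s$reliability_fraction, fit$reliability_fraction,
               tolerance = 1e-9)
})

test_that("the generalized eigenproblem is solved on the reduced subspace", {
  inp <- make_direct_input(noise_sd = 0.3, n_trials = 40, seed = 7)
  fit <- fit_rca(inp, 2)
  cv <- cross_trial_covariances(inp)
  v <- fit$basis
  lhs <- t(v) %*% cv$R_between %*% fit$W
  rhs <- t(v) %*% cv$R_within %*% fit$W %*% diag(fit$eigvals[1:2])
  expect_lt(norm(lhs - rhs, "F") / norm(lhs, "F"), 1e-8)
  expect_true(all(diff(fit$eigvals) <= 1e-12))  # descending
  # sign convention: each topography's largest-|value| entry positive
  for (j in 1:2) expect_gt(fit$A[which.max(abs(fit$A[, j])), j], 0)
  expect_equal(sqrt(colSums(fit$A^2)), c(1, 1), tolerance = 1e-12)
})

test_that("projection through filters behaves like the matched filter it is", {
  # selector filter: identity column picks out one channel's response
  inp <- make_direct_input(noise_sd = 0.2, n_trials = 20, seed = 8)
  fit <- fit_rca(inp, 2)
  raw <- small_session(trial_s = 3, noise = quiet_noise())
  s <- preprocess_chain(raw)
  sp <- session_spectra(s)
  ca <- coherent_average(sp, "1F")
  sel <- fit
  sel$W <- matrix(0, 128, 1)
  sel$W[75, 1] <- 1
  pr <- rc_project(sel, ca[ca$condition == 1, ])
  ch75 <- ca[ca$condition == 1 & ca$channel == 75, ]
  expect_equal(pr$coeff, ch75$coeff)
  expect_equal(pr$amp, ch75$amp)

  # amplitude invariant under a global phase rotation of the input
  rot <- ca[ca$condition == 1, ]
  rot$coeff <- rot$coeff * exp(0.7i)
  rot$noise_coeff_lo <- rot$noise_coeff_lo * exp(0.7i)
  rot$noise_coeff_hi <- rot$noise_coeff_hi * exp(0.7i)
  expect_equal(rc_project(fit, rot)$amp,
               rc_project(fit, ca[ca$condition == 1, ])$amp)
  expect_error(rc_project(fit, ca[ca$channel < 100, ]), "mismatch")
})

test_that("a ground-truth-aligned filter beats the best single channel SNR", {
  gt <- default_ground_truth("vernier", the_montage)
  wins <- vapply(1:20, function(s) {
    withr::with_seed(s + 500, {
      z_sig <- gt$source1$topography * 1.5
      n_ep <- 40
      zz <- matrix(complex(real = rnorm(n_ep * 128, 0, 1.2),
                           imaginary = rnorm(n_ep * 128, 0, 1.2)),
                   n_ep) + matrix(z_sig, n_ep, 128, byrow = TRUE)
      nz1 <- matrix(complex(real = rnorm(n_ep * 128, 0, 1.2),
                            imaginary = rnorm(n_ep * 128, 0, 1.2)), n_ep)
      w <- gt$source1$topography
      snr_filter <- snr_db(Mod(mean(zz %*% w)), Mod(mean(nz1 %*% w)))
      ch <- which.max(abs(w))
      snr_chan <- snr_db(Mod(mean(zz[, ch])), Mod(mean(nz1[, ch])))
      snr_filter >= snr_chan
    })
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("reliability_explained normalizes over positive eigenvalues", {
  # two reliable sources with weak residual structure: many trials and a
  # moderate subspace keep the estimation bulk small
  inp <- make_direct_input(noise_sd = 0.2, n_trials = 200, eppt = 2, seed = 9)
  fit <- fit_rca(inp, 2, rank = 12)
  expect_equal(reliability_explained(fit, k = length(fit$eigvals)), 1)
  expect_gte(reliability_explained(fit, 2), 0.9)  # two-source input
  # rank-1 reliable structure: k = 1 captures ~everything
  inp1 <- make_direct_input(noise_sd = 0.1, n_trials = 200, eppt = 2,
                            single_source = TRUE, seed = 10)
  fit1 <- fit_rca(inp1, 2, rank = 12)
  expect_gte(reliability_explained(fit1, 1), 0.9)
  broken <- fit
  broken$eigvals <- c(-1, -2)
  expect_warning(out <- reliability_explained(broken, 1), "undefined")
  expect_true(is.na(out))
})

test_that("phase-randomized input shows no reliability beyond the permutation null", {
  inp <- make_direct_input(noise_sd = 0.5, n_trials = 40, seed = 11)
  null_inp <- phase_randomize_epochs(inp, seed = 12)
  fit <- fit_rca(null_inp, 1)
  null_dist <- rca_permutation_null(null_inp, n_perm = 100, seed = 13)
  expect_lte(fit$eigvals[1], stats::quantile(null_dist, 0.95))
  # while the intact input's reliability exceeds the no-phase-locking null
  # (a within-condition permutation of the intact input preserves its
  # condition-locked means, so the randomized input provides the null)
  fit_sig <- fit_rca(inp, 1)
  expect_gt(fit_sig$eigvals[1], stats::quantile(null_dist, 0.95) * 1.5)
})

test_that("tidy and glance summarize an rca_model", {
  skip_if_not_installed("broom")
  fit <- fit_rca(make_direct_input(0.3, n_trials = 20, seed = 15), 2)
  td <- broom::tidy(fit)
  expect_identical(nrow(td), length(fit$eigvals))
  expect_equal(sum(td$reliability_fraction), 1)
  gl <- broom::glance(fit)
  expect_identical(gl$n_components, 2L)
  expect_identical(gl$harmonic, "1F")
})
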