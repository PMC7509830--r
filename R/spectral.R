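# Bin-centered Fourier analysis: epoching, DFT with single-sided ASD
# scaling, coherent (complex) averaging, neighbor-bin noise estimates.

#' Split one trial into analysis epochs
#'
#' Discards the first `discard_s` seconds (steady-state settling), then
#' tiles the remainder with non-overlapping epochs of `epoch_s` seconds;
#' a partial tail is dropped. A 12-s trial yields 5 epochs with the
#' defaults.
#'
#' @param trial_data Channels x samples matrix for one trial.
#' @param fs Sampling rate (Hz).
#' @param discard_s Seconds discarded at trial start.
#' @param epoch_s Epoch length in seconds.
#' @return List of channels x samples matrices (possibly empty, with a
#'   warning, if the trial is too short).
#' @export
epoch_trial <- function(trial_data, fs, discard_s = 1, epoch_s = 2) {
  if (is.vector(trial_data)) trial_data <- matrix(trial_data, nrow = 1)
  n <- ncol(trial_data)
  skip <- round(discard_s * fs)
  len <- round(epoch_s * fs)
  n_ep <- (n - skip) %/% len
  if (n_ep < 1) {
    warning("trial too short for one epoch after the discard window")
    return(list())
  }
  lapply(seq_len(n_ep), function(i) {
    trial_data[, skip + (i - 1) * len + seq_len(len), drop = FALSE]
  })
}

#' DFT of one epoch with amplitude-spectral-density scaling
#'
#' Rectangular window (epochs contain whole stimulus cycles, so harmonics
#' are exactly bin-centered and leakage-free), single-sided scaling such
#' that a pure cosine of amplitude A at a bin center yields coefficient
#' magnitude A (microvolts ASD). The coefficient of `cos(2*pi*f*t - phi)`
#' is `A * exp(-1i * phi)`, so `Arg` of the coefficient is minus the
#' cosine lag: `sin(2*pi*f*t)` reads phase 270 degrees.
#'
#' @param epoch Channels x samples matrix (or a vector, one channel).
#' @param fs Sampling rate (Hz).
#' @param expected_len If not `NULL`, error unless the epoch has exactly
#'   this many samples (no silent zero-padding).
#' @return List with `freqs` (Hz; spacing `fs/n`) and `coeffs`
#'   (channels x bins complex matrix, bins `0..n/2`).
#' @export
dft_epoch <- function(epoch, fs, expected_len = NULL) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  if (!is.null(expected_len) && n != expected_len) {
    stop("epoch length mismatch: got ", n, ", expected ", expected_len,
         " samples (refusing to zero-pad)")
  }
  spec <- t(stats::mvfft(t(epoch))) / n   # channels x n
  nb <- n %/% 2 + 1L
  coeffs <- spec[, seq_len(nb), drop = FALSE]
  scale <- c(1, rep(2, nb - 2L), if (n %% 2 == 0) 1 else 2)
  coeffs <- coeffs * matrix(scale, nrow(coeffs), nb, byrow = TRUE)
  list(freqs = (seq_len(nb) - 1L) * fs / n, coeffs = coeffs)
}

#' Epoch a full session and Fourier-transform every epoch
#'
#' Runs trial-wise epoching (with the 1-s discard), threshold artifact
#' rejection, and the bin-centered DFT, keeping bins up to `max_freq_hz`.
#' Requires a fully preprocessed session (resampled, filtered,
#' re-referenced), so that 2-s epochs hold exactly 6 stimulus cycles of
#' 140 samples.
#'
#' Rejection granularity: epochs are screened with [reject_epochs()]; with
#' `reject = "trial"` (default) a trial with any over-threshold epoch is
#' excluded whole - matching exclusion reported per trial - while
#' `reject = "epoch"` drops only the flagged epochs. `reject = "none"`
#' disables screening. The report always counts dropped epochs.
#'
#' @param session A preprocessed `raw_session`.
#' @param config An [analysis_config()].
#' @param reject `"trial"`, `"epoch"` or `"none"` (`TRUE`/`FALSE` are
#'   accepted aliases for `"trial"`/`"none"`).
#' @param max_freq_hz Highest retained frequency bin.
#' @return Object of class `epoch_spectra`: `coeffs` (complex array
#'   epochs x channels x bins), `freqs`, `epochs` (tibble: `epoch`,
#'   `trial`, `block`, `condition`, `epoch_in_trial`), `fs`, and `report`
#'   (the rejection [preprocess_report()]).
#' @export
session_spectra <- function(session, config = analysis_config(),
                            reject = "trial", max_freq_hz = 50) {
  if (isTRUE(reject)) reject <- "trial"
  if (isFALSE(reject)) reject <- "none"
  reject <- match.arg(reject, c("trial", "epoch", "none"))
  if (!identical(session$stages, .PREPROC_STAGES)) {
    stop("session_spectra needs a fully preprocessed session (stages ",
         paste(.PREPROC_STAGES, collapse = " -> "), ")")
  }
  fs <- session$fs
  if (abs(fs - config$resample_hz) > 1e-9) {
    stop("session rate (", fs, " Hz) does not match config$resample_hz")
  }
  len <- round(config$epoch_len_s * fs)
  nb_keep <- floor(max_freq_hz / (1 / config$epoch_len_s)) + 1L

  ev <- session$events
  coeff_list <- vector("list", nrow(ev))
  meta_list <- vector("list", nrow(ev))
  rej_list <- vector("list", nrow(ev))
  n_total_epochs <- 0L
  for (i in seq_len(nrow(ev))) {
    idx <- ev$onset[i] + seq_len(round(ev$duration_s[i] * fs))
    eps <- epoch_trial(session$data[, idx, drop = FALSE], fs,
                       config$discard_s, config$epoch_len_s)
    if (!length(eps)) next
    n_total_epochs <- n_total_epochs + length(eps)
    keep <- seq_along(eps)
    if (reject != "none") {
      rep_i <- reject_epochs(eps, config$reject_threshold_uv,
                             config$max_bad_fraction)
      drop <- rep_i$rejected_epochs
      if (length(drop) && reject == "trial") drop <- seq_along(eps)
      if (length(drop)) {
        rej_list[[i]] <- tibble::tibble(trial = ev$trial[i],
                                        epoch_in_trial = drop)
        keep <- setdiff(keep, drop)
      }
    }
    if (!length(keep)) next
    block <- vapply(eps[keep], function(e) {
      dft_epoch(e, fs, expected_len = len)$coeffs[, seq_len(nb_keep),
                                                  drop = FALSE]
    }, matrix(complex(1), nrow(session$data), nb_keep))
    coeff_list[[i]] <- aperm(block, c(3, 1, 2))
    meta_list[[i]] <- tibble::tibble(
      trial = ev$trial[i], block = ev$block[i], condition = ev$condition[i],
      epoch_in_trial = keep
    )
  }
  meta <- dplyr::bind_rows(meta_list)
  if (!nrow(meta)) stop("no epochs survived; check trial durations/threshold")
  meta$epoch <- seq_len(nrow(meta))
  coeffs <- do.call(abind3, coeff_list[!vapply(coeff_list, is.null, TRUE)])
  rejected <- dplyr::bind_rows(rej_list)
  structure(
    list(
      coeffs = coeffs,
      freqs = (seq_len(nb_keep) - 1L) / config$epoch_len_s,
      epochs = meta[, c("epoch", "trial", "block", "condition",
                        "epoch_in_trial")],
      fs = fs,
      scaling = "asd-uv",
      report = preprocess_report(
        rejected_epochs = rejected,
        n_epochs = n_total_epochs,
        threshold_uv = config$reject_threshold_uv
      )
    ),
    class = "epoch_spectra"
  )
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n1 <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(parts[[1]][1] * 0, dim = c(n1, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' @export
print.epoch_spectra <- function(x, ...) {
  cat("<epoch_spectra>", dim(x$coeffs)[1], "epochs x", dim(x$coeffs)[2],
      "channels x", dim(x$coeffs)[3], "bins (",
      sprintf("%.1f-%.1f Hz", min(x$freqs), max(x$freqs)), ")\n")
  invisible(x)
}

# index of the bin centered on f (error if not exactly bin-centered)
.bin_index <- function(freqs, f) {
  i <- which(abs(freqs - f) < 1e-9)
  if (length(i) != 1L) stop("frequency ", f, " Hz is not a bin center")
  i
}

#' Coherent average of complex coefficients per condition
#'
#' Averages the complex Fourier coefficients (not their magnitudes) over
#' all surviving epochs of each condition - flat pooling over epochs and
#' trials - at the requested harmonic, and estimates the noise floor as
#' the mean of the magnitudes of the two neighbor-bin coherent averages
#' (e.g. 2.5 and 3.5 Hz for the 3 Hz 1F response). With
#' `noise_method = "epoch_mag"` the neighbor-bin noise is instead the mean
#' over epochs of per-epoch magnitudes (incoherent estimate).
#'
#' @param spectra An `epoch_spectra`.
#' @param harmonic `"1F"` or `"2F"`.
#' @param stim_freq_hz Stimulus frequency (Hz).
#' @param noise_method `"coherent"` (default) or `"epoch_mag"`.
#' @return Tibble with one row per condition x channel: `condition`,
#'   `harmonic`, `freq_hz`, `channel`, `coeff` (complex coherent mean),
#'   `amp`, `phase_deg`, `noise_coeff_lo`, `noise_coeff_hi`, `noise_amp`,
#'   `snr_db`, `n_epochs`.
#' @export
coherent_average <- function(spectra, harmonic = c("1F", "2F"),
                             stim_freq_hz = 3,
                             noise_method = c("coherent", "epoch_mag")) {
  harmonic <- match.arg(harmonic)
  noise_method <- match.arg(noise_method)
  f <- stim_freq_hz * if (harmonic == "1F") 1 else 2
  ib <- .bin_index(spectra$freqs, f)
  ilo <- .bin_index(spectra$freqs, f - 0.5)
  ihi <- .bin_index(spectra$freqs, f + 0.5)
  conds <- sort(unique(spectra$epochs$condition))
  n_ch <- dim(spectra$coeffs)[2]
  rows <- lapply(conds, function(cc) {
    sel <- which(spectra$epochs$condition == cc)
    zc <- colMeans(spectra$coeffs[sel, , ib, drop = FALSE])[, 1]
    zlo <- colMeans(spectra$coeffs[sel, , ilo, drop = FALSE])[, 1]
    zhi <- colMeans(spectra$coeffs[sel, , ihi, drop = FALSE])[, 1]
    noise <- if (noise_method == "coherent") {
      (Mod(zlo) + Mod(zhi)) / 2
    } else {
      (colMeans(Mod(spectra$coeffs[sel, , ilo, drop = FALSE]))[, 1] +
       colMeans(Mod(spectra$coeffs[sel, , ihi, drop = FALSE]))[, 1]) / 2
    }
    tibble::tibble(
      condition = cc, harmonic = harmonic, freq_hz = f,
      channel = seq_len(n_ch),
      coeff = zc, amp = Mod(zc), phase_deg = phase_deg(zc),
      noise_coeff_lo = zlo, noise_coeff_hi = zhi, noise_amp = noise,
      snr_db = snr_db(Mod(zc), noise), n_epochs = length(sel)
    )
  })
  dplyr::bind_rows(rows)
}

#' Signal-to-noise ratio in dB
#'
#' `10 * log10(signal_amp^2 / noise_amp^2)` - the power ratio of the
#' harmonic amplitude to the neighbor-bin noise amplitude. Zero noise
#' gives `+Inf` with a warning.
#'
#' @param signal_amp,noise_amp Amplitudes (same units), vectorized.
#' @return SNR in dB.
#' @export
#' @examples
#' snr_db(10, 1)  # 20 dB
snr_db <- function(signal_amp, noise_amp) {
  if (any(noise_amp < 0)) stop("noise_amp must be >= 0")
  if (any(noise_amp == 0)) warning("zero noise amplitude; returning +Inf")
  10 * log10(signal_amp^2 / noise_amp^2)
}
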