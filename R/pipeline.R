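# End-to-end analysis: preprocessing -> epoch spectra -> per-task RCA ->
# component tuning -> latency dynamics; plus ground-truth recovery scoring.

#' Run the full SSVEP analysis on a session
#'
#' Preprocesses the session (resample to 420 Hz, 0.3-50 Hz zero-phase
#' band-pass, bad-channel replacement, common average reference), epochs
#' and Fourier-transforms it with threshold rejection, then fits RCA per
#' task and harmonic on the pooled 5-level epoch coefficients, projects
#' the per-condition coherent averages through the learned filters, and
#' derives per-component tuning curves and the RC1-RC2 latency lag at 1F.
#'
#' @param session A `raw_session` (native rate; not yet preprocessed).
#' @param montage An `eeg_montage`.
#' @param config An [analysis_config()].
#' @param bad_channels Sensor ids to replace during preprocessing.
#' @param tasks Tasks to analyze (present in the condition table).
#' @param n_components Components retained per RCA fit.
#' @param harmonics Harmonics to analyze (RCA is fitted per harmonic).
#' @return Object of class `ssvep_analysis`: `spectra_report`, and per
#'   task a list with `models` (per harmonic `rca_model`), `responses`
#'   (projected component responses), `tuning` (per-component tuning
#'   tibble) and `latency` (per-level RC1-RC2 lag at the first harmonic
#'   analyzed).
#' @export
analyze_session <- function(session, montage = load_montage(),
                            config = analysis_config(),
                            bad_channels = integer(0),
                            tasks = c("vernier", "letter"),
                            n_components = 2, harmonics = c("1F", "2F")) {
  ct <- session$condition_table
  pre <- preprocess_session(session, montage, config, bad_channels)
  spectra <- session_spectra(pre$session, config)
  pre$session <- NULL   # free the full-rate data; only spectra are needed
  gc(verbose = FALSE)
  out <- analyze_spectra(spectra, ct, config, tasks, n_components, harmonics)
  out$preprocess_report <- pre$report
  out
}

#' Analyze precomputed epoch spectra
#'
#' The core of [analyze_session()], starting from an `epoch_spectra`
#' object: per-task RCA fits, component projections, tuning curves and
#' the RC1-RC2 latency lag. Useful when the preprocessing chain is run
#' stage-by-stage (e.g. to bound memory on long sessions).
#'
#' @param spectra An `epoch_spectra` from [session_spectra()].
#' @param condition_table Condition lookup (`condition`, `task`, `level`,
#'   `logmar`).
#' @inheritParams analyze_session
#' @return An `ssvep_analysis` (without a preprocessing report).
#' @export
analyze_spectra <- function(spectra, condition_table,
                            config = analysis_config(),
                            tasks = c("vernier", "letter"),
                            n_components = 2, harmonics = c("1F", "2F")) {
  ct <- condition_table
  tasks <- intersect(tasks, unique(ct$task))
  per_task <- lapply(tasks, function(task) {
    conds <- ct$condition[ct$task == task]
    models <- list()
    responses <- list()
    for (h in harmonics) {
      inp <- rca_input(spectra, conds, h, config$stim_freq_hz)
      mod <- fit_rca(inp, n_components)
      hv <- coherent_average(spectra, h, config$stim_freq_hz)
      hv <- hv[hv$condition %in% conds, ]
      resp <- rc_project(mod, hv)
      resp <- tibble::add_column(resp, task = task, .before = 1)
      models[[h]] <- mod
      responses[[h]] <- resp
    }
    resp_all <- dplyr::bind_rows(responses)
    tuning <- dplyr::bind_rows(lapply(harmonics, function(h) {
      dplyr::bind_rows(lapply(paste0("RC", seq_len(n_components)), function(comp) {
        component_tuning(responses[[h]], comp, ct)
      }))
    }))
    h1 <- harmonics[1]
    latency <- component_latency_lag(
      component_tuning(responses[[h1]], "RC1", ct),
      component_tuning(responses[[h1]], "RC2", ct)
    )
    list(task = task, models = models, responses = resp_all,
         tuning = tuning, latency = latency)
  })
  names(per_task) <- tasks
  structure(
    list(tasks = per_task, spectra_report = spectra$report,
         preprocess_report = NULL, config = config),
    class = "ssvep_analysis"
  )
}

#' @export
print.ssvep_analysis <- function(x, ...) {
  cat("<ssvep_analysis> tasks:", paste(names(x$tasks), collapse = ", "), "\n")
  print(x$spectra_report)
  invisible(x)
}

#' Score an analysis against simulation ground truth
#'
#' Matches each task's 1F components to the ground-truth source
#' topographies (maximum total |correlation| assignment), corrects
#' polarity flips (a negative match correlation adds 180 degrees to the
#' component phase), and compares the recovered per-level latency lag of
#' the source-2-matched component relative to the source-1-matched
#' component with the true lag.
#'
#' @param analysis An `ssvep_analysis`.
#' @param gts Named list of `ground_truth` objects (by task).
#' @return List with `match` (tibble: `task`, `component`, `source`, `r`)
#'   and `lag` (tibble: `task`, `level`, `logmar`, `lag_est_ms`,
#'   `lag_true_ms`, `err_ms`).
#' @export
evaluate_recovery <- function(analysis, gts) {
  match_rows <- list()
  lag_rows <- list()
  for (task in names(analysis$tasks)) {
    res <- analysis$tasks[[task]]
    gt <- gts[[task]]
    if (is.null(gt)) next
    h1 <- names(res$models)[1]
    model <- res$models[[h1]]
    topos <- cbind(gt$source1$topography, gt$source2$topography)
    mm <- match_components(model, topos)
    match_rows[[task]] <- tibble::add_column(mm, task = task, .before = 1)

    comp_for_source <- function(s) mm$component[mm$source == s]
    sgn_for_source <- function(s) sign(mm$r[mm$source == s])
    t1 <- component_tuning(res$responses[res$responses$harmonic == h1, ],
                           comp_for_source(1))
    t2 <- component_tuning(res$responses[res$responses$harmonic == h1, ],
                           comp_for_source(2))
    flip <- function(tb, s) {
      if (s < 0) tb$phase_deg <- (tb$phase_deg + 180) %% 360
      tb
    }
    t1 <- flip(t1, sgn_for_source(1))
    t2 <- flip(t2, sgn_for_source(2))
    lag <- component_latency_lag(t1, t2)
    lag_rows[[task]] <- tibble::tibble(
      task = task, level = lag$level, logmar = lag$logmar,
      lag_est_ms = lag$latency_ms, lag_true_ms = gt$lag_ms,
      err_ms = lag$latency_ms - gt$lag_ms
    )
  }
  list(match = dplyr::bind_rows(match_rows),
       lag = dplyr::bind_rows(lag_rows))
}

#' Pool epoch spectra across sessions
#'
#' Concatenates `epoch_spectra` objects from several recording sessions
#' (e.g. different subjects) into one, renumbering trials and epochs so
#' trial identities stay distinct. All inputs must share the frequency
#' grid and sampling rate. Pooling observations across subjects before
#' fitting RCA mirrors the pooled component analysis used for grand
#' averages.
#'
#' @param spectra_list List of `epoch_spectra` objects.
#' @return A pooled `epoch_spectra` (the rejection report keeps the
#'   summed epoch counts).
#' @export
pool_spectra <- function(spectra_list) {
  stopifnot(length(spectra_list) >= 1)
  f0 <- spectra_list[[1]]$freqs
  for (sp in spectra_list) {
    if (!isTRUE(all.equal(sp$freqs, f0))) {
      stop("spectra disagree on the frequency grid")
    }
  }
  offset <- 0L
  metas <- list()
  for (i in seq_along(spectra_list)) {
    m <- spectra_list[[i]]$epochs
    m$trial <- m$trial + offset
    offset <- offset + max(m$trial) + 1L
    metas[[i]] <- m
  }
  out <- spectra_list[[1]]
  out$coeffs <- do.call(abind3, lapply(spectra_list, `[[`, "coeffs"))
  out$epochs <- dplyr::bind_rows(metas)
  out$epochs$epoch <- seq_len(nrow(out$epochs))
  n_tot <- sum(vapply(spectra_list, function(s) s$report$n_epochs, numeric(1)))
  n_rej <- sum(vapply(spectra_list, function(s) {
    r <- s$report$rejected_epochs
    if (is.data.frame(r)) nrow(r) else length(r)
  }, numeric(1)))
  out$report <- preprocess_report(
    rejected_epochs = n_tot - (n_tot - n_rej),  # count only
    n_epochs = n_tot,
    threshold_uv = spectra_list[[1]]$report$threshold_uv
  )
  out$report$rejected_epochs <- n_rej
  out$report$rejection_fraction <- if (n_tot > 0) n_rej / n_tot else 0
  out
}

#' Simulate and analyze a pooled multi-subject study
#'
#' Runs the complete study the package is validated on: `n_subjects`
#' sessions are simulated from the same ground truth (independent noise,
#' schedules and artifacts per subject), each is preprocessed and
#' Fourier-transformed, the epoch spectra are pooled across subjects, and
#' the pooled spectra are analyzed (RCA per task/harmonic, tuning,
#' latency). Sessions are processed one at a time and only their spectra
#' retained, to bound memory.
#'
#' @param n_subjects Number of simulated subjects/sessions.
#' @param seed Integer master seed; subject `k` uses `seed * 100 + k` for
#'   its session and schedule.
#' @param gt Named list of `ground_truth` objects; default both tasks.
#' @param noise A [noise_spec()].
#' @param montage An `eeg_montage`.
#' @param config An [analysis_config()].
#' @param tasks Tasks to analyze.
#' @return List with `analysis` (an `ssvep_analysis`), `recovery` (from
#'   [evaluate_recovery()]), `gt`, and `spectra` (the pooled
#'   `epoch_spectra`).
#' @export
recovery_study <- function(n_subjects = 3, seed = 1, gt = NULL,
                           noise = noise_spec(), montage = load_montage(),
                           config = analysis_config(),
                           tasks = c("vernier", "letter")) {
  if (is.null(gt)) {
    gt <- list(vernier = default_ground_truth("vernier", montage),
               letter = default_ground_truth("letter", montage))
  }
  sps <- vector("list", n_subjects)
  for (k in seq_len(n_subjects)) {
    sk <- seed * 100L + k
    sched <- build_schedule(seed = sk + 7L)
    raw <- simulate_session(sched, gt, noise, fs = 500, seed = sk,
                            montage = montage)
    s <- resample_session(raw, config$resample_hz, config$stim_freq_hz)
    rm(raw); gc(verbose = FALSE)
    s <- bandpass_session(s, config$bandpass_hz[1], config$bandpass_hz[2])
    s <- replace_bad_channels(s, integer(0), montage)$session
    s <- rereference_average(s)
    sps[[k]] <- session_spectra(s, config)
    rm(s); gc(verbose = FALSE)
  }
  pooled <- pool_spectra(sps)
  rm(sps); gc(verbose = FALSE)
  analysis <- analyze_spectra(pooled, default_condition_table(), config,
                              tasks = tasks)
  list(analysis = analysis, recovery = evaluate_recovery(analysis, gt),
       gt = gt, spectra = pooled)
}
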