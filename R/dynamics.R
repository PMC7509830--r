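# Tuning curves, phase-difference latency estimation with wrap-around
# candidates, and the accompanying statistical tests.

#' Phase of a complex coefficient in degrees
#'
#' `Arg(z)` mapped to \[0, 360). Under the package's DFT convention the
#' coefficient of `cos(2*pi*f*t - phi)` is `A * exp(-1i*phi)`, so the
#' reported phase is minus the cosine lag: `1 -> 0`, `1i -> 90`,
#' `sin(2*pi*f*t) -> 270`.
#'
#' @param z Complex vector.
#' @return Phase in degrees, \[0, 360); `NA` (with a warning) where
#'   `z == 0`.
#' @export
phase_deg <- function(z) {
  out <- (Arg(z) * 180 / pi) %% 360
  out[abs(out - 360) < 1e-9] <- 0   # guard the wrap boundary
  if (any(Mod(z) == 0)) {
    warning("phase undefined for zero coefficient(s)")
    out[Mod(z) == 0] <- NA_real_
  }
  out
}

#' Minimal signed phase difference
#'
#' `phi2 - phi1` wrapped to the interval (-180, 180]; the boundary maps
#' to +180.
#'
#' @param phi1_deg,phi2_deg Phases in degrees (any real values).
#' @return Signed difference in degrees.
#' @export
#' @examples
#' phase_difference(10, 350)  # -20
phase_difference <- function(phi1_deg, phi2_deg) {
  d <- (phi2_deg - phi1_deg) %% 360
  d - 360 * (d > 180)
}

#' Convert a phase difference to latency candidates
#'
#' A periodic response defines latency only modulo one stimulus period
#' (1000/freq ms), so alongside the principal value
#' `delta_deg / (360 * freq) * 1000` the full candidate family
#' `latency + k * period` is reported for `k in {-1, 0, 1, 2}`. The
#' principal (`k = 0`) candidate is the default choice; disambiguation is
#' left to external plausibility arguments. At 3 Hz, 180 degrees
#' corresponds to 166.7 ms (one half period of 333.3 ms).
#'
#' @param delta_deg Signed phase difference in degrees.
#' @param freq_hz Harmonic frequency (> 0).
#' @param k_set Integer wrap-around candidates.
#' @return Tibble: `delta_phase_deg`, `freq_hz`, `latency_ms` (rounded to
#'   0.1 ms), `chosen_k`, and list-column `candidates_ms`.
#' @export
#' @examples
#' phase_to_latency(180, 3)$latency_ms  # 166.7
phase_to_latency <- function(delta_deg, freq_hz, k_set = -1:2) {
  if (any(freq_hz <= 0)) stop("freq_hz must be > 0")
  period_ms <- 1000 / freq_hz
  lat <- delta_deg / (360 * freq_hz) * 1000
  tibble::tibble(
    delta_phase_deg = delta_deg,
    freq_hz = freq_hz,
    latency_ms = round(lat, 1),
    chosen_k = 0L,
    candidates_ms = purrr::map2(lat, period_ms, function(l, p) {
      round(l + k_set * p, 1)
    })
  )
}

#' Per-component tuning table
#'
#' Reshapes a projected component-response table (from [rc_project()])
#' into per-level tuning rows for one component, joining stimulus levels
#' from a condition table.
#'
#' @param responses Tibble from [rc_project()].
#' @param component Component name (e.g. `"RC1"`).
#' @param condition_table Condition lookup with `condition`, `task`,
#'   `level`, `logmar`.
#' @return Tibble: `component`, `task`, `harmonic`, `freq_hz`, `level`,
#'   `logmar`, `amplitude`, `phase_deg`, `snr_db`, `noise_amp`, `coeff`.
#' @export
component_tuning <- function(responses, component,
                             condition_table = default_condition_table()) {
  sub <- responses[responses$component == component, ]
  if (!nrow(sub)) stop("no rows for component ", component)
  sub$task <- NULL   # re-derived from the condition table
  ct <- condition_table[, c("condition", "task", "level", "logmar")]
  out <- dplyr::inner_join(sub, ct, by = "condition")
  out <- dplyr::arrange(out, .data$level)
  tibble::tibble(
    component = component, task = out$task, harmonic = out$harmonic,
    freq_hz = out$freq_hz, level = out$level, logmar = out$logmar,
    amplitude = out$amp, phase_deg = out$phase_deg,
    snr_db = out$snr_db, noise_amp = out$noise_amp, coeff = out$coeff
  )
}

#' Latency lag between two components, per stimulus level
#'
#' Computes, at each level, the signed phase lag of component 2 relative
#' to component 1 and converts it to latency: positive values mean
#' component 2 lags (responds later than) component 1. Because the
#' package's reported phase is minus the cosine lag, the lag in degrees
#' is `phase1 - phase2` wrapped to (-180, 180].
#'
#' @param tuning1,tuning2 Per-component tuning tables from
#'   [component_tuning()], with identical task/harmonic/levels.
#' @return Tibble: `level`, `logmar`, `delta_phase_deg`, `freq_hz`,
#'   `latency_ms` (positive = component 2 lags), `chosen_k`,
#'   `candidates_ms`.
#' @export
component_latency_lag <- function(tuning1, tuning2) {
  if (!identical(tuning1$level, tuning2$level) ||
      !isTRUE(all.equal(tuning1$logmar, tuning2$logmar)) ||
      !identical(tuning1$freq_hz, tuning2$freq_hz)) {
    stop("tuning tables disagree on levels or harmonic frequency")
  }
  # lag2 - lag1 = (-phase2) - (-phase1) = phase1 - phase2
  lag_deg <- phase_difference(tuning2$phase_deg, tuning1$phase_deg)
  out <- phase_to_latency(lag_deg, tuning1$freq_hz[1])
  tibble::add_column(out, level = tuning1$level, logmar = tuning1$logmar,
                     .before = 1)
}

#' Paired signal-vs-noise t test
#'
#' Two-sided paired t-test of signal amplitudes against the neighbor-bin
#' noise amplitudes (one pair per subject or session, each typically
#' averaged over stimulus levels first). If all differences are zero the
#' test is reported as `t = 0, p = 1`; a nonzero constant difference has
#' zero variance and is flagged degenerate.
#'
#' @param signal_amps,noise_amps Paired amplitude vectors, `n >= 3`.
#' @return Tibble: `t`, `df`, `p`, `degenerate`.
#' @export
snr_significance <- function(signal_amps, noise_amps) {
  stopifnot(length(signal_amps) == length(noise_amps))
  n <- length(signal_amps)
  if (n < 3) stop("need at least 3 pairs")
  d <- signal_amps - noise_amps
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, mean(abs(d)))) {
    if (all(abs(d) < .Machine$double.eps^0.5)) {
      return(tibble::tibble(t = 0, df = n - 1L, p = 1, degenerate = FALSE))
    }
    warning("zero variance of paired differences; t undefined")
    return(tibble::tibble(t = NA_real_, df = n - 1L, p = NA_real_,
                          degenerate = TRUE))
  }
  ht <- stats::t.test(signal_amps, noise_amps, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, degenerate = FALSE)
}

#' Two-factor repeated-measures ANOVA (component x level)
#'
#' Compares tuning functions between reliable components: a two-way
#' repeated-measures ANOVA fitted as a linear mixed model
#' (`value ~ rc * logmar + (1 | subject)`, F tests with Satterthwaite
#' degrees of freedom via lmerTest). By default `logmar` enters as a
#' numeric covariate, giving single-degree-of-freedom tests of the level
#' trend and its interaction with component; set
#' `logmar_as_factor = TRUE` for the fully factorial version. The
#' `"aov"` engine instead runs the classical univariate repeated-measures
#' ANOVA with within-subject error strata.
#'
#' @param data Data frame with one row per subject x component x level.
#' @param value,rc,logmar,subject Column names (strings) of the dependent
#'   variable, component factor, level variable and subject id.
#' @param logmar_as_factor Treat the level variable as a factor.
#' @param engine `"lmm"` (default) or `"aov"`.
#' @return Tibble: `effect`, `df1`, `df2`, `F`, `p`.
#' @export
rm_anova_2way <- function(data, value = "value", rc = "rc",
                          logmar = "logmar", subject = "subject",
                          logmar_as_factor = FALSE,
                          engine = c("lmm", "aov")) {
  engine <- match.arg(engine)
  d <- data.frame(
    value = data[[value]],
    rc = factor(data[[rc]]),
    logmar = if (logmar_as_factor || engine == "aov") {
      factor(data[[logmar]])
    } else {
      as.numeric(data[[logmar]])
    },
    subject = factor(data[[subject]])
  )
  if (nlevels(d$subject) < 2) stop("need at least 2 subjects")
  if (engine == "lmm") {
    fit <- lmerTest::lmer(value ~ rc * logmar + (1 | subject), data = d)
    a <- stats::anova(fit)
    tibble::tibble(
      effect = rownames(a),
      df1 = a$NumDF, df2 = a$DenDF,
      F = a$`F value`, p = a$`Pr(>F)`
    )
  } else {
    fit <- stats::aov(value ~ rc * logmar + Error(subject / (rc * logmar)),
                      data = d)
    sm <- summary(fit)
    rows <- list()
    for (stratum in sm) {
      tab <- stratum[[1]]
      keep <- !grepl("Residuals", rownames(tab))
      if (!any(keep)) next
      res <- tab[!keep, , drop = FALSE]
      for (i in which(keep)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          effect = trimws(rownames(tab)[i]),
          df1 = tab$Df[i], df2 = res$Df[1],
          F = tab$`F value`[i], p = tab$`Pr(>F)`[i]
        )
      }
    }
    dplyr::bind_rows(rows)
  }
}
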