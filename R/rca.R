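# Reliable Components Analysis: spatial filters maximizing trial-to-trial
# reliability of complex harmonic coefficients, via a generalized
# eigenproblem on cross-trial covariance matrices.

#' Assemble RCA input from epoch spectra
#'
#' Extracts the complex coefficients at one harmonic for the selected
#' conditions and stacks them as real observations: every epoch
#' contributes two rows (its real-part vector and its imaginary-part
#' vector) over the 128 channels; all levels of a task are pooled.
#'
#' @param spectra An `epoch_spectra`.
#' @param conditions Condition ids to pool (e.g. one task's 5 levels).
#' @param harmonic `"1F"` or `"2F"`.
#' @param stim_freq_hz Stimulus frequency (Hz).
#' @return Object of class `rca_input`: `obs` (2 x epochs rows x channels),
#'   `trial` (per-row trial id), `slot` (per-row alignment slot within
#'   trial: epoch position x {re, im}), `harmonic`, `freq_hz`.
#' @export
rca_input <- function(spectra, conditions, harmonic = c("1F", "2F"),
                      stim_freq_hz = 3) {
  harmonic <- match.arg(harmonic)
  f <- stim_freq_hz * if (harmonic == "1F") 1 else 2
  ib <- .bin_index(spectra$freqs, f)
  sel <- which(spectra$epochs$condition %in% conditions)
  if (!length(sel)) stop("no epochs for the requested conditions")
  z <- spectra$coeffs[sel, , ib, drop = FALSE][, , 1, drop = TRUE]
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  meta <- spectra$epochs[sel, ]
  n_ep <- nrow(z)
  obs <- matrix(0, 2L * n_ep, ncol(z))
  obs[seq(1, 2 * n_ep, by = 2), ] <- Re(z)
  obs[seq(2, 2 * n_ep, by = 2), ] <- Im(z)
  trial <- rep(meta$trial, each = 2L)
  slot <- paste0(rep(meta$epoch_in_trial, each = 2L), c("re", "im"))
  structure(
    list(obs = obs, trial = trial, slot = slot,
         condition = rep(meta$condition, each = 2L),
         part = rep(c("re", "im"), n_ep),
         harmonic = harmonic, freq_hz = f),
    class = "rca_input"
  )
}

#' Build an rca_input directly from an observation matrix
#'
#' Lower-level constructor used in simulations and tests.
#'
#' @param obs Real matrix (rows = observations, columns = channels).
#' @param trial Per-row trial grouping labels.
#' @param condition Per-row condition labels (trial pairing is restricted
#'   to repeats of the same condition); default: a single condition.
#' @param slot Optional per-row alignment slot within trial; defaults to
#'   the running index within each trial.
#' @param part Optional per-row centering group (e.g. `"re"`/`"im"`);
#'   default: one group.
#' @param harmonic,freq_hz Metadata labels.
#' @return An `rca_input`.
#' @export
as_rca_input <- function(obs, trial, condition = NULL, slot = NULL,
                         part = NULL, harmonic = "1F", freq_hz = 3) {
  stopifnot(is.matrix(obs), nrow(obs) == length(trial))
  if (is.null(slot)) {
    slot <- stats::ave(seq_along(trial), trial, FUN = seq_along)
  }
  structure(list(obs = obs, trial = trial, slot = as.character(slot),
                 condition = condition %||% rep(1L, nrow(obs)),
                 part = part %||% rep("all", nrow(obs)),
                 harmonic = harmonic, freq_hz = freq_hz),
            class = "rca_input")
}

#' Cross-trial and within-trial covariance matrices
#'
#' After centering the observations on their grand mean - real-part and
#' imaginary-part rows are centered separately, i.e. the complex grand
#' mean is removed - `R_between` is the average, over all ordered pairs
#' of distinct trials that are repeats of the same condition, of the
#' cross-covariance of the two trials' observations; `R_within` is the
#' pooled auto-covariance over all observations.
#'
#' Two points follow from what "trial-to-trial consistency" means for a
#' stimulus-locked response. First, pairs are restricted to repeats of
#' the same condition: when several stimulus levels are pooled, pairing
#' across different levels would cancel the level-specific (centered)
#' response patterns. Second, because the phase-locked response is common
#' to every epoch of a trial, the cross-covariance of two trials is taken
#' between their per-trial mean observations (per centering part, i.e.
#' the real and imaginary rows are averaged separately): all between-trial
#' epoch products carry the same signal information, and averaging them
#' all - which is what the product of trial means is - minimizes the
#' noise variance of the estimate. Trials that lost epochs to artifact
#' rejection simply contribute means over their surviving epochs.
#'
#' @param input An `rca_input` with at least 2 trials of some condition.
#' @return List with `R_between` and `R_within` (both channels x channels,
#'   symmetric; `R_within` positive semi-definite), plus `n_trials`,
#'   `n_obs`, `n_pairs` (unordered same-condition trial pairs).
#' @export
cross_trial_covariances <- function(input) {
  obs <- input$obs
  trial <- input$trial
  part <- input$part %||% rep("all", nrow(obs))
  cond <- input$condition %||% rep(1L, nrow(obs))
  x <- obs
  for (p in unique(part)) {
    rows <- part == p
    x[rows, ] <- sweep(obs[rows, , drop = FALSE], 2,
                       colMeans(obs[rows, , drop = FALSE]))
  }
  n_t <- length(unique(trial))
  if (n_t < 2L) stop("cross-trial covariances need at least 2 trials")
  r_within <- crossprod(x) / nrow(x)

  # per-trial, per-part mean observations (rowsum sorts by group label,
  # as does table(), so the two align)
  key <- paste(trial, part, sep = "\r")
  sums <- rowsum(x, key)
  counts <- as.vector(table(key))
  means <- sums / counts
  m_trial <- sub("\r.*$", "", rownames(sums))
  trial_cond <- tapply(cond, trial, function(v) v[1])

  acc <- matrix(0, ncol(x), ncol(x))
  total_pairs <- 0L
  for (cc in unique(trial_cond)) {
    trials_c <- names(trial_cond)[trial_cond == cc]
    if (length(trials_c) < 2L) next
    rows_c <- which(m_trial %in% trials_c)
    groups <- split(rows_c, m_trial[rows_c])
    sizes <- lengths(groups)
    if (length(unique(sizes)) != 1L) {
      stop("trials differ in centering-part structure within a condition")
    }
    m <- sizes[[1]]
    n_c <- length(groups)
    s <- Reduce(`+`, lapply(groups, function(g) means[g, , drop = FALSE]))
    diag_sum <- Reduce(`+`, lapply(groups, function(g) {
      crossprod(means[g, , drop = FALSE])
    }))
    acc <- acc + (crossprod(s) - diag_sum) / (2 * m)
    total_pairs <- total_pairs + n_c * (n_c - 1L) / 2L
  }
  if (total_pairs == 0L) stop("no same-condition trial pairs available")
  r_between <- acc / total_pairs
  r_between <- (r_between + t(r_between)) / 2
  list(R_between = r_between, R_within = r_within,
       n_trials = n_t, n_obs = nrow(x), n_pairs = as.integer(total_pairs))
}

#' Fit Reliable Components Analysis
#'
#' Solves the generalized eigenproblem `R_between w = lambda R_within w`
#' on a rank-reduced subspace: `R_within` is first projected onto its top
#' principal components (enough to retain `var_keep` of its variance,
#' capped at `rank_cap`), whitened, and the symmetrized projected
#' `R_between` is eigendecomposed there. Eigenvalues (trial-to-trial
#' reliability ratios) are returned in descending order. Each retained
#' filter is scaled so its forward topography `A = R_within W` has unit
#' norm, with the sign fixed so the topography's largest-magnitude entry
#' is positive.
#'
#' @param input An `rca_input`.
#' @param n_components Number of components to retain (filters kept).
#' @param rank Optional fixed subspace rank; default chosen by `var_keep`.
#' @param var_keep Fraction of `R_within` variance the subspace retains.
#' @param rank_cap Upper bound on the subspace rank.
#' @return Object of class `rca_model`: `W` (channels x k filters), `A`
#'   (channels x k forward topographies), `eigvals` (all subspace
#'   eigenvalues, descending), `reliability_fraction`, `n_components`,
#'   `rank`, `basis` (subspace basis), `harmonic`, `freq_hz`.
#' @export
fit_rca <- function(input, n_components = 2, rank = NULL, var_keep = 0.999,
                    rank_cap = 60) {
  cv <- cross_trial_covariances(input)
  ew <- eigen(cv$R_within, symmetric = TRUE)
  tol <- max(ew$values) * 1e-10
  pos <- which(ew$values > tol)
  if (!length(pos)) stop("R_within is numerically zero")
  r <- if (!is.null(rank)) {
    min(rank, length(pos))
  } else {
    min(which(cumsum(ew$values[pos]) / sum(ew$values[pos]) >= var_keep)[1],
        rank_cap, length(pos))
  }
  v <- ew$vectors[, seq_len(r), drop = FALSE]
  d <- ew$values[seq_len(r)]
  if (any(d <= tol)) stop("R_within singular on the requested subspace; ",
                          "reduce rank")
  wh <- v %*% diag(1 / sqrt(d), r)          # whitening map
  m <- t(wh) %*% cv$R_between %*% wh
  m <- (m + t(m)) / 2
  em <- eigen(m, symmetric = TRUE)
  n_components <- as.integer(min(n_components, r))
  w_all <- wh %*% em$vectors
  w <- w_all[, seq_len(n_components), drop = FALSE]
  a <- cv$R_within %*% w
  for (j in seq_len(n_components)) {
    s <- sqrt(sum(a[, j]^2))
    if (s > 0) { a[, j] <- a[, j] / s; w[, j] <- w[, j] / s }
    peak <- which.max(abs(a[, j]))
    if (a[peak, j] < 0) { a[, j] <- -a[, j]; w[, j] <- -w[, j] }
    # biorthogonal filter scale: t(w) %*% a = 1, so projected component
    # coefficients read as microvolt amplitudes of the unit-norm
    # topography (w' R_w w > 0, so the sign fix is preserved)
    s2 <- sum(w[, j] * a[, j])
    if (s2 > 0) w[, j] <- w[, j] / s2
  }
  lambda <- em$values
  structure(
    list(
      W = w, A = a, eigvals = lambda,
      reliability_fraction = pmax(lambda, 0) / sum(pmax(lambda, 0)),
      n_components = n_components, rank = r, basis = v,
      harmonic = input$harmonic, freq_hz = input$freq_hz,
      R_between = cv$R_between, R_within = cv$R_within
    ),
    class = "rca_model"
  )
}

#' @export
print.rca_model <- function(x, ...) {
  cat("<rca_model>", x$n_components, "components on rank-", x$rank,
      " subspace; top eigenvalues: ",
      paste(signif(utils::head(x$eigvals, 3), 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Fraction of trial-to-trial reliability explained
#'
#' Sum of the top-k positive eigenvalues over the sum of all positive
#' eigenvalues.
#'
#' @param model An `rca_model`.
#' @param k Number of leading components.
#' @return Fraction in \[0, 1\] (`NA` with a warning if no eigenvalue is
#'   positive).
#' @export
reliability_explained <- function(model, k = 2) {
  lam <- model$eigvals
  pos <- pmax(lam, 0)
  if (sum(pos) == 0) {
    warning("no positive reliability eigenvalues; fraction undefined")
    return(NA_real_)
  }
  k <- min(k, length(lam))
  sum(pos[seq_len(k)]) / sum(pos)
}

#' Project coherent averages into component space
#'
#' Applies the spatial filters to each condition's channel-space coherent
#' average: the component coefficient is `t(W) %*% coeff`, and the noise
#' estimate is the mean magnitude of the two neighbor-bin coherent
#' averages passed through the same filters.
#'
#' @param model An `rca_model`.
#' @param harm_tbl Coherent-average table from [coherent_average()].
#' @return Tibble with one row per component x condition: `component`,
#'   `condition`, `harmonic`, `freq_hz`, `coeff`, `amp`, `phase_deg`,
#'   `noise_amp`, `snr_db`, `n_epochs`.
#' @export
rc_project <- function(model, harm_tbl) {
  n_ch <- nrow(model$W)
  conds <- unique(harm_tbl$condition)
  rows <- lapply(conds, function(cc) {
    sub <- harm_tbl[harm_tbl$condition == cc, ]
    sub <- sub[order(sub$channel), ]
    if (nrow(sub) != n_ch) {
      stop("channel dimension mismatch: ", nrow(sub), " vs ", n_ch)
    }
    z <- as.vector(t(model$W) %*% sub$coeff)
    zlo <- as.vector(t(model$W) %*% sub$noise_coeff_lo)
    zhi <- as.vector(t(model$W) %*% sub$noise_coeff_hi)
    noise <- (Mod(zlo) + Mod(zhi)) / 2
    tibble::tibble(
      component = paste0("RC", seq_along(z)),
      condition = cc,
      harmonic = sub$harmonic[1], freq_hz = sub$freq_hz[1],
      coeff = z, amp = Mod(z), phase_deg = phase_deg(z),
      noise_amp = noise, snr_db = snr_db(Mod(z), noise),
      n_epochs = sub$n_epochs[1]
    )
  })
  dplyr::bind_rows(rows)
}

#' Match fitted components to reference topographies
#'
#' Assigns each of the model's forward topographies to one reference
#' topography (columns of `topos`), maximizing the total absolute Pearson
#' correlation over all assignments (exhaustive search; intended for the
#' small component counts RCA retains). Reports the signed correlation -
#' a negative `r` means the component is polarity-flipped relative to the
#' reference.
#'
#' @param model An `rca_model`.
#' @param topos Channels x sources matrix of reference topographies.
#' @return Tibble: `component`, `source` (column index of `topos`), `r`.
#' @export
match_components <- function(model, topos) {
  topos <- as.matrix(topos)
  k <- model$n_components
  s <- ncol(topos)
  stopifnot(s >= 1, s <= 6)  # exhaustive assignment only for small counts
  cmat <- stats::cor(model$A, topos)   # k x s
  n_assign <- min(k, s)
  perms <- .permutations(seq_len(s))
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    sel <- p[seq_len(n_assign)]
    val <- sum(abs(cmat[cbind(seq_len(n_assign), sel)]))
    if (val > best_val) { best_val <- val; best <- sel }
  }
  tibble::tibble(
    component = paste0("RC", seq_len(n_assign)),
    source = best,
    r = cmat[cbind(seq_len(n_assign), best)]
  )
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Permutation null for the top reliability eigenvalue
#'
#' Re-fits RCA after randomly permuting the epoch-to-trial assignment
#' within each condition (keeping each epoch's real/imaginary row pair
#' together), which destroys trial-to-trial consistency beyond the
#' condition-locked mean while preserving the pooled within-trial
#' covariance and the condition structure. Returns the top eigenvalue of
#' each permuted fit, for use as a null distribution. Note that a
#' stimulus-locked mean response survives any trial permutation, so this
#' null is informative for inputs without phase-locked structure (e.g.
#' after [phase_randomize_epochs()]).
#'
#' @param input An `rca_input`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param ... Passed to [fit_rca()].
#' @return Numeric vector of length `n_perm`.
#' @export
rca_permutation_null <- function(input, n_perm = 200, seed = 1, ...) {
  n_rows <- nrow(input$obs)
  # epoch units are consecutive (re, im) row pairs
  stopifnot(n_rows %% 2L == 0L)
  n_ep <- n_rows %/% 2L
  ep_cond <- input$condition[2L * seq_len(n_ep) - 1L]
  .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- seq_len(n_ep)
      for (cc in unique(ep_cond)) {
        in_c <- which(ep_cond == cc)
        perm[in_c] <- in_c[sample(length(in_c))]
      }
      rows <- as.vector(rbind(2L * perm - 1L, 2L * perm))
      shuffled <- input
      shuffled$obs <- input$obs[rows, , drop = FALSE]
      # trial/slot/condition labels keep their positions: epochs move
      # between trials of the same condition
      fit <- fit_rca(shuffled, n_components = 1, ...)
      fit$eigvals[1]
    }, numeric(1))
  })
}

#' Randomize the phase of every epoch
#'
#' Rotates each epoch's complex coefficient vector by an independent
#' uniform phase, destroying cross-trial phase consistency while leaving
#' each epoch's spatial amplitude structure intact. Used to build
#' reliability null inputs.
#'
#' @param input An `rca_input` (rows in re/im pairs).
#' @param seed Integer seed.
#' @return The phase-randomized `rca_input`.
#' @export
phase_randomize_epochs <- function(input, seed = 1) {
  n_rows <- nrow(input$obs)
  stopifnot(n_rows %% 2L == 0L)
  n_ep <- n_rows %/% 2L
  .with_seed(seed, {
    th <- stats::runif(n_ep, 0, 2 * pi)
    for (e in seq_len(n_ep)) {
      re <- input$obs[2L * e - 1L, ]
      im <- input$obs[2L * e, ]
      input$obs[2L * e - 1L, ] <- cos(th[e]) * re - sin(th[e]) * im
      input$obs[2L * e, ] <- sin(th[e]) * re + cos(th[e]) * im
    }
    input
  })
}

# ---- broom-style methods --------------------------------------------------

#' @exportS3Method broom::tidy
tidy.rca_model <- function(x, ...) {
  tibble::tibble(
    component = paste0("RC", seq_along(x$eigvals)),
    eigenvalue = x$eigvals,
    reliability_fraction = x$reliability_fraction,
    retained = seq_along(x$eigvals) <= x$n_components
  )
}

#' @exportS3Method broom::glance
glance.rca_model <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    rank = x$rank,
    harmonic = x$harmonic,
    reliability_top2 = reliability_explained(x, 2)
  )
}
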