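# Stimulus and schedule arithmetic: logMAR conversions, acuity series,
# Vernier grating / letter-array frame generation, block/trial schedules.

#' logMAR conversions
#'
#' `arcmin_to_logmar()` is `log10(x)` for a size/offset in arcminutes;
#' `logmar_to_arcmin()` is its inverse. logMAR 0 corresponds to a minimum
#' angle of resolution of 1 arcmin.
#'
#' @param x Size or offset in arcminutes (> 0).
#' @param logmar logMAR value.
#' @return Numeric vector.
#' @export
#' @examples
#' arcmin_to_logmar(5.6)  # ~0.75
arcmin_to_logmar <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) stop("arcmin values must be > 0")
  log10(x)
}

#' @rdname arcmin_to_logmar
#' @export
logmar_to_arcmin <- function(logmar) 10^logmar

#' Build a graded acuity condition series
#'
#' Returns `n` stimulus levels between two logMAR endpoints, inclusive.
#' The default spacing is equal steps in logMAR ("equal log steps"); the
#' alternative `"arcmin"` spacing interpolates linearly in arcminutes.
#' Physical size is the Vernier offset in arcmin (`10^logmar`) for the
#' vernier task, or the letter height in arcmin (`5 * 10^logmar`, the
#' standard 5-arcmin optotype at logMAR 0) for the letter task.
#'
#' @param task `"vernier"` or `"letter"`.
#' @param lo_logmar,hi_logmar Series endpoints (logMAR), `lo < hi`.
#' @param n Number of levels (>= 2).
#' @param spacing `"logmar"` (default) or `"arcmin"`.
#' @return Tibble with columns `task`, `level`, `logmar`, `physical_arcmin`.
#' @export
#' @examples
#' build_series("vernier", 0.15, 0.75)
build_series <- function(task = c("vernier", "letter"), lo_logmar, hi_logmar,
                         n = 5, spacing = c("logmar", "arcmin")) {
  task <- match.arg(task)
  spacing <- match.arg(spacing)
  if (!(lo_logmar < hi_logmar)) stop("lo_logmar must be < hi_logmar")
  if (n < 2) stop("n must be >= 2")
  logmar <- if (spacing == "logmar") {
    seq(lo_logmar, hi_logmar, length.out = n)
  } else {
    arcmin_to_logmar(seq(logmar_to_arcmin(lo_logmar),
                         logmar_to_arcmin(hi_logmar), length.out = n))
  }
  physical <- logmar_to_arcmin(logmar) * if (task == "letter") 5 else 1
  tibble::tibble(task = task, level = seq_len(n), logmar = logmar,
                 physical_arcmin = physical)
}

#' Default 10-condition table
#'
#' Conditions 1-5: Vernier offsets at five equal log steps, 0.15-0.75
#' logMAR (1.4-5.6 arcmin). Conditions 6-10: letter sizes at five equal
#' log steps, 0.15-1.06 logMAR.
#'
#' @return Tibble with columns `condition`, `task`, `level`, `logmar`,
#'   `physical_arcmin`.
#' @export
default_condition_table <- function() {
  v <- build_series("vernier", 0.15, 0.75)
  l <- build_series("letter", 0.15, 1.06)
  out <- rbind(v, l)
  tibble::add_column(out, condition = seq_len(nrow(out)), .before = 1)
}

# run expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a block/trial schedule
#'
#' Each block holds `per_block_per_cond` trials of each condition in
#' seeded random order; defaults reproduce the protocol of 8 blocks x 2
#' trials x 10 conditions = 16 trials per condition, 20 trials per block,
#' 12 s per trial.
#'
#' @param n_blocks Number of blocks.
#' @param per_block_per_cond Trials per condition within each block.
#' @param conditions Number of conditions, or a vector of condition ids.
#' @param trial_s Trial duration in seconds.
#' @param seed Integer seed for the within-block permutations.
#' @return Tibble with columns `block`, `trial` (global 1-based index),
#'   `condition`, `duration_s`; the seed is kept in attribute `"seed"`.
#' @export
#' @examples
#' sched <- build_schedule(seed = 1)
#' table(sched$condition)  # 16 each
build_schedule <- function(n_blocks = 8, per_block_per_cond = 2,
                           conditions = 10, trial_s = 12, seed = 1) {
  if (length(conditions) == 1L) conditions <- seq_len(conditions)
  stopifnot(n_blocks >= 1, per_block_per_cond >= 1, length(conditions) >= 1,
            trial_s > 0)
  blocks <- .with_seed(seed, lapply(seq_len(n_blocks), function(b) {
    sample(rep(conditions, per_block_per_cond))
  }))
  out <- tibble::tibble(
    block = rep(seq_len(n_blocks), each = length(conditions) * per_block_per_cond),
    condition = unlist(blocks),
    duration_s = trial_s
  )
  out <- tibble::add_column(out, trial = seq_len(nrow(out)), .after = "block")
  attr(out, "seed") <- seed
  out
}

# ---- frames --------------------------------------------------------------

#' Vernier grating frame pair
#'
#' Builds the two alternation states of the Vernier stimulus: a vertical
#' square-wave grating (`base`), and the same grating with alternating
#' horizontal bands displaced laterally by the offset (`modulated`).
#' Displaced bands alternate with static bands of the same height,
#' starting with a static band at the top. Shifts wrap circularly, so the
#' two frames have exactly equal mean luminance.
#'
#' @param offset_arcmin Lateral offset of the displaced bands (arcmin).
#' @param field_deg Square field size (deg).
#' @param band_height_deg Height of each static/displaced band (deg).
#' @param sf_cpd Grating spatial frequency (cycles/deg).
#' @param contrast Michelson contrast of the grating.
#' @param pixel_deg Degrees per pixel.
#' @param subpixel If `TRUE` (default), non-integer pixel offsets are
#'   rendered by linear interpolation of the column shift; if `FALSE`,
#'   offsets below one pixel are an error and shifts are rounded.
#' @return List with elements `base` and `modulated`, each a list
#'   (`image` rows x cols in \[0,1\], `pixel_deg`, `state`).
#' @export
make_vernier_frames <- function(offset_arcmin, field_deg = 12,
                                band_height_deg = 2, sf_cpd = 2,
                                contrast = 0.9, pixel_deg = 1 / 60,
                                subpixel = TRUE) {
  npx <- round(field_deg / pixel_deg)
  half_px <- round(1 / (sf_cpd * pixel_deg) / 2)
  if (half_px < 1) stop("grating period is below one pixel")
  profile <- rep(rep(c(0.5 + contrast / 2, 0.5 - contrast / 2),
                     each = half_px), length.out = npx)

  offset_px <- offset_arcmin / 60 / pixel_deg
  if (!subpixel) {
    if (offset_arcmin > 0 && offset_px < 1) {
      stop("offset below one pixel; enable subpixel rendering")
    }
    offset_px <- round(offset_px)
  }
  shift_circ <- function(v, s) {
    # circular shift by integer s (rightward)
    n <- length(v)
    s <- ((s %% n) + n) %% n
    if (s == 0) v else c(v[(n - s + 1):n], v[seq_len(n - s)])
  }
  s0 <- floor(offset_px)
  frac <- offset_px - s0
  shifted <- (1 - frac) * shift_circ(profile, s0) + frac * shift_circ(profile, s0 + 1)

  band_px <- round(band_height_deg / pixel_deg)
  band_of_row <- ((seq_len(npx) - 1) %/% band_px) %% 2  # 0 static, 1 displaced
  base <- matrix(profile, nrow = npx, ncol = npx, byrow = TRUE)
  modulated <- base
  if (any(band_of_row == 1)) {
    modulated[band_of_row == 1, ] <- matrix(shifted, nrow = sum(band_of_row == 1),
                                            ncol = npx, byrow = TRUE)
  }
  list(
    base = list(image = base, pixel_deg = pixel_deg, state = "base"),
    modulated = list(image = modulated, pixel_deg = pixel_deg,
                     state = "modulated")
  )
}

# 5x5 monospaced optotype-style bitmaps (Sloan letter set), 1 = ink
.optotype_font <- function() {
  raw <- list(
    C = c("11111", "10000", "10000", "10000", "11111"),
    D = c("11110", "10001", "10001", "10001", "11110"),
    H = c("10001", "10001", "11111", "10001", "10001"),
    K = c("10010", "10100", "11000", "10100", "10010"),
    N = c("10001", "11001", "10101", "10011", "10001"),
    O = c("01110", "10001", "10001", "10001", "01110"),
    R = c("11110", "10001", "11110", "10100", "10011"),
    S = c("01111", "10000", "01110", "00001", "11110"),
    V = c("10001", "10001", "10001", "01010", "00100"),
    Z = c("11111", "00010", "00100", "01000", "11111")
  )
  lapply(raw, function(rows) {
    do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  })
}

# nearest-neighbor upscale of a bitmap to h x h pixels
.scale_glyph <- function(glyph, h) {
  idx <- pmin(nrow(glyph), floor(seq(0, 1 - 1e-9, length.out = h) * nrow(glyph)) + 1)
  glyph[idx, idx, drop = FALSE]
}

#' Letter-array frame pair
#'
#' Builds the two alternation states of the letter stimulus: an array of
#' random optotype-style letters (`intact`) and a Fourier phase-scrambled
#' version (`scrambled`) with an identical 2D amplitude spectrum. Letters
#' are laid out with between-letter and between-line spacing of one
#' letter width/height. Phase scrambling preserves the mean luminance and
#' RMS contrast exactly but lets individual pixels stray outside \[0,1\]
#' (the scrambled frame is deliberately not clipped, so its spectrum
#' matches the intact frame's to numerical precision).
#'
#' @param letter_height_arcmin Letter height (arcmin); must map to >= 5 px.
#' @param field_deg Field height and width in degrees, default `c(9, 16)`.
#' @param pixel_deg Degrees per pixel.
#' @param contrast Michelson contrast of letters against the background.
#' @param seed Integer seed controlling letter identities and the
#'   scrambling phases.
#' @return List with elements `intact` and `scrambled` frames.
#' @export
make_letter_frames <- function(letter_height_arcmin, field_deg = c(9, 16),
                               pixel_deg = 1 / 60, contrast = 0.9, seed = 1) {
  h <- round(letter_height_arcmin / 60 / pixel_deg)
  if (h < 5) stop("letter height below 5 pixels; increase size or resolution")
  npx <- round(field_deg / pixel_deg)  # (rows, cols)
  pitch <- 2 * h                       # letter + one-letter-width spacing
  n_rows <- npx[1] %/% pitch
  n_cols <- npx[2] %/% pitch
  if (n_rows < 1 || n_cols < 1) stop("field too small for one letter")

  lum_bg <- 0.5 + contrast / 2
  lum_ink <- 0.5 - contrast / 2
  font <- .optotype_font()
  img <- matrix(lum_bg, npx[1], npx[2])
  .with_seed(seed, {
    ids <- sample(names(font), n_rows * n_cols, replace = TRUE)
    off_r <- (npx[1] - n_rows * pitch + h) %/% 2
    off_c <- (npx[2] - n_cols * pitch + h) %/% 2
    k <- 0
    for (r in seq_len(n_rows)) {
      for (cc in seq_len(n_cols)) {
        k <- k + 1
        g <- .scale_glyph(font[[ids[k]]], h)
        rr <- off_r + (r - 1) * pitch + seq_len(h)
        ccs <- off_c + (cc - 1) * pitch + seq_len(h)
        patch <- img[rr, ccs]
        patch[g == 1] <- lum_ink
        img[rr, ccs] <- patch
      }
    }
    f <- stats::fft(img)
    ref <- stats::fft(matrix(stats::runif(length(img)), nrow(img)))
    phase <- ref / ifelse(Mod(ref) > 0, Mod(ref), 1)
    scrambled <- Re(stats::fft(Mod(f) * phase, inverse = TRUE)) / length(img)
    list(
      intact = list(image = img, pixel_deg = pixel_deg, state = "base"),
      scrambled = list(image = scrambled, pixel_deg = pixel_deg,
                       state = "modulated")
    )
  })
}

#' Write a stimulus frame to PNG
#'
#' Clips to \[0,1\] for display; requires the `png` package.
#'
#' @param frame A frame as returned by [make_vernier_frames()] or
#'   [make_letter_frames()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  png::writePNG(pmin(pmax(frame$image, 0), 1), path)
  invisible(path)
}
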