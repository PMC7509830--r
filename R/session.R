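#' Construct a raw EEG session
#'
#' The session container used throughout the package: a channels x samples
#' voltage matrix (microvolts), its sampling rate, a trial event table and
#' the condition lookup table.
#'
#' Events use 0-based sample indices with half-open windows
#' `[onset, onset + duration_s * fs)`.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param events Data frame with columns `trial`, `block`, `condition`,
#'   `onset` (0-based sample index), `duration_s`.
#' @param condition_table Data frame with columns `condition`,
#'   `task` (`"vernier"` or `"letter"`), `logmar`, and optionally `level`.
#' @param stages Character vector of preprocessing stages already applied
#'   (normally left empty; managed by the preprocessing functions).
#' @param blinks Optional data frame of injected artifact windows
#'   (`onset`, `duration_s`), recorded by the simulator for validation.
#' @return An object of class `raw_session`.
#' @export
raw_session <- function(data, fs, events, condition_table,
                        stages = character(0), blinks = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), length(fs) == 1L, fs > 0)
  events <- tibble::as_tibble(events)
  condition_table <- tibble::as_tibble(condition_table)
  need_ev <- c("trial", "block", "condition", "onset", "duration_s")
  miss <- setdiff(need_ev, names(events))
  if (length(miss)) stop("events table is missing field(s): ",
                         paste(miss, collapse = ", "))
  need_ct <- c("condition", "task", "logmar")
  miss <- setdiff(need_ct, names(condition_table))
  if (length(miss)) stop("condition_table is missing field(s): ",
                         paste(miss, collapse = ", "))
  x <- structure(
    list(data = data, fs = fs, events = events,
         condition_table = condition_table,
         stages = stages, blinks = blinks),
    class = "raw_session"
  )
  validate_session(x)
  x
}

#' Validate a raw session
#'
#' Checks that all event windows fit within the data, that every event's
#' condition is present in the condition table, and that tasks are valid.
#'
#' @param session A `raw_session`.
#' @param config Optional [analysis_config()]; if given, also checks that
#'   the sampling rate exceeds twice the band-pass high edge.
#' @return The session, invisibly.
#' @export
validate_session <- function(session, config = NULL) {
  stopifnot(inherits(session, "raw_session"))
  ev <- session$events
  n <- ncol(session$data)
  ends <- ev$onset + round(ev$duration_s * session$fs)
  if (any(ev$onset < 0) || any(ends > n)) {
    stop("event windows do not fit within the data")
  }
  missing_cond <- setdiff(ev$condition, session$condition_table$condition)
  if (length(missing_cond)) {
    stop("events reference unknown condition(s): ",
         paste(missing_cond, collapse = ", "))
  }
  if (!all(session$condition_table$task %in% c("vernier", "letter"))) {
    stop("condition_table$task must be 'vernier' or 'letter'")
  }
  if (!is.null(config) && session$fs <= 2 * config$bandpass_hz[2]) {
    stop("sampling rate must exceed twice the band-pass high edge")
  }
  invisible(session)
}

#' @export
print.raw_session <- function(x, ...) {
  cat("<raw_session>", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$fs, "Hz,", nrow(x$events), "trials\n")
  if (length(x$stages)) cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the frequency-domain analysis constants: 3 Hz stimulus
#' alternation with harmonics at 1F = 3 Hz and 2F = 6 Hz, neighbor noise
#' bins at +/- 0.5 Hz, 2-s epochs after a 1-s discard, resampling to
#' 420 Hz (an integer 140 samples per 3 Hz cycle), a 0.3-50 Hz band-pass,
#' and the artifact rejection threshold.
#'
#' @param stim_freq_hz Stimulus alternation frequency (Hz).
#' @param epoch_len_s Epoch length in seconds; must contain an integer
#'   number of stimulus cycles.
#' @param discard_s Seconds discarded at the start of each trial (steady
#'   state settling).
#' @param resample_hz Analysis sampling rate; must give an integer number
#'   of samples per stimulus cycle.
#' @param bandpass_hz Length-2 band edges in Hz.
#' @param reject_threshold_uv Artifact threshold in microvolts; the
#'   per-subject range in the underlying protocol is 30-80.
#' @param max_bad_fraction Fraction of over-threshold samples above which
#'   an epoch is rejected. The default 0.05 guarantees that a blink-length
#'   artifact cannot evade screening by straddling two epochs (each side
#'   would fall below a 0.1 cutoff).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(stim_freq_hz = 3, epoch_len_s = 2, discard_s = 1,
                            resample_hz = 420, bandpass_hz = c(0.3, 50),
                            reject_threshold_uv = 60, max_bad_fraction = 0.05) {
  cycles <- epoch_len_s * stim_freq_hz
  if (abs(cycles - round(cycles)) > 1e-9) {
    stop("epoch_len_s * stim_freq_hz must be an integer number of cycles")
  }
  spc <- resample_hz / stim_freq_hz
  if (abs(spc - round(spc)) > 1e-9) {
    stop("resample_hz / stim_freq_hz must be an integer (samples per cycle)")
  }
  if (!(length(bandpass_hz) == 2L && bandpass_hz[1] < bandpass_hz[2])) {
    stop("bandpass_hz must be increasing band edges")
  }
  if (reject_threshold_uv < 30 || reject_threshold_uv > 80) {
    warning("reject_threshold_uv outside the conventional 30-80 uV range")
  }
  structure(
    list(
      stim_freq_hz = stim_freq_hz,
      harmonics = c(`1F` = stim_freq_hz, `2F` = 2 * stim_freq_hz),
      noise_bins_hz = list(`1F` = stim_freq_hz + c(-0.5, 0.5),
                           `2F` = 2 * stim_freq_hz + c(-0.5, 0.5)),
      epoch_len_s = epoch_len_s, discard_s = discard_s,
      resample_hz = resample_hz, bandpass_hz = bandpass_hz,
      reject_threshold_uv = reject_threshold_uv,
      max_bad_fraction = max_bad_fraction
    ),
    class = "analysis_config"
  )
}

# ---- serialization -------------------------------------------------------

#' Write a session to disk
#'
#' `"native"` is the package's own container: the 8-byte magic `SSVEPR01`,
#' a 4-byte little-endian header length, a JSON header (fields `fs`,
#' `n_channels`, `n_samples`, `events`, `condition_table`, `stages`,
#' `blinks`), then the voltage matrix as little-endian float64 in
#' channel-major order. It round-trips sessions losslessly.
#'
#' `"edf"` writes European Data Format (16-bit) for interoperability; the
#' event and condition tables go to a JSON sidecar `<path>.json` because
#' plain EDF has no annotation table. EDF quantizes voltages to the
#' per-channel physical range, so the round trip is only accurate to
#' ~1/65535 of the channel range.
#'
#' @param session A `raw_session`.
#' @param path Output file path.
#' @param dialect `"native"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, dialect = c("native", "edf")) {
  dialect <- match.arg(dialect)
  validate_session(session)
  if (dialect == "native") .write_native(session, path) else .write_edf(session, path)
  invisible(path)
}

#' Read a session from disk
#'
#' Reads the native ssvepr container or a 128-channel EDF file (with its
#' JSON sidecar holding the event and condition tables; see
#' [write_session()]). A channel count other than 128 is an error.
#'
#' @param path File path.
#' @param dialect `"native"` or `"edf"`.
#' @return A `raw_session`.
#' @export
read_session <- function(path, dialect = c("native", "edf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  s <- if (dialect == "native") .read_native(path) else .read_edf(path)
  if (nrow(s$data) != 128L) {
    stop("channel-count mismatch: expected 128 channels, found ", nrow(s$data))
  }
  s
}

.write_native <- function(session, path) {
  header <- list(
    fs = session$fs,
    n_channels = nrow(session$data),
    n_samples = ncol(session$data),
    events = session$events,
    condition_table = session$condition_table,
    stages = session$stages,
    blinks = session$blinks
  )
  hjson <- charToRaw(jsonlite::toJSON(header, dataframe = "columns",
                                      digits = NA, null = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SSVEPR01"), con)
  writeBin(as.integer(length(hjson)), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  writeBin(as.vector(session$data), con, size = 8L, endian = "little")
}

.read_native <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "SSVEPR01")) stop("not a native ssvepr session file")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  h <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  nval <- h$n_channels * h$n_samples
  x <- readBin(con, "double", nval, size = 8L, endian = "little")
  if (length(x) != nval) stop("truncated session file: ", path)
  if (is.null(h$events)) stop("session file is missing field: events")
  raw_session(
    data = matrix(x, nrow = h$n_channels),
    fs = as.numeric(h$fs),
    events = tibble::as_tibble(h$events),
    condition_table = tibble::as_tibble(h$condition_table),
    stages = as.character(unlist(h$stages)),
    blinks = if (is.null(h$blinks)) NULL else tibble::as_tibble(h$blinks)
  )
}

# fixed-width ASCII field, space padded
.edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

.write_edf <- function(session, path) {
  data <- session$data
  fs <- session$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer sampling rate")
  ns <- nrow(data)
  n_samples <- ncol(data)
  if (n_samples %% fs != 0) stop("EDF export needs a whole number of 1-s records")
  n_rec <- n_samples %/% fs
  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  pad <- pmax(1e-6, (pmax_ - pmin_) * 0.001)
  pmin_ <- pmin_ - pad; pmax_ <- pmax_ + pad
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(.edf_field(x, width)), con)
  wr("0", 8); wr("ssvepr synthetic", 80); wr("ssvepr session", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (i in seq_len(ns)) wr(sprintf("EEG %03d", i), 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(formatC(pmin_[i], digits = 5, format = "g"), 8)
  for (i in seq_len(ns)) wr(formatC(pmax_[i], digits = 5, format = "g"), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round((data[, idx] - pmin_) * scale + dmin)
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  sidecar <- list(events = session$events,
                  condition_table = session$condition_table,
                  stages = session$stages)
  writeLines(jsonlite::toJSON(sidecar, dataframe = "columns", digits = NA),
             paste0(path, ".json"))
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(rawToChar(readBin(con, "raw", width)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  per(16); per(80); per(8)
  pmin_ <- as.numeric(per(8)); pmax_ <- as.numeric(per(8))
  dmin <- as.numeric(per(8)); dmax <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8))
  per(32)
  if (length(unique(spr)) != 1L) stop("EDF with heterogeneous rates unsupported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw_block <- readBin(con, "integer", ns * spr[1], size = 2L,
                         signed = TRUE, endian = "little")
    block <- matrix(raw_block, nrow = spr[1])  # samples x signals
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(block) * scale + (pmin_ - dmin * scale)
  }
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("EDF session is missing field: events (no sidecar ", sidecar_path, ")")
  }
  sc <- jsonlite::fromJSON(sidecar_path)
  if (is.null(sc$events)) stop("EDF sidecar is missing field: events")
  raw_session(
    data = data, fs = fs,
    events = tibble::as_tibble(sc$events),
    condition_table = tibble::as_tibble(sc$condition_table),
    stages = as.character(unlist(sc$stages))
  )
}
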