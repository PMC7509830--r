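#' Load a packaged 128-sensor montage
#'
#' Reads a sensor geometry packaged with ssvepr and builds the neighbor
#' structure used for bad-channel replacement and topographic plotting.
#' Sensors lie on the unit sphere with the nose along +y, the vertex along
#' +z and the left ear along -x. Neighbors are the 6 nearest sensors by
#' chord distance, symmetrized (so a sensor can end up with more than 6).
#'
#' The packaged layout `"geodesic128"` is a synthetic geodesic-style
#' approximation of a 128-channel sensor net: sensor numbering places the
#' conventional posterior electrodes of interest (65, 66, 75, 83, 90, 91)
#' at left-lateral, medial and right-lateral occipital positions. No
#' analysis in the package depends on absolute sensor coordinates beyond
#' this neighbor structure.
#'
#' @param resource_name Name of a packaged layout. Currently `"geodesic128"`.
#' @return An object of class `eeg_montage`: a list with `sensors`
#'   (tibble: `sensor`, `x`, `y`, `z`) and `neighbors` (list of integer
#'   vectors indexed by sensor id).
#' @export
#' @examples
#' mon <- load_montage()
#' length(mon$neighbors[[75]])
load_montage <- function(resource_name = "geodesic128") {
  file <- switch(resource_name,
    geodesic128 = system.file("extdata", "geodesic128_synthetic.tsv",
                              package = "ssvepr"),
    stop("unknown montage resource: ", resource_name)
  )
  if (!nzchar(file) || !file.exists(file)) {
    stop("montage resource file not found for '", resource_name, "'")
  }
  tab <- utils::read.delim(file, sep = "\t")
  if (!all(c("sensor", "x", "y", "z") %in% names(tab))) {
    stop("malformed montage resource: need columns sensor, x, y, z")
  }
  if (nrow(tab) != 128L || !identical(sort(tab$sensor), 1:128)) {
    stop("malformed montage resource: expected sensors 1..128, got ",
         nrow(tab), " rows")
  }
  tab <- tab[order(tab$sensor), ]
  pos <- as.matrix(tab[, c("x", "y", "z")])
  nbr <- .knn_neighbors(pos, k = 6L)
  out <- list(
    name = resource_name,
    sensors = tibble::as_tibble(tab),
    neighbors = nbr
  )
  class(out) <- "eeg_montage"
  validate_montage(out)
  out
}

# symmetrized k-nearest-neighbor lists by chord distance
.knn_neighbors <- function(pos, k = 6L) {
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    adj[i, order(d[i, ])[seq(2L, k + 1L)]] <- TRUE
  }
  adj <- adj | t(adj)
  lapply(seq_len(n), function(i) which(adj[i, ]))
}

#' Validate montage invariants
#'
#' Checks sensor count, unit-norm positions, neighbor symmetry, minimum
#' degree and connectivity of the neighbor graph.
#'
#' @param montage An `eeg_montage`.
#' @return The montage, invisibly. Errors if an invariant is violated.
#' @export
validate_montage <- function(montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (nrow(montage$sensors) != 128L) stop("montage must have 128 sensors")
  pos <- montage_positions(montage)
  if (any(abs(sqrt(rowSums(pos^2)) - 1) > 1e-3)) {
    stop("montage positions must lie on the unit sphere")
  }
  nbr <- montage$neighbors
  deg <- lengths(nbr)
  if (any(deg < 3L)) stop("every sensor needs >= 3 neighbors")
  for (i in seq_along(nbr)) {
    for (j in nbr[[i]]) {
      if (!(i %in% nbr[[j]])) stop("neighbor relation not symmetric")
    }
  }
  # connectivity via breadth-first search
  seen <- logical(128L); seen[1L] <- TRUE; queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (j in nbr[[i]]) if (!seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
  }
  if (!all(seen)) stop("montage neighbor graph is not connected")
  invisible(montage)
}

#' Sensor positions as a matrix
#'
#' @param montage An `eeg_montage`.
#' @return 128 x 3 numeric matrix (rows ordered by sensor id).
#' @export
montage_positions <- function(montage) {
  as.matrix(montage$sensors[, c("x", "y", "z")])
}

#' k nearest sensors by chord distance
#'
#' Used by bad-channel replacement: returns the `k` sensors nearest to
#' `sensor`, excluding `exclude` (e.g. other bad channels) and the sensor
#' itself. The search is over all sensors, not just adjacency, so it can
#' widen past the immediate neighborhood when exclusions remove candidates.
#'
#' @param montage An `eeg_montage`.
#' @param sensor Sensor id (1..128).
#' @param k Number of sensors to return.
#' @param exclude Integer vector of sensor ids to skip.
#' @return Integer vector of `k` sensor ids, nearest first.
#' @export
nearest_sensors <- function(montage, sensor, k = 6L, exclude = integer(0)) {
  pos <- montage_positions(montage)
  d <- sqrt(colSums((t(pos) - pos[sensor, ])^2))
  d[c(sensor, exclude)] <- Inf
  ok <- which(is.finite(d))
  if (length(ok) < k) stop("fewer than ", k, " candidate sensors available")
  order(d)[seq_len(k)]
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage>", x$name, "- 128 sensors,",
      "median degree", stats::median(lengths(x$neighbors)), "\n")
  invisible(x)
}
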