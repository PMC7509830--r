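# Generates inst/extdata/geodesic128_synthetic.tsv: a synthetic 128-sensor
# geodesic-style layout on the unit sphere (nose +y, vertex +z, left -x).
# Points are placed by a golden-angle spiral over a spherical cap reaching
# just below the equator (ears/occiput coverage), then ids are relabeled so
# the electrodes of interest (65, 66, 75, 83, 90, 91) sit at plausible
# posterior scalp positions. Coordinates are synthetic: only the neighbor
# structure and rough anatomy matter to the package.

n <- 128
z_min <- -0.35
golden <- pi * (3 - sqrt(5))

k <- seq_len(n)
z <- seq(1 - 0.5 / n, z_min + 0.5 / n, length.out = n) * 1 # vertex -> rim
theta <- golden * (k - 1)
r <- sqrt(pmax(0, 1 - z^2))
x <- r * cos(theta)
y <- r * sin(theta)
pos <- cbind(x, y, z)
pos <- pos / sqrt(rowSums(pos^2))

anchors <- list(
  `75` = c( 0.00, -0.99,  0.02),   # occipital pole (Oz-like)
  `65` = c(-0.62, -0.74,  0.12),   # left lateral occipital
  `66` = c(-0.45, -0.86,  0.20),
  `83` = c( 0.33, -0.92,  0.10),   # right medial-posterior
  `90` = c( 0.62, -0.74,  0.12),   # right lateral occipital
  `91` = c( 0.74, -0.60,  0.20)
)

ord <- seq_len(n)  # ord[i] = row of pos assigned to sensor id i
claimed <- integer(0)
for (id_chr in names(anchors)) {
  id <- as.integer(id_chr)
  a <- anchors[[id_chr]]
  a <- a / sqrt(sum(a^2))
  d <- colSums((t(pos[ord, ]) - a)^2)
  d[claimed] <- Inf
  j <- which.min(d)  # sensor id currently nearest the anchor
  tmp <- ord[id]; ord[id] <- ord[j]; ord[j] <- tmp
  claimed <- c(claimed, id)
}
pos <- pos[ord, ]

# sanity: 6-NN symmetrized graph is connected, all degrees >= 3
D <- as.matrix(dist(pos))
adj <- matrix(FALSE, n, n)
for (i in seq_len(n)) {
  nb <- order(D[i, ])[2:7]
  adj[i, nb] <- TRUE
}
adj <- adj | t(adj)
stopifnot(all(rowSums(adj) >= 3))
reach <- 1L
repeat {
  new <- unique(c(reach, which(rowSums(adj[reach, , drop = FALSE]) > 0)))
  new <- sort(unique(c(new, unlist(lapply(reach, function(i) which(adj[i, ]))))))
  if (length(new) == length(reach)) break
  reach <- new
}
stopifnot(length(reach) == n)

out <- data.frame(
  sensor = seq_len(n),
  x = round(pos[, 1], 6),
  y = round(pos[, 2], 6),
  z = round(pos[, 3], 6)
)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(out, "inst/extdata/geodesic128_synthetic.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote", nrow(out), "sensors\n")
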