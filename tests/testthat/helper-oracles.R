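# Independent oracles and small geometric fixtures used across the suite.
# These deliberately use brute-force / closed-form routes distinct from the
# package implementation.

# Brute-force mean distance to the k nearest neighbours (O(n^2)).
brute_knn_mean_dist <- function(xyz, k) {
  n <- nrow(xyz)
  vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    mean(sort(d[-i])[seq_len(k)])
  }, numeric(1))
}

# Exhaustive Otsu: between-class variance at every bin edge, from raw values.
brute_otsu <- function(v, n_bins = 256L) {
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / n_bins
  edges <- lo + seq_len(n_bins - 1L) * width
  sb <- vapply(edges, function(t) {
    c0 <- v[v < t]; c1 <- v[v >= t]
    if (length(c0) == 0L || length(c1) == 0L) return(-Inf)
    w0 <- length(c0) / length(v)
    w1 <- 1 - w0
    w0 * w1 * (mean(c0) - mean(c1))^2
  }, numeric(1))
  edges[which.max(sb)]
}

# Closed-form OLS via the normal equations.
normal_eq_fit <- function(a, e) {
  X <- cbind(1, a)
  beta <- solve(t(X) %*% X, t(X) %*% e)
  list(intercept = beta[1], slope = beta[2])
}

# A large flat square sheet at z = 0 (two triangles), side `side` cm.
flat_sheet <- function(side = 40) {
  triangle_mesh(
    rbind(c(0, 0, 0), c(side, 0, 0), c(side, side, 0), c(0, side, 0)),
    rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  )
}

# Evenly spaced points on a circle: by symmetry every point has identical
# k-NN mean distance, the textbook case the statistical filter must not touch.
ring_cloud <- function(n = 100, radius = 5) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  point_cloud(cbind(radius * cos(ang), radius * sin(ang), 0))
}

# Regular planar grid cloud at z = 0.
grid_cloud <- function(nx = 10, ny = 10, spacing = 1) {
  g <- expand.grid(x = seq_len(nx) * spacing, y = seq_len(ny) * spacing)
  point_cloud(cbind(g$x, g$y, 0))
}

# A vertical open stem tube cloud (deterministic ring sampling).
stem_tube_cloud <- function(height = 12, radius = 0.15, n_ring = 16,
                            n_z = 240) {
  ang <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  zs <- seq(0, height, length.out = n_z)
  point_cloud(cbind(
    radius * rep(cos(ang), times = n_z),
    radius * rep(sin(ang), times = n_z),
    rep(zs, each = n_ring)
  ))
}

expect_mesh_equal <- function(a, b) {
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
}
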