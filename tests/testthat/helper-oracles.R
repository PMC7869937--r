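# Independent brute-force oracles and small cloud builders shared across the
# suite. Everything here recomputes quantities from first principles (O(n^2)
# searches, closed-form geometry) so it never shares code paths with the
# package implementation.

random_cloud <- function(n, seed, xr = c(0, 2), yr = c(0, 2), zr = c(0, 0.5)) {
  withr::with_seed(seed, point_cloud(
    x = runif(n, xr[1], xr[2]), y = runif(n, yr[1], yr[2]),
    z = runif(n, zr[1], zr[2]),
    r = sample(0:255, n, TRUE), g = sample(0:255, n, TRUE),
    b = sample(0:255, n, TRUE)))
}

grid_cloud <- function(nx, ny, step = 0.1, z = 0, g = 160) {
  gdf <- expand.grid(x = (seq_len(nx) - 1) * step,
                     y = (seq_len(ny) - 1) * step)
  point_cloud(gdf$x, gdf$y, rep(z, nrow(gdf)),
              r = 80, g = g, b = 40)
}

# closed-form orthogonal distance of p to the TLS plane of rows `nb`
oracle_plane_distance <- function(p, nb) {
  ctr <- colMeans(nb)
  cc <- sweep(nb, 2, ctr)
  sv <- svd(cc)
  normal <- sv$v[, 3]
  abs(sum((p - ctr) * normal))
}

# O(n^2) per-point roughness: exhaustive neighbor search + SVD plane fit
oracle_roughness <- function(xyz, radius) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  vapply(seq_len(n), function(i) {
    ni <- which(d[i, ] <= radius & seq_len(n) != i)
    if (length(ni) < 3) return(NA_real_)
    nb <- xyz[ni, , drop = FALSE]
    cc <- sweep(nb, 2, colMeans(nb))
    sv <- svd(cc)
    if (sv$d[2] <= max(sv$d[1], .Machine$double.eps) * 1e-6)
      return(NA_real_)
    oracle_plane_distance(xyz[i, ], nb)
  }, 0)
}

# O(n^2) mean distance to the k nearest neighbors
oracle_knn_mean_dist <- function(xyz, k) {
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  apply(d, 1, function(row) mean(sort(row)[seq_len(k)]))
}

# ray-casting point-in-polygon (boundary handled by on-segment test)
oracle_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  on_edge <- function(x, y) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- ring[i, 1]; y1 <- ring[i, 2]
      x2 <- ring[j, 1]; y2 <- ring[j, 2]
      cross <- (x - x1) * (y2 - y1) - (y - y1) * (x2 - x1)
      if (abs(cross) < 1e-12 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12)
        return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    if (on_edge(x, y)) return(TRUE)
    inside <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- ring[i, 2]; y2 <- ring[j, 2]
      if ((y1 > y) != (y2 > y)) {
        xint <- ring[i, 1] + (y - y1) / (y2 - y1) * (ring[j, 1] - ring[i, 1])
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

# brute-force flood fill over a set of voxel coordinate rows
oracle_components <- function(vox, connectivity = 26) {
  n <- nrow(vox)
  lab <- integer(n)
  adjacent <- function(a, b) {
    d <- abs(vox[a, ] - vox[b, ])
    if (max(d) > 1) return(FALSE)
    if (connectivity == 6) sum(d) == 1 else max(d) == 1
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (b in seq_len(n)) {
        if (lab[b] == 0L && adjacent(a, b)) {
          lab[b] <- cur
          queue <- c(queue, b)
        }
      }
    }
  }
  lab
}

min_pairwise_dist <- function(xyz) min(stats::dist(xyz))

pc_mat <- function(pc) cbind(pc$x, pc$y, pc$z)
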