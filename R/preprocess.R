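#' Statistical outlier removal
#'
#' The classic k-nearest-neighbor distance filter for photogrammetric point
#' clouds. For every point the mean Euclidean distance to its `k` nearest
#' neighbors is computed; a single Gaussian is fitted to these per-point mean
#' distances over the whole cloud, and points whose mean distance exceeds
#' \eqn{\mu + n_\sigma \sigma} are removed. The threshold is one-sided: short
#' distances indicate agreement with the surface, not outliers.
#'
#' @param cloud A point-cloud tibble with more than `k` points.
#' @param k Neighborhood size (default 20).
#' @param n_sigma Gaussian threshold multiplier (default 3).
#' @return The filtered cloud (stage `"filtered"`), with a [filter_report()]
#'   attribute recording counts and thresholds.
#' @seealso [plane_fit_outlier_removal()]
#' @export
statistical_outlier_removal <- function(cloud, k = 20, n_sigma = 3) {
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud)
  if (n <= k)
    stop("cloud has ", n, " points but k = ", k,
         "; lower k below the point count", call. = FALSE)
  nn <- RANN::nn2(pc_xyz(cloud), k = k + 1)        # first neighbor is self
  mean_dist <- rowMeans(nn$nn.dists[, -1, drop = FALSE])
  mu <- mean(mean_dist)
  sigma <- stats::sd(mean_dist)
  thr <- mu + n_sigma * sigma
  keep <- mean_dist <= thr | sigma == 0
  out <- set_stage(cloud[keep, , drop = FALSE], "filtered")
  attr(out, "filter_report") <- tibble::tibble(
    filter = "statistical", k = k, n_sigma = n_sigma,
    n_input = n, n_removed = sum(!keep),
    mean = mu, sd = sigma, threshold = thr, n_degenerate = 0L)
  out
}

#' Plane-fit outlier removal
#'
#' For every point a total-least-squares plane is fitted to its `k` nearest
#' neighbors (query excluded) and the point's orthogonal distance to that
#' plane is recorded. A Gaussian is fitted to these distances over the whole
#' cloud and points with distance above \eqn{\mu + n_\sigma \sigma} are
#' removed. Points whose neighborhood is degenerate (all neighbors collinear,
#' so no plane is defined) are retained and counted in the report.
#'
#' @inheritParams statistical_outlier_removal
#' @return The filtered cloud (stage `"filtered"`) with a [filter_report()]
#'   attribute.
#' @export
plane_fit_outlier_removal <- function(cloud, k = 20, n_sigma = 3) {
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud)
  if (n <= k)
    stop("cloud has ", n, " points but k = ", k,
         "; lower k below the point count", call. = FALSE)
  xyz <- pc_xyz(cloud)
  nn <- RANN::nn2(xyz, k = k + 1)
  dist <- plane_distances(xyz, nn$nn.idx[, -1, drop = FALSE])
  n_degenerate <- sum(is.na(dist))
  ok <- !is.na(dist)
  mu <- mean(dist[ok])
  sigma <- stats::sd(dist[ok])
  thr <- mu + n_sigma * sigma
  keep <- is.na(dist) | dist <= thr | sigma == 0
  if (n_degenerate > 0)
    warning(n_degenerate,
            " point(s) had degenerate (collinear) neighborhoods; retained",
            call. = FALSE)
  out <- set_stage(cloud[keep, , drop = FALSE], "filtered")
  attr(out, "filter_report") <- tibble::tibble(
    filter = "plane_fit", k = k, n_sigma = n_sigma,
    n_input = n, n_removed = sum(!keep),
    mean = mu, sd = sigma, threshold = thr, n_degenerate = n_degenerate)
  out
}

#' Retrieve the report attached by an outlier filter
#'
#' @param cloud A cloud returned by [statistical_outlier_removal()] or
#'   [plane_fit_outlier_removal()].
#' @return A one-row tibble of counts and thresholds, or `NULL`.
#' @export
filter_report <- function(cloud) attr(cloud, "filter_report", exact = TRUE)

# Orthogonal distance of each point to the TLS plane of its listed neighbors.
# idx: n x k matrix of neighbor row indices (0 = missing). NA where the
# neighborhood is degenerate (rank < 2 after centering).
plane_distances <- function(xyz, idx) {
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ni <- idx[i, ]
    ni <- ni[ni > 0L]
    if (length(ni) < 3L) { out[i] <- NA_real_; next }
    nb <- xyz[ni, , drop = FALSE]
    ctr <- colMeans(nb)
    cc <- sweep(nb, 2, ctr)
    cv <- crossprod(cc) / nrow(cc)
    ev <- eigen(cv, symmetric = TRUE)
    # collinear: the two smallest eigenvalues both ~ 0 relative to the largest
    if (ev$values[2] <= max(ev$values[1], .Machine$double.eps) * 1e-12) {
      out[i] <- NA_real_
      next
    }
    normal <- ev$vectors[, 3]
    out[i] <- abs(sum((xyz[i, ] - ctr) * normal))
  }
  out
}

#' Read height-bar reference elevations
#'
#' @param path CSV with columns `bar_id, measured_z, cloud_z` (meters): the
#'   surveyed elevation of each reference bar and the elevation read off the
#'   point cloud at the bar.
#' @return A tibble of height bars.
#' @export
read_height_bars <- function(path) {
  bars <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("bar_id", "measured_z", "cloud_z")
  if (!all(need %in% names(bars)))
    stop("height-bar file needs columns ", toString(need), call. = FALSE)
  if (any(!is.finite(bars$measured_z)) || any(!is.finite(bars$cloud_z)))
    stop("height-bar elevations must be finite", call. = FALSE)
  bars
}

#' Calibrate cloud elevation against surveyed height bars
#'
#' Shifts the whole cloud in z by the mean of (surveyed elevation − cloud
#' elevation) over the reference bars, so the cloud's height datum matches the
#' survey. The applied offset and the per-bar residuals after the shift are
#' attached as attributes.
#'
#' @param cloud A point-cloud tibble.
#' @param bars A tibble with columns `bar_id`, `measured_z`, `cloud_z`
#'   (see [read_height_bars()]).
#' @return The shifted cloud; `height_offset()` returns the offset in meters
#'   and `height_residuals()` the per-bar residual tibble.
#' @export
adjust_height <- function(cloud, bars) {
  cloud <- as_point_cloud(cloud)
  if (is.null(bars) || nrow(bars) == 0)
    stop("adjust_height needs at least one height bar", call. = FALSE)
  if (any(!is.finite(bars$measured_z)) || any(!is.finite(bars$cloud_z)))
    stop("height-bar elevations must be finite", call. = FALSE)
  offs <- bars$measured_z - bars$cloud_z
  offset <- mean(offs)
  out <- cloud
  out$z <- out$z + offset
  attr(out, "height_offset") <- offset
  attr(out, "height_residuals") <- tibble::tibble(
    bar_id = bars$bar_id,
    residual = bars$measured_z - (bars$cloud_z + offset))
  out
}

#' @rdname adjust_height
#' @export
height_offset <- function(cloud) attr(cloud, "height_offset", exact = TRUE)

#' @rdname adjust_height
#' @export
height_residuals <- function(cloud) attr(cloud, "height_residuals",
                                         exact = TRUE)
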