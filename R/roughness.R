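#' Per-point surface roughness
#'
#' The roughness of a point is its Euclidean distance (meters) to the
#' total-least-squares plane of all *other* points within a sphere of the
#' given radius. The query point is excluded from its own plane fit — the
#' distance is measured to the surface the neighbors define, not to one the
#' point itself helped place. Points with fewer than 3 neighbors, or with a
#' degenerate (collinear) neighborhood, get `NA` roughness and are counted.
#'
#' The statistic is invariant under rigid motions of the cloud.
#'
#' @param cloud A point-cloud tibble.
#' @param radius Neighborhood sphere radius in meters (default 0.10).
#' @return `cloud` with an additional `roughness` column (meters, `NA` where
#'   undefined); `attr(, "n_undefined")` counts the undefined points.
#' @export
point_roughness <- function(cloud, radius = 0.10) {
  cloud <- as_point_cloud(cloud)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  n <- nrow(cloud)
  out <- cloud
  if (n == 0) {
    out$roughness <- numeric(0)
    attr(out, "n_undefined") <- 0L
    return(out)
  }
  xyz <- pc_xyz(cloud)
  idx <- radius_neighbors(xyz, radius)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    ni <- idx[[i]]
    if (length(ni) < 3L) { vals[i] <- NA_real_; next }
    nb <- xyz[ni, , drop = FALSE]
    ctr <- colMeans(nb)
    cc <- sweep(nb, 2, ctr)
    ev <- eigen(crossprod(cc), symmetric = TRUE)
    if (ev$values[2] <= max(ev$values[1], .Machine$double.eps) * 1e-12) {
      vals[i] <- NA_real_  # collinear neighbors: no plane
      next
    }
    vals[i] <- abs(sum((xyz[i, ] - ctr) * ev$vectors[, 3]))
  }
  out$roughness <- vals
  attr(out, "n_undefined") <- sum(is.na(vals))
  out
}

# all-other-points-within-radius neighbor lists (self excluded), growing k
# until every neighborhood fits
radius_neighbors <- function(xyz, radius) {
  n <- nrow(xyz)
  k <- min(n, 33L)
  repeat {
    nn <- RANN::nn2(xyz, xyz, k = k, searchtype = "radius", radius = radius)
    full <- nn$nn.idx[, k] != 0L
    if (!any(full) || k == n) break
    k <- min(n, k * 4L)
  }
  lapply(seq_len(n), function(i) {
    ids <- nn$nn.idx[i, ]
    ids[ids != 0L & ids != i]
  })
}

#' Plot-level canopy roughness
#'
#' Aggregates a field of per-point roughness values into the plot-level
#' canopy roughness trait
#' \deqn{CR = IQR \times med,}
#' the product of the interquartile range and the median of the point
#' roughness values, in square meters. Both factors are lengths, so CR scales
#' with the square of any uniform scaling of the roughness values; a flat
#' canopy (constant roughness) has CR = 0. Quantiles use linear interpolation
#' of order statistics (R's default type 7), fixed for reproducibility.
#' Undefined (`NA`) roughness values are excluded rather than zero-filled —
#' zero-filling would deflate the median on sparse plots.
#'
#' @param roughness Either a cloud with a `roughness` column (as returned by
#'   [point_roughness()]) or a bare numeric vector of roughness values in
#'   meters. At least 4 defined values are required for the quartiles.
#' @param variant `"product"` (default) computes `IQR * med`; `"ratio"`
#'   computes `IQR / med`, retained for sensitivity analysis.
#' @return A one-row tibble: `n_points`, `n_undefined`, `med_m`, `iqr_m`,
#'   `cr_m2`.
#' @export
canopy_roughness <- function(roughness, variant = c("product", "ratio")) {
  variant <- match.arg(variant)
  if (is.data.frame(roughness)) {
    if (is.null(roughness$roughness))
      stop("data frame has no `roughness` column", call. = FALSE)
    values <- roughness$roughness
  } else {
    values <- as.numeric(roughness)
  }
  n_undef <- sum(is.na(values))
  vals <- values[!is.na(values)]
  if (length(vals) < 4)
    stop("canopy roughness needs >= 4 defined point-roughness values (got ",
         length(vals), ")", call. = FALSE)
  if (any(vals < 0)) stop("roughness values must be >= 0", call. = FALSE)
  med <- stats::median(vals)
  qs <- stats::quantile(vals, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  cr <- if (variant == "product") iqr * med else iqr / med
  tibble::tibble(n_points = length(vals), n_undefined = n_undef,
                 med_m = med, iqr_m = iqr, cr_m2 = cr)
}

#' Canopy roughness for every plot of a field
#'
#' Runs the per-plot trait chain on a (vegetation) point cloud: clip to the
#' plot polygon, split into rows by voxel connected components, drop the two
#' border rows, pool the interior-row points, compute per-point roughness,
#' and aggregate with [canopy_roughness()]. Plots that fail anywhere along
#' the chain (empty clip, fewer than 3 rows, too few defined roughness
#' values) are reported with a reason instead of aborting the field.
#'
#' @param cloud A point-cloud tibble. If a `class` column is present only the
#'   vegetation points are used.
#' @param plot_map A plot-map tibble.
#' @param radius Roughness neighborhood radius (default 0.10 m).
#' @param grid_step,min_cluster_size,connectivity,across Row-extraction
#'   parameters, see [extract_rows()].
#' @param drop_border Drop the first and last row of each plot (default
#'   TRUE).
#' @param variant Canopy-roughness variant, see [canopy_roughness()].
#' @return A tibble with one row per plot: `plot_id`, `genotype`, `status`
#'   (`"ok"` or a failure reason), `n_points`, `n_undefined`, `med_m`,
#'   `iqr_m`, `cr_m2`.
#' @export
compute_plot_traits <- function(cloud, plot_map, radius = 0.10,
                                grid_step = 0.15, min_cluster_size = 50,
                                connectivity = 26, across = "x",
                                drop_border = TRUE,
                                variant = "product") {
  cloud <- as_point_cloud(cloud)
  plot_map <- as_plot_map(plot_map)
  if (!is.null(cloud$class)) cloud <- vegetation_points(cloud)
  geno <- plot_genotypes(plot_map)
  ids <- unique(plot_map$plot_id)
  purrr::map_dfr(ids, function(pid) {
    base <- tibble::tibble(plot_id = pid,
                           genotype = geno$genotype[geno$plot_id == pid][1],
                           status = "ok", n_points = NA_integer_,
                           n_undefined = NA_integer_, med_m = NA_real_,
                           iqr_m = NA_real_, cr_m2 = NA_real_)
    res <- tryCatch({
      pc <- clip_by_polygon(cloud, plot_map, plot_id = pid)
      if (nrow(pc) == 0) stop("empty plot after clipping")
      rows <- extract_rows(pc, grid_step = grid_step,
                           min_cluster_size = min_cluster_size,
                           connectivity = connectivity, across = across)
      if (drop_border) rows <- drop_border_rows(rows)
      rough <- point_roughness(rows, radius = radius)
      cr <- canopy_roughness(rough, variant = variant)
      base$n_points <- cr$n_points
      base$n_undefined <- cr$n_undefined
      base$med_m <- cr$med_m
      base$iqr_m <- cr$iqr_m
      base$cr_m2 <- cr$cr_m2
      base
    }, error = function(e) {
      base$status <- conditionMessage(e)
      base
    })
    res
  })
}

#' Write a plot-trait table to CSV
#'
#' @param traits The tibble from [compute_plot_traits()], optionally joined
#'   with measured AGB.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plot_traits <- function(traits, path) {
  readr::write_csv(traits, path)
  invisible(path)
}
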