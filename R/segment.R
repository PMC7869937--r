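#' Radiometric vegetation/soil classification
#'
#' Labels every point vegetation or soil by a single cut-off on the green
#' color band (8-bit). Under the default direction, points with
#' `g >= green_cutoff` are vegetation (greener = plant at a dense canopy
#' stage); soil radiometry varies, so the direction is exposed as a flag. The
#' split is an exact partition and re-running it is idempotent.
#'
#' @param cloud A point-cloud tibble.
#' @param green_cutoff 8-bit green threshold (default 115).
#' @param direction `"veg_ge_cutoff"` (default) or `"veg_lt_cutoff"`.
#' @return `cloud` with an additional factor column `class` (levels
#'   `vegetation`, `soil`); attributes `green_cutoff` and `class_counts`.
#' @export
classify_vegetation <- function(cloud, green_cutoff = 115,
                                direction = c("veg_ge_cutoff",
                                              "veg_lt_cutoff")) {
  cloud <- as_point_cloud(cloud)
  direction <- match.arg(direction)
  if (green_cutoff < 0 || green_cutoff > 255)
    stop("green_cutoff must lie in [0, 255]", call. = FALSE)
  is_veg <- if (direction == "veg_ge_cutoff") cloud$g >= green_cutoff
            else cloud$g < green_cutoff
  out <- cloud
  out$class <- factor(ifelse(is_veg, "vegetation", "soil"),
                      levels = c("vegetation", "soil"))
  attr(out, "green_cutoff") <- green_cutoff
  attr(out, "class_counts") <- c(vegetation = sum(is_veg),
                                 soil = sum(!is_veg))
  set_stage(out, "vegetation")
}

#' Extract the vegetation subset of a classified cloud
#'
#' @param classified A cloud returned by [classify_vegetation()].
#' @return The vegetation points only.
#' @export
vegetation_points <- function(classified) {
  if (is.null(classified$class))
    stop("cloud has no `class` column; run classify_vegetation() first",
         call. = FALSE)
  set_stage(classified[classified$class == "vegetation", , drop = FALSE],
            "vegetation")
}

#' Audit a classification against reference labels
#'
#' Emulates a manual accuracy check: draws `n_sample` points without
#' replacement (all points if the cloud is smaller), crosses predicted against
#' reference labels, and reports overall accuracy and Cohen's kappa from the
#' 2x2 confusion table.
#'
#' @param classified A cloud with a `class` column.
#' @param truth Character/factor vector of reference labels
#'   (`"vegetation"`/`"soil"`), aligned with the cloud rows.
#' @param n_sample Number of audit points (default 1000).
#' @param seed Integer seed for the sample.
#' @return A list with `accuracy`, `kappa`, `n_audited` and the `confusion`
#'   table.
#' @export
audit_classification <- function(classified, truth, n_sample = 1000, seed) {
  if (is.null(classified$class))
    stop("cloud has no `class` column", call. = FALSE)
  n <- nrow(classified)
  if (length(truth) != n)
    stop("truth labels (", length(truth), ") do not align with cloud rows (",
         n, ")", call. = FALSE)
  take <- if (n_sample >= n) seq_len(n)
          else withr::with_seed(seed, sample.int(n, n_sample))
  lv <- c("vegetation", "soil")
  pred <- factor(as.character(classified$class[take]), levels = lv)
  ref <- factor(as.character(truth)[take], levels = lv)
  tab <- table(pred = pred, ref = ref)
  acc <- sum(diag(tab)) / sum(tab)
  # Cohen's kappa from the confusion table
  pe <- sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) 1 else (acc - pe) / (1 - pe)
  list(accuracy = acc, kappa = kappa, n_audited = length(take),
       confusion = tab)
}

## ---- voxel connected components --------------------------------------------

# integer voxel coordinates, origin at the cloud minimum corner
voxelize <- function(xyz, grid_step) {
  origin <- apply(xyz, 2, min)
  iv <- floor(sweep(xyz, 2, origin) / grid_step)
  # guard against points exactly on the max face landing in their own cell
  storage.mode(iv) <- "integer"
  iv
}

# component label per voxel (rows of unique voxel matrix), via igraph
voxel_components <- function(vox, connectivity = 26) {
  n <- nrow(vox)
  span <- max(vox) - min(vox) + 3L
  enc <- function(m) (as.numeric(m[, 1]) * span + m[, 2]) * span + m[, 3]
  key <- enc(vox)
  lookup <- stats::setNames(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  edges <- integer(0)
  for (j in seq_len(nrow(offs))) {
    nb_key <- as.character(enc(sweep(vox, 2, -offs[j, ])))
    hit <- lookup[nb_key]
    src <- which(!is.na(hit))
    if (length(src)) edges <- c(edges, rbind(src, unname(hit[src])))
  }
  if (length(edges) == 0) return(seq_len(n))
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Extract plant rows by voxel connected components
#'
#' Discretizes the plot into a regular 3-D grid (`grid_step`, origin at the
#' plot's minimum corner), links occupied voxels into connected components
#' (26-connectivity by default, 6 as an option), and assigns each point its
#' voxel's component. Components with fewer than `min_cluster_size` points
#' cannot represent homogeneous plant growth and are discarded. Surviving
#' components are numbered `row_id = 1, 2, ...` in order of their mean
#' coordinate along `across`, the axis perpendicular to the planting rows.
#'
#' @param plot_cloud A non-empty point-cloud tibble (one plot's vegetation).
#' @param grid_step Voxel edge length in meters (default 0.15).
#' @param min_cluster_size Minimum points per retained cluster (default 50;
#'   clusters with fewer than 50 points are removed, 50 or more are kept).
#' @param connectivity 26 (default) or 6.
#' @param across Name of the cross-row coordinate, `"x"` (default) or `"y"`.
#' @return The points of the retained clusters, with a `row_id` column and
#'   stage `"row"`. `attr(, "row_summary")` tabulates per-row point and voxel
#'   counts; `attr(, "n_dropped_points")` counts points in discarded clusters.
#' @export
extract_rows <- function(plot_cloud, grid_step = 0.15, min_cluster_size = 50,
                         connectivity = c(26, 6), across = c("x", "y")) {
  plot_cloud <- as_point_cloud(plot_cloud)
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  connectivity <- as.integer(connectivity)
  across <- match.arg(across)
  if (grid_step <= 0) stop("grid_step must be positive", call. = FALSE)
  if (nrow(plot_cloud) == 0) stop("plot cloud is empty", call. = FALSE)
  xyz <- pc_xyz(plot_cloud)
  iv <- voxelize(xyz, grid_step)
  uv <- unique(iv)
  memb_vox <- voxel_components(uv, connectivity = connectivity)
  span <- max(uv) - min(uv) + 3L
  enc <- function(m) (as.numeric(m[, 1]) * span + m[, 2]) * span + m[, 3]
  memb_pt <- memb_vox[match(enc(iv), enc(uv))]

  sizes <- table(memb_pt)
  keep_comp <- as.integer(names(sizes)[sizes >= min_cluster_size])
  keep <- memb_pt %in% keep_comp
  kept <- plot_cloud[keep, , drop = FALSE]
  comp <- memb_pt[keep]

  cross_coord <- kept[[across]]
  order_means <- tapply(cross_coord, comp, mean)
  ranks <- rank(order_means, ties.method = "first")
  row_id <- as.integer(ranks[as.character(comp)])
  kept$row_id <- row_id

  row_levels <- sort(unique(row_id))
  pt_counts <- as.integer(table(factor(row_id, levels = row_levels)))
  vox_counts <- tapply(enc(iv)[keep], row_id, function(k) length(unique(k)))
  across_means <- as.numeric(tapply(cross_coord, row_id, mean))
  summary <- tibble::tibble(
    row_id = row_levels,
    n_points = pt_counts,
    n_voxels = as.integer(vox_counts[as.character(row_levels)]),
    mean_across = across_means)
  out <- set_stage(kept, "row")
  attr(out, "row_summary") <- summary
  attr(out, "n_dropped_points") <- sum(!keep)
  out
}

#' Drop the border rows of a plot
#'
#' Removes the first and last clusters in cross-row order so border effects
#' (edge plants growing into open space) do not bias the canopy trait; an
#' 8-row plot keeps its 6 interior rows.
#'
#' @param rowed_cloud A cloud with a `row_id` column, as returned by
#'   [extract_rows()].
#' @return The interior-row points (at least 3 rows are required).
#' @export
drop_border_rows <- function(rowed_cloud) {
  if (is.null(rowed_cloud$row_id))
    stop("cloud has no `row_id` column; run extract_rows() first",
         call. = FALSE)
  ids <- sort(unique(rowed_cloud$row_id))
  if (length(ids) < 3)
    stop("need at least 3 rows to define an interior (got ", length(ids),
         ")", call. = FALSE)
  keep <- !(rowed_cloud$row_id %in% c(ids[1], ids[length(ids)]))
  out <- rowed_cloud[keep, , drop = FALSE]
  summary <- attr(rowed_cloud, "row_summary", exact = TRUE)
  if (!is.null(summary))
    attr(out, "row_summary") <-
      summary[!(summary$row_id %in% c(ids[1], ids[length(ids)])), ,
              drop = FALSE]
  set_stage(out, "row")
}
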