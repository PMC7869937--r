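#' Colored point clouds as tibbles
#'
#' Throughout canopyr a colored point cloud is an ordinary tibble with numeric
#' columns `x`, `y`, `z` (meters) and integer color columns `r`, `g`, `b`
#' (8-bit, 0--255). Every stage function takes such a tibble first and returns
#' one, so stages chain with the pipe. `point_cloud()` builds one from vectors
#' and `as_point_cloud()` validates an existing data frame, coercing colors to
#' 8-bit integers.
#'
#' Two optional attributes travel with a cloud: `stage`, the provenance label
#' of the pipeline step that produced it (one of `r toString(pc_stages())`),
#' and `crs`, a free-text coordinate-system tag. dplyr verbs may drop them;
#' stage functions reset `stage` on their output.
#'
#' @param x,y,z Numeric coordinate vectors in meters.
#' @param r,g,b Integer color channels in \[0, 255\].
#' @param stage Provenance label, see [pc_stages()].
#' @param crs Optional free-text coordinate-system tag.
#' @return A tibble with columns `x`, `y`, `z`, `r`, `g`, `b`.
#' @examples
#' pc <- point_cloud(x = c(0, 1), y = c(0, 1), z = c(0, 0),
#'                   r = c(80, 90), g = c(160, 170), b = c(60, 70))
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(),
                        r = integer(), g = integer(), b = integer(),
                        stage = "raw", crs = NULL) {
  as_point_cloud(
    tibble::tibble(x = as.double(x), y = as.double(y), z = as.double(z),
                   r = r, g = g, b = b),
    stage = stage, crs = crs
  )
}

#' @rdname point_cloud
#' @param df A data frame with columns `x`, `y`, `z`, `r`, `g`, `b` (extra
#'   columns such as `class`, `plot_id` or `row_id` are kept).
#' @export
as_point_cloud <- function(df, stage = NULL, crs = NULL) {
  need <- c("x", "y", "z", "r", "g", "b")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    if (all(c("x", "y", "z") %in% names(df)) &&
        any(c("r", "g", "b") %in% missing_cols)) {
      stop("no radiometry: point cloud lacks color column(s) ",
           toString(intersect(c("r", "g", "b"), missing_cols)), call. = FALSE)
    }
    stop("not a point cloud: missing column(s) ", toString(missing_cols),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  for (cc in c("x", "y", "z")) {
    v <- out[[cc]]
    if (!is.numeric(v)) stop("coordinate column '", cc, "' is not numeric",
                             call. = FALSE)
    if (length(v) && any(!is.finite(v)))
      stop("non-finite value in coordinate column '", cc, "'", call. = FALSE)
    out[[cc]] <- as.double(v)
  }
  for (cc in c("r", "g", "b")) {
    v <- out[[cc]]
    if (!is.numeric(v)) stop("color column '", cc, "' is not numeric",
                             call. = FALSE)
    iv <- as.integer(round(v))
    if (length(iv) && (anyNA(iv) || any(iv < 0L | iv > 255L)))
      stop("color column '", cc, "' outside 8-bit range [0, 255]",
           call. = FALSE)
    out[[cc]] <- iv
  }
  if (!is.null(stage)) attr(out, "stage") <- match.arg(stage, pc_stages())
  if (!is.null(crs)) attr(out, "crs") <- crs
  out
}

#' Provenance vocabulary for point-cloud stages
#'
#' @return Character vector of the recognised stage labels.
#' @export
pc_stages <- function() {
  c("raw", "filtered", "regularized", "vegetation", "plot", "row")
}

#' @rdname pc_stages
#' @param cloud A point-cloud tibble.
#' @export
pc_stage <- function(cloud) attr(cloud, "stage", exact = TRUE)

# internal: tag stage without revalidating
set_stage <- function(cloud, stage) {
  attr(cloud, "stage") <- stage
  cloud
}

# internal: n x 3 coordinate matrix
pc_xyz <- function(cloud) {
  cbind(cloud$x, cloud$y, cloud$z)
}

#' Plot maps as long tibbles
#'
#' A plot map assigns points to experimental plots. It is a long tibble with
#' one row per polygon vertex: columns `plot_id` (character), `genotype`
#' (character), `vertex_index` (integer, ordering the ring) and `x`, `y`
#' (meters). Rings are simple (non-self-intersecting) and need not repeat the
#' first vertex; the closing edge is implied.
#'
#' @param df A data frame with columns `plot_id`, `genotype`, `vertex_index`,
#'   `x`, `y`.
#' @return A validated plot-map tibble.
#' @export
as_plot_map <- function(df) {
  need <- c("plot_id", "genotype", "vertex_index", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("not a plot map: missing column(s) ", toString(missing_cols),
         call. = FALSE)
  out <- tibble::as_tibble(df)
  out$plot_id <- as.character(out$plot_id)
  out$genotype <- as.character(out$genotype)
  out$vertex_index <- as.integer(out$vertex_index)
  out <- dplyr::arrange(out, .data$plot_id, .data$vertex_index)
  split_rows <- split(seq_len(nrow(out)), out$plot_id)
  for (pid in names(split_rows)) {
    ring <- out[split_rows[[pid]], c("x", "y")]
    ring <- ring[!duplicated(ring), , drop = FALSE]
    if (nrow(ring) < 3)
      stop("plot '", pid, "': polygon needs >= 3 distinct vertices",
           call. = FALSE)
    if (abs(pracma::polyarea(ring$x, ring$y)) <= 0)
      stop("plot '", pid, "': degenerate polygon (zero area)", call. = FALSE)
  }
  out
}

# internal: vertex ring (matrix, open) for one plot
plot_ring <- function(plot_map, plot_id) {
  sub <- plot_map[plot_map$plot_id == plot_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown plot_id '", plot_id, "'", call. = FALSE)
  sub <- sub[order(sub$vertex_index), , drop = FALSE]
  ring <- cbind(sub$x, sub$y)
  # drop an explicitly repeated closing vertex
  n <- nrow(ring)
  if (n > 3 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  ring
}

#' Genotype lookup from a plot map
#'
#' @param plot_map A plot-map tibble.
#' @return A tibble with one row per plot: `plot_id`, `genotype`.
#' @export
plot_genotypes <- function(plot_map) {
  dplyr::distinct(plot_map, .data$plot_id, .data$genotype)
}
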