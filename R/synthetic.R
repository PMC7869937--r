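#' Specify a synthetic soybean field
#'
#' Collects the parameters of the synthetic field generator. The defaults
#' emulate the layout and radiometry of a UAS-imaged soybean trial at the
#' full-flowering (R2) stage: 8 planted rows per plot at 0.76 m spacing, a
#' dense green canopy clearly separated from the soil in the green band, a
#' sinusoidal canopy-surface irregularity whose amplitude drives the
#' roughness trait, photogrammetric point densities of several hundred points
#' per square meter with optional holes, and sparse gross outliers.
#'
#' @param n_plots Number of plots.
#' @param rows_per_plot Planted rows per plot (default 8).
#' @param row_spacing Row spacing in meters (default 0.76).
#' @param row_length Row length in meters (default 2).
#' @param row_width Width of the canopy strip over each row (default 0.30 m).
#' @param canopy_height Mean canopy height in meters (default 0.6).
#' @param taper_width Width of the canopy edge taper on each side of a row
#'   strip (default 0.08 m): the canopy surface falls linearly to the ground
#'   over this distance, emulating the arched edge of a real row canopy
#'   instead of a vertical cliff no nadir reconstruction would produce.
#' @param bump_amplitude Canopy-surface bump amplitude per plot, meters;
#'   recycled to `n_plots` (default 0.03).
#' @param bump_wavelength Bump wavelength in meters (default 0.4, chosen so
#'   the 0.10 m roughness neighborhood sees curvature).
#' @param jitter_sd Gaussian surface jitter, meters (default 0.005).
#' @param base_density Point density in points/m² (default 700, the order of
#'   magnitude a photogrammetric survey delivers).
#' @param veg_green_range,soil_green_range 8-bit green-band intervals for the
#'   two classes (defaults `c(150, 220)` and `c(60, 110)`, disjoint across
#'   the 115 classification cut-off).
#' @param n_outliers Gross outliers scattered in an inflated bounding box
#'   (default 0).
#' @param dropout_fraction Fraction of points removed as random circular
#'   holes (default 0).
#' @param plot_gap Gap between adjacent plots in meters (default 0.5).
#' @param field_margin Extra field extent beyond the plot polygons at the row
#'   ends (default 0.4 m): rows continue past the plot boundary as they do in
#'   a real trial, so the meshing edge artifacts of a finite cloud fall
#'   outside every plot polygon.
#' @param genotypes Genotype labels recycled across plots (default generates
#'   one label per 4 plots).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `field_spec` list.
#' @export
field_spec <- function(n_plots = 8, rows_per_plot = 8, row_spacing = 0.76,
                       row_length = 2, row_width = 0.30, canopy_height = 0.6,
                       taper_width = 0.08,
                       bump_amplitude = 0.03, bump_wavelength = 0.4,
                       jitter_sd = 0.005, base_density = 700,
                       veg_green_range = c(150, 220),
                       soil_green_range = c(60, 110),
                       n_outliers = 0, dropout_fraction = 0,
                       plot_gap = 0.5, field_margin = 0.4, genotypes = NULL,
                       seed = 1) {
  stopifnot(n_plots >= 1, rows_per_plot >= 1, row_spacing > 0,
            row_length > 0, row_width > 0, row_width <= row_spacing,
            taper_width >= 0, taper_width <= row_width / 2,
            base_density > 0, all(bump_amplitude >= 0),
            bump_wavelength > 0, jitter_sd >= 0,
            dropout_fraction >= 0, dropout_fraction < 1, n_outliers >= 0)
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] >= 0 &&
    r[2] <= 255
  if (!rng_ok(veg_green_range) || !rng_ok(soil_green_range))
    stop("green ranges must be ordered and within [0, 255]", call. = FALSE)
  if (is.null(genotypes)) {
    n_geno <- max(1L, ceiling(n_plots / 4))
    genotypes <- sprintf("SYN-G%02d", seq_len(n_geno))
  }
  structure(list(
    n_plots = as.integer(n_plots), rows_per_plot = as.integer(rows_per_plot),
    row_spacing = row_spacing, row_length = row_length, row_width = row_width,
    canopy_height = canopy_height, taper_width = taper_width,
    bump_amplitude = rep_len(bump_amplitude, n_plots),
    bump_wavelength = bump_wavelength, jitter_sd = jitter_sd,
    base_density = base_density,
    veg_green_range = veg_green_range, soil_green_range = soil_green_range,
    n_outliers = as.integer(n_outliers), dropout_fraction = dropout_fraction,
    plot_gap = plot_gap, field_margin = field_margin,
    genotypes = rep_len(genotypes, n_plots), seed = as.integer(seed)),
    class = "field_spec")
}

#' Generate a synthetic colored field point cloud with ground truth
#'
#' Builds a UAS-like colored point cloud of `n_plots` plots laid out side by
#' side along x. Soil points sit on the plane z = 0 with soil-colored
#' radiometry; vegetation points sample the row-ridge surface
#' \deqn{z = h + a \sin(2\pi x/\lambda)\,\sin(2\pi y/\lambda) + \epsilon}
#' over each planted row strip, with the per-plot amplitude `a` the known
#' driver of canopy roughness. Optional gross outliers are scattered
#' uniformly in an inflated bounding box, and optional dropout carves random
#' circular holes. One random stream per call, split per plot, makes any
#' plot's subset reproducible on its own.
#'
#' @param spec A [field_spec()] (or arguments to build one, passed as
#'   `...`).
#' @param ... When `spec` is missing, forwarded to [field_spec()].
#' @return A list of class `synthetic_field`:
#'   \describe{
#'     \item{cloud}{point-cloud tibble of the whole field}
#'     \item{plot_map}{plot-map tibble (rectangular plot polygons)}
#'     \item{truth_points}{per-point tibble: `label`
#'       (vegetation/soil/outlier), `plot_id`, `row_id`}
#'     \item{truth_plots}{per-plot tibble: `plot_id`, `genotype`,
#'       `amplitude`}
#'   }
#' @export
generate_field <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- field_spec(...)
  stopifnot(inherits(spec, "field_spec"))
  plot_w <- spec$rows_per_plot * spec$row_spacing
  plot_l <- spec$row_length
  plot_seeds <- withr::with_seed(spec$seed,
                                 sample.int(.Machine$integer.max - 1,
                                            spec$n_plots + 1))
  parts <- vector("list", spec$n_plots)
  map_parts <- vector("list", spec$n_plots)
  for (p in seq_len(spec$n_plots)) {
    x0 <- (p - 1) * (plot_w + spec$plot_gap)
    parts[[p]] <- generate_plot(spec, p, x0, plot_seeds[p])
    map_parts[[p]] <- tibble::tibble(
      plot_id = sprintf("P%03d", p), genotype = spec$genotypes[p],
      vertex_index = 1:4,
      x = x0 + c(0, plot_w, plot_w, 0),
      y = c(0, 0, plot_l, plot_l))
  }
  pts <- dplyr::bind_rows(parts)

  # sparse gross outliers in an inflated bounding box
  if (spec$n_outliers > 0) {
    pts <- dplyr::bind_rows(pts, withr::with_seed(plot_seeds[
      spec$n_plots + 1], {
      rx <- range(pts$x); ry <- range(pts$y)
      dx <- diff(rx) * 0.1 + 0.5
      tibble::tibble(
        x = stats::runif(spec$n_outliers, rx[1] - dx, rx[2] + dx),
        y = stats::runif(spec$n_outliers, ry[1] - dx, ry[2] + dx),
        z = stats::runif(spec$n_outliers, -2, spec$canopy_height + 5),
        r = sample(0:255, spec$n_outliers, replace = TRUE),
        g = sample(0:255, spec$n_outliers, replace = TRUE),
        b = sample(0:255, spec$n_outliers, replace = TRUE),
        label = "outlier", plot_id = NA_character_, row_id = NA_integer_)
    }))
  }

  # dropout: random circular holes (vegetation and soil alike)
  if (spec$dropout_fraction > 0) {
    pts <- withr::with_seed(plot_seeds[spec$n_plots + 1] %% 1000L + 7L, {
      target <- floor(spec$dropout_fraction * nrow(pts))
      drop <- logical(nrow(pts))
      hole_r <- 0.15
      guard <- 0L
      while (sum(drop) < target && guard < 10000L) {
        guard <- guard + 1L
        cx <- stats::runif(1, min(pts$x), max(pts$x))
        cy <- stats::runif(1, min(pts$y), max(pts$y))
        inside <- (pts$x - cx)^2 + (pts$y - cy)^2 < hole_r^2 &
          pts$label != "outlier"
        drop <- drop | inside
      }
      pts[!drop, , drop = FALSE]
    })
  }

  cloud <- as_point_cloud(pts[, c("x", "y", "z", "r", "g", "b")],
                          stage = "raw")
  truth_points <- pts[, c("label", "plot_id", "row_id")]
  structure(list(
    cloud = cloud,
    plot_map = as_plot_map(dplyr::bind_rows(map_parts)),
    truth_points = tibble::as_tibble(truth_points),
    truth_plots = tibble::tibble(
      plot_id = sprintf("P%03d", seq_len(spec$n_plots)),
      genotype = spec$genotypes,
      amplitude = spec$bump_amplitude),
    spec = spec), class = "synthetic_field")
}

# one plot: soil carpet plus vegetation row ridges
generate_plot <- function(spec, p, x0, seed) {
  plot_w <- spec$rows_per_plot * spec$row_spacing
  plot_l <- spec$row_length
  amp <- spec$bump_amplitude[p]
  m <- spec$field_margin
  withr::with_seed(seed, {
    # rows continue past the plot polygon at both ends, as in a real field
    area <- plot_w * (plot_l + 2 * m)
    n_tot <- stats::rpois(1, spec$base_density * area)
    x <- stats::runif(n_tot, 0, plot_w)
    y <- stats::runif(n_tot, -m, plot_l + m)
    # row centers across x; a point is vegetation if inside a row strip
    centers <- (seq_len(spec$rows_per_plot) - 0.5) * spec$row_spacing
    j <- pmax(1L, pmin(spec$rows_per_plot,
                       as.integer(floor(x / spec$row_spacing)) + 1L))
    row_of <- ifelse(abs(x - centers[j]) <= spec$row_width / 2, j,
                     NA_integer_)
    is_veg <- !is.na(row_of)
    z <- numeric(n_tot)
    gx <- x0 + x
    # cross-row profile tapers the base height to the ground at the strip
    # edges (arched canopy edge, no cliff); the bump and jitter terms ride on
    # top unscaled so the roughness signal covers the whole strip
    d_edge <- spec$row_width / 2 -
      abs(x[is_veg] - centers[row_of[is_veg]])
    prof <- if (spec$taper_width > 0) pmin(1, d_edge / spec$taper_width)
            else rep(1, length(d_edge))
    z[is_veg] <- pmax(0, prof * spec$canopy_height +
      amp * sin(2 * pi * gx[is_veg] / spec$bump_wavelength) *
            sin(2 * pi * y[is_veg] / spec$bump_wavelength) +
      stats::rnorm(sum(is_veg), 0, spec$jitter_sd))
    g <- integer(n_tot)
    g[is_veg] <- sample(spec$veg_green_range[1]:spec$veg_green_range[2],
                        sum(is_veg), replace = TRUE)
    g[!is_veg] <- sample(spec$soil_green_range[1]:spec$soil_green_range[2],
                         sum(!is_veg), replace = TRUE)
    r <- integer(n_tot)
    r[is_veg] <- pmax(0, pmin(255, g[is_veg] - sample(60:100, sum(is_veg),
                                                      replace = TRUE)))
    r[!is_veg] <- pmax(0, pmin(255, g[!is_veg] + sample(10:40, sum(!is_veg),
                                                        replace = TRUE)))
    b <- integer(n_tot)
    b[is_veg] <- sample(20:70, sum(is_veg), replace = TRUE)
    b[!is_veg] <- sample(40:90, sum(!is_veg), replace = TRUE)
    tibble::tibble(
      x = gx, y = y, z = z, r = r, g = g, b = b,
      label = ifelse(is_veg, "vegetation", "soil"),
      plot_id = sprintf("P%03d", p),
      row_id = row_of)
  })
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat("<synthetic_field>", nrow(x$cloud), "points,",
      x$spec$n_plots, "plots,", x$spec$rows_per_plot, "rows/plot\n")
  invisible(x)
}

#' Simulate measured aboveground biomass for synthetic plots
#'
#' Generates per-plot AGB from canopy roughness through a chosen model plus
#' Gaussian noise, truncated at zero. With `model = NULL` a linear model is
#' calibrated so the simulated AGB matches the scale of a real soybean trial
#' at full flowering — target mean 150.3 g/m² and standard deviation
#' 42.3 g/m² — given the spread of the supplied roughness values: the slope
#' is \eqn{a = \sqrt{\max(sd_t^2 - \sigma^2, 0)}/sd(cr)} and the intercept
#' centers the mean.
#'
#' @param cr Numeric vector of per-plot canopy roughness (m²), or a trait
#'   tibble with a `cr_m2` column.
#' @param model An `agb_model`, a list `list(family =, coefficients =)`, or
#'   `NULL` for the calibrated linear default.
#' @param noise_sd Gaussian noise standard deviation in g/m² (default 10).
#' @param seed Integer seed.
#' @param target_mean,target_sd Calibration targets used when `model` is
#'   `NULL` (defaults 150.3 and 42.3 g/m²).
#' @return A tibble: `plot_id` (if available), `cr`, `agb` (g/m²).
#' @export
simulate_agb <- function(cr, model = NULL, noise_sd = 10, seed = 1,
                         target_mean = 150.3, target_sd = 42.3) {
  plot_id <- NULL
  if (is.data.frame(cr)) {
    plot_id <- cr$plot_id
    cr <- cr$cr_m2 %||% cr$cr
  }
  if (any(!is.finite(cr))) stop("cr must be finite", call. = FALSE)
  n <- length(cr)
  if (is.null(model)) {
    s <- stats::sd(cr)
    a <- if (n > 1 && s > 0) sqrt(max(target_sd^2 - noise_sd^2, 0)) / s else 0
    model <- list(family = "linear",
                  coefficients = c(a = a, b = target_mean - a * mean(cr)))
  }
  mu <- predict_family(model, cr)
  agb <- withr::with_seed(seed, mu + stats::rnorm(n, 0, noise_sd))
  agb <- pmax(agb, 0)
  out <- tibble::tibble(cr = cr, agb = agb)
  if (!is.null(plot_id)) out <- dplyr::bind_cols(
    tibble::tibble(plot_id = plot_id), out)
  out
}

predict_family <- function(model, xv) {
  if (inherits(model, "agb_model")) return(predict(model, xv))
  cf <- model$coefficients
  switch(model$family,
    linear = cf[["a"]] * xv + cf[["b"]],
    power = cf[["a"]] * xv^cf[["b"]],
    exponential = cf[["a"]] * exp(cf[["b"]] * xv),
    polynomial2 = cf[["a"]] * xv^2 + cf[["b"]] * xv + cf[["c"]],
    logarithmic = cf[["a"]] * log(xv) + cf[["b"]],
    stop("unknown model family ", model$family, call. = FALSE))
}
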