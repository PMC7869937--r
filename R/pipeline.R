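#' Pipeline configuration
#'
#' Collects every stage parameter of the canopy-roughness pipeline, with
#' defaults at the values the method was developed with: 20-point
#' neighborhoods and a 3-sigma threshold for both outlier filters, 500
#' points/m² resampling density, 1 cm Poisson-disk spacing, green cut-off
#' 115, 0.15 m voxel grid with a 50-point minimum cluster, 0.10 m roughness
#' radius, standardized-residual limit 2 and a 3-plot minimum per reported
#' genotype. The configuration is validated before any computation and
#' round-trips through JSON.
#'
#' @param k,n_sigma Outlier-filter neighborhood size and threshold.
#' @param density Resampling density, points/m².
#' @param poisson_min_dist Poisson-disk minimum spacing, m.
#' @param max_hole_perimeter,smooth_radius,smooth_iterations Mesh-repair and
#'   smoothing parameters.
#' @param green_cutoff,green_direction Vegetation classification.
#' @param grid_step,min_cluster,connectivity,across Row extraction.
#' @param roughness_radius Roughness neighborhood radius, m.
#' @param family Regression family, see [model_families()].
#' @param residual_limit Standardized-residual bound for plot rejection.
#' @param min_genotype_plots Minimum plots per genotype in the report.
#' @param regularize Run the mesh/resample/thin stage (default TRUE).
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory for artifacts (`NULL`: write nothing).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(k = 20, n_sigma = 3, density = 500,
                            poisson_min_dist = 0.01,
                            max_hole_perimeter = 0.5, smooth_radius = 0.10,
                            smooth_iterations = 1, green_cutoff = 115,
                            green_direction = "veg_ge_cutoff",
                            grid_step = 0.15, min_cluster = 50,
                            connectivity = 26, across = "x",
                            roughness_radius = 0.10, family = "linear",
                            residual_limit = 2, min_genotype_plots = 3,
                            regularize = TRUE, seed = 1, out_dir = NULL) {
  cfg <- list(k = k, n_sigma = n_sigma, density = density,
              poisson_min_dist = poisson_min_dist,
              max_hole_perimeter = max_hole_perimeter,
              smooth_radius = smooth_radius,
              smooth_iterations = smooth_iterations,
              green_cutoff = green_cutoff,
              green_direction = green_direction, grid_step = grid_step,
              min_cluster = min_cluster, connectivity = connectivity,
              across = across, roughness_radius = roughness_radius,
              family = family, residual_limit = residual_limit,
              min_genotype_plots = min_genotype_plots,
              regularize = isTRUE(regularize), seed = as.integer(seed),
              out_dir = out_dir)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg,
                                           call. = FALSE)
  check(cfg$k >= 3, "k must be >= 3")
  check(cfg$n_sigma > 0, "n_sigma must be positive")
  check(cfg$density > 0, "density must be positive")
  check(cfg$poisson_min_dist > 0, "poisson_min_dist must be positive")
  check(cfg$green_cutoff >= 0 && cfg$green_cutoff <= 255,
        "green_cutoff must lie in [0, 255]")
  check(cfg$green_direction %in% c("veg_ge_cutoff", "veg_lt_cutoff"),
        "unknown green_direction")
  check(cfg$grid_step > 0, "grid_step must be positive")
  check(cfg$min_cluster >= 1, "min_cluster must be >= 1")
  check(cfg$connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  check(cfg$across %in% c("x", "y"), "across must be 'x' or 'y'")
  check(cfg$roughness_radius > 0, "roughness_radius must be positive")
  check(cfg$family %in% model_families(), "unknown model family")
  check(cfg$residual_limit > 0, "residual_limit must be positive")
  check(cfg$min_genotype_plots >= 1, "min_genotype_plots must be >= 1")
  invisible(cfg)
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return For `read_pipeline_config()`, a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full canopy-roughness pipeline
#'
#' Executes the stages in order on an in-memory field: statistical and
#' plane-fit outlier removal, optional height calibration, regularization
#' (mesh, hole repair, smoothing, resampling, Poisson-disk thinning),
#' vegetation classification, per-plot trait extraction (clip, rows, border
#' removal, roughness, canopy roughness), plot-outlier rejection and LOOCV
#' regression against measured AGB, and the per-genotype error table.
#' Identical configuration and inputs produce identical outputs. When
#' `config$out_dir` is set, the trait table, LOOCV predictions, genotype
#' table, model and a machine-readable run log (parameters, seed, per-stage
#' point counts) are written there with stable file names.
#'
#' @param cloud A raw point-cloud tibble.
#' @param plot_map A plot-map tibble.
#' @param agb A data frame with `plot_id` and `agb` (g/m²), the measured
#'   biomass per plot.
#' @param config A [pipeline_config()].
#' @param bars Optional height-bar tibble for [adjust_height()].
#' @return A list of class `pipeline_result`: `traits`, `report`
#'   (`agb_report`), `genotype_table`, `removed_plots`, `run_log`.
#' @export
run_pipeline <- function(cloud, plot_map, agb, config = pipeline_config(),
                         bars = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  cloud <- as_point_cloud(cloud)
  plot_map <- as_plot_map(plot_map)
  log_config <- unclass(config)
  log_config$out_dir <- NULL   # machine-local path, not part of the run identity
  log <- list(config = log_config, stages = list())
  note <- function(stage, n, extra = NULL)
    log$stages[[stage]] <<- c(list(n_points = n), extra)
  stage_ctx <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  note("input", nrow(cloud))

  stat <- stage_ctx("statistical_outlier_removal",
                    statistical_outlier_removal(cloud, k = config$k,
                                                n_sigma = config$n_sigma))
  note("statistical_outlier_removal", nrow(stat),
       list(report = as.list(filter_report(stat))))
  filt <- stage_ctx("plane_fit_outlier_removal",
                    plane_fit_outlier_removal(stat, k = config$k,
                                              n_sigma = config$n_sigma))
  note("plane_fit_outlier_removal", nrow(filt),
       list(report = as.list(filter_report(filt))))

  if (!is.null(bars)) {
    filt <- stage_ctx("adjust_height", adjust_height(filt, bars))
    note("adjust_height", nrow(filt),
         list(offset = height_offset(filt)))
  }

  if (config$regularize) {
    filt <- stage_ctx("regularize", regularize_cloud(
      filt, density = config$density, min_dist = config$poisson_min_dist,
      max_hole_perimeter = config$max_hole_perimeter,
      smooth_radius = config$smooth_radius,
      smooth_iterations = config$smooth_iterations, seed = config$seed))
    note("regularize", nrow(filt))
  }

  classified <- stage_ctx("classify_vegetation", classify_vegetation(
    filt, green_cutoff = config$green_cutoff,
    direction = config$green_direction))
  note("classify_vegetation", nrow(classified),
       list(counts = as.list(attr(classified, "class_counts"))))

  traits <- stage_ctx("compute_plot_traits", compute_plot_traits(
    classified, plot_map, radius = config$roughness_radius,
    grid_step = config$grid_step, min_cluster_size = config$min_cluster,
    connectivity = config$connectivity, across = config$across))
  note("compute_plot_traits", sum(traits$n_points, na.rm = TRUE),
       list(n_plots_ok = sum(traits$status == "ok"),
            failed = as.list(stats::setNames(
              traits$status[traits$status != "ok"],
              traits$plot_id[traits$status != "ok"]))))

  eval_set <- traits |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::select("plot_id", "genotype", cr = "cr_m2") |>
    dplyr::inner_join(tibble::as_tibble(agb)[, c("plot_id", "agb")],
                      by = "plot_id")
  p_coef <- family_n_coef[[config$family]]
  if (nrow(eval_set) > p_coef + 2) {
    kept <- stage_ctx("reject_plot_outliers", reject_plot_outliers(
      eval_set, family = config$family, limit = config$residual_limit))
    removed <- removed_plots(kept)
    note("reject_plot_outliers", nrow(kept),
         list(n_removed = nrow(removed)))
  } else {
    kept <- eval_set
    removed <- tibble::tibble(plot_id = character(),
                              std_residual = numeric(), pass = integer())
    note("reject_plot_outliers", nrow(kept),
         list(n_removed = 0L, skipped = "too few plots for rejection"))
  }

  report <- stage_ctx("loocv", loocv(kept, family = config$family))
  geno_tab <- tryCatch(
    genotype_report(report, min_plots = config$min_genotype_plots),
    error = function(e) tibble::tibble())
  note("regression", nrow(kept),
       list(metrics = as.list(report$metrics)))

  result <- structure(list(traits = traits, report = report,
                           genotype_table = geno_tab,
                           removed_plots = removed, run_log = log),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", sum(x$traits$status == "ok"), "of",
      nrow(x$traits), "plots with traits;",
      nrow(x$removed_plots), "plot outlier(s) removed\n")
  print(x$report)
  invisible(x)
}

#' Write pipeline artifacts to a run directory
#'
#' Writes `plot_traits.csv`, `loocv_predictions.csv`, `genotype_table.csv`,
#' `model.json`, `removed_plots.csv` and `run_log.json` with stable names.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$traits, file.path(out_dir, "plot_traits.csv"))
  readr::write_csv(result$report$predictions,
                   file.path(out_dir, "loocv_predictions.csv"))
  readr::write_csv(result$genotype_table,
                   file.path(out_dir, "genotype_table.csv"))
  readr::write_csv(result$removed_plots,
                   file.path(out_dir, "removed_plots.csv"))
  jsonlite::write_json(list(
    family = result$report$model$family,
    coefficients = as.list(result$report$model$coefficients),
    metrics = as.list(result$report$metrics)),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
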