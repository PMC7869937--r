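#' Univariate biomass model families
#'
#' @return Character vector of the supported family names.
#' @export
model_families <- function() {
  c("linear", "power", "exponential", "polynomial2", "logarithmic")
}

family_n_coef <- c(linear = 2L, power = 2L, exponential = 2L,
                   polynomial2 = 3L, logarithmic = 2L)

check_eval_set <- function(data, x = "cr", y = "agb") {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  if (!all(c(x, y) %in% names(data)))
    stop("`data` needs columns `", x, "` and `", y, "`", call. = FALSE)
  if (any(!is.finite(data[[x]])) || any(!is.finite(data[[y]])))
    stop("non-finite values in `", x, "` or `", y, "`", call. = FALSE)
  if (!"plot_id" %in% names(data))
    data$plot_id <- as.character(seq_len(nrow(data)))
  data
}

check_domain <- function(data, family, x = "cr", y = "agb") {
  if (family %in% c("power", "logarithmic")) {
    bad <- data$plot_id[data[[x]] <= 0]
    if (length(bad) > 0)
      stop(family, " model requires ", x, " > 0; offending plot(s): ",
           toString(bad), call. = FALSE)
  }
  if (family %in% c("power", "exponential")) {
    bad <- data$plot_id[data[[y]] <= 0]
    if (length(bad) > 0)
      stop(family, " model requires ", y, " > 0; offending plot(s): ",
           toString(bad), call. = FALSE)
  }
  invisible(data)
}

#' Fit a univariate AGB model
#'
#' Fits one of five trend-line families relating aboveground biomass `y` to
#' canopy roughness `x`:
#' \describe{
#'   \item{linear}{\eqn{y = a x + b}, ordinary least squares}
#'   \item{power}{\eqn{y = a x^b}, least squares of \eqn{\ln y} on
#'     \eqn{\ln x}, back-transformed}
#'   \item{exponential}{\eqn{y = a e^{b x}}, least squares of \eqn{\ln y} on
#'     \eqn{x}}
#'   \item{polynomial2}{\eqn{y = a x^2 + b x + c}, ordinary least squares}
#'   \item{logarithmic}{\eqn{y = a \ln x + b}, ordinary least squares}
#' }
#' Power and exponential fits are log-linearized (the spreadsheet trend-line
#' convention) rather than iterative nonlinear least squares, so fits are
#' deterministic and bit-reproducible.
#'
#' @param data A data frame with columns `cr` (canopy roughness, m²) and
#'   `agb` (measured AGB, g/m²); `plot_id` and `genotype` are carried along
#'   if present.
#' @param family One of [model_families()].
#' @param x,y Column names for the predictor and response.
#' @return An object of class `agb_model`: list with `family`,
#'   `coefficients` (named per the family's formula above), the underlying
#'   `lm` fit, and the fitting data.
#' @export
fit_model <- function(data, family = model_families(), x = "cr", y = "agb") {
  family <- match.arg(family)
  data <- check_eval_set(data, x, y)
  n <- nrow(data)
  p <- family_n_coef[[family]]
  if (n < p)
    stop("need at least ", p, " plots for the ", family,
         " family (got ", n, ")", call. = FALSE)
  check_domain(data, family, x, y)
  xv <- data[[x]]
  yv <- data[[y]]
  fit <- switch(family,
    linear = stats::lm(yv ~ xv),
    polynomial2 = stats::lm(yv ~ xv + I(xv^2)),
    logarithmic = stats::lm(yv ~ log(xv)),
    power = stats::lm(log(yv) ~ log(xv)),
    exponential = stats::lm(log(yv) ~ xv))
  cf <- stats::coef(fit)
  coefficients <- switch(family,
    linear = c(a = unname(cf[2]), b = unname(cf[1])),
    polynomial2 = c(a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1])),
    logarithmic = c(a = unname(cf[2]), b = unname(cf[1])),
    power = c(a = unname(exp(cf[1])), b = unname(cf[2])),
    exponential = c(a = unname(exp(cf[1])), b = unname(cf[2])))
  structure(list(family = family, coefficients = coefficients, fit = fit,
                 data = data, x = x, y = y),
            class = "agb_model")
}

#' @export
print.agb_model <- function(x, ...) {
  eqn <- model_equation(x)
  cat("<agb_model> family:", x$family, "\n  ", eqn, "\n  n =",
      nrow(x$data), "plots\n")
  invisible(x)
}

model_equation <- function(model) {
  cf <- signif(model$coefficients, 6)
  switch(model$family,
    linear = sprintf("y = %g x + %g", cf["a"], cf["b"]),
    power = sprintf("y = %g x^%g", cf["a"], cf["b"]),
    exponential = sprintf("y = %g e^(%g x)", cf["a"], cf["b"]),
    polynomial2 = sprintf("y = %g x^2 + %g x + %g", cf["a"], cf["b"],
                          cf["c"]),
    logarithmic = sprintf("y = %g ln(x) + %g", cf["a"], cf["b"]))
}

#' Predict AGB from a fitted model
#'
#' @param object An `agb_model`.
#' @param newdata A data frame with the predictor column, or a numeric vector
#'   of canopy-roughness values.
#' @param ... Unused.
#' @return Numeric vector of predicted AGB (g/m²).
#' @export
predict.agb_model <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$data[[object$x]]
        else if (is.numeric(newdata)) newdata
        else newdata[[object$x]]
  cf <- object$coefficients
  switch(object$family,
    linear = cf["a"] * xv + cf["b"],
    power = cf["a"] * xv^cf["b"],
    exponential = cf["a"] * exp(cf["b"] * xv),
    polynomial2 = cf["a"] * xv^2 + cf["b"] * xv + cf["c"],
    logarithmic = cf["a"] * log(xv) + cf["b"]) |> unname()
}

#' @export
tidy.agb_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.agb_model <- function(x, ...) {
  obs <- x$data[[x$y]]
  pred <- predict(x)
  m <- error_metrics(pred, obs)
  tibble::tibble(family = x$family, n = nrow(x$data),
                 r2 = cor(pred, obs)^2, rmse = m$rmse, rrmse = m$rrmse,
                 ase = m$ase, mpse = m$mpse)
}

#' Regression error metrics for biomass estimation
#'
#' Four errors comparing predicted with measured AGB:
#' \deqn{RMSE = \sqrt{\sum_i (\hat y_i - y_i)^2 / n}}
#' \deqn{RRMSE = 100 \cdot RMSE / \bar y}
#' \deqn{ASE = \frac{100}{n} \sum_i \frac{\hat y_i - y_i}{y_i}
#'   \quad\textrm{(signed)}}
#' \deqn{MPSE = \frac{100}{n} \sum_i \frac{|\hat y_i - y_i|}{y_i}}
#' RMSE is in the units of the observations (g/m²); the other three are
#' percentages. By the triangle inequality `mpse >= |ase|` always.
#'
#' @param y_pred,y_obs Equal-length numeric vectors; observations must be
#'   nonzero (relative errors are undefined at zero).
#' @return A one-row tibble: `rmse`, `rrmse`, `ase`, `mpse`.
#' @export
error_metrics <- function(y_pred, y_obs) {
  if (length(y_pred) != length(y_obs))
    stop("y_pred and y_obs must have equal length", call. = FALSE)
  if (length(y_obs) == 0) stop("empty input", call. = FALSE)
  if (any(y_obs == 0))
    stop("zero observation: relative errors are undefined", call. = FALSE)
  if (mean(y_obs) == 0)
    stop("mean observation is zero: RRMSE undefined", call. = FALSE)
  n <- length(y_obs)
  rmse <- sqrt(sum((y_pred - y_obs)^2) / n)
  tibble::tibble(
    rmse = rmse,
    rrmse = 100 * rmse / mean(y_obs),
    ase = (100 / n) * sum((y_pred - y_obs) / y_obs),
    mpse = (100 / n) * sum(abs(y_pred - y_obs) / y_obs))
}

#' Leave-one-out cross-validation of a biomass model
#'
#' For each plot, fits the chosen family on the remaining plots and predicts
#' the withheld one; the error metrics are computed from the out-of-fold
#' predictions. The headline R² is the squared Pearson correlation between
#' out-of-fold predicted and observed AGB (the 1:1 scatter validation); the
#' in-sample R² of the full-data fit is also reported. Folds whose training
#' subset violates a domain constraint are skipped and logged.
#'
#' @inheritParams fit_model
#' @return An object of class `agb_report`: list with the full-data `model`,
#'   `predictions` (tibble: `plot_id`, `genotype`, `cr`, `agb`, `pred`),
#'   `metrics` (one-row tibble: `r2`, `r2_insample`, `rmse`, `rrmse`, `ase`,
#'   `mpse`, `n`, `n_skipped`), and `skipped` fold log.
#' @export
loocv <- function(data, family = model_families(), x = "cr", y = "agb") {
  family <- match.arg(family)
  data <- check_eval_set(data, x, y)
  n <- nrow(data)
  p <- family_n_coef[[family]]
  if (n < p + 1)
    stop("LOOCV needs at least ", p + 1, " plots for the ", family,
         " family (got ", n, ")", call. = FALSE)
  pred <- rep(NA_real_, n)
  skipped <- character(0)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    fold <- tryCatch(fit_model(train, family, x = x, y = y),
                     error = function(e) e)
    if (inherits(fold, "error")) {
      skipped <- c(skipped, paste0(data$plot_id[i], ": ",
                                   conditionMessage(fold)))
      next
    }
    pred[i] <- predict(fold, data[i, , drop = FALSE])
  }
  ok <- !is.na(pred)
  if (sum(ok) < 3)
    stop("fewer than 3 completed LOOCV folds", call. = FALSE)
  full <- fit_model(data, family, x = x, y = y)
  m <- error_metrics(pred[ok], data[[y]][ok])
  in_pred <- predict(full)
  predictions <- tibble::tibble(
    plot_id = data$plot_id,
    genotype = if ("genotype" %in% names(data)) data$genotype
               else NA_character_,
    cr = data[[x]], agb = data[[y]], pred = pred)
  metrics <- tibble::tibble(
    r2 = cor(pred[ok], data[[y]][ok])^2,
    r2_insample = cor(in_pred, data[[y]])^2,
    rmse = m$rmse, rrmse = m$rrmse, ase = m$ase, mpse = m$mpse,
    n = sum(ok), n_skipped = length(skipped))
  structure(list(model = full, predictions = predictions, metrics = metrics,
                 skipped = skipped),
            class = "agb_report")
}

#' @export
print.agb_report <- function(x, ...) {
  cat("<agb_report> LOOCV of", x$model$family, "model on",
      x$metrics$n, "plots\n  ", model_equation(x$model), "\n")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.agb_report <- function(x, ...) x$predictions

#' @export
glance.agb_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(family = x$model$family), x$metrics)
}

#' @export
augment.agb_model <- function(x, data = x$data, ...) {
  data$.fitted <- predict(x, data)
  data$.resid <- data[[x$y]] - data$.fitted
  tibble::as_tibble(data)
}

#' Iterative plot-outlier rejection by standardized residual
#'
#' Fits the model, standardizes the residuals by their sample standard
#' deviation, removes every plot with `|standardized residual| > limit`,
#' refits, and repeats until none exceed the limit. Errs if removal would
#' leave too few plots to fit.
#'
#' @inheritParams fit_model
#' @param limit Standardized-residual bound (default 2).
#' @return The retained data, with attribute `"removed"`: a tibble of
#'   rejected `plot_id`s, their standardized residuals and the pass in which
#'   they were removed (accessor [removed_plots()]).
#' @export
reject_plot_outliers <- function(data, family = model_families(), limit = 2,
                                 x = "cr", y = "agb") {
  family <- match.arg(family)
  data <- check_eval_set(data, x, y)
  p <- family_n_coef[[family]]
  if (nrow(data) <= p + 2)
    stop("need more than ", p + 2, " plots for outlier rejection",
         call. = FALSE)
  removed <- tibble::tibble(plot_id = character(), std_residual = numeric(),
                            pass = integer())
  pass <- 0L
  repeat {
    pass <- pass + 1L
    model <- fit_model(data, family, x = x, y = y)
    res <- data[[y]] - predict(model, data)
    s <- stats::sd(res)
    # an (almost) exact fit has no outliers; guard against standardizing
    # numerical noise
    if (s <= max(1e-8 * stats::sd(data[[y]]), 1e-12)) break
    std <- res / s
    out <- abs(std) > limit
    if (!any(out)) break
    if (nrow(data) - sum(out) < p + 2)
      stop("outlier rejection exhausted the data (", nrow(data) - sum(out),
           " plots would remain)", call. = FALSE)
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      plot_id = data$plot_id[out], std_residual = std[out], pass = pass))
    data <- data[!out, , drop = FALSE]
  }
  attr(data, "removed") <- removed
  data
}

#' @rdname reject_plot_outliers
#' @param data_out The tibble returned by `reject_plot_outliers()`.
#' @export
removed_plots <- function(data_out) attr(data_out, "removed", exact = TRUE)

#' Per-genotype error report
#'
#' Recomputes the four error metrics per genotype over that genotype's
#' out-of-fold LOOCV predictions. Genotypes represented by fewer than
#' `min_plots` plots are omitted; the best and worst genotype by RRMSE are
#' flagged.
#'
#' @param report An `agb_report` from [loocv()] whose predictions carry
#'   genotype labels (or pass `data` with a `genotype` column to supply
#'   them).
#' @param data Optional data frame with `plot_id` and `genotype` to (re)label
#'   the predictions.
#' @param min_plots Minimum plots per reported genotype (default 3).
#' @return A tibble: `genotype`, `n_plots`, `rmse`, `rrmse`, `ase`, `mpse`,
#'   `flag` (`"best"`/`"worst"` by RRMSE or `NA`).
#' @export
genotype_report <- function(report, data = NULL, min_plots = 3) {
  stopifnot(inherits(report, "agb_report"))
  preds <- report$predictions
  if (!is.null(data)) {
    if (!all(c("plot_id", "genotype") %in% names(data)))
      stop("`data` needs plot_id and genotype columns", call. = FALSE)
    preds$genotype <- data$genotype[match(preds$plot_id, data$plot_id)]
  }
  if (all(is.na(preds$genotype)))
    stop("no genotype labels available", call. = FALSE)
  preds <- preds[!is.na(preds$pred), , drop = FALSE]
  out <- preds |>
    dplyr::group_by(.data$genotype) |>
    dplyr::filter(dplyr::n() >= min_plots) |>
    dplyr::summarise(n_plots = dplyr::n(),
                     metrics = error_metrics(.data$pred, .data$agb),
                     .groups = "drop") |>
    tidyr::unpack("metrics")
  out$flag <- NA_character_
  if (nrow(out) > 0) {
    out$flag[which.min(out$rrmse)] <- "best"
    out$flag[which.max(out$rrmse)] <- "worst"
  }
  out
}
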