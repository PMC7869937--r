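eval_set <- function(x, y, genotype = NULL) {
  out <- tibble::tibble(plot_id = sprintf("P%02d", seq_along(x)),
                        cr = x, agb = y)
  if (!is.null(genotype)) out$genotype <- genotype
  out
}

true_curve <- function(family, x) {
  switch(family,
    linear = 3000 * x - 200,
    power = 250 * x^1.8,
    exponential = 60 * exp(1.5 * x),
    polynomial2 = 400 * x^2 - 100 * x + 120,
    logarithmic = 180 * log(x) + 400)
}

test_that("every family recovers generating coefficients on noiseless data", {
  x <- seq(0.2, 1.4, length.out = 24)
  want <- list(linear = c(a = 3000, b = -200),
               power = c(a = 250, b = 1.8),
               exponential = c(a = 60, b = 1.5),
               polynomial2 = c(a = 400, b = -100, c = 120),
               logarithmic = c(a = 180, b = 400))
  for (fam in model_families()) {
    fit <- fit_model(eval_set(x, true_curve(fam, x)), fam)
    expect_equal(fit$coefficients, want[[fam]], tolerance = 1e-9)
    expect_equal(predict(fit, x), true_curve(fam, x), tolerance = 1e-8)
  }
})

test_that("simple exact fits: y = 2x + 1, y = 2x^3, constant y", {
  d <- eval_set(c(1, 2, 3), c(3, 5, 7))
  expect_equal(fit_model(d, "linear")$coefficients, c(a = 2, b = 1),
               tolerance = 1e-12)
  d3 <- eval_set(c(0.5, 1, 2, 4), 2 * c(0.5, 1, 2, 4)^3)
  pw <- fit_model(d3, "power")
  expect_equal(pw$coefficients, c(a = 2, b = 3), tolerance = 1e-9)
  dc <- eval_set(1:5, rep(7, 5))
  cf <- fit_model(dc, "linear")$coefficients
  expect_equal(unname(cf), c(0, 7), tolerance = 1e-12)
})

test_that("domain violations name the offending plots", {
  d <- eval_set(c(-1, 1, 2, 3, 4), c(10, 20, 30, 40, 50))
  expect_error(fit_model(d, "power"), "P01")
  expect_error(fit_model(d, "logarithmic"), "P01")
  dneg <- eval_set(1:5, c(-5, 10, 20, 30, 40))
  expect_error(fit_model(dneg, "exponential"), "P01")
  expect_error(fit_model(eval_set(1:2, 1:2), "polynomial2"), "at least 3")
})

test_that("error metrics reproduce hand arithmetic and invariants", {
  m <- error_metrics(c(110, 190), c(100, 200))
  expect_equal(m$rmse, 10, tolerance = 1e-12)
  expect_equal(m$rrmse, 100 * 10 / 150, tolerance = 1e-12)
  expect_equal(m$ase, 2.5, tolerance = 1e-12)
  expect_equal(m$mpse, 7.5, tolerance = 1e-12)

  same <- error_metrics(c(5, 6, 7), c(5, 6, 7))
  expect_true(all(unlist(same) == 0))

  # direct-summation oracle on random vectors; MPSE >= |ASE| always
  for (s in 1:20) {
    y <- withr::with_seed(s, runif(30, 50, 250))
    p <- withr::with_seed(s + 100, y + rnorm(30, 0, 25))
    m <- error_metrics(p, y)
    n <- length(y)
    expect_equal(m$rmse, sqrt(sum((p - y)^2) / n), tolerance = 1e-10)
    expect_equal(m$rrmse, 100 * m$rmse / mean(y), tolerance = 1e-10)
    expect_equal(m$ase, 100 * mean((p - y) / y), tolerance = 1e-10)
    expect_equal(m$mpse, 100 * mean(abs(p - y) / y), tolerance = 1e-10)
    expect_gte(m$mpse, abs(m$ase))
  }
  expect_error(error_metrics(1, c(1, 2)), "equal length")
  expect_error(error_metrics(c(1, 2), c(0, 2)), "zero observation")
})

test_that("loocv is exact on noiseless data and matches 2-point folds", {
  x <- seq(0.3, 1.2, length.out = 12)
  rep <- loocv(eval_set(x, 2 * x + 1), "linear")
  expect_equal(rep$predictions$pred, 2 * x + 1, tolerance = 1e-9)
  expect_equal(rep$metrics$rmse, 0, tolerance = 1e-9)
  expect_equal(rep$metrics$r2, 1)

  # n = 3: each fold is the closed-form line through the other two points
  d <- eval_set(c(1, 2, 4), c(2, 3, 7))
  rep3 <- loocv(d, "linear")
  line <- function(x1, y1, x2, y2, x0) y1 + (y2 - y1) / (x2 - x1) * (x0 - x1)
  expect_equal(rep3$predictions$pred,
               c(line(2, 3, 4, 7, 1), line(1, 2, 4, 7, 2),
                 line(1, 2, 2, 3, 4)), tolerance = 1e-12)
})

test_that("loocv rmse is no better than in-sample rmse", {
  for (s in 1:5) {
    x <- withr::with_seed(s, runif(25, 0.2, 1.2))
    y <- withr::with_seed(s + 50, 3000 * x - 200 + rnorm(25, 0, 30))
    d <- eval_set(x, y)
    rep <- loocv(d, "linear")
    fit <- fit_model(d, "linear")
    insample <- sqrt(mean((predict(fit) - y)^2))
    expect_gte(rep$metrics$rmse, insample - 1e-9)
  }
})

test_that("loocv metrics are invariant under plot permutation", {
  x <- withr::with_seed(7, runif(20, 0.2, 1.2))
  y <- withr::with_seed(8, 3000 * x - 200 + rnorm(20, 0, 25))
  d <- eval_set(x, y)
  base <- loocv(d, "linear")
  perm <- withr::with_seed(9, d[sample.int(20), ])
  shuffled <- loocv(perm, "linear")
  expect_equal(shuffled$metrics$rmse, base$metrics$rmse, tolerance = 1e-12)
  expect_equal(shuffled$metrics$r2, base$metrics$r2, tolerance = 1e-12)
})

test_that("coefficient recovery under noise has near-nominal coverage", {
  hits <- 0L
  for (s in 1:100) {
    x <- withr::with_seed(1000 + s, runif(30, 0.2, 1.2))
    y <- withr::with_seed(2000 + s, 150 * x + 60 + rnorm(30, 0, 10))
    fit <- fit_model(eval_set(x, y), "linear")$fit
    se <- sqrt(diag(vcov(fit)))
    est <- coef(fit)
    ok <- abs(est[2] - 150) <= 3 * se[2] && abs(est[1] - 60) <= 3 * se[1]
    hits <- hits + ok
  }
  expect_gte(hits, 95L)
})

test_that("outlier rejection removes a gross outlier and converges", {
  x <- seq(0.2, 1.2, length.out = 20)
  y <- withr::with_seed(3, 3000 * x - 200 + rnorm(20, 0, 15))
  y[7] <- y[7] + 2000   # ~10 sigma off the line after refit
  d <- eval_set(x, y)
  kept <- reject_plot_outliers(d, "linear", limit = 2)
  expect_identical(removed_plots(kept)$plot_id, "P07")

  # post-condition: refit has max |standardized residual| <= limit
  fit <- fit_model(kept, "linear")
  std <- (kept$agb - predict(fit, kept)) / sd(kept$agb - predict(fit, kept))
  expect_lte(max(abs(std)), 2)

  # clean data: identity
  yc <- withr::with_seed(3, 3000 * x - 200 + rnorm(20, 0, 10))
  clean <- eval_set(x, yc)
  fitc <- fit_model(clean, "linear")
  stdc <- abs(yc - predict(fitc, clean)) / sd(yc - predict(fitc, clean))
  if (max(stdc) <= 2) {
    keptc <- reject_plot_outliers(clean, "linear")
    expect_identical(nrow(keptc), 20L)
    expect_identical(nrow(removed_plots(keptc)), 0L)
  }
})

test_that("rejection loop satisfies the residual bound on seeded datasets", {
  for (s in 1:10) {
    x <- withr::with_seed(s, runif(30, 0.2, 1.2))
    y <- withr::with_seed(s + 31, 2000 * x + 100 + rnorm(30, 0, 40))
    kept <- reject_plot_outliers(eval_set(x, y), "linear", limit = 2)
    fit <- fit_model(kept, "linear")
    res <- kept$agb - predict(fit, kept)
    expect_lte(max(abs(res / sd(res))), 2 + 1e-12)
  }
})

test_that("genotype report groups metrics and honors the plot minimum", {
  x <- withr::with_seed(11, runif(24, 0.3, 1.2))
  geno <- rep(c("G1", "G2", "G3"), times = c(11, 11, 2))
  noise_sd <- c(G1 = 5, G2 = 30, G3 = 5)[geno]
  y <- withr::with_seed(12, 2500 * x + 100 + rnorm(24, 0, noise_sd))
  d <- eval_set(x, y, genotype = geno)
  rep <- loocv(d, "linear")
  gt <- genotype_report(rep, min_plots = 3)
  expect_setequal(gt$genotype, c("G1", "G2"))   # G3 has only 2 plots
  expect_lt(gt$rrmse[gt$genotype == "G1"], gt$rrmse[gt$genotype == "G2"])
  expect_identical(gt$flag[gt$genotype == "G1"], "best")
  expect_identical(gt$flag[gt$genotype == "G2"], "worst")

  # single genotype: table equals the global metrics
  d1 <- eval_set(x, y, genotype = rep("G", 24))
  rep1 <- loocv(d1, "linear")
  gt1 <- genotype_report(rep1)
  expect_equal(gt1$rmse, rep1$metrics$rmse, tolerance = 1e-12)
  expect_equal(gt1$mpse, rep1$metrics$mpse, tolerance = 1e-12)
})

test_that("broom-style methods return tidy tibbles", {
  x <- seq(0.3, 1.2, length.out = 10)
  d <- eval_set(x, 2500 * x + 100, genotype = rep("G", 10))
  fit <- fit_model(d, "linear")
  td <- tidy(fit)
  expect_identical(td$term, c("a", "b"))
  gl <- glance(fit)
  expect_identical(gl$family, "linear")
  expect_equal(gl$r2, 1)
  au <- augment(fit)
  expect_true(all(abs(au$.resid) < 1e-9))

  rep <- loocv(d, "linear")
  expect_identical(nrow(tidy(rep)), 10L)
  expect_identical(glance(rep)$family, "linear")
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
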