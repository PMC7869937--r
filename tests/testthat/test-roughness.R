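test_that("coplanar clouds have zero roughness everywhere", {
  pc <- grid_cloud(12, 12, step = 0.03)
  rf <- point_roughness(pc, radius = 0.10)
  expect_true(all(!is.na(rf$roughness)))
  expect_lt(max(rf$roughness), 1e-12)
})

test_that("square-corner neighborhood gives the closed-form distance", {
  # query 0.05 m above the centroid of 4 corners of a 0.1 m square on z = 0:
  # the neighbor plane is z = 0 by symmetry, distance = 0.05
  pc <- point_cloud(x = c(0, -0.05, 0.05, 0.05, -0.05),
                    y = c(0, -0.05, -0.05, 0.05, 0.05),
                    z = c(0.05, 0, 0, 0, 0), r = 1, g = 1, b = 1)
  rf <- point_roughness(pc, radius = 0.10)
  expect_equal(rf$roughness[1], 0.05, tolerance = 1e-12)
})

test_that("roughness matches the brute-force oracle on seeded clouds", {
  for (s in 1:4) {
    n <- c(150, 400, 800, 1500)[s]
    pc <- random_cloud(n, seed = 80 + s, zr = c(0, 0.2))
    rf <- point_roughness(pc, radius = 0.10)
    want <- oracle_roughness(pc_mat(pc), 0.10)
    expect_identical(is.na(rf$roughness), is.na(want))
    ok <- !is.na(want)
    expect_lt(max(abs(rf$roughness[ok] - want[ok])), 1e-9)
  }
})

test_that("roughness is invariant under rigid motions", {
  pc <- random_cloud(500, seed = 91, zr = c(0, 0.3))
  rf <- point_roughness(pc, radius = 0.10)
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, byrow = TRUE)
  tilt <- matrix(c(1, 0, 0,
                   0, cos(0.3), -sin(0.3),
                   0, sin(0.3), cos(0.3)), 3, byrow = TRUE)
  moved_xyz <- pc_mat(pc) %*% t(tilt %*% rot)
  moved <- pc
  moved$x <- moved_xyz[, 1] + 10
  moved$y <- moved_xyz[, 2] - 5
  moved$z <- moved_xyz[, 3] + 2
  rf2 <- point_roughness(moved, radius = 0.10)
  ok <- !is.na(rf$roughness)
  expect_identical(is.na(rf2$roughness), !ok)
  expect_lt(max(abs(rf2$roughness[ok] - rf$roughness[ok])), 1e-9)
})

test_that("points without enough neighbors are flagged undefined", {
  pc <- point_cloud(x = c(0, 1, 1.01, 1.02, 1.03), y = c(0, 0, 0.01, 0, 0.01),
                    z = 0, r = 1, g = 1, b = 1)
  rf <- point_roughness(pc, radius = 0.1)
  expect_true(is.na(rf$roughness[1]))
  expect_identical(attr(rf, "n_undefined"),
                   sum(is.na(rf$roughness)))
  expect_error(point_roughness(pc, radius = 0), "positive")
})

test_that("canopy roughness follows the quantile convention on {1..5}", {
  cr <- canopy_roughness(c(1, 2, 3, 4, 5))
  expect_identical(cr$med_m, 3)
  expect_identical(cr$iqr_m, 2)
  expect_identical(cr$cr_m2, 6)
  # oracle: direct linear interpolation of order statistics
  v <- c(0.2, 0.5, 0.1, 0.9, 0.3, 0.7)
  sv <- sort(v)
  h <- function(p) {
    hh <- (length(v) - 1) * p + 1
    lo <- floor(hh)
    sv[lo] + (hh - lo) * (sv[min(lo + 1, length(v))] - sv[lo])
  }
  want_iqr <- h(0.75) - h(0.25)
  want_med <- h(0.5)
  got <- canopy_roughness(v)
  expect_equal(got$iqr_m, want_iqr)
  expect_equal(got$med_m, want_med)
  expect_equal(got$cr_m2, want_iqr * want_med)
})

test_that("canopy roughness degenerate and scaling behavior", {
  expect_identical(canopy_roughness(rep(0.42, 10))$cr_m2, 0)
  v <- withr::with_seed(5, runif(50))
  base <- canopy_roughness(v)$cr_m2
  expect_equal(canopy_roughness(3 * v)$cr_m2, 9 * base)
  # permutation and duplication invariance
  expect_identical(canopy_roughness(rev(v))$cr_m2, base)
  # duplication is invariant only asymptotically under interpolating
  # quantiles; the declared convention shifts quartile positions at finite n
  expect_equal(canopy_roughness(rep(v, 2))$cr_m2, base, tolerance = 0.05)
  expect_error(canopy_roughness(c(1, 2, 3)), ">= 4")
  expect_error(canopy_roughness(c(-1, 1, 2, 3)), ">= 0")
  # ratio variant for sensitivity analysis
  expect_equal(canopy_roughness(v, variant = "ratio")$cr_m2,
               canopy_roughness(v)$iqr_m / canopy_roughness(v)$med_m)
})

test_that("undefined roughness values are excluded, not zero-filled", {
  vals <- c(NA, NA, 1, 2, 3, 4, 5)
  cr <- canopy_roughness(vals)
  expect_identical(cr$n_undefined, 2L)
  expect_identical(cr$med_m, 3)
})

test_that("plot traits are translation invariant and flag failing plots", {
  field <- generate_field(n_plots = 2, row_length = 1, base_density = 250,
                          bump_amplitude = 0.05, seed = 101)
  cl <- classify_vegetation(field$cloud)
  tr <- compute_plot_traits(cl, field$plot_map)
  expect_true(all(tr$status == "ok"))
  # the two plots share one generator amplitude; their CR should be close
  expect_lt(abs(diff(tr$cr_m2)) / mean(tr$cr_m2), 0.25)

  # identical plot translated: identical CR
  shift <- cl
  shift$x <- shift$x + 50
  shift$y <- shift$y + 20
  pm2 <- field$plot_map
  pm2$x <- pm2$x + 50
  pm2$y <- pm2$y + 20
  tr2 <- compute_plot_traits(shift, pm2)
  expect_equal(tr2$cr_m2, tr$cr_m2, tolerance = 1e-9)

  # a plot polygon with no points inside is reported, not fatal
  pm3 <- dplyr::bind_rows(field$plot_map, tibble::tibble(
    plot_id = "EMPTY", genotype = "g", vertex_index = 1:4,
    x = c(100, 101, 101, 100), y = c(0, 0, 1, 1)))
  tr3 <- compute_plot_traits(cl, pm3)
  expect_identical(sum(tr3$status == "ok"), 2L)
  expect_match(tr3$status[tr3$plot_id == "EMPTY"], "empty")
})

test_that("a single planar row yields CR of zero", {
  pc <- grid_cloud(200, 8, step = 0.02, g = 180)  # 4 m x 0.14 m planar ridge
  pc$z <- 0.5
  tr <- point_roughness(pc, radius = 0.1)
  expect_lt(canopy_roughness(tr)$cr_m2, 1e-18)
})

test_that("CR increases with generator bump amplitude", {
  amps <- c(0, 0.02, 0.05, 0.10)
  field <- generate_field(n_plots = 4, row_length = 1, base_density = 250,
                          bump_amplitude = amps, seed = 111)
  tr <- compute_plot_traits(classify_vegetation(field$cloud), field$plot_map)
  expect_true(all(tr$status == "ok"))
  expect_true(all(diff(tr$cr_m2) > 0))
})
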