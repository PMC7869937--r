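planar_mesh <- function(nx = 5, ny = 5, step = 0.5) {
  build_mesh(grid_cloud(nx, ny, step = step))
}

test_that("delaunay mesh covers a square and counts grid triangles", {
  sq <- point_cloud(c(0, 1, 1, 0), c(0, 0, 1, 1), 0, 1, 1, 1)
  mesh <- build_mesh(sq)
  expect_identical(nrow(mesh$triangles), 2L)
  expect_equal(mesh_area(mesh), 1)
  expect_identical(nrow(mesh$vertices), 4L)

  for (n in c(4L, 7L)) {
    mesh <- planar_mesh(n, n)
    expect_identical(nrow(mesh$triangles), 2L * (n - 1L) * (n - 1L))
    expect_equal(mesh_area(mesh), ((n - 1) * 0.5)^2)
  }
  expect_error(build_mesh(point_cloud(1:5, 2 * (1:5), 0, 1, 1, 1)),
               "collinear")
  expect_error(build_mesh(point_cloud(1:2, 1:2, 0, 1, 1, 1)), "3 points")
})

test_that("hole repair restores the area of a punctured mesh and logs skips", {
  mesh <- planar_mesh(6, 6)
  full_area <- mesh_area(mesh)
  # puncture: remove one interior triangle
  drop <- which(apply(mesh$triangles, 1, function(tr) {
    v <- mesh$vertices[tr, ]
    all(v$x > 0.4) && all(v$x < 2.1) && all(v$y > 0.4) && all(v$y < 2.1)
  }))[1]
  holed <- surface_mesh(mesh$vertices, mesh$triangles[-drop, ])
  expect_lt(mesh_area(holed), full_area)

  repaired <- repair_holes(holed, max_hole_perimeter = 5)
  expect_equal(mesh_area(repaired), full_area)
  expect_true(attr(repaired, "repair_log")$filled)

  # a hole larger than the limit stays open and is logged
  left_open <- repair_holes(holed, max_hole_perimeter = 0.1)
  expect_equal(mesh_area(left_open), mesh_area(holed))
  expect_false(attr(left_open, "repair_log")$filled)

  # hole-free mesh is untouched
  same <- repair_holes(mesh)
  expect_identical(same$triangles, mesh$triangles)
})

test_that("laplacian smoothing fixes planes, shrinks spikes, respects iterations = 0", {
  mesh <- planar_mesh(7, 7)
  sm <- laplacian_smooth(mesh, radius = 0.8)
  expect_equal(pc_mat(sm$vertices), pc_mat(mesh$vertices), tolerance = 1e-12)

  spiky <- grid_cloud(7, 7, step = 0.5)
  mid <- which(spiky$x == 1.5 & spiky$y == 1.5)
  spiky$z[mid] <- 0.3
  spike_mesh <- build_mesh(spiky)
  out <- laplacian_smooth(spike_mesh, radius = 0.8)
  expect_lt(out$vertices$z[mid], 0.3)
  expect_gt(out$vertices$z[mid], 0)

  expect_identical(laplacian_smooth(spike_mesh, iterations = 0), spike_mesh)
  expect_error(laplacian_smooth(spike_mesh, radius = -1), "positive")
})

test_that("boundary vertices stay fixed under smoothing", {
  pc <- grid_cloud(6, 6, step = 0.4)
  pc$z <- withr::with_seed(4, runif(36, 0, 0.2))
  mesh <- build_mesh(pc)
  out <- laplacian_smooth(mesh, radius = 0.9)
  edge <- pc$x %in% c(0, 2) | pc$y %in% c(0, 2)
  expect_equal(out$vertices$z[edge], pc$z[edge])
})

test_that("surface sampling honors the density count and stays on the mesh", {
  mesh <- build_mesh(point_cloud(c(0, 2, 2, 0), c(0, 0, 1, 1), 0, 1, 1, 1))
  expect_equal(mesh_area(mesh), 2)
  s <- sample_surface(mesh, density = 500, seed = 1)
  expect_identical(nrow(s), 1000L)
  expect_true(all(abs(s$z) < 1e-12))  # planar mesh: samples on the plane
  expect_true(all(s$x >= 0 & s$x <= 2 & s$y >= 0 & s$y <= 1))
  expect_identical(sample_surface(mesh, density = 500, seed = 1), s)
})

test_that("triangle sampling weights follow the area ratio", {
  # two triangles with area ratio 1:3
  verts <- point_cloud(c(0, 1, 0, 3), c(0, 0, 1, 1), 0, 1, 1, 1)
  mesh <- surface_mesh(verts, rbind(c(1, 2, 3), c(2, 4, 3)))
  areas <- canopyr:::triangle_areas(mesh)
  expect_equal(areas[2] / areas[1], 3)
  hits <- vapply(1:20, function(s) {
    pts <- sample_surface(mesh, density = 500, seed = s)
    mean(pts$x + 1e-9 > pts$y)  # right of the diagonal = big triangle
  }, 0)
  expect_gt(mean(hits), 0.70)
  expect_lt(mean(hits), 0.80)
})

test_that("sampled colors are barycentric blends of vertex colors", {
  verts <- point_cloud(c(0, 1, 0), c(0, 0, 1), 0, r = c(0, 0, 0),
                       g = c(100, 200, 100), b = 0)
  mesh <- surface_mesh(verts, matrix(c(1, 2, 3), 1))
  s <- sample_surface(mesh, density = 3000, seed = 2)
  expect_true(all(s$g >= 100 & s$g <= 200))
  expect_gt(cor(s$x, s$g), 0.99)  # g grows toward the g=200 vertex
})

test_that("poisson thinning enforces spacing and maximality", {
  pair <- point_cloud(c(0, 0.005), 0, 0, 1, 1, 1)
  expect_identical(nrow(poisson_disk_thin(pair, 0.01, seed = 1)), 1L)

  spaced <- grid_cloud(5, 5, step = 0.02)
  expect_identical(nrow(poisson_disk_thin(spaced, 0.01, seed = 1)), 25L)

  cl <- random_cloud(10000, seed = 17, xr = c(0, 1), yr = c(0, 1),
                     zr = c(0, 0.05))
  thin <- poisson_disk_thin(cl, 0.01, seed = 18)
  expect_lt(nrow(thin), nrow(cl))
  expect_gte(min_pairwise_dist(pc_mat(thin)), 0.01)
  # maximality: every rejected point is within min_dist of an accepted one
  rejected <- cl[!(paste(cl$x, cl$y, cl$z) %in%
                     paste(thin$x, thin$y, thin$z)), ]
  nn <- RANN::nn2(pc_mat(thin), pc_mat(rejected), k = 1)
  expect_lt(max(nn$nn.dists), 0.01)

  expect_identical(nrow(poisson_disk_thin(point_cloud(), 0.01, seed = 1)), 0L)
})

test_that("thinned planar density stays below the packing bound", {
  cl <- random_cloud(8000, seed = 23, xr = c(0, 1), yr = c(0, 1),
                     zr = c(0, 0))
  thin <- poisson_disk_thin(cl, 0.01, seed = 5)
  # disc packing bound: one point per (pi/(2*sqrt(3))) * d^2 at best
  expect_gt(nrow(thin), 0)
  expect_lt(nrow(thin), 1 / (0.01^2 * pi / (2 * sqrt(3))) * 1.01)
})

test_that("regularize chain preserves flat surfaces", {
  cl <- random_cloud(3000, seed = 29, xr = c(0, 2), yr = c(0, 2),
                     zr = c(0, 0))
  out <- regularize_cloud(cl, density = 300, seed = 30)
  expect_gt(nrow(out), 100)
  expect_lt(sqrt(mean(out$z^2)), 1e-6)
})
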