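#' Surface meshes
#'
#' A `surface_mesh` is a list with `vertices` (a point-cloud tibble) and
#' `triangles` (an integer matrix, three vertex indices per row). Meshes are
#' 2.5-D terrain surfaces: triangulation happens in the (x, y) projection and
#' is lifted to z, the natural convention for nadir-imaged crop canopies,
#' which are height fields.
#'
#' @param vertices A point-cloud tibble.
#' @param triangles Integer matrix with 3 columns of vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as_point_cloud(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range", call. = FALSE)
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, area ",
      signif(mesh_area(x), 6), " m^2\n", sep = "")
  invisible(x)
}

#' Total 3-D surface area of a mesh
#'
#' @param mesh A `surface_mesh`.
#' @return Area in square meters.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

triangle_areas <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(numeric(0))
  v <- pc_xyz(mesh$vertices)
  a <- v[mesh$triangles[, 1], , drop = FALSE]
  b <- v[mesh$triangles[, 2], , drop = FALSE]
  c_ <- v[mesh$triangles[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Triangulate a point cloud into a canopy surface mesh
#'
#' Delaunay triangulation of the (x, y) projection, lifted to z (2.5-D). The
#' mesh vertex set equals the input cloud; triangles cover the x-y convex
#' hull.
#'
#' @param cloud A point-cloud tibble with at least 3 non-collinear points
#'   (distinct in projection).
#' @return A [surface_mesh()].
#' @export
build_mesh <- function(cloud) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) < 3)
    stop("build_mesh needs at least 3 points", call. = FALSE)
  if (anyDuplicated(cbind(cloud$x, cloud$y)))
    stop("duplicate (x, y) positions; a 2.5-D surface needs unique ",
         "projected points", call. = FALSE)
  if (collinear_xy(cloud$x, cloud$y))
    stop("all points are collinear in the x-y projection", call. = FALSE)
  tri <- interp::tri.mesh(cloud$x, cloud$y)
  tm <- interp::triangles(tri)
  surface_mesh(cloud, tm[, c("node1", "node2", "node3"), drop = FALSE])
}

collinear_xy <- function(x, y) {
  if (length(x) < 3) return(TRUE)
  x <- x - x[1]; y <- y - y[1]
  cross <- x[2] * y - y[2] * x
  all(abs(cross) < 1e-12 * max(1, max(abs(x)), max(abs(y))))
}

## ---- boundary / hole machinery ---------------------------------------------

# edges appearing in exactly one triangle, as a 2-column index matrix
boundary_edges <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(matrix(integer(0), ncol = 2))
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- names(which(table(key) == 1))
  e[key %in% once, , drop = FALSE]
}

# link boundary edges into closed loops (lists of vertex indices)
boundary_loops <- function(edges) {
  if (nrow(edges) == 0) return(list())
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  unvisited_key <- paste(pmin(edges[, 1], edges[, 2]),
                         pmax(edges[, 1], edges[, 2]))
  used <- stats::setNames(rep(FALSE, length(unvisited_key)), unvisited_key)
  loops <- list()
  for (s in seq_len(nrow(edges))) {
    k0 <- unvisited_key[s]
    if (used[[k0]]) next
    loop <- c(edges[s, 1], edges[s, 2])
    used[[k0]] <- TRUE
    ok <- TRUE
    repeat {
      cur <- loop[length(loop)]
      nexts <- adj[[as.character(cur)]]
      found <- NA_integer_
      for (nx in nexts) {
        k <- paste(pmin(cur, nx), pmax(cur, nx))
        if (!used[[k]]) { found <- nx; used[[k]] <- TRUE; break }
      }
      if (is.na(found)) {  # loop closes (back at start) or is open/non-manifold
        ok <- loop[length(loop)] != loop[1] &&
          any(adj[[as.character(loop[length(loop)])]] == loop[1])
        break
      }
      if (found == loop[1]) { ok <- TRUE; break }
      loop <- c(loop, found)
    }
    if (ok) loops[[length(loops) + 1]] <- loop
  }
  loops
}

loop_perimeter <- function(mesh, loop) {
  v <- pc_xyz(mesh$vertices)[c(loop, loop[1]), , drop = FALSE]
  sum(sqrt(rowSums(diff(v)^2)))
}

loop_area_xy <- function(mesh, loop) {
  abs(pracma::polyarea(mesh$vertices$x[loop], mesh$vertices$y[loop]))
}

# ear-clipping triangulation of a simple polygon given as vertex indices,
# using the x-y projection
ear_clip <- function(mesh, loop) {
  x <- mesh$vertices$x
  y <- mesh$vertices$y
  idx <- loop
  if (pracma::polyarea(x[idx], y[idx]) < 0) idx <- rev(idx)  # make CCW
  tris <- matrix(integer(0), ncol = 3)
  guard <- 0L
  while (length(idx) > 3) {
    n <- length(idx)
    clipped <- FALSE
    for (i in seq_len(n)) {
      a <- idx[if (i == 1) n else i - 1]
      b <- idx[i]
      c_ <- idx[if (i == n) 1 else i + 1]
      cross <- (x[b] - x[a]) * (y[c_] - y[a]) - (y[b] - y[a]) * (x[c_] - x[a])
      if (cross <= 0) next  # reflex or degenerate corner
      others <- setdiff(idx, c(a, b, c_))
      if (length(others) > 0 &&
          any(point_in_tri(x[others], y[others],
                           x[c(a, b, c_)], y[c(a, b, c_)]))) next
      tris <- rbind(tris, c(a, b, c_))
      idx <- idx[-i]
      clipped <- TRUE
      break
    }
    if (!clipped) { guard <- guard + 1L; if (guard > 2L) return(NULL) }
  }
  rbind(tris, idx)
}

point_in_tri <- function(px, py, tx, ty) {
  d1 <- (px - tx[2]) * (ty[1] - ty[2]) - (tx[1] - tx[2]) * (py - ty[2])
  d2 <- (px - tx[3]) * (ty[2] - ty[3]) - (tx[2] - tx[3]) * (py - ty[3])
  d3 <- (px - tx[1]) * (ty[3] - ty[1]) - (tx[3] - tx[1]) * (py - ty[1])
  has_neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  has_pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(has_neg & has_pos)
}

#' Fill small holes in a surface mesh
#'
#' Interior boundary loops (meshing gaps) whose perimeter does not exceed
#' `max_hole_perimeter` are filled by planar ear-clipping triangulation of the
#' loop in the x-y projection. The outer boundary — identified as the boundary
#' loop enclosing the largest projected area — is never filled. Vertex
#' coordinates are unchanged. Non-manifold loops and oversized holes are
#' skipped and counted in the `repair_log` attribute.
#'
#' @param mesh A `surface_mesh`.
#' @param max_hole_perimeter Largest hole perimeter (meters, 3-D) to fill.
#'   The default 0.5 m fills within-row gaps without bridging the 0.76 m
#'   inter-row spacing.
#' @return The repaired mesh; `attr(, "repair_log")` lists each interior loop
#'   with its perimeter and whether it was filled.
#' @export
repair_holes <- function(mesh, max_hole_perimeter = 0.5) {
  stopifnot(inherits(mesh, "surface_mesh"))
  loops <- boundary_loops(boundary_edges(mesh))
  log <- tibble::tibble(loop = integer(), n_vertices = integer(),
                        perimeter = numeric(), filled = logical())
  if (length(loops) <= 1) {        # only the outer boundary (or closed mesh)
    attr(mesh, "repair_log") <- log
    return(mesh)
  }
  areas <- vapply(loops, function(l) loop_area_xy(mesh, l), 0)
  outer <- which.max(areas)
  tris <- mesh$triangles
  for (j in seq_along(loops)) {
    if (j == outer) next
    per <- loop_perimeter(mesh, loops[[j]])
    filled <- FALSE
    if (per <= max_hole_perimeter) {
      patch <- ear_clip(mesh, loops[[j]])
      if (!is.null(patch)) {
        tris <- rbind(tris, patch)
        filled <- TRUE
      }
    }
    log <- dplyr::bind_rows(log, tibble::tibble(
      loop = j, n_vertices = length(loops[[j]]), perimeter = per,
      filled = filled))
  }
  out <- surface_mesh(mesh$vertices, tris)
  attr(out, "repair_log") <- log
  out
}

#' Laplacian mesh smoothing over a metric radius
#'
#' Moves every interior vertex toward the centroid of all mesh vertices
#' within a Euclidean `radius` of it (unweighted), repeated `iterations`
#' times. Only the component of the displacement along the local surface
#' normal is applied — tangential drift is suppressed, the standard
#' anti-shrinkage variant — so any locally coplanar neighborhood is an exact
#' fixed point and a perfectly planar mesh is left unchanged. Boundary
#' vertices are kept fixed so the mesh footprint is preserved. An optional
#' `mask` restricts smoothing to selected vertices, matching workflows where
#' smoothing is applied only around chosen locations.
#'
#' @param mesh A `surface_mesh`.
#' @param radius Neighborhood radius in meters (default 0.10).
#' @param iterations Number of smoothing passes (default 1; 0 is the
#'   identity).
#' @param mask Optional logical/integer vector of vertices allowed to move.
#' @return The smoothed mesh (same connectivity).
#' @export
laplacian_smooth <- function(mesh, radius = 0.10, iterations = 1,
                             mask = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (iterations == 0) return(mesh)
  nv <- nrow(mesh$vertices)
  movable <- rep(TRUE, nv)
  be <- boundary_edges(mesh)
  movable[unique(as.vector(be))] <- FALSE
  if (!is.null(mask)) {
    allow <- rep(FALSE, nv)
    allow[mask] <- TRUE
    movable <- movable & allow
  }
  v <- pc_xyz(mesh$vertices)
  for (it in seq_len(iterations)) {
    nn <- RANN::nn2(v, v[movable, , drop = FALSE],
                    k = min(nv, 128), searchtype = "radius", radius = radius)
    newv <- v
    rows <- which(movable)
    for (q in seq_along(rows)) {
      ids <- nn$nn.idx[q, ]
      ids <- ids[ids > 0L]
      if (length(ids) < 3) next
      nb <- v[ids, , drop = FALSE]
      ctr <- colMeans(nb)
      cc <- sweep(nb, 2, ctr)
      ev <- eigen(crossprod(cc), symmetric = TRUE)
      if (ev$values[2] <= max(ev$values[1], .Machine$double.eps) * 1e-12)
        next  # collinear neighborhood: no surface normal
      normal <- ev$vectors[, 3]
      disp <- sum((ctr - v[rows[q], ]) * normal)
      newv[rows[q], ] <- v[rows[q], ] + disp * normal
    }
    v <- newv
  }
  verts <- mesh$vertices
  verts$x <- v[, 1]; verts$y <- v[, 2]; verts$z <- v[, 3]
  surface_mesh(verts, mesh$triangles)
}

#' Resample a mesh to a uniform point density
#'
#' Draws `round(density * mesh_area(mesh))` points uniformly over the surface:
#' triangles are chosen with probability proportional to their 3-D area and
#' positions (and colors) are barycentrically interpolated.
#'
#' @param mesh A `surface_mesh` with positive area.
#' @param density Target density in points per square meter (default 500).
#' @param seed Integer seed; sampling is reproducible for a fixed seed.
#' @return A point-cloud tibble, stage `"regularized"`.
#' @export
sample_surface <- function(mesh, density = 500, seed) {
  stopifnot(inherits(mesh, "surface_mesh"))
  areas <- triangle_areas(mesh)
  total <- sum(areas)
  if (total <= 0) stop("mesh has zero surface area", call. = FALSE)
  n <- round(density * total)
  if (n == 0) return(set_stage(point_cloud(), "regularized"))
  v <- pc_xyz(mesh$vertices)
  col <- cbind(mesh$vertices$r, mesh$vertices$g, mesh$vertices$b)
  withr::with_seed(seed, {
    ti <- sample.int(nrow(mesh$triangles), n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
  })
  w1 <- 1 - r1
  w2 <- r1 * (1 - r2)
  w3 <- r1 * r2
  a <- mesh$triangles[ti, 1]; b <- mesh$triangles[ti, 2]
  c_ <- mesh$triangles[ti, 3]
  xyz <- v[a, , drop = FALSE] * w1 + v[b, , drop = FALSE] * w2 +
    v[c_, , drop = FALSE] * w3
  rgb <- col[a, , drop = FALSE] * w1 + col[b, , drop = FALSE] * w2 +
    col[c_, , drop = FALSE] * w3
  out <- point_cloud(xyz[, 1], xyz[, 2], xyz[, 3],
                     round(rgb[, 1]), round(rgb[, 2]), round(rgb[, 3]))
  set_stage(out, "regularized")
}

#' Dart-throwing Poisson-disk thinning
#'
#' Visits the points in a seeded random order, accepting each point iff no
#' previously accepted point lies within `min_dist` (3-D Euclidean). The
#' result is a maximal subset with minimum pairwise spacing `min_dist`: every
#' rejected point is within `min_dist` of an accepted one.
#'
#' @param cloud A point-cloud tibble.
#' @param min_dist Minimum spacing in meters (default 0.01, i.e. 1 cm).
#' @param seed Integer seed controlling the visiting order.
#' @return The thinned cloud, stage `"regularized"`; original point order is
#'   preserved among survivors.
#' @export
poisson_disk_thin <- function(cloud, min_dist = 0.01, seed) {
  cloud <- as_point_cloud(cloud)
  if (min_dist <= 0) stop("min_dist must be positive", call. = FALSE)
  n <- nrow(cloud)
  if (n == 0) return(set_stage(cloud, "regularized"))
  ord <- withr::with_seed(seed, sample.int(n))
  xyz <- pc_xyz(cloud)
  cell <- floor(xyz / min_dist)
  keys <- paste(cell[, 1], cell[, 2], cell[, 3], sep = "_")
  env <- new.env(hash = TRUE, size = n)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d2 <- min_dist^2
  accepted <- logical(n)
  for (i in ord) {
    nb_keys <- paste(cell[i, 1] + offs[, 1], cell[i, 2] + offs[, 2],
                     cell[i, 3] + offs[, 3], sep = "_")
    ok <- TRUE
    for (k in nb_keys) {
      ids <- env[[k]]
      if (!is.null(ids)) {
        dx <- xyz[ids, 1] - xyz[i, 1]
        dy <- xyz[ids, 2] - xyz[i, 2]
        dz <- xyz[ids, 3] - xyz[i, 3]
        if (any(dx * dx + dy * dy + dz * dz < d2)) { ok <- FALSE; break }
      }
    }
    if (ok) {
      accepted[i] <- TRUE
      env[[keys[i]]] <- c(env[[keys[i]]], i)
    }
  }
  set_stage(cloud[accepted, , drop = FALSE], "regularized")
}

#' Regularize a point cloud to uniform density
#'
#' Convenience chain for the full regularization stage: Delaunay mesh →
#' hole repair → Laplacian smoothing → uniform surface resampling →
#' Poisson-disk thinning.
#'
#' @param cloud A point-cloud tibble.
#' @param density Resampling density, points per square meter (default 500).
#' @param min_dist Poisson-disk minimum spacing (default 0.01 m).
#' @param max_hole_perimeter Passed to [repair_holes()].
#' @param smooth_radius,smooth_iterations Passed to [laplacian_smooth()].
#' @param seed Integer seed for the stochastic steps.
#' @return A regularized point-cloud tibble.
#' @export
regularize_cloud <- function(cloud, density = 500, min_dist = 0.01,
                             max_hole_perimeter = 0.5, smooth_radius = 0.10,
                             smooth_iterations = 1, seed) {
  mesh <- build_mesh(cloud)
  mesh <- repair_holes(mesh, max_hole_perimeter = max_hole_perimeter)
  mesh <- laplacian_smooth(mesh, radius = smooth_radius,
                           iterations = smooth_iterations)
  dense <- sample_surface(mesh, density = density, seed = seed)
  poisson_disk_thin(dense, min_dist = min_dist, seed = seed + 1L)
}
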