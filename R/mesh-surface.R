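# Triangulated surface meshes ------------------------------------------------

#' Construct a triangulated surface mesh
#'
#' A surface mesh stores vertex coordinates in millimetres and a triangle
#' index table (1-based). Meshes produced by the synthetic generators are
#' watertight (every edge shared by exactly two triangles) with outward
#' oriented normals.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param triangles integer matrix, one row per triangle, three vertex indices.
#' @param label optional name (e.g. a bone name).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, label = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop_input("vertices must have 3 columns")
  if (ncol(triangles) != 3L) stop_input("triangles must have 3 columns")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop_input("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles, label = label),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh", if (!is.null(x$label)) paste0("'", x$label, "'") else "",
      "\n  vertices:", nrow(x$vertices), " triangles:", nrow(x$triangles), "\n")
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Per-triangle areas (mm^2)
#' @param mesh a `surface_mesh`.
#' @return numeric vector of triangle areas.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  0.5 * row_norms(cross3(a, b))
}

#' Per-triangle unit normals (counter-clockwise orientation)
#' @param mesh a `surface_mesh`.
#' @return numeric matrix of unit normals, one row per triangle.
#' @export
triangle_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cross3(a, b)
  n / pmax(row_norms(n), .Machine$double.xmin)
}

#' Area-weighted per-vertex unit normals
#' @param mesh a `surface_mesh`.
#' @return numeric matrix, one unit normal per vertex.
#' @export
vertex_normals <- function(mesh) {
  tr <- mesh$triangles
  v <- mesh$vertices
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  fn <- cross3(a, b)  # length = 2 * area, so area weighting is implicit
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- rowsum(fn[, c], tr[, k])
      idx <- as.integer(rownames(acc))
      n[idx, c] <- n[idx, c] + acc[, 1]
    }
  }
  n / pmax(row_norms(n), .Machine$double.xmin)
}

#' Check watertightness and orientation of a surface mesh
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' triangles; consistent orientation additionally requires each shared edge to
#' be traversed once in each direction.
#'
#' @param mesh a `surface_mesh`.
#' @return list with `watertight`, `oriented`, `min_area` and `n_boundary_edges`.
#' @export
mesh_is_watertight <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key_und)
  watertight <- all(cnt == 2L)
  oriented <- !any(duplicated(key_dir))
  list(watertight = watertight,
       oriented = oriented && watertight,
       min_area = if (nrow(tr)) min(triangle_areas(mesh)) else 0,
       n_boundary_edges = sum(cnt == 1L))
}

#' Enclosed volume of a watertight mesh (mm^3)
#' @param mesh a watertight, outward-oriented `surface_mesh`.
#' @return enclosed volume (signed; positive for outward orientation).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  sum(rowSums(p1 * cross3(p2, p3))) / 6
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

# UV-sphere triangulation: n_theta latitude bands, n_phi meridians.
# Watertight by construction (pole fans + quad strips split in two).
unit_sphere_mesh <- function(n_theta = 12L, n_phi = 18L) {
  stopifnot(n_theta >= 3L, n_phi >= 3L)
  theta <- seq(0, pi, length.out = n_theta + 1L)[-c(1L, n_theta + 1L)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  g <- expand.grid(phi = phi, theta = theta)
  ring <- cbind(sin(g$theta) * cos(g$phi),
                sin(g$theta) * sin(g$phi),
                cos(g$theta))
  vtx <- rbind(c(0, 0, 1), ring, c(0, 0, -1))
  top <- 1L
  bot <- nrow(vtx)
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  tris <- list()
  # top fan (theta ring 1)
  j <- seq_len(n_phi)
  tris[[1]] <- cbind(top, idx(1L, j), idx(1L, j + 1L))
  # strips
  if (n_theta > 2L) {
    for (i in seq_len(n_theta - 2L)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      tris[[length(tris) + 1L]] <- cbind(a, c2, b)
      tris[[length(tris) + 1L]] <- cbind(b, c2, d)
    }
  }
  # bottom fan
  i <- n_theta - 1L
  tris[[length(tris) + 1L]] <- cbind(bot, idx(i, j + 1L), idx(i, j))
  surface_mesh(vtx, do.call(rbind, tris))
}

#' Triangulated superellipsoid surface
#'
#' Superellipsoids generalise ellipsoids via the implicit form
#' `|x/a|^p + |y/b|^p + |z/c|^p = 1`; exponents above 2 give boxier solids.
#' The surface is a radially warped watertight UV sphere.
#'
#' @param semiaxes length-3 positive numeric (mm).
#' @param exponent shape exponent `p >= 1` (2 = ellipsoid).
#' @param center length-3 numeric (mm).
#' @param rotation 3x3 rotation matrix applied about the center.
#' @param taper linear cross-section taper along the local y axis (fraction;
#'   0 = none, |taper| < 1). Breaks the y-mirror symmetry, as bone shafts do.
#' @param bend quadratic z-offset along the local y axis (fraction of the y
#'   semiaxis). Breaks the z-mirror symmetry (a slight "banana" curvature).
#' @param n_theta,n_phi sphere resolution.
#' @param label optional name.
#' @return a watertight `surface_mesh`.
#' @export
superellipsoid_mesh <- function(semiaxes, exponent = 2, center = c(0, 0, 0),
                                rotation = diag(3), taper = 0, bend = 0,
                                n_theta = 12L, n_phi = 18L,
                                label = NULL) {
  if (any(!is.finite(semiaxes)) || any(semiaxes <= 0))
    stop_param("semiaxes must be positive and finite")
  if (exponent < 1) stop_param("exponent must be >= 1")
  if (abs(taper) >= 1) stop_param("|taper| must be < 1")
  sph <- unit_sphere_mesh(n_theta, n_phi)
  d <- sph$vertices
  r <- (abs(d[, 1] / semiaxes[1])^exponent +
        abs(d[, 2] / semiaxes[2])^exponent +
        abs(d[, 3] / semiaxes[3])^exponent)^(-1 / exponent)
  v <- d * r
  if (taper != 0 || bend != 0) {
    s <- 1 + taper * v[, 2] / semiaxes[2]
    v[, 1] <- v[, 1] * s
    v[, 3] <- v[, 3] * s + bend * semiaxes[2] * (v[, 2] / semiaxes[2])^2
  }
  v <- v %*% t(rotation)
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, sph$triangles, label = label)
}

# Implicit inside test for a (rotated, translated, tapered, bent)
# superellipsoid spec: list(center, semiaxes, exponent, rotation, taper, bend).
# The taper/bend warps are inverted exactly before evaluating the implicit.
superellipsoid_inside <- function(points, spec, inflate = 0) {
  p <- sweep(points, 2, spec$center)
  p <- p %*% spec$rotation  # R^T x = x %*% R
  taper <- spec$taper %||% 0
  bend <- spec$bend %||% 0
  if (taper != 0 || bend != 0) {
    b <- spec$semiaxes[2]
    s <- pmax(1 + taper * p[, 2] / b, 0.1)
    p[, 3] <- (p[, 3] - bend * b * (p[, 2] / b)^2) / s
    p[, 1] <- p[, 1] / s
  }
  ax <- spec$semiaxes + inflate
  val <- abs(p[, 1] / ax[1])^spec$exponent +
         abs(p[, 2] / ax[2])^spec$exponent +
         abs(p[, 3] / ax[3])^spec$exponent
  val <= 1
}

#' Rigidly perturb (and optionally noise) a surface mesh
#'
#' Utility for building registration test fixtures with a known ground-truth
#' transform. Rotation (intrinsic XYZ Euler angles, degrees) and translation
#' are applied about the origin, then iid Gaussian noise is added per
#' coordinate. The applied transform is stored in attribute
#' `"true_transform"` for recovery tests.
#'
#' @param mesh a `surface_mesh`.
#' @param rotation length-3 Euler angles (degrees).
#' @param translation length-3 translation (mm).
#' @param noise_sd per-coordinate Gaussian noise (mm).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return perturbed `surface_mesh` with a `"true_transform"` attribute
#'   (list with `rotation` 3x3 and `translation`).
#' @export
perturb_shape <- function(mesh, rotation = c(0, 0, 0), translation = c(0, 0, 0),
                          noise_sd = 0, seed = 0L) {
  R <- rotation_xyz(rotation)
  v <- mesh$vertices %*% t(R)
  v <- sweep(v, 2, translation, "+")
  if (noise_sd > 0)
    v <- v + with_seed(seed, matrix(rnorm(length(v), sd = noise_sd), nrow(v), 3))
  out <- surface_mesh(v, mesh$triangles, label = mesh$label)
  attr(out, "true_transform") <- list(rotation = R, translation = translation)
  out
}
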