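# Shared fixtures and independent oracles -------------------------------------

# axis-aligned box surface [0,a]x[0,b]x[0,c], watertight, outward normals
box_surface <- function(a = 1, b = 1, c3 = 1) {
  v <- as.matrix(expand.grid(x = c(0, a), y = c(0, b), z = c(0, c3)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

# uniaxial bar lattice mesh along x with element set "bone" covering all
# elements, plus node sets at the two ends
bar_mesh <- function(length_mm = 20, h = 2, n_thick = 2) {
  tm <- generate_tet_mesh(box_surface(length_mm, h, h), h / n_thick)
  tm$element_sets$bone <- seq_len(nrow(tm$tets))
  tm$node_sets$root <- which(abs(tm$nodes[, 1]) < 1e-9)
  tm$node_sets$tip <- which(abs(tm$nodes[, 1] - length_mm) < 1e-9)
  tm
}

# consistent nodal traction on the bar tip face (sigma in MPa, +x direction)
bar_tip_load <- function(mesh, sigma) {
  bf <- boundary_faces(mesh)
  tipx <- max(mesh$nodes[, 1])
  sel <- apply(matrix(mesh$nodes[bf[, 1:3], 1], ncol = 3), 1,
               function(x) all(abs(x - tipx) < 1e-9))
  faces <- bf[sel, , drop = FALSE]
  f <- numeric(3L * nrow(mesh$nodes))
  for (r in seq_len(nrow(faces))) {
    v <- mesh$nodes[faces[r, 1:3], ]
    area <- 0.5 * sqrt(sum(pracma_cross(v[2, ] - v[1, ], v[3, ] - v[1, ])^2))
    for (k in 1:3) {
      dof <- 3L * (faces[r, k] - 1L) + 1L
      f[dof] <- f[dof] + sigma * area / 3
    }
  }
  f
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# independent point-to-triangle distance: barycentric plane projection
# (2x2 solve) if interior, else minimum over the three edge segments
pt_tri_dist_oracle <- function(p, a, b, c3) {
  u <- b - a; v <- c3 - a; w <- p - a
  uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
  wu <- sum(w * u); wv <- sum(w * v)
  den <- uu * vv - uv * uv
  if (den > 1e-30) {
    s <- (wu * vv - wv * uv) / den
    t <- (wv * uu - wu * uv) / den
    if (s >= 0 && t >= 0 && s + t <= 1) {
      q <- a + s * u + t * v
      return(sqrt(sum((p - q)^2)))
    }
  }
  seg <- function(p0, p1) {
    d <- p1 - p0
    tt <- sum((p - p0) * d) / max(sum(d * d), 1e-300)
    tt <- min(max(tt, 0), 1)
    sqrt(sum((p - (p0 + tt * d))^2))
  }
  min(seg(a, b), seg(a, c3), seg(b, c3))
}

# O(V_A * T_B) directed Hausdorff oracle (max-min point-triangle scan)
hausdorff_oracle <- function(A, B) {
  tb <- B$triangles; vb <- B$vertices
  dmax <- 0
  dall <- numeric(nrow(A$vertices))
  for (i in seq_len(nrow(A$vertices))) {
    p <- A$vertices[i, ]
    dmin <- Inf
    for (t in seq_len(nrow(tb))) {
      d <- pt_tri_dist_oracle(p, vb[tb[t, 1], ], vb[tb[t, 2], ],
                              vb[tb[t, 3], ])
      if (d < dmin) dmin <- d
    }
    dall[i] <- dmin
    if (dmin > dmax) dmax <- dmin
  }
  list(max = dmax, all = dall)
}

# small random watertight test mesh
random_blob <- function(seed, n_theta = 8L, n_phi = 10L) {
  set.seed(seed)
  superellipsoid_mesh(runif(3, 4, 12), runif(1, 1.6, 3),
                      center = runif(3, -5, 5),
                      rotation = rotation_from_euler(runif(3, -40, 40)),
                      taper = runif(1, -0.2, 0.2), bend = runif(1, -0.1, 0.1),
                      n_theta = n_theta, n_phi = n_phi)
}

rotation_from_euler <- function(deg) {
  r <- deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), -sin(r[1]), 0, sin(r[1]), cos(r[1])),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(r[2]), 0, sin(r[2]), 0, 1, 0, -sin(r[2]), 0, cos(r[2])),
               3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(r[3]), -sin(r[3]), 0, sin(r[3]), cos(r[3]), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# rigid perturbation with total rotation magnitude <= 30 degrees
bounded_perturbation <- function(mesh, seed) {
  set.seed(seed)
  rot <- runif(3, -30 / sqrt(3), 30 / sqrt(3))
  tr <- runif(3, -20, 20)
  perturb_shape(mesh, rot, tr, noise_sd = 0, seed = seed)
}

# stance curve groups on the common 101-point base
make_curve_group <- function(n_trials, seed, shift = 0, shift_idx = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_trials * 101), n_trials, 101)
  if (!is.null(shift_idx)) m[, shift_idx] <- m[, shift_idx] + shift
  m
}
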