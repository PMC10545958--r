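# Linear-elastic constant-strain tetrahedral finite elements -------------------

#' Linear elastic material
#' @param youngs_modulus Young's modulus E (MPa), > 0.
#' @param poisson_ratio Poisson's ratio in (-1, 0.5).
#' @return object of class `fe_material`.
#' @export
material <- function(youngs_modulus, poisson_ratio) {
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop_param("youngs_modulus must be positive")
  if (!is.finite(poisson_ratio) || poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop_param("poisson_ratio must be in (-1, 0.5)")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio), class = "fe_material")
}

#' Default study materials: bone and encapsulating soft tissue
#'
#' Bone: E = 7300 MPa, nu = 0.3. Lumped soft tissue: E = 0.15 MPa, nu = 0.45.
#' Both linearly elastic and isotropic.
#' @return named list of `fe_material`.
#' @export
default_materials <- function() {
  list(bone = material(7300, 0.3), soft = material(0.15, 0.45))
}

# isotropic elasticity matrix in Voigt order xx,yy,zz,xy,yz,zx (engineering
# shear strains), unit Young's modulus
elasticity_matrix_unitE <- function(nu) {
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

#' Mesh quality report (scaled Jacobian gate)
#'
#' Computes the per-element scaled Jacobian and flags elements at or below
#' the 0.3 quality gate; inverted elements (non-positive volume under the
#' stored ordering) are listed separately as hard failures.
#'
#' @param mesh a `tet_mesh`.
#' @param gate quality threshold (default 0.3).
#' @return list with `jacobian` (per element), `flagged` (ids <= gate),
#'   `inverted` (ids), `pass` (logical: no flagged, no inverted) and
#'   `min_jacobian`.
#' @export
check_mesh_quality <- function(mesh, gate = 0.3) {
  j <- scaled_jacobian(mesh)
  v <- tet_volumes(mesh)
  inverted <- which(v <= 0)
  flagged <- which(j <= gate)
  list(jacobian = j, flagged = setdiff(flagged, inverted),
       inverted = inverted,
       pass = length(flagged) == 0L && length(inverted) == 0L,
       min_jacobian = min(j))
}

# Per-element geometry cache: constant strain-displacement matrices B
# (6 x 12 x E), volumes, and dof index table (E x 12).
fe_element_cache <- function(mesh) {
  n <- mesh$nodes; t4 <- mesh$tets
  ne <- nrow(t4)
  x1 <- n[t4[, 1], , drop = FALSE]; x2 <- n[t4[, 2], , drop = FALSE]
  x3 <- n[t4[, 3], , drop = FALSE]; x4 <- n[t4[, 4], , drop = FALSE]
  e1 <- x2 - x1; e2 <- x3 - x1; e3 <- x4 - x1
  det <- rowSums(e1 * cross3(e2, e3))
  if (any(det <= 0)) stop_input("inverted elements in mesh")
  V <- det / 6
  # rows of inverse of C = [e1; e2; e3] (C %*% grad = I): grad N_{2,3,4}
  # inverse via adjugate: inv(C)^T rows are cross products / det
  g2 <- cross3(e2, e3) / det  # gradient of N2
  g3 <- cross3(e3, e1) / det
  g4 <- cross3(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)  # each E x 3
  B <- array(0, dim = c(6, 12, ne))
  for (k in 1:4) {
    gx <- grads[[k]][, 1]; gy <- grads[[k]][, 2]; gz <- grads[[k]][, 3]
    c0 <- 3 * (k - 1)
    B[1, c0 + 1, ] <- gx
    B[2, c0 + 2, ] <- gy
    B[3, c0 + 3, ] <- gz
    B[4, c0 + 1, ] <- gy; B[4, c0 + 2, ] <- gx
    B[5, c0 + 2, ] <- gz; B[5, c0 + 3, ] <- gy
    B[6, c0 + 1, ] <- gz; B[6, c0 + 3, ] <- gx
  }
  dofs <- matrix(0L, ne, 12)
  for (k in 1:4) dofs[, 3 * (k - 1) + 1:3] <-
    cbind(3L * (t4[, k] - 1L) + 1L, 3L * (t4[, k] - 1L) + 2L,
          3L * t4[, k])
  list(B = B, V = V, dofs = dofs, ne = ne, ndof = 3L * nrow(n))
}

# unit-modulus element stiffness triplets for a set of elements sharing nu
fe_unit_triplets <- function(cache, elems, nu) {
  D <- elasticity_matrix_unitE(nu)
  ne <- length(elems)
  B <- cache$B[, , elems, drop = FALSE]
  V <- cache$V[elems]
  Ke <- array(0, dim = c(12, 12, ne))
  for (a in 1:6) for (b in 1:6) {
    if (D[a, b] == 0) next
    Ba <- matrix(B[a, , ], 12, ne)
    Bb <- matrix(B[b, , ], 12, ne)
    for (i in 1:12) {
      Ke[i, , ] <- Ke[i, , ] + array(rep(Ba[i, ] * D[a, b], each = 12) *
                                       as.vector(Bb), dim = c(12, ne))
    }
  }
  Ke <- sweep(Ke, 3, V, "*")
  d <- cache$dofs[elems, , drop = FALSE]
  ii <- d[, rep(1:12, times = 12), drop = FALSE]
  jj <- d[, rep(1:12, each = 12), drop = FALSE]
  list(i = as.vector(t(ii)), j = as.vector(t(jj)),
       x = as.vector(Ke), elem = rep(elems, each = 144))
}

#' Assemble the global stiffness matrix
#'
#' Constant-strain tetrahedral elements with isotropic linear elasticity.
#' Every element must be covered by exactly one entry of `materials`, a named
#' list of `fe_material` keyed by element-set name (e.g.
#' `list(bone = ..., soft = ...)`). Per-element Young's moduli may be
#' overridden via `E_override` (numeric vector over all elements, NA = keep),
#' which is how density-dependent moduli enter during remodelling.
#'
#' The assembled operator is symmetric positive semi-definite with exactly
#' six rigid-body zero-energy modes before constraints.
#'
#' @param mesh a `tet_mesh`.
#' @param materials named list of `fe_material` keyed by element set.
#' @param E_override optional per-element Young's modulus vector (MPa).
#' @param cache optional result of a previous assembly's `$cache` for reuse.
#' @return list with `K` (sparse dgCMatrix), `cache`, `E` (per element),
#'   `nu` (per element).
#' @export
assemble_stiffness <- function(mesh, materials, E_override = NULL,
                               cache = NULL) {
  ne <- nrow(mesh$tets)
  E <- rep(NA_real_, ne); nu <- rep(NA_real_, ne)
  for (nm in names(materials)) {
    ids <- mesh$element_sets[[nm]]
    if (is.null(ids)) next
    E[ids] <- materials[[nm]]$youngs_modulus
    nu[ids] <- materials[[nm]]$poisson_ratio
  }
  if (anyNA(E))
    stop_input("missing material for ", sum(is.na(E)), " element(s)")
  if (!is.null(E_override)) {
    keep <- !is.na(E_override)
    E[keep] <- E_override[keep]
  }
  if (is.null(cache)) cache <- fe_element_cache(mesh)
  if (is.null(cache$triplets)) {
    trips <- list()
    for (nuval in unique(nu)) {
      elems <- which(nu == nuval)
      trips[[length(trips) + 1L]] <- fe_unit_triplets(cache, elems, nuval)
    }
    cache$triplets <- list(
      i = unlist(lapply(trips, `[[`, "i")),
      j = unlist(lapply(trips, `[[`, "j")),
      x = unlist(lapply(trips, `[[`, "x")),
      elem = unlist(lapply(trips, `[[`, "elem")))
  }
  tp <- cache$triplets
  K <- Matrix::sparseMatrix(i = tp$i, j = tp$j, x = tp$x * E[tp$elem],
                            dims = c(cache$ndof, cache$ndof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  list(K = K, cache = cache, E = E, nu = nu)
}

#' Add axial spring connectors to a stiffness operator
#'
#' Each node pair gets a linear axial spring of stiffness `k` (N/mm) along
#' the pair's current direction (the plantar fascia is modelled as five such
#' 200 N/mm connectors from the calcaneus notch to the metatarsal bases).
#' Symmetry is preserved.
#'
#' @param K sparse global stiffness (dgCMatrix).
#' @param mesh the `tet_mesh` supplying node coordinates.
#' @param pairs integer matrix with two columns of node ids.
#' @param k spring stiffness (N/mm), scalar or per pair.
#' @return modified sparse operator.
#' @export
add_connectors <- function(K, mesh, pairs, k = 200) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  k <- rep_len(k, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    if (k[r] == 0) next
    i <- pairs[r, 1]; j <- pairs[r, 2]
    d <- mesh$nodes[j, ] - mesh$nodes[i, ]
    len <- sqrt(sum(d * d))
    if (len < 1e-9) stop_input("coincident nodes in connector pair")
    nhat <- d / len
    kb <- k[r] * (nhat %o% nhat)
    di <- 3L * (i - 1L) + 1:3; dj <- 3L * (j - 1L) + 1:3
    K[di, di] <- K[di, di] + kb
    K[dj, dj] <- K[dj, dj] + kb
    K[di, dj] <- K[di, dj] - kb
    K[dj, di] <- K[dj, di] - kb
  }
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Assign plantar boundary faces to anatomical regions
#'
#' Boundary faces whose three nodes all belong to the `plantar` node set are
#' located by their centroid's fractional position along/across the foot and
#' assigned a region of the archetype's scheme with full coverage (bands a
#' scheme lacks are merged into the nearest covered band, e.g. the FB midfoot
#' belongs to the rearfoot posteriorly and the forefoot anteriorly).
#'
#' @param mesh a `tet_mesh` from [generate_foot_model()] (needs provenance
#'   `foot_length`/`foot_width` and the `plantar` node set).
#' @param scheme `"NF"`, `"HB"` or `"FB"`.
#' @return data.frame with face node columns `n1,n2,n3`, `element`, `area`,
#'   centroid coordinates and `region`.
#' @export
plantar_face_regions <- function(mesh, scheme = c("NF", "HB", "FB")) {
  scheme <- match.arg(scheme)
  pl <- mesh$node_sets$plantar
  if (!length(pl)) stop_input("plantar node set is empty")
  bf <- boundary_faces(mesh)
  inpl <- matrix(bf[, 1:3] %in% pl, ncol = 3)
  faces <- bf[rowSums(inpl) == 3L, , drop = FALSE]
  if (!nrow(faces)) stop_input("no plantar boundary faces")
  v1 <- mesh$nodes[faces[, 1], , drop = FALSE]
  v2 <- mesh$nodes[faces[, 2], , drop = FALSE]
  v3 <- mesh$nodes[faces[, 3], , drop = FALSE]
  cen <- (v1 + v2 + v3) / 3
  area <- 0.5 * row_norms(cross3(v2 - v1, v3 - v1))
  L <- mesh$provenance$foot_length
  W <- mesh$provenance$foot_width
  if (is.null(L) || is.null(W))
    stop_input("mesh provenance lacks foot dimensions")
  fy <- pmin(pmax(cen[, 2] / L, 0), 1)
  fx <- pmin(pmax((cen[, 1] + W / 2) / W, 0), 1)
  med <- fx < 0.5
  region <- character(nrow(cen))
  if (scheme == "NF") {
    band <- ifelse(fy < BAND_REAR, "rear", ifelse(fy < BAND_MID, "mid",
            ifelse(fy < BAND_FORE, "fore", "toes")))
    region[band == "rear"] <- ifelse(med[band == "rear"],
                                     "medial_rearfoot", "lateral_rearfoot")
    region[band == "mid"] <- ifelse(med[band == "mid"],
                                    "medial_midfoot", "lateral_midfoot")
    region[band == "fore"] <- ifelse(med[band == "fore"],
                                     "medial_forefoot", "lateral_forefoot")
    region[band == "toes"] <- ifelse(fx[band == "toes"] < 0.45,
                                     "hallux", "other_toes")
  } else if (scheme == "HB") {
    band <- ifelse(fy < 0.43, "rear", ifelse(fy < BAND_FORE, "fore", "toes"))
    region[band == "rear"] <- ifelse(med[band == "rear"],
                                     "medial_rearfoot", "lateral_rearfoot")
    region[band == "fore"] <- ifelse(med[band == "fore"],
                                     "medial_forefoot", "lateral_forefoot")
    region[band == "toes"] <- ifelse(fx[band == "toes"] < 0.45,
                                     "hallux", "lateral_forefoot")
  } else {
    band <- ifelse(fy < 0.5, "rear", "fore")
    region[band == "rear"] <- ifelse(med[band == "rear"],
                                     "medial_rearfoot", "lateral_rearfoot")
    region[band == "fore"] <- ifelse(med[band == "fore"],
                                     "medial_forefoot", "lateral_forefoot")
  }
  out <- data.frame(n1 = faces[, 1], n2 = faces[, 2], n3 = faces[, 3],
                    element = faces[, 4], area = area,
                    cx = cen[, 1], cy = cen[, 2], cz = cen[, 3],
                    region = region)
  out
}

#' Consistent nodal forces from regional plantar pressures
#'
#' Applies each region's pressure (kPa) over its plantar boundary faces as
#' consistent nodal loads: one third of pressure times face area per face
#' node, directed along the face's inward normal (into the solid). The total
#' applied force equals the sum over regions of pressure times region area.
#'
#' @param mesh a `tet_mesh`.
#' @param faces data.frame from [plantar_face_regions()], or any data.frame
#'   with `n1,n2,n3,element,region` columns.
#' @param pressures named numeric, kPa per region; every face's region must
#'   be present.
#' @return numeric load vector of length 3 * n_nodes (N).
#' @export
apply_plantar_pressure <- function(mesh, faces, pressures) {
  miss <- setdiff(unique(faces$region), names(pressures))
  if (length(miss))
    stop_input("unassigned plantar face region(s): ",
               paste(miss, collapse = ", "))
  f <- numeric(3L * nrow(mesh$nodes))
  v1 <- mesh$nodes[faces$n1, , drop = FALSE]
  v2 <- mesh$nodes[faces$n2, , drop = FALSE]
  v3 <- mesh$nodes[faces$n3, , drop = FALSE]
  cr <- cross3(v2 - v1, v3 - v1)  # outward, |cr| = 2A
  # inward normal force: pressure pushes into the solid
  p <- as.numeric(pressures[faces$region])  # kPa = 1e-3 N/mm^2
  fvec <- -cr / 2 * p * 1e-3 / 3  # per node of the face (N)
  for (k in 1:3) {
    nd <- faces[[paste0("n", k)]]
    for (c3 in 1:3) {
      acc <- rowsum(fvec[, c3], nd)
      ids <- as.integer(rownames(acc))
      f[3L * (ids - 1L) + c3] <- f[3L * (ids - 1L) + c3] + acc[, 1]
    }
  }
  f
}

#' Distributed Achilles tendon load
#'
#' The calf-muscle pull is modelled as point loads of equal share over the
#' `achilles` node set, with total magnitude `force` (default 0.5 body
#' weight) along `direction` (default the local tibia axis, i.e. from the
#' Achilles centroid towards the fixed proximal plane centroid).
#'
#' @param mesh a `tet_mesh` with `achilles` and `fixed_proximal` node sets.
#' @param force total force magnitude (N).
#' @param direction optional unit direction; computed from the mesh if NULL.
#' @return numeric load vector of length 3 * n_nodes (N).
#' @export
achilles_load <- function(mesh, force, direction = NULL) {
  ach <- mesh$node_sets$achilles
  if (!length(ach)) stop_input("achilles node set is empty")
  if (is.null(direction)) {
    top <- colMeans(mesh$nodes[mesh$node_sets$fixed_proximal, , drop = FALSE])
    cen <- colMeans(mesh$nodes[ach, , drop = FALSE])
    direction <- top - cen
  }
  direction <- direction / sqrt(sum(direction^2))
  f <- numeric(3L * nrow(mesh$nodes))
  share <- force / length(ach)
  for (c3 in 1:3)
    f[3L * (ach - 1L) + c3] <- f[3L * (ach - 1L) + c3] + share * direction[c3]
  f
}

#' Solve the constrained quasi-static system
#'
#' Direct sparse Cholesky solve of `K u = f` with homogeneous Dirichlet
#' constraints on all components of `fixed_nodes`. Reports the free-dof
#' residual and the reaction forces at the fixed dofs; per-element stresses
#' are recovered from the constant-strain fields.
#'
#' @param K sparse global stiffness (with any connectors added).
#' @param f load vector (N).
#' @param fixed_nodes integer node ids to clamp.
#' @param mesh the `tet_mesh` (for stress recovery).
#' @param cache element cache from [assemble_stiffness()].
#' @param E,nu per-element material fields from [assemble_stiffness()].
#' @param fixed_values optional prescribed displacements at the fixed nodes
#'   (matrix `length(fixed_nodes) x 3`, mm); zero by default.
#' @return object of class `fe_solution`: list with `displacements`
#'   (n_nodes x 3, mm), `stress` (E x 6 Voigt, MPa), `von_mises` (MPa),
#'   `reactions` (fixed dofs, N), `residual` (relative), `fixed_dofs`.
#' @export
fe_solve <- function(K, f, fixed_nodes, mesh, cache, E, nu,
                     fixed_values = NULL) {
  ndof <- nrow(K)
  if (!length(fixed_nodes)) stop_input("no fixed nodes: system is singular")
  fixed_nodes <- as.integer(fixed_nodes)
  fixed <- sort(unique(as.vector(vapply(1:3, function(c3)
    3L * (fixed_nodes - 1L) + c3, integer(length(fixed_nodes))))))
  free <- setdiff(seq_len(ndof), fixed)
  Kff <- K[free, free, drop = FALSE]
  u <- numeric(ndof)
  f0 <- f
  if (!is.null(fixed_values)) {
    fv <- matrix(fixed_values, ncol = 3)
    uc <- numeric(ndof)
    for (c3 in 1:3) uc[3L * (fixed_nodes - 1L) + c3] <- fv[, c3]
    u[fixed] <- uc[fixed]
    f <- f - as.numeric(K[, fixed, drop = FALSE] %*% u[fixed])
  }
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE),
                 error = function(e)
    stop(errorCondition(paste0("singular constrained system ",
                               "(insufficient constraints to remove ",
                               "rigid-body modes): ", conditionMessage(e)),
                        class = c("footform_singular_error", "error"))))
  uf <- as.numeric(Matrix::solve(ch, f[free]))
  fn <- sqrt(sum(f[free]^2))
  # a few steps of iterative refinement: the bone/soft modulus contrast makes
  # the raw factorisation residual marginal
  for (it in 1:4) {
    res <- f[free] - as.numeric(Kff %*% uf)
    residual <- if (fn > 0) sqrt(sum(res^2)) / fn else sqrt(sum(res^2))
    if (residual < 1e-10) break
    uf <- uf + as.numeric(Matrix::solve(ch, res))
  }
  res <- f[free] - as.numeric(Kff %*% uf)
  residual <- if (fn > 0) sqrt(sum(res^2)) / fn else sqrt(sum(res^2))
  u[free] <- uf
  reactions <- as.numeric(K[fixed, , drop = FALSE] %*% u) - f0[fixed]
  # element stresses
  ue <- matrix(u[cache$dofs], nrow = cache$ne)  # E x 12
  strain <- matrix(0, cache$ne, 6)
  for (a in 1:6)
    strain[, a] <- rowSums(ue * t(matrix(cache$B[a, , ], 12, cache$ne)))
  stress <- matrix(0, cache$ne, 6)
  for (nuval in unique(nu)) {
    sel <- which(nu == nuval)
    D <- elasticity_matrix_unitE(nuval)
    stress[sel, ] <- (strain[sel, , drop = FALSE] %*% t(D)) * E[sel]
  }
  structure(list(displacements = matrix(u, ncol = 3, byrow = TRUE),
                 u = u, stress = stress, von_mises = von_mises(stress),
                 reactions = reactions, fixed_dofs = fixed,
                 residual = residual, strain = strain),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("fe_solution: %d nodes, %d elements\n",
              nrow(x$displacements), nrow(x$stress)))
  cat(sprintf("  max |u| %.4g mm, peak von Mises %.4g MPa, residual %.2e\n",
              max(abs(x$displacements)), max(x$von_mises), x$residual))
  invisible(x)
}

#' Von Mises equivalent stress
#'
#' `sqrt(0.5 * ((s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2) +
#' 3 * (s12^2 + s23^2 + s31^2))` for Voigt rows `xx,yy,zz,xy,yz,zx`.
#'
#' @param stress numeric matrix E x 6 (Voigt, MPa) or length-6 vector.
#' @return numeric vector of equivalent stresses (MPa).
#' @export
von_mises <- function(stress) {
  if (is.null(dim(stress))) stress <- matrix(stress, nrow = 1)
  sqrt(0.5 * ((stress[, 1] - stress[, 2])^2 +
              (stress[, 2] - stress[, 3])^2 +
              (stress[, 3] - stress[, 1])^2) +
       3 * (stress[, 4]^2 + stress[, 5]^2 + stress[, 6]^2))
}

#' Per-element strain energy (N mm)
#' @param solution an `fe_solution`.
#' @param cache element cache used for the solve.
#' @return numeric vector, 0.5 * stress : strain * volume per element.
#' @export
strain_energy <- function(solution, cache) {
  0.5 * rowSums(solution$stress * solution$strain) * cache$V
}
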