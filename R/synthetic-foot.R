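# Parametric synthetic foot geometry ------------------------------------------
#
# Bones are superellipsoid primitives laid out in a foot frame:
#   x: medial (-) to lateral (+), y: heel (0) to toe (foot_length), z: up.
# Fidelity is topological/metric (bone count, overall dimensions, arch height,
# calcaneal inclination), sufficient to exercise shape, FE and remodelling
# stages; the bones are not anatomically faithful reconstructions.

FOOT_BONES <- c("calcaneus", "talus", "tibia", "fibula",
                paste0("metatarsal_", 1:5))

# Layout of bone primitives in "layout" coordinates (pre bounding-box fit).
# Returns list of specs: center, semiaxes, exponent, rotation, label.
foot_bone_layout <- function(params, jitter) {
  L <- params$foot_length; W <- params$foot_width
  incl <- params$calcaneal_inclination * pi / 180
  ahr <- params$arch_height_ratio
  specs <- list()

  # calcaneus: long axis y, pitched up anteriorly by the inclination angle
  cal_sem <- c(0.17 * W, 0.105 * L, 0.07 * L) * jitter$scale[["calcaneus"]]
  cal_rot <- rotation_xyz(c(params$calcaneal_inclination, 0, 0))
  zext <- sqrt((cal_sem[2] * sin(incl))^2 + (cal_sem[3] * cos(incl))^2)
  cal_c <- c(0, 0.16 * L, 0.035 * L + zext) + c(jitter$shift[["calcaneus"]], 0)
  specs$calcaneus <- list(center = cal_c, semiaxes = cal_sem, exponent = 2.5,
                          rotation = cal_rot, taper = 0.18, bend = 0.08)

  # talus sits on the anterior-superior calcaneus
  tal_sem <- c(0.13 * W, 0.078 * L, 0.042 * L) * jitter$scale[["talus"]]
  tal_c <- c(0,
             cal_c[2] + 0.07 * L * cos(incl),
             cal_c[3] + 0.085 * L * sin(incl) + 0.055 * L) +
    c(jitter$shift[["talus"]], 0)
  specs$talus <- list(center = tal_c, semiaxes = tal_sem, exponent = 2.2,
                      rotation = diag(3), taper = 0.16, bend = 0.14)

  # tibia and fibula: vertical columns ending at a common proximal plane
  z_top <- tal_c[3] + 0.05 * L + 0.36 * L
  tib_sem <- c(0.115 * W, 0.055 * L, 0.20 * L) * jitter$scale[["tibia"]]
  tib_c <- c(-0.03 * W, tal_c[2], z_top - tib_sem[3]) +
    c(jitter$shift[["tibia"]], 0)
  specs$tibia <- list(center = tib_c, semiaxes = tib_sem, exponent = 2.2,
                      rotation = diag(3), taper = 0.20, bend = 0.12)
  fib_sem <- c(0.055 * W, 0.035 * L, 0.19 * L) * jitter$scale[["fibula"]]
  fib_c <- c(0.17 * W, tal_c[2], z_top - fib_sem[3]) +
    c(jitter$shift[["fibula"]], 0)
  specs$fibula <- list(center = fib_c, semiaxes = fib_sem, exponent = 2,
                       rotation = diag(3), taper = 0.20, bend = 0.12)

  # metatarsals: anterior rays; posterior bases rise with the arch.
  # Their centroid height above the calcaneus base is set after the calcaneus
  # mesh is generated (see generate_foot_bones), via field `z_rel_cal_base`.
  met_t <- c(0.080, 0.068, 0.060, 0.058, 0.056)
  met_x <- c(-0.62, -0.31, 0, 0.31, 0.62) * (0.5 * W) * 0.72
  arch_dz <- ahr * 0.25 * L
  beta <- atan2(arch_dz, 0.30 * L)  # anterior tip pitched down to the ground
  for (k in 1:5) {
    nm <- paste0("metatarsal_", k)
    sem <- c(met_t[k] * 0.5 * W, 0.135 * L, met_t[k] * 0.5 * W) *
      jitter$scale[[nm]]
    ctr <- c(met_x[k], 0.72 * L, NA_real_)  # z filled in later
    ctr[1:2] <- ctr[1:2] + jitter$shift[[nm]]
    specs[[nm]] <- list(center = ctr, semiaxes = sem, exponent = 2,
                        rotation = rotation_xyz(c(-beta * 180 / pi, 0, 0)),
                        taper = 0.20, bend = 0.06,
                        z_rel_cal_base = arch_dz)
  }
  specs
}

foot_bone_jitter <- function(params) {
  with_seed(params$seed, {
    scale <- lapply(FOOT_BONES, function(b)
      pmin(pmax(rnorm(3, 1, 0.015), 0.95), 1.05))
    shift <- lapply(FOOT_BONES, function(b) rnorm(2, 0, 0.3))
    names(scale) <- names(shift) <- FOOT_BONES
    list(scale = scale, shift = shift)
  })
}

#' Generate the bone surfaces of a synthetic foot archetype
#'
#' Builds nine labelled watertight bone surfaces (calcaneus, talus, tibia,
#' fibula, five metatarsals) from superellipsoid primitives positioned by the
#' archetype's arch height ratio and calcaneal inclination. After assembly the
#' x/y coordinates are affinely fitted so the overall bounding box measures
#' exactly `foot_width` by `foot_length`. A small seed-controlled jitter of
#' primitive sizes and placements makes each seed a distinct "subject" while
#' keeping the generator a pure function of `(params, seed)`.
#'
#' @param params an `archetype_params` object.
#' @param n_theta,n_phi surface resolution per bone.
#' @return an object of class `shape_set`: list with `meshes` (named list of
#'   `surface_mesh`), `params`, `specs` (implicit primitive definitions in
#'   layout coordinates) and `frame` (the layout-to-foot affine map and
#'   derived z landmarks).
#' @export
generate_foot_bones <- function(params, n_theta = 12L, n_phi = 18L) {
  if (!inherits(params, "archetype_params"))
    stop_param("params must be an archetype_params object")
  jit <- foot_bone_jitter(params)
  specs <- foot_bone_layout(params, jit)

  build <- function(sp, label) superellipsoid_mesh(
    sp$semiaxes, sp$exponent, sp$center, sp$rotation,
    taper = sp$taper %||% 0, bend = sp$bend %||% 0,
    n_theta = n_theta, n_phi = n_phi, label = label)

  meshes <- list()
  meshes$calcaneus <- build(specs$calcaneus, "calcaneus")
  z_cal_base <- min(meshes$calcaneus$vertices[, 3])
  for (nm in FOOT_BONES[-1]) {
    is_met <- !is.na(match(nm, paste0("metatarsal_", 1:5)))
    if (is_met) specs[[nm]]$center[3] <- z_cal_base + specs[[nm]]$z_rel_cal_base
    meshes[[nm]] <- build(specs[[nm]], nm)
    if (is_met) {
      # pin the vertex centroid (not the primitive centre, which the
      # taper/bend warps shift) at the prescribed arch height
      dz <- specs[[nm]]$center[3] - mean(meshes[[nm]]$vertices[, 3])
      meshes[[nm]]$vertices[, 3] <- meshes[[nm]]$vertices[, 3] + dz
      specs[[nm]]$center[3] <- specs[[nm]]$center[3] + dz
    }
  }

  # fit x to [-W/2, W/2] and y to [0, L] exactly; z untouched
  allv <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  sx <- params$foot_width / diff(xr)
  sy <- params$foot_length / diff(yr)
  ox <- -params$foot_width / 2 - sx * xr[1]
  oy <- -sy * yr[1]
  for (nm in names(meshes)) {
    v <- meshes[[nm]]$vertices
    v[, 1] <- sx * v[, 1] + ox
    v[, 2] <- sy * v[, 2] + oy
    meshes[[nm]]$vertices <- v
  }
  frame <- list(sx = sx, ox = ox, sy = sy, oy = oy,
                z_cal_base = z_cal_base,
                z_top = max(meshes$tibia$vertices[, 3]),
                foot_length = params$foot_length,
                foot_width = params$foot_width)
  structure(list(meshes = meshes, params = params, specs = specs,
                 frame = frame),
            class = "shape_set")
}

#' @export
print.shape_set <- function(x, ...) {
  cat("shape_set [", x$params$archetype, "]: ", length(x$meshes),
      " bones, seed ", x$params$seed, "\n", sep = "")
  for (m in x$meshes)
    cat(sprintf("  %-14s %4d vertices, %4d triangles\n", m$label,
                nrow(m$vertices), nrow(m$triangles)))
  invisible(x)
}

# map foot-frame points back to layout coordinates for implicit tests
foot_to_layout <- function(points, frame) {
  cbind((points[, 1] - frame$ox) / frame$sx,
        (points[, 2] - frame$oy) / frame$sy,
        points[, 3])
}

#' Generate an assembled foot finite-element mesh
#'
#' Builds a single conforming tetrahedral mesh of the whole foot on a
#' structured lattice: cells are classified as a named bone (via the
#' archetype's implicit primitives), encapsulating soft tissue (a 5 mm
#' inflation of the bone union) or plantar pad (soft tissue filling each
#' footprint column down to a flat ground plane 6 mm under the lowest bone).
#' Element sets `bone`, `soft` and one `bone_<name>` set per bone are
#' created, plus node sets `fixed_proximal` (tibia/fibula proximal plane),
#' `plantar` (ground plane), `achilles` (posterior-superior calcaneal
#' surface) and five `fascia_cal_k`/`fascia_met_k` single-node anchor pairs
#' linking the calcaneus notch to the metatarsal bases.
#'
#' @param bones a `shape_set` from [generate_foot_bones()], or an
#'   `archetype_params` object.
#' @param target_edge lattice cell edge (mm); 6 mm gives a mesh of a few
#'   thousand tets suitable for iterative remodelling at desk scale.
#' @param soft_inflate soft-tissue inflation of each bone primitive (mm).
#' @param pad_depth soft pad depth under the lowest bone point (mm).
#' @param bone_capture half-width added to bone primitives when claiming
#'   lattice cells, so thin metatarsals survive coarse lattices (mm);
#'   defaults to 0.35 of the cell edge.
#' @return a `tet_mesh` with the element/node sets described above and
#'   provenance fields `foot_length`, `foot_width`, `archetype`.
#' @export
generate_foot_model <- function(bones, target_edge = 9, soft_inflate = 5,
                                pad_depth = 6, bone_capture = NULL) {
  if (inherits(bones, "archetype_params")) bones <- generate_foot_bones(bones)
  if (!inherits(bones, "shape_set")) stop_param("bones must be a shape_set")
  params <- bones$params
  frame <- bones$frame
  if (is.null(bone_capture)) bone_capture <- 0.35 * target_edge

  allv <- do.call(rbind, lapply(bones$meshes, `[[`, "vertices"))
  zg <- min(allv[, 3]) - pad_depth
  z_top <- frame$z_top
  m <- soft_inflate + 1
  x0 <- c(-params$foot_width / 2 - m, min(allv[, 2]) - m, zg)
  x1 <- c(params$foot_width / 2 + m, max(allv[, 2]) + m, z_top)
  ext <- x1 - x0
  n <- pmax(2L, as.integer(round(ext / target_edge)))
  h <- ext / n
  cx <- x0[1] + (seq_len(n[1]) - 0.5) * h[1]
  cy <- x0[2] + (seq_len(n[2]) - 0.5) * h[2]
  cz <- x0[3] + (seq_len(n[3]) - 0.5) * h[3]
  centers <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  lay <- foot_to_layout(centers, frame)
  # layout-frame inflation equivalents (x/y are scaled axes; use conservative
  # isotropic inflation divided by the smaller scale so coverage is sufficient)
  lab <- rep(NA_character_, nrow(centers))
  for (nm in rev(FOOT_BONES)) {  # calcaneus last so it wins overlaps
    sp <- bones$specs[[nm]]
    ins <- superellipsoid_inside(lay, sp, inflate = bone_capture)
    lab[ins] <- nm
  }
  soft <- is.na(lab)
  insoft <- rep(FALSE, nrow(centers))
  for (nm in FOOT_BONES) {
    sp <- bones$specs[[nm]]
    insoft <- insoft | superellipsoid_inside(lay, sp, inflate = soft_inflate)
  }
  # midfoot soft-tissue bridge: the tarsal/plantar-arch volume joining the
  # talus region to the metatarsal bases (no tarsal bone primitives exist)
  tal <- bones$specs$talus
  met_c <- colMeans(do.call(rbind, lapply(paste0("metatarsal_", 1:5),
                                          function(nm)
                                            bones$specs[[nm]]$center)))
  bw2 <- max(abs(met_c[1]), 0.30 * params$foot_width)
  bridge <- list(center = c(0, (tal$center[2] + met_c[2]) / 2,
                            (tal$center[3] + met_c[3]) / 2),
                 semiaxes = c(0.32 * params$foot_width,
                              0.60 * (met_c[2] - tal$center[2]),
                              max(0.08 * params$foot_length,
                                  0.7 * abs(tal$center[3] - met_c[3]))),
                 exponent = 2.2, rotation = diag(3))
  insoft <- insoft | superellipsoid_inside(lay, bridge, inflate = soft_inflate)
  lab[soft & insoft] <- "soft"
  lab_a <- array(lab, dim = n)
  # plantar pad: fill footprint columns down to the ground plane
  occ <- !is.na(lab_a)
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) {
    col <- occ[i, j, ]
    if (any(col)) {
      k1 <- which(col)[1]
      if (k1 > 1L) lab_a[i, j, seq_len(k1 - 1L)] <- "soft"
    }
  }
  mask <- !is.na(lab_a)
  lt <- lattice_tets(x0, h, mask, cell_label = lab_a)
  esets <- lt$element_sets
  bone_ids <- sort(unlist(esets[names(esets) %in% FOOT_BONES],
                          use.names = FALSE))
  element_sets <- c(list(bone = bone_ids, soft = esets$soft %||% integer(0)),
                    setNames(esets[intersect(FOOT_BONES, names(esets))],
                             paste0("bone_", intersect(FOOT_BONES,
                                                       names(esets)))))
  mesh <- tet_mesh(lt$nodes, lt$tets, element_sets = element_sets,
                   provenance = list(target_edge = target_edge,
                                     cell_size = h,
                                     foot_length = params$foot_length,
                                     foot_width = params$foot_width,
                                     archetype = params$archetype,
                                     ground_z = zg))
  # drop floating lattice islands (rare stray cells from the inflation test);
  # the mechanical model is the single connected body
  comp <- mesh_components(mesh)
  if (max(comp) > 1L) {
    ecomp <- comp[mesh$tets[, 1]]
    mesh <- subset_tet_mesh(mesh, which(ecomp == 1L))
  }
  nz <- mesh$nodes[, 3]
  tolz <- 1e-9 + 1e-12 * abs(z_top)
  mesh$node_sets$plantar <- which(abs(nz - zg) < h[3] * 1e-6 + 1e-9)
  mesh$node_sets$fixed_proximal <- which(nz > max(nz) - h[3] * 1e-6 - 1e-9)
  # achilles: posterior-superior calcaneal bone nodes
  cal_nodes <- sort(unique(as.vector(
    mesh$tets[mesh$element_sets$bone_calcaneus %||% integer(0), ])))
  if (length(cal_nodes)) {
    cp <- mesh$nodes[cal_nodes, , drop = FALSE]
    cc <- colMeans(cp)
    # tendon insertion: a small posterior-superior surface patch, not the
    # whole posterior quadrant (the pull must load the tuberosity locally)
    surf <- sort(unique(as.vector(boundary_faces(mesh)[, 1:3])))
    ycut <- stats::quantile(cp[, 2], 0.10)
    zcut <- stats::quantile(cp[, 3], 0.60)
    sel <- cp[, 2] <= ycut & cp[, 3] > zcut & (cal_nodes %in% surf)
    if (!any(sel)) sel <- cp[, 2] < cc[2] & cp[, 3] > cc[3]
    if (!any(sel)) sel <- cp[, 3] > cc[3]
    mesh$node_sets$achilles <- cal_nodes[sel]
  } else mesh$node_sets$achilles <- integer(0)
  # fascia anchors: calcaneus notch (anterior-inferior) and metatarsal bases
  nearest_node <- function(cand, pt) {
    if (!length(cand)) cand <- seq_len(nrow(mesh$nodes))
    d <- row_norms(sweep(mesh$nodes[cand, , drop = FALSE], 2, pt))
    cand[which.min(d)]
  }
  if (length(cal_nodes)) {
    cp <- mesh$nodes[cal_nodes, , drop = FALSE]
    notch_pt <- c(mean(cp[, 1]), max(cp[, 2]), min(cp[, 3]))
    notch <- nearest_node(cal_nodes, notch_pt)
  } else notch <- nearest_node(integer(0), c(0, 0.2 * params$foot_length, zg))
  for (k in 1:5) {
    mnodes <- sort(unique(as.vector(
      mesh$tets[mesh$element_sets[[paste0("bone_metatarsal_", k)]] %||% integer(0), ])))
    if (length(mnodes)) {
      mp <- mesh$nodes[mnodes, , drop = FALSE]
      base_pt <- c(mean(mp[, 1]), min(mp[, 2]), min(mp[, 3]))
      mb <- nearest_node(mnodes, base_pt)
    } else {
      mb <- nearest_node(integer(0),
                         c((k - 3) * params$foot_width / 6,
                           0.65 * params$foot_length, zg + pad_depth))
    }
    mesh$node_sets[[paste0("fascia_cal_", k)]] <- notch
    mesh$node_sets[[paste0("fascia_met_", k)]] <- mb
  }
  if (!length(mesh$node_sets$plantar)) stop_input("empty plantar node set")
  if (!length(mesh$node_sets$fixed_proximal))
    stop_input("empty fixed_proximal node set")
  mesh
}

#' Assign per-element apparent density phantoms
#'
#' Reference density fields for evaluating remodelling predictions:
#' `uniform` assigns a constant; `cortical_shell` assigns `rho_max` to every
#' element owning at least one boundary face and `rho_trab` elsewhere
#' (mimicking a dense cortical shell around lumped trabecular bone);
#' `gradient` ramps linearly with element centroid z from `rho_min` to
#' `rho_max`.
#'
#' @param mesh a `tet_mesh`.
#' @param pattern `"uniform"`, `"cortical_shell"` or `"gradient"`.
#' @param value constant for `"uniform"` (g/cm^3).
#' @param rho_min,rho_max density bounds (g/cm^3).
#' @param rho_trab trabecular density for `"cortical_shell"`.
#' @return numeric vector of per-element densities, class `density_field`.
#' @export
make_density_phantom <- function(mesh, pattern = c("uniform", "cortical_shell",
                                                   "gradient"),
                                 value = 1.0, rho_min = 0.05, rho_max = 1.8,
                                 rho_trab = 0.3) {
  if (!inherits(mesh, "tet_mesh")) stop_param("mesh must be a tet_mesh")
  if (is.character(pattern) && length(pattern) == 1 &&
      !pattern %in% c("uniform", "cortical_shell", "gradient"))
    stop_param("unknown phantom pattern: ", pattern)
  pattern <- match.arg(pattern)
  ne <- nrow(mesh$tets)
  rho <- switch(pattern,
    uniform = rep(min(max(value, rho_min), rho_max), ne),
    cortical_shell = {
      bf <- boundary_faces(mesh)
      shell <- unique(bf[, "element"])
      r <- rep(rho_trab, ne); r[shell] <- rho_max; r
    },
    gradient = {
      zc <- (mesh$nodes[mesh$tets[, 1], 3] + mesh$nodes[mesh$tets[, 2], 3] +
             mesh$nodes[mesh$tets[, 3], 3] + mesh$nodes[mesh$tets[, 4], 3]) / 4
      zr <- range(zc)
      if (diff(zr) == 0) rep((rho_min + rho_max) / 2, ne)
      else rho_min + (zc - zr[1]) / diff(zr) * (rho_max - rho_min)
    })
  structure(rho, class = "density_field", rho_min = rho_min, rho_max = rho_max)
}
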