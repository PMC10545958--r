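# Synthetic archetype generators ----------------------------------------------

test_that("archetype parameter validation rejects inconsistent inputs", {
  shares <- default_archetype("NF")$regional_load_shares
  expect_error(archetype_params(80, 214, 0.2, 20, 52, shares, "NF"),
               class = "footform_parameter_error")
  expect_error(archetype_params(Inf, 84, 0.2, 20, 52, shares, "NF"),
               class = "footform_parameter_error")
  bad <- shares; bad[1] <- bad[1] + 0.1
  expect_error(archetype_params(214, 84, 0.2, 20, 52, bad, "NF"),
               class = "footform_parameter_error")
  expect_error(archetype_params(214, 84, 1.5, 20, 52, shares, "NF"),
               class = "footform_parameter_error")
  expect_error(archetype_params(214, 84, 0.2, 20, 52, shares[-1], "NF"),
               class = "footform_parameter_error")
})

test_that("generated feet have the prescribed dimensions and ordering", {
  for (seed in 0:4) {
    lens <- sapply(c("NF", "HB", "FB"), function(a) {
      b <- generate_foot_bones(default_archetype(a, seed = seed))
      allv <- do.call(rbind, lapply(b$meshes, function(m) m$vertices))
      diff(range(allv[, 2]))
    })
    expect_equal(unname(lens["NF"]), 214.06, tolerance = 0.5 / 214.06)
    expect_equal(unname(lens["HB"]), 202.81, tolerance = 0.5 / 202.81)
    expect_equal(unname(lens["FB"]), 165.86, tolerance = 0.5 / 165.86)
    expect_true(lens["NF"] > lens["HB"] && lens["HB"] > lens["FB"])
  }
})

test_that("flat-arch limit places metatarsal centroids at the calcaneus base", {
  shares <- default_archetype("NF")$regional_load_shares
  p0 <- archetype_params(214.06, 84.17, 0, 20, 52.2, shares, "NF", seed = 2)
  b0 <- generate_foot_bones(p0)
  zb <- min(b0$meshes$calcaneus$vertices[, 3])
  for (k in 1:5) {
    zc <- mean(b0$meshes[[paste0("metatarsal_", k)]]$vertices[, 3])
    expect_lt(abs(zc - zb), 0.1)
  }
})

test_that("bone generation is a pure function of params and seed", {
  p <- default_archetype("HB", seed = 11)
  b1 <- generate_foot_bones(p)
  b2 <- generate_foot_bones(p)
  for (nm in names(b1$meshes))
    expect_identical(b1$meshes[[nm]]$vertices, b2$meshes[[nm]]$vertices)
  b3 <- generate_foot_bones(default_archetype("HB", seed = 12))
  expect_false(identical(b1$meshes$calcaneus$vertices,
                         b3$meshes$calcaneus$vertices))
})

test_that("all generated bone surfaces are watertight with sane triangles", {
  b <- generate_foot_bones(default_archetype("FB", seed = 1))
  for (m in b$meshes) {
    wt <- mesh_is_watertight(m)
    expect_true(wt$watertight)
    expect_true(wt$oriented)
    expect_gt(wt$min_area, 1e-9)
    expect_gt(mesh_volume(m), 0)
  }
})

test_that("lattice tetrahedralisation matches closed-form counts and volumes", {
  cube <- box_surface(1, 1, 1)
  tm <- generate_tet_mesh(cube, 0.5)
  expect_identical(nrow(tm$tets), 48L)  # 6 n^3 with n = 2
  expect_equal(sum(tet_volumes(tm)), 1, tolerance = 1e-9)
  expect_gt(min(scaled_jacobian(tm)), 0.3)

  sph <- superellipsoid_mesh(c(10, 10, 10), 2, n_theta = 24L, n_phi = 36L)
  tms <- generate_tet_mesh(sph, 2)
  expect_equal(sum(tet_volumes(tms)), 4 / 3 * pi * 1000, tolerance = 0.05)
  expect_gt(min(scaled_jacobian(tms)), 0.3)
  # stair-step boundary stays within one target edge of the true surface
  bf <- boundary_faces(tms)
  bverts <- tms$nodes[unique(as.vector(bf[, 1:3])), ]
  r <- sqrt(rowSums(bverts^2))
  expect_lt(max(abs(r - 10)), 2)
})

test_that("tetrahedralising a non-watertight surface is a topology error", {
  cube <- box_surface()
  holey <- surface_mesh(cube$vertices, cube$triangles[-1, ])
  expect_error(generate_tet_mesh(holey, 0.5),
               class = "footform_topology_error")
})

test_that("rigid perturbation stores an exact recoverable ground truth", {
  m <- generate_foot_bones(default_archetype("NF"))$meshes$talus
  p0 <- perturb_shape(m, c(0, 0, 0), c(0, 0, 0), 0)
  expect_equal(p0$vertices, m$vertices, tolerance = 1e-15)
  pt <- perturb_shape(m, c(0, 0, 0), c(3, 0, 0), 0)
  d <- sqrt(rowSums((pt$vertices - m$vertices)^2))
  expect_equal(d, rep(3, nrow(m$vertices)), tolerance = 1e-12)
  n1 <- perturb_shape(m, c(5, -3, 2), c(1, 2, 3), noise_sd = 0.1, seed = 7)
  n2 <- perturb_shape(m, c(5, -3, 2), c(1, 2, 3), noise_sd = 0.1, seed = 7)
  expect_identical(n1$vertices, n2$vertices)
})

test_that("density phantoms reproduce their defining patterns", {
  tm <- generate_tet_mesh(box_surface(4, 4, 4), 1)
  u <- make_density_phantom(tm, "uniform", value = 1.0)
  expect_true(all(u == 1.0))
  cs <- make_density_phantom(tm, "cortical_shell", rho_trab = 0.3)
  # brute-force boundary ownership scan
  bf <- boundary_faces(tm)
  own <- sort(unique(bf[, "element"]))
  expect_identical(sort(which(cs == 1.8)), own)
  expect_true(all(cs[-own] == 0.3))
  g <- make_density_phantom(tm, "gradient")
  zc <- (tm$nodes[tm$tets[, 1], 3] + tm$nodes[tm$tets[, 2], 3] +
         tm$nodes[tm$tets[, 3], 3] + tm$nodes[tm$tets[, 4], 3]) / 4
  expect_true(all(g[zc == min(zc)] == min(g)))
  expect_true(all(g[zc == max(zc)] == max(g)))
  expect_error(make_density_phantom(tm, "swirl"),
               class = "footform_parameter_error")
})

test_that("pressure series honour shares, GRF template and scheme zeros", {
  for (a in c("NF", "HB", "FB")) {
    p <- default_archetype(a, seed = 3)
    ser <- generate_pressure_series(p, n_frames = 51L)
    grf <- compute_grf(ser)
    # two-peak template: peak force ~ 1.1 BW
    expect_equal(max(grf), 1.1 * p$body_mass * 9.81, tolerance = 0.02)
    # regional integrals proportional to shares within 2%
    rmap <- region_map(dim(ser$frames)[2:3], a)
    pm <- matrix(ser$frames, nrow = 51)
    for (r in names(p$regional_load_shares)) {
      cells <- which(rmap == r)
      fr <- rowSums(pm[, cells, drop = FALSE]) * cell_area(ser) * 1e-3
      expect_equal(sum(fr) / sum(grf), unname(p$regional_load_shares[[r]]),
                   tolerance = 0.02)
    }
    if (a != "NF") {
      nf_map <- region_map(dim(ser$frames)[2:3], "NF")
      dead <- c("other_toes", "medial_midfoot", "lateral_midfoot",
                if (a == "FB") "hallux")
      cells <- which(nf_map %in% dead)
      expect_true(all(pm[, cells] == 0))
    }
  }
})

test_that("single-region loading keeps the CoP at that region's centroid", {
  base <- default_archetype("FB")
  shares <- c(medial_forefoot = 0, lateral_forefoot = 0,
              medial_rearfoot = 1, lateral_rearfoot = 0)
  p <- archetype_params(165.86, 65.25, 0.7, 65, 47.5, shares, "FB")
  ser <- generate_pressure_series(p, noise_cv = 0)
  rmap <- region_map(dim(ser$frames)[2:3], "FB")
  cen <- region_centroids(rmap, ser$cell_size)["medial_rearfoot", ]
  traj <- cop_trajectory(ser)
  ok <- is.finite(traj$x_mm)
  expect_true(all(abs(traj$x_mm[ok] - cen["x"]) < 1e-9))
  expect_true(all(abs(traj$y_mm[ok] - cen["y"]) < 1e-9))
})

test_that("pressure generator rejects degenerate sampling requests", {
  p <- default_archetype("NF")
  expect_error(generate_pressure_series(p, n_frames = 5L),
               class = "footform_parameter_error")
  expect_error(generate_pressure_series(p, grid_shape = c(3L, 6L)),
               class = "footform_parameter_error")
})

test_that("assembled foot models pass the quality gate with all sets present", {
  for (a in c("NF", "FB")) {
    mesh <- generate_foot_model(default_archetype(a), target_edge = 11)
    q <- check_mesh_quality(mesh)
    expect_true(q$pass)
    expect_gt(q$min_jacobian, 0.3)
    expect_gt(length(mesh$node_sets$plantar), 0)
    expect_gt(length(mesh$node_sets$fixed_proximal), 0)
    expect_gt(length(mesh$node_sets$achilles), 0)
    for (k in 1:5) {
      expect_length(mesh$node_sets[[paste0("fascia_cal_", k)]], 1)
      expect_length(mesh$node_sets[[paste0("fascia_met_", k)]], 1)
    }
    expect_true(all(tet_volumes(mesh) > 0))
    expect_identical(max(mesh_components(mesh)), 1L)
  }
})
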