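# Constant-strain tetrahedral elasticity --------------------------------------

test_that("scaled Jacobian scores ideal and degenerate elements correctly", {
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  m1 <- tet_mesh(reg, matrix(1:4, 1))
  expect_equal(check_mesh_quality(m1)$min_jacobian, 1, tolerance = 1e-9)
  sliver <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 1e-6))
  q <- check_mesh_quality(tet_mesh(sliver, matrix(1:4, 1)))
  expect_lt(q$min_jacobian, 0.3)
  expect_identical(q$flagged, 1L)
  expect_false(q$pass)
  lat <- generate_tet_mesh(box_surface(3, 2, 2), 1)
  expect_true(check_mesh_quality(lat)$pass)
})

test_that("single-tet stiffness is symmetric PSD with six rigid modes", {
  set.seed(11)
  nodes <- matrix(rnorm(12), 4, 3)
  if (det(rbind(nodes[2, ] - nodes[1, ], nodes[3, ] - nodes[1, ],
                nodes[4, ] - nodes[1, ])) < 0) nodes <- nodes[c(1, 2, 4, 3), ]
  m <- tet_mesh(nodes, matrix(1:4, 1), element_sets = list(all = 1L))
  asm <- assemble_stiffness(m, list(all = material(1000, 0.3)))
  K <- as.matrix(asm$K)
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < max(abs(ev)) * 1e-10), 6L)
  asm2 <- assemble_stiffness(m, list(all = material(2000, 0.3)))
  expect_equal(as.matrix(asm2$K), 2 * K, tolerance = 1e-12)
  for (i in 1:100) {
    u <- rnorm(12)
    expect_gte(sum(u * (K %*% u)), -1e-9 * sum(u^2))
  }
})

test_that("missing element materials are refused", {
  m <- bar_mesh(4, 2, 1)
  expect_error(assemble_stiffness(m, list(nonexistent = material(1, 0.3))),
               class = "footform_input_error")
})

test_that("plantar pressure produces consistent nodal loads", {
  # flat 1000 mm^2 patch: bottom of a 40x25x4 block under 100 kPa
  tm <- generate_tet_mesh(box_surface(40, 25, 4), 4)
  tm$node_sets$plantar <- which(abs(tm$nodes[, 3]) < 1e-9)
  bf <- boundary_faces(tm)
  onpl <- matrix(bf[, 1:3] %in% tm$node_sets$plantar, ncol = 3)
  faces <- as.data.frame(bf[rowSums(onpl) == 3, , drop = FALSE])
  names(faces) <- c("n1", "n2", "n3", "element")
  faces$region <- "patch"
  f <- apply_plantar_pressure(tm, faces, c(patch = 100))
  fz <- sum(f[seq(3, length(f), 3)])
  expect_equal(fz, 100 * 1000 * 1e-3, tolerance = 1e-9)  # 100 N upward
  expect_equal(sum(f[seq(1, length(f), 3)]), 0, tolerance = 1e-9)
  expect_equal(sum(f[seq(2, length(f), 3)]), 0, tolerance = 1e-9)
  # zero pressure -> zero loads
  expect_true(all(apply_plantar_pressure(tm, faces, c(patch = 0)) == 0))
  # splitting a region leaves the load unchanged
  faces2 <- faces
  faces2$region <- ifelse(seq_len(nrow(faces2)) %% 2 == 0, "a", "b")
  f2 <- apply_plantar_pressure(tm, faces2, c(a = 100, b = 100))
  expect_equal(f2, f, tolerance = 1e-12)
  # unassigned region -> error
  expect_error(apply_plantar_pressure(tm, faces2, c(a = 100)),
               class = "footform_input_error")
})

test_that("axial spring connectors behave like textbook springs", {
  # bar with a spring across its length: fix one end, pull the far node
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0))
  dummy <- tet_mesh(rbind(nodes, c(0, 1, 0), c(0, 0, 1)),
                    matrix(c(1, 2, 3, 4), 1))
  K0 <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(12, 12))
  K <- add_connectors(K0, dummy, cbind(1, 2), k = 200)
  # elongation under axial force F: e = F / k
  Kred <- as.matrix(K)[4, 4]
  expect_equal(200 / Kred, 1, tolerance = 1e-12)  # F = 200 N -> 1 mm
  expect_equal(as.matrix(add_connectors(K0, dummy, cbind(1, 2), k = 0)),
               as.matrix(K0), tolerance = 1e-15)
  # spring energy 0.5 k e^2 for random displacements
  set.seed(2)
  for (i in 1:20) {
    u <- rnorm(12)
    nhat <- c(1, 0, 0)
    e <- sum((u[4:6] - u[1:3]) * nhat)
    expect_equal(0.5 * as.numeric(t(u) %*% as.matrix(K) %*% u),
                 0.5 * 200 * e^2, tolerance = 1e-9)
  }
  expect_error(add_connectors(K0, dummy, cbind(1, 1), k = 200),
               class = "footform_input_error")
})

test_that("uniaxial bar under 7.3 MPa traction strains by exactly 1e-3", {
  m <- bar_mesh(20, 4, 2)
  asm <- assemble_stiffness(m, list(bone = material(7300, 0.3)))
  f <- bar_tip_load(m, 7.3)
  # roller supports: clamp x at root, plus minimal lateral fixity to remove
  # rigid modes without constraining the Poisson contraction
  root <- m$node_sets$root
  ndof <- 3L * nrow(m$nodes)
  fixed_dofs <- c(3L * (root - 1L) + 1L)
  ry <- root[which.min(abs(m$nodes[root, 2]) + abs(m$nodes[root, 3]))]
  rz <- root[which.min(abs(m$nodes[root, 2] - max(m$nodes[root, 2])) +
                         abs(m$nodes[root, 3]))]
  fixed_dofs <- c(fixed_dofs, 3L * (ry - 1L) + 2L, 3L * (ry - 1L) + 3L,
                  3L * (rz - 1L) + 3L)
  free <- setdiff(seq_len(ndof), fixed_dofs)
  Kff <- asm$K[free, free]
  u <- numeric(ndof)
  u[free] <- as.numeric(Matrix::solve(Kff, f[free]))
  tip <- m$node_sets$tip
  ux <- u[3L * (tip - 1L) + 1L]
  expect_equal(mean(ux), 1e-3 * 20, tolerance = 1e-8)
  expect_equal(unname(diff(range(ux))), 0, tolerance = 1e-10)
})

test_that("patch test: imposed linear fields are reproduced exactly", {
  m <- bar_mesh(6, 3, 2)
  m$element_sets$all <- seq_len(nrow(m$tets))
  asm <- assemble_stiffness(m, list(all = material(100, 0.25)))
  A <- matrix(c(1e-3, 4e-4, -2e-4,
                3e-4, -5e-4, 1e-4,
                -1e-4, 2e-4, 6e-4), 3, 3, byrow = TRUE)
  surf <- sort(unique(as.vector(boundary_faces(m)[, 1:3])))
  ufix <- m$nodes[surf, , drop = FALSE] %*% t(A)
  sol <- fe_solve(asm$K, numeric(3L * nrow(m$nodes)), surf, m, asm$cache,
                  asm$E, asm$nu, fixed_values = ufix)
  expect_lt(sol$residual, 1e-8)
  exact <- m$nodes %*% t(A)
  expect_equal(sol$displacements, exact, tolerance = 1e-8)
  S <- (A + t(A)) / 2
  exp_strain <- c(S[1, 1], S[2, 2], S[3, 3],
                  2 * S[1, 2], 2 * S[2, 3], 2 * S[3, 1])
  for (a in 1:6)
    expect_equal(unname(sol$strain[, a]), rep(exp_strain[a], nrow(m$tets)),
                 tolerance = 1e-8)
})

test_that("global equilibrium: reactions balance applied loads", {
  m <- bar_mesh(12, 4, 2)
  asm <- assemble_stiffness(m, list(bone = material(7300, 0.3)))
  f <- bar_tip_load(m, 5)
  sol <- fe_solve(asm$K, f, m$node_sets$root, m, asm$cache, asm$E, asm$nu)
  expect_lt(sol$residual, 1e-8)
  for (c3 in 1:3) {
    applied <- sum(f[seq(c3, length(f), 3)])
    reac <- sum(sol$reactions[seq(c3, length(sol$reactions), 3)])
    expect_equal(applied + reac, 0, tolerance = 1e-6 * max(1, abs(applied)))
  }
})

test_that("insufficiently constrained systems raise a singular-system error", {
  m <- bar_mesh(8, 4, 1)
  asm <- assemble_stiffness(m, list(bone = material(100, 0.3)))
  onenode <- m$node_sets$root[1]
  suppressWarnings(
    expect_error(fe_solve(asm$K, bar_tip_load(m, 1), onenode, m, asm$cache,
                          asm$E, asm$nu),
                 class = "footform_singular_error"))
})

test_that("von Mises invariants hold for canonical stress states", {
  expect_equal(von_mises(c(5, 0, 0, 0, 0, 0)), 5)
  expect_equal(von_mises(c(-3, 0, 0, 0, 0, 0)), 3)
  expect_equal(von_mises(c(7, 7, 7, 0, 0, 0)), 0)
  expect_equal(von_mises(c(0, 0, 0, 2, 0, 0)), 2 * sqrt(3))
  expect_equal(von_mises(c(0, 0, 0, 0, 0, -1.5)), 1.5 * sqrt(3))
})

test_that("cantilever deflection converges monotonically towards beam theory", {
  E <- 1000; nu <- 0.3; Lb <- 40; h <- 4; P <- 1
  I <- h^4 / 12
  eb <- P * Lb^3 / (3 * E * I)
  err <- sapply(1:3, function(n) {
    tm <- generate_tet_mesh(box_surface(Lb, h, h), h / n)
    tm$element_sets$all <- seq_len(nrow(tm$tets))
    asm <- assemble_stiffness(tm, list(all = material(E, nu)))
    fixed <- which(abs(tm$nodes[, 1]) < 1e-9)
    tipn <- which(abs(tm$nodes[, 1] - Lb) < 1e-9)
    f <- numeric(3L * nrow(tm$nodes))
    f[3L * (tipn - 1L) + 3L] <- -P / length(tipn)
    sol <- fe_solve(asm$K, f, fixed, tm, asm$cache, asm$E, asm$nu)
    abs(mean(sol$displacements[tipn, 3]) + eb) / eb
  })
  # linear tetrahedra are overly stiff in slender bending; the error must
  # shrink monotonically under refinement even though it remains large at
  # these coarse levels
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], err[1] / 2)
})

test_that("rearfoot strain-energy share orders FB > HB > NF", {
  shares <- sapply(c("NF", "HB", "FB"), function(a) {
    p <- default_archetype(a, seed = 0)
    mesh <- generate_foot_model(p, target_edge = 11)
    ser <- generate_pressure_series(p)
    st <- regional_stats(ser, region_map(dim(ser$frames)[2:3], a))
    lc <- foot_load_case(mesh, setNames(st$mean_kpa, st$region),
                         p$body_mass * 9.81)
    asm <- assemble_stiffness(mesh, default_materials())
    K <- add_connectors(asm$K, mesh, lc$connector_pairs, lc$connector_k)
    sol <- fe_solve(K, lc$f, lc$fixed_nodes, mesh, asm$cache, asm$E, asm$nu)
    en <- strain_energy(sol, asm$cache)
    sum(en[(mesh$nodes[mesh$tets[, 1], 2] + mesh$nodes[mesh$tets[, 2], 2] +
            mesh$nodes[mesh$tets[, 3], 2] + mesh$nodes[mesh$tets[, 4], 2]) / 4 <
           0.31 * p$foot_length]) / sum(en)
  })
  expect_true(shares[["FB"]] > shares[["HB"]])
  expect_true(shares[["HB"]] > shares[["NF"]])
})
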