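# ICP, correspondence, SSM, error maps and Hausdorff --------------------------

test_that("ICP of a mesh onto itself is the identity", {
  m <- generate_foot_bones(default_archetype("NF"))$meshes$talus
  fit <- icp_align(m, m)
  expect_lt(fit$rms, 1e-9)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
})

test_that("ICP recovers known rigid transforms on noiseless inputs", {
  m <- generate_foot_bones(default_archetype("NF"))$meshes$calcaneus
  for (seed in 0:19) {
    pert <- bounded_perturbation(m, seed)
    fit <- icp_align(m, pert)
    tt <- attr(pert, "true_transform")
    expect_lt(fit$rms, 1e-3)
    expect_lt(norm(fit$transform$rotation - tt$rotation, "F"), 1e-3)
    expect_lt(max(abs(fit$transform$translation - tt$translation)), 1e-3)
  }
})

test_that("ICP RMS history is monotone non-increasing", {
  b <- generate_foot_bones(default_archetype("HB", seed = 5))
  for (bn in c("calcaneus", "metatarsal_2", "fibula")) {
    m <- b$meshes[[bn]]
    fit <- icp_align(m, bounded_perturbation(m, 31))
    expect_true(all(diff(fit$rms_history) <= 1e-12))
  }
})

test_that("degenerate collinear vertex sets raise an alignment error", {
  line <- surface_mesh(cbind(seq_len(12), 0, 0),
                       cbind(1:10, 2:11, 3:12))
  expect_error(icp_align(line, line), class = "footform_alignment_error")
})

test_that("closest-point correspondence is idempotent and topology-preserving", {
  m <- generate_foot_bones(default_archetype("NF"))$meshes$metatarsal_1
  self <- correspond(m, m)
  expect_equal(self$vertices, m$vertices, tolerance = 1e-9)
  expect_identical(self$triangles, m$triangles)
  vn <- vertex_normals(m)
  infl <- surface_mesh(m$vertices + vn, m$triangles)
  cor <- correspond(m, infl)
  disp <- sqrt(rowSums((cor$vertices - m$vertices)^2))
  expect_equal(mean(disp), 1.0, tolerance = 0.05)
  expect_identical(nrow(cor$triangles), nrow(m$triangles))
  expect_error(correspond(m, surface_mesh(matrix(0, 0, 3),
                                          matrix(0L, 0, 3))),
               class = "footform_input_error")
})

test_that("centroid alignment centres shapes and preserves geometry", {
  b <- generate_foot_bones(default_archetype("NF"))
  m <- b$meshes$talus
  shifted <- lapply(c(0, 10, -25), function(d)
    surface_mesh(sweep(m$vertices, 2, c(d, 2 * d, -d), "+"), m$triangles))
  al <- centroid_align(shifted)
  for (s in al) expect_equal(colMeans(s$vertices), c(0, 0, 0),
                             tolerance = 1e-9)
  expect_equal(al[[1]]$vertices, al[[2]]$vertices, tolerance = 1e-9)
  d0 <- dist(m$vertices[1:20, ])
  d1 <- dist(al[[3]]$vertices[1:20, ])
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)
})

test_that("shape PCA matches a dense covariance eigendecomposition", {
  set.seed(7)
  tris <- matrix(c(1, 2, 3), 1)
  shapes <- lapply(1:5, function(i)
    surface_mesh(matrix(rnorm(30, sd = 2), 10, 3), tris))
  ssm <- build_ssm(shapes)
  X <- t(sapply(shapes, function(s) as.vector(t(s$vertices))))
  ev <- eigen(cov(X), symmetric = TRUE)$values[seq_along(ssm$variances)]
  expect_equal(ssm$variances, ev, tolerance = 1e-9)
  expect_true(all(diff(ssm$variances) <= 1e-12))
  expect_lte(length(ssm$variances), length(shapes) - 1L)
  # modes orthonormal
  G <- crossprod(ssm$modes)
  expect_equal(G, diag(ncol(ssm$modes)), tolerance = 1e-9)
  # full-mode reconstruction is exact
  for (i in c(1, 4)) {
    rec <- ssm_shape(ssm, ssm$scores[i, ])
    expect_equal(rec$vertices, shapes[[i]]$vertices, tolerance = 1e-6)
  }
})

test_that("SSM rank behaviour on degenerate shape sets", {
  m <- generate_foot_bones(default_archetype("NF"))$meshes$talus
  two <- build_ssm(list(m, perturb_shape(m, c(0, 0, 0), c(1, 0, 0))))
  expect_identical(sum(two$variances > 1e-9), 1L)
  three <- build_ssm(list(m, m, m))
  expect_true(all(three$variances < 1e-12))
  expect_error(build_ssm(list(m)), class = "footform_input_error")
})

test_that("signed error maps follow the outward-growth convention", {
  m <- generate_foot_bones(default_archetype("NF"))$meshes$calcaneus
  expect_equal(unclass(error_map(m, m)), rep(0, nrow(m$vertices)),
               tolerance = 1e-12, ignore_attr = TRUE)
  vn <- vertex_normals(m)
  infl <- surface_mesh(m$vertices + 2 * vn, m$triangles)
  em <- error_map(m, infl)
  expect_equal(unclass(em), rep(2, nrow(m$vertices)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # swapping reference and morphed flips the sign (inflation case)
  em_rev <- error_map(infl, m)
  expect_true(all(em_rev < 0))
  expect_equal(mean(em_rev), -2, tolerance = 0.1)
  expect_error(error_map(m, surface_mesh(m$vertices[-1, , drop = FALSE],
                                         matrix(c(1L, 2L, 3L), 1))),
               class = "footform_input_error")
  # unsigned mode works on arbitrary meshes
  emu <- error_map(m, infl, signed = FALSE)
  expect_equal(mean(emu), 2, tolerance = 0.1)
})

test_that("Hausdorff summaries match rigid offsets and the brute-force oracle", {
  m <- superellipsoid_mesh(c(8, 5, 3), 2.2, taper = 0.15, bend = 0.1,
                           n_theta = 8L, n_phi = 10L)  # 132 triangles
  expect_lt(hausdorff(m, m)$hausdorff, 1e-12)
  mt <- perturb_shape(m, c(0, 0, 0), c(3, 0, 0))
  h <- hausdorff(m, mt)
  expect_equal(h$hausdorff, 3, tolerance = 1e-6)
  expect_gte(h$hausdorff, h$hausdorff_ab - 1e-12)
  expect_gte(h$hausdorff, h$hausdorff_ba - 1e-12)

  m2 <- random_blob(21)
  h12 <- hausdorff(m, m2)
  oracle <- hausdorff_oracle(m, m2)
  expect_equal(h12$hausdorff_ab, oracle$max, tolerance = 1e-9)
  expect_equal(h12$dist_ab, oracle$all, tolerance = 1e-9)
  expect_equal(h12$gaussian_mean, mean(c(h12$dist_ab, h12$dist_ba)),
               tolerance = 1e-12)
  expect_gte(h12$gaussian_sd, 0)

  # triangle-inequality-like bound on translated copies
  mA <- m
  mB <- perturb_shape(m, c(0, 0, 0), c(2, 0, 0))
  mC <- perturb_shape(m, c(0, 0, 0), c(5, 0, 0))
  expect_lte(hausdorff(mA, mC)$hausdorff,
             hausdorff(mA, mB)$hausdorff + hausdorff(mB, mC)$hausdorff + 1e-9)
})

test_that("morphing bound archetypes onto NF reports smaller metatarsals", {
  ref <- generate_foot_bones(default_archetype("NF", seed = 0))
  mean_signed <- sapply(c("HB", "FB"), function(a) {
    b <- generate_foot_bones(default_archetype(a, seed = 0))
    vals <- sapply(paste0("metatarsal_", 1:5), function(bn) {
      fit <- icp_align(b$meshes[[bn]], ref$meshes[[bn]])
      cor <- correspond(ref$meshes[[bn]], fit$aligned)
      mean(error_map(ref$meshes[[bn]], cor))
    })
    mean(vals)
  })
  # bound-foot metatarsals sit inside the NF reference (negative growth),
  # more so for the full-bound foot
  expect_lt(mean_signed[["HB"]], 0)
  expect_lt(mean_signed[["FB"]], mean_signed[["HB"]])
})
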