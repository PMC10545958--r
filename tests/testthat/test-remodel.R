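# Strain-adaptive density remodelling -----------------------------------------

test_that("daily stimulus scales with cycles and density as specified", {
  expect_equal(daily_stimulus(0, 1), 0)
  expect_equal(daily_stimulus(2.5, 1.8, n = 10000, m = 4, rho_max = 1.8),
               10 * 2.5, tolerance = 1e-12)
  expect_equal(10000^(1 / 4), 10)
  # strictly decreasing in density at fixed stress
  rhos <- seq(0.2, 1.8, by = 0.2)
  psis <- daily_stimulus(1, rhos)
  expect_true(all(diff(psis) < 0))
  expect_error(daily_stimulus(1, c(0.5, 0)), class = "footform_input_error")
})

test_that("density update has a lazy zone, linear excess response and clamps", {
  pr <- remodel_params(setpoint_stimulus = 50, lazy_zone_halfwidth = 0.1,
                       rate_constant = 2e-4, dt = 1)
  rho <- rep(1, 5)
  expect_identical(update_density(rho, rep(50, 5), pr), rho)
  expect_identical(update_density(rho, rep(50 * 1.05, 5), pr), rho)
  # psi = 2 psi* (1+w): drho = c_r * psi* * (1+w) * dt
  up <- update_density(rho, rep(2 * 50 * 1.1, 5), pr)
  expect_equal(up, rho + 2e-4 * 50 * 1.1, tolerance = 1e-12)
  # clamped at rho_max under sustained overload
  expect_identical(update_density(rep(1.8, 3), rep(1e6, 3), pr),
                   rep(1.8, 3))
  # per-step cap limits large excursions
  pr2 <- remodel_params(rate_constant = 1, max_step = 0.05)
  expect_equal(update_density(1, 1e4, pr2), 1.05, tolerance = 1e-12)
})

test_that("density-modulus coupling matches the power law and bone modulus", {
  expect_equal(modulus_from_density(0.5, B = 1000, beta = 1), 500)
  expect_equal(modulus_from_density(1.24), 3790 * 1.24^3, tolerance = 1e-12)
  expect_equal(modulus_from_density(1.24), 7300, tolerance = 0.02)
  rhos <- seq(0.1, 1.8, by = 0.1)
  expect_true(all(diff(modulus_from_density(rhos)) > 0))
})

test_that("remodel parameter validation enforces physical ranges", {
  expect_error(remodel_params(setpoint_stimulus = 0),
               class = "footform_parameter_error")
  expect_error(remodel_params(lazy_zone_halfwidth = 1),
               class = "footform_parameter_error")
  expect_error(remodel_params(rho_min = 2, rho_max = 1),
               class = "footform_parameter_error")
})

# shared bar model: uniform uniaxial stress, so the stimulus field is uniform.
# Poisson's ratio 0 keeps the fully clamped root from perturbing the stress.
bar_case <- function(sigma, m) {
  f <- bar_tip_load(m, sigma)
  list(f = f, fixed_nodes = m$node_sets$root)
}
bar_mats <- list(bone = material(7300, 0))

test_that("a bar at exactly the setpoint stimulus is a fixed point", {
  m <- bar_mesh(12, 4, 1)
  pr <- remodel_params(setpoint_stimulus = 50, n_days = 10)
  # choose rho0 so that psi(rho0, sigma) = psi*: rho0 = rho_max
  # and sigma = psi*/n^(1/m)
  sigma <- 50 / 10
  rho0 <- 1.8
  # E from density so the FE field stays consistent
  hist <- run_remodelling(m, bar_case(sigma, m), rho0, pr, materials = bar_mats)
  expect_equal(hist$density[nrow(hist$density), ],
               hist$density[1, ], tolerance = 1e-12)
  expect_true(hist$converged)
})

test_that("an overloaded bar stiffens until the stimulus re-enters the lazy
           zone, matching the analytic fixed point with no lazy zone", {
  m <- bar_mesh(12, 4, 1)
  sigma <- 3  # uniform stress, MPa
  # no lazy zone: terminal density solves n^(1/m) sigma (rho_max/rho)^2 = psi*
  pr <- remodel_params(setpoint_stimulus = 50, lazy_zone_halfwidth = 0,
                       n_days = 120)
  rho_star <- 1.8 * sqrt(10 * sigma / 50)
  hist <- run_remodelling(m, bar_case(sigma, m), 0.8, pr, materials = bar_mats)
  term <- hist$density[nrow(hist$density), ]
  expect_equal(mean(term), rho_star, tolerance = 0.01)
  # monotone approach from below
  expect_true(all(diff(hist$mass_g) >= -1e-9))
  # with the lazy zone the terminal stimulus lands inside the band
  pr2 <- remodel_params(setpoint_stimulus = 50, lazy_zone_halfwidth = 0.1,
                        n_days = 80)
  hist2 <- run_remodelling(m, bar_case(sigma, m), 0.8, pr2, materials = bar_mats)
  psi_t <- hist2$psi_final
  # the stimulus approaches the band edge asymptotically from above
  expect_true(all(psi_t >= 50 * 0.9 * (1 - 1e-4) &
                    psi_t <= 50 * 1.1 * (1 + 1e-4)))
})

test_that("an unloaded bar resorbs to the minimum density", {
  m <- bar_mesh(8, 4, 1)
  pr <- remodel_params(setpoint_stimulus = 50, n_days = 40,
                       rate_constant = 0.01)
  hist <- run_remodelling(m, bar_case(0, m), 0.8, pr, materials = bar_mats)
  expect_true(all(hist$density[nrow(hist$density), ] == pr$rho_min))
  expect_true(hist$converged)
})

test_that("scaling the load increases terminal bone mass", {
  m <- bar_mesh(12, 4, 1)
  pr <- remodel_params(setpoint_stimulus = 50, n_days = 60)
  h1 <- run_remodelling(m, bar_case(2, m), 0.8, pr, materials = bar_mats)
  h2 <- run_remodelling(m, bar_case(3, m), 0.8, pr, materials = bar_mats)
  expect_gte(tail(h2$mass_g, 1), tail(h1$mass_g, 1))
})

test_that("density map comparison ranks regions and flags degeneracy", {
  pred <- c(1, 2, 3, 4, 5, 6)
  regions <- list(a = 1:2, b = 3:4, c = 5:6)
  same <- compare_density_maps(pred, pred, regions)
  expect_equal(same$rank_correlation, 1.0)
  expect_true(same$agreement)
  const <- compare_density_maps(pred, rep(1, 6), regions)
  expect_true(const$degenerate)
  expect_true(is.na(const$rank_correlation))
  expect_error(compare_density_maps(pred, pred[-1], regions),
               class = "footform_input_error")
})

test_that("a cortical-shell phantom is matched by a stressed-shell prediction", {
  tm <- generate_tet_mesh(box_surface(6, 6, 6), 1.5)
  ref <- make_density_phantom(tm, "cortical_shell", rho_trab = 0.3)
  bf <- boundary_faces(tm)
  shell <- sort(unique(bf[, "element"]))
  core <- setdiff(seq_len(nrow(tm$tets)), shell)
  # prediction from a high-stress shell: density rises where stress is high
  pred <- rep(0.5, nrow(tm$tets)); pred[shell] <- 1.6
  cmp <- compare_density_maps(pred, unclass(ref),
                              list(shell = shell, core = core))
  expect_equal(cmp$rank_correlation, 1.0)
  expect_true(cmp$agreement)
  expect_identical(which.max(cmp$table$mean_predicted),
                   which.max(cmp$table$mean_reference))
})
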