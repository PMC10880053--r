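test_that("non-interacting bodies feel no force; cell list equals all-pairs", {
  # two dumbbells far beyond every cutoff
  st <- polylobe:::db_state(rbind(c(5, 5, 5), c(15, 15, 15)),
                            rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)), 40)
  f <- compute_forces_torques(st)
  expect_equal(f$force, matrix(0, 2, 3))
  expect_equal(f$torque, matrix(0, 2, 3))
  expect_identical(f$energy, 0)

  # dense random configuration: cell-list result identical to O(N^2)
  st <- lattice_state(20, "TP", sigma_G = 0.3, seed = 9)
  st$centers <- with_seed_local(10, st$centers +
                                  matrix(runif(60, -1, 1), 20, 3)) %%
    st$box_edge
  f1 <- compute_forces_torques(st, use_cell_list = TRUE)
  f2 <- compute_forces_torques(st, use_cell_list = FALSE)
  expect_equal(f1$force, f2$force, tolerance = 1e-12)
  expect_equal(f1$torque, f2$torque, tolerance = 1e-12)
  expect_equal(f1$energy, f2$energy, tolerance = 1e-12)
})

test_that("bonded dimer sits at a zero-net-force stationary point", {
  fr <- make_fixture("dimer")
  st <- attr(fr, "state")
  f <- compute_forces_torques(st)
  expect_equal(f$force, matrix(0, 2, 3), tolerance = 1e-9)
  expect_equal(nrow(bonded_lobe_pairs(fr)), 1L)
})

test_that("zero-friction thermostat reduces to NVE velocity-Verlet", {
  st <- lattice_state(8, "DB", seed = 2, T_star = 0.5)
  p_nve <- integrator_params(T_star = 0.5, thermostat = FALSE)
  p_g0 <- integrator_params(T_star = 0.5, gamma_t = 0, gamma_r = 0,
                            thermostat = TRUE, rng_seed = 7)
  a <- step_system(st, params = p_nve, n_steps = 200)
  b <- step_system(st, params = p_g0, n_steps = 200)
  expect_equal(a$centers, b$centers, tolerance = 1e-14)
  expect_equal(a$quats, b$quats, tolerance = 1e-14)
  expect_equal(a$vels, b$vels, tolerance = 1e-14)
})

test_that("stepping is deterministic given the noise seed", {
  st <- lattice_state(8, "DB", sigma_G = 0.2, seed = 3)
  p <- integrator_params(T_star = 0.4, rng_seed = 123)
  a <- step_system(st, params = p, n_steps = 50)
  b <- step_system(st, params = p, n_steps = 50)
  expect_identical(a$centers, b$centers)
  expect_identical(a$vels, b$vels)
  expect_identical(a$angmom, b$angmom)
})

test_that("NVE energy is conserved; quaternions and rigid bodies stay exact", {
  spec <- system_spec(27, "DB", T_star = 1, rng_seed = 3)
  st <- initialize_configuration(spec)
  # relax transient contacts, then measure microcanonical drift
  st <- step_system(st, params = integrator_params(T_star = 1, rng_seed = 9),
                    n_steps = 5000)
  res <- polylobe:::run_core(st, integrator_params(T_star = 1,
                                                   thermostat = FALSE),
                             10000, 0, 100, 1, 3, TRUE, 42)
  E <- res$scalars[, 2] + res$scalars[, 3] + res$scalars[, 4]
  drift <- abs(E[length(E)] - E[1]) / abs(E[1])
  expect_lt(drift, 1e-4)

  st2 <- polylobe:::update_state(st, res)
  expect_true(all(abs(sqrt(rowSums(st2$quats^2)) - 1) < 1e-9))

  # rigid-body constraint: intra-particle site distances unchanged
  d_intra <- function(s) {
    out <- c()
    for (p in unique(s$particle)) {
      m <- as.matrix(s[s$particle == p, c("x", "y", "z")])
      out <- c(out, dist(m))
    }
    out
  }
  expect_equal(d_intra(site_positions(st2)), d_intra(site_positions(st)),
               tolerance = 1e-10)
})

test_that("kinetic temperatures equilibrate to T* (translation and rotation)", {
  for (Ts in c(0.2, 1.0)) {
    spec <- system_spec(27, "DB", T_star = Ts, rng_seed = 5)
    st <- initialize_configuration(spec)
    res <- polylobe:::run_core(st, integrator_params(T_star = Ts,
                                                     rng_seed = 11),
                               30000, 0, 200, 1, 3, TRUE, 123)
    sc <- res$scalars[-(1:25), , drop = FALSE]  # discard equilibration
    Tt <- 2 * sc[, 3] / (3 * 27)
    Tr <- 2 * sc[, 4] / (3 * 27)
    # batch-mean standard errors (samples 1 time unit apart, ~independent)
    for (Tk in list(Tt, Tr)) {
      se <- sd(Tk) / sqrt(length(Tk) / 2)  # conservative n_eff
      expect_lt(abs(mean(Tk) - Ts), 3 * se)
    }
  }
})

test_that("run_simulation obeys its recording and determinism contracts", {
  spec <- system_spec(8, "DB", T_star = 0.5, poly = poly_spec(sigma_G = 0.2),
                      rng_seed = 6)
  p <- integrator_params(T_star = 0.5, rng_seed = 21)
  # no production -> equilibration scalars only, no frames
  t0 <- run_simulation(spec, p, n_equil = 1000, n_prod = 0, log_every = 250)
  expect_length(t0$frames, 0)
  expect_true(all(t0$scalars$phase == "equilibration"))

  t1 <- run_simulation(spec, p, n_equil = 500, n_prod = 1000,
                       write_every = 250, log_every = 250)
  t2 <- run_simulation(spec, p, n_equil = 500, n_prod = 1000,
                       write_every = 250, log_every = 250)
  expect_length(t1$frames, 4)
  expect_identical(t1$scalars, t2$scalars)
  for (k in seq_along(t1$frames))
    expect_identical(t1$frames[[k]]$sites, t2$frames[[k]]$sites)
  # written trajectories are byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  write_xyz(t1$frames, f1); write_xyz(t2$frames, f2)
  expect_identical(readLines(f1), readLines(f2))

  # production log carries physical scalars (temperature checked at length
  # in the thermostat tests)
  prod <- t1$scalars[t1$scalars$phase == "production", ]
  expect_true(all(prod$T_inst > 0) && all(is.finite(prod$U)))
})

test_that("instability and hard-core violations are signalled", {
  st <- lattice_state(8, "DB", seed = 2)
  bad <- integrator_params(T_star = 1, dt = 5, thermostat = FALSE)
  st$vels <- matrix(10, 8, 3)
  expect_error(step_system(st, params = bad, n_steps = 5), "unstable|hard-core")

  # two seeds inside the surface-shift distance
  st2 <- polylobe:::db_state(rbind(c(5, 5, 5), c(5, 5, 5.9)),
                             rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)), 20)
  expect_error(compute_forces_torques(st2), "hard-core")
})
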