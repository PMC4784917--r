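test_that("physical-to-dimensionless conversions reproduce worked values", {
  # 100 nm hydrodynamic diameter in 1 mPa s water at 293 K
  tau <- brownian_relaxation_time(1e-3, 100e-9, 293)
  expect_equal(tau, 3 * 1e-3 * pi * (100e-9)^3 / 6 / (k_B * 293))
  expect_equal(tau, 3.883e-4, tolerance = 1e-3)
  expect_equal(brownian_relaxation_time(1e-3, 0, 293), 0)

  expect_equal(unitless_field(1e-18, 5e-3, 300), 1.207, tolerance = 1e-3)
  expect_equal(unitless_field(0, 5e-3, 300), 0)
  expect_equal(unitless_field(2e-18, 5e-3, 300),
               2 * unitless_field(1e-18, 5e-3, 300))

  expect_equal(unitless_frequency(400, 0.5e-3), 0.2)
  expect_equal(unitless_frequency(1 / tau, tau), 1)
  expect_equal(unitless_frequency(1000, 0.5e-3), 0.5)

  expect_equal(master_variable(6, 0.5), 12)
  expect_equal(master_variable(3, 3), 1)
  expect_identical(master_variable(2 * 6, 2 * 0.5), master_variable(6, 0.5))

  expect_equal(reynolds_number(1e3, 1e3, 1e-7, 1e-3), 1e-5)
  expect_equal(reynolds_number(1e3, 0, 1e-7, 1e-3), 0)
  expect_equal(reynolds_number(1, 1, 1, 1), 1)

  expect_equal(moment_from_core(20e-9, 250e3), 8.378e-18, tolerance = 1e-3)
  expect_equal(moment_from_core(0, 250e3), 0)
  expect_equal(moment_from_core(20e-9, 500e3), 2 * moment_from_core(20e-9, 250e3))
})

test_that("domain errors are raised for non-physical inputs", {
  expect_error(brownian_relaxation_time(-1e-3, 1e-7, 293), "viscosity")
  expect_error(brownian_relaxation_time(1e-3, 1e-7, 0), "temperature")
  expect_error(unitless_field(1e-18, 5e-3, -1), "temperature")
  expect_error(unitless_frequency(0, 1e-3), "frequency")
  expect_error(master_variable(1, 0), "omega")
  expect_error(reynolds_number(1e3, 1e3, 1e-7, 0), "viscosity")
  expect_error(sample_lognormal_radii(50e-9, -1e-9, 10), "s_r")
  expect_error(msb_environment(viscosity = 0), "viscosity")
  expect_error(msb_particle_spec(0, 50e-9, 250e3), "radii")
})

test_that("the master variable cancels temperature exactly", {
  mu <- moment_from_core(20e-9, 250e3)
  A_at <- function(temp) {
    tau <- brownian_relaxation_time(1e-3, 100e-9, temp)
    master_variable(unitless_field(mu, 5e-3, temp),
                    unitless_frequency(1000, tau))
  }
  As <- vapply(seq(250, 350, 10), A_at, numeric(1))
  expect_lt(max(abs(As / As[1] - 1)), 1e-12)
})

test_that("SI unit round-trips are exact", {
  # mT -> T and nm -> m rescaling commutes with the conversions
  expect_identical(unitless_field(1e-18, 5e-3, 300),
                   unitless_field(1e-18, 5 * 1e-3, 300))
  r_nm <- 20
  expect_equal(moment_from_core(r_nm * 1e-9, 250e3),
               250e3 * (4 / 3) * pi * (r_nm)^3 * 1e-27,
               tolerance = 1e-15)
})

test_that("lognormal radius sampler is moment-matched and distributed per the model", {
  expect_identical(sample_lognormal_radii(50e-9, 0, 5), rep(50e-9, 5))

  # scale parameter for a 10% coefficient of variation
  sig <- sqrt(log(1 + 0.1^2))
  expect_equal(sig, 0.09975, tolerance = 1e-4)

  r <- sample_lognormal_radii(50e-9, 5e-9, 1e6, seed = 42)
  expect_true(all(r > 0))
  expect_lt(abs(mean(r) / 50e-9 - 1), 0.005)
  expect_lt(abs(sd(r) / 5e-9 - 1), 0.02)

  # distributional test against the analytic lognormal density
  r2 <- sample_lognormal_radii(50e-9, 5e-9, 1e5, seed = 43)
  ks <- stats::ks.test(r2, stats::plnorm,
                       meanlog = log(50e-9) - sig^2 / 2, sdlog = sig)
  expect_gt(ks$p.value, 0.01)

  # deterministic for a fixed seed
  expect_identical(sample_lognormal_radii(50e-9, 5e-9, 100, seed = 7),
                   sample_lognormal_radii(50e-9, 5e-9, 100, seed = 7))
})

test_that("ensemble master variable matches closed-form lognormal moments", {
  spec <- msb_particle_spec(20e-9, 50e-9, Ms = 250e3, cv = 0.10)
  env <- msb_environment(1e-3, 293)
  fld <- msb_drive_field(5e-3, 1000)

  # <r^3> = m^3 (1 + cv^2)^3 for a moment-matched lognormal, so the dispersion
  # factor cancels between <xi0> (core volume) and <Omega> (hydrodynamic
  # volume) and the exact ensemble A equals the monodisperse A.
  mu_mono <- moment_from_core(20e-9, 250e3)
  tau_mono <- brownian_relaxation_time(1e-3, 100e-9, 293)
  A_exact <- master_variable(unitless_field(mu_mono, 5e-3, 293),
                             unitless_frequency(1000, tau_mono))

  ens <- sample_ensemble(spec, env, n = 1e5, seed = 5)
  expect_lt(abs(ensemble_master_variable(ens, fld, env) / A_exact - 1), 0.01)

  # monodisperse ensemble reproduces the single-particle value exactly
  spec0 <- msb_particle_spec(20e-9, 50e-9, Ms = 250e3, cv = 0)
  ens0 <- sample_ensemble(spec0, env, n = 10, seed = 5)
  expect_equal(ensemble_master_variable(ens0, fld, env), A_exact,
               tolerance = 1e-12)

  # linear in the drive amplitude
  fld2 <- msb_drive_field(10e-3, 1000)
  expect_equal(ensemble_master_variable(ens, fld2, env),
               2 * ensemble_master_variable(ens, fld, env), tolerance = 1e-12)
})
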