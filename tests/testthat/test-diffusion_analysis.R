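test_that("ensemble MSD equals the naive double-loop oracle", {
  ens <- make_gaussian_walk_fixture(D = 0.02, n_walkers = 5, duration = 9,
                                    seed = 31)
  msd <- compute_msd(ens)
  # brute force: loop over walkers and times
  for (r in seq_along(ens$times)) {
    acc <- 0
    for (w in 1:5)
      acc <- acc + (ens$x[r, w] - ens$x[1, w])^2 + (ens$y[r, w] - ens$y[1, w])^2
    expect_equal(msd$msd[r], acc / 5)
  }
  expect_equal(msd$msd[1], 0)
})

test_that("stationary trajectories give identically zero MSD", {
  ens <- make_gaussian_walk_fixture(D = 0, n_walkers = 3, duration = 20)
  expect_true(all(compute_msd(ens)$msd == 0))
})

test_that("alpha fit recovers exact power laws to machine precision", {
  t_grid <- seq(1, 2000, by = 7)
  for (a in seq(0.1, 1.0, by = 0.1)) {
    msd <- make_powerlaw_msd_fixture(D = 0.200e-3, alpha = a, t_grid = t_grid)
    fit <- fit_alpha(msd, window = c(1, 2000))
    expect_equal(fit$alpha, a, tolerance = 1e-10)
    expect_equal(fit$log_prefactor, log(4 * 0.200e-3), tolerance = 1e-8)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
  }
  expect_error(fit_alpha(make_powerlaw_msd_fixture(1e-4, 0.5, c(1, 2, 3))),
               "5")
})

test_that("apparent diffusion median matches the isotropic Gaussian closed form", {
  # 2-D squared displacement is exponential => median D_app = ln(2) * D
  D <- 0.200e-3
  ens <- make_gaussian_walk_fixture(D, n_walkers = 10000, duration = 1000,
                                    seed = 12, record_interval = 100)
  dapp <- compute_dapp(ens, t_obs = 1000)
  expect_lt(abs(dapp$median / (log(2) * D) - 1), 0.03)
  expect_true(all(dapp$values >= 0))
  expect_equal(dapp$median, median(dapp$values))
  expect_error(compute_dapp(ens, t_obs = 333), "recorded")
})

test_that("Kusumi fit inverts its own model exactly", {
  D <- 0.200e-3
  L_true <- 0.25
  t_grid <- seq(1, 2000)
  msd <- data.frame(t = t_grid,
                    msd = (L_true^2 / 3) * (1 - exp(-10 * D * t_grid / L_true^2)),
                    n = 1)
  fit <- fit_kusumi(msd, D_input = D)
  expect_equal(fit$L, 0.25, tolerance = 1e-4)
  expect_lt(fit$residual, 1e-12)
})

test_that("residence time inverts the anomalous spread law", {
  # alpha = 1 reduces to the normal-diffusion identity
  expect_equal(residence_time(0.1, 1, 0.200e-3), 0.1^2 / (4 * 0.200e-3))
  # direct evaluation at the PSD scale
  expect_equal(residence_time(0.125, 0.3, 0.138e-3),
               (0.125^2 / (4 * 0.138e-3))^(1 / 0.3), tolerance = 1e-12)
  expect_equal(residence_time(0.125, 0.3, 0.138e-3), 6.9e4, tolerance = 0.01)
  expect_equal(residence_time(0.125, 0.4, 0.138e-3), 4.3e3, tolerance = 0.01)
  # strictly decreasing in alpha, strictly increasing in distance
  a_grid <- seq(0.2, 1, by = 0.1)
  expect_true(all(diff(residence_time(0.125, a_grid, 0.2e-3)) < 0))
  d_grid <- seq(0.05, 0.5, by = 0.05)
  expect_true(all(diff(residence_time(d_grid, 0.5, 0.2e-3)) > 0))
  expect_error(residence_time(0.1, 0, 0.2e-3), "alpha")
})

test_that("powerlaw fixture and residence time satisfy the algebraic identity", {
  D <- 0.200e-3; a <- 0.35; d <- 0.1
  t_star <- residence_time(d, a, D)
  msd <- make_powerlaw_msd_fixture(D, a, t_grid = t_star)
  expect_equal(msd$msd, d^2, tolerance = 1e-12)
})

test_that("dissociation constants convert to kBT binding energies", {
  expect_equal(kd_to_kbt(1e-6), 13.7, tolerance = 0.005)
  expect_equal(kd_to_kbt(1e-5), 11.4, tolerance = 0.005)
  # linear in ln(1/Kd): squaring Kd doubles the energy
  expect_equal(kd_to_kbt(1e-8), 2 * kd_to_kbt(1e-4), tolerance = 1e-12)
  expect_error(kd_to_kbt(2), "Kd")
  expect_error(kd_to_kbt(0), "Kd")
})

test_that("unbinding time follows the attempt-rate arithmetic", {
  expect_equal(unbind_time(13), 1e-6 / exp(-13), tolerance = 1e-12)
  expect_equal(unbind_time(13), 0.44, tolerance = 0.01)
  expect_equal(unbind_time(0), 1e-6)
})

test_that("PSD crowding calculators reproduce the printed arithmetic", {
  expect_equal(psd_mass_fraction(1.83e-15, 3.06e6, 1.4e-21), 42.7,
               tolerance = 0.002)
  # mass = volume * density gives exactly 100%
  expect_equal(psd_mass_fraction(4.284e-15, 3.06e6, 1.4e-21), 100)
  # linear in mass
  expect_equal(psd_mass_fraction(0.915e-15, 3.06e6, 1.4e-21),
               psd_mass_fraction(1.83e-15, 3.06e6, 1.4e-21) / 2)
  # occupied volume: 100 kDa molecule has r ~ 3.05 nm, V ~ 119 nm^3
  expect_equal(occupied_volume_fraction(1, 1e5, 119), 1, tolerance = 0.01)
  expect_equal(occupied_volume_fraction(0, 1e5, 3.06e6), 0)
  expect_equal(occupied_volume_fraction(10000, 1e5, 3.06e6), 0.39,
               tolerance = 0.01)
})

test_that("retention fraction counts wrapped positions half-openly", {
  cfg <- unit_config(width = 10, duration = 20, n_walkers = 5)
  fld <- make_obstacle_field(cfg, 1)                 # frozen walkers
  inner <- psd_region(2, 2, 8, 8)
  fld$sites[5 * cfg$nx + 5 + 1] <- as.raw(0)
  ens <- simulate_ensemble(cfg, fld, start_fixed(5, 5), seed = 2)
  expect_equal(retention_fraction(ens, inner, 20), 1)
  outside <- psd_region(0, 0, 2, 2)
  expect_equal(retention_fraction(ens, outside, 20), 0)
  expect_error(retention_fraction(ens, inner, 7.5), "recorded")
})
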