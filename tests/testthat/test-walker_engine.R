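test_that("free walker takes unit lattice steps, all four equally likely", {
  cfg <- unit_config(width = 50, duration = 20000, n_walkers = 1)
  fld <- make_obstacle_field(cfg, 0)
  tr <- simulate_walker(cfg, fld, c(25, 25), walker_seed = 3)
  dxs <- diff(tr$x_um)
  dys <- diff(tr$y_um)
  # one axis moves by exactly dx each step, the other stays
  expect_true(all(abs(dxs) + abs(dys) == 1))
  moves <- paste(dxs, dys)
  counts <- table(factor(moves, levels = c("-1 0", "1 0", "0 -1", "0 1")))
  chi <- suppressWarnings(chisq.test(counts))
  expect_gt(chi$p.value, 1e-4)
})

test_that("collisions with obstacles return the walker to its origin", {
  cfg <- unit_config(width = 10, duration = 200, n_walkers = 1)
  fld <- make_obstacle_field(cfg, 1)
  fld$sites[5 * cfg$nx + 5 + 1] <- as.raw(0)   # free site at (5, 5) only
  tr <- simulate_walker(cfg, fld, c(5, 5), walker_seed = 1)
  expect_true(all(tr$i == 5 & tr$j == 5))
  expect_true(all(tr$x_um == tr$x_um[1]))
})

test_that("trajectories are reproducible for a fixed seed", {
  cfg <- unit_config(width = 30, duration = 300, n_walkers = 8)
  fld <- make_obstacle_field(cfg, 0.3, seed = 2)
  e1 <- simulate_ensemble(cfg, fld, seed = 5)
  e2 <- simulate_ensemble(cfg, fld, seed = 5)
  e3 <- simulate_ensemble(cfg, fld, seed = 6)
  expect_identical(e1$x, e2$x)
  expect_identical(e1$bound, e2$bound)
  expect_false(identical(e1$x, e3$x))
  # walkers use distinct streams
  expect_false(identical(e1$x[, 1], e1$x[, 2]))
})

test_that("a one-walker ensemble equals simulate_walker", {
  cfg <- unit_config(width = 20, duration = 100, n_walkers = 1)
  fld <- make_obstacle_field(cfg, 0.2, seed = 3)
  ens <- simulate_ensemble(cfg, fld, start_fixed(3, 4), seed = 9)
  tr <- simulate_walker(cfg, fld, c(3, 4), walker_seed = 9)
  expect_equal(ens$x[, 1], tr$x_um)
  expect_equal(ens$i[, 1], tr$i)
})

test_that("free-diffusion MSD matches 4 D t within sampling error", {
  cfg <- unit_config(width = 60, duration = 200, n_walkers = 400)
  fld <- make_obstacle_field(cfg, 0)
  ens <- simulate_ensemble(cfg, fld, seed = 17)
  msd <- compute_msd(ens)
  for (t in c(50, 100, 200)) {
    row <- which(msd$t == t)
    d2 <- (ens$x[row, ] - ens$x[1, ])^2 + (ens$y[row, ] - ens$y[1, ])^2
    se <- sd(d2) / sqrt(length(d2))
    expect_lt(abs(msd$msd[row] - 4 * cfg$D_free * t), 3 * se)
  }
})

test_that("unwrapped displacement is unbounded on a small torus", {
  cfg <- unit_config(width = 10, duration = 2000, n_walkers = 100)
  fld <- make_obstacle_field(cfg, 0)
  ens <- simulate_ensemble(cfg, fld, seed = 4)
  msd <- compute_msd(ens)
  expect_gt(msd$msd[nrow(msd)], (cfg$width / 2)^2)
  # wrapped indices stay on the lattice
  expect_true(all(ens$i >= 0 & ens$i < cfg$nx))
})

test_that("walkers never rest on an obstacle site unless bound there", {
  cfg <- unit_config(width = 40, duration = 400, n_walkers = 20)
  fld <- make_obstacle_field(cfg, 0.35, seed = 8)
  fld <- assign_binding(fld, 0.3, energy_fixed(2), seed = 9)
  ens <- simulate_ensemble(cfg, fld, seed = 10)
  codes <- matrix(as.integer(fld$sites[ens$j * cfg$nx + ens$i + 1L]),
                  nrow = nrow(ens$i))
  expect_true(all(codes == 0L | (codes == 2L)))
  # on a plain obstacle never; on a bindable site when bound (or for the
  # single step after a failed/isotropic release)
  expect_true(all(codes[ens$bound] == 2L))
})

test_that("binding at E = 0 never persists for consecutive steps", {
  cfg <- unit_config(width = 5, duration = 4000, n_walkers = 10)
  fld <- single_trap_field(cfg, E = 0, seed = 2)
  ens <- simulate_ensemble(cfg, fld, seed = 3)
  expect_gt(sum(ens$bound), 0)                      # binding does occur
  consec <- ens$bound[-1, , drop = FALSE] & ens$bound[-nrow(ens$bound), , drop = FALSE]
  expect_equal(sum(consec), 0L)
})

test_that("binding equilibrium matches the exact Markov-chain oracle", {
  for (E in c(0, 1, 3)) {
    cfg <- unit_config(width = 5, duration = 3000, n_walkers = 100)
    fld <- single_trap_field(cfg, E, seed = 2)
    obst <- which(fld$sites != as.raw(0), arr.ind = TRUE) - 1L
    expected <- markov_bound_fraction(cfg$nx, cfg$ny, obst[1, ], E)
    # closed form by detailed balance: bound weight e^E vs 24 free sites
    expect_equal(expected, exp(E) / (24 + exp(E)), tolerance = 1e-10)
    ens <- simulate_ensemble(cfg, fld, seed = 30 + E)
    burn <- ens$times > 500
    frac_by_walker <- colMeans(ens$bound[burn, ])
    se <- sd(frac_by_walker) / sqrt(length(frac_by_walker))
    expect_lt(abs(mean(frac_by_walker) - expected), 3 * se)
  }
})

test_that("start policies validate their preconditions", {
  cfg <- unit_config(width = 10, duration = 50, n_walkers = 2)
  fld <- make_obstacle_field(cfg, 1)
  expect_error(simulate_ensemble(cfg, fld), "unoccupied")
  fld$sites[1] <- as.raw(0)
  expect_error(simulate_walker(cfg, fld, c(5, 5)), "occupied")
  psd <- psd_region(0, 0, 5, 5)
  fld2 <- make_obstacle_field(cfg, 1, region = psd)
  expect_error(
    simulate_ensemble(cfg, fld2, start_uniform_in_region(psd)), "unoccupied")
})

test_that("reference step rule agrees with the engine on forced moves", {
  cfg <- unit_config(width = 10, duration = 10, n_walkers = 1)
  # walled-in walker stays put under both implementations
  fld <- make_obstacle_field(cfg, 1)
  fld$sites[5 * cfg$nx + 5 + 1] <- as.raw(0)
  st <- list(i = 5L, j = 5L, wi = 0L, wj = 0L, bound = FALSE)
  set.seed(1)
  for (k in 1:20) st <- step_walker(st, fld)
  expect_equal(st$i, 5L)
  expect_equal(st$j, 5L)
  # free lattice: reference rule conserves |step| = 1
  fld0 <- make_obstacle_field(cfg, 0)
  st <- list(i = 5L, j = 5L, wi = 0L, wj = 0L, bound = FALSE)
  set.seed(2)
  for (k in 1:50) {
    prev <- st
    st <- step_walker(st, fld0)
    d <- abs(st$i + st$wi * cfg$nx - prev$i - prev$wi * cfg$nx) +
         abs(st$j + st$wj * cfg$ny - prev$j - prev$wj * cfg$ny)
    expect_equal(d, 1)
  }
})
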