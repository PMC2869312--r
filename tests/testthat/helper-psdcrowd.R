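# Shared helpers: unit-lattice configs (dt = 1 ms, D_free = 0.25 um^2/ms
# gives dx = 1 um, so lattice indices coincide with physical coordinates)
# and the exact Markov-chain oracle for binding equilibrium.

unit_config <- function(width = 50, height = width, duration = 500,
                        n_walkers = 50, seed = 42L, record_interval = 1) {
  make_config(dt = 1, D_free = 0.25, width = width, height = height,
              duration = duration, n_walkers = n_walkers, seed = seed,
              record_interval = record_interval)
}

# A unit-lattice field with a single bindable obstacle of energy E on an
# n x n torus.
single_trap_field <- function(config, E, seed = 1L) {
  field <- make_obstacle_field(config, C = 1 / (config$nx * config$ny),
                               seed = seed)
  assign_binding(field, P = 1, energy_fixed(E), seed = seed)
}

# Exact stationary bound fraction for a single bindable site on an
# nx x ny torus, by brute-force enumeration of the (free sites + bound)
# Markov chain.  Built independently of the simulation engine: states and
# transition probabilities are written down directly from the model rules.
markov_bound_fraction <- function(nx, ny, obstacle, E) {
  sites <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
  is_obst <- sites$i == obstacle[1] & sites$j == obstacle[2]
  free <- which(!is_obst)
  n_free <- length(free)
  id <- function(i, j) which(sites$i == (i %% nx) & sites$j == (j %% ny))
  n_states <- n_free + 1L                       # free sites + bound state
  P <- matrix(0, n_states, n_states)
  state_of <- integer(nx * ny)
  state_of[free] <- seq_len(n_free)
  B <- n_states
  for (k in seq_len(n_free)) {
    s <- free[k]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      t <- id(sites$i[s] + d[1], sites$j[s] + d[2])
      if (is_obst[t]) P[k, B] <- P[k, B] + 0.25          # contact -> bind
      else P[k, state_of[t]] <- P[k, state_of[t]] + 0.25 # move
    }
  }
  p_un <- exp(-E)
  P[B, B] <- 1 - p_un
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    t <- id(obstacle[1] + d[1], obstacle[2] + d[2])
    P[B, state_of[t]] <- P[B, state_of[t]] + p_un / 4    # isotropic release
  }
  stopifnot(all(abs(rowSums(P) - 1) < 1e-12))
  ev <- eigen(t(P))
  pi_s <- abs(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
  pi_s <- pi_s / sum(pi_s)
  pi_s[B]
}
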