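# The five in-silico experiments, as reproducible parameterized runs.

#' Anomalous-exponent sweep over crowding
#'
#' For each crowding value: populate a whole-membrane random obstacle
#' field, run the ensemble, compute the MSD and fit the anomalous
#' exponent.  With the default geometry (2 x 2 µm torus, 400 walkers,
#' 2000 ms) the resulting alpha(C) curve is sigmoidal: alpha ~ 1 for
#' C < 0.3, a steep drop over 0.3 < C < 0.5, and alpha ~ 0 for C > 0.5.
#' Obstacle fields and walker streams are derived from `config$seed`, so
#' the sweep is reproducible.
#'
#' @param C_values crowding fractions in `[0, 1]`.
#' @param config a `sim_config`.
#' @param window alpha-fit window in ms (default `[10, duration]`).
#' @param arrangement obstacle arrangement, `"random"` or `"regular"`.
#' @return a data.frame of class `sweep_result` with one row per C:
#'   `C`, `alpha`, `r2`, `msd_final` (µm² at the last recorded time),
#'   `median_dapp` (at the largest recorded time at or below 1000 ms),
#'   `n_walkers`, `seed`.
#' @export
run_alpha_sweep <- function(C_values, config, window = c(10, Inf),
                            arrangement = "random") {
  rows <- lapply(seq_along(C_values), function(k) {
    C <- C_values[k]
    fseed <- derive_seed(config$seed, 1000L + k)
    field <- make_obstacle_field(config, C, arrangement = arrangement,
                                 seed = fseed)
    ens <- simulate_ensemble(config, field,
                             seed = derive_seed(config$seed, 2000L + k))
    msd <- compute_msd(ens)
    af <- fit_alpha(msd, window)
    t_obs <- max(ens$times[ens$times <= 1000])
    data.frame(C = C, alpha = af$alpha, r2 = af$r2,
               msd_final = msd$msd[nrow(msd)],
               median_dapp = compute_dapp(ens, t_obs)$median,
               n_walkers = config$n_walkers, seed = config$seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' PSD trapping experiment
#'
#' Receptors are released at uniform random unoccupied sites inside a
#' centered square PSD whose interior is crowded at fraction C (the
#' extra-synaptic membrane is obstacle-free), and their position is
#' queried after `t_query` ms.  The retention fraction against C is
#' switch-like: 0.25 (the PSD's share of a 1 x 1 µm membrane) at C = 0,
#' near 1 for C > 0.6.
#'
#' @param C_values crowding fractions inside the PSD.
#' @param config a `sim_config`; default geometry is a 1 x 1 µm torus
#'   simulated for 1000 ms with 400 walkers.
#' @param psd_size PSD side length in µm.
#' @param t_query query time in ms.
#' @return a `sweep_result` with columns `C`, `retention`, `n_walkers`,
#'   `seed`.
#' @export
run_trapping_experiment <- function(C_values,
                                    config = make_config(width = 1, height = 1,
                                                         duration = 1000,
                                                         n_walkers = 400),
                                    psd_size = 0.5, t_query = 1000) {
  psd <- centered_psd(config, psd_size)
  rows <- lapply(seq_along(C_values), function(k) {
    C <- C_values[k]
    field <- make_obstacle_field(config, C, region = psd,
                                 seed = derive_seed(config$seed, 1000L + k))
    ens <- simulate_ensemble(config, field, start_uniform_in_region(psd),
                             seed = derive_seed(config$seed, 2000L + k))
    data.frame(C = C, retention = retention_fraction(ens, psd, t_query),
               n_walkers = config$n_walkers, seed = config$seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Binding-fraction sweep
#'
#' Whole-membrane field crowded at `C` with a fraction P of the PSD
#' molecules able to bind the receptor (per-site energies drawn from
#' `energy`).  With the default `C = 0.45` and energies uniform on
#' 4-8 k_B*T, receptors are trapped at P = 0 while even modest binding
#' fractions (P > 0.2) restore nearly normal (if slow) diffusion.
#'
#' @param P_values bindable fractions in `[0, 1]`.
#' @param config a `sim_config`.
#' @param C crowding fraction (default 0.45).
#' @param energy an energy spec (default `energy_uniform(4, 8)`).
#' @param window alpha-fit window in ms.
#' @return a `sweep_result` with columns `P`, `alpha`, `r2`, `msd_final`,
#'   `n_walkers`, `seed`.
#' @export
run_binding_fraction_sweep <- function(P_values, config, C = 0.45,
                                       energy = energy_uniform(4, 8),
                                       window = c(10, Inf)) {
  rows <- lapply(seq_along(P_values), function(k) {
    P <- P_values[k]
    field <- make_obstacle_field(config, C,
                                 seed = derive_seed(config$seed, 1000L + k))
    field <- assign_binding(field, P, energy,
                            seed = derive_seed(config$seed, 3000L + k))
    ens <- simulate_ensemble(config, field,
                             seed = derive_seed(config$seed, 2000L + k))
    msd <- compute_msd(ens)
    af <- fit_alpha(msd, window)
    data.frame(P = P, alpha = af$alpha, r2 = af$r2,
               msd_final = msd$msd[nrow(msd)],
               n_walkers = config$n_walkers, seed = config$seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Uniform-binding energy sweep
#'
#' Whole-membrane field at crowding `C` with every PSD molecule bindable
#' (P = 1) at one shared binding energy E.  Diffusion is anomalous only
#' transiently; on the late window it is normal (alpha ~ 1) with a
#' reduced prefactor (tortuosity), the crossover time growing with E.
#'
#' @param E_values binding energies in k_B*T.
#' @param config a `sim_config`.
#' @param C crowding fraction (default 0.45).
#' @param window alpha-fit window in ms; the default `[500, Inf)` fits the
#'   late, linear part of the log-log curve.
#' @return a `sweep_result` with columns `E`, `alpha`, `r2`, `msd_final`,
#'   `n_walkers`, `seed`.
#' @export
run_uniform_binding_sweep <- function(E_values, config, C = 0.45,
                                      window = c(500, Inf)) {
  rows <- lapply(seq_along(E_values), function(k) {
    E <- E_values[k]
    field <- make_obstacle_field(config, C,
                                 seed = derive_seed(config$seed, 1000L + k))
    field <- assign_binding(field, 1, energy_fixed(E),
                            seed = derive_seed(config$seed, 3000L + k))
    ens <- simulate_ensemble(config, field,
                             seed = derive_seed(config$seed, 2000L + k))
    msd <- compute_msd(ens)
    af <- fit_alpha(msd, window)
    data.frame(E = E, alpha = af$alpha, r2 = af$r2,
               msd_final = msd$msd[nrow(msd)],
               n_walkers = config$n_walkers, seed = config$seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Regular-obstacle control
#'
#' Same pipeline as [run_alpha_sweep()] but with obstacles on a periodic
#' pattern: a regular distribution increases tortuosity (lower MSD
#' prefactor) but yields normal diffusion (alpha ~ 1), demonstrating that
#' randomness of the obstacle field, not obstruction per se, produces the
#' anomalous exponent.
#'
#' @param C crowding fraction.
#' @param config a `sim_config`.
#' @param window alpha-fit window in ms.
#' @return a one-row `sweep_result` (same columns as [run_alpha_sweep()]).
#' @export
run_regular_obstacle_control <- function(C, config, window = c(10, Inf)) {
  run_alpha_sweep(C, config, window, arrangement = "regular")
}

# Count of walkers whose wrapped position lies inside `region`, per record.
count_in_region <- function(config, region, iw, jw) {
  xw <- (iw + 0.5) * config$dx
  yw <- (jw + 0.5) * config$dx
  inside <- xw >= region$x0 & xw < region$x1 & yw >= region$y0 & yw < region$y1
  rowSums(inside)
}

#' Activity-dependent stimulation experiment
#'
#' Receptors diffuse over a membrane whose centered PSD is crowded at
#' fraction C (extra-synaptic membrane free).  The timeline has three
#' phases: `pre_ms` of free dynamics, `stim_ms` of stimulation during
#' which a random fraction `frac_activated` of the PSD molecules becomes
#' bindable at one shared energy E, and `post_ms` after the stimulus, when
#' the activated molecules revert to plain obstacles and any still-bound
#' receptor is released isotropically.  The summary statistic is the
#' percent change of the mean PSD-resident receptor count between the
#' first and last `window_ms` of the run.
#'
#' @param C_values crowding fractions.
#' @param E_values stimulation binding energies in k_B*T.
#' @param config a `sim_config`; its membrane and walker count set the
#'   geometry (defaults in the field: 2 x 2 µm, 500 walkers).
#' @param psd_size PSD side length in µm.
#' @param pre_ms,stim_ms,post_ms phase durations in ms.
#' @param frac_activated fraction of PSD molecules activated by the
#'   stimulus.
#' @param window_ms averaging window for the pre/post counts, ms.
#' @param keep_series if `TRUE`, attach the per-record PSD-resident count
#'   series for each (C, E) cell as attribute `"series"`.
#' @return a data.frame of class `stimulation_result` with one row per
#'   (C, E): `C`, `E`, `percent_change`, `pre_mean`, `post_mean`,
#'   `n_walkers`, `seed`.
#' @export
run_stimulation_experiment <- function(C_values, E_values,
                                       config = make_config(width = 2, height = 2,
                                                            duration = 1300,
                                                            n_walkers = 500),
                                       psd_size = 0.5,
                                       pre_ms = 500, stim_ms = 100,
                                       post_ms = 700,
                                       frac_activated = 0.1,
                                       window_ms = 400,
                                       keep_series = FALSE) {
  if (any(E_values < 0)) stop_invalid("E_values", "must be non-negative")
  psd <- centered_psd(config, psd_size)
  dtrec <- config$record_interval
  spr <- config$steps_per_record
  n_pre <- as.integer(round(pre_ms / dtrec)) * spr
  n_stim <- as.integer(round(stim_ms / dtrec)) * spr
  n_post <- as.integer(round(post_ms / dtrec)) * spr
  n_w <- config$n_walkers

  grid <- expand.grid(E = E_values, C = C_values)[, c("C", "E")]
  series <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))

  for (g in seq_len(nrow(grid))) {
    C <- grid$C[g]; E <- grid$E[g]
    cell_seed <- derive_seed(config$seed, 100L * g)
    base <- make_obstacle_field(config, C, region = psd,
                                seed = derive_seed(cell_seed, 1L))
    starts <- draw_start_sites(config, base, start_uniform_free(), n_w,
                               derive_seed(cell_seed, 2L))
    state <- new_state(starts, config$nx)

    # stimulated field: frac_activated of the PSD molecules become bindable
    stim_field <- assign_binding(base, frac_activated, energy_fixed(E),
                                 seed = derive_seed(cell_seed, 3L))

    r1 <- run_engine(config, base, state, n_pre, cell_seed, 0)
    s1 <- list(i = r1$final_i, j = r1$final_j, wi = r1$final_wi,
               wj = r1$final_wj, bound = r1$final_bound)
    r2 <- run_engine(config, stim_field, s1, n_stim, cell_seed, n_w)
    s2 <- list(i = r2$final_i, j = r2$final_j, wi = r2$final_wi,
               wj = r2$final_wj, bound = r2$final_bound)

    # stimulation ends: activated molecules revert to obstacles and any
    # still-bound receptor is released isotropically to a free neighbour
    s2 <- release_bound(s2, base, derive_seed(cell_seed, 4L))
    r3 <- run_engine(config, base, s2, n_post, cell_seed, 2L * n_w)

    iw <- rbind(matrix(as.integer(state$i), 1), r1$iw, r2$iw, r3$iw)
    jw <- rbind(matrix(as.integer(state$j), 1), r1$jw, r2$jw, r3$jw)
    counts <- count_in_region(config, psd, iw, jw)
    t_rec <- seq(0, by = dtrec, length.out = length(counts))
    total <- pre_ms + stim_ms + post_ms
    pre_mean <- mean(counts[t_rec < window_ms])
    post_mean <- mean(counts[t_rec > total - window_ms])
    rows[[g]] <- data.frame(C = C, E = E,
                            percent_change = 100 * (post_mean - pre_mean) / pre_mean,
                            pre_mean = pre_mean, post_mean = post_mean,
                            n_walkers = n_w, seed = config$seed)
    if (keep_series)
      series[[g]] <- data.frame(t_ms = t_rec, n_inside = counts)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stimulation_result", "data.frame")
  if (keep_series) attr(out, "series") <- series
  out
}

# Release bound walkers isotropically: each moves to a uniformly chosen
# unoccupied neighbour of its binding site (stays put, unbound, if none).
release_bound <- function(state, field, seed) {
  idx <- which(state$bound)
  if (length(idx) == 0) { state$bound[] <- FALSE; return(state) }
  nx <- field$nx; ny <- field$ny
  with_seed(seed, {
    for (w in idx) {
      i <- state$i[w]; j <- state$j[w]
      wi <- state$wi[w]; wj <- state$wj[w]
      cand <- list()
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        ti <- i + d[1]; tj <- j + d[2]; twi <- wi; twj <- wj
        if (ti < 0) { ti <- nx - 1L; twi <- twi - 1L }
        if (ti >= nx) { ti <- 0L; twi <- twi + 1L }
        if (tj < 0) { tj <- ny - 1L; twj <- twj - 1L }
        if (tj >= ny) { tj <- 0L; twj <- twj + 1L }
        if (field$sites[tj * nx + ti + 1L] == as.raw(0))
          cand[[length(cand) + 1L]] <- c(ti, tj, twi, twj)
      }
      if (length(cand) > 0) {
        p <- cand[[sample.int(length(cand), 1L)]]
        state$i[w] <- p[1]; state$j[w] <- p[2]
        state$wi[w] <- p[3]; state$wj[w] <- p[4]
      }
      state$bound[w] <- FALSE
    }
    state
  })
}
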