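# Per-step Monte Carlo dynamics and ensemble simulation.

#' Start-site policies
#'
#' Where walkers are released at t = 0: uniformly over the unoccupied sites
#' of the whole membrane, uniformly over the unoccupied sites of a region,
#' or at a fixed lattice site (0-based indices).  Walkers are independent,
#' so several may share a start site.
#'
#' @param region a `psd_region`.
#' @param i,j 0-based lattice indices.
#' @return a start-policy object consumed by [simulate_ensemble()].
#' @export
start_uniform_free <- function() {
  structure(list(type = "uniform-free"), class = "start_policy")
}

#' @rdname start_uniform_free
#' @export
start_uniform_in_region <- function(region) {
  if (!inherits(region, "psd_region"))
    stop_invalid("region", "must be a psd_region")
  structure(list(type = "uniform-region", region = region),
            class = "start_policy")
}

#' @rdname start_uniform_free
#' @export
start_fixed <- function(i, j) {
  structure(list(type = "fixed", i = as.integer(i), j = as.integer(j)),
            class = "start_policy")
}

# Draw n start sites (1-based linear indices into the site matrix).
draw_start_sites <- function(config, field, policy, n, seed) {
  if (policy$type == "fixed") {
    k <- policy$j * field$nx + policy$i + 1L
    if (field$sites[k] != as.raw(0))
      stop_invalid("start_site", "start site is occupied by a PSD molecule")
    return(rep.int(k, n))
  }
  mask <- if (policy$type == "uniform-region")
    region_mask(config, policy$region) else matrix(TRUE, field$nx, field$ny)
  free <- which(mask & (field$sites == as.raw(0)))
  if (length(free) == 0L)
    stop("start region contains no unoccupied sites", call. = FALSE)
  with_seed(seed, free[sample.int(length(free), n, replace = TRUE)])
}

# Low-level bridge to the compiled engine.  `state` is a list of vectors
# (i, j, wi, wj, bound) describing each walker; returns records plus the
# final state so that protocol phases can be chained.
run_engine <- function(config, field, state, n_steps, master_seed,
                       stream_offset = 0) {
  has_binding <- !is.null(field$energy) && any(field$sites == as.raw(2))
  p_unbind <- if (has_binding) exp(-field$energy) else matrix(0, 1, 1)
  sim_ensemble_cpp(field$sites, p_unbind, has_binding,
                   as.integer(state$i), as.integer(state$j),
                   as.integer(state$wi), as.integer(state$wj),
                   as.logical(state$bound),
                   as.integer(n_steps), as.integer(config$steps_per_record),
                   as.double(master_seed), as.double(stream_offset))
}

new_state <- function(start_idx, nx) {
  i <- (start_idx - 1L) %% nx
  j <- (start_idx - 1L) %/% nx
  list(i = i, j = j, wi = integer(length(i)), wj = integer(length(i)),
       bound = logical(length(i)))
}

assemble_ensemble <- function(config, field, state0, res, start_policy,
                              master_seed) {
  n <- length(state0$i)
  t_rec <- seq_len(nrow(res$iu)) * config$record_interval
  times <- c(0, t_rec)
  # unwrapped positions in um, site centres
  x <- rbind((state0$i + 0.5) * config$dx, (res$iu + 0.5) * config$dx)
  y <- rbind((state0$j + 0.5) * config$dx, (res$ju + 0.5) * config$dx)
  iw <- rbind(as.integer(state0$i), res$iw)
  jw <- rbind(as.integer(state0$j), res$jw)
  bound <- rbind(state0$bound, res$bound)
  dimnames(x) <- dimnames(y) <- dimnames(iw) <- dimnames(jw) <-
    dimnames(bound) <- NULL
  structure(list(times = times, x = x, y = y, i = iw, j = jw, bound = bound,
                 config = config,
                 field_info = list(C_target = field$C_target,
                                   P_target = field$P_target,
                                   arrangement = field$arrangement,
                                   region = field$region),
                 start_policy = start_policy, seed = master_seed,
                 final_state = list(i = res$final_i, j = res$final_j,
                                    wi = res$final_wi, wj = res$final_wj,
                                    bound = res$final_bound)),
            class = "ensemble_result")
}

#' Simulate an ensemble of independent receptors
#'
#' Runs `config$n_walkers` non-interacting random walkers over one obstacle
#' field for `config$duration` ms.  Each step a walker draws an axis and a
#' direction uniformly; moving into a free site succeeds, colliding with a
#' plain obstacle returns it to its original position (elastic collision),
#' and contacting a bindable site binds it there.  A bound walker unbinds
#' each step with probability `exp(-E)` and is then released isotropically
#' to a uniformly chosen unoccupied neighbour.  Each walker owns an RNG
#' stream derived from `(seed, walker index)`, so results are reproducible
#' and independent of execution order.
#'
#' @param config a `sim_config`.
#' @param field an `obstacle_field` on the same lattice.
#' @param start_policy a start policy (see [start_uniform_free()]).
#' @param seed master seed; defaults to `config$seed`.
#' @return an `ensemble_result`: shared `times` (ms, including t = 0),
#'   matrices `x`, `y` (unwrapped positions, µm), `i`, `j` (wrapped lattice
#'   indices), `bound` flags — one column per walker — plus the config and
#'   a field descriptor.
#' @examples
#' cfg <- make_config(width = 1, height = 1, duration = 50, n_walkers = 20)
#' fld <- make_obstacle_field(cfg, C = 0.2)
#' ens <- simulate_ensemble(cfg, fld)
#' compute_msd(ens)[1:5, ]
#' @export
simulate_ensemble <- function(config, field,
                              start_policy = start_uniform_free(),
                              seed = config$seed) {
  if (!inherits(config, "sim_config")) stop_invalid("config", "not a sim_config")
  if (!inherits(field, "obstacle_field")) stop_invalid("field", "not an obstacle_field")
  if (field$nx != config$nx || field$ny != config$ny)
    stop_invalid("field", "field lattice does not match config")
  starts <- draw_start_sites(config, field, start_policy, config$n_walkers,
                             derive_seed(seed, 0L))
  state0 <- new_state(starts, config$nx)
  res <- run_engine(config, field, state0, config$n_steps, seed)
  assemble_ensemble(config, field, state0, res, start_policy, seed)
}

#' Simulate a single receptor trajectory
#'
#' @param config a `sim_config` (its `n_walkers` is ignored).
#' @param field an `obstacle_field`.
#' @param start_site 0-based lattice indices `c(i, j)` of an unoccupied
#'   start site.
#' @param walker_seed RNG seed for this walker's stream.
#' @return a data.frame with columns `t_ms`, `x_um`, `y_um` (unwrapped),
#'   `i`, `j` (wrapped lattice indices) and `bound`.
#' @export
simulate_walker <- function(config, field, start_site,
                            walker_seed = config$seed) {
  policy <- start_fixed(start_site[1], start_site[2])
  cfg1 <- config
  cfg1$n_walkers <- 1L
  ens <- simulate_ensemble(cfg1, field, policy, seed = walker_seed)
  data.frame(t_ms = ens$times,
             x_um = ens$x[, 1], y_um = ens$y[, 1],
             i = ens$i[, 1], j = ens$j[, 1],
             bound = ens$bound[, 1])
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Ensemble of %d walkers, %d records over %g ms (C = %.3g)\n",
              ncol(x$x), length(x$times), max(x$times),
              x$field_info$C_target))
  invisible(x)
}

#' One Monte Carlo step (reference implementation)
#'
#' Pure-R single-step dynamics, used as an executable statement of the
#' per-step rule and as a cross-check oracle for the compiled engine.
#' Consumes draws from R's RNG in the fixed order: axis, direction,
#' (release) — matching the compiled engine's draw order.
#'
#' @param state list with `i`, `j` (0-based wrapped site), `wi`, `wj`
#'   (winding counts) and `bound` flag.
#' @param field an `obstacle_field`.
#' @return the updated state.
#' @export
step_walker <- function(state, field) {
  nx <- field$nx; ny <- field$ny
  sites <- field$sites
  code_at <- function(i, j) as.integer(sites[j * nx + i + 1L])
  wrap <- function(i, j, wi, wj) {
    if (i < 0)  { i <- nx - 1L; wi <- wi - 1L }
    if (i >= nx) { i <- 0L; wi <- wi + 1L }
    if (j < 0)  { j <- ny - 1L; wj <- wj - 1L }
    if (j >= ny) { j <- 0L; wj <- wj + 1L }
    list(i = i, j = j, wi = wi, wj = wj)
  }
  if (isTRUE(state$bound)) {
    E <- field$energy[state$j * nx + state$i + 1L]
    if (runif(1) < exp(-E)) {
      nb <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
      free <- Filter(function(d) {
        w <- wrap(state$i + d[1], state$j + d[2], state$wi, state$wj)
        code_at(w$i, w$j) == 0L
      }, nb)
      state$bound <- FALSE
      if (length(free) > 0) {
        k <- min(floor(runif(1) * length(free)) + 1, length(free))
        w <- wrap(state$i + free[[k]][1], state$j + free[[k]][2],
                  state$wi, state$wj)
        state[c("i", "j", "wi", "wj")] <- w
      }
    }
    return(state)
  }
  axis_x <- runif(1) < 0.5
  neg <- runif(1) < 0.5
  d <- if (axis_x) c(if (neg) -1L else 1L, 0L) else c(0L, if (neg) -1L else 1L)
  w <- wrap(state$i + d[1], state$j + d[2], state$wi, state$wj)
  code <- code_at(w$i, w$j)
  if (code == 0L) {
    state[c("i", "j", "wi", "wj")] <- w
  } else if (code == 2L) {
    state[c("i", "j", "wi", "wj")] <- w
    state$bound <- TRUE
  }
  state
}
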