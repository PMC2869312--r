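# Simulation world: physical constants, the discrete toroidal membrane,
# PSD regions, and obstacle/binding fields.

#' Create a simulation configuration
#'
#' Fixes the physical constants and discretization of a run.  The lattice
#' spacing is derived from the time step and the free diffusion coefficient
#' as the root-mean-square displacement of a freely diffusing molecule over
#' one step, `dx = sqrt(4 * D_free * dt)`; with the defaults
#' (`dt = 1e-3` ms, `D_free = 0.200e-3` µm²/ms) this gives
#' `dx = 8.9e-4` µm.
#'
#' @param dt time step in ms.
#' @param D_free free (unobstructed) diffusion coefficient in µm²/ms.
#' @param width,height membrane size in µm.
#' @param duration total simulated time in ms.
#' @param n_walkers ensemble size (number of independent receptors).
#' @param seed master RNG seed (non-negative integer below 2^31).
#' @param record_interval position-recording interval in ms; must be an
#'   integer multiple of `dt`.
#' @return an object of class `sim_config` with derived fields `dx`
#'   (lattice spacing, µm), `nx`, `ny` (grid dimensions), `n_steps` and
#'   `steps_per_record`.
#' @examples
#' cfg <- make_config(width = 2, height = 2, duration = 2000, n_walkers = 400)
#' cfg$dx  # 8.9e-4 um
#' @export
make_config <- function(dt = 1e-3, D_free = 0.200e-3,
                        width = 2, height = 2,
                        duration = 2000, n_walkers = 400,
                        seed = 1L, record_interval = 1) {
  check_positive(dt, "dt")
  check_positive(D_free, "D_free")
  check_positive(width, "width")
  check_positive(height, "height")
  check_positive(duration, "duration")
  check_positive(n_walkers, "n_walkers")
  check_positive(record_interval, "record_interval")
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 || seed >= 2^31)
    stop_invalid("seed", "must be a non-negative integer below 2^31")

  spr <- record_interval / dt
  if (abs(spr - round(spr)) > 1e-9)
    stop_invalid("record_interval", "must be an integer multiple of dt")
  spr <- as.integer(round(spr))

  dx <- sqrt(4 * D_free * dt)
  nx <- as.integer(round(width / dx))
  ny <- as.integer(round(height / dx))
  if (nx < 2L || ny < 2L)
    stop_invalid("width", "membrane must span at least 2 x 2 lattice sites")

  n_steps <- as.integer(round(duration / dt))
  # round the number of recorded frames, not the raw step count, so that
  # duration need not be an exact multiple of record_interval * dt
  n_steps <- as.integer(floor(n_steps / spr) * spr)
  if (n_steps < spr)
    stop_invalid("duration", "must cover at least one record_interval")

  structure(list(dt = dt, D_free = D_free, dx = dx,
                 width = width, height = height,
                 nx = nx, ny = ny,
                 duration = duration, record_interval = record_interval,
                 n_steps = n_steps, steps_per_record = spr,
                 n_walkers = as.integer(n_walkers), seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  membrane: %g x %g um  (%d x %d sites, dx = %.4g um)\n",
              x$width, x$height, x$nx, x$ny, x$dx))
  cat(sprintf("  dt = %g ms, D_free = %g um^2/ms\n", x$dt, x$D_free))
  cat(sprintf("  duration = %g ms, record every %g ms, %d walkers, seed %d\n",
              x$duration, x$record_interval, x$n_walkers, x$seed))
  invisible(x)
}

#' Define a rectangular PSD region
#'
#' An axis-aligned rectangle on the membrane, in µm.  Membership is
#' half-open (`[x0, x1) x [y0, y1)`) so adjacent regions tile without
#' overlap; a lattice site belongs to the region when its centre does.
#'
#' @param x0,y0,x1,y1 rectangle corners in µm with `x0 < x1`, `y0 < y1`.
#' @return an object of class `psd_region`.
#' @export
psd_region <- function(x0, y0, x1, y1) {
  if (!all(is.finite(c(x0, y0, x1, y1))))
    stop_invalid("region", "corners must be finite")
  if (x0 < 0 || y0 < 0 || x0 >= x1 || y0 >= y1)
    stop_invalid("region", "need 0 <= x0 < x1 and 0 <= y0 < y1")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "psd_region")
}

#' Centered square PSD region
#'
#' Convenience constructor for the usual geometry: a square PSD of side
#' `size` centered on a `width` x `height` membrane.
#'
#' @param config a `sim_config` (supplies the membrane size).
#' @param size PSD side length in µm (default 0.5).
#' @return a `psd_region`.
#' @export
centered_psd <- function(config, size = 0.5) {
  x0 <- (config$width - size) / 2
  y0 <- (config$height - size) / 2
  psd_region(x0, y0, x0 + size, y0 + size)
}

# Logical matrix marking lattice sites whose centre lies in `region`
# (whole membrane when region is NULL).
region_mask <- function(config, region = NULL) {
  if (is.null(region))
    return(matrix(TRUE, config$nx, config$ny))
  if (region$x1 > config$width + 1e-12 || region$y1 > config$height + 1e-12)
    stop_invalid("region", "must lie inside the membrane")
  cx <- (seq_len(config$nx) - 0.5) * config$dx
  cy <- (seq_len(config$ny) - 0.5) * config$dx
  outer(cx >= region$x0 & cx < region$x1, cy >= region$y0 & cy < region$y1,
        FUN = "&")
}

#' Populate a field of static PSD molecules
#'
#' Places immobile PSD molecules (obstacles) on the lattice so that a
#' fraction `C` of the sites of the target region is occupied.  With the
#' random arrangement exactly `round(C * n_region_sites)` sites are drawn
#' uniformly without replacement; the regular arrangement tiles the region
#' with a periodic block pattern whose density is closest to `C`
#' (obstacles at local offsets `(i mod p) < q`, `(j mod p) < q`).
#'
#' @param config a `sim_config`.
#' @param C target crowding fraction in `[0, 1]` (fraction of region sites
#'   occupied by PSD molecules).
#' @param region a `psd_region`, or `NULL` for the whole membrane.
#' @param arrangement `"random"` (default) or `"regular"`.
#' @param seed RNG seed for the random arrangement; defaults to
#'   `config$seed`.
#' @return an object of class `obstacle_field`: site codes (0 free,
#'   1 obstacle, 2 bindable obstacle), optional per-site binding energy,
#'   and bookkeeping (`C_target`, realized occupancy, arrangement, region).
#' @examples
#' cfg <- make_config(width = 1, height = 1, duration = 10, n_walkers = 10)
#' fld <- make_obstacle_field(cfg, C = 0.45)
#' fld$n_occupied / fld$n_region_sites  # ~0.45
#' @export
make_obstacle_field <- function(config, C, region = NULL,
                                arrangement = c("random", "regular"),
                                seed = config$seed) {
  arrangement <- match.arg(arrangement)
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C < 0 || C > 1)
    stop_invalid("C", "crowding fraction must lie in [0, 1]")

  mask <- region_mask(config, region)
  idx <- which(mask)
  n_region <- length(idx)
  sites <- matrix(as.raw(0), config$nx, config$ny)

  if (arrangement == "random") {
    n_occ <- round(C * n_region)
    if (n_occ > 0) {
      pick <- with_seed(seed, sample(idx, n_occ, replace = FALSE))
      sites[pick] <- as.raw(1)
    }
  } else {
    # periodic block pattern: density (q/p)^2, chosen closest to C
    best <- c(1L, if (C >= 0.5) 1L else 0L)
    best_err <- abs((best[2] / best[1])^2 - C)
    for (p in 1:12) for (q in 0:p) {
      err <- abs((q / p)^2 - C)
      if (err < best_err - 1e-12) { best <- c(p, q); best_err <- err }
    }
    p <- best[1]; q <- best[2]
    if (q > 0) {
      # local (0-based) offsets within the region's bounding box of rows/cols
      ri <- which(apply(mask, 1, any)); rj <- which(apply(mask, 2, any))
      li <- integer(config$nx); li[ri] <- seq_along(ri) - 1L
      lj <- integer(config$ny); lj[rj] <- seq_along(rj) - 1L
      pat <- outer((li %% p) < q, (lj %% p) < q, FUN = "&") & mask
      sites[pat] <- as.raw(1)
    }
  }

  structure(list(sites = sites, energy = NULL,
                 nx = config$nx, ny = config$ny, dx = config$dx,
                 region = region, C_target = C,
                 P_target = NA_real_, energy_spec = NULL,
                 arrangement = arrangement, seed = as.integer(seed),
                 n_region_sites = n_region,
                 n_occupied = sum(sites != as.raw(0))),
            class = "obstacle_field")
}

#' @export
print.obstacle_field <- function(x, ...) {
  cat(sprintf("Obstacle field: %d x %d sites, %s arrangement\n",
              x$nx, x$ny, x$arrangement))
  cat(sprintf("  C_target = %.3f, realized %d / %d region sites (%.3f)\n",
              x$C_target, x$n_occupied, x$n_region_sites,
              x$n_occupied / max(1L, x$n_region_sites)))
  if (!is.na(x$P_target))
    cat(sprintf("  bindable fraction P = %.3f (%d sites)\n",
                x$P_target, sum(x$sites == as.raw(2))))
  invisible(x)
}

#' Binding-energy specifications
#'
#' `energy_fixed(E)` assigns the same binding energy `E` (in k_B*T) to every
#' bindable site; `energy_uniform(lo, hi)` draws one energy per bindable
#' site i.i.d. uniform on `[lo, hi]`.
#'
#' @param E,lo,hi binding energies in k_B*T, non-negative.
#' @return an object of class `energy_spec`.
#' @export
energy_fixed <- function(E) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E < 0)
    stop_invalid("E", "binding energy must be non-negative")
  structure(list(type = "fixed", E = E), class = "energy_spec")
}

#' @rdname energy_fixed
#' @export
energy_uniform <- function(lo, hi) {
  if (!all(is.finite(c(lo, hi))) || lo < 0 || hi < lo)
    stop_invalid("energy", "need 0 <= lo <= hi")
  structure(list(type = "uniform", lo = lo, hi = hi), class = "energy_spec")
}

#' Mark a fraction of PSD molecules as binding sites
#'
#' Converts a fraction `P` of the occupied sites into bindable sites
#' (chosen uniformly) and assigns each a binding energy per `energy_spec`.
#' A diffusing receptor that contacts a bindable site binds; while bound it
#' unbinds each step with probability `exp(-E)`, so the mean bound duration
#' is `exp(E)` steps.
#'
#' @param field an `obstacle_field`.
#' @param P fraction of occupied sites that can bind, in `[0, 1]`.
#' @param energy_spec an [energy_fixed()] or [energy_uniform()] spec.
#' @param seed RNG seed for site selection and energy draws.
#' @return the field with `sites` codes updated and an `energy` matrix
#'   (k_B*T, zero outside bindable sites).
#' @export
assign_binding <- function(field, P, energy_spec, seed = field$seed) {
  if (!inherits(field, "obstacle_field"))
    stop_invalid("field", "must be an obstacle_field")
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P < 0 || P > 1)
    stop_invalid("P", "bindable fraction must lie in [0, 1]")
  if (!inherits(energy_spec, "energy_spec"))
    stop_invalid("energy_spec", "use energy_fixed() or energy_uniform()")

  sites <- field$sites
  sites[sites == as.raw(2)] <- as.raw(1)   # reset any previous assignment
  occ <- which(sites == as.raw(1))
  n_bind <- round(P * length(occ))
  energy <- matrix(0, field$nx, field$ny)
  if (n_bind > 0) {
    drawn <- with_seed(seed, {
      pick <- sample(occ, n_bind, replace = FALSE)
      e <- if (energy_spec$type == "fixed") rep(energy_spec$E, n_bind)
           else runif(n_bind, energy_spec$lo, energy_spec$hi)
      list(pick = pick, e = e)
    })
    sites[drawn$pick] <- as.raw(2)
    energy[drawn$pick] <- drawn$e
  }
  field$sites <- sites
  field$energy <- energy
  field$P_target <- P
  field$energy_spec <- energy_spec
  field
}

#' Export an obstacle field as a site table
#'
#' Plain-text view of the occupied sites for inspection or replay:
#' one row per occupied site with 0-based lattice indices.
#'
#' @param field an `obstacle_field`.
#' @return a data.frame with columns `i`, `j`, `bindable`, `energy`.
#' @export
field_site_table <- function(field) {
  occ <- which(field$sites != as.raw(0), arr.ind = TRUE)
  bindable <- field$sites[occ] == as.raw(2)
  energy <- if (is.null(field$energy)) rep(0, nrow(occ)) else field$energy[occ]
  data.frame(i = occ[, 1] - 1L, j = occ[, 2] - 1L,
             bindable = bindable, energy = energy)
}
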