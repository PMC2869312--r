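# Configuration files, trajectory tables, and synthetic fixtures.

config_keys <- c("dt", "D_free", "width", "height", "duration",
                 "record_interval", "n_walkers", "seed")
param_keys <- c("region", "C", "P", "arrangement", "energy")

#' Load a run configuration from a YAML file
#'
#' Reads a structured-text (`key: value`) configuration, applies defaults
#' (`dt = 1e-3` ms, `D_free = 0.200e-3` µm²/ms, `record_interval = 1` ms)
#' and validates.  Recognized simulation keys: `dt`, `D_free`, `width`,
#' `height`, `duration`, `record_interval`, `n_walkers`, `seed`; optional
#' protocol blocks: `region` (`x0`, `y0`, `x1`, `y1`), `C`, `P`,
#' `arrangement`, `energy` (`type: fixed, E:` or `type: uniform, lo:, hi:`).
#' Unknown keys are rejected.
#'
#' @param path file path.
#' @return a list with elements `config` (a `sim_config`) and `params`
#'   (protocol parameters, possibly empty).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c(config_keys, param_keys))
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  args <- raw[intersect(names(raw), config_keys)]
  config <- do.call(make_config, args)
  params <- raw[intersect(names(raw), param_keys)]
  if (!is.null(params$C) && (params$C < 0 || params$C > 1))
    stop("invalid `C`: crowding fraction must lie in [0, 1]", call. = FALSE)
  if (!is.null(params$P) && (params$P < 0 || params$P > 1))
    stop("invalid `P`: bindable fraction must lie in [0, 1]", call. = FALSE)
  if (!is.null(params$region))
    params$region <- do.call(psd_region, params$region[c("x0", "y0", "x1", "y1")])
  if (!is.null(params$energy)) {
    e <- params$energy
    params$energy <- if (identical(e$type, "fixed")) energy_fixed(e$E)
                     else if (identical(e$type, "uniform")) energy_uniform(e$lo, e$hi)
                     else stop("invalid `energy`: type must be fixed or uniform",
                               call. = FALSE)
  }
  list(config = config, params = params)
}

#' Save a run configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(save_config(x, path))`
#' reproduces the configuration.
#'
#' @param config a `sim_config`.
#' @param path output path.
#' @param params optional protocol parameter list as returned by
#'   [load_config()].
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path, params = list()) {
  out <- unclass(config)[config_keys]
  if (!is.null(params$region))
    params$region <- unclass(params$region)
  if (!is.null(params$energy))
    params$energy <- unclass(params$energy)
  yaml::write_yaml(c(out, params), path)
  invisible(path)
}

#' Write / read a trajectory ensemble as delimited text
#'
#' Tab-separated table with one row per (walker, record): columns
#' `walker_id`, `t_ms`, `x_um`, `y_um` (unwrapped, full precision), `i`,
#' `j` (wrapped lattice indices) and `bound`.  A `# key: value` header
#' carries the configuration echo and master seed so the ensemble
#' round-trips losslessly.
#'
#' @param ensemble an `ensemble_result`.
#' @param path file path.
#' @return `path` invisibly (write); an `ensemble_result` (read).
#' @export
write_trajectories <- function(ensemble, path) {
  cfg <- ensemble$config
  hdr <- c(sprintf("# psdcrowd trajectories v1"),
           sprintf("# dt: %.17g", cfg$dt),
           sprintf("# D_free: %.17g", cfg$D_free),
           sprintf("# width: %.17g", cfg$width),
           sprintf("# height: %.17g", cfg$height),
           sprintf("# duration: %.17g", cfg$duration),
           sprintf("# record_interval: %.17g", cfg$record_interval),
           sprintf("# n_walkers: %d", ncol(ensemble$x)),
           sprintf("# seed: %d", as.integer(ensemble$seed)),
           sprintf("# units: t_ms in ms, x_um/y_um in um"),
           "walker_id\tt_ms\tx_um\ty_um\ti\tj\tbound")
  n_rec <- length(ensemble$times)
  n_w <- ncol(ensemble$x)
  rows <- sprintf("%d\t%.17g\t%.17g\t%.17g\t%d\t%d\t%d",
                  rep(seq_len(n_w), each = n_rec),
                  rep(ensemble$times, n_w),
                  as.vector(ensemble$x), as.vector(ensemble$y),
                  as.vector(ensemble$i), as.vector(ensemble$j),
                  as.integer(as.vector(ensemble$bound)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(sprintf("^# %s: ", key), hdr, value = TRUE)
    if (length(m) != 1L)
      stop(sprintf("malformed trajectory file: missing header `%s`", key),
           call. = FALSE)
    as.numeric(sub(sprintf("^# %s: ", key), "", m))
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L)
    stop("malformed trajectory file: no data rows", call. = FALSE)
  body <- body[-1]  # column header
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 7L)
  if (length(bad) > 0)
    stop(sprintf("malformed row at line %d: expected 7 fields",
                 bad[1] + length(hdr) + 1L), call. = FALSE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 7, byrow = TRUE)
  n_w <- as.integer(get("n_walkers"))
  if (nrow(m) %% n_w != 0)
    stop(sprintf("truncated trajectory file: %d rows not divisible by %d walkers",
                 nrow(m), n_w), call. = FALSE)
  n_rec <- nrow(m) %/% n_w
  config <- make_config(dt = get("dt"), D_free = get("D_free"),
                        width = get("width"), height = get("height"),
                        duration = get("duration"),
                        record_interval = get("record_interval"),
                        n_walkers = n_w, seed = as.integer(get("seed")))
  shape <- function(col) matrix(m[, col], nrow = n_rec, ncol = n_w)
  structure(list(times = m[seq_len(n_rec), 2],
                 x = shape(3), y = shape(4),
                 i = shape(5), j = shape(6),
                 bound = shape(7) != 0,
                 config = config,
                 field_info = list(C_target = NA_real_, P_target = NA_real_,
                                   arrangement = NA_character_, region = NULL),
                 start_policy = NULL, seed = config$seed,
                 final_state = NULL),
            class = "ensemble_result")
}

#' Gaussian random-walk fixture
#'
#' Off-lattice ensemble of 2-D Gaussian walks with per-interval
#' displacement variance `2 D record_interval` per axis — exact normal
#' diffusion with known `D`.  Used to validate the analysis operators
#' independently of the lattice engine.
#'
#' @param D diffusion coefficient in µm²/ms (`D = 0` gives stationary
#'   walkers).
#' @param n_walkers ensemble size.
#' @param duration total time in ms.
#' @param seed RNG seed.
#' @param record_interval recording interval in ms.
#' @return an `ensemble_result` (wrapped lattice indices are absent).
#' @export
make_gaussian_walk_fixture <- function(D, n_walkers, duration, seed = 1L,
                                       record_interval = 1) {
  if (D < 0) stop_invalid("D", "must be non-negative")
  n_rec <- floor(duration / record_interval)
  sdev <- sqrt(2 * D * record_interval)
  xy <- with_seed(seed, list(
    x = matrix(rnorm(n_rec * n_walkers, sd = sdev), n_rec, n_walkers),
    y = matrix(rnorm(n_rec * n_walkers, sd = sdev), n_rec, n_walkers)))
  x <- rbind(0, apply(xy$x, 2, cumsum))
  y <- rbind(0, apply(xy$y, 2, cumsum))
  config <- make_config(dt = record_interval, D_free = max(D, 1e-12),
                        width = 2, height = 2, duration = duration,
                        n_walkers = n_walkers, seed = seed,
                        record_interval = record_interval)
  structure(list(times = seq(0, by = record_interval, length.out = n_rec + 1),
                 x = x, y = y, i = NULL, j = NULL,
                 bound = matrix(FALSE, n_rec + 1, n_walkers),
                 config = config,
                 field_info = list(C_target = 0, P_target = NA_real_,
                                   arrangement = "none", region = NULL),
                 start_policy = NULL, seed = as.integer(seed),
                 final_state = NULL),
            class = "ensemble_result")
}

#' Noise-free power-law MSD fixture
#'
#' Evaluates `MSD(t) = 4 D t^alpha` exactly on a time grid; [fit_alpha()]
#' recovers `alpha` to machine precision on this fixture.
#'
#' @param D prefactor diffusion coefficient in µm²/ms.
#' @param alpha anomalous exponent in `(0, 1]`.
#' @param t_grid times in ms.
#' @return an `msd_curve`.
#' @export
make_powerlaw_msd_fixture <- function(D, alpha, t_grid) {
  check_positive(D, "D")
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha", "must lie in (0, 1]")
  out <- data.frame(t = t_grid, msd = 4 * D * t_grid^alpha, n = NA_integer_)
  class(out) <- c("msd_curve", "data.frame")
  out
}
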