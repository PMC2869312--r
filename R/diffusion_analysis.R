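# Trajectory ensembles -> MSD, anomalous exponent, apparent diffusion
# coefficients, Kusumi confinement fits, and closed-form calculators.

#' Ensemble mean squared displacement
#'
#' Origin-referenced MSD over the ensemble:
#' `MSD(t) = (1/N) * sum_i |r_i(t) - r_i(0)|^2`, computed from unwrapped
#' positions.  This is the spread from the point of origin, not a
#' sliding-window time average.
#'
#' @param ensemble an `ensemble_result`.
#' @return a data.frame of class `msd_curve` with columns `t` (ms),
#'   `msd` (µm²) and `n` (ensemble size).
#' @export
compute_msd <- function(ensemble) {
  if (is.null(ensemble$x) || ncol(ensemble$x) < 1L)
    stop("ensemble contains no trajectories", call. = FALSE)
  dx2 <- (ensemble$x - rep(ensemble$x[1, ], each = nrow(ensemble$x)))^2 +
         (ensemble$y - rep(ensemble$y[1, ], each = nrow(ensemble$y)))^2
  out <- data.frame(t = ensemble$times, msd = rowMeans(dx2),
                    n = ncol(ensemble$x))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the anomalous diffusion exponent
#'
#' Under anomalous diffusion `MSD = 4 D t^alpha`, so the slope of
#' `log(MSD)` against `log(t)` over a fitting window gives the anomalous
#' exponent alpha (alpha = 1 is normal diffusion).  The default window
#' `[10, Inf)` ms excludes the early transient.
#'
#' @param msd an `msd_curve` (or data.frame with columns `t`, `msd`).
#' @param window numeric `c(t_lo, t_hi)` in ms; only points with
#'   `t_lo <= t <= t_hi`, `t > 0` and `msd > 0` enter the fit.
#' @return an object of class `alpha_fit` with `alpha`, `log_prefactor`
#'   (intercept, natural log), `window`, `r2` and `n_points`.
#' @examples
#' msd <- make_powerlaw_msd_fixture(D = 2e-4, alpha = 0.5,
#'                                  t_grid = seq(1, 2000))
#' fit_alpha(msd)$alpha  # 0.5
#' @export
fit_alpha <- function(msd, window = c(10, Inf)) {
  keep <- msd$t >= window[1] & msd$t <= window[2] & msd$t > 0 & msd$msd > 0
  if (sum(keep) < 5L)
    stop("fewer than 5 usable points in the fitting window", call. = FALSE)
  ly <- log(msd$msd[keep])
  fit <- lm(ly ~ log(msd$t[keep]))
  alpha <- unname(coef(fit)[2])
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(residuals(fit)^2) / sst else 1
  if (!is.finite(alpha) || alpha < 0 || alpha > 1.2)
    warning(sprintf("fitted alpha = %.3f outside the expected [0, 1.2] range",
                    alpha))
  structure(list(alpha = alpha,
                 log_prefactor = unname(coef(fit)[1]),
                 window = window,
                 r2 = r2,
                 n_points = sum(keep)),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("alpha = %.4f (r^2 = %.4f, %d points, window [%g, %g] ms)\n",
              x$alpha, x$r2, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' Per-walker apparent diffusion coefficients
#'
#' `D_app = |r(t_obs) - r(0)|^2 / (4 t_obs)` from unwrapped positions: the
#' diffusion coefficient an observer would infer from the displacement
#' after a set observation time.
#'
#' @param ensemble an `ensemble_result`.
#' @param t_obs observation time in ms; must be a recorded time.
#' @return an object of class `dapp_distribution` with the per-walker
#'   `values` (µm²/ms), `t_obs` and the empirical `median`.
#' @export
compute_dapp <- function(ensemble, t_obs = 1000) {
  row <- which(abs(ensemble$times - t_obs) < 1e-9)
  if (length(row) != 1L)
    stop(sprintf("t_obs = %g ms is not a recorded time", t_obs), call. = FALSE)
  d2 <- (ensemble$x[row, ] - ensemble$x[1, ])^2 +
        (ensemble$y[row, ] - ensemble$y[1, ])^2
  values <- unname(d2 / (4 * t_obs))
  structure(list(values = values, t_obs = t_obs, median = median(values)),
            class = "dapp_distribution")
}

#' @export
print.dapp_distribution <- function(x, ...) {
  cat(sprintf("D_app over %d walkers at t_obs = %g ms: median %.4g um^2/ms\n",
              length(x$values), x$t_obs, x$median))
  invisible(x)
}

#' Fit the Kusumi confined-diffusion model
#'
#' Fits `MSD(t) = (L^2/3) * (1 - exp(-10 D t / L^2))` by nonlinear least
#' squares over the confinement length `L`, with the diffusion coefficient
#' fixed at `D_input` (under the confinement interpretation the within-
#' corral coefficient equals the free one).  `L` is initialized at
#' `sqrt(3 * max(msd))`, the value implied by a fully saturated curve.
#'
#' @param msd an `msd_curve`.
#' @param D_input diffusion coefficient to hold fixed, µm²/ms.
#' @return an object of class `kusumi_fit` with `L` (µm), `D_input`, the
#'   residual sum of squares and the underlying `nls` fit.
#' @export
fit_kusumi <- function(msd, D_input) {
  check_positive(D_input, "D_input")
  pts <- msd[msd$t > 0, , drop = FALSE]
  if (nrow(pts) < 5L)
    stop("need at least 5 MSD points", call. = FALSE)
  L0 <- sqrt(3 * max(pts$msd))
  fit <- minpack.lm::nlsLM(
    msd ~ (L^2 / 3) * (1 - exp(-10 * D_input * t / L^2)),
    data = pts, start = list(L = L0),
    lower = 1e-6, control = minpack.lm::nls.lm.control(maxiter = 200))
  L <- abs(unname(coef(fit)[1]))
  structure(list(L = L, D_input = D_input,
                 residual = sum(residuals(fit)^2), fit = fit),
            class = "kusumi_fit")
}

#' @export
print.kusumi_fit <- function(x, ...) {
  cat(sprintf("Kusumi fit: L = %.4g um (%.0f nm), D fixed at %g um^2/ms\n",
              x$L, x$L * 1e3, x$D_input))
  invisible(x)
}

#' Predicted PSD residence time under anomalous diffusion
#'
#' Inverts `distance = sqrt(4 D t^alpha)` for the time at which the root
#' mean squared spread reaches a given distance: the expected time for a
#' receptor released at the centre of a PSD to reach its boundary.
#'
#' @param distance_um distance to cover in µm.
#' @param alpha anomalous exponent in `(0, 1]`.
#' @param D_free diffusion coefficient in µm²/ms.
#' @return time in ms (vectorized over any argument).
#' @examples
#' residence_time(0.125, alpha = 0.3, D_free = 0.138e-3)  # ~6.9e4 ms
#' @export
residence_time <- function(distance_um, alpha, D_free) {
  if (any(alpha <= 0)) stop_invalid("alpha", "must be positive")
  if (any(alpha > 1)) stop_invalid("alpha", "must be at most 1")
  if (any(distance_um <= 0)) stop_invalid("distance_um", "must be positive")
  if (any(D_free <= 0)) stop_invalid("D_free", "must be positive")
  (distance_um^2 / (4 * D_free))^(1 / alpha)
}

#' Fraction of walkers inside a region at a query time
#'
#' Uses the wrapped position (site centre) at `t_query` with half-open
#' region membership.
#'
#' @param ensemble an `ensemble_result`.
#' @param region a `psd_region`.
#' @param t_query query time in ms; must be recorded.
#' @return the retention fraction in `[0, 1]`.
#' @export
retention_fraction <- function(ensemble, region, t_query) {
  row <- which(abs(ensemble$times - t_query) < 1e-9)
  if (length(row) != 1L)
    stop(sprintf("t_query = %g ms is not a recorded time", t_query),
         call. = FALSE)
  dx <- ensemble$config$dx
  xw <- (ensemble$i[row, ] + 0.5) * dx
  yw <- (ensemble$j[row, ] + 0.5) * dx
  mean(xw >= region$x0 & xw < region$x1 & yw >= region$y0 & yw < region$y1)
}

#' Convert a dissociation constant to binding energy
#'
#' `E = R T ln(1 / Kd) / 2.5` in k_B*T units, with `R T = 2.479` kJ/mol
#' (298 K) and 2.5 kJ/mol per k_B*T.
#'
#' @param Kd_molar dissociation constant in molar, in `(0, 1)`.
#' @return binding energy in k_B*T.
#' @examples
#' kd_to_kbt(1e-6)  # ~13.7 kBT
#' @export
kd_to_kbt <- function(Kd_molar) {
  if (any(Kd_molar <= 0)) stop_invalid("Kd_molar", "must be positive")
  if (any(Kd_molar >= 1))
    stop_invalid("Kd_molar", "must be below 1 M (non-binding regime)")
  2.479 * log(1 / Kd_molar) / 2.5
}

#' Expected time to unbind
#'
#' With binding attempts at a characteristic rate of one per `attempt_s`
#' seconds and a per-attempt escape probability `exp(-E)`, the expected
#' time to unbind is `attempt_s * exp(E)`.
#'
#' @param E_kbt binding energy in k_B*T.
#' @param attempt_s characteristic attempt time in seconds (default 1 µs).
#' @return expected unbinding time in seconds.
#' @examples
#' unbind_time(13)  # 1e-6 / exp(-13) = 0.44
#' @export
unbind_time <- function(E_kbt, attempt_s = 1e-6) {
  if (any(E_kbt < 0)) stop_invalid("E_kbt", "must be non-negative")
  attempt_s * exp(E_kbt)
}

#' PSD mass-fraction crowding estimate
#'
#' Percent of the PSD volume occupied by macromolecules by mass:
#' `100 * mass / (volume * density)`.
#'
#' @param psd_mass_g PSD mass in grams.
#' @param psd_volume_nm3 PSD volume in nm³.
#' @param protein_density_g_per_nm3 protein density in g/nm³
#'   (default 1.4e-21).
#' @return percentage.
#' @examples
#' psd_mass_fraction(1.83e-15, 3.06e6)  # ~43 percent
#' @export
psd_mass_fraction <- function(psd_mass_g, psd_volume_nm3,
                              protein_density_g_per_nm3 = 1.4e-21) {
  check_positive(psd_mass_g, "psd_mass_g")
  check_positive(psd_volume_nm3, "psd_volume_nm3")
  check_positive(protein_density_g_per_nm3, "protein_density_g_per_nm3")
  100 * psd_mass_g / (psd_volume_nm3 * protein_density_g_per_nm3)
}

#' Occupied-volume fraction of the PSD
#'
#' Estimates the fraction of the PSD volume occupied by `n_molecules`
#' globular proteins.  The per-molecule radius follows from the protein
#' density: `r = [(0.75/pi) MW / (rho * A)]^(1/3)` nm with
#' `rho = 1.4e-21` g/nm³ and `A` Avogadro's number.
#'
#' @param n_molecules number of molecules.
#' @param mw_daltons molecular weight in Daltons (g/mol).
#' @param psd_volume_nm3 PSD volume in nm³.
#' @return occupied volume fraction (dimensionless).
#' @examples
#' occupied_volume_fraction(10000, 1e5, 3.06e6)  # ~0.39
#' @export
occupied_volume_fraction <- function(n_molecules, mw_daltons, psd_volume_nm3) {
  if (n_molecules < 0) stop_invalid("n_molecules", "must be non-negative")
  check_positive(mw_daltons, "mw_daltons")
  check_positive(psd_volume_nm3, "psd_volume_nm3")
  avogadro <- 6.02214076e23
  rho <- 1.4e-21   # g/nm^3
  r <- ((0.75 / pi) * mw_daltons / (rho * avogadro))^(1 / 3)
  v_mol <- (4 / 3) * pi * r^3
  n_molecules * v_mol / psd_volume_nm3
}
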