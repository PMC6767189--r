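# Hansen solubility parameter from per-frame cohesive energy density, the
# Flory-Huggins interaction parameter, Flory-Rehner crosslink density and
# equilibrium swelling, and the Fujita free-volume diffusion model.

.ENERGY_J_PER_MOL <- c("kcal/mol" = 4184, "kJ/mol" = 1000, "J/mol" = 1)

# CED in MPa from a per-mole energy and a per-frame volume in Angstrom^3:
# (E [J/mol] / N_A) / (V * 1e-30 [m^3]) / 1e6
.ced_mpa <- function(energy, volume_A3, energy_unit) {
  ju <- .ENERGY_J_PER_MOL[energy_unit]
  if (is.na(ju)) {
    stop("unknown energy unit '", energy_unit, "'; supported: ",
         paste(names(.ENERGY_J_PER_MOL), collapse = ", "), call. = FALSE)
  }
  (energy * ju / .AVOGADRO) / (volume_A3 * 1e-30) / 1e6
}

#' Hansen solubility parameter from per-frame energetics
#'
#' The cohesive energy density of frame i is `CED_i = E_i / V_i` (nonbonded
#' energy over cell volume) and the solubility parameter is
#' \eqn{\delta_i = \sqrt{CED_i}} in MPa^0.5. The default reduces the series
#' to the mean and standard deviation of the per-frame \eqn{\delta_i}
#' (`method = "mean-of-sqrt"`); `"sqrt-of-mean"` instead takes the square
#' root of the mean CED.
#'
#' Nonbonded energies from force fields are typically negative (attractive);
#' with `sign = "magnitude"` (default) their absolute value is used as the
#' cohesive energy. With `sign = "as-is"` a negative CED is an error naming
#' the offending frame.
#'
#' @param series A [thermo_series] with `energy` and `volume` columns
#'   (volume in Angstrom^3, energy in the series' declared unit).
#' @param method `"mean-of-sqrt"` or `"sqrt-of-mean"`.
#' @param sign `"magnitude"` or `"as-is"`.
#' @return A `solubility_result`: `delta_mean`, `delta_sd` (MPa^0.5),
#'   `per_frame` deltas, `ced_mean` (MPa), `n`.
#' @export
hansen_delta <- function(series, method = c("mean-of-sqrt", "sqrt-of-mean"),
                         sign = c("magnitude", "as-is")) {
  method <- match.arg(method)
  sign <- match.arg(sign)
  if (is.null(series$energy) || is.null(series$volume)) {
    stop("series must carry energy and volume columns", call. = FALSE)
  }
  unit <- attr(series, "units")$energy %||% "kcal/mol"
  ced <- .ced_mpa(series$energy, series$volume, unit)
  if (sign == "magnitude") {
    ced <- abs(ced)
  } else if (any(ced < 0)) {
    stop("negative cohesive energy at frame ", which(ced < 0)[1],
         " under 'as-is' sign convention", call. = FALSE)
  }
  deltas <- sqrt(ced)
  delta_mean <- if (method == "mean-of-sqrt") mean(deltas) else
    sqrt(mean(ced))
  structure(list(delta_mean = delta_mean,
                 delta_sd = if (length(deltas) > 1L) stats::sd(deltas) else 0,
                 per_frame = deltas, ced_mean = mean(ced),
                 n = length(deltas), method = method),
            class = "solubility_result")
}

#' @export
print.solubility_result <- function(x, ...) {
  cat(sprintf("<solubility_result> delta = %.4g +/- %.2g MPa^0.5 (N = %d)\n",
              x$delta_mean, x$delta_sd, x$n))
  invisible(x)
}

#' Flory-Huggins interaction parameter from solubility parameters
#'
#' \eqn{\chi_{sp} = V (\delta_s - \delta_p)^2 / (R T)} with V the solvent
#' molar volume. In the units used here (cm^3/mol and MPa^0.5) the conversion
#' factors cancel: `chi = v * (ds - dp)^2 / (8.314... * T)`. Always >= 0,
#' zero iff the solubility parameters match, and scales as 1/T.
#'
#' @param delta_s,delta_p Solvent and polymer solubility parameters, MPa^0.5.
#' @param v_solvent_molar Solvent molar volume in cm^3/mol (> 0).
#' @param temperature Temperature in K (> 0).
#' @return Dimensionless chi.
#' @examples
#' chi_parameter(47.8, 27.2, v_solvent_molar = 18, temperature = 298)
#' @export
chi_parameter <- function(delta_s, delta_p, v_solvent_molar, temperature) {
  stopifnot(temperature > 0, v_solvent_molar > 0)
  # (v * 1e-6 m^3/mol) * ((ds-dp)^2 * 1e6 Pa) / (R T): the 1e-6/1e6 cancel
  v_solvent_molar * (delta_s - delta_p)^2 / (.R_GAS * temperature)
}

#' Flory-Rehner crosslink density
#'
#' Evaluates
#' \deqn{d = \frac{\ln(1 - v_s) + v_s + \chi v_s^2}
#'            {V_{sol} (v_s^{1/3} - 2 v_s \phi)}}
#' with `v_s` the polymer volume fraction at swelling equilibrium, `phi` the
#' polymer molar fraction and `V_sol` the solvent molar volume. The
#' expression is evaluated as written; note that its sign flips when the
#' denominator crosses zero (a warning flags a negative denominator).
#'
#' @param v_s Polymer volume fraction in the swollen gel, in (0, 1).
#' @param chi Flory-Huggins interaction parameter.
#' @param v_solvent_molar Solvent molar volume (cm^3/mol).
#' @param phi Polymer molar fraction.
#' @return Crosslink density in mol/cm^3 (given `V_sol` in cm^3/mol).
#' @export
flory_rehner_crosslink <- function(v_s, chi, v_solvent_molar, phi) {
  stopifnot(v_s > 0, v_s < 1, v_solvent_molar > 0)
  numerator <- log(1 - v_s) + v_s + chi * v_s^2
  denominator <- v_solvent_molar * (v_s^(1 / 3) - 2 * v_s * phi)
  if (abs(denominator) < 1e-12) {
    stop("singular Flory-Rehner denominator: v_s^(1/3) - 2 v_s phi ~ 0",
         call. = FALSE)
  }
  if (denominator < 0) {
    warning("Flory-Rehner denominator is negative; the sign of the ",
            "crosslink density flips across this zero", call. = FALSE)
  }
  numerator / denominator
}

#' Equilibrium swelling degree
#'
#' `Q = 1 / v_s`, the reciprocal of the equilibrium polymer volume fraction.
#'
#' @param v_s Polymer volume fraction (> 0).
#' @return Swelling degree.
#' @export
swelling_degree <- function(v_s) {
  stopifnot(all(v_s > 0))
  1 / v_s
}

#' Fujita free-volume diffusion model
#'
#' Forward model: \eqn{D = D_0 R T A e^{-B/FFV}} for a penetrant diffusing in
#' a polymer with fractional free volume FFV. Its (natural) logarithm is
#' linear, \eqn{\ln D = C + \ln T - B/FFV} with \eqn{C = \ln(D_0 R A)}, so
#' `fujita_fit()` regresses `ln D - ln T` on `1/FFV` and recovers `C`
#' (intercept) and `B` (minus the slope) by least squares.
#'
#' @param D0 Pre-exponential diffusion coefficient at zero penetrant
#'   concentration.
#' @param A,B Fujita constants (`B > 0` for a physically meaningful
#'   free-volume dependence).
#' @param FFV Fractional free volume (> 0).
#' @param temperature Temperature in K (> 0).
#' @return `fujita_forward()`: the diffusion coefficient D.
#' @export
fujita_forward <- function(D0, A, B, FFV, temperature) {
  stopifnot(all(FFV > 0), all(temperature > 0))
  D0 * .R_GAS * temperature * A * exp(-B / FFV)
}

#' @rdname fujita_forward
#' @param D Observed diffusion coefficients (> 0).
#' @return `fujita_fit()`: a `diffusion_model` with `C`, `B`, `d0_times_a`
#'   (`= exp(C)/R`, the product D0*A, not separable from a fit) and the
#'   underlying `regression_fit`.
#' @export
fujita_fit <- function(D, FFV, temperature) {
  stopifnot(length(D) >= 3L, all(D > 0), all(FFV > 0), all(temperature > 0),
            length(D) == length(FFV), length(D) == length(temperature))
  x <- 1 / FFV
  if (max(x) - min(x) == 0) {
    stop("collinear design: FFV does not vary", call. = FALSE)
  }
  fit <- linear_fit_anova(x, log(D) - log(temperature))
  structure(list(C = fit$intercept, B = -fit$slope,
                 d0_times_a = exp(fit$intercept) / .R_GAS, fit = fit),
            class = "diffusion_model")
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf("<diffusion_model> ln D = %.4g + ln T - %.4g / FFV\n",
              x$C, x$B))
  invisible(x)
}
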