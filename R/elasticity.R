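#' Elasticity model parameters
#'
#' Mass density and Poisson's ratio of the Rayleigh surface-wave model.
#' Defaults are the soft-tissue values used for skin: density 1020 kg/m3
#' (1.02 g/cm3) and Poisson's ratio 0.5 (incompressible).
#'
#' @param mass_density kg/m3, > 0.
#' @param poisson_ratio dimensionless, in (-1, 0.5].
#' @return an `elasticity_params`.
#' @export
elasticity_params <- function(mass_density = 1020, poisson_ratio = 0.5) {
  if (!is.finite(mass_density) || mass_density <= 0) {
    stop("mass density must be > 0")
  }
  if (!is.finite(poisson_ratio) || poisson_ratio <= -1 ||
      poisson_ratio > 0.5) {
    stop("Poisson's ratio must be in (-1, 0.5]")
  }
  structure(list(mass_density = mass_density, poisson_ratio = poisson_ratio),
            class = "elasticity_params")
}

#' Rayleigh surface-wave modulus coefficient
#'
#' The coefficient `k` relating bulk Young's modulus to squared SAW
#' velocity, `E[kPa] = k * (V[m/s])^2`, under the Rayleigh approximation:
#' \deqn{k = 2 \rho (1+\nu)^3 / (0.87 + 1.12\nu)^2 \times 10^{-3}.}
#' At the soft-tissue defaults (1020 kg/m3, 0.5) this evaluates to 3.367
#' kPa s2/m2; the conventionally quoted skin coefficient is the rounded
#' 3.35 (see [velocity_to_modulus()]).
#'
#' @param params an [elasticity_params()].
#' @return coefficient in kPa s2/m2.
#' @examples
#' rayleigh_constant(elasticity_params()) # ~3.35
#' @export
rayleigh_constant <- function(params = elasticity_params()) {
  stopifnot(inherits(params, "elasticity_params"))
  nu <- params$poisson_ratio
  2 * params$mass_density * (1 + nu)^3 / (0.87 + 1.12 * nu)^2 * 1e-3
}

#' Convert SAW velocity to bulk Young's modulus
#'
#' `E = coefficient * V^2` in kPa. The default coefficient is 3.35, the
#' standard rounded skin value (density 1.02 g/cm3, Poisson's ratio 0.5);
#' pass `coefficient = rayleigh_constant(params)` to use the exact
#' Rayleigh-model value for other materials.
#'
#' @param v SAW velocity, m/s, >= 0 (vectorized).
#' @param coefficient modulus coefficient, kPa s2/m2.
#' @return Young's modulus in kPa.
#' @examples
#' velocity_to_modulus(6.78) # ~154 kPa
#' @export
velocity_to_modulus <- function(v, coefficient = 3.35) {
  if (any(v < 0, na.rm = TRUE)) stop("velocity must be >= 0")
  coefficient * v^2
}

#' Invert the modulus conversion
#'
#' @param e Young's modulus, kPa, >= 0.
#' @param coefficient modulus coefficient, kPa s2/m2.
#' @return SAW velocity in m/s; exact inverse of [velocity_to_modulus()].
#' @export
modulus_to_velocity <- function(e, coefficient = 3.35) {
  if (any(e < 0, na.rm = TRUE)) stop("modulus must be >= 0")
  sqrt(e / coefficient)
}

#' Aggregate per-slice velocities into a modulus estimate
#'
#' Two aggregation conventions exist and differ because the conversion is
#' quadratic: `"from-mean"` converts the mean velocity (`E(mean(v))`, with
#' the spread propagated to first order as `2 k vbar sd(v)`), while
#' `"per-slice"` converts each velocity and averages the moduli. The mode
#' used is recorded in the result.
#'
#' @param velocities numeric vector of per-slice velocities, m/s.
#' @param mode `"from-mean"` (default) or `"per-slice"`.
#' @param coefficient modulus coefficient, kPa s2/m2.
#' @return list with `modulus_kpa`, `sd_kpa`, `mode`, `n`,
#'   `velocity_mean`, `velocity_sd`.
#' @export
modulus_report <- function(velocities, mode = c("from-mean", "per-slice"),
                           coefficient = 3.35) {
  mode <- match.arg(mode)
  v <- velocities[!is.na(velocities)]
  if (!length(v)) stop("no velocities to aggregate")
  vm <- mean(v)
  vs <- if (length(v) > 1) sd(v) else 0
  if (mode == "from-mean") {
    list(modulus_kpa = velocity_to_modulus(vm, coefficient),
         sd_kpa = 2 * coefficient * vm * vs,
         mode = mode, n = length(v), velocity_mean = vm, velocity_sd = vs)
  } else {
    e <- velocity_to_modulus(v, coefficient)
    list(modulus_kpa = mean(e),
         sd_kpa = if (length(e) > 1) sd(e) else 0,
         mode = mode, n = length(v), velocity_mean = vm, velocity_sd = vs)
  }
}
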