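#' Krogh-Erlang model parameters
#'
#' Parameter bundle for the classical Krogh-Erlang cylinder: a vessel of
#' radius `r_ves` is the sole O2 source for a coaxial tissue cylinder of
#' radius `r_t`, through whose outer surface no O2 flows.
#'
#' @param cmro2 Volumetric O2 consumption rate, umol cm^-3 min^-1.
#' @param p_ves pO2 at the vessel wall, mmHg.
#' @param r_ves Vessel radius, um.
#' @param r_t Tissue-cylinder radius, um.
#' @param constants A [tissue_constants()] bundle.
#' @return Object of class `krogh_params`.
#' @export
#' @examples
#' p <- krogh_params(cmro2 = 2, p_ves = 60, r_ves = 10, r_t = 80)
#' krogh_po2(c(10, 40, 80), p)
krogh_params <- function(cmro2, p_ves, r_ves, r_t, constants = tissue_constants()) {
  check_radii(r_ves, r_t)
  if (cmro2 < 0) abort("`cmro2` must be >= 0.", class = "odaciti_invalid_parameter")
  structure(
    list(cmro2 = cmro2, p_ves = p_ves, r_ves = r_ves, r_t = r_t,
         constants = constants),
    class = "krogh_params"
  )
}

#' ODACITI model parameters
#'
#' Extends the Krogh-Erlang cylinder with a transitional annulus supplied by
#' the capillary bed: the net radial O2 flux vanishes at a radius `r0` that
#' may lie inside `r_t`, not necessarily at `r_t` itself. The model is
#' parameterised by the log-term coefficient `beta` (the quantity the fit
#' estimates); `r0 = sqrt(r_ves^2 - beta / (2 k))` with
#' `k = cmro2 / (4 D alpha)` is derived from it.
#'
#' For a physically interpretable parameter set `r_ves < r0 <= r_t`; sets
#' violating this are accepted with a warning because they arise routinely as
#' intermediate fit iterates.
#'
#' @inheritParams krogh_params
#' @param beta Coefficient of the `log(r / r_ves)` term, mmHg. Equal to
#'   `cmro2 * (r_ves^2 - r0^2) / (2 D alpha)`; negative when the arteriole
#'   delivers O2 outward.
#' @return Object of class `odaciti_params` (with derived element `r0`, um;
#'   `NA` when `cmro2 = 0`).
#' @export
#' @examples
#' cst <- tissue_constants()
#' beta <- r0_to_beta(80, cmro2 = 2, r_ves = 10, constants = cst)
#' odaciti_params(cmro2 = 2, p_ves = 60, r_ves = 10, r_t = 80, beta = beta)
odaciti_params <- function(cmro2, p_ves, r_ves, r_t, beta,
                           constants = tissue_constants()) {
  check_radii(r_ves, r_t)
  if (cmro2 < 0) abort("`cmro2` must be >= 0.", class = "odaciti_invalid_parameter")
  r0 <- if (cmro2 > 0) beta_to_r0(beta, cmro2, r_ves, constants) else NA_real_
  if (cmro2 > 0 && (is.nan(r0) || r0 <= r_ves || r0 > r_t)) {
    warn(sprintf(
      "Parameter set is not physical: r0 = %.3f um lies outside (r_ves, r_t] = (%g, %g].",
      r0, r_ves, r_t))
  }
  structure(
    list(cmro2 = cmro2, p_ves = p_ves, r_ves = r_ves, r_t = r_t, beta = beta,
         r0 = r0, constants = constants),
    class = "odaciti_params"
  )
}

check_radii <- function(r_ves, r_t) {
  if (!(is.numeric(r_ves) && is.numeric(r_t) && r_ves > 0 && r_ves < r_t)) {
    abort("Radii must satisfy 0 < r_ves < r_t.", class = "odaciti_invalid_parameter")
  }
  invisible(NULL)
}

#' Convert between the log-term coefficient beta and the zero-flux radius r0
#'
#' The two parameterisations of the ODACITI transitional annulus are related
#' by `beta = cmro2 (r_ves^2 - r0^2) / (2 D alpha)` (a bijection for
#' `cmro2 > 0`). `r0_to_beta()` evaluates that formula; `beta_to_r0()` inverts
#' it.
#'
#' @param beta Log-term coefficient, mmHg.
#' @param r0 Zero net-flux radius, um.
#' @param cmro2 O2 consumption rate, umol cm^-3 min^-1; must be > 0.
#' @param r_ves Vessel radius, um.
#' @param constants A [tissue_constants()] bundle.
#' @return The converted value (um for `beta_to_r0`, mmHg for `r0_to_beta`).
#' @export
beta_to_r0 <- function(beta, cmro2, r_ves, constants = tissue_constants()) {
  if (cmro2 <= 0) {
    abort("r0 is undefined for cmro2 = 0 (any beta gives a pure log profile).",
          class = "odaciti_undefined")
  }
  k <- quarter_coef(cmro2, constants)
  arg <- r_ves^2 - beta / (2 * k)
  if (arg < 0) return(NaN)
  sqrt(arg)
}

#' @rdname beta_to_r0
#' @export
r0_to_beta <- function(r0, cmro2, r_ves, constants = tissue_constants()) {
  2 * quarter_coef(cmro2, constants) * (r_ves^2 - r0^2)
}

#' Krogh-Erlang radial pO2 solution
#'
#' Evaluates `p_ves + k (r^2 - r_ves^2 - 2 r_t^2 log(r / r_ves))` with
#' `k = cmro2 / (4 D alpha)`, the steady-state pO2 at distance `r` from the
#' vessel axis when the central vessel supplies the whole tissue cylinder.
#' Defined only on `[r_ves, r_t]`: outside that annulus the solution has no
#' physiological meaning and the function throws a domain error.
#'
#' @param r_um Radial distance(s) from the vessel axis, um.
#' @param p A [krogh_params()] object.
#' @return pO2 in mmHg, same length as `r_um`.
#' @export
krogh_po2 <- function(r_um, p) {
  stopifnot(inherits(p, "krogh_params"))
  if (any(r_um < p$r_ves - 1e-9 | r_um > p$r_t + 1e-9)) {
    abort("`r_um` outside [r_ves, r_t]: the Krogh-Erlang solution is only defined there.",
          class = "odaciti_domain_error")
  }
  r <- pmin(pmax(r_um, p$r_ves), p$r_t)
  k <- quarter_coef(p$cmro2, p$constants)
  p$p_ves + k * (r^2 - p$r_ves^2 - 2 * p$r_t^2 * log(r / p$r_ves))
}

#' ODACITI radial pO2 solution
#'
#' Piecewise steady-state solution of the 2-D diffusion-consumption equation
#' around a diving arteriole with capillary-bed backflow:
#' \itemize{
#'   \item `r < r_ves`: constant `p_ves` (the perivascular dye pool shows no
#'     gradient);
#'   \item `r_ves <= r <= r_t`:
#'     `p_ves + k (r^2 - r_ves^2 - 2 r_ves^2 log(r/r_ves)) + beta log(r/r_ves)`;
#'   \item `r > r_t`: the constant-flux log continuation
#'     `p_ves + k (r_t^2 - r_ves^2 - 2 r_ves^2 log(r/r_ves) + 2 r_t^2 log(r/r_t)) + beta log(r/r_ves)`.
#' }
#' The three pieces are continuous at `r_ves` and `r_t` and have a continuous
#' derivative at `r_t`. When `beta = cmro2 (r_ves^2 - r_t^2) / (2 D alpha)`
#' (i.e. `r0 = r_t`) the middle piece reduces exactly to the Krogh-Erlang
#' solution.
#'
#' @param r_um Radial distance(s), um; any value >= 0.
#' @param p An [odaciti_params()] object.
#' @return pO2 in mmHg.
#' @export
odaciti_po2 <- function(r_um, p) {
  stopifnot(inherits(p, "odaciti_params"))
  if (any(r_um < 0)) abort("`r_um` must be >= 0.", class = "odaciti_domain_error")
  k <- quarter_coef(p$cmro2, p$constants)
  rv <- p$r_ves; rt <- p$r_t
  out <- numeric(length(r_um))
  inner <- r_um < rv
  mid <- !inner & r_um <= rt
  outer <- r_um > rt
  out[inner] <- p$p_ves
  r <- r_um[mid]
  out[mid] <- p$p_ves + k * (r^2 - rv^2 - 2 * rv^2 * log(r / rv)) +
    p$beta * log(r / rv)
  r <- r_um[outer]
  out[outer] <- p$p_ves +
    k * (rt^2 - rv^2 - 2 * rv^2 * log(r / rv) + 2 * rt^2 * log(r / rt)) +
    p$beta * log(r / rv)
  out
}

#' Total O2 flux through a cylindrical surface, Krogh-Erlang model
#'
#' Returns the total flux (per unit axial length) of O2 crossing the
#' cylindrical surface of radius `r`: `cmro2 * pi * (r_t^2 - r^2)`, i.e. the
#' consumption of the tissue outside `r`. Units: umol cm^-1 min^-1. Zero at
#' `r = r_t` (the Krogh closure condition).
#'
#' @inheritParams krogh_po2
#' @return Flux per unit length, umol cm^-1 min^-1.
#' @export
krogh_flux <- function(r_um, p) {
  stopifnot(inherits(p, "krogh_params"))
  if (any(r_um < p$r_ves - 1e-9 | r_um > p$r_t + 1e-9)) {
    abort("`r_um` outside [r_ves, r_t].", class = "odaciti_domain_error")
  }
  p$cmro2 * pi * (p$r_t^2 - r_um^2) * 1e-8
}

#' Total O2 flux through a cylindrical surface, ODACITI model
#'
#' For `r_ves <= r <= r_t` the flux per unit length is
#' `-2 pi D alpha beta - cmro2 pi (r^2 - r_ves^2)`: O2 diffusing out of the
#' arteriole minus what the tissue inside `r` has already consumed. For
#' `r > r_t` the flux is constant at its `r_t` value (delivery and
#' consumption balance in the capillary bed). Vanishes at `r = r0`.
#'
#' @param r_um Radial distance(s), um; must be >= `r_ves`.
#' @param p An [odaciti_params()] object.
#' @return Flux per unit length, umol cm^-1 min^-1.
#' @export
odaciti_flux <- function(r_um, p) {
  stopifnot(inherits(p, "odaciti_params"))
  if (any(r_um < p$r_ves - 1e-9)) {
    abort("`r_um` must be >= r_ves.", class = "odaciti_domain_error")
  }
  r_eff <- pmin(r_um, p$r_t)
  -2 * pi * dalpha_per_min(p$constants) * p$beta -
    p$cmro2 * pi * (r_eff^2 - p$r_ves^2) * 1e-8
}
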