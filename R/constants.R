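#' Physical constants for oxygen transport in brain tissue
#'
#' Bundle of the two tissue constants every diffusion calculation needs: the
#' free diffusion coefficient of O2 and its solubility. Defaults are the
#' standard literature values for cortical tissue: D = 4e-5 cm^2/s and
#' alpha = 1.39 uM/mmHg.
#'
#' All user-facing interfaces work in "measurement units": radii in um, pO2 in
#' mmHg, CMRO2 in umol cm^-3 min^-1. The conversion to CGS-seconds units
#' happens in one place (internal helpers below), never at call sites.
#'
#' @param d_cm2_per_s O2 diffusion coefficient in cm^2/s.
#' @param alpha_uM_per_mmHg O2 solubility in uM/mmHg.
#' @return An object of class `tissue_constants`.
#' @export
#' @examples
#' tissue_constants()
tissue_constants <- function(d_cm2_per_s = 4e-5, alpha_uM_per_mmHg = 1.39) {
  if (!is.numeric(d_cm2_per_s) || length(d_cm2_per_s) != 1 || d_cm2_per_s <= 0) {
    abort("`d_cm2_per_s` must be a single positive number.", class = "odaciti_invalid_parameter")
  }
  if (!is.numeric(alpha_uM_per_mmHg) || length(alpha_uM_per_mmHg) != 1 || alpha_uM_per_mmHg <= 0) {
    abort("`alpha_uM_per_mmHg` must be a single positive number.", class = "odaciti_invalid_parameter")
  }
  structure(
    list(d_cm2_per_s = d_cm2_per_s, alpha_uM_per_mmHg = alpha_uM_per_mmHg),
    class = "tissue_constants"
  )
}

#' @export
print.tissue_constants <- function(x, ...) {
  cat("Tissue O2 constants: D =", x$d_cm2_per_s, "cm^2/s, alpha =",
      x$alpha_uM_per_mmHg, "uM/mmHg\n")
  invisible(x)
}

# CMRO2/(4 D alpha) in mmHg/um^2, for `cmro2` in umol cm^-3 min^-1.
# Chain: umol cm^-3 min^-1 -> /60 -> per s; alpha uM/mmHg -> *1e-3 ->
# umol cm^-3 mmHg^-1; result mmHg/cm^2 -> *1e-8 -> mmHg/um^2.
quarter_coef <- function(cmro2, constants) {
  alpha_molar <- constants$alpha_uM_per_mmHg * 1e-3
  (cmro2 / 60) / (4 * constants$d_cm2_per_s * alpha_molar) * 1e-8
}

# D * alpha in umol cm^-1 min^-1 mmHg^-1 (flux unit conversion)
dalpha_per_min <- function(constants) {
  constants$d_cm2_per_s * constants$alpha_uM_per_mmHg * 1e-3 * 60
}
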