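#' Tidy a radial CMRO2 model fit
#'
#' @param x A `cmro2_fit`.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate`, `unit`.
#' @export
tidy.cmro2_fit <- function(x, ...) {
  out <- tibble(
    term = c("cmro2", "p_ves", "beta"),
    estimate = c(x$cmro2, x$p_ves, x$beta),
    unit = c("umol cm^-3 min^-1", "mmHg", "mmHg"))
  if (x$model == "krogh") out <- out[out$term != "beta", ]
  out
}

#' @rdname tidy.cmro2_fit
#' @export
glance.cmro2_fit <- function(x, ...) {
  tibble(model = x$model, cmro2 = x$cmro2, p_ves = x$p_ves, beta = x$beta,
         r0 = x$r0, r_ves = x$r_ves, r_t = x$r_t, sse = x$sse,
         n_points = x$n_points, condition = x$condition,
         depth_um = x$depth_um, arteriole_id = x$arteriole_id,
         subject_id = x$subject_id)
}

#' Tidy a phosphorescence decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("n0", "tau_us", "offset"),
         estimate = c(x$n0, x$tau_us, x$offset))
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(tau_us = x$tau_us, n0 = x$n0, offset = x$offset, sse = x$sse,
         n_bins_used = x$n_bins_used)
}
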