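#' Simulate a photon-counting phosphorescence decay trace
#'
#' Emulates gated photon-counting acquisition: after a `gate_us`-long
#' excitation gate, photon counts are accumulated in uniform `bin_us` bins
#' over a `window_us` acquisition window, for `n_cycles` excitation cycles.
#' The expected count in the bin starting at time `t` (measured from gate
#' closure) is `n_cycles * (n0 * exp(-(t - fit_origin_us) / tau_us) + offset)`
#' and observed counts are Poisson draws (photon counting), unless
#' `noise = FALSE`.
#'
#' Time zero of the single-exponential model is `fit_origin_us` after gate
#' closure, matching the convention that the decay amplitude is referenced to
#' the start of the fitted window (the earlier bins are contaminated by the
#' instrument response in real data).
#'
#' @param tau_us True phosphorescence lifetime, us (> 0).
#' @param n0 Expected counts per cycle per bin at the fit origin.
#' @param offset Baseline counts per cycle per bin (>= 0).
#' @param n_cycles Number of accumulated excitation cycles (>= 1).
#' @param seed Optional integer seed; identical seeds give identical traces.
#' @param noise If `FALSE`, return the expected counts (non-integer) instead
#'   of Poisson draws.
#' @param point_id Identifier stored in the `point_id` column.
#' @param gate_us,window_us,bin_us Acquisition geometry: excitation gate
#'   length, acquisition window and bin width, us.
#' @param fit_origin_us Offset of the model time origin after gate closure, us.
#' @return A `decay_trace` tibble with columns `point_id`, `bin_start_us`,
#'   `counts`, `n_cycles` and attributes `gate_us`, `bin_us`.
#' @export
#' @examples
#' tr <- simulate_decay(tau_us = 30, n0 = 10, n_cycles = 1000, seed = 1)
#' fit_decay(tr)
simulate_decay <- function(tau_us, n0, offset = 0, n_cycles = 1, seed = NULL,
                           noise = TRUE, point_id = 1L,
                           gate_us = 13, window_us = 287, bin_us = 2,
                           fit_origin_us = 5) {
  if (!is.numeric(tau_us) || tau_us <= 0) {
    abort("`tau_us` must be > 0.", class = "odaciti_invalid_parameter")
  }
  if (n_cycles < 1) {
    abort("`n_cycles` must be >= 1.", class = "odaciti_invalid_parameter")
  }
  if (n0 <= 0 || offset < 0) {
    abort("`n0` must be > 0 and `offset` >= 0.", class = "odaciti_invalid_parameter")
  }
  t <- seq(0, window_us - bin_us, by = bin_us)
  mu <- n_cycles * (n0 * exp(-(t - fit_origin_us) / tau_us) + offset)
  counts <- if (noise) {
    if (!is.null(seed)) {
      withr_seed <- get_seed_state()
      on.exit(restore_seed_state(withr_seed), add = TRUE)
      set.seed(seed)
    }
    rpois(length(mu), mu)
  } else {
    mu
  }
  out <- tibble(point_id = point_id, bin_start_us = t, counts = counts,
                n_cycles = n_cycles)
  structure(out, gate_us = gate_us, bin_us = bin_us,
            class = c("decay_trace", class(out)))
}

get_seed_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Fit a single-exponential phosphorescence decay
#'
#' Nonlinear least squares of `N(t) = N0 * exp(-t'/tau) + x` to binned photon
#' counts, with `t' = bin_start_us - fit_start_us` and only bins at
#' `t >= fit_start_us` used (the early bins carry the instrument response).
#' The optimizer is bounded Levenberg-Marquardt ([minpack.lm::nlsLM()]) with
#' `tau` initialised from the log-linear slope of background-subtracted
#' counts; a failed fit is restarted from `tau = 30` us and, if it still does
#' not converge, a fit-failure error carrying the diagnostics is thrown.
#' Bins are equally weighted (unweighted least squares).
#'
#' @param trace A `decay_trace` tibble (columns `bin_start_us`, `counts`).
#' @param fit_start_us Start of the fit window, us after gate closure.
#' @return A `decay_fit` object: list with `n0`, `tau_us`, `offset`, `sse`,
#'   `n_bins_used`, and the fitted values.
#' @export
fit_decay <- function(trace, fit_start_us = 5) {
  stopifnot(is.data.frame(trace))
  use <- trace$bin_start_us >= fit_start_us
  t <- trace$bin_start_us[use] - fit_start_us
  y <- as.numeric(trace$counts[use])
  if (length(y) < 5) {
    abort("Fewer than 5 bins remain after the fit-start cut.",
          class = "odaciti_fit_failure")
  }
  if (all(y == 0)) {
    abort("All counts are zero; decay cannot be fitted.",
          class = "odaciti_fit_failure")
  }

  x0 <- max(mean(tail(y, max(3L, length(y) %/% 10))), 0)
  pos <- which(y - x0 > 0)
  tau0 <- if (length(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(y[pos] - x0) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else 30
  } else 30
  tau0 <- min(max(tau0, 1), 300)
  n00 <- max(y[1] - x0, max(y) * 0.5, 1e-6)

  do_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ n0 * exp(-t / tau) + x,
        start = start,
        lower = c(n0 = 1e-12, tau = 1e-3, x = 0),
        upper = c(n0 = Inf, tau = 1e5, x = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
  }
  fit <- do_fit(list(n0 = n00, tau = tau0, x = x0))
  if (inherits(fit, "error")) {
    fit <- do_fit(list(n0 = n00, tau = 30, x = x0))
  }
  if (inherits(fit, "error")) {
    abort(paste0("Decay fit failed to converge: ", conditionMessage(fit)),
          class = "odaciti_fit_failure")
  }
  cf <- coef(fit)
  fitted_vals <- cf[["n0"]] * exp(-t / cf[["tau"]]) + cf[["x"]]
  structure(
    list(n0 = unname(cf[["n0"]]), tau_us = unname(cf[["tau"]]),
         offset = unname(cf[["x"]]), sse = sum((y - fitted_vals)^2),
         n_bins_used = length(y), fit_start_us = fit_start_us,
         t_us = t + fit_start_us, fitted = fitted_vals),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Decay fit: tau = %.3f us, N0 = %.2f, offset = %.3f (SSE %.3g over %d bins)\n",
              x$tau_us, x$n0, x$offset, x$sse, x$n_bins_used))
  invisible(x)
}

#' Fractional residual of a decay fit
#'
#' Sum over the fit-window bins of `|data - fit| / fit`, the quality-control
#' metric used to decide how many excitation cycles suffice for a stable
#' lifetime estimate. Undefined (error) when the fitted value is not
#' positive in some bin.
#'
#' @param trace The `decay_trace` the fit was computed from.
#' @param fit The corresponding [fit_decay()] result.
#' @return A non-negative scalar; zero iff the data equal the fit on the
#'   window.
#' @export
fractional_residual <- function(trace, fit) {
  stopifnot(inherits(fit, "decay_fit"))
  use <- trace$bin_start_us >= fit$fit_start_us
  y <- as.numeric(trace$counts[use])
  if (length(y) != length(fit$fitted)) {
    abort("Trace and fit windows do not match.", class = "odaciti_invalid_parameter")
  }
  if (any(fit$fitted <= 0)) {
    abort("Fitted value <= 0 in some bin; fractional residual undefined.",
          class = "odaciti_undefined")
  }
  sum(abs(y - fit$fitted) / fit$fitted)
}

#' Lifetime-to-pO2 calibration
#'
#' Constructor for the empirical biexponential map
#' `pO2(tau) = a1 exp(-tau/t1) + a2 exp(-tau/t2) + y0`. With positive
#' amplitudes the map is strictly decreasing in the lifetime: more O2 means
#' stronger quenching and a faster decay.
#'
#' @param a1,t1_us,a2,t2_us,y0 Calibration constants (amplitudes in mmHg,
#'   times in us).
#' @return Object of class `lifetime_calibration`.
#' @export
lifetime_calibration <- function(a1, t1_us, a2, t2_us, y0) {
  if (t1_us <= 0 || t2_us <= 0) {
    abort("Calibration time constants must be > 0.", class = "odaciti_invalid_parameter")
  }
  structure(list(a1 = a1, t1_us = t1_us, a2 = a2, t2_us = t2_us, y0 = y0),
            class = "lifetime_calibration")
}

#' Default (synthetic) lifetime calibration
#'
#' The constants of the probe calibration are instrument- and batch-specific
#' and must normally be supplied by the user (see [read_calibration()]). This
#' default is a synthetic stand-in with the qualitative shape of a real
#' phosphorescence-quenching calibration, mapping lifetimes of roughly
#' 8-92 us onto pO2 0-160 mmHg. It is suitable for simulation and testing,
#' not for calibrated measurements.
#'
#' @return A [lifetime_calibration()] object.
#' @export
default_calibration <- function() {
  lifetime_calibration(a1 = 200, t1_us = 15, a2 = 60, t2_us = 45, y0 = -8)
}

#' Convert phosphorescence lifetime to pO2
#'
#' @param tau_us Lifetime(s), us (> 0).
#' @param cal A [lifetime_calibration()]; defaults to the synthetic
#'   [default_calibration()].
#' @return pO2 in mmHg.
#' @export
lifetime_to_po2 <- function(tau_us, cal = default_calibration()) {
  stopifnot(inherits(cal, "lifetime_calibration"))
  if (any(tau_us <= 0)) abort("`tau_us` must be > 0.", class = "odaciti_invalid_parameter")
  cal$a1 * exp(-tau_us / cal$t1_us) + cal$a2 * exp(-tau_us / cal$t2_us) + cal$y0
}

#' Numerically invert a lifetime calibration
#'
#' Bisection inverse of [lifetime_to_po2()] over `tau` in
#' `(tau_min, tau_max]`; valid for strictly decreasing (positive-amplitude)
#' calibrations.
#'
#' @param po2_mmhg pO2 value(s) to invert, mmHg.
#' @param cal A [lifetime_calibration()].
#' @param tau_min,tau_max Search bracket, us.
#' @return Lifetime(s), us.
#' @export
po2_to_lifetime <- function(po2_mmhg, cal = default_calibration(),
                            tau_min = 1e-6, tau_max = 500) {
  vapply(po2_mmhg, function(p) {
    stats::uniroot(function(tau) lifetime_to_po2(tau, cal) - p,
                   lower = tau_min, upper = tau_max, tol = 1e-10)$root
  }, numeric(1))
}

#' Filter measurement records by accumulated cycle count
#'
#' Motion-corrupted acquisitions leave fewer usable excitation cycles per
#' point; points are kept only when at least `min_cycles` cycles were
#' accumulated (inclusive boundary). Input order is preserved.
#'
#' @param points A data frame with an `n_cycles` column.
#' @param min_cycles Minimum number of cycles, default 500.
#' @return The filtered data frame (same type as the input).
#' @export
filter_points_by_cycles <- function(points, min_cycles = 500) {
  stopifnot(is.data.frame(points))
  if (!"n_cycles" %in% names(points)) {
    abort("`points` must carry an `n_cycles` column.", class = "odaciti_schema_error")
  }
  points[points$n_cycles >= min_cycles, , drop = FALSE]
}

#' Fit all decay traces of a point table and map lifetimes to pO2
#'
#' Pipeline convenience: groups a long trace table (one row per bin) by
#' `point_id`, fits each decay, applies the cycle-count filter and the
#' calibration, and returns one row per point.
#'
#' @param traces Data frame with columns `point_id`, `bin_start_us`,
#'   `counts`, `n_cycles`.
#' @param cal A [lifetime_calibration()] or `NULL` to skip pO2 conversion.
#' @param fit_start_us Fit-window start, us.
#' @param min_cycles Cycle-count filter threshold (applied before fitting).
#' @return Tibble with columns `point_id`, `tau_us`, `po2_mmhg` (if
#'   calibrated), `n0`, `offset`, `sse`, `n_cycles`.
#' @export
fit_decays <- function(traces, cal = default_calibration(), fit_start_us = 5,
                       min_cycles = 500) {
  stopifnot(is.data.frame(traces))
  needed <- c("point_id", "bin_start_us", "counts", "n_cycles")
  missing_cols <- setdiff(needed, names(traces))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "odaciti_schema_error")
  }
  traces <- filter_points_by_cycles(traces, min_cycles)
  out <- traces |>
    dplyr::group_by(.data$point_id) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_decay(df, fit_start_us = fit_start_us)
      tibble(tau_us = f$tau_us, n0 = f$n0, offset = f$offset, sse = f$sse,
             n_bins_used = f$n_bins_used, n_cycles = df$n_cycles[1])
    }) |>
    dplyr::ungroup()
  if (!is.null(cal)) {
    out$po2_mmhg <- lifetime_to_po2(out$tau_us, cal)
  }
  out
}
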