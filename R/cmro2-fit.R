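# Design matrices for the radial models. Both the ODACITI and the
# Krogh-Erlang predictions are linear in their free parameters
# (p_ves, cmro2, beta), so the least-squares fits are solved exactly by QR
# with a one-step active set for the cmro2 >= 0 bound.

odaciti_design <- function(r, r_ves, r_t, constants) {
  ku <- quarter_coef(1, constants)   # per unit cmro2
  g <- ifelse(r < r_ves, 0,
       ifelse(r <= r_t,
              ku * (r^2 - r_ves^2 - 2 * r_ves^2 * log(r / r_ves)),
              ku * (r_t^2 - r_ves^2 - 2 * r_ves^2 * log(r / r_ves) +
                      2 * r_t^2 * log(r / r_t))))
  h <- ifelse(r < r_ves, 0, log(r / r_ves))
  cbind(intercept = 1, g = g, h = h)
}

krogh_design <- function(r, r_ves, r_t, constants) {
  ku <- quarter_coef(1, constants)
  cbind(intercept = 1,
        g = ku * (r^2 - r_ves^2 - 2 * r_t^2 * log(r / r_ves)))
}

#' Fit the ODACITI model to a radial pO2 profile
#'
#' Least-squares estimation of CMRO2, the vessel-wall pO2 and the log-term
#' coefficient beta, given the arteriolar radius `r_ves` and the
#' capillary-free radius `r_t` (fixed at 80 um by default, the observed size
#' of the capillary-free periarteriolar space). All profile points
#' participate, including those inside the vessel and beyond `r_t` -- the
#' ability to use the capillary-bed plateau is the model's point.
#'
#' The prediction is linear in the three free parameters, so the global
#' optimum is computed directly by QR decomposition; the physical bound
#' `cmro2 >= 0` is enforced by refitting with CMRO2 pinned at zero when the
#' unconstrained optimum is negative (with a warning). A condition-number
#' diagnostic of the design matrix is recorded and a warning is emitted above
#' 1e6, where beta and CMRO2 become practically unidentifiable (profiles
#' with no data beyond the zero-flux radius).
#'
#' @param profile A `radial_profile` (columns `r_um`, `po2_mmhg`).
#' @param r_ves Arteriolar radius, um.
#' @param r_t Capillary-free tissue radius, um; default 80.
#' @param constants A [tissue_constants()] bundle.
#' @param weights Optional per-point weights.
#' @return A `cmro2_fit` object; see [tidy()] / [glance()] methods.
#' @export
#' @examples
#' truth <- krogh_params(cmro2 = 2, p_ves = 60, r_ves = 10, r_t = 80)
#' prof <- generate_krogh_synthetic(truth)
#' fit <- fit_odaciti(prof, r_ves = 10, r_t = 80)
#' glance(fit)
fit_odaciti <- function(profile, r_ves, r_t = 80,
                        constants = tissue_constants(), weights = NULL) {
  fit_radial_model(profile, r_ves, r_t, constants, weights, model = "odaciti")
}

#' Fit the Krogh-Erlang model to a radial pO2 profile
#'
#' Comparison fit: least squares of the classical cylinder solution over
#' CMRO2 and the vessel-wall pO2, restricted to the model's domain of
#' validity `r_ves <= r <= r_t` (points outside are dropped). At least 4
#' in-domain points are required.
#'
#' @inheritParams fit_odaciti
#' @param r_t Assumed tissue-cylinder radius, um.
#' @return A `cmro2_fit` object.
#' @export
fit_krogh <- function(profile, r_ves, r_t,
                      constants = tissue_constants(), weights = NULL) {
  fit_radial_model(profile, r_ves, r_t, constants, weights, model = "krogh")
}

fit_radial_model <- function(profile, r_ves, r_t, constants, weights, model) {
  stopifnot(is.data.frame(profile))
  if (!all(c("r_um", "po2_mmhg") %in% names(profile))) {
    abort("Profile needs columns `r_um` and `po2_mmhg`.",
          class = "odaciti_schema_error")
  }
  check_radii(r_ves, r_t)
  r <- profile$r_um; y <- profile$po2_mmhg
  if (model == "krogh") {
    keep <- r >= r_ves & r <= r_t
    if (sum(keep) < 4) {
      abort("Fewer than 4 points inside [r_ves, r_t] for the Krogh fit.",
            class = "odaciti_insufficient_data")
    }
    r <- r[keep]; y <- y[keep]
    if (!is.null(weights)) weights <- weights[keep]
  } else {
    if (length(r) < 8) {
      abort("ODACITI fit needs at least 8 profile points.",
            class = "odaciti_insufficient_data")
    }
    if (max(r) <= r_ves) {
      abort("Profile has no points beyond the vessel radius.",
            class = "odaciti_insufficient_data")
    }
  }
  X <- if (model == "odaciti") odaciti_design(r, r_ves, r_t, constants)
       else krogh_design(r, r_ves, r_t, constants)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  sw <- sqrt(w)

  degenerate <- sd(y) < .Machine$double.eps^0.5
  if (degenerate) {
    warn("Profile is constant; returning cmro2 = 0.")
    cf <- c(intercept = mean(y), g = 0, h = 0)[seq_len(ncol(X))]
  } else {
    cf <- qr.coef(qr(X * sw), y * sw)
    if (cf[["g"]] < 0) {
      warn("Unconstrained CMRO2 estimate was negative; refit with cmro2 = 0.")
      keep_cols <- setdiff(colnames(X), "g")
      cf0 <- qr.coef(qr(X[, keep_cols, drop = FALSE] * sw), y * sw)
      cf <- setNames(numeric(ncol(X)), colnames(X))
      cf[keep_cols] <- cf0
    }
  }
  cond <- kappa(X * sw, exact = TRUE)
  if (cond > 1e6) {
    warn(sprintf(
      "Design condition number %.3g > 1e6: cmro2 and beta are poorly identified (no data beyond r0?).",
      cond))
  }
  fitted_vals <- drop(X %*% cf)
  beta <- if (model == "odaciti") unname(cf[["h"]]) else NA_real_
  cmro2 <- unname(cf[["g"]])
  r0 <- if (model == "odaciti" && cmro2 > 0) {
    beta_to_r0(beta, cmro2, r_ves, constants)
  } else NA_real_
  structure(
    list(model = model, cmro2 = cmro2, p_ves = unname(cf[["intercept"]]),
         beta = beta, r0 = r0, r_ves = r_ves, r_t = r_t,
         sse = sum(w * (y - fitted_vals)^2), n_points = length(y),
         condition = cond, constants = constants,
         data = tibble(r_um = r, po2_mmhg = y, fitted = fitted_vals),
         depth_um = attr(profile, "depth_um") %||% NA_real_,
         arteriole_id = attr(profile, "arteriole_id") %||% NA_character_,
         subject_id = attr(profile, "subject_id") %||% NA_character_),
    class = "cmro2_fit"
  )
}

#' @export
print.cmro2_fit <- function(x, ...) {
  cat(sprintf("%s fit: CMRO2 = %.4f umol cm^-3 min^-1, p_ves = %.2f mmHg",
              toupper(x$model), x$cmro2, x$p_ves))
  if (x$model == "odaciti") {
    cat(sprintf(", beta = %.3f mmHg (r0 = %.1f um)", x$beta, x$r0))
  }
  cat(sprintf("\n  SSE %.4g over %d points (Rves %.1f, Rt %.1f um)\n",
              x$sse, x$n_points, x$r_ves, x$r_t))
  invisible(x)
}

#' Predict model pO2 from a fitted object
#'
#' @param object A `cmro2_fit`.
#' @param r_um Radii at which to evaluate, um; defaults to the fitted radii.
#' @param ... Unused.
#' @return pO2 in mmHg.
#' @export
predict.cmro2_fit <- function(object, r_um = NULL, ...) {
  if (is.null(r_um)) r_um <- object$data$r_um
  X <- if (object$model == "odaciti") {
    odaciti_design(r_um, object$r_ves, object$r_t, object$constants)
  } else {
    krogh_design(r_um, object$r_ves, object$r_t, object$constants)
  }
  cf <- c(object$p_ves, object$cmro2, object$beta)[seq_len(ncol(X))]
  drop(X %*% cf)
}

#' Sensitivity of the CMRO2 estimate to the assumed capillary-free radius
#'
#' Re-fits both models while the assumed `r_t` is varied over `rt_values`
#' (the Krogh fit restricted to `[r_ves, r_t]` each time) and reports the
#' relative CMRO2 error against the known truth. The summary attributes give
#' the mean and worst-case absolute error over the range for each model --
#' the mean is the headline robustness number, the worst case (attained at
#' the low end of the range) the pessimistic one.
#'
#' @param profile A `radial_profile` of synthetic data with known truth.
#' @param r_ves Arteriolar radius, um.
#' @param rt_values Assumed radii to scan, um; default `seq(60, 80, 5)`.
#' @param true_cmro2 The generating CMRO2.
#' @param constants A [tissue_constants()] bundle.
#' @return An `rt_sensitivity` tibble: `r_t_assumed`, `model`, `cmro2_hat`,
#'   `error_pct`, with attribute `summary` (per-model mean/max error).
#' @export
rt_sensitivity <- function(profile, r_ves, rt_values = seq(60, 80, by = 5),
                           true_cmro2, constants = tissue_constants()) {
  if (any(rt_values <= r_ves)) {
    abort("All `rt_values` must exceed `r_ves`.", class = "odaciti_invalid_parameter")
  }
  res <- purrr::map_dfr(rt_values, function(rt) {
    one <- function(model) {
      est <- tryCatch({
        f <- if (model == "odaciti") {
          fit_odaciti(profile, r_ves = r_ves, r_t = rt, constants = constants)
        } else {
          fit_krogh(profile, r_ves = r_ves, r_t = rt, constants = constants)
        }
        f$cmro2
      }, error = function(e) NA_real_)
      tibble(r_t_assumed = rt, model = model, cmro2_hat = est,
             error_pct = 100 * abs(est - true_cmro2) / true_cmro2)
    }
    dplyr::bind_rows(one("odaciti"), one("krogh"))
  })
  summ <- res |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_error_pct = mean(.data$error_pct, na.rm = TRUE),
                     max_error_pct = max(.data$error_pct, na.rm = TRUE),
                     .groups = "drop")
  structure(res, summary = summ, true_cmro2 = true_cmro2,
            class = c("rt_sensitivity", class(tibble())))
}

#' Estimate the arteriolar radius from an intensity profile
#'
#' The vessel radius is half the full width at half maximum (FWHM) of the
#' fluorescence intensity profile drawn across the arteriole. The half-max
#' level is midway between the profile baseline (its minimum) and its peak;
#' crossings on each side of the peak are located by linear interpolation.
#'
#' @param profile Data frame with `position_um` and `intensity`.
#' @return `r_ves` in um.
#' @export
#' @examples
#' pos <- seq(0, 60, 0.1)
#' prof <- data.frame(position_um = pos,
#'                    intensity = exp(-(pos - 30)^2 / (2 * 5^2)))
#' estimate_rves(prof)  # ~ 1.1774 * 5
estimate_rves <- function(profile) {
  stopifnot(is.data.frame(profile))
  if (!all(c("position_um", "intensity") %in% names(profile))) {
    abort("Profile needs columns `position_um` and `intensity`.",
          class = "odaciti_schema_error")
  }
  x <- profile$position_um; yv <- profile$intensity
  o <- order(x); x <- x[o]; yv <- yv[o]
  imax <- which.max(yv)
  if (imax == 1 || imax == length(yv)) {
    abort("Intensity maximum must be interior to the profile.",
          class = "odaciti_profile_error")
  }
  half <- (min(yv) + max(yv)) / 2
  cross <- function(idx_range, from_peak) {
    below <- which(yv[idx_range] < half)
    if (!length(below)) {
      abort("No half-maximum crossing on one side of the peak.",
            class = "odaciti_profile_error")
    }
    if (from_peak == "left") {
      i2 <- idx_range[max(below)]            # last below-half sample left of peak
      i1 <- i2 + 1L
    } else {
      i2 <- idx_range[min(below)]            # first below-half sample right of peak
      i1 <- i2 - 1L
    }
    x[i2] + (half - yv[i2]) / (yv[i1] - yv[i2]) * (x[i1] - x[i2])
  }
  xl <- cross(seq_len(imax - 1L), "left")
  xr <- cross(seq(imax + 1L, length(yv)), "right")
  (xr - xl) / 2
}

#' Average repeated CMRO2 estimates of the same imaging plane
#'
#' When a plane (subject x arteriole x depth) was acquired several times the
#' per-acquisition estimates are arithmetically averaged.
#'
#' @param estimates Tibble with columns `cmro2` and the plane identifiers
#'   `subject_id`, `arteriole_id`, `depth_um` (plus optionally `p_ves`,
#'   `beta`).
#' @return One row per plane with averaged `cmro2` (and `p_ves`, `beta` when
#'   present) and the number of acquisitions `n`.
#' @export
average_plane_estimates <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  ids <- c("subject_id", "arteriole_id", "depth_um")
  missing_cols <- setdiff(c(ids, "cmro2"), names(estimates))
  if (length(missing_cols)) {
    abort(paste0("Missing plane identifier column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "odaciti_grouping_error")
  }
  avg_cols <- intersect(c("cmro2", "p_ves", "beta"), names(estimates))
  estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(avg_cols), mean),
                     n = dplyr::n(), .groups = "drop")
}
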