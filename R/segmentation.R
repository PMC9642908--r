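#' Interpolate radial pO2 vectors around the arteriole center
#'
#' Draws `n_radii` equally spaced directions from the arteriole center and
#' interpolates the grid's pO2 values along each at `step_um` spacing, from
#' the vessel wall out to the field-of-view edge in that direction.
#' Interpolation is bilinear when the points form a regular lattice (the
#' usual square measurement grid) and inverse-distance weighted over the
#' nearest points otherwise.
#'
#' @param grid A `po2_grid` (or data frame with `x_um`, `y_um`, `po2_mmhg`).
#' @param center Arteriole center `c(x, y)`, um; defaults to the grid
#'   attribute.
#' @param r_ves Arteriole radius, um; defaults to the grid attribute.
#' @param n_radii Number of directions (default 20, i.e. 18 degrees apart).
#' @param step_um Radial sampling step, um.
#' @return A `radial_vectors` tibble: `direction`, `angle_rad`, `r_um`,
#'   `po2`.
#' @export
extract_radial_vectors <- function(grid, center = attr(grid, "center"),
                                   r_ves = attr(grid, "r_ves_um"),
                                   n_radii = 20, step_um = 2) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 4)
  if (is.null(center) || length(center) != 2) {
    abort("`center` must be a length-2 coordinate.", class = "odaciti_invalid_parameter")
  }
  if (is.null(r_ves) || is.na(r_ves)) r_ves <- 0
  bb <- c(range(grid$x_um), range(grid$y_um))
  if (center[1] < bb[1] || center[1] > bb[2] ||
      center[2] < bb[3] || center[2] > bb[4]) {
    abort("Arteriole center lies outside the measurement grid.",
          class = "odaciti_geometry_error")
  }
  interp <- make_interpolator(grid)
  angles <- (seq_len(n_radii) - 1) * 2 * pi / n_radii
  purrr::map_dfr(seq_len(n_radii), function(k) {
    th <- angles[k]
    u <- c(cos(th), sin(th))
    # distance to the bounding box edge along this direction
    tx <- if (u[1] > 0) (bb[2] - center[1]) / u[1]
          else if (u[1] < 0) (bb[1] - center[1]) / u[1] else Inf
    ty <- if (u[2] > 0) (bb[4] - center[2]) / u[2]
          else if (u[2] < 0) (bb[3] - center[2]) / u[2] else Inf
    r_max <- min(tx, ty)
    r <- seq(max(r_ves, step_um * 1e-6), r_max, by = step_um)
    tibble(direction = k, angle_rad = th, r_um = r,
           po2 = interp(center[1] + r * u[1], center[2] + r * u[2]))
  }) |>
    structure(class = c("radial_vectors", class(tibble())))
}

# Regular-lattice bilinear interpolation with IDW fallback for scattered
# layouts (no Delaunay interpolation is available in the dependency set).
make_interpolator <- function(grid) {
  xs <- sort(unique(grid$x_um)); ys <- sort(unique(grid$y_um))
  is_lattice <- length(xs) * length(ys) == nrow(grid) &&
    nrow(dplyr::distinct(grid, .data$x_um, .data$y_um)) == nrow(grid)
  if (is_lattice) {
    m <- matrix(NA_real_, length(xs), length(ys))
    ix <- match(grid$x_um, xs); iy <- match(grid$y_um, ys)
    m[cbind(ix, iy)] <- grid$po2_mmhg
    function(qx, qy) {
      i <- pmin(pmax(findInterval(qx, xs), 1L), length(xs) - 1L)
      j <- pmin(pmax(findInterval(qy, ys), 1L), length(ys) - 1L)
      tx <- (qx - xs[i]) / (xs[i + 1L] - xs[i])
      ty <- (qy - ys[j]) / (ys[j + 1L] - ys[j])
      tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
      (1 - tx) * (1 - ty) * m[cbind(i, j)] + tx * (1 - ty) * m[cbind(i + 1L, j)] +
        (1 - tx) * ty * m[cbind(i, j + 1L)] + tx * ty * m[cbind(i + 1L, j + 1L)]
    }
  } else {
    px <- grid$x_um; py <- grid$y_um; pv <- grid$po2_mmhg
    function(qx, qy) {
      vapply(seq_along(qx), function(q) {
        d2 <- (px - qx[q])^2 + (py - qy[q])^2
        if (min(d2) < 1e-12) return(pv[which.min(d2)])
        near <- order(d2)[seq_len(min(4L, length(d2)))]
        w <- 1 / d2[near]
        sum(w * pv[near]) / sum(w)
      }, numeric(1))
    }
  }
}

#' Smooth radial pO2 vectors with a cubic smoothing spline
#'
#' Applies, per direction, a cubic smoothing spline in the MATLAB `csaps`
#' parameterisation: the spline minimises
#' `p * sum((y - s)^2) + (1 - p) * integral(s'')^2`. `p = 1` interpolates the
#' samples; `p -> 0` tends to the least-squares line; the default
#' `p = 0.001` smooths strongly at the 2-um sampling used here. Internally
#' this maps onto [stats::smooth.spline()] via
#' `lambda = (1 - p) / p / range(r)^3`.
#'
#' Adds `po2_smooth` and the first spatial derivative `dpo2_dr` (mmHg/um) to
#' the vectors.
#'
#' @param vectors A `radial_vectors` tibble (or a single-direction tibble
#'   with `r_um`, `po2`).
#' @param p Smoothing parameter in (0, 1].
#' @return The input with `po2_smooth` and `dpo2_dr` columns added.
#' @export
smooth_vector <- function(vectors, p = 0.001) {
  stopifnot(is.data.frame(vectors))
  if (!"direction" %in% names(vectors)) vectors$direction <- 1L
  if (p <= 0 || p > 1) abort("`p` must be in (0, 1].", class = "odaciti_invalid_parameter")
  vectors |>
    dplyr::group_by(.data$direction) |>
    dplyr::group_modify(function(df, key) {
      stopifnot(nrow(df) >= 4)
      rng <- diff(range(df$r_um))
      lam <- max((1 - p) / p, 1e-12) / rng^3
      sp <- smooth.spline(df$r_um, df$po2, lambda = lam,
                          keep.data = FALSE, all.knots = TRUE)
      df$po2_smooth <- predict(sp, df$r_um)$y
      df$dpo2_dr <- predict(sp, df$r_um, deriv = 1)$y
      df
    }) |>
    dplyr::ungroup() |>
    structure(class = c("radial_vectors", class(tibble())))
}

#' Per-direction inclusion cutoff from the smoothed radial derivative
#'
#' Along each direction pO2 should fall monotonically away from the
#' arteriole and level off in the capillary bed. Points are therefore
#' included from the vessel wall outward until the smoothed derivative
#' `dpO2/dr` first reaches zero (crossing from negative); beyond that radius
#' the profile is either flat or rising again -- typically because another
#' oxygenated vessel lies in that direction -- and is excluded.
#'
#' Degenerate directions are retained but flagged: a vector whose derivative
#' is non-negative from the start gets a cutoff at its first radius
#' (`flag = "degenerate"`); a vector that never stops falling is included in
#' full (`flag = "no_crossing"`).
#'
#' `rule = "literal"` instead includes the radii where the smoothed
#' derivative is positive, the alternative textual reading of the inclusion
#' criterion; it is provided for comparison only.
#'
#' @param vectors Smoothed vectors from [smooth_vector()].
#' @param rule `"zero_crossing"` (default) or `"literal"`.
#' @return Tibble `direction`, `cutoff_um`, `flag` (and `keep_pos` list
#'   column under the literal rule).
#' @export
roi_from_derivative <- function(vectors, rule = c("zero_crossing", "literal")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(vectors))
  if (!"dpo2_dr" %in% names(vectors)) {
    abort("Vectors must be smoothed first (see `smooth_vector()`).",
          class = "odaciti_invalid_parameter")
  }
  vectors |>
    dplyr::group_by(.data$direction) |>
    dplyr::group_modify(function(df, key) {
      d <- df$dpo2_dr; r <- df$r_um
      if (rule == "literal") {
        keep <- d > 0
        return(tibble(cutoff_um = if (any(keep)) max(r[keep]) else r[1],
                      flag = "literal", keep_pos = list(r[keep])))
      }
      if (d[1] >= 0) {
        tibble(cutoff_um = r[1], flag = "degenerate")
      } else if (all(d < 0)) {
        tibble(cutoff_um = r[length(r)], flag = "no_crossing")
      } else {
        i <- which(d >= 0)[1]
        # linear interpolation of the zero crossing between r[i-1] and r[i]
        r0 <- r[i - 1] + (0 - d[i - 1]) / (d[i] - d[i - 1]) * (r[i] - r[i - 1])
        tibble(cutoff_um = r0, flag = "ok")
      }
    }) |>
    dplyr::ungroup()
}

#' Build the ROI mask: derivative criterion plus low-tail augmentation
#'
#' A grid point is included when (a) its radius is within the derivative
#' cutoff of its direction sector (reason `"derivative"`), or (b) its pO2
#' lies within the low `fraction` tail of the grid's pO2 distribution
#' (reason `"low_tail"`), which re-admits inter-capillary tissue points at
#' any radius. The derivative reason takes precedence in the labelling; the
#' mask is the plain union. Quantiles are linear-interpolation quantiles and
#' ties at the threshold are included.
#'
#' @param grid The `po2_grid`.
#' @param cutoffs Result of [roi_from_derivative()].
#' @param center Arteriole center; defaults to the grid attribute.
#' @param fraction Low-tail fraction in (0, 1); default 0.35.
#' @param n_radii Number of direction sectors the cutoffs refer to.
#' @return An `roi_mask` tibble: `point`, `x_um`, `y_um`, `r_um`,
#'   `direction`, `included`, `reason`, `cutoff_um`.
#' @export
augment_with_low_tail <- function(grid, cutoffs, center = attr(grid, "center"),
                                  fraction = 0.35,
                                  n_radii = max(cutoffs$direction)) {
  stopifnot(is.data.frame(grid), is.data.frame(cutoffs))
  if (fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be in (0, 1).", class = "odaciti_invalid_parameter")
  }
  dx <- grid$x_um - center[1]; dy <- grid$y_um - center[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  sector <- (round(ang / (2 * pi / n_radii)) %% n_radii) + 1L
  cut_of <- cutoffs$cutoff_um[match(sector, cutoffs$direction)]
  in_deriv <- r <= cut_of
  q <- unname(quantile(grid$po2_mmhg, fraction, type = 7))
  in_tail <- grid$po2_mmhg <= q
  reason <- dplyr::case_when(in_deriv ~ "derivative",
                             in_tail ~ "low_tail",
                             TRUE ~ "excluded")
  structure(
    tibble(point = seq_len(nrow(grid)), x_um = grid$x_um, y_um = grid$y_um,
           r_um = r, direction = sector, included = in_deriv | in_tail,
           reason = reason, cutoff_um = cut_of),
    tail_threshold = q, fraction = fraction,
    class = c("roi_mask", class(tibble())))
}

#' Collapse ROI points into a radial pO2 profile
#'
#' Maps each included point to its Euclidean distance from the arteriole
#' center. Unbinned (default) the raw `(r, pO2)` pairs are returned, sorted
#' by radius; with `bin_um` set, points are averaged within radial bins of
#' that width (bin centers reported).
#'
#' @param grid The `po2_grid`.
#' @param mask An `roi_mask` from [augment_with_low_tail()]; `NULL` uses all
#'   points.
#' @param center Arteriole center.
#' @param bin_um Optional bin width, um.
#' @return A `radial_profile` tibble (`r_um`, `po2_mmhg`, and `n` per bin in
#'   binned mode).
#' @export
collapse_to_radial_profile <- function(grid, mask = NULL,
                                       center = attr(grid, "center"),
                                       bin_um = NULL) {
  stopifnot(is.data.frame(grid))
  keep <- if (is.null(mask)) rep(TRUE, nrow(grid)) else mask$included
  if (!any(keep)) abort("ROI mask is empty.", class = "odaciti_empty_roi")
  g <- grid[keep, , drop = FALSE]
  r <- sqrt((g$x_um - center[1])^2 + (g$y_um - center[2])^2)
  df <- tibble(r_um = r, po2_mmhg = g$po2_mmhg)
  if (!is.null(bin_um)) {
    df <- df |>
      dplyr::mutate(bin = floor(.data$r_um / bin_um)) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(r_um = (.data$bin[1] + 0.5) * bin_um,
                       po2_mmhg = mean(.data$po2_mmhg), n = dplyr::n(),
                       .groups = "drop") |>
      dplyr::select(-"bin")
  }
  df <- dplyr::arrange(df, .data$r_um)
  as_radial_profile(df, r_ves_um = attr(grid, "r_ves_um") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-call ROI segmentation of a pO2 grid
#'
#' Runs the full segmentation chain -- radial interpolation, spline
#' smoothing, derivative cutoffs, low-tail augmentation, radial collapse --
#' and returns all intermediates.
#'
#' @inheritParams extract_radial_vectors
#' @param spline_p Smoothing parameter (see [smooth_vector()]).
#' @param tail Low-tail fraction.
#' @param rule Derivative rule (see [roi_from_derivative()]).
#' @param bin_um Optional radial bin width for the collapsed profile.
#' @return A `segmentation` list: `profile`, `mask`, `cutoffs`, `vectors`.
#' @export
segment_grid <- function(grid, center = attr(grid, "center"),
                         r_ves = attr(grid, "r_ves_um"), n_radii = 20,
                         step_um = 2, spline_p = 0.001, tail = 0.35,
                         rule = "zero_crossing", bin_um = NULL) {
  vectors <- extract_radial_vectors(grid, center = center, r_ves = r_ves,
                                    n_radii = n_radii, step_um = step_um)
  vectors <- smooth_vector(vectors, p = spline_p)
  cutoffs <- roi_from_derivative(vectors, rule = rule)
  mask <- augment_with_low_tail(grid, cutoffs, center = center,
                                fraction = tail, n_radii = n_radii)
  profile <- collapse_to_radial_profile(grid, mask, center = center,
                                        bin_um = bin_um)
  structure(list(profile = profile, mask = mask, cutoffs = cutoffs,
                 vectors = vectors, center = center, r_ves = r_ves),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  n_inc <- sum(x$mask$included)
  cat(sprintf("Segmentation: %d / %d points included (%d derivative, %d low-tail)\n",
              n_inc, nrow(x$mask), sum(x$mask$reason == "derivative"),
              sum(x$mask$reason == "low_tail")))
  flags <- table(x$cutoffs$flag)
  cat("  direction flags:", paste(names(flags), flags, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the capillary-free radius Rt from annotated capillary positions
#'
#' Rt is measured as the mean, over direction sectors, of the distance from
#' the arteriole center to the nearest annotated capillary in that sector.
#'
#' @param center Arteriole center `c(x, y)`, um.
#' @param capillary_points Data frame with `x_um`, `y_um` of capillary
#'   locations.
#' @param mask Optional `roi_mask`; when given, only capillaries within the
#'   segmented ROI's spatial extent contribute.
#' @param n_sectors Number of direction sectors (default 20).
#' @return Rt estimate, um.
#' @export
measure_rt <- function(center, capillary_points, mask = NULL, n_sectors = 20) {
  stopifnot(is.data.frame(capillary_points))
  if (nrow(capillary_points) == 0) {
    abort("No capillaries annotated; Rt undefined.", class = "odaciti_undefined")
  }
  dx <- capillary_points$x_um - center[1]
  dy <- capillary_points$y_um - center[2]
  r <- sqrt(dx^2 + dy^2)
  if (!is.null(mask)) {
    keep <- r <= max(mask$r_um[mask$included])
    if (any(keep)) { r <- r[keep]; dx <- dx[keep]; dy <- dy[keep] }
  }
  ang <- atan2(dy, dx) %% (2 * pi)
  sector <- (round(ang / (2 * pi / n_sectors)) %% n_sectors) + 1L
  nearest <- tapply(r, sector, min)
  mean(nearest)
}
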