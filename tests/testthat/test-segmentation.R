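test_that("radial vectors from a symmetric grid are identical across directions", {
  g <- symmetric_grid(n = 61)
  vec <- extract_radial_vectors(g, n_radii = 20, step_um = 2)
  expect_equal(dplyr::n_distinct(vec$direction), 20)
  # directions 18 degrees apart
  angs <- sort(unique(vec$angle_rad))
  expect_equal(diff(angs), rep(pi / 10, 19), tolerance = 1e-12)
  # compare the directions on their common radial support
  # away from the slope kink at the vessel wall (where bilinear
  # interpolation of the 5-um lattice is locally first-order)
  common <- vec |>
    dplyr::filter(.data$r_um >= 20) |>
    dplyr::group_by(.data$r_um) |>
    dplyr::filter(dplyr::n() == 20) |>
    dplyr::summarise(spread = diff(range(.data$po2)))
  expect_lt(max(common$spread), 0.75)
})

test_that("interpolated vectors track the analytic field", {
  g <- symmetric_grid(n = 61)   # 5-um lattice
  vec <- extract_radial_vectors(g, n_radii = 8, step_um = 2)
  vec <- vec[vec$r_um >= 20, ]   # clear of the vessel-wall slope kink
  expect_lt(max(abs(vec$po2 - krogh_plateau_fun(vec$r_um))), 1)
})

test_that("scattered (non-lattice) grids fall back to local inverse-distance weighting", {
  set.seed(31)
  pts <- tibble::tibble(x_um = runif(400, -150, 150),
                        y_um = runif(400, -150, 150))
  g <- as_po2_grid(
    tibble::tibble(x_um = pts$x_um, y_um = pts$y_um,
                   po2_mmhg = 30 + 0.05 * pts$x_um),
    center = c(0, 0), r_ves_um = 10)
  vec <- extract_radial_vectors(g, n_radii = 4, step_um = 10)
  expect_true(all(is.finite(vec$po2)))
  expect_lt(max(abs(vec$po2 - (30 + 0.05 * (vec$r_um * cos(vec$angle_rad))))), 3)
})

test_that("center outside the grid hull raises a geometry error", {
  g <- symmetric_grid(n = 21)
  expect_error(extract_radial_vectors(g, center = c(500, 0)),
               class = "odaciti_geometry_error")
})

test_that("spline smoothing preserves lines, interpolates at p = 1, and denoises", {
  r <- seq(10, 110, 2)
  lin <- tibble::tibble(direction = 1L, r_um = r, po2 = 80 - 0.3 * r)
  for (p in c(1e-4, 0.001, 0.5, 1)) {
    sm <- smooth_vector(lin, p = p)
    expect_lt(max(abs(sm$po2_smooth - lin$po2)), 1e-6)
  }
  p <- ref_krogh()
  truth <- krogh_plateau_fun(r)
  set.seed(17)
  better <- vapply(1:10, function(i) {
    noisy <- tibble::tibble(direction = 1L, r_um = r, po2 = truth + rnorm(length(r), 0, 2))
    sm <- smooth_vector(noisy, p = 0.001)
    rms <- function(x) sqrt(mean(x^2))
    rms(sm$po2_smooth - truth) < rms(noisy$po2 - truth)
  }, logical(1))
  expect_true(all(better))
  # p = 1 reproduces arbitrary samples (interpolating limit)
  set.seed(18)
  wig <- tibble::tibble(direction = 1L, r_um = r, po2 = rnorm(length(r), 40, 5))
  expect_lt(max(abs(smooth_vector(wig, p = 1)$po2_smooth - wig$po2)), 1e-4)
})

test_that("derivative cutoffs stop at the first flattening and flag degenerate cases", {
  r <- seq(10, 140, 2)
  mk <- function(po2) smooth_vector(tibble::tibble(direction = 1L, r_um = r, po2 = po2),
                                    p = 0.001)
  # monotone fall to an exact plateau at r = 80
  flat <- mk(krogh_plateau_fun(r))
  cut <- roi_from_derivative(flat)
  expect_equal(cut$flag, "ok")
  expect_lt(abs(cut$cutoff_um - 80), 8)
  # secondary oxygenated vessel at r = 110
  bump <- mk(krogh_plateau_fun(r) + 25 * exp(-(r - 110)^2 / 50))
  cut2 <- roi_from_derivative(bump)
  expect_lt(cut2$cutoff_um, 110)
  # strictly increasing vector: degenerate, cut at the first radius
  inc <- mk(20 + 0.2 * r)
  cut3 <- roi_from_derivative(inc)
  expect_equal(cut3$flag, "degenerate")
  expect_equal(cut3$cutoff_um, 10)
  # strictly decreasing vector: no crossing, kept in full and flagged
  dec <- mk(120 - 0.5 * r)
  cut4 <- roi_from_derivative(dec)
  expect_equal(cut4$flag, "no_crossing")
  expect_equal(cut4$cutoff_um, max(r))
  # literal textual rule keeps only rising stretches
  lit <- roi_from_derivative(bump, rule = "literal")
  expect_equal(lit$flag, "literal")
})

test_that("low-tail augmentation uses interpolation quantiles with inclusive ties", {
  # grid of values 1..100: the 35% tail is exactly 1..35
  set.seed(23)
  xy <- tidyr::expand_grid(x_um = seq(-45, 45, 10), y_um = seq(-45, 45, 10))
  g <- as_po2_grid(
    tibble::tibble(x_um = xy$x_um, y_um = xy$y_um, po2_mmhg = sample(1:100)),
    center = c(0, 0), r_ves_um = 5)
  cuts <- tibble::tibble(direction = 1:20, cutoff_um = 0, flag = "ok")
  mask <- augment_with_low_tail(g, cuts, fraction = 0.35)
  expect_setequal(g$po2_mmhg[mask$included], 1:35)
  expect_true(all(mask$reason[mask$included] == "low_tail"))
  # uniform grid: every value sits at the quantile, all included
  gu <- as_po2_grid(tibble::tibble(x_um = xy$x_um, y_um = xy$y_um, po2_mmhg = 7),
                    center = c(0, 0), r_ves_um = 5)
  expect_true(all(augment_with_low_tail(gu, cuts, fraction = 0.35)$included))
  # enlarging the fraction never shrinks the mask
  m35 <- augment_with_low_tail(g, cuts, fraction = 0.35)
  m50 <- augment_with_low_tail(g, cuts, fraction = 0.50)
  expect_true(all(!m35$included | m50$included))
  # derivative reason takes precedence over the tail label
  cuts2 <- tibble::tibble(direction = 1:20, cutoff_um = 100, flag = "ok")
  m2 <- augment_with_low_tail(g, cuts2, fraction = 0.35)
  expect_true(all(m2$reason == "derivative"))
})

test_that("radial collapse maps points to Euclidean distance and bins by group means", {
  g <- as_po2_grid(tibble::tibble(x_um = 30, y_um = 40, po2_mmhg = 55),
                   center = c(0, 0), r_ves_um = 5)
  prof <- collapse_to_radial_profile(g, NULL, c(0, 0))
  expect_equal(prof$r_um, 50)
  expect_equal(prof$po2_mmhg, 55)
  # binned means equal a brute-force group-by
  gg <- symmetric_grid(n = 21)
  for (bw in c(2, 5)) {
    prof_b <- collapse_to_radial_profile(gg, NULL, c(0, 0), bin_um = bw)
    r <- sqrt(gg$x_um^2 + gg$y_um^2)
    brute <- tapply(gg$po2_mmhg, floor(r / bw), mean)
    expect_equal(prof_b$po2_mmhg[order(prof_b$r_um)],
                 as.numeric(brute[order(as.numeric(names(brute)))]))
  }
  # every grid point contributes at most once
  prof_all <- collapse_to_radial_profile(gg, NULL, c(0, 0))
  expect_equal(nrow(prof_all), nrow(gg))
  expect_error(collapse_to_radial_profile(gg, tibble::tibble(included = rep(FALSE, nrow(gg))),
                                          c(0, 0)),
               class = "odaciti_empty_roi")
})

test_that("the full pipeline recovers a symmetric generating profile", {
  g <- symmetric_grid(n = 61)
  seg <- segment_grid(g)
  expect_lt(max(abs(seg$profile$po2_mmhg - krogh_plateau_fun(seg$profile$r_um))), 1)
  # collapsed radii are exact, so the profile values are exact samples
  expect_equal(seg$profile$po2_mmhg,
               krogh_plateau_fun(seg$profile$r_um), tolerance = 1e-12)
})

test_that("segmentation excludes the neighbourhood of a planted oxygenated vessel", {
  f <- solve_poisson_2d(fig2d_geometry(mesh_um = 1.25), cmro2 = 2)
  pts <- square_grid(20, 300)
  pts <- pts[sqrt(pts$x_um^2 + pts$y_um^2) <= 131, ]
  g <- sample_field_to_grid(f, pts)
  seg <- segment_grid(g)
  near <- sqrt((seg$mask$x_um - 110)^2 + seg$mask$y_um^2) <= 20
  kept_by_derivative <- seg$mask$reason[near] == "derivative"
  expect_gte(mean(!kept_by_derivative), 0.9)
})

test_that("Rt is measured as the mean nearest-capillary distance per sector", {
  expect_equal(measure_rt(c(0, 0), tibble::tibble(x_um = 80, y_um = 0)), 80)
  caps <- tibble::tibble(x_um = c(70, -80, 0), y_um = c(0, 0, 90))
  expect_equal(measure_rt(c(0, 0), caps), 80)
  src <- fig2d_geometry()$sources
  caps2 <- tibble::tibble(x_um = src$cx[src$label == "capillary"],
                          y_um = src$cy[src$label == "capillary"])
  rt <- measure_rt(c(0, 0), caps2)
  expect_gte(rt, 80); expect_lte(rt, 130)
  expect_error(measure_rt(c(0, 0), caps2[0, ]), class = "odaciti_undefined")
})
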