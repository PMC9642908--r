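test_that("vessel radius comes from the half-maximum width of an intensity profile", {
  # rectangular pulse of width 20
  pos <- seq(0, 60, 0.01)
  rect <- tibble::tibble(position_um = pos,
                         intensity = ifelse(pos >= 20 & pos < 40, 100, 0))
  expect_equal(estimate_rves(rect), 10, tolerance = 0.01)
  # Gaussian: FWHM = 2.3548 sd
  s <- 5
  gaus <- tibble::tibble(position_um = pos,
                         intensity = exp(-(pos - 30)^2 / (2 * s^2)))
  expect_equal(estimate_rves(gaus), 2.3548 * s / 2, tolerance = 0.01)
  # triangle, baseline 0, apex 100, base width 30 -> half width 15, r = 7.5
  tri <- tibble::tibble(position_um = pos,
                        intensity = pmax(0, 100 * (1 - abs(pos - 30) / 15)))
  expect_equal(estimate_rves(tri), 7.5, tolerance = 0.01)
  # pathological profiles are refused
  expect_error(estimate_rves(tibble::tibble(position_um = pos, intensity = pos)),
               class = "odaciti_profile_error")
})

test_that("noiseless model-generated profiles are recovered exactly", {
  set.seed(41)
  for (i in 1:5) {
    rv <- runif(1, 5, 12); rt <- runif(1, 60, 100)
    cm <- runif(1, 0.5, 4); pv <- runif(1, 40, 90)
    r0 <- runif(1, rv + 10, rt)
    beta <- r0_to_beta(r0, cm, rv, ref_constants)
    po <- odaciti_params(cm, pv, rv, rt, beta, constants = ref_constants)
    r <- seq(0, 120, 2)
    prof <- as_radial_profile(tibble::tibble(r_um = r, po2_mmhg = odaciti_po2(r, po)))
    fit <- fit_odaciti(prof, r_ves = rv, r_t = rt, constants = ref_constants)
    expect_equal(fit$cmro2, cm, tolerance = 1e-6)
    expect_equal(fit$p_ves, pv, tolerance = 1e-6)
    expect_equal(fit$beta, beta, tolerance = 1e-6)
    expect_equal(fit$r0, r0, tolerance = 1e-4)
  }
  # Krogh-with-plateau data at the correct tissue radius
  prof <- generate_krogh_synthetic(ref_krogh())
  fit <- fit_odaciti(prof, r_ves = 10, r_t = 80)
  expect_equal(fit$cmro2, 2, tolerance = 1e-2 * 1e-4)
  kfit <- fit_krogh(prof, r_ves = 10, r_t = 80)
  expect_equal(kfit$cmro2, 2, tolerance = 1e-8)
  expect_equal(kfit$p_ves, 60, tolerance = 1e-8)
})

test_that("flat profiles yield zero consumption", {
  prof <- as_radial_profile(tibble::tibble(r_um = seq(10, 80, 2), po2_mmhg = 40))
  expect_warning(fit <- fit_odaciti(prof, 10, 80), "constant")
  expect_equal(fit$cmro2, 0)
  kprof <- generate_krogh_synthetic(ref_krogh(0))
  expect_warning(kfit <- fit_krogh(kprof, 10, 80), "constant")
  expect_equal(kfit$cmro2, 0, tolerance = 1e-10)
})

test_that("the capillary-aware fit is less sensitive to a misjudged tissue radius", {
  prof <- generate_krogh_synthetic(ref_krogh())
  od60 <- fit_odaciti(prof, r_ves = 10, r_t = 60)
  ke60 <- fit_krogh(prof, r_ves = 10, r_t = 60)
  expect_lt(abs(od60$cmro2 - 2), abs(ke60$cmro2 - 2))
  sens <- rt_sensitivity(prof, r_ves = 10, true_cmro2 = 2)
  expect_equal(nrow(sens), 10)        # 5 assumed radii x 2 models
  at_true <- sens[sens$r_t_assumed == 80, ]
  expect_lt(max(at_true$error_pct), 0.01)
  summ <- attr(sens, "summary")
  expect_lt(summ$mean_error_pct[summ$model == "odaciti"],
            summ$mean_error_pct[summ$model == "krogh"])
})

test_that("estimates recover truth within 10 percent under measurement noise", {
  set.seed(59)
  errs <- vapply(1:50, function(i) {
    cm <- runif(1, 0.5, 4); pv <- runif(1, 40, 90); rv <- runif(1, 5, 15)
    p <- krogh_params(cm, pv, rv, 80, constants = ref_constants)
    g <- add_gaussian_noise(generate_krogh_synthetic_grid(p), sigma = 2)
    prof <- collapse_to_radial_profile(g)
    fit <- suppressWarnings(fit_odaciti(prof, rv, 80))
    (fit$cmro2 - cm) / cm
  }, numeric(1))
  expect_lt(median(abs(errs)) * 100, 10)
  # no systematic sign bias (two-sided sign test)
  expect_gt(stats::binom.test(sum(errs > 0), length(errs))$p.value, 0.01)
})

test_that("fits are invariant to point order and uniform duplication", {
  prof <- generate_krogh_synthetic(ref_krogh())
  base <- fit_odaciti(prof, 10, 80)
  shuf <- as_radial_profile(prof[sample(nrow(prof)), ])
  dup <- as_radial_profile(dplyr::bind_rows(prof, prof))
  expect_equal(fit_odaciti(shuf, 10, 80)$cmro2, base$cmro2, tolerance = 1e-10)
  expect_equal(fit_odaciti(dup, 10, 80)$cmro2, base$cmro2, tolerance = 1e-10)
})

test_that("identifiability degrades without data beyond the zero-flux radius", {
  p <- ref_krogh()
  full <- fit_odaciti(generate_krogh_synthetic(p), 10, 80)
  trunc <- as_radial_profile(tibble::tibble(
    r_um = seq(12, 40, 2), po2_mmhg = krogh_po2(seq(12, 40, 2), p)))
  tfit <- fit_odaciti(trunc, 10, 80)
  expect_gt(tfit$condition, full$condition)
  expect_true(is.finite(tfit$condition))
})

test_that("ignoring capillary delivery biases the cylinder-model estimate downwards", {
  # data generated with the zero-flux radius inside Rt: part of the tissue is
  # capillary-fed, so the purely arteriolar model sees a shallower depression
  # and underestimates consumption
  beta <- r0_to_beta(60, 2, 10, ref_constants)
  po <- odaciti_params(2, 60, 10, 80, beta, constants = ref_constants)
  r <- seq(0, 100, 2)
  prof <- as_radial_profile(tibble::tibble(r_um = r, po2_mmhg = odaciti_po2(r, po)))
  kfit <- fit_krogh(prof, 10, 80)
  expect_lt(kfit$cmro2, 2 * 0.95)
})

test_that("repeated acquisitions of a plane average arithmetically", {
  one <- tibble::tibble(subject_id = "m1", arteriole_id = "a1", depth_um = 100,
                        cmro2 = 1.7, p_ves = 55, beta = -12)
  expect_equal(average_plane_estimates(one)$cmro2, 1.7)
  two <- dplyr::bind_rows(one, dplyr::mutate(one, cmro2 = 2.0))
  avg <- average_plane_estimates(two)
  expect_equal(avg$cmro2, 1.85)
  expect_equal(avg$n, 2L)
  # randomized table matches a brute-force group-by
  set.seed(71)
  tbl <- tibble::tibble(
    subject_id = sample(c("m1", "m2"), 40, TRUE),
    arteriole_id = sample(c("a1", "a2"), 40, TRUE),
    depth_um = sample(c(100, 200), 40, TRUE),
    cmro2 = runif(40, 0.5, 3))
  avg2 <- average_plane_estimates(tbl)
  brute <- aggregate(cmro2 ~ subject_id + arteriole_id + depth_um, tbl, mean)
  m <- merge(as.data.frame(avg2), brute,
             by = c("subject_id", "arteriole_id", "depth_um"))
  expect_equal(m$cmro2.x, m$cmro2.y)
  expect_error(average_plane_estimates(tbl[, "cmro2", drop = FALSE]),
               class = "odaciti_grouping_error")
})

test_that("broom-style accessors expose the fitted parameters", {
  fit <- fit_odaciti(generate_krogh_synthetic(ref_krogh()), 10, 80)
  td <- tidy(fit)
  expect_equal(td$term, c("cmro2", "p_ves", "beta"))
  expect_equal(td$estimate[1], fit$cmro2)
  gl <- glance(fit)
  expect_equal(gl$model, "odaciti")
  expect_equal(gl$n_points, nrow(generate_krogh_synthetic(ref_krogh())))
  pred <- predict(fit, c(10, 40, 80))
  expect_equal(pred[1], fit$p_ves, tolerance = 1e-8)
})

test_that("consumption is identifiable from the azimuthally complete reference field", {
  # the azimuthal mean of the 2-D field over a source-free annulus satisfies
  # the radial consumption equation exactly, so the fit on ALL grid points
  # of the multi-vessel field recovers the generating rate; compare the
  # segmented variant in the end-to-end validation checks
  f <- solve_poisson_2d(fig2d_geometry(mesh_um = 1.25), cmro2 = 2)
  pts <- square_grid(20, 300)
  pts <- pts[sqrt(pts$x_um^2 + pts$y_um^2) <= 131, ]
  g <- sample_field_to_grid(f, pts)
  fit <- fit_odaciti(collapse_to_radial_profile(g), r_ves = 7.5, r_t = 80)
  expect_lt(abs(fit$cmro2 - 2) / 2, 0.10)
})
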