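test_that("noiseless decay traces round-trip their generating parameters", {
  tr <- simulate_decay(tau_us = 30, n0 = 100, offset = 5, n_cycles = 1,
                       noise = FALSE)
  expect_equal(nrow(tr), 143)                      # 2-us bins over 287 us
  # counts proportional to exp(-t/30) after offset removal
  t <- tr$bin_start_us
  expect_equal(diff(log(tr$counts - 5)), rep(-2 / 30, 142), tolerance = 1e-10)
  fit <- fit_decay(tr)
  expect_equal(fit$tau_us, 30, tolerance = 1e-6)
  expect_equal(fit$n0, 100, tolerance = 1e-6)
  expect_equal(fit$offset, 5, tolerance = 1e-4)
  expect_equal(fit$n_bins_used, sum(t >= 5))
})

test_that("seeded simulation is reproducible and obeys parameter checks", {
  a <- simulate_decay(30, n0 = 2, n_cycles = 1000, seed = 1)
  b <- simulate_decay(30, n0 = 2, n_cycles = 1000, seed = 1)
  expect_identical(a$counts, b$counts)
  c2 <- simulate_decay(30, n0 = 2, n_cycles = 1000, seed = 2)
  expect_false(identical(a$counts, c2$counts))
  expect_error(simulate_decay(-3, n0 = 1, n_cycles = 100),
               class = "odaciti_invalid_parameter")
  expect_error(simulate_decay(30, n0 = 1, n_cycles = 0),
               class = "odaciti_invalid_parameter")
})

test_that("large photon counts recover the generating lifetime within 1 percent", {
  tr <- simulate_decay(30, n0 = 1, offset = 0.01, n_cycles = 1e6, seed = 3)
  fit <- fit_decay(tr)
  expect_lt(abs(fit$tau_us - 30) / 30, 0.01)
})

test_that("fitted lifetimes agree with a brute-force profile grid search", {
  # oracle: scan tau over 0.5-300 us in 0.1-us steps, profiling N0 and the
  # offset out by linear least squares at each tau, and keep the best SSE
  grid_tau <- seq(0.5, 300, by = 0.1)
  oracle_tau <- function(trace, fit_start = 5) {
    use <- trace$bin_start_us >= fit_start
    t <- trace$bin_start_us[use] - fit_start
    y <- as.numeric(trace$counts[use])
    B <- exp(-outer(t, 1 / grid_tau))           # bins x taus
    n <- length(y)
    s_bb <- colSums(B^2); s_b <- colSums(B)
    s_by <- drop(crossprod(B, y)); s_y <- sum(y)
    det <- s_bb * n - s_b^2
    a <- (s_by * n - s_b * s_y) / det           # amplitude
    c0 <- (s_bb * s_y - s_b * s_by) / det       # offset
    sse <- sum(y^2) - a * s_by - c0 * s_y
    grid_tau[which.min(sse)]
  }
  tr <- simulate_decay(25, n0 = 200, offset = 2, n_cycles = 1000, seed = 7)
  expect_lte(abs(fit_decay(tr)$tau_us - oracle_tau(tr)), 0.1)
  set.seed(42)
  for (i in 1:10) {
    tau <- runif(1, 8, 120)
    tr <- simulate_decay(tau, n0 = runif(1, 1, 20), offset = runif(1, 0, 0.3),
                         n_cycles = 1000)
    expect_lte(abs(fit_decay(tr)$tau_us - oracle_tau(tr)), 0.1)
  }
})

test_that("slower decays map to lower oxygen", {
  t20 <- simulate_decay(20, n0 = 10, n_cycles = 2000, seed = 5)
  t40 <- simulate_decay(40, n0 = 10, n_cycles = 2000, seed = 6)
  f20 <- fit_decay(t20); f40 <- fit_decay(t40)
  expect_lt(f20$tau_us, f40$tau_us)
  expect_gt(lifetime_to_po2(f20$tau_us), lifetime_to_po2(f40$tau_us))
})

test_that("the calibration map is monotone and numerically invertible", {
  cal <- default_calibration()
  tau <- seq(0.5, 500, by = 0.5)
  expect_true(all(diff(lifetime_to_po2(tau, cal)) < 0))
  # tau limits
  expect_equal(lifetime_to_po2(1e6, cal), cal$y0, tolerance = 1e-6)
  expect_equal(lifetime_to_po2(1e-9, cal), cal$a1 + cal$a2 + cal$y0,
               tolerance = 1e-6)
  # random positive-amplitude calibrations stay monotone; inverse round-trips
  set.seed(8)
  for (i in 1:20) {
    c2 <- lifetime_calibration(runif(1, 50, 400), runif(1, 5, 40),
                               runif(1, 10, 150), runif(1, 20, 90),
                               runif(1, -20, 5))
    expect_true(all(diff(lifetime_to_po2(tau, c2)) < 0))
  }
  for (tau0 in c(12, 30, 75, 200)) {
    p <- lifetime_to_po2(tau0, cal)
    expect_equal(po2_to_lifetime(p, cal), tau0, tolerance = 1e-6)
  }
})

test_that("fractional residual is zero iff the fit matches, and sums unit deviations", {
  tr <- simulate_decay(30, n0 = 50, offset = 1, n_cycles = 1, noise = FALSE)
  fit <- fit_decay(tr)
  expect_equal(fractional_residual(tr, fit), 0, tolerance = 1e-6)
  # deviate one bin by exactly its fitted value -> residual 1
  tr2 <- tr
  j <- which(tr2$bin_start_us >= 5)[10]
  jf <- 10  # corresponding index within the fit window
  tr2$counts[j] <- tr2$counts[j] + fit$fitted[jf]
  expect_equal(fractional_residual(tr2, fit), 1, tolerance = 1e-6)
  expect_gte(fractional_residual(tr2, fit), 0)
})

test_that("residuals shrink as excitation cycles accumulate", {
  mean_resid <- function(cycles) {
    mean(vapply(1:15, function(s) {
      tr <- simulate_decay(30, n0 = 1, offset = 0.02, n_cycles = cycles,
                           seed = 1000 * cycles + s)
      fit <- fit_decay(tr)
      fractional_residual(tr, fit) / fit$n_bins_used
    }, numeric(1)))
  }
  expect_lt(mean_resid(1000), mean_resid(100))
})

test_that("the cycle-count filter keeps records at or above threshold, in order", {
  pts <- tibble::tibble(id = 1:3, n_cycles = c(400, 500, 1000))
  kept <- filter_points_by_cycles(pts)
  expect_equal(kept$id, 2:3)
  expect_equal(nrow(filter_points_by_cycles(pts[0, ])), 0)
  expect_identical(filter_points_by_cycles(pts, min_cycles = 0), pts)
  expect_error(filter_points_by_cycles(tibble::tibble(x = 1)),
               class = "odaciti_schema_error")
})

test_that("the per-point pipeline fits, filters and calibrates a trace table", {
  traces <- dplyr::bind_rows(
    simulate_decay(20, n0 = 10, n_cycles = 1000, seed = 21, point_id = 1L),
    simulate_decay(45, n0 = 10, n_cycles = 800, seed = 22, point_id = 2L),
    simulate_decay(30, n0 = 10, n_cycles = 300, seed = 23, point_id = 3L))
  out <- fit_decays(traces)
  expect_equal(out$point_id, 1:2)          # 300-cycle point filtered out
  expect_equal(out$tau_us, c(20, 45), tolerance = 0.05)
  expect_true(all(out$po2_mmhg == lifetime_to_po2(out$tau_us)))
  expect_error(fit_decays(traces[, -1]), class = "odaciti_schema_error")
})

test_that("degenerate traces raise fit failures with diagnostics", {
  tr <- simulate_decay(30, n0 = 1, n_cycles = 1, noise = FALSE)
  tr$counts <- rep(0, nrow(tr))
  expect_error(fit_decay(tr), class = "odaciti_fit_failure")
  expect_error(fit_decay(tr[1:4, ]), class = "odaciti_fit_failure")
})
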