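test_that("truncation fit recovers exact mono-exponentials", {
  te <- echo_times(proto_megre)
  f <- truncation_fit(echo_series(te, 100 * exp(-100 * te)), sigma = 0)
  expect_equal(f$r2star_hat, 100, tolerance = 1e-6)
  expect_equal(f$n_echoes_used, 12L)
  expect_true(f$converged)
  # constant series: R2* = 0 exactly (boundary attainable)
  f0 <- truncation_fit(echo_series(te, rep(42, 12)), sigma = 0)
  expect_lt(abs(f0$r2star_hat), 1e-9)
  # all-zero series is flagged, not fitted
  fz <- truncation_fit(echo_series(te, rep(0, 12)), sigma = 1)
  expect_false(fz$converged)
  expect_true(is.na(fz$r2star_hat))
})

test_that("echo truncation beats the full fit on floor-corrupted decay", {
  te <- echo_times(proto_megre)
  sigma <- 2.5
  s <- pmax(100 * exp(-400 * te), 1.2533 * sigma) # noise floor plateau
  ser <- echo_series(te, s)
  trunc <- truncation_fit(ser, sigma)
  full <- truncation_fit(ser, sigma = 0) # floor rule never fires
  expect_equal(full$n_echoes_used, 12L)
  expect_lt(trunc$n_echoes_used, 12L)
  expect_lt(abs(trunc$r2star_hat - 400) / 400, 0.02)
  expect_gt(abs(full$r2star_hat - 400), abs(trunc$r2star_hat - 400))
})

test_that("dixon magnitude fit recovers water, fat and R2*", {
  ser <- forward_series(80, 20, 150, proto_wip)
  fit <- dixon_magnitude_fit(ser, the_spectrum, proto_wip)
  expect_equal(fit$w_hat, 80, tolerance = 1e-3)
  expect_equal(fit$f_hat, 20, tolerance = 1e-3)
  expect_equal(fit$r2star_hat, 150, tolerance = 1e-3)
  expect_false(fit$swap_flag) # water-dominant data carry no swap evidence
  # pure water input yields near-zero fat fraction
  serw <- forward_series(100, 0, 90, proto_wip)
  expect_lt(dixon_magnitude_fit(serw, the_spectrum, proto_wip)$pdff_hat, 0.01)
  expect_error(
    dixon_magnitude_fit(ser, the_spectrum, proto_wip,
                        fit_config(grid_min = 5, grid_max = 5)),
    "degenerate")
})

test_that("water/fat role exchange is near-degenerate: the classic swap", {
  ser <- forward_series(20, 80, 150, proto_wip) # fat-dominant truth
  glob <- dixon_magnitude_fit(ser, the_spectrum, proto_wip,
                              resolve = "global")
  expect_equal(glob$pdff_hat, 0.8, tolerance = 1e-3)
  expect_true(glob$swap_flag)
  # product-style resolution forces the water-dominant minimum
  wat <- dixon_magnitude_fit(ser, the_spectrum, proto_wip,
                             resolve = "prefer_water")
  expect_lt(wat$pdff_hat, 0.5)
  expect_true(wat$swap_flag)
  expect_gte(wat$residual, glob$residual)
})

test_that("grid-scan optimum is no worse than a 1 1/s brute-force scan", {
  cfg <- fit_config()
  for (par in list(c(85, 15, 60), c(60, 25, 340), c(95, 4, 700))) {
    ser <- forward_series(par[1], par[2], par[3], proto_wip, sigma = 0)
    # corrupt mildly so the optimum is not trivially zero
    s <- ser$magnitude * (1 + c(0.01, -0.01, 0.005, 0, -0.005, 0.01))
    ser <- echo_series(ser$te, s)
    fit <- dixon_magnitude_fit(ser, the_spectrum, proto_wip, cfg)
    brute <- vapply(seq(0, 1200, by = 1), function(r) {
      d <- exp(-r * ser$te)
      cf <- fat_dephasing(the_spectrum, ser$te, 1.5)
      # exhaustive over a (w, f) lattice around the signal scale
      wv <- seq(0, 120, by = 4)
      min(vapply(wv, function(w) {
        min(vapply(wv, function(f) {
          sum((Mod(w + cf * f) * d - s)^2)
        }, numeric(1)))
      }, numeric(1)))
    }, numeric(1))
    expect_lte(fit$residual, min(brute) + 1e-9)
  }
})

test_that("r2star cap clamps and flags the product emulation", {
  ser <- forward_series(90, 10, 600, proto_wip)
  fit <- dixon_magnitude_fit(ser, the_spectrum, proto_wip,
                             fit_config(r2star_cap = 400))
  expect_equal(fit$r2star_hat, 400)
  expect_true(fit$capped)
})

test_that("noise-corrected fit: sigma = 0 limit and inverse-crime recovery", {
  ser <- forward_series(80, 20, 150, proto_wip)
  d <- dixon_magnitude_fit(ser, the_spectrum, proto_wip, resolve = "global")
  nc <- noise_corrected_fit(ser, the_spectrum, proto_wip, sigma = 0)
  expect_equal(nc$r2star_hat, d$r2star_hat, tolerance = 1e-6)
  expect_equal(nc$w_hat, d$w_hat, tolerance = 1e-6)
  # series constructed as the exact Rician expectation of a decaying voxel
  sigma <- 5
  te <- echo_times(proto_wip)
  cf <- fat_dephasing(the_spectrum, te, 1.5)
  for (r2 in c(200, 500)) {
    nu <- noiseless_magnitude(tissue_state(100, 0, r2), cf, te)
    ser <- echo_series(te, rician_mean(nu, sigma))
    fit <- noise_corrected_fit(ser, the_spectrum, proto_wip, sigma)
    expect_equal(fit$w_hat, 100, tolerance = 5e-3)
    expect_equal(fit$r2star_hat, r2, tolerance = r2 * 5e-3)
    expect_lt(fit$f_hat, 1)
  }
})

test_that("swap detection reverses fat-dominant maps and round-trips", {
  pdff_map <- matrix(0.85, 4, 4)
  maps <- list(w = matrix(15, 4, 4), f = matrix(85, 4, 4), pdff = pdff_map)
  mask <- matrix(TRUE, 4, 4)
  out <- detect_and_reverse_swap(maps, mask)
  expect_true(out$swap)
  expect_equal(stats::median(out$maps$pdff[mask]), 0.15)
  expect_equal(out$maps$w, matrix(85, 4, 4))
  low <- detect_and_reverse_swap(list(w = matrix(90, 2, 2),
                                      f = matrix(8, 2, 2),
                                      pdff = matrix(0.08, 2, 2)),
                                 matrix(TRUE, 2, 2))
  expect_false(low$swap)
  expect_error(detect_and_reverse_swap(maps, matrix(FALSE, 4, 4)), "empty")
})

test_that("a swapped patient, globally fitted and reversed, matches the unswapped arm", {
  tiny <- phantom_spec(c(10, 10), 5, c(5.5, 5.5), c(20, 22))
  sp1 <- cohort_spec(n_patients = 1, swap_rate = 1, sigma = 1, seed = 21)
  sp0 <- cohort_spec(n_patients = 1, swap_rate = 0, sigma = 1, seed = 21)
  co1 <- simulate_cohort(sp1, protocols = list(proto_qdx), phantom = tiny)
  co0 <- simulate_cohort(sp0, protocols = list(proto_qdx), phantom = tiny)
  expect_true(co1[[1]]$swap_applied)
  te <- echo_times(proto_qdx)
  liver <- co1[[1]]$labels == "liver"
  fit1 <- fit_map(co1[[1]]$series_by_protocol[[1]], te, "dixon",
                  spectrum = the_spectrum, proto = proto_qdx,
                  resolve = "global", mask = liver)
  fit0 <- fit_map(co0[[1]]$series_by_protocol[[1]], te, "dixon",
                  spectrum = the_spectrum, proto = proto_qdx,
                  resolve = "global", mask = liver)
  rev1 <- detect_and_reverse_swap(fit1, liver)
  expect_true(rev1$swap)
  expect_false(detect_and_reverse_swap(fit0, liver)$swap)
  m1 <- mean(rev1$maps$r2star[liver])
  m0 <- mean(fit0$r2star[liver])
  expect_equal(m1, m0, tolerance = 0.05 * m0)
  expect_lt(stats::median(rev1$maps$pdff[liver]), 0.5)
})

test_that("all three fitters are deterministic functions of their input", {
  ser <- forward_series(70, 12, 220, proto_wip, sigma = 0)
  s <- echo_series(ser$te, ser$magnitude + 0.3 * sin(1:6)) # fixed perturbation
  f1 <- noise_corrected_fit(s, the_spectrum, proto_wip, 2)
  f2 <- noise_corrected_fit(s, the_spectrum, proto_wip, 2)
  expect_identical(f1, f2)
  t1 <- truncation_fit(s, 2)
  t2 <- truncation_fit(s, 2)
  expect_identical(t1, t2)
})
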