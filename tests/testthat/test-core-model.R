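test_that("protocol stores ms at the boundary, seconds inside", {
  p <- protocol("x", initial_te_ms = 1.04, delta_te_ms = 1.17, n_echoes = 6)
  te <- echo_times(p)
  expect_equal(te, (1.04 + (0:5) * 1.17) * 1e-3)
  expect_true(all(diff(te) > 0))
  expect_error(protocol("x", 0, 1, 6), "initial_te")
  expect_error(protocol("x", 1, 1, 2), "n_echoes")
})

test_that("protocol presets reproduce the study echo trains", {
  last_te_ms <- function(p) echo_times(p)[p$n_echoes] * 1e3
  expect_equal(last_te_ms(proto_megre), 16.50)
  expect_equal(last_te_ms(proto_qdx), 14.28)
  expect_equal(last_te_ms(proto_wip), 6.89)
  expect_equal(proto_megre$extras$fat_saturation, "CHESS")
})

test_that("fat spectrum validates and serializes", {
  expect_error(fat_spectrum(numeric(0), numeric(0)), "at least one peak")
  expect_error(fat_spectrum(-3.4, 0.9), "sum to 1")
  sp <- the_spectrum
  expect_equal(sum(sp$amplitude), 1, tolerance = 1e-12)
  tmp <- tempfile(fileext = ".json")
  write_fat_spectrum(sp, tmp)
  sp2 <- read_fat_spectrum(tmp)
  expect_equal(sp2$shift_ppm, sp$shift_ppm)
  expect_equal(sp2$amplitude, sp$amplitude)
})

test_that("fat dephasing: unity at te = 0, periodic, bounded", {
  expect_equal(fat_dephasing(the_spectrum, 0), 1 + 0i)
  single <- fat_spectrum(-3.4, 1)
  period <- 1 / (3.4e-6 * 42.577e6 * 1.5)
  expect_lt(Mod(fat_dephasing(single, period) - 1), 1e-9)
  expect_lt(Mod(fat_dephasing(single, 0.123 + period) -
                fat_dephasing(single, 0.123)), 1e-9)
  expect_lt(Mod(fat_dephasing(single, period / 2) - (-1)), 1e-9)
  te_grid <- seq(0, 20e-3, length.out = 41)
  expect_true(all(Mod(fat_dephasing(the_spectrum, te_grid)) <= 1 + 1e-12))
})

test_that("noiseless magnitude: mono-exponential limit, cancellation, fixture", {
  st <- tissue_state(100, 0, 100)
  expect_equal(noiseless_magnitude(st, 1 + 0i, 10e-3), 100 * exp(-1))
  # opposed-phase cancellation
  expect_equal(noiseless_magnitude(tissue_state(50, 50, 80), -1 + 0i, 5e-3), 0)
  # frozen regression fixture, independently evaluated with numpy
  val <- noiseless_magnitude(tissue_state(80, 20, 150),
                             fat_dephasing(the_spectrum, 1.04e-3, 1.5),
                             1.04e-3)
  expect_equal(val, 74.29728663398505, tolerance = 1e-12)
  # monotone nonincreasing in te at fixed real-positive c
  te <- seq(0, 15e-3, length.out = 30)
  v <- noiseless_magnitude(tissue_state(70, 30, 120), 1 + 0i, te)
  expect_true(all(diff(v) <= 0))
})

test_that("rician mean: closed form matches quadrature and limits", {
  expect_equal(rician_mean(0, 1), sqrt(pi / 2), tolerance = 1e-12)
  expect_identical(rician_mean(7.3, 0), 7.3)
  # frozen quadrature values (scipy, 1e-13 tolerance)
  expect_equal(rician_mean(1, 1), 1.5485724605511457, tolerance = 1e-9)
  expect_equal(rician_mean(2.5, 1.3), 2.870307296675324, tolerance = 1e-9)
  expect_equal(rician_mean(0, 2), 2.5066282746310007, tolerance = 1e-9)
  expect_error(rician_mean(-1, 1), "nu")
  expect_error(rician_mean(1, -1), "sigma")
})

test_that("rician mean: 1e-6 relative agreement with quadrature over snr 0..50", {
  sigma <- 1.7
  snr <- c(0, 0.05, 0.2, 0.5, 1, 2, 3.7, 5, 8, 12, 20, 33, 50)
  for (r in snr) {
    nu <- r * sigma
    expect_equal(rician_mean(nu, sigma), rice_mean_quad(nu, sigma),
                 tolerance = 1e-6)
  }
  # a second sigma scale, since the mean is not scale-free in the test
  for (r in c(0.3, 1.5, 10, 50)) {
    nu <- r * 0.08
    expect_equal(rician_mean(nu, 0.08), rice_mean_quad(nu, 0.08),
                 tolerance = 1e-6)
  }
})

test_that("rician mean: strictly increasing in nu, bounded below", {
  nu <- seq(0, 40, by = 0.25)
  m <- rician_mean(nu, 1.3)
  expect_true(all(diff(m) > 0))
  expect_true(all(m >= pmax(nu, 1.3 * sqrt(pi / 2)) - 1e-12))
  # continuity across the asymptotic switch at nu/sigma = 300
  lo <- rician_mean(299.99 * 2, 2)
  hi <- rician_mean(300.01 * 2, 2)
  expect_equal(hi - lo, 0.04, tolerance = 1e-4) # d(mean)/d(nu) ~ 1
  # extreme SNR stays finite and sane
  expect_equal(rician_mean(2e4, 2), 2e4 + 4 / (2 * 2e4), tolerance = 1e-12)
})

test_that("expected signal composes the pieces", {
  st <- tissue_state(80, 20, 150)
  noiseless <- expected_signal(st, the_spectrum, proto_wip, 0)
  expect_equal(noiseless$te, echo_times(proto_wip))
  expect_equal(length(noiseless$magnitude), proto_wip$n_echoes)
  # constant series for r2star = 0, f = 0
  flat <- expected_signal(tissue_state(50, 0, 0), the_spectrum, proto_wip, 3)
  expect_equal(flat$magnitude, rep(rician_mean(50, 3), 6))
  # Rice-mean lower bound across a parameter grid
  for (r2 in c(0, 60, 300, 900)) {
    for (pf in c(0, 0.1, 0.4)) {
      st <- tissue_state(100 * (1 - pf), 100 * pf, r2)
      noisy <- expected_signal(st, the_spectrum, proto_qdx, 4)
      clean <- expected_signal(st, the_spectrum, proto_qdx, 0)
      expect_true(all(noisy$magnitude >= clean$magnitude - 1e-12))
    }
  }
})

test_that("echo series invariants are enforced", {
  expect_error(echo_series(c(1, 1, 2) * 1e-3, c(1, 1, 1)), "increasing")
  expect_error(echo_series(c(1, 2) * 1e-3, c(1, -1)), "magnitude")
  expect_error(echo_series(c(1, 2) * 1e-3, c(1, 1, 1)), "length")
})
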