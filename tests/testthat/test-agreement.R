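test_that("linear regression matches the normal equations", {
  x <- c(1, 2, 3, 4)
  fit <- linear_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  flat <- linear_regression(x, rep(5, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  set.seed(11)
  xr <- stats::rnorm(40); yr <- 1.7 * xr - 3 + stats::rnorm(40)
  fr <- linear_regression(xr, yr)
  X <- cbind(1, xr)
  beta <- solve(t(X) %*% X, t(X) %*% yr) # normal-equations oracle
  expect_equal(fr$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fr$slope, beta[2], tolerance = 1e-10)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
})

test_that("bland-altman differences, SD and limits of agreement", {
  x <- c(10, 20, 30, 40)
  ba0 <- bland_altman(x, x)
  expect_equal(unlist(ba0[1:4]), c(mean_diff = 0, sd_diff = 0,
                                   loa_low = 0, loa_high = 0))
  ba5 <- bland_altman(x, x + 5)
  expect_equal(ba5$mean_diff, 5)
  expect_equal(ba5$sd_diff, 0)
  set.seed(2)
  y <- x + stats::rnorm(4, 2, 3)
  ba <- bland_altman(x, y)
  d <- y - x
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / 3))
  expect_equal(ba$loa_high, mean(d) + 1.96 * stats::sd(d))
  expect_lte(ba$loa_low, ba$mean_diff)
  expect_lte(ba$mean_diff, ba$loa_high)
})

test_that("Lin's CCC penalizes location shift and matches its moments", {
  x <- c(2, 4, 6, 9, 12)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  shifted <- lin_ccc(x, x + 3)
  r <- stats::cor(x, x + 3)
  expect_lt(shifted$ccc, r)
  set.seed(4)
  y <- 1.2 * x + stats::rnorm(5)
  got <- lin_ccc(x, y)$ccc
  # brute-force n-denominator moment computation
  n <- 5
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  oracle <- 2 * sxy / (sum((x - mean(x))^2) / n + sum((y - mean(y))^2) / n +
                         (mean(x) - mean(y))^2)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(lin_ccc(x, y)$rating,
               if (got < 0.9) "poor" else if (got < 0.95) "moderate"
               else if (got <= 0.99) "substantial" else "almost perfect")
  ci <- lin_ccc(x, y)
  expect_true(ci$ci_low <= ci$ccc && ci$ccc <= ci$ci_high)
})

test_that("contingency construction counts and validates", {
  t1 <- build_contingency("yes", "yes", labels = c("no", "yes"))
  expect_equal(sum(t1), 1)
  expect_equal(t1["yes", "yes"], 1, ignore_attr = TRUE)
  a <- c("a", "b", "c", "a")
  td <- build_contingency(a, a)
  expect_true(all(td[upper.tri(td) | lower.tri(td)] == 0))
  # hand-counted 10-pair fixture
  pa <- c("no", "no", "yes", "yes", "no", "yes", "no", "no", "yes", "no")
  pb <- c("no", "yes", "yes", "no", "no", "yes", "no", "no", "yes", "yes")
  tt <- build_contingency(pa, pb, labels = c("no", "yes"))
  expect_equal(unclass(tt), matrix(c(4L, 1L, 2L, 3L), 2, 2,
               dimnames = list(c("no", "yes"), c("no", "yes"))))
  expect_error(build_contingency(c("a", "b"), "a"), "same length")
  expect_error(contingency_table(matrix(1:6, 2, 3)), "square")
  expect_error(contingency_table(matrix(c(1, -1, 0, 2), 2)), "nonnegative")
})

test_that("overall agreement: published examples and permutation invariance", {
  t100 <- contingency_table(matrix(c(134, 0, 0, 252), 2, byrow = TRUE))
  expect_equal(overall_agreement(t100), 100)
  t9275 <- contingency_table(matrix(c(106, 28, 0, 252), 2, byrow = TRUE))
  expect_equal(round_half_up(overall_agreement(t9275), 2), 92.75)
  d4 <- contingency_table(diag(c(5L, 9L, 2L, 7L)))
  expect_equal(overall_agreement(d4), 100)
  # simultaneous row/column permutation leaves agreement unchanged
  set.seed(6)
  m <- matrix(rpois(16, 5), 4)
  tbl <- contingency_table(m)
  perm <- sample(4)
  tp <- contingency_table(m[perm, perm])
  expect_equal(overall_agreement(tp), overall_agreement(tbl))
})

test_that("Cohen's kappa: published examples, oracle, symmetry, bounds", {
  k1 <- cohens_kappa(contingency_table(matrix(c(106, 28, 0, 252), 2,
                                              byrow = TRUE)))
  expect_equal(round_half_up(k1$kappa, 3), 0.832)
  k2 <- cohens_kappa(contingency_table(matrix(c(106, 34, 0, 246), 2,
                                              byrow = TRUE)))
  expect_equal(round_half_up(k2$kappa, 3), 0.799)
  kp <- cohens_kappa(contingency_table(diag(c(12L, 30L, 4L))))
  expect_equal(kp$kappa, 1)
  expect_equal(kp$se, 0)
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(rpois(9, 8) + 1L, 3)
    tbl <- contingency_table(m)
    got <- cohens_kappa(tbl)
    # direct-formula oracle
    n <- sum(m)
    po <- sum(diag(m)) / n
    pe <- sum(rowSums(m) * colSums(m)) / n^2
    expect_equal(got$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
    expect_equal(cohens_kappa(contingency_table(t(m)))$kappa, got$kappa,
                 tolerance = 1e-12)
    expect_lte(got$kappa, 1)
  }
  # kappa = 1 iff the off-diagonal is empty
  mixed <- contingency_table(matrix(c(10, 1, 0, 10), 2))
  expect_lt(cohens_kappa(mixed)$kappa, 1)
  # degenerate marginals are flagged undefined
  degen <- contingency_table(matrix(c(7, 0, 0, 0), 2))
  expect_true(is.na(cohens_kappa(degen)$kappa))
})

test_that("contingency tables round-trip through CSV", {
  tbl <- paper_table("henninger_hankins", "easl")
  tmp <- tempfile(fileext = ".csv")
  write_contingency(tbl, tmp)
  back <- read_contingency(tmp)
  expect_equal(unclass(back), unclass(tbl))
})
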