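test_that("fit_ols reproduces hand-solved examples", {
  # exact line through (0,1), (1,3), (2,5)
  f <- fit_ols(c(1, 3, 5), cbind(intercept = 1, x = 0:2))
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(f$sigma, 0, tolerance = 1e-10)
  # normal equations by hand for (0,0), (1,1), (2,1): Sxy = 1, Sxx = 2
  g <- fit_ols(c(0, 1, 1), cbind(intercept = 1, x = 0:2))
  expect_equal(unname(g$coefficients), c(1 / 6, 1 / 2), tolerance = 1e-12)
  # intercept-only design returns the sample mean
  h <- fit_ols(c(2, 4, 9), cbind(intercept = rep(1, 3)))
  expect_equal(unname(h$coefficients), 5, tolerance = 1e-12)
})

test_that("fit_ols agrees with a brute-force normal-equations solver", {
  set.seed(101)
  for (case in 1:20) {
    n <- sample(10:60, 1)
    p <- sample(2:4, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- c("intercept", paste0("b", seq_len(p - 1)))
    y <- rnorm(n)
    f <- fit_ols(y, X)
    o <- brute_ols(y, X)
    expect_equal(unname(f$coefficients), unname(o$coefficients),
                 tolerance = 1e-10)
    expect_equal(unname(f$std_errors), unname(o$std_errors),
                 tolerance = 1e-10)
  }
})

test_that("fit_ols errors name the failure mode", {
  X <- cbind(intercept = 1, a = 1:4, twice_a = 2 * (1:4))
  expect_error(fit_ols(rnorm(4), X), "collinear term\\(s\\): (a|twice_a)")
  expect_error(fit_ols(rnorm(2), cbind(1, 1:2, rnorm(2))),
               "insufficient data")
  expect_error(fit_ols(rnorm(3), cbind(1, 1:4)), "length")
})

test_that("first-difference slope equals the within (demeaned) estimator", {
  for (seed in c(3, 17)) {
    pan <- generate_baseline_panel(base3(theta = 0.8, n = 400), seed)
    fd <- concurrent_change_change(pan, 1L, 0L)
    wi <- within_two_wave(pan, 1L, 0L)
    expect_equal(unname(fd$coefficients[c("x", "z")]),
                 unname(wi[c("x", "z")]), tolerance = 1e-10)
  }
})

test_that("concurrent estimates are invariant to per-individual outcome shifts", {
  pan <- generate_baseline_panel(base3(theta = 1, n = 300), 8L)
  shifted <- as.data.frame(pan)
  shift <- rnorm(300, sd = 10)
  shifted$y <- shifted$y + shift[shifted$id]
  f0 <- concurrent_change_change(pan)
  f1 <- concurrent_change_change(shifted)
  expect_equal(f0$coefficients, f1$coefficients, tolerance = 1e-10)
})

test_that("each analysis model fits the printed design", {
  pan <- generate_baseline_panel(base3(theta = 0.5, n = 5000), 21L)
  df <- as.data.frame(pan)
  d <- function(v, w1, w0) v[df$wave == w1] - v[df$wave == w0]
  at <- function(v, w) v[df$wave == w]
  cc <- concurrent_change_change(pan)
  expect_equal(unname(cc$coefficients),
               unname(brute_ols(d(df$y, 1, 0),
                                cbind(1, d(df$x, 1, 0),
                                      d(df$z, 1, 0)))$coefficients),
               tolerance = 1e-10)
  cs <- change_score(pan)
  expect_equal(unname(cs$coefficients),
               unname(brute_ols(d(df$y, 1, 0),
                                cbind(1, at(df$x, 0),
                                      at(df$z, 0)))$coefficients),
               tolerance = 1e-10)
  lc <- lagged_change_change(pan)
  expect_equal(unname(lc$coefficients),
               unname(brute_ols(d(df$y, 2, 1),
                                cbind(1, d(df$x, 1, 0),
                                      d(df$z, 1, 0)))$coefficients),
               tolerance = 1e-10)
  xs <- cross_sectional(pan, 0L)
  expect_equal(unname(xs$coefficients),
               unname(brute_ols(at(df$y, 0),
                                cbind(1, at(df$x, 0),
                                      at(df$z, 0)))$coefficients),
               tolerance = 1e-10)
  expect_true(all(vapply(list(cc, cs, lc, xs),
                         function(f) all(f$std_errors >= 0), logical(1))))
  expect_equal(cc$n_used, 5000L)
})

test_that("estimators reject latent columns and missing waves", {
  pan <- generate_baseline_panel(base3(n = 50), 2L)
  leaky <- cbind(as.data.frame(pan), u = rnorm(150))
  expect_error(concurrent_change_change(leaky), "latent")
  expect_error(concurrent_change_change(pan, 5L, 0L), "wave 5 not found")
  two_wave <- as.data.frame(pan)[as.data.frame(pan)$wave < 2, ]
  expect_error(lagged_change_change(two_wave), "3 waves")
  expect_error(concurrent_change_change(pan, 0L, 1L), "later_wave")
})

test_that("concurrent slope on the DAG's implied moments is exactly beta", {
  sem <- build_fig1_sem(dgp_params(beta = 1.7, theta = 0.9))
  co <- regression_from_covariance(
    sem, sem_contrast("dY1", "Y1", "Y0"),
    list(sem_contrast("dX1", "X1", "X0"), sem_contrast("dZ1", "Z1", "Z0")))
  expect_equal(unname(co[["dX1"]]), 1.7, tolerance = 1e-12)
})
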