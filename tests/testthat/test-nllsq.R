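test_that("noiseless data is a zero-residual fixed point and init perturbations wash out", {
  d <- make_clean_dataset(kd = 5000, u = 800, b = 780, seed = 1)
  f0 <- fit_nllsq(d, init = c(kd = 5000, u = 800, b = 780))
  expect_true(f0$converged)
  expect_lt(f0$rss, 1e-16 * sum(d$response^2))
  expect_equal(f0$estimates[["kd_nM"]], 5000, tolerance = 1e-8)

  f2 <- fit_nllsq(d, init = c(kd = 10000, u = 1600, b = 390))
  expect_equal(f2$estimates[["kd_nM"]], 5000, tolerance = 1e-6)
  expect_equal(f2$estimates[["u"]], 800, tolerance = 1e-6)
  expect_equal(f2$estimates[["b"]], 780, tolerance = 1e-6)

  # default (data-driven) init also recovers the truth
  f3 <- fit_nllsq(d)
  expect_equal(f3$estimates[["kd_nM"]], 5000, tolerance = 1e-6)
  expect_lte(f3$rss, sum((d$response - predict(f3, d$concentration_nM))^2) + 1e-12)
})

test_that("too-small datasets are rejected", {
  d <- titration_data(1, c(100, 50, 25), c(1, 2, 3))
  expect_error(fit_nllsq(d), "more than 3 points")
})

test_that("profile machinery reproduces the quadratic closed form", {
  # RSS(p) = rss0 + a (p - p_hat)^2 crosses rss0 * (1 + F/(N-P)) at
  # p_hat +/- sqrt(rss0 * F / (a (N - P)))
  rss0 <- 2.5
  a <- 0.8
  p_hat <- 3
  n <- 48
  P <- 3
  Fq <- qf(0.95, 1, n - P)
  thr <- rss0 * (1 + Fq / (n - P))
  half <- sqrt(rss0 * Fq / (a * (n - P)))
  pi_ <- mstfit:::profile_interval(function(p) rss0 + a * (p - p_hat)^2,
                                   p_hat, thr, window = c(-100, 100))
  expect_false(pi_$open_lower || pi_$open_upper)
  expect_equal(pi_$lower, p_hat - half, tolerance = 1e-7)
  expect_equal(pi_$upper, p_hat + half, tolerance = 1e-7)
})

test_that("confidence endpoints sit on the F threshold and match a brute-force grid profile", {
  d <- generate_dataset(test_case_params(5000, 780, 800, repeats = 1,
                                         outlier_fraction = 0, seed = 9))
  fit <- fit_nllsq(d)
  ci <- confint(fit, parm = "kd_nM")
  thr <- fit$rss * (1 + qf(0.95, 1, fit$n_points - 3) / (fit$n_points - 3))
  prof <- mstfit:::profile_rss_fun(fit, "kd_nM")
  for (endpt in ci["kd_nM", ]) {
    expect_lt(abs(prof(endpt) - thr), 1e-6 * fit$rss)
  }
  grid <- 10^seq(log10(ci[1, "lower"]) - 0.3, log10(ci[1, "upper"]) + 0.3,
                 length.out = 1000)
  gci <- oracle_grid_ci_kd(fit$data, fit$cfl, grid, thr)
  step <- diff(log10(grid[1:2]))
  expect_lt(abs(log10(ci[1, "lower"]) - log10(gci[1])), 1.5 * step)
  expect_lt(abs(log10(ci[1, "upper"]) - log10(gci[2])), 1.5 * step)
  # interval brackets the estimate
  expect_lt(ci[1, "lower"], fit$estimates[["kd_nM"]])
  expect_gt(ci[1, "upper"], fit$estimates[["kd_nM"]])
})

test_that("near-zero noise collapses the confidence interval onto the estimate", {
  d <- make_clean_dataset(kd = 2000, u = 800, b = 780, seed = 2)
  fit <- fit_nllsq(d)
  ci <- confint(fit)
  expect_lt(ci["kd_nM", "upper"] - ci["kd_nM", "lower"], 1e-6 * 2000)
  expect_lt(ci["u", "upper"] - ci["u", "lower"], 1e-6 * 800)
})

test_that("an uninformative profile is reported open-ended at the window edge", {
  # no binding signal at all: refitting the plateaus absorbs any fixed KD,
  # so the profile is flat and never reaches the threshold on either side
  d <- make_clean_dataset(kd = 500, u = 800, b = 800, noise_sd = 1,
                          seed = 23)
  fit <- fit_nllsq(d)
  ci <- confint(fit, parm = "kd_nM")
  open <- attr(ci, "open")
  expect_true(all(open["kd_nM", ]))
  expect_equal(unname(ci["kd_nM", ]), c(1e-3, 1e6))
})

test_that("on clean low-noise data both estimators agree within their intervals", {
  d <- generate_dataset(test_case_params(10800, 926, 894, noise_sd = 0.5,
                                         repeats = 3, outlier_fraction = 0,
                                         seed = 5))
  nf <- fit_nllsq(d)
  bf <- fit_bayes(d, mcmc = quick_mcmc(seed = 5, n = 2500))
  kd_b <- median(bf$draws$kd_nM)
  h <- hdi(bf$draws$kd_nM)
  ci <- confint(nf, parm = "kd_nM")
  expect_gt(nf$estimates[["kd_nM"]], h[["lower"]])
  expect_lt(nf$estimates[["kd_nM"]], h[["upper"]])
  expect_gt(kd_b, ci[1, "lower"])
  expect_lt(kd_b, ci[1, "upper"])
})
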