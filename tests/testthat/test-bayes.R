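test_that("Student-t log-likelihood matches closed forms and the density normalizes", {
  d1 <- titration_data(1, 100, 5)
  th <- list(kd = 100, u = 5, b = 5, cfl = 50, nu = 1, lambda = 1)
  # at the peak of a standard Cauchy (nu = 1, lambda = 1) the density is 1/pi
  expect_equal(log_likelihood(d1, th), log(1 / pi))

  # density integrates to 1 over the observation for assorted (nu, lambda)
  for (par in list(c(1, 1), c(3, 0.2), c(7, 5), c(30, 0.01))) {
    dens <- function(y) {
      vapply(y, function(yy) {
        exp(log_likelihood(titration_data(1, 100, yy),
                           list(kd = 100, u = 2, b = 9, cfl = 50,
                                nu = par[1], lambda = par[2])))
      }, 1)
    }
    expect_equal(integrate(dens, -Inf, Inf, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  }

  # at nu = 30 the t density has converged to N(mu, sigma): within 1% of
  # the normal density near the centre and within the analytic t-vs-normal
  # gap (about 5% in density at 2 sigma) across the central region
  sigma <- 2
  y <- seq(-2 * sigma, 2 * sigma, length.out = 41) + 7
  dens_t <- vapply(y, function(yy) {
    exp(log_likelihood(titration_data(1, 100, yy),
                       list(kd = 100, u = 7, b = 7, cfl = 50, nu = 30,
                            lambda = 1 / sigma^2)))
  }, 1)
  dens_n <- dnorm(y, 7, sigma)
  rel <- abs(dens_t - dens_n) / dens_n
  expect_true(all(rel[abs(y - 7) <= 0.3 * sigma] < 0.01))
  expect_true(all(rel < 0.06))

  # sums over points, and respects prior support when priors are supplied
  d2 <- titration_data(1, c(100, 100), c(5, 5))
  expect_equal(log_likelihood(d2, th), 2 * log(1 / pi))
  pr <- prior_config(cfl_mu = 50)
  th_bad <- th
  th_bad$kd <- 1e7
  expect_identical(log_likelihood(d2, th_bad, pr), -Inf)
  expect_gt(log_likelihood(d2, th, pr), -Inf)
})

test_that("hdi agrees with the exhaustive window-scan oracle", {
  expect_equal(unname(hdi(rep(3.5, 10))), c(3.5, 3.5))
  # sorted 1..100 at 95%: any 95-run has width 94; first window wins ties
  expect_equal(unname(hdi(1:100)), c(1, 95))
  set.seed(42)
  for (i in 1:25) {
    x <- switch(1 + i %% 4,
                rnorm(200), rexp(151), 10^rnorm(97), c(rnorm(80), rnorm(20, 9)))
    for (mass in c(0.5, 0.9, 0.95)) {
      expect_equal(unname(hdi(x, mass)), oracle_hdi(x, mass))
    }
  }
  set.seed(1)
  h <- hdi(rnorm(1e5))
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.05 / 1.96)
  expect_error(hdi(1))
  expect_error(hdi(1:10, mass = 1))
})

test_that("a noiseless dataset is recovered within 1% and draws respect the priors", {
  d <- make_clean_dataset(kd = 5000, u = 800, b = 780, seed = 2)
  fit <- fit_bayes(d, mcmc = quick_mcmc(seed = 2))
  est <- coef(fit)
  expect_equal(est[["kd_nM"]], 5000, tolerance = 0.01)
  expect_equal(est[["u"]], 800, tolerance = 0.01)
  expect_equal(est[["b"]], 780, tolerance = 0.01)

  pr <- fit$priors
  dr <- fit$draws
  expect_true(all(dr$kd_nM >= pr$kd_bounds[1] & dr$kd_nM <= pr$kd_bounds[2]))
  expect_true(all(dr$u >= pr$u_bounds[1] & dr$u <= pr$u_bounds[2]))
  expect_true(all(dr$b >= pr$b_bounds[1] & dr$b <= pr$b_bounds[2]))
  expect_true(all(dr$cfl_nM >= pr$cfl_bounds[1] &
                    dr$cfl_nM <= pr$cfl_bounds[2]))
  expect_true(all(dr$nu %in% pr$nu_bounds[1]:pr$nu_bounds[2]))
  expect_true(all(dr$lambda >= pr$lambda_bounds[1] &
                    dr$lambda <= pr$lambda_bounds[2]))
})

test_that("sampling is reproducible from the seed", {
  d <- generate_dataset(test_case_params(5000, 780, 800, seed = 6))
  f1 <- fit_bayes(d, mcmc = mcmc_config(n_iterations = 300, n_tune = 200,
                                        seed = 9))
  f2 <- fit_bayes(d, mcmc = mcmc_config(n_iterations = 300, n_tune = 200,
                                        seed = 9))
  expect_identical(f1$draws, f2$draws)
})

test_that("a no-signal dataset leaves KD prior-dominated", {
  d <- make_clean_dataset(kd = 5000, u = 800, b = 800, noise_sd = 1,
                          seed = 2)
  fit <- fit_bayes(d, mcmc = quick_mcmc(seed = 2, n = 3000))
  h <- hdi(fit$draws$kd_nM)
  # the HDI stays about as wide as the prior itself: no information on KD
  expect_gt(h[["upper"]] - h[["lower"]], 0.5 * diff(fit$priors$kd_bounds))
  expect_gt(h[["upper"]] / 5000, 100)  # >= 2 decades above the truth scale
})

test_that("posterior curve swarm evaluates joint draws on the requested grid", {
  d <- make_clean_dataset(kd = 2000, u = 800, b = 780, noise_sd = 0.2,
                          repeats = 3, seed = 12)
  fit <- fit_bayes(d, mcmc = quick_mcmc(seed = 12))
  grid <- c(0, 10^seq(0, 6, length.out = 25))
  expect_identical(dim(posterior_curve_swarm(fit, 0, grid)), c(0L, 26L))
  set.seed(1)
  sw <- posterior_curve_swarm(fit, 10, grid)
  idx <- attr(sw, "draw")
  # each curve at c = 0 is that draw's unbound plateau
  expect_equal(sw[, 1], fit$draws$u[idx])
  # a tight posterior collapses onto a single curve
  d_mat <- as.matrix(dist(sw, method = "maximum"))
  expect_lt(max(d_mat), 3 * 0.2)
  expect_error(posterior_curve_swarm(fit, nrow(fit$draws) + 1, grid))
})

test_that("affinity comparison is symmetric, decisive when supports separate, and matches a resampling oracle", {
  set.seed(77)
  a <- 10^rnorm(4000, 3, 0.2)
  expect_equal(compare_affinities(a, a)$prob_a_tighter, 0.5,
               tolerance = 0.05)
  cmp <- compare_affinities(runif(1000, 1, 2), runif(1500, 10, 20))
  expect_identical(cmp$prob_a_tighter, 1)
  expect_identical(cmp$n_pairs, 1000L)

  # posteriors shaped like the experimental micromolar contrast:
  # A ~ 1.6 uM (HDI 0.72-3.0), B ~ 80.7 uM (HDI 12.2-398)
  ka <- rlnorm(5000, log(1.6e3), (log(3.0) - log(0.72)) / (2 * 1.96))
  kb <- rlnorm(5000, log(80.7e3), (log(398.2) - log(12.2)) / (2 * 1.96))
  expect_gt(compare_affinities(ka, kb)$prob_a_tighter, 0.95)
})

test_that("credible intervals narrow as replicate series accumulate", {
  # a single random dataset can buck the trend, so compare the median HDI
  # width over a handful of generation seeds per replicate level
  width <- function(r, s) {
    d <- generate_dataset(test_case_params(5000, 780, 800, repeats = r,
                                           seed = s))
    fit <- fit_bayes(d, mcmc = quick_mcmc(seed = s, n = 3000))
    diff(hdi(fit$draws$kd_nM))
  }
  seeds <- 101:105
  med <- vapply(c(1, 3, 10), function(r) {
    median(vapply(seeds, function(s) width(r, s), 1))
  }, 1)
  expect_true(all(diff(med) < 0))
})

test_that("responses outside the prior window are rescaled and mapped back", {
  d <- make_clean_dataset(kd = 2000, u = 80000, b = 78000, noise_sd = 20,
                          seed = 3)
  fit <- fit_bayes(d, mcmc = quick_mcmc(seed = 3))
  expect_false(is.null(fit$rescale))
  expect_equal(coef(fit)[["u"]], 80000, tolerance = 0.01)
  expect_equal(coef(fit)[["b"]], 78000, tolerance = 0.01)
  expect_equal(coef(fit)[["kd_nM"]], 2000, tolerance = 0.05)
})

test_that("draw export and YAML summaries round-trip", {
  d <- make_clean_dataset(kd = 1000, u = 800, b = 780, noise_sd = 0.5,
                          seed = 14)
  fit <- fit_bayes(d, mcmc = quick_mcmc(seed = 14, n = 500))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, f1)
  back <- read.csv(f1)
  expect_equal(back$kd_nM, fit$draws$kd_nM, tolerance = 1e-6)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_fit_yaml(fit, f2)
  y <- yaml::read_yaml(f2)
  expect_equal(y$parameters$kd_nM$median, median(fit$draws$kd_nM),
               tolerance = 1e-6)
  expect_identical(y$method, "robust_bayes")
})
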