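# Independent oracles used across the suite. Each deliberately avoids the
# implementation path it checks.

# Bound fraction via bisection on the equilibrium polynomial:
# complex x solves x * KD = (cfl - x)(c - x), 0 <= x <= min(c, cfl).
oracle_bound_fraction <- function(c, kd, cfl, tol = 1e-14) {
  if (c == 0) return(0)
  h <- function(x) (cfl - x) * (c - x) - x * kd
  lo <- 0
  hi <- min(c, cfl)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  ((lo + hi) / 2) / cfl
}

# Narrowest 95% window by explicit exhaustive scan over sorted samples.
oracle_hdi <- function(x, mass = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  k <- min(n, ceiling(mass * n))
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1L)) {
    if (xs[i + k - 1L] - xs[i] < best[2] - best[1]) {
      best <- c(xs[i], xs[i + k - 1L])
    }
  }
  best
}

# Brute-force grid profile of the KD confidence bound: re-minimize (U, B)
# on a fixed KD grid (linear model at fixed KD) and take the outermost grid
# points whose RSS stays below the threshold.
oracle_grid_ci_kd <- function(dataset, cfl, grid, threshold) {
  rss_at <- vapply(grid, function(kd) {
    s <- cfl + dataset$concentration_nM + kd
    fb <- 2 * dataset$concentration_nM /
      (s + sqrt(s^2 - 4 * cfl * dataset$concentration_nM))
    r <- lm.fit(cbind(1 - fb, fb), dataset$response)
    sum(r$residuals^2)
  }, 1)
  inside <- which(rss_at < threshold)
  c(grid[min(inside)], grid[max(inside)])
}

# Small clean dataset generator for fitter tests.
make_clean_dataset <- function(kd = 5000, u = 800, b = 780, cfl = 50,
                               noise_sd = 0, repeats = 1, seed = 1) {
  generate_dataset(test_case_params(
    kd_true = kd, b_true = b, u_true = u, noise_sd = noise_sd,
    pipette_sd_ul = 0, repeats = repeats, cfl_true = cfl,
    outlier_fraction = 0, seed = seed))
}

# Reduced-effort sampler settings for unit tests (study-condition settings
# are exercised in the acceptance suite).
quick_mcmc <- function(seed = 1, n = 1500) {
  mcmc_config(n_iterations = n, n_tune = 500, seed = seed)
}
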