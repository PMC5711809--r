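#' Prior configuration for the robust Bayesian binding model
#'
#' The model places bounded, deliberately weak priors on every parameter:
#' uniform priors on KD (nM), on the two response plateaus U and B, on the
#' Student-t precision-like scale lambda, and a discrete uniform prior on the
#' integer degrees of freedom nu in \[1, 30\]. The labelled-partner
#' concentration c_fl gets a truncated normal prior centred on its nominal
#' (pipetted) value with precision `cfl_tau`; the default `cfl_tau =
#' 10 * cfl_mu` ties the prior width to the nominal concentration and is
#' deliberately tight -- c_fl is nearly known, and the prior mainly absorbs
#' small labelling/loading errors. Override `cfl_tau` for a looser belief.
#'
#' @param cfl_mu Nominal labelled-partner concentration (nM).
#' @param cfl_tau Precision (1/variance, nM^-2) of the c_fl prior.
#'   Default `10 * cfl_mu`.
#' @param kd_bounds,u_bounds,b_bounds,cfl_bounds,lambda_bounds Numeric
#'   `c(lower, upper)` prior supports. KD and c_fl bounds are in nM; U, B in
#'   response units; lambda in 1/response^2.
#' @param nu_bounds Integer bounds of the discrete uniform prior on the
#'   Student-t degrees of freedom.
#' @param kd_log10 If `TRUE`, sample log10(KD) uniformly between the log10
#'   bounds instead of KD itself (scale-free alternative; off by default to
#'   keep the flat-KD prior of the reference model).
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(cfl_mu, cfl_tau = 10 * cfl_mu,
                         kd_bounds = c(1, 1e6),
                         u_bounds = c(0, 1000),
                         b_bounds = c(0, 1000),
                         cfl_bounds = c(0, 1e5),
                         nu_bounds = c(1L, 30L),
                         lambda_bounds = c(0, 100),
                         kd_log10 = FALSE) {
  chk <- function(b, nm) {
    if (!(is.numeric(b) && length(b) == 2L && all(is.finite(b)) &&
          b[1] < b[2])) {
      stop("`", nm, "` must be c(lower, upper) with lower < upper")
    }
  }
  chk(kd_bounds, "kd_bounds"); chk(u_bounds, "u_bounds")
  chk(b_bounds, "b_bounds"); chk(cfl_bounds, "cfl_bounds")
  chk(nu_bounds, "nu_bounds"); chk(lambda_bounds, "lambda_bounds")
  stopifnot(is.numeric(cfl_mu), length(cfl_mu) == 1L, cfl_mu > 0,
            is.numeric(cfl_tau), length(cfl_tau) == 1L, cfl_tau > 0,
            all(nu_bounds == floor(nu_bounds)), nu_bounds[1] >= 1)
  structure(list(kd_bounds = kd_bounds, u_bounds = u_bounds,
                 b_bounds = b_bounds, cfl_mu = cfl_mu, cfl_tau = cfl_tau,
                 cfl_bounds = cfl_bounds,
                 nu_bounds = as.integer(nu_bounds),
                 lambda_bounds = lambda_bounds,
                 kd_log10 = isTRUE(kd_log10)),
            class = "prior_config")
}

#' MCMC sampler settings
#'
#' @param n_iterations Posterior draws kept per chain (default 5000).
#' @param n_tune Warm-up iterations discarded before sampling (adaptation
#'   plus burn-in; default 1000).
#' @param n_chains Number of chains (default 1; use >= 2 to obtain the
#'   split-chain convergence diagnostic).
#' @param seed Integer seed; chain k uses `seed + k - 1`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 5000, n_tune = 1000, n_chains = 1,
                        seed = 1L) {
  stopifnot(n_iterations >= 1, n_tune >= 0, n_chains >= 1,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(n_iterations = as.integer(n_iterations),
                 n_tune = as.integer(n_tune),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# Student-t log-density in the (mu, nu, lambda) parameterization:
# lambda is precision-like, so the density is
#   G((nu+1)/2)/G(nu/2) * sqrt(lambda/(pi nu)) * [1 + lambda (y-mu)^2/nu]^-((nu+1)/2)
st_logpdf <- function(y, mu, nu, lambda) {
  lgamma((nu + 1) / 2) - lgamma(nu / 2) + 0.5 * log(lambda / (pi * nu)) -
    (nu + 1) / 2 * log1p(lambda * (y - mu)^2 / nu)
}

#' Log-likelihood of the robust binding model
#'
#' Sum over all dataset points of the Student-t log-density with location
#' given by the mass-action binding curve at the point's concentration,
#' degrees of freedom `nu` and precision-like scale `lambda`. The heavy t
#' tails are what makes the fit robust: an outlying point far from the curve
#' costs only logarithmically, not quadratically, so it cannot drag the
#' curve the way it does under a normal (least-squares) likelihood.
#'
#' @param dataset A [titration_data()] frame.
#' @param theta Named list or vector with elements `kd`, `u`, `b`, `cfl`
#'   (nM / response units), `nu` (integer >= 1) and `lambda` (> 0).
#' @param priors Optional [prior_config()]; when given, a `theta` outside
#'   the prior support returns `-Inf`.
#' @return A single log-probability.
#' @export
log_likelihood <- function(dataset, theta, priors = NULL) {
  d <- validate_titration(dataset)
  th <- as.list(theta)
  need <- c("kd", "u", "b", "cfl", "nu", "lambda")
  miss <- setdiff(need, names(th))
  if (length(miss)) stop("theta lacks: ", paste(miss, collapse = ", "))
  if (!is.null(priors)) {
    stopifnot(inherits(priors, "prior_config"))
    inb <- function(x, b) x >= b[1] && x <= b[2]
    if (!(inb(th$kd, priors$kd_bounds) && inb(th$u, priors$u_bounds) &&
          inb(th$b, priors$b_bounds) && inb(th$cfl, priors$cfl_bounds) &&
          inb(th$nu, priors$nu_bounds) && th$nu == floor(th$nu) &&
          inb(th$lambda, priors$lambda_bounds))) {
      return(-Inf)
    }
  }
  stopifnot(th$kd > 0, th$cfl > 0, th$nu >= 1, th$lambda > 0)
  mu <- mass_action_response(d$concentration_nM, kd = th$kd, u = th$u,
                             b = th$b, cfl = th$cfl)
  sum(st_logpdf(d$response, mu, th$nu, th$lambda))
}

# JAGS source for the model. KD is either uniform on its natural scale or
# (kd_log10 = TRUE) uniform on log10 scale. nu is a shifted categorical.
jags_model_string <- function(kd_log10) {
  kd_prior <- if (kd_log10) {
    "  lkd ~ dunif(lkd_lo, lkd_hi)\n  KD <- pow(10, lkd)"
  } else {
    "  KD ~ dunif(kd_lo, kd_hi)"
  }
  paste0("model {\n",
    "  for (i in 1:N) {\n",
    "    mu[i] <- U + (B - U) * (cfl + c[i] + KD -\n",
    "      sqrt((cfl + c[i] + KD)^2 - 4 * cfl * c[i])) / (2 * cfl)\n",
    "    D[i] ~ dt(mu[i], lambda, nu)\n",
    "  }\n",
    kd_prior, "\n",
    "  U ~ dunif(u_lo, u_hi)\n",
    "  B ~ dunif(b_lo, b_hi)\n",
    "  cfl ~ dnorm(cfl_mu, cfl_tau) T(cfl_lo, cfl_hi)\n",
    "  nucat ~ dcat(pnu[])\n",
    "  nu <- nu_lo - 1 + nucat\n",
    "  lambda ~ dunif(lam_lo, lam_hi)\n",
    "}\n")
}

# Data-driven starting values shared by both fitters: plateaus from the
# extreme-concentration responses, KD from the geometric mid of the range.
default_init <- function(d) {
  ord <- order(d$concentration_nM)
  lo3 <- utils::head(ord, 3L)
  hi3 <- utils::tail(ord, 3L)
  c(kd = sqrt(min(d$concentration_nM) * max(d$concentration_nM)),
    u = mean(d$response[lo3]), b = mean(d$response[hi3]))
}

#' Fit the robust Bayesian binding model by MCMC
#'
#' Samples the joint posterior of `(KD, U, B, c_fl, nu, lambda)` under the
#' bounded priors of [prior_config()] and the Student-t likelihood of
#' [log_likelihood()], with the mass-action curve as the location. Sampling
#' is delegated to JAGS (adaptive Metropolis/slice-within-Gibbs for the
#' continuous parameters, categorical Gibbs for the integer degrees of
#' freedom), seeded per chain for reproducibility.
#'
#' When responses fall outside the prior response window, they are affinely
#' mapped into it before sampling and all affected draws (U, B, lambda) are
#' mapped back afterwards, so the returned posterior is always on the data's
#' own scale; the recorded map is stored in the fit.
#'
#' @param dataset A [titration_data()] frame (non-empty).
#' @param priors A [prior_config()]. Default: nominal c_fl of 50 nM, or the
#'   dataset's ground-truth c_fl when generated synthetically.
#' @param mcmc An [mcmc_config()].
#' @return An object of class `mst_bayes` with components `draws` (data
#'   frame of posterior draws: `kd_nM`, `u`, `b`, `cfl_nM`, `nu`, `lambda`,
#'   `chain`), `data`, `priors`, `mcmc`, `rescale` and `diagnostics`
#'   (per-parameter effective sample size and, with >= 2 chains, split-chain
#'   R-hat; R-hat > 1.05 raises a warning, not an error).
#' @examples
#' \donttest{
#' d <- generate_dataset(test_case_params(5000, 780, 800, seed = 1))
#' fit <- fit_bayes(d, mcmc = mcmc_config(n_iterations = 1000))
#' summary(fit)
#' }
#' @export
fit_bayes <- function(dataset, priors = NULL, mcmc = mcmc_config()) {
  d <- validate_titration(dataset)
  stopifnot(inherits(mcmc, "mcmc_config"))
  if (is.null(priors)) {
    gt <- attr(dataset, "ground_truth")
    cfl0 <- if (!is.null(gt$cfl_true)) gt$cfl_true else 50
    priors <- prior_config(cfl_mu = cfl0)
  }
  stopifnot(inherits(priors, "prior_config"))

  # Affine rescale into the prior response window if needed
  y <- d$response
  resc <- NULL
  win <- range(priors$u_bounds, priors$b_bounds)
  if (min(y) < win[1] || max(y) > win[2]) {
    span <- diff(range(y))
    if (span == 0) span <- 1
    a <- 0.8 * diff(win) / span
    b0 <- win[1] + 0.1 * diff(win) - a * min(y)
    y <- a * y + b0
    resc <- list(a = a, b = b0)
  }

  init0 <- default_init(data.frame(concentration_nM = d$concentration_nM,
                                   response = y))
  clamp <- function(x, b) min(max(x, b[1] + 1e-9 * diff(b)),
                              b[2] - 1e-9 * diff(b))
  r0 <- y - mass_action_response(d$concentration_nM,
                                 kd = clamp(init0[["kd"]], priors$kd_bounds),
                                 u = init0[["u"]], b = init0[["b"]],
                                 cfl = priors$cfl_mu)
  lam0 <- clamp(1 / max(stats::var(r0), 1e-6), priors$lambda_bounds)
  nu_lo <- priors$nu_bounds[1]; nu_hi <- priors$nu_bounds[2]
  n_nu <- nu_hi - nu_lo + 1L

  jd <- list(D = y, c = d$concentration_nM, N = nrow(d),
             u_lo = priors$u_bounds[1], u_hi = priors$u_bounds[2],
             b_lo = priors$b_bounds[1], b_hi = priors$b_bounds[2],
             cfl_mu = priors$cfl_mu, cfl_tau = priors$cfl_tau,
             cfl_lo = priors$cfl_bounds[1], cfl_hi = priors$cfl_bounds[2],
             pnu = rep(1 / n_nu, n_nu), nu_lo = nu_lo,
             lam_lo = priors$lambda_bounds[1],
             lam_hi = priors$lambda_bounds[2])
  if (priors$kd_log10) {
    lb <- log10(pmax(priors$kd_bounds, .Machine$double.xmin))
    jd$lkd_lo <- lb[1]; jd$lkd_hi <- lb[2]
  } else {
    jd$kd_lo <- priors$kd_bounds[1]; jd$kd_hi <- priors$kd_bounds[2]
  }

  inits <- lapply(seq_len(mcmc$n_chains), function(k) {
    ini <- list(U = clamp(init0[["u"]], priors$u_bounds),
                B = clamp(init0[["b"]], priors$b_bounds),
                cfl = clamp(priors$cfl_mu, priors$cfl_bounds),
                nucat = min(10L, n_nu),
                lambda = lam0,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = mcmc$seed + k - 1L)
    if (priors$kd_log10) {
      ini$lkd <- log10(clamp(init0[["kd"]], priors$kd_bounds))
    } else {
      ini$KD <- clamp(init0[["kd"]], priors$kd_bounds)
    }
    ini
  })

  model <- rjags::jags.model(textConnection(jags_model_string(priors$kd_log10)),
                             data = jd, inits = inits,
                             n.chains = mcmc$n_chains,
                             n.adapt = max(mcmc$n_tune, 100L), quiet = TRUE)
  samp <- rjags::coda.samples(model,
                              c("KD", "U", "B", "cfl", "nu", "lambda"),
                              n.iter = mcmc$n_iterations,
                              progress.bar = "none")

  ess <- tryCatch(coda::effectiveSize(samp), error = function(e) NULL)
  mats <- lapply(samp, as.matrix)
  draws <- do.call(rbind, mats)
  chain <- rep(seq_along(mats), vapply(mats, nrow, 1L))
  out <- data.frame(kd_nM = draws[, "KD"], u = draws[, "U"],
                    b = draws[, "B"], cfl_nM = draws[, "cfl"],
                    nu = as.integer(draws[, "nu"]),
                    lambda = draws[, "lambda"], chain = chain)
  if (!is.null(resc)) {
    out$u <- (out$u - resc$b) / resc$a
    out$b <- (out$b - resc$b) / resc$a
    out$lambda <- out$lambda * resc$a^2
  }

  diag <- data.frame(parameter = c("kd_nM", "u", "b", "cfl_nM", "nu",
                                   "lambda"))
  key <- c(kd_nM = "KD", u = "U", b = "B", cfl_nM = "cfl", nu = "nu",
           lambda = "lambda")
  diag$ess <- if (is.null(ess)) NA_real_ else unname(ess[key[diag$parameter]])
  diag$rhat <- vapply(key[diag$parameter], function(p) {
    split_rhat(lapply(mats, function(m) m[, p]))
  }, numeric(1))
  if (mcmc$n_chains >= 2 && any(diag$rhat > 1.05, na.rm = TRUE)) {
    warning("split-chain R-hat > 1.05 for: ",
            paste(diag$parameter[which(diag$rhat > 1.05)], collapse = ", "),
            "; consider more iterations or chains")
  }

  structure(list(draws = out, data = d, priors = priors, mcmc = mcmc,
                 rescale = resc, diagnostics = diag,
                 call = match.call()),
            class = "mst_bayes")
}

# Split-chain potential scale reduction factor (rank-free classic form):
# each chain is halved, then the usual between/within variance ratio.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    if (n < 2L) return(NULL)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  if (length(halves) < 2L) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  m <- length(halves)
  means <- vapply(halves, mean, 1)
  vars <- vapply(halves, stats::var, 1)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Highest density interval of a sample
#'
#' The narrowest contiguous interval containing at least `mass` of the
#' sample: among all windows of `ceiling(mass * n)` consecutive order
#' statistics, the shortest one (ties broken to the first, i.e. lowest,
#' window).
#'
#' @param x Numeric sample, length >= 2.
#' @param mass Probability mass, in (0, 1). Default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1e4))
#' @export
hdi <- function(x, mass = 0.95) {
  stopifnot(is.numeric(x), all(is.finite(x)),
            is.numeric(mass), length(mass) == 1L, mass > 0, mass < 1)
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples for an HDI")
  xs <- sort(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = xs[1L], upper = xs[n]))
  width <- xs[k:n] - xs[1:(n - k + 1L)]
  i <- which.min(width)  # which.min takes the first minimum: lowest window
  c(lower = xs[i], upper = xs[i + k - 1L])
}

#' Binding curves from random posterior draws
#'
#' Evaluates the mass-action curve on a concentration grid for `n_curves`
#' parameter sets drawn jointly (whole rows, never mix-and-matched
#' marginals) from the posterior. Plotted together these form the "swarm"
#' that visualizes curve-level posterior uncertainty.
#'
#' @param fit An [fit_bayes()] result, or a data frame of draws with columns
#'   `kd_nM`, `u`, `b`, `cfl_nM`.
#' @param n_curves Number of curves (0 allowed; must not exceed the number
#'   of draws).
#' @param c_grid Concentrations (nM, >= 0) at which to evaluate.
#' @return A numeric matrix, `n_curves` rows x `length(c_grid)` columns,
#'   with the selected draw indices as the `draw` attribute.
#' @export
posterior_curve_swarm <- function(fit, n_curves = 10, c_grid) {
  draws <- if (inherits(fit, "mst_bayes")) fit$draws else fit
  stopifnot(is.data.frame(draws),
            all(c("kd_nM", "u", "b", "cfl_nM") %in% names(draws)),
            n_curves >= 0, n_curves == floor(n_curves),
            is.numeric(c_grid), all(is.finite(c_grid)), all(c_grid >= 0))
  if (n_curves > nrow(draws)) {
    stop("n_curves (", n_curves, ") exceeds the number of draws (",
         nrow(draws), ")")
  }
  idx <- if (n_curves > 0) sample.int(nrow(draws), n_curves) else integer()
  curves <- matrix(NA_real_, n_curves, length(c_grid))
  for (j in seq_along(idx)) {
    r <- draws[idx[j], ]
    curves[j, ] <- mass_action_response(c_grid, kd = r$kd_nM, u = r$u,
                                        b = r$b, cfl = r$cfl_nM)
  }
  attr(curves, "draw") <- idx
  curves
}

#' Posterior A/B comparison of two binding affinities
#'
#' Pairs equally thinned draws from two KD posteriors and reports the
#' posterior probability that interaction A binds tighter (KD_A < KD_B),
#' together with the posterior sample of `log10(KD_A / KD_B)`. Because both
#' inputs are full posteriors, the comparison propagates the complete
#' uncertainty of both fits -- the Bayesian analogue of an A/B test.
#'
#' @param a,b [fit_bayes()] results, or numeric vectors of posterior KD
#'   draws (any common unit).
#' @return An object of class `affinity_comparison`: list with
#'   `prob_a_tighter`, `log10_ratio` (posterior sample) and its `hdi`.
#' @export
compare_affinities <- function(a, b) {
  ka <- if (inherits(a, "mst_bayes")) a$draws$kd_nM else as.numeric(a)
  kb <- if (inherits(b, "mst_bayes")) b$draws$kd_nM else as.numeric(b)
  stopifnot(length(ka) >= 1, length(kb) >= 1,
            all(is.finite(ka)), all(is.finite(kb)),
            all(ka > 0), all(kb > 0))
  n <- min(length(ka), length(kb))
  thin_to <- function(x, n) x[round(seq(1, length(x), length.out = n))]
  ka <- thin_to(ka, n); kb <- thin_to(kb, n)
  lr <- log10(ka / kb)
  # ties split evenly so that comparing a posterior against itself gives 1/2
  structure(list(prob_a_tighter = mean(ka < kb) + 0.5 * mean(ka == kb),
                 log10_ratio = lr,
                 hdi = if (n >= 2) hdi(lr) else c(lower = lr, upper = lr),
                 n_pairs = n),
            class = "affinity_comparison")
}

#' @export
print.affinity_comparison <- function(x, ...) {
  cat(sprintf("Posterior affinity comparison (%d paired draws)\n",
              x$n_pairs))
  cat(sprintf("  P(KD_A < KD_B)        = %.3f\n", x$prob_a_tighter))
  cat(sprintf("  log10(KD_A/KD_B)      = %.2f  [95%% HDI %.2f, %.2f]\n",
              stats::median(x$log10_ratio), x$hdi[1], x$hdi[2]))
  invisible(x)
}
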