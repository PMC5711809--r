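#' @export
print.mst_bayes <- function(x, ...) {
  m <- stats::median(x$draws$kd_nM)
  h <- hdi(x$draws$kd_nM)
  cat("Robust Bayesian binding fit (Student-t likelihood)\n")
  cat(sprintf("  %d points, %d chain(s) x %d draws\n", nrow(x$data),
              x$mcmc$n_chains, x$mcmc$n_iterations))
  cat(sprintf("  KD = %.4g nM  [95%% HDI %.4g, %.4g]\n", m, h[1], h[2]))
  invisible(x)
}

#' Posterior summary of a robust Bayesian binding fit
#'
#' Posterior medians and 95% highest density intervals of all model
#' parameters, plus the binding free energy implied by each KD draw at the
#' given temperature. The median is the headline point estimate throughout.
#'
#' @param object An `mst_bayes` fit.
#' @param mass HDI probability mass (default 0.95).
#' @param temperature Temperature in kelvin for the free-energy conversion.
#' @param ... Unused.
#' @return A `summary.mst_bayes` object: data frame of `parameter`,
#'   `median`, `hdi_lower`, `hdi_upper` with diagnostics attached.
#' @export
summary.mst_bayes <- function(object, mass = 0.95, temperature = 297.15,
                              ...) {
  dr <- object$draws
  dg <- delta_G(dr$kd_nM, temperature)
  cols <- list(kd_nM = dr$kd_nM, u = dr$u, b = dr$b, cfl_nM = dr$cfl_nM,
               nu = dr$nu, lambda = dr$lambda, delta_G_kJ_mol = dg)
  tab <- data.frame(
    parameter = names(cols),
    median = vapply(cols, stats::median, 1),
    hdi_lower = vapply(cols, function(v) hdi(v, mass)[1], 1),
    hdi_upper = vapply(cols, function(v) hdi(v, mass)[2], 1),
    row.names = NULL
  )
  structure(list(table = tab, mass = mass, temperature = temperature,
                 diagnostics = object$diagnostics,
                 n_points = nrow(object$data)),
            class = "summary.mst_bayes")
}

#' @export
print.summary.mst_bayes <- function(x, ...) {
  cat(sprintf("Robust Bayesian binding fit: %d points; %.0f%% HDI; T = %g K\n",
              x$n_points, 100 * x$mass, x$temperature))
  tab <- x$table
  tab$median <- signif(tab$median, 4)
  tab$hdi_lower <- signif(tab$hdi_lower, 4)
  tab$hdi_upper <- signif(tab$hdi_upper, 4)
  print.data.frame(tab, row.names = FALSE)
  if (all(is.finite(x$diagnostics$rhat))) {
    cat(sprintf("max split R-hat %.3f; min ESS %.0f\n",
                max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  }
  invisible(x)
}

#' @export
coef.mst_bayes <- function(object, ...) {
  dr <- object$draws
  c(kd_nM = stats::median(dr$kd_nM), u = stats::median(dr$u),
    b = stats::median(dr$b), cfl_nM = stats::median(dr$cfl_nM))
}

#' Posterior-median binding curve
#'
#' Evaluates the mass-action curve at the posterior medians of
#' `(KD, U, B, c_fl)`.
#'
#' @param object An `mst_bayes` fit.
#' @param newdata Concentrations (nM) at which to evaluate; defaults to the
#'   fitted dataset's concentrations.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.mst_bayes <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$data$concentration_nM else {
    as.numeric(newdata)
  }
  p <- coef(object)
  mass_action_response(cc, kd = p[["kd_nM"]], u = p[["u"]], b = p[["b"]],
                       cfl = p[["cfl_nM"]])
}

#' @export
residuals.mst_bayes <- function(object, ...) {
  object$data$response - predict(object)
}

#' Plot a robust Bayesian binding fit
#'
#' Data points on a log concentration axis, a swarm of binding curves from
#' random joint posterior draws, and the posterior-median curve.
#'
#' @param x An `mst_bayes` fit.
#' @param n_curves Number of swarm curves (default 10).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mst_bayes <- function(x, n_curves = 10, ...) {
  d <- x$data
  grid <- 10^seq(log10(min(d$concentration_nM)),
                 log10(max(d$concentration_nM)), length.out = 100)
  sw <- posterior_curve_swarm(x, min(n_curves, nrow(x$draws)), grid)
  ylim <- range(d$response, sw)
  graphics::plot(d$concentration_nM, d$response, log = "x",
                 xlab = "ligand concentration (nM)", ylab = "response",
                 col = d$replicate, pch = 16, ylim = ylim, ...)
  for (j in seq_len(nrow(sw))) {
    graphics::lines(grid, sw[j, ],
                    col = grDevices::adjustcolor("steelblue", 0.35))
  }
  graphics::lines(grid, predict(x, grid), lwd = 2)
  invisible(x)
}

#' Export posterior draws / fit summary to disk
#'
#' `write_draws()` writes the posterior draws as delimited text (one row per
#' iteration; columns `kd_nM`, `u`, `b`, `cfl_nM`, `nu`, `lambda`, `chain`).
#' `write_fit_yaml()` writes a YAML summary report: point estimates,
#' 95% intervals, free energy at the configured temperature, and the
#' settings used.
#'
#' @param fit An `mst_bayes` or `mst_nllsq` fit.
#' @param path Output file path.
#' @param temperature Kelvin, for the free-energy entry.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "mst_bayes"))
  utils::write.csv(fit$draws, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
write_fit_yaml <- function(fit, path, temperature = 297.15) {
  rep <- if (inherits(fit, "mst_bayes")) {
    s <- summary(fit, temperature = temperature)$table
    rows <- lapply(seq_len(nrow(s)), function(i) {
      list(median = s$median[i],
           hdi = c(s$hdi_lower[i], s$hdi_upper[i]))
    })
    names(rows) <- s$parameter
    list(method = "robust_bayes", parameters = rows,
         temperature_K = temperature,
         mcmc = unclass(fit$mcmc))
  } else if (inherits(fit, "mst_nllsq")) {
    ci <- stats::confint(fit)
    est <- coef(fit)
    rows <- lapply(names(est), function(p) {
      list(estimate = unname(est[[p]]),
           ci = unname(c(ci[p, "lower"], ci[p, "upper"])))
    })
    names(rows) <- names(est)
    list(method = "nllsq", parameters = rows,
         delta_G_kJ_mol = delta_G(est[["kd_nM"]], temperature),
         temperature_K = temperature,
         rss = fit$rss, converged = fit$converged)
  } else {
    stop("unsupported fit object")
  }
  yaml::write_yaml(rep, path)
  invisible(path)
}
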