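#' Classical nonlinear least-squares binding fit
#'
#' Fits the three-parameter mass-action curve `(KD, U, B)` to a titration
#' dataset by minimizing the residual sum of squares with the MINPACK
#' Levenberg-Marquardt algorithm ([minpack.lm::nls.lm()]). The
#' labelled-partner concentration `cfl` is held fixed at its nominal value
#' (it is known from the experimental setup), so P = 3 parameters are
#' estimated. KD is optimized on the log scale internally to keep it
#' positive; results are reported on the natural nM scale.
#'
#' This is the classical comparator to [fit_bayes()]: a quadratic loss
#' weighs every point by its squared distance to the curve, so single
#' outlying observations can displace the estimate arbitrarily far.
#'
#' @param dataset A [titration_data()] frame with more than 3 points.
#' @param init Optional named vector `c(kd, u, b)` of starting values
#'   (nM / response units). Default: U from the mean response at the 3
#'   lowest concentrations, B at the 3 highest, KD at the geometric mean of
#'   the concentration range -- scale-free and reproducible.
#' @param cfl Fixed labelled-partner concentration (nM). Default: the
#'   dataset's ground-truth value if generated synthetically, else 50.
#' @return An object of class `mst_nllsq`: list with `estimates`
#'   (`kd_nM`, `u`, `b`), `rss`, `n_points`, `n_params` (3), `cfl`,
#'   `converged`, `init` and `data`. Deterministic given `init`.
#' @examples
#' d <- generate_dataset(test_case_params(5000, 780, 800, seed = 3,
#'                                        outlier_fraction = 0))
#' fit_nllsq(d)
#' @export
fit_nllsq <- function(dataset, init = NULL, cfl = NULL) {
  d <- validate_titration(dataset)
  if (nrow(d) <= 3L) stop("need more than 3 points for a 3-parameter fit")
  if (is.null(cfl)) {
    gt <- attr(dataset, "ground_truth")
    cfl <- if (!is.null(gt$cfl_true)) gt$cfl_true else 50
  }
  stopifnot(is.numeric(cfl), length(cfl) == 1L, cfl > 0)
  if (is.null(init)) init <- default_init(d)
  stopifnot(all(c("kd", "u", "b") %in% names(init)),
            all(is.finite(unlist(init))), init[["kd"]] > 0)

  resid_fun <- function(par) {
    d$response - mass_action_response(d$concentration_nM,
                                      kd = exp(par[["lkd"]]),
                                      u = par[["u"]], b = par[["b"]],
                                      cfl = cfl)
  }
  res <- minpack.lm::nls.lm(
    par = c(lkd = log(init[["kd"]]), u = init[["u"]], b = init[["b"]]),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  est <- c(kd_nM = exp(res$par[["lkd"]]), u = res$par[["u"]],
           b = res$par[["b"]])
  structure(list(estimates = est, rss = sum(res$fvec^2),
                 n_points = nrow(d), n_params = 3L, cfl = cfl,
                 converged = res$info %in% 1:4, info = res$info,
                 init = init, data = d, call = match.call()),
            class = "mst_nllsq")
}

#' @export
print.mst_nllsq <- function(x, ...) {
  cat("Nonlinear least-squares binding fit (Levenberg-Marquardt)\n")
  cat(sprintf("  %d points, RSS = %.6g, converged: %s\n", x$n_points,
              x$rss, x$converged))
  cat(sprintf("  KD = %.4g nM, U = %.4g, B = %.4g (cfl fixed at %g nM)\n",
              x$estimates[["kd_nM"]], x$estimates[["u"]],
              x$estimates[["b"]], x$cfl))
  invisible(x)
}

#' @export
coef.mst_nllsq <- function(object, ...) object$estimates

#' @export
predict.mst_nllsq <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$data$concentration_nM else {
    as.numeric(newdata)
  }
  e <- object$estimates
  mass_action_response(cc, kd = e[["kd_nM"]], u = e[["u"]], b = e[["b"]],
                       cfl = object$cfl)
}

#' @export
residuals.mst_nllsq <- function(object, ...) {
  object$data$response - predict(object)
}

# RSS profile for one fixed parameter, re-minimizing the other two.
# Fixing kd leaves a model linear in (u, b): solved exactly by lm.
# Fixing u or b leaves one nonlinear parameter (kd): nls.lm warm-started
# at the full-fit optimum.
profile_rss_fun <- function(fit, parameter) {
  d <- fit$data
  cfl <- fit$cfl
  e <- fit$estimates
  if (parameter == "kd_nM") {
    function(kd) {
      fb <- bound_fraction(d$concentration_nM, kd, cfl)
      r <- stats::lm.fit(cbind(1 - fb, fb), d$response)
      sum(r$residuals^2)
    }
  } else {
    fixed <- if (parameter == "u") "u" else "b"
    other <- if (parameter == "u") "b" else "u"
    function(val) {
      fn <- function(par) {
        th <- c(kd = exp(par[["lkd"]]), stats::setNames(val, fixed),
                stats::setNames(par[["other"]], other))
        d$response - mass_action_response(d$concentration_nM,
                                          kd = th[["kd"]], u = th[["u"]],
                                          b = th[["b"]], cfl = cfl)
      }
      res <- minpack.lm::nls.lm(
        par = c(lkd = log(e[["kd_nM"]]), other = e[[other]]),
        fn = fn,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14))
      sum(res$fvec^2)
    }
  }
}

# Find where g(p) = rss_profile(p) - threshold crosses zero on each side of
# the optimum p_hat. Outward bracketing (multiplicative for scale
# parameters), then uniroot. Returns the window edge, flagged open, when the
# threshold is never crossed inside the window.
profile_interval <- function(rss_fun, p_hat, threshold, window,
                             multiplicative = FALSE, n_steps = 60L) {
  g <- function(p) rss_fun(p) - threshold
  one_side <- function(dir) {
    steps <- if (multiplicative) {
      ratio <- if (dir > 0) (window[2] / p_hat)^(1 / n_steps) else {
        (window[1] / p_hat)^(1 / n_steps)
      }
      p_hat * ratio^seq_len(n_steps)
    } else {
      edge <- if (dir > 0) window[2] else window[1]
      p_hat + (edge - p_hat) * (seq_len(n_steps) / n_steps)^2
    }
    prev <- p_hat
    for (p in steps) {
      if (g(p) > 0) {
        r <- stats::uniroot(g, sort(c(prev, p)), tol = 1e-10 * max(1, abs(p_hat)))
        return(list(value = r$root, open = FALSE))
      }
      prev <- p
    }
    list(value = if (dir > 0) window[2] else window[1], open = TRUE)
  }
  lo <- one_side(-1)
  hi <- one_side(1)
  list(lower = lo$value, upper = hi$value,
       open_lower = lo$open, open_upper = hi$open)
}

#' F-statistic profile confidence intervals for an NLLSQ fit
#'
#' For each parameter p, the interval is the set of values for which the
#' re-minimized residual sum of squares `RSS(p)` (over the remaining
#' parameters) stays below the F-statistic threshold
#' `RSS * (1 + F / (N - P))`, where `F` is the F quantile at the given
#' confidence level with degrees of freedom 1 and `N - P`. Endpoints are
#' located by outward bracketing and root finding on the profile; when the
#' profile never reaches the threshold inside the search window the bound
#' is reported at the window edge and flagged open-ended (a hallmark of an
#' unidentified parameter, e.g. a titration that never approaches
#' saturation).
#'
#' @param object A converged `mst_nllsq` fit.
#' @param parm Parameters to profile; default all of `kd_nM`, `u`, `b`.
#' @param level Confidence level (default 0.95).
#' @param threshold `"f1"` (default) uses the threshold above;
#'   `"joint"` inflates it to `RSS * (1 + P * F_(P, N-P) / (N - P))`, the
#'   joint confidence-region criterion.
#' @param kd_window Search window for KD (nM).
#' @param response_window Search half-window for U and B, as a multiple of
#'   the observed response range around the estimate (default 10).
#' @param ... Unused.
#' @return Matrix with columns `lower`, `upper`; logical matrix attribute
#'   `"open"` marks window-clipped (open-ended) bounds.
#' @export
confint.mst_nllsq <- function(object, parm = c("kd_nM", "u", "b"),
                              level = 0.95, threshold = c("f1", "joint"),
                              kd_window = c(1e-3, 1e6),
                              response_window = 10, ...) {
  if (!object$converged) stop("fit did not converge; no profile intervals")
  threshold <- match.arg(threshold)
  parm <- match.arg(parm, several.ok = TRUE)
  n <- object$n_points
  p <- object$n_params
  thr <- if (threshold == "f1") {
    object$rss * (1 + stats::qf(level, 1, n - p) / (n - p))
  } else {
    object$rss * (1 + p * stats::qf(level, p, n - p) / (n - p))
  }
  rng <- diff(range(object$data$response))
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  open <- matrix(FALSE, length(parm), 2,
                 dimnames = list(parm, c("lower", "upper")))
  for (pr in parm) {
    est <- object$estimates[[pr]]
    if (thr - object$rss <= max(1e-12, 1e-10 * object$rss)) {
      # degenerate (near-zero RSS): the threshold collapses onto the minimum
      out[pr, ] <- c(est, est)
      next
    }
    if (pr == "kd_nM") {
      win <- kd_window
      mult <- TRUE
    } else {
      win <- est + c(-1, 1) * response_window * max(rng, 1)
      mult <- FALSE
    }
    pi_ <- profile_interval(profile_rss_fun(object, pr), est, thr, win,
                            multiplicative = mult)
    out[pr, ] <- c(pi_$lower, pi_$upper)
    open[pr, ] <- c(pi_$open_lower, pi_$open_upper)
  }
  attr(out, "open") <- open
  attr(out, "level") <- level
  out
}

#' @export
summary.mst_nllsq <- function(object, level = 0.95,
                              temperature = 297.15, ...) {
  ci <- stats::confint(object, level = level)
  structure(list(estimates = object$estimates, ci = ci, rss = object$rss,
                 n_points = object$n_points, converged = object$converged,
                 delta_G_kJ_mol = delta_G(object$estimates[["kd_nM"]],
                                          temperature),
                 temperature = temperature, level = level),
            class = "summary.mst_nllsq")
}

#' @export
print.summary.mst_nllsq <- function(x, ...) {
  cat(sprintf("NLLSQ binding fit: %d points, RSS %.6g, converged %s\n",
              x$n_points, x$rss, x$converged))
  open <- attr(x$ci, "open")
  for (p in rownames(x$ci)) {
    cat(sprintf("  %-6s %.4g  [%s%.4g, %.4g%s]\n", p, x$estimates[[p]],
                if (open[p, 1]) "<" else "", x$ci[p, 1], x$ci[p, 2],
                if (open[p, 2]) ">" else ""))
  }
  cat(sprintf("  delta G = %.1f kJ/mol at %g K\n", x$delta_G_kJ_mol,
              x$temperature))
  invisible(x)
}

#' @export
plot.mst_nllsq <- function(x, ...) {
  d <- x$data
  grid <- 10^seq(log10(min(d$concentration_nM)),
                 log10(max(d$concentration_nM)), length.out = 100)
  graphics::plot(d$concentration_nM, d$response, log = "x",
                 xlab = "ligand concentration (nM)", ylab = "response",
                 col = d$replicate, pch = 16, ...)
  graphics::lines(grid, predict(x, grid), lwd = 2)
  invisible(x)
}
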