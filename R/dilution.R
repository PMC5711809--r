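#' Pipette specification
#'
#' Describes the pipetting step used to build a serial dilution: the targeted
#' volume and the pipette's coefficient of variation (CoV, std/mean). Each
#' dilution step mixes two pipetted volumes (carried-over solution and fresh
#' buffer) drawn from the same specification, so both events share one CoV.
#'
#' @param target_volume Targeted pipetted volume in microlitres. Must be > 0.
#' @param cov Coefficient of variation of the delivered volume
#'   (dimensionless, std/mean). Must be >= 0. ISO 8655-compliant pipettes
#'   stay below 0.01 at typical MST volumes.
#' @return An object of class `pipette_spec`.
#' @examples
#' pipette_spec(target_volume = 10, cov = 0.01)
#' @export
pipette_spec <- function(target_volume = 10, cov = 0.01) {
  stopifnot(is.numeric(target_volume), length(target_volume) == 1L,
            is.finite(target_volume), target_volume > 0,
            is.numeric(cov), length(cov) == 1L, is.finite(cov), cov >= 0)
  structure(list(target_volume = target_volume, cov = cov),
            class = "pipette_spec")
}

#' @export
print.pipette_spec <- function(x, ...) {
  cat(sprintf("Pipette: target volume %g ul, CoV %g (sd %g ul)\n",
              x$target_volume, x$cov, x$cov * x$target_volume))
  invisible(x)
}

#' Targeted concentrations of a two-fold serial dilution
#'
#' The ideal (error-free) concentrations of a serial two-fold dilution form a
#' geometric series: element k is `c_starting / 2^k`, for k = 0 (the stock)
#' through `n_steps`.
#'
#' @param c_starting Stock (highest) ligand concentration in nM. Must be > 0.
#' @param n_steps Number of dilution steps (non-negative integer). The
#'   returned vector has `n_steps + 1` elements.
#' @return Numeric vector of targeted concentrations in nM, highest first.
#' @examples
#' targeted_concentrations(800, 3)  # 800 400 200 100
#' @export
targeted_concentrations <- function(c_starting, n_steps) {
  stopifnot(is.numeric(c_starting), length(c_starting) == 1L,
            is.finite(c_starting), c_starting > 0,
            is.numeric(n_steps), length(n_steps) == 1L,
            is.finite(n_steps), n_steps >= 0, n_steps == floor(n_steps))
  c_starting * 0.5^(0:n_steps)
}

# Draw n positive N(mean, sd) deviates; non-positive draws are rejected and
# redrawn (a delivered volume cannot be <= 0; negligible at realistic CoV).
rpos_norm <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a serial dilution with pipetting error
#'
#' Simulates the latent concentrations realized by a serial two-fold dilution
#' in which every step mixes two independently pipetted volumes, each normally
#' distributed around the targeted volume with the pipette's CoV. Step k
#' multiplies the previous concentration by `N_a / (N_a + N_b)`, so relative
#' errors compound multiplicatively down the series -- a biased random walk
#' whose log-variance grows with the step index, and whose asymmetry biases
#' late concentrations below target at large CoV.
#'
#' @param c_starting Stock concentration in nM (> 0). The stock itself is
#'   assumed exact; only dilution steps add error.
#' @param n_steps Number of dilution steps (>= 0). Default 15, i.e. 16
#'   concentrations, the capillary count of common MST instruments.
#' @param pipette A [pipette_spec()]. `cov = 0` reproduces the targeted
#'   geometric series exactly.
#' @param seed Optional integer seed. When supplied, the series is a
#'   deterministic function of the arguments and the global RNG state is left
#'   untouched; when `NULL`, draws come from (and advance) the current RNG
#'   stream.
#' @return An object of class `dilution_series`: a list with `concentrations`
#'   (realized, nM), `targeted` (ideal, nM), `c_starting`, `n_steps` and
#'   `pipette`. Both vectors have length `n_steps + 1` with index 1 = stock.
#' @examples
#' s <- simulate_dilution_series(1000, 15, pipette_spec(10, 0.01), seed = 1)
#' range(s$concentrations / s$targeted)
#' @export
simulate_dilution_series <- function(c_starting, n_steps = 15,
                                     pipette = pipette_spec(),
                                     seed = NULL) {
  stopifnot(inherits(pipette, "pipette_spec"))
  targeted <- targeted_concentrations(c_starting, n_steps)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  conc <- numeric(n_steps + 1L)
  conc[1L] <- c_starting
  if (n_steps > 0) {
    v <- pipette$target_volume
    sd <- pipette$cov * v
    if (sd == 0) {
      conc[] <- targeted
    } else {
      # draws are consumed pairwise per step, so step k of the series is a
      # function of step k-1 and the k-th pair alone (Markov structure)
      draws <- rpos_norm(2L * n_steps, v, sd)
      na <- draws[seq(1L, 2L * n_steps, by = 2L)]
      nb <- draws[seq(2L, 2L * n_steps, by = 2L)]
      conc[-1L] <- c_starting * cumprod(na / (na + nb))
    }
  }
  structure(list(concentrations = conc, targeted = targeted,
                 c_starting = c_starting, n_steps = n_steps,
                 pipette = pipette),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("Serial two-fold dilution: %d steps from %g nM (CoV %g)\n",
              x$n_steps, x$c_starting, x$pipette$cov))
  dev <- log10(x$concentrations / x$targeted)
  cat(sprintf("  max |log10 realized/targeted| = %.4g\n", max(abs(dev))))
  invisible(x)
}
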