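#' Parameters of a synthetic titration test case
#'
#' Bundles the ground-truth parameters used to generate an
#' outlier-contaminated synthetic titration dataset: the binding parameters,
#' the response noise, the pipetting error driving the serial-dilution
#' concentration error, the replicate count and the outlier contamination
#' level.
#'
#' Defaults mirror the benchmark simulation conditions: the labelled-partner
#' concentration is 50 nM, the stock ligand concentration is `100 * kd_true`
#' so that the 16-point two-fold series brackets KD symmetrically on the log
#' scale, the pipetting error is given as an absolute volume standard
#' deviation (in ul) on a 10 ul targeted transfer volume, and 20% of points
#' are replaced by uniform outliers spanning the U-B range plus a 25% margin.
#'
#' @param kd_true True dissociation constant (nM).
#' @param b_true,u_true True bound / unbound response plateaus.
#' @param noise_sd Standard deviation of the additive normal measurement
#'   error, in response units. Applied once per observation at response
#'   level; it does not scale with dilution step.
#' @param pipette_sd_ul Absolute standard deviation of the pipetted volume,
#'   in ul (the benchmark cases use 0.1-2 ul).
#' @param repeats Number of replicate dilution series (>= 1).
#' @param cfl_true Labelled-partner concentration (nM).
#' @param c_starting Stock ligand concentration (nM).
#' @param n_steps Dilution steps per series (16 points when 15).
#' @param outlier_fraction Fraction of all points replaced by uniform
#'   outliers, in \[0, 1\].
#' @param target_volume_ul Targeted pipetting volume (ul); together with
#'   `pipette_sd_ul` it fixes the pipette CoV.
#' @param seed Integer RNG seed making generation deterministic.
#' @return An object of class `test_case_params`.
#' @seealso [generate_dataset()], [table1_cases()]
#' @export
test_case_params <- function(kd_true, b_true, u_true, noise_sd = 1,
                             pipette_sd_ul = 0.1, repeats = 3,
                             cfl_true = 50, c_starting = 100 * kd_true,
                             n_steps = 15, outlier_fraction = 0.2,
                             target_volume_ul = 10, seed = 1L) {
  stopifnot(kd_true > 0, cfl_true > 0, c_starting > 0,
            noise_sd >= 0, pipette_sd_ul >= 0, target_volume_ul > 0,
            repeats >= 1, repeats == floor(repeats),
            n_steps >= 0, n_steps == floor(n_steps),
            outlier_fraction >= 0, outlier_fraction <= 1,
            is.finite(b_true), is.finite(u_true))
  structure(list(kd_true = kd_true, b_true = b_true, u_true = u_true,
                 noise_sd = noise_sd, pipette_sd_ul = pipette_sd_ul,
                 repeats = as.integer(repeats), cfl_true = cfl_true,
                 c_starting = c_starting, n_steps = as.integer(n_steps),
                 outlier_fraction = outlier_fraction,
                 target_volume_ul = target_volume_ul,
                 seed = as.integer(seed)),
            class = "test_case_params")
}

#' @export
print.test_case_params <- function(x, ...) {
  cat(sprintf(paste0("Synthetic test case: KD %g nM, B %g, U %g, ",
                     "noise sd %g, pipette sd %g ul on %g ul, %d repeat(s), ",
                     "%.0f%% outliers, seed %d\n"),
              x$kd_true, x$b_true, x$u_true, x$noise_sd, x$pipette_sd_ul,
              x$target_volume_ul, x$repeats, 100 * x$outlier_fraction,
              x$seed))
  invisible(x)
}

#' The ten benchmark simulation cases
#'
#' Returns the parameter grid of the ten synthetic benchmark cases used to
#' compare the robust Bayesian fit against NLLSQ: KD spanning 0.05-5 uM,
#' plateaus B = 780 (795 in case 5) and U = 800, response noise sd 0.5-2,
#' pipette volume sd 0.1 or 0.2 ul, and 1, 3 or 10 replicate series. Cases
#' differ pairwise in exactly one knob: case 1 vs 6 (pipetting error),
#' 1/7/8 (repeats), 1/9/10 (noise).
#'
#' @return A data frame with columns `case`, `kd_true_uM`, `b_true`,
#'   `u_true`, `noise_sd`, `pipette_sd_ul`, `repeats`.
#' @export
table1_cases <- function() {
  data.frame(
    case = 1:10,
    kd_true_uM    = c(5, 0.5, 0.1, 0.05, 0.5, 5, 5, 5, 5, 5),
    b_true        = c(780, 780, 780, 780, 795, 780, 780, 780, 780, 780),
    u_true        = rep(800, 10),
    noise_sd      = c(1, 1, 1, 1, 1, 1, 1, 1, 0.5, 2),
    pipette_sd_ul = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.2, 0.1, 0.1, 0.1, 0.1),
    repeats       = c(3L, 3L, 3L, 3L, 3L, 3L, 1L, 10L, 3L, 3L)
  )
}

#' Parameters for one benchmark case
#'
#' @param case Case number, 1-10.
#' @param seed RNG seed.
#' @param ... Overrides passed on to [test_case_params()].
#' @return A `test_case_params` object.
#' @export
case_params <- function(case, seed = 1L, ...) {
  tab <- table1_cases()
  stopifnot(length(case) == 1L, case %in% tab$case)
  r <- tab[tab$case == case, ]
  args <- list(kd_true = r$kd_true_uM * 1e3, b_true = r$b_true,
               u_true = r$u_true, noise_sd = r$noise_sd,
               pipette_sd_ul = r$pipette_sd_ul, repeats = r$repeats,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(test_case_params, args)
}

#' Generate an outlier-contaminated synthetic titration dataset
#'
#' For each replicate a fresh serial dilution is simulated (with pipetting
#' error compounding down the series), the ideal mass-action response is
#' evaluated at the *realized* concentrations, and i.i.d. normal measurement
#' noise is added. Then `floor(outlier_fraction * N)` points, chosen
#' uniformly without replacement across the whole dataset, are replaced by
#' draws from a uniform distribution covering the U-B response range widened
#' by a margin of `0.25 * |B - U|` on both sides. The recorded x-coordinate
#' of every point is the *targeted* concentration -- the analyst never
#' observes the realized one -- so the fitted models face concentration
#' errors they do not model, as real fits do.
#'
#' @param params A [test_case_params()] object.
#' @return A [titration_data()] frame with `true_concentration_nM` and
#'   `is_outlier` columns and the generator parameters attached as the
#'   `ground_truth` attribute. Deterministic given `params$seed`.
#' @examples
#' d <- generate_dataset(test_case_params(kd_true = 5000, b_true = 780,
#'                                        u_true = 800, seed = 7))
#' table(d$is_outlier)
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "test_case_params"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)

  pip <- pipette_spec(params$target_volume_ul,
                      params$pipette_sd_ul / params$target_volume_ul)
  n_per <- params$n_steps + 1L
  rep_id <- rep(seq_len(params$repeats), each = n_per)
  targeted <- true_c <- numeric(params$repeats * n_per)
  for (r in seq_len(params$repeats)) {
    s <- simulate_dilution_series(params$c_starting, params$n_steps, pip)
    i <- (r - 1L) * n_per + seq_len(n_per)
    targeted[i] <- s$targeted
    true_c[i] <- s$concentrations
  }
  resp <- mass_action_response(true_c, kd = params$kd_true,
                               u = params$u_true, b = params$b_true,
                               cfl = params$cfl_true) +
    stats::rnorm(length(true_c), 0, params$noise_sd)

  n <- length(resp)
  n_out <- floor(params$outlier_fraction * n)
  is_out <- rep(FALSE, n)
  if (n_out > 0) {
    idx <- sample.int(n, n_out)
    m <- 0.25 * abs(params$b_true - params$u_true)
    lo <- min(params$u_true, params$b_true) - m
    hi <- max(params$u_true, params$b_true) + m
    resp[idx] <- stats::runif(n_out, lo, hi)
    is_out[idx] <- TRUE
  }
  titration_data(replicate = rep_id, concentration_nM = targeted,
                 response = resp, true_concentration_nM = true_c,
                 is_outlier = is_out, ground_truth = unclass(params))
}
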