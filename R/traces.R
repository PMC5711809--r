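#' Cold / hot analysis windows for MST time traces
#'
#' An MST measurement records capillary fluorescence before and during an
#' infrared-laser pulse (time zero = laser on). The normalized response is
#' the ratio of mean fluorescence in a "hot" window, taken late in the
#' heating phase where both the fast temperature-jump response of the
#' fluorophore and the slower thermophoretic depletion have developed,
#' to a "cold" window taken entirely before the laser fires.
#'
#' @param cold `c(t_start, t_end)` seconds, entirely before 0.
#'   Default `c(-3, -1)`.
#' @param hot `c(t_start, t_end)` seconds. Default `c(27, 29)`.
#' @return An object of class `window_config`.
#' @export
window_config <- function(cold = c(-3, -1), hot = c(27, 29)) {
  stopifnot(is.numeric(cold), length(cold) == 2L, cold[1] < cold[2],
            is.numeric(hot), length(hot) == 2L, hot[1] < hot[2])
  if (cold[2] > 0) stop("cold window must lie entirely before time 0")
  structure(list(cold = cold, hot = hot), class = "window_config")
}

#' Construct an MST time trace
#'
#' @param capillary Capillary id (integer).
#' @param concentration_nM Ligand concentration in this capillary (nM, > 0).
#' @param time_s Sample times in seconds, strictly increasing; 0 = laser on.
#' @param fluorescence Fluorescence counts, >= 0.
#' @return An object of class `mst_trace`.
#' @export
mst_trace <- function(capillary, concentration_nM, time_s, fluorescence) {
  stopifnot(length(time_s) == length(fluorescence),
            length(time_s) >= 1L,
            all(is.finite(time_s)), all(diff(time_s) > 0),
            all(is.finite(fluorescence)), all(fluorescence >= 0),
            is.numeric(concentration_nM), concentration_nM > 0)
  structure(list(capillary = as.integer(capillary),
                 concentration_nM = as.numeric(concentration_nM),
                 time_s = as.numeric(time_s),
                 fluorescence = as.numeric(fluorescence)),
            class = "mst_trace")
}

#' @export
print.mst_trace <- function(x, ...) {
  cat(sprintf("MST trace: capillary %d, %g nM, %d samples (%g to %g s)\n",
              x$capillary, x$concentration_nM, length(x$time_s),
              min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Normalized fluorescence response of an MST trace
#'
#' `fnorm = scale * mean(F in hot window) / mean(F in cold window)`, with
#' the conventional per-mil scale of 1000: a constant trace yields 1000,
#' thermophoretic depletion pushes the value below it. The single hot/cold
#' ratio combines the temperature-jump and thermophoresis contributions.
#'
#' With `detrend = TRUE` a straight line is fitted to the cold-window
#' samples and extrapolated across the trace; the hot-window fluorescence
#' is then referenced to this extrapolated baseline instead of the cold
#' mean, which cancels linear photobleaching drift.
#'
#' @param trace An [mst_trace()], or anything with numeric `time_s` and
#'   `fluorescence` components of equal length.
#' @param windows A [window_config()].
#' @param scale Output scale; 1000 (per-mil, the default) or 1 for a plain
#'   ratio.
#' @param detrend Apply cold-anchored linear detrending (default `FALSE`).
#' @return A single numeric response value.
#' @examples
#' tr <- mst_trace(1, 100, seq(-5, 30, 0.5), rep(800, 71))
#' fnorm(tr)  # 1000
#' @export
fnorm <- function(trace, windows = window_config(), scale = 1000,
                  detrend = FALSE) {
  stopifnot(inherits(windows, "window_config"),
            is.numeric(trace$time_s), is.numeric(trace$fluorescence),
            length(trace$time_s) == length(trace$fluorescence))
  t <- trace$time_s
  f <- trace$fluorescence
  in_cold <- t >= windows$cold[1] & t <= windows$cold[2]
  in_hot <- t >= windows$hot[1] & t <= windows$hot[2]
  if (!any(in_cold)) stop("no samples in the cold window")
  if (!any(in_hot)) stop("no samples in the hot window")
  if (detrend && sum(in_cold) >= 2L) {
    base <- stats::lm.fit(cbind(1, t[in_cold]), f[in_cold])$coefficients
    ref <- mean(base[1] + base[2] * t[in_hot])
  } else {
    ref <- mean(f[in_cold])
  }
  if (ref == 0) stop("cold-window reference fluorescence is zero")
  scale * mean(f[in_hot]) / ref
}

#' Reduce a set of MST traces to a titration dataset
#'
#' Computes [fnorm()] for every trace and assembles one dataset point per
#' capillary, ordered by descending ligand concentration (the order in
#' which a serial dilution is loaded).
#'
#' @param traces List of [mst_trace()] objects.
#' @param windows A [window_config()].
#' @param replicate Replicate id assigned to all points (default 1).
#' @param ... Passed to [fnorm()] (`scale`, `detrend`).
#' @return A [titration_data()] frame. Duplicate concentrations within the
#'   replicate raise a warning but are all kept.
#' @export
traces_to_dataset <- function(traces, windows = window_config(),
                              replicate = 1L, ...) {
  stopifnot(is.list(traces), length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "mst_trace")))
  conc <- vapply(traces, function(x) x$concentration_nM, 1)
  resp <- vapply(traces, fnorm, 1, windows = windows, ...)
  if (anyDuplicated(conc)) {
    warning("duplicate ligand concentrations within replicate ", replicate,
            "; keeping all points")
  }
  ord <- order(conc, decreasing = TRUE)
  titration_data(replicate = rep(as.integer(replicate), length(conc)),
                 concentration_nM = conc[ord], response = resp[ord])
}

#' Read MST time traces from delimited text
#'
#' Long-format comma-separated text with columns `capillary`,
#' `concentration_nM`, `time_s`, `fluorescence`; lines starting with `#`
#' are metadata and skipped.
#'
#' @param path File path.
#' @return List of [mst_trace()] objects, one per capillary.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", encoding = "UTF-8")
  need <- c("capillary", "concentration_nM", "time_s", "fluorescence")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("'", path, "' lacks column(s): ", paste(miss, collapse = ", "))
  }
  lapply(split(d, d$capillary), function(g) {
    g <- g[order(g$time_s), ]
    mst_trace(g$capillary[1], g$concentration_nM[1], g$time_s,
              g$fluorescence)
  })
}
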