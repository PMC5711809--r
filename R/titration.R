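#' Construct a titration dataset
#'
#' A titration dataset is a data frame with one row per measured point and
#' mandatory columns `replicate` (integer id, contiguous from 1),
#' `concentration_nM` (the targeted ligand concentration the analyst knows,
#' > 0) and `response` (the scalar readout: Fnorm, T-jump or fluorescence
#' yield). Synthetic datasets may additionally carry `true_concentration_nM`
#' (the latent concentration realized by the simulated dilution) and
#' `is_outlier` (logical), plus a `ground_truth` attribute holding the
#' generator parameters; experimental datasets carry neither.
#'
#' @param replicate Integer vector of replicate ids.
#' @param concentration_nM Targeted ligand concentrations (nM, > 0).
#' @param response Measured responses (finite).
#' @param true_concentration_nM Optional latent concentrations (nM).
#' @param is_outlier Optional logical outlier flags.
#' @param ground_truth Optional list of generator parameters
#'   (see [test_case_params()]).
#' @return A `data.frame` of class `titration`.
#' @export
titration_data <- function(replicate, concentration_nM, response,
                           true_concentration_nM = NULL, is_outlier = NULL,
                           ground_truth = NULL) {
  d <- data.frame(replicate = as.integer(replicate),
                  concentration_nM = as.numeric(concentration_nM),
                  response = as.numeric(response))
  if (!is.null(true_concentration_nM)) {
    d$true_concentration_nM <- as.numeric(true_concentration_nM)
  }
  if (!is.null(is_outlier)) d$is_outlier <- as.logical(is_outlier)
  class(d) <- c("titration", "data.frame")
  attr(d, "ground_truth") <- ground_truth
  validate_titration(d)
}

validate_titration <- function(d) {
  need <- c("replicate", "concentration_nM", "response")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("titration data lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(d) == 0L) stop("titration data has no rows")
  if (any(!is.finite(d$concentration_nM)) || any(d$concentration_nM <= 0)) {
    stop("all concentrations must be finite and > 0")
  }
  if (any(!is.finite(d$response))) stop("all responses must be finite")
  reps <- sort(unique(d$replicate))
  if (!identical(reps, seq_along(reps))) {
    stop("replicate ids must be contiguous integers starting at 1")
  }
  d
}

#' @export
print.titration <- function(x, ...) {
  gt <- attr(x, "ground_truth")
  cat(sprintf("Titration dataset: %d points, %d replicate(s), %g-%g nM%s\n",
              nrow(x), length(unique(x$replicate)),
              min(x$concentration_nM), max(x$concentration_nM),
              if (is.null(gt)) "" else " [synthetic, ground truth attached]"))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read / write titration datasets as delimited text
#'
#' Datasets are stored as comma-separated text with a header row, '.' decimal
#' separator and UTF-8 encoding. Recognized columns are `replicate`,
#' `concentration_nM`, `response` and optionally `true_concentration_nM` and
#' `is_outlier`; unknown columns are preserved verbatim, so `save` followed by
#' `load` is an identity on the tabular content.
#'
#' @param path File path.
#' @return `read_titration()` returns a `titration` data frame.
#' @examples
#' d <- titration_data(1, c(100, 50), c(800, 799))
#' f <- tempfile(fileext = ".csv")
#' write_titration(d, f)
#' read_titration(f)
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- tryCatch(
    utils::read.csv(path, check.names = FALSE, encoding = "UTF-8"),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(d) == 0L) stop("no data rows in '", path, "'")
  need <- c("replicate", "concentration_nM", "response")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("'", path, "' lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (col in intersect(c("replicate", "concentration_nM", "response",
                          "true_concentration_nM"), names(d))) {
    v <- d[[col]]
    bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed value in column '%s' at data line %d of '%s'",
                   col, bad[1L], path))
    }
    d[[col]] <- as.numeric(v)
  }
  if ("is_outlier" %in% names(d)) d$is_outlier <- as.logical(d$is_outlier)
  d$replicate <- as.integer(d$replicate)
  class(d) <- c("titration", "data.frame")
  validate_titration(d)
}

#' @rdname read_titration
#' @param dataset A `titration` data frame (or coercible data frame).
#' @export
write_titration <- function(dataset, path) {
  stopifnot(is.data.frame(dataset))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
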