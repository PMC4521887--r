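#' Temporal filters
#'
#' A temporal filter is a vector of 20 taps over lags `tau = 0..19` stimulus
#' bins (most recent bin first), the resolution at which spike-triggered
#' averages and covariance eigenvectors are estimated. Filters may be kept
#' raw or normalized so the sum of squared taps equals one.
#'
#' @param taps Numeric vector of filter taps (lag 0 first).
#' @param norm_convention `"raw"` or `"unit"`.
#' @return An object of class `temporal_filter` (numeric vector with
#'   attributes).
#' @export
temporal_filter <- function(taps, norm_convention = c("raw", "unit")) {
  norm_convention <- match.arg(norm_convention)
  taps <- as.numeric(taps)
  if (norm_convention == "unit") {
    ss <- sum(taps^2)
    if (abs(ss - 1) > 1e-10)
      stop("unit-norm filter must have sum of squared taps equal to 1",
           call. = FALSE)
  }
  structure(taps, class = "temporal_filter", norm_convention = norm_convention)
}

#' Normalize a filter to unit L2 norm
#'
#' @param filter Numeric vector or `temporal_filter`.
#' @return A unit-norm `temporal_filter`.
#' @export
normalize_filter <- function(filter) {
  taps <- as.numeric(filter)
  nrm <- sqrt(sum(taps^2))
  if (nrm == 0) stop("cannot normalize an all-zero filter", call. = FALSE)
  temporal_filter(taps / nrm, "unit")
}

#' @export
print.temporal_filter <- function(x, ...) {
  cat(sprintf("Temporal filter: %d taps (%s norm), extreme tap %.3f at lag %d\n",
              length(x), attr(x, "norm_convention"),
              as.numeric(x)[which.max(abs(x))], which.max(abs(x)) - 1L))
  invisible(x)
}

#' Build a canonical biphasic Off-type temporal filter
#'
#' A difference-of-gamma-functions surrogate for a measured retinal ganglion
#' cell STA: a dominant negative (Off) lobe followed by a weaker positive
#' rebound, on the 20-bin lag grid. The slow default time-to-peak of 100 ms
#' matches the sluggish temporal filtering of salamander retinal ganglion
#' cells.
#'
#' @param time_to_peak_ms Latency of the (negative) main lobe peak in ms.
#' @param biphasic_ratio Amplitude of the positive rebound lobe relative to
#'   the main lobe (0 < ratio < 1 for a biphasic Off filter).
#' @param n_lags Number of taps (default 20).
#' @param dt Bin width in seconds (default 1/30).
#' @return A unit-norm `temporal_filter` whose most extreme tap is negative.
#' @examples
#' f <- make_canonical_filter()
#' sum(f^2)
#' @export
make_canonical_filter <- function(time_to_peak_ms = 100,
                                  biphasic_ratio = 0.45,
                                  n_lags = 20L,
                                  dt = 1 / 30) {
  if (time_to_peak_ms <= 0 || time_to_peak_ms >= n_lags * dt * 1000)
    stop("time_to_peak_ms must lie within the filter span", call. = FALSE)
  if (biphasic_ratio < 0 || biphasic_ratio >= 1)
    stop("biphasic_ratio must lie in [0, 1)", call. = FALSE)
  tau <- (seq_len(n_lags) - 1) * dt * 1000  # lag in ms
  g <- function(t, peak, shape) {
    x <- pmax(t, 0) / peak
    (x^shape) * exp(shape * (1 - x))  # gamma-like bump, max 1 at t = peak
  }
  main <- g(tau, time_to_peak_ms, 5)
  rebound <- g(tau, 1.9 * time_to_peak_ms, 7)
  taps <- -(main - biphasic_ratio * rebound)
  if (biphasic_ratio > 0 && max(taps) <= 0)
    stop("requested biphasic shape degenerated to monophasic", call. = FALSE)
  normalize_filter(taps)
}

#' Write / read temporal filters as CSV
#'
#' Columns: `lag_bin` (0-based), `lag_ms`, one column per filter.
#'
#' @param filters A named list of filters (numeric vectors).
#' @param path File path.
#' @param dt Bin width in seconds.
#' @return `write_filters_csv` returns `path` invisibly; `read_filters_csv`
#'   returns a named list of numeric vectors.
#' @export
write_filters_csv <- function(filters, path, dt = 1 / 30) {
  stopifnot(is.list(filters), length(filters) > 0)
  n <- length(filters[[1]])
  df <- data.frame(lag_bin = seq_len(n) - 1L,
                   lag_ms = (seq_len(n) - 1L) * dt * 1000)
  for (nm in names(filters)) df[[nm]] <- as.numeric(filters[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_filters_csv
#' @export
read_filters_csv <- function(path) {
  df <- utils::read.csv(path)
  cols <- setdiff(names(df), c("lag_bin", "lag_ms"))
  stats::setNames(lapply(cols, function(cl) df[[cl]]), cols)
}
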