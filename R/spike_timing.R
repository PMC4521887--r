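# Quantification of activation-dependent spike latency: filter-output
# peaks, relative spike-time histograms per activation bin, quadratic peak
# localisation, and the shift-vs-activation slope.

#' Activation level estimate from STA filtering
#'
#' Filters the stimulus with the (unit-norm) STA; the causal filter output
#' serves as an estimate of the cell's activation level. The first
#' `length(sta) - 1` bins lack a full history and are returned as `NA`.
#'
#' @param trace A `stim_trace` (normalized; the filter output of unit-SD
#'   white noise through a unit-norm filter has unit variance).
#' @param sta Unit-norm temporal filter.
#' @return Numeric activation series, same length as the trace.
#' @export
activation_signal <- function(trace, sta) {
  stopifnot(inherits(trace, "stim_trace"))
  taps <- as.numeric(sta)
  if (abs(sum(taps^2) - 1) > 1e-6)
    stop("sta must be unit-norm", call. = FALSE)
  filter_stimulus(trace$samples, taps)
}

#' Spike-timing profile versus activation level
#'
#' Finds local maxima of the activation signal (strictly greater than the
#' left neighbour and at least the right neighbour, so a plateau counts
#' once at its leftmost bin), bins them by peak value into `n_bins`
#' equal-count bins, and collects spike trains in a window of `window_ms`
#' around each maximum. Only the `kept` bins with the highest activation
#' levels are analysed (histograms at low activation are dominated by
#' noise): per bin, the averaged spike train is normalized to peak 1 and
#' the characteristic spike-time shift is the abscissa of the vertex of
#' the parabola through the histogram's largest point and its two
#' neighbours. A straight line fitted to shift versus mean peak activation
#' summarises the latency dependence; its slope is in ms per activation
#' unit. Negative shifts are expected: the activation estimate carries the
#' average stimulus-to-spike delay, and the shifts are corrections to it.
#'
#' @param activation Activation series from [activation_signal()].
#' @param spikes Binned spike counts aligned to the activation series.
#' @param dt Bin width in seconds (default 1/30).
#' @param contrast_label `"high"` or `"low"`; sets the default number of
#'   kept bins (10 and 4 respectively, reflecting the different data mass
#'   per condition).
#' @param n_bins Number of equal-count activation bins (default 40).
#' @param window_ms Collection window around each maximum (default 367 ms,
#'   i.e. 11 bins at 30 Hz).
#' @param kept Number of top activation bins analysed; default by
#'   `contrast_label`.
#' @param bins_use Optional logical mask (same length as `activation`)
#'   restricting which bins may contribute local maxima, e.g. one contrast
#'   condition of an alternating trace.
#' @return A `timing_profile` list: `bins` (data frame with mean peak
#'   `activation`, `shift_ms`, `edge` flag), `histograms` (kept x window
#'   matrix), `time_ms` (window axis), `slope` (ms per activation unit),
#'   `intercept`, and settings.
#' @export
timing_profile <- function(activation, spikes, dt = 1 / 30,
                           contrast_label = c("high", "low"),
                           n_bins = 40L, window_ms = 367,
                           kept = NULL, bins_use = NULL) {
  contrast_label <- match.arg(contrast_label)
  if (is.null(kept)) kept <- if (contrast_label == "high") 10L else 4L
  if (kept > n_bins) stop("kept bins exceed n_bins", call. = FALSE)
  a <- as.numeric(activation)
  counts <- as.integer(spikes)
  if (length(a) != length(counts))
    stop("activation and spikes differ in length", call. = FALSE)
  hw <- max(1L, floor(window_ms / 1000 / dt / 2))
  n <- length(a)
  i <- 2:(n - 1)
  is_max <- !is.na(a[i]) & !is.na(a[i - 1]) & !is.na(a[i + 1]) &
    a[i] > a[i - 1] & a[i] >= a[i + 1]
  maxima <- i[is_max]
  if (!is.null(bins_use)) maxima <- maxima[bins_use[maxima]]
  maxima <- maxima[maxima > hw & maxima <= n - hw]
  if (length(maxima) < n_bins)
    stop("need at least ", n_bins, " usable local maxima", call. = FALSE)
  peaks <- a[maxima]
  ord <- order(peaks)
  grp <- as.integer(ceiling(seq_along(ord) * (n_bins / length(ord))))
  keep_grp <- (n_bins - kept + 1L):n_bins
  time_ms <- (-hw:hw) * dt * 1000

  res <- lapply(keep_grp, function(gbin) {
    mx <- maxima[ord][grp == gbin]
    H <- gather_windows(counts, mx + hw, 2L * hw + 1L)  # cols m+hw .. m-hw
    h <- rev(colMeans(H))
    pk <- mean(a[mx])
    if (max(h) == 0)
      return(list(activation = pk, shift = NA_real_, edge = TRUE, hist = h))
    h <- h / max(h)
    j <- which.max(h)
    if (j == 1L || j == length(h))
      return(list(activation = pk, shift = NA_real_, edge = TRUE, hist = h))
    denom <- h[j - 1] - 2 * h[j] + h[j + 1]
    off <- if (denom == 0) 0 else 0.5 * (h[j - 1] - h[j + 1]) / denom
    list(activation = pk, shift = time_ms[j] + off * dt * 1000,
         edge = FALSE, hist = h)
  })
  bins <- data.frame(
    activation = vapply(res, `[[`, numeric(1), "activation"),
    shift_ms = vapply(res, `[[`, numeric(1), "shift"),
    edge = vapply(res, `[[`, logical(1), "edge"))
  use <- !bins$edge
  if (sum(use) >= 2) {
    fit <- stats::lm(shift_ms ~ activation, data = bins[use, ])
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    slope_se <- summary(fit)$coefficients[2, 2]
  } else {
    slope <- intercept <- slope_se <- NA_real_
  }
  structure(
    list(bins = bins,
         histograms = do.call(rbind, lapply(res, `[[`, "hist")),
         time_ms = time_ms,
         slope = slope, slope_se = slope_se, intercept = intercept,
         contrast = contrast_label, n_bins = as.integer(n_bins),
         kept = as.integer(kept), window_ms = window_ms,
         n_maxima = length(maxima)),
    class = "timing_profile")
}

#' @export
print.timing_profile <- function(x, ...) {
  cat(sprintf("Spike-timing profile (%s contrast): %d/%d activation bins kept\n",
              x$contrast, x$kept, x$n_bins))
  cat(sprintf("  shift vs activation: slope %.2f ms/unit (SE %.2f), intercept %.1f ms\n",
              x$slope, x$slope_se, x$intercept))
  invisible(x)
}

#' Compare latency-shift slopes between groups of cells or models
#'
#' Summarises per-group mean absolute slope with its standard error and
#' tests all pairwise differences with two-sample t-tests (Bonferroni
#' corrected when more than two groups are compared).
#'
#' @param profiles_by_group Named list; each element is a list of
#'   `timing_profile` objects (or a numeric vector of slopes) for one
#'   group. Groups with fewer than 2 usable slopes are dropped with a
#'   warning.
#' @param alpha Significance level (default 0.05).
#' @return A list with `summary` (data frame: group, n, `mean_abs_slope`,
#'   `se`) and `tests` (data frame of pairwise comparisons with raw and
#'   corrected p values and a `significant` flag).
#' @export
compare_slopes <- function(profiles_by_group, alpha = 0.05) {
  if (length(profiles_by_group) < 2)
    stop("need at least 2 groups", call. = FALSE)
  slopes <- lapply(profiles_by_group, function(g) {
    s <- if (is.numeric(g)) g
    else vapply(g, function(p) p$slope, numeric(1))
    s[is.finite(s)]
  })
  ok <- vapply(slopes, length, integer(1)) >= 2
  if (!all(ok)) {
    warning("dropping groups with fewer than 2 slopes: ",
            paste(names(slopes)[!ok], collapse = ", "), call. = FALSE)
    slopes <- slopes[ok]
  }
  if (length(slopes) < 2)
    stop("fewer than 2 usable groups remain", call. = FALSE)
  summ <- data.frame(
    group = names(slopes),
    n = vapply(slopes, length, integer(1)),
    mean_abs_slope = vapply(slopes, function(s) mean(abs(s)), numeric(1)),
    se = vapply(slopes, function(s) stats::sd(abs(s)) / sqrt(length(s)),
                numeric(1)),
    row.names = NULL)
  prs <- utils::combn(names(slopes), 2, simplify = FALSE)
  p_raw <- vapply(prs, function(pr)
    stats::t.test(abs(slopes[[pr[1]]]), abs(slopes[[pr[2]]]))$p.value,
    numeric(1))
  n_tests <- if (length(slopes) > 2) length(prs) else 1L
  p_adj <- pmin(p_raw * n_tests, 1)
  tests <- data.frame(
    group_a = vapply(prs, `[`, character(1), 1),
    group_b = vapply(prs, `[`, character(1), 2),
    p_value = p_raw, p_bonferroni = p_adj,
    significant = p_adj < alpha)
  list(summary = summ, tests = tests)
}
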