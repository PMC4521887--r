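# Information-theoretic ranking of STC features, finite-sample bias
# correction, total single-spike information, QC filtering and cell-type
# classification.

#' Information carried by a stimulus feature about single spikes
#'
#' Estimates `I_feature(k) = Integral ds P(s|spike) log2(P(s|spike)/P(s))`,
#' where `s` is the projection of the stimulus window onto the unit-norm
#' feature `k`, `P(s)` the prior projection distribution and `P(s|spike)`
#' the spike-conditional one. The integral is discretized with bins of
#' width `bin_width` stimulus standard deviations, anchored at zero;
#' spike-conditional samples outside the prior's occupied range are clipped
#' into the terminal occupied bins so the divergence stays finite. Bins
#' with zero prior mass are excluded from the sum.
#'
#' @param trace A per-contrast-normalized `stim_trace` (unit SD, so the
#'   projection of white noise onto a unit-norm feature has unit SD).
#' @param spikes Binned spike counts aligned to `trace`.
#' @param feature Unit-norm temporal filter.
#' @param bin_width Histogram bin width as a fraction of the stimulus SD
#'   (default 0.1).
#' @param contrast_label Optional restriction of the prior (and spikes) to
#'   one contrast condition.
#' @return An `info_estimate` list: `bits` (non-negative), `bin_width`,
#'   `n_spikes`, `bias_corrected = FALSE`.
#' @export
feature_information <- function(trace, spikes, feature, bin_width = 0.1,
                                contrast_label = NULL) {
  stopifnot(inherits(trace, "stim_trace"))
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  taps <- as.numeric(feature)
  if (abs(sum(taps^2) - 1) > 1e-6)
    stop("feature must be unit-norm", call. = FALSE)
  pr <- projection_sets(trace, spikes, taps, contrast_label)
  if (pr$n_spikes < 100)
    warning("fewer than 100 spikes; information estimate will be strongly ",
            "biased", call. = FALSE)
  bits <- discrete_kl_1d(pr$prior, pr$spike, pr$weights, bin_width)
  info_estimate(bits, bin_width, pr$n_spikes)
}

#' Joint information carried by two orthogonal features
#'
#' Same estimator as [feature_information()] on the two-dimensional
#' distribution of projections onto `k1` and `k2`.
#'
#' @inheritParams feature_information
#' @param k1,k2 Unit-norm temporal filters, orthogonal within `1e-6`.
#' @return An `info_estimate` list.
#' @export
two_feature_information <- function(trace, spikes, k1, k2, bin_width = 0.1,
                                    contrast_label = NULL) {
  stopifnot(inherits(trace, "stim_trace"))
  k1 <- as.numeric(k1); k2 <- as.numeric(k2)
  if (abs(sum(k1 * k2)) > 1e-6)
    stop("k1 and k2 must be orthogonal", call. = FALSE)
  p1 <- projection_sets(trace, spikes, k1, contrast_label)
  p2 <- projection_sets(trace, spikes, k2, contrast_label)
  n_cells_occupied <- function(x, y, w)
    length(unique(paste(floor(x / w), floor(y / w))))
  if (p1$n_spikes > 0 &&
      n_cells_occupied(p1$spike, p2$spike, bin_width) > 0.5 * p1$n_spikes)
    warning("sparse two-dimensional occupancy; joint information will be ",
            "strongly biased", call. = FALSE)
  bits <- discrete_kl_2d(cbind(p1$prior, p2$prior), cbind(p1$spike, p2$spike),
                         p1$weights, bin_width)
  info_estimate(bits, bin_width, p1$n_spikes)
}

info_estimate <- function(bits, bin_width, n_spikes, bias_corrected = FALSE) {
  structure(list(bits = max(bits, 0), bin_width = bin_width,
                 n_spikes = n_spikes, bias_corrected = bias_corrected),
            class = "info_estimate")
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("Feature information: %.4f bits/spike (%d spikes, bin %.2g SD%s)\n",
              x$bits, x$n_spikes, x$bin_width,
              if (x$bias_corrected) ", bias corrected" else ""))
  invisible(x)
}

# prior and spike-conditional projections of a feature; the projection of
# the window ending at bin t equals the causal filter output at t
projection_sets <- function(trace, spikes, taps, contrast_label = NULL) {
  g <- filter_stimulus(trace$samples, taps)
  use <- !is.na(g)
  if (!is.null(contrast_label)) use <- use & trace$label == contrast_label
  counts <- as.integer(spikes)
  counts[!use] <- 0L
  sel <- counts > 0L
  list(prior = g[use],
       spike = g[sel],
       weights = counts[sel],
       n_spikes = sum(counts))
}

# weighted 1-D histogram KL divergence in bits, bins anchored at 0
discrete_kl_1d <- function(prior, spike, weights, w) {
  if (length(spike) == 0) return(0)
  b_pr <- floor(prior / w)
  rng <- range(b_pr)
  b_sp <- pmin(pmax(floor(spike / w), rng[1]), rng[2])
  p <- tabulate(b_pr - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  q <- numeric(length(p))
  idx <- b_sp - rng[1] + 1L
  for (i in seq_along(idx)) q[idx[i]] <- q[idx[i]] + weights[i]
  p <- p / sum(p)
  q <- q / sum(q)
  ok <- p > 0 & q > 0
  sum(q[ok] * log2(q[ok] / p[ok]))
}

# 2-D variant; columns of `prior`/`spike` are the two projections
discrete_kl_2d <- function(prior, spike, weights, w) {
  if (nrow(spike) == 0) return(0)
  b1 <- floor(prior[, 1] / w); b2 <- floor(prior[, 2] / w)
  r1 <- range(b1); r2 <- range(b2)
  s1 <- pmin(pmax(floor(spike[, 1] / w), r1[1]), r1[2])
  s2 <- pmin(pmax(floor(spike[, 2] / w), r2[1]), r2[2])
  n1 <- r1[2] - r1[1] + 1L
  key_pr <- (b1 - r1[1]) + n1 * (b2 - r2[1]) + 1L
  key_sp <- (s1 - r1[1]) + n1 * (s2 - r2[1]) + 1L
  nkey <- n1 * (r2[2] - r2[1] + 1L)
  p <- tabulate(key_pr, nbins = nkey)
  q <- numeric(nkey)
  for (i in seq_along(key_sp)) q[key_sp[i]] <- q[key_sp[i]] + weights[i]
  p <- p / sum(p)
  q <- q / sum(q)
  ok <- p > 0 & q > 0
  sum(q[ok] * log2(q[ok] / p[ok]))
}

#' Finite-sample bias correction by extrapolation to infinite data
#'
#' Plug-in information estimates are biased upwards, asymptotically in
#' proportion to the inverse sample size. Given estimates at several data
#' fractions, the information is regressed on the inverse sample size by
#' ordinary least squares and the intercept (the `1/N -> 0` limit) is
#' returned; negative intercepts are floored at zero.
#'
#' @param fractions Numeric vector of data fractions in (0, 1], spanning at
#'   least `[0.8, 1]` in at least 3 points.
#' @param bits Information estimates (bits/spike) at those fractions.
#' @param bin_width,n_spikes Metadata carried into the returned estimate
#'   (`n_spikes` = full-data spike count).
#' @return An `info_estimate` with `bias_corrected = TRUE`.
#' @export
bias_correct <- function(fractions, bits, bin_width = 0.1,
                         n_spikes = NA_integer_) {
  if (length(fractions) < 3)
    stop("need at least 3 data fractions", call. = FALSE)
  if (min(fractions) > 0.8 + 1e-9 || max(fractions) < 1 - 1e-9)
    stop("fractions must span [0.8, 1]", call. = FALSE)
  if (length(bits) != length(fractions))
    stop("fractions and bits differ in length", call. = FALSE)
  if (diff(range(bits)) > 0.5 * abs(mean(bits)) && mean(bits) != 0)
    warning("information estimates vary wildly across fractions; ",
            "extrapolation is unreliable", call. = FALSE)
  fit <- stats::lm(bits ~ I(1 / fractions))  # 1/fraction is proportional to 1/N
  info_estimate(unname(stats::coef(fit)[1]), bin_width, n_spikes,
                bias_corrected = TRUE)
}

#' Bias-corrected feature information by spike subsampling
#'
#' Convenience wrapper: estimates [feature_information()] (or, with two
#' features, [two_feature_information()]) on random spike subsets at the
#' given data fractions (uniform draws without replacement, averaged over
#' `n_draws` draws per fraction) and extrapolates to infinite sample size
#' with [bias_correct()].
#'
#' @inheritParams feature_information
#' @param features A single unit-norm filter, or a list of two orthogonal
#'   filters for joint information.
#' @param fractions Data fractions (default `seq(0.8, 1, by = 0.05)`).
#' @param n_draws Subsample draws averaged per fraction (default 10; 1
#'   reproduces a single-draw scheme).
#' @param seed Integer seed for the subsampling stream.
#' @return An `info_estimate` with `bias_corrected = TRUE`.
#' @export
corrected_information <- function(trace, spikes, features,
                                  fractions = seq(0.8, 1, by = 0.05),
                                  n_draws = 10L, bin_width = 0.1,
                                  contrast_label = NULL, seed = 1L) {
  stopifnot(inherits(trace, "stim_trace"))
  if (!is.list(features)) features <- list(features)
  # project once; subsampling then only re-histograms the spike projections
  g <- lapply(features, function(f) filter_stimulus(trace$samples, f))
  use <- !is.na(g[[1]])
  if (!is.null(contrast_label)) use <- use & trace$label == contrast_label
  counts <- as.integer(spikes)
  counts[!use] <- 0L
  ev <- spike_events(counts)
  n_total <- length(ev)
  if (n_total == 0) stop("no usable spikes", call. = FALSE)
  prior1 <- g[[1]][use]
  sev1 <- g[[1]][ev]
  if (length(features) == 2L) {
    prior2 <- g[[2]][use]
    sev2 <- g[[2]][ev]
  }
  est_sub <- function(idx) {
    w <- rep(1, length(idx))
    if (length(features) == 1L)
      discrete_kl_1d(prior1, sev1[idx], w, bin_width)
    else
      discrete_kl_2d(cbind(prior1, prior2), cbind(sev1[idx], sev2[idx]),
                     w, bin_width)
  }
  bits <- with_local_seed(seed, vapply(fractions, function(f) {
    m <- max(1L, round(f * n_total))
    mean(vapply(seq_len(n_draws), function(d) {
      idx <- if (m == n_total) seq_len(n_total) else sample.int(n_total, m)
      est_sub(idx)
    }, numeric(1)))
  }, numeric(1)))
  bias_correct(fractions, bits, bin_width, n_total)
}

#' Total information transmitted by single spikes
#'
#' Computes `I_one_spike = 1/(rbar T) Integral dt r(t) log2(r(t)/rbar)`
#' from a trial-averaged firing-rate trace at stimulus resolution; bins
#' with `r(t) = 0` contribute zero. The normalized integral is invariant
#' under uniform time rescaling, so no bin width is needed.
#'
#' @param rate_trace Firing-rate vector `r(t)` (any common rate unit), e.g.
#'   a PSTH from repeated identical white-noise trials ([trial_rate()]).
#' @param mean_rate Mean rate `rbar`; defaults to `mean(rate_trace)`.
#' @param n_trials Number of trials behind the rate estimate (metadata).
#' @return A `single_spike_info` list with `bits` and metadata.
#' @export
single_spike_information <- function(rate_trace, mean_rate = NULL,
                                     n_trials = NA_integer_) {
  r <- as.numeric(rate_trace)
  if (any(r < 0)) stop("rates must be non-negative", call. = FALSE)
  if (all(r == 0)) stop("all-zero rate trace", call. = FALSE)
  rbar <- if (is.null(mean_rate)) mean(r) else mean_rate
  pos <- r > 0
  bits <- sum((r[pos] / rbar) * log2(r[pos] / rbar)) / length(r)
  structure(list(bits = bits, mean_rate = rbar, n_bins = length(r),
                 n_trials = n_trials),
            class = "single_spike_info")
}

#' @export
print.single_spike_info <- function(x, ...) {
  cat(sprintf("Single-spike information: %.4f bits/spike (mean rate %.3g)\n",
              x$bits, x$mean_rate))
  invisible(x)
}

#' Trial-averaged firing rate from repeated spike trains
#'
#' @param spike_list List of binned spike trains from repeats of the same
#'   stimulus sequence (equal lengths).
#' @param dt Bin width in seconds.
#' @return Numeric rate trace in Hz with attribute `n_trials`.
#' @export
trial_rate <- function(spike_list, dt = 1 / 30) {
  if (length(spike_list) < 2)
    stop("need at least 2 trials for a rate estimate", call. = FALSE)
  M <- do.call(cbind, lapply(spike_list, as.integer))
  structure(rowMeans(M) / dt, n_trials = length(spike_list))
}

#' Classify a cell from the information content of its STC eigenvectors
#'
#' Uses the per-eigenvector information of the high-contrast spectrum
#' (`v_i` = eigenvector of the i-th largest eigenvalue). Quality control
#' first: a cell is discarded if no eigenvector reaches
#' `info_threshold` bits/spike, or if its two most informative eigenvectors
#' are not drawn from the spectrum ends `{v1, v19, v20}` with the most
#' informative at an end (`v1` or `v20`). Then:
#' * Type I — the two most informative features are `v19` and `v20`
#'   (feature pair `k1 = v20`, `k2 = v19`);
#' * Type II — `v1` is among the top two and carries at least
#'   `info_threshold` bits/spike (`k1 = v1`, `k2 = v20`);
#' * Type III — `v1` is informative above `v19` but below the threshold
#'   (`k1 = v20`, `k2 = v1`).
#'
#' @param info_by_eigvec Numeric vector of (bias-corrected) information
#'   values, one per eigenvector, ordered `v1 ... v20`.
#' @param info_threshold Bits/spike defining "particularly informative"
#'   (default 0.8).
#' @return A `cell_type_label` list: `label` in
#'   `c("TypeI", "TypeII", "TypeIII", "discarded")`, `k1_source`/
#'   `k2_source` (eigenvector names, `NA` if discarded), and the
#'   information values used.
#' @export
classify_cell <- function(info_by_eigvec, info_threshold = 0.8) {
  info <- as.numeric(info_by_eigvec)
  n <- length(info)
  if (n < 3 || anyNA(info))
    stop("need a complete information value per eigenvector", call. = FALSE)
  vname <- function(i) paste0("v", i)
  ends <- c(1L, n)
  allowed <- c(1L, n - 1L, n)
  ord <- order(info, decreasing = TRUE)
  top2 <- ord[1:2]
  out <- function(label, k1, k2) {
    structure(list(label = label,
                   k1_source = if (is.na(k1)) NA_character_ else vname(k1),
                   k2_source = if (is.na(k2)) NA_character_ else vname(k2),
                   info = info, info_threshold = info_threshold),
              class = "cell_type_label")
  }
  if (max(info) < info_threshold) return(out("discarded", NA, NA))
  # the Type I pair {v19, v20} is valid in either information order
  if (setequal(top2, c(n - 1L, n))) return(out("TypeI", n, n - 1L))
  if (!all(top2 %in% allowed) || !(top2[1] %in% ends))
    return(out("discarded", NA, NA))
  if (1L %in% top2 && info[1L] >= info_threshold) return(out("TypeII", 1L, n))
  out("TypeIII", n, 1L)
}

#' @export
print.cell_type_label <- function(x, ...) {
  if (x$label == "discarded") {
    cat("Cell classification: discarded by quality control\n")
  } else {
    cat(sprintf("Cell classification: %s (k1 = %s, k2 = %s)\n",
                x$label, x$k1_source, x$k2_source))
  }
  n <- length(x$info)
  cat(sprintf("  info: v1 %.3f, v%d %.3f, v%d %.3f bits/spike (threshold %.2g)\n",
              x$info[1], n - 1L, x$info[n - 1L], n, x$info[n],
              x$info_threshold))
  invisible(x)
}
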