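# Reconstruction of contrast-specific STAs from STC-derived feature bases,
# On/Off pathway separation by clustering of spike-triggered stimuli, and
# Off-pathway re-analysis.

#' Feature basis for STA reconstruction
#'
#' Bundles an ordered set of unit-norm temporal filters (usually the two
#' most informative STC eigenvectors `k1`, `k2`, or the non-orthogonal
#' pathway filters `kON`, `kOFF`) with their provenance.
#'
#' @param filters Named list of unit-norm filters (first two are `k1`,
#'   `k2`).
#' @param source_contrast `"high"`, `"low"` or `NA`: the contrast condition
#'   the features were derived from.
#' @param source_indices Optional eigenvector indices (e.g. `c(20, 19)`).
#' @param check_orthogonal Require pairwise orthogonality within `1e-6`
#'   (`TRUE` for STC eigenvector bases; set `FALSE` for `kON`/`kOFF`).
#' @return A `feature_basis` object.
#' @export
feature_basis <- function(filters, source_contrast = NA_character_,
                          source_indices = NULL, check_orthogonal = TRUE) {
  stopifnot(is.list(filters), length(filters) >= 1)
  filters <- lapply(filters, as.numeric)
  for (f in filters)
    if (abs(sum(f^2) - 1) > 1e-6)
      stop("basis filters must be unit-norm", call. = FALSE)
  A <- do.call(cbind, filters)
  G <- crossprod(A)
  ortho <- max(abs(G - diag(ncol(A)))) < 1e-6
  if (check_orthogonal && !ortho)
    stop("basis filters are not pairwise orthonormal", call. = FALSE)
  if (is.null(names(filters)))
    names(filters) <- paste0("k", seq_along(filters))
  structure(list(filters = filters, source_contrast = source_contrast,
                 source_indices = source_indices, orthogonal = ortho),
            class = "feature_basis")
}

#' @export
print.feature_basis <- function(x, ...) {
  cat(sprintf("Feature basis: %s (%s, %sorthogonal)\n",
              paste(names(x$filters), collapse = ", "),
              if (is.na(x$source_contrast)) "unknown source"
              else paste0(x$source_contrast, "-contrast source"),
              if (x$orthogonal) "" else "non-"))
  invisible(x)
}

#' Split episodes into training and test sets
#'
#' Feature estimation and STA estimation must not reuse the same spikes;
#' episodes are therefore split, per contrast condition, into a randomly
#' chosen training fraction (features) and the remaining test episodes
#' (STA).
#'
#' @param trace A `stim_trace`.
#' @param spikes Binned spike counts aligned to `trace`.
#' @param train_fraction Fraction of episodes per contrast used for
#'   training (default 0.8).
#' @param seed Integer seed for the episode draw.
#' @return A list with `train`/`test` spike trains (counts zeroed outside
#'   the respective episodes) and `train_episodes`/`test_episodes` (indices).
#' @export
split_train_test <- function(trace, spikes, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(trace, "stim_trace"))
  et <- episode_table(trace)
  counts <- as.integer(spikes)
  train_eps <- integer(0)
  for (lab in unique(et$label)) {
    eps <- et$episode[et$label == lab]
    if (length(eps) < 5)
      stop("need at least 5 episodes per contrast to split", call. = FALSE)
    n_train <- min(length(eps) - 1L, max(1L, round(train_fraction * length(eps))))
    train_eps <- c(train_eps,
                   with_local_seed(seed + match(lab, unique(et$label)),
                                   sample(eps, n_train)))
  }
  in_train <- trace$episode %in% train_eps
  tr <- counts; tr[!in_train] <- 0L
  te <- counts; te[in_train] <- 0L
  list(train = binned_spikes(tr), test = binned_spikes(te),
       train_episodes = sort(train_eps),
       test_episodes = sort(setdiff(et$episode, train_eps)))
}

#' Fit an STA as a linear combination of basis features
#'
#' Solves the least-squares problem `sta ~ alpha_1 k_1 + alpha_2 k_2 (+
#' ...)` by the normal equations (general least squares, valid also for
#' non-orthogonal bases such as `kON`/`kOFF`, whose squared weights are
#' then not bounded by one). The goodness of fit is the coefficient of
#' determination with the time-mean-centred denominator,
#' `R^2 = 1 - sum((sta - fit)^2) / sum((sta - mean(sta))^2)`.
#'
#' @param basis A [feature_basis()].
#' @param sta Unit-norm target filter (the test-set STA).
#' @return An `sta_fit` list: `alpha` (named weights), `fitted`, `r2`,
#'   `sta`, `basis`.
#' @export
fit_sta <- function(basis, sta) {
  stopifnot(inherits(basis, "feature_basis"))
  y <- as.numeric(sta)
  if (abs(sum(y^2) - 1) > 1e-6)
    stop("target STA must be unit-norm", call. = FALSE)
  A <- do.call(cbind, basis$filters)
  if (nrow(A) != length(y))
    stop("basis and STA are on different lag grids", call. = FALSE)
  if (kappa(A, exact = TRUE) > 1e8)
    stop("collinear basis (condition number > 1e8)", call. = FALSE)
  alpha <- drop(solve(crossprod(A), crossprod(A, y)))
  names(alpha) <- names(basis$filters)
  fitted <- drop(A %*% alpha)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(list(alpha = alpha, fitted = fitted, r2 = r2, sta = y,
                 basis = basis),
            class = "sta_fit")
}

#' @export
print.sta_fit <- function(x, ...) {
  cat(sprintf("STA fit: R^2 = %.4f; weights %s\n", x$r2,
              paste(sprintf("%s = %.3f", names(x$alpha), x$alpha),
                    collapse = ", ")))
  invisible(x)
}

#' Coefficient of determination for the contrast-induced STA difference
#'
#' Quantifies how much of the change of the STA between contrasts a single
#' feature basis captures:
#' `R^2 = 1 - sum(((sta_hi - sta_lo) - (fit_hi - fit_lo))^2) /
#' sum(((sta_hi - sta_lo) - mean(sta_hi - sta_lo))^2)`. Values may be
#' negative when the basis misses the direction of change.
#'
#' @param fit_high,fit_low [fit_sta()] results for the high- and
#'   low-contrast STA, obtained with the same basis.
#' @return A single numeric value.
#' @export
sta_difference_r2 <- function(fit_high, fit_low) {
  stopifnot(inherits(fit_high, "sta_fit"), inherits(fit_low, "sta_fit"))
  if (length(fit_high$sta) != length(fit_low$sta))
    stop("fits are on different lag grids", call. = FALSE)
  if (!identical(names(fit_high$alpha), names(fit_low$alpha)) ||
      !isTRUE(all.equal(fit_high$basis$filters, fit_low$basis$filters,
                        tolerance = 1e-12)))
    stop("both fits must use the same basis", call. = FALSE)
  d <- fit_high$sta - fit_low$sta
  dh <- fit_high$fitted - fit_low$fitted
  1 - sum((d - dh)^2) / sum((d - mean(d))^2)
}

#' Separate On- and Off-pathway spikes by clustering
#'
#' Projects all spike-triggered stimulus windows onto `k1` and `k2` and
#' splits them into two clusters by k-means (k = 2, squared-Euclidean, 20
#' random restarts). The spike-count-weighted mean window of each cluster
#' yields the raw pathway STAs; the cluster whose filter has a positive
#' most-extreme tap is labelled ON, the other OFF. By construction the
#' full STA is the count-weighted average of the two cluster STAs.
#'
#' @inheritParams compute_sta
#' @param k1,k2 Unit-norm features spanning the projection plane.
#' @param seed Integer seed for the k-means restarts.
#' @return A `pathway_filters` list: `kON`/`kOFF` (unit-norm), `kON_raw`/
#'   `kOFF_raw`, cluster sizes, `on_fraction`, per-condition spike trains
#'   `on_spikes`/`off_spikes`, and the full raw STA.
#' @export
split_on_off <- function(trace, spikes, k1, k2, seed = 1L, n_lags = 20L) {
  stopifnot(inherits(trace, "stim_trace"))
  ev <- usable_events(trace, spikes, n_lags)
  if (length(ev) < 200)
    stop("need at least 200 usable spikes for pathway separation",
         call. = FALSE)
  g1 <- filter_stimulus(trace$samples, as.numeric(k1))
  g2 <- filter_stimulus(trace$samples, as.numeric(k2))
  P <- cbind(g1[ev], g2[ev])
  km <- with_local_seed(seed,
                        stats::kmeans(P, centers = 2L, nstart = 20L))
  W <- gather_windows(trace$samples, ev, n_lags)
  sta1 <- colMeans(W[km$cluster == 1L, , drop = FALSE])
  sta2 <- colMeans(W[km$cluster == 2L, , drop = FALSE])
  ext <- function(v) v[which.max(abs(v))]
  e1 <- ext(sta1); e2 <- ext(sta2)
  if ((e1 > 0) == (e2 > 0)) {
    warning("both cluster STAs have the same polarity; labelling the one ",
            "with the more positive extreme tap as ON", call. = FALSE)
    on_id <- if (e1 > e2) 1L else 2L
  } else {
    on_id <- if (e1 > 0) 1L else 2L
  }
  off_id <- 3L - on_id
  sizes <- as.integer(table(factor(km$cluster, levels = 1:2)))
  if (min(sizes) < 20)
    warning("degenerate cluster with fewer than 20 spikes", call. = FALSE)
  n_bins <- length(trace$samples)
  on_sta <- if (on_id == 1L) sta1 else sta2
  off_sta <- if (on_id == 1L) sta2 else sta1
  structure(
    list(kON = normalize_filter(on_sta),
         kOFF = normalize_filter(off_sta),
         kON_raw = on_sta, kOFF_raw = off_sta,
         sta_raw = colMeans(W),
         cluster_sizes = c(on = sizes[on_id], off = sizes[off_id]),
         on_fraction = sizes[on_id] / length(ev),
         on_spikes = events_to_counts(ev[km$cluster == on_id], n_bins),
         off_spikes = events_to_counts(ev[km$cluster == off_id], n_bins)),
    class = "pathway_filters")
}

#' @export
print.pathway_filters <- function(x, ...) {
  cat(sprintf("On/Off pathway separation: %d On / %d Off spikes (On fraction %.1f%%)\n",
              x$cluster_sizes["on"], x$cluster_sizes["off"],
              100 * x$on_fraction))
  invisible(x)
}

#' Re-run the spike-triggered analysis on Off-cluster spikes
#'
#' Performs the full STA/STC/significance/fit pipeline on the spikes
#' assigned to the Off-pathway cluster alone. The two most informative
#' eigenvectors of the resulting spectrum form the feature basis with
#' which the Off-pathway STA is fitted.
#'
#' @inheritParams test_significance
#' @param spikes_off Off-cluster spike train (e.g. `split_on_off()$off_spikes`).
#' @param contrast_label Optional prior restriction for the information
#'   ranking.
#' @return A list with `spectrum` (`stc_spectrum` with significance flags),
#'   `basis` (`feature_basis` of the two most informative eigenvectors),
#'   `fit` (`sta_fit` of the unit-norm Off STA) and `sta` (raw).
#' @export
off_pathway_reanalysis <- function(trace, spikes_off, n_repeats = 1000L,
                                   ci = 0.95, seed = 1L, n_lags = 20L,
                                   contrast_label = NULL,
                                   tail = c("outer", "both")) {
  tail <- match.arg(tail)
  if (sum(as.integer(spikes_off)) == 0)
    stop("empty Off cluster", call. = FALSE)
  spec <- test_significance(trace, spikes_off, n_repeats = n_repeats,
                            ci = ci, seed = seed, n_lags = n_lags,
                            tail = tail)
  info <- vapply(seq_len(n_lags), function(i)
    suppressWarnings(
      feature_information(trace, spikes_off, spec$vectors[, i],
                          contrast_label = contrast_label)$bits),
    numeric(1))
  top <- order(info, decreasing = TRUE)[1:2]
  basis <- feature_basis(
    list(k1 = spec$vectors[, top[1]], k2 = spec$vectors[, top[2]]),
    source_indices = top)
  sta <- compute_sta(trace, spikes_off, n_lags)
  fit <- fit_sta(basis, normalize_filter(sta))
  list(spectrum = spec, basis = basis, fit = fit, sta = as.numeric(sta),
       info = info)
}
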