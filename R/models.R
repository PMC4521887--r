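#' Binned spike trains
#'
#' Spike trains are represented as non-negative integer counts per stimulus
#' bin, aligned with a `stim_trace`. `spike_events()` expands counts into a
#' vector of bin indices (one entry per spike, multi-spike bins repeated)
#' and `events_to_counts()` is its inverse.
#'
#' @param counts Non-negative integer vector of spike counts per bin.
#' @return `binned_spikes()` returns an integer vector of class
#'   `binned_spikes`.
#' @export
binned_spikes <- function(counts) {
  counts <- as.integer(round(counts))
  if (any(counts < 0)) stop("spike counts must be non-negative", call. = FALSE)
  structure(counts, class = "binned_spikes")
}

#' @export
print.binned_spikes <- function(x, ...) {
  cat(sprintf("Binned spike train: %d spikes in %d bins (max count %d)\n",
              sum(x), length(x), max(x)))
  invisible(x)
}

#' @rdname binned_spikes
#' @export
spike_events <- function(counts) {
  rep(seq_along(counts), counts)
}

#' @rdname binned_spikes
#' @param bins Bin indices of individual spikes.
#' @param n_bins Total number of bins of the aligned trace.
#' @export
events_to_counts <- function(bins, n_bins) {
  binned_spikes(tabulate(bins, nbins = n_bins))
}

#' Causal convolution of a stimulus with a temporal filter
#'
#' Computes the generator signal `g(t) = sum_tau f(tau) s(t - tau)` at
#' stimulus resolution. The first `length(filter) - 1` bins lack a full
#' stimulus history; they are returned as `NA` unless `pad0 = TRUE`, in
#' which case missing history is treated as zero (as during model
#' simulation from a silent past).
#'
#' @param samples Stimulus sample vector (or a `stim_trace`).
#' @param filter Temporal filter (lag 0 first).
#' @param pad0 Replace the undefined leading bins by zero-padded output.
#' @return Numeric vector of filter outputs, same length as the stimulus.
#' @export
filter_stimulus <- function(samples, filter, pad0 = FALSE) {
  if (inherits(samples, "stim_trace")) samples <- samples$samples
  f <- as.numeric(filter)
  g <- as.numeric(stats::filter(samples, f, method = "convolution", sides = 1))
  if (pad0) {
    head <- seq_len(min(length(f) - 1L, length(samples)))
    g[head] <- vapply(head, function(t)
      sum(f[seq_len(t)] * samples[t - seq_len(t) + 1L]), numeric(1))
  }
  g
}

# ---------------------------------------------------------------------------
# parameter containers

#' Parameters of the spike-feedback threshold model
#'
#' A linear temporal filter followed by a hard threshold produces spikes;
#' each spike increments a feedback signal that is subtracted from the
#' filter output before thresholding and decays exponentially between
#' spikes. The model is a compact account of spike-generation-driven gain
#' control and reproduces contrast adaptation of temporal filtering.
#'
#' @param filter Temporal filter (applied to the raw contrast sequence).
#' @param threshold Spike threshold on the net drive (default 0.2).
#' @param increment Feedback increase per spike (default 3.0).
#' @param tau_ms Feedback decay time constant in ms (default 250).
#' @return A `spike_feedback_params` list.
#' @export
spike_feedback_params <- function(filter = make_canonical_filter(),
                                  threshold = 0.2,
                                  increment = 3.0,
                                  tau_ms = 250) {
  if (tau_ms <= 0) stop("tau_ms must be positive", call. = FALSE)
  if (increment < 0) stop("increment must be non-negative", call. = FALSE)
  structure(list(filter = as.numeric(filter), threshold = threshold,
                 increment = increment, tau_ms = tau_ms),
            class = "spike_feedback_params")
}

#' Parameters of the linear-nonlinear-kinetic (LNK) model
#'
#' A linear filter and sigmoidal nonlinearity `u(t) = 1/(1 + exp(-a(x -
#' theta)))` drive a first-order kinetic block with a resting state R, an
#' active state A and two inactive states I1, I2. The input `u(t)`
#' modulates both the R->A and the I1->I2 transition; occupancy of the
#' slowly recovering I2 state implements contrast adaptation akin to
#' vesicle depletion at bipolar cell terminals. The model output is the
#' active-state occupancy A(t), standing in for the ganglion cell membrane
#' potential. Spikes are generated, by default, at upward crossings of
#' `spike_threshold` by A(t) — the deterministic threshold readout that
#' also drives the spike-feedback model, keeping spike times locked to the
#' stimulus. An inhomogeneous-Poisson readout with rate
#' `rate_scale * max(A(t) - spike_threshold, 0)` is available as
#' `spike_mode = "poisson"`; its rate-epoch smearing acts like spike-time
#' jitter on the filter time scale and leaves a latency-type signature in
#' the covariance spectrum.
#'
#' Transition rates (per second, scaled by `u` where noted) are surrogate
#' defaults in the slow-recovery regime; the originating study reports its
#' exact values only graphically. All rates must satisfy
#' `rate * u * dt <= 1` for the forward-Euler update to conserve occupancy.
#'
#' @param filter Temporal filter (applied to the raw contrast sequence).
#' @param input_gain Amplitude of the linear stage (the filter is scaled by
#'   this factor before the nonlinearity; default 6). Sets the operating
#'   point on the sigmoid: the default lets strong high-contrast
#'   excursions reach the saturating range, the synaptic-depression
#'   regime, while low contrast stays mostly sub-linear.
#' @param gain Sigmoid gain `a` (default 2.5).
#' @param offset Sigmoid offset `theta` (default 2).
#' @param r_activate R->A rate per unit `u` (default 100 /s).
#' @param r_inactivate A->I1 rate (default 10 /s).
#' @param r_cascade I1->I2 rate per unit `u` (default 5 /s).
#' @param r_recover_i1 I1->R rate (default 3 /s).
#' @param r_recover_i2 I2->R rate (default 0.2 /s; the slow-recovery
#'   pathway).
#' @param spike_threshold Occupancy threshold for spiking (default 0.09,
#'   sitting in the upper tail of the A(t) distribution under the standard
#'   stimulus).
#' @param rate_scale Firing rate in Hz per unit supra-threshold occupancy
#'   for the Poisson readout (default 1000).
#' @param spike_mode `"threshold_crossing"` (default) or `"poisson"`.
#' @param n_substeps Forward-Euler substeps per stimulus bin (default 10;
#'   the fast depletion fluxes of the strong-drive regime are not stable
#'   at the full 33 ms step).
#' @return An `lnk_params` list.
#' @export
lnk_params <- function(filter = make_canonical_filter(),
                       input_gain = 6,
                       gain = 2.5,
                       offset = 2,
                       r_activate = 100,
                       r_inactivate = 10,
                       r_cascade = 5,
                       r_recover_i1 = 3,
                       r_recover_i2 = 0.2,
                       spike_threshold = 0.09,
                       rate_scale = 1000,
                       spike_mode = c("threshold_crossing", "poisson"),
                       n_substeps = 10L) {
  rates <- c(r_activate, r_inactivate, r_cascade, r_recover_i1, r_recover_i2)
  if (any(rates < 0)) stop("kinetic rates must be non-negative", call. = FALSE)
  spike_mode <- match.arg(spike_mode)
  structure(list(filter = as.numeric(filter), input_gain = input_gain,
                 gain = gain, offset = offset,
                 r_activate = r_activate, r_inactivate = r_inactivate,
                 r_cascade = r_cascade, r_recover_i1 = r_recover_i1,
                 r_recover_i2 = r_recover_i2,
                 spike_threshold = spike_threshold, rate_scale = rate_scale,
                 spike_mode = spike_mode, n_substeps = as.integer(n_substeps)),
            class = "lnk_params")
}

#' Parameters of the latency-shift LN-Poisson model
#'
#' A plain LN cascade with threshold-linear nonlinearity `a[x - theta]_+`
#' and inhomogeneous Poisson spiking, followed by an activation-dependent
#' latency rule: the firing-rate range `[0, rate_ceiling]` is divided
#' linearly into `n_levels` levels, and a spike generated at level `L` is
#' delayed by `shift_scale * (n_levels - L)` stimulus bins (rates above the
#' ceiling count as the top level). Weakly driven spikes are thus delayed
#' most; `shift_scale = 0` recovers the plain LN model.
#'
#' For non-integer `shift_scale` the delay in bins is realised by
#' stochastic rounding, so the expected delay follows the scaled rule
#' exactly.
#'
#' @param filter Temporal filter (applied to the raw contrast sequence).
#' @param gain Threshold-linear gain `a` in Hz (default 20).
#' @param threshold Threshold `theta` (default 0.08).
#' @param rate_ceiling Top of the level range in Hz (default 15).
#' @param n_levels Number of activation levels (default 4).
#' @param shift_scale Multiplier on the `(n_levels - L)`-bin delay rule
#'   (default 1).
#' @return A `latency_shift_params` list.
#' @export
latency_shift_params <- function(filter = make_canonical_filter(),
                                 gain = 20,
                                 threshold = 0.08,
                                 rate_ceiling = 15,
                                 n_levels = 4L,
                                 shift_scale = 1) {
  if (rate_ceiling <= 0) stop("rate_ceiling must be positive", call. = FALSE)
  if (n_levels < 1) stop("need at least one level", call. = FALSE)
  structure(list(filter = as.numeric(filter), gain = gain,
                 threshold = threshold, rate_ceiling = rate_ceiling,
                 n_levels = as.integer(n_levels), shift_scale = shift_scale),
            class = "latency_shift_params")
}

#' Parameters of the plain LN-Poisson control model
#'
#' @param filter Temporal filter (applied to the raw contrast sequence).
#' @param gain Threshold-linear gain `a` in Hz (default 20).
#' @param threshold Threshold `theta` (default 0.08).
#' @return An `ln_params` list.
#' @export
ln_params <- function(filter = make_canonical_filter(),
                      gain = 20,
                      threshold = 0.08) {
  structure(list(filter = as.numeric(filter), gain = gain,
                 threshold = threshold),
            class = "ln_params")
}

# ---------------------------------------------------------------------------
# simulators

#' Simulate the plain LN-Poisson control model
#'
#' @param trace A raw (un-normalized) `stim_trace`; the filter acts on the
#'   contrast-valued samples.
#' @param params [ln_params()].
#' @param seed Integer seed for the Poisson draw.
#' @return A `binned_spikes` train aligned to `trace`, with the underlying
#'   rate (Hz) attached as attribute `rate`.
#' @export
simulate_ln <- function(trace, params = ln_params(), seed = 1L) {
  stopifnot(inherits(trace, "stim_trace"))
  g <- filter_stimulus(trace$samples, params$filter, pad0 = TRUE)
  rate <- params$gain * pmax(g - params$threshold, 0)
  counts <- with_local_seed(seed, stats::rpois(length(rate), rate * trace$dt))
  out <- binned_spikes(counts)
  attr(out, "rate") <- rate
  out
}

#' Simulate the latency-shift LN-Poisson model
#'
#' Spikes are generated exactly as in [simulate_ln()] and then delayed
#' according to the firing rate at their generation bin (see
#' [latency_shift_params()]); spikes shifted past the end of the trace are
#' dropped.
#'
#' @inheritParams simulate_ln
#' @param params [latency_shift_params()].
#' @return A `binned_spikes` train; attribute `rate` holds the generation
#'   rate (Hz).
#' @export
simulate_latency_shift <- function(trace, params = latency_shift_params(),
                                   seed = 1L) {
  stopifnot(inherits(trace, "stim_trace"))
  g <- filter_stimulus(trace$samples, params$filter, pad0 = TRUE)
  rate <- params$gain * pmax(g - params$threshold, 0)
  n <- length(rate)
  counts <- with_local_seed(seed, {
    base <- stats::rpois(n, rate * trace$dt)
    ev <- rep(seq_len(n), base)
    if (length(ev)) {
      lvl <- pmin(floor(rate[ev] / (params$rate_ceiling / params$n_levels)) + 1,
                  params$n_levels)
      delay <- params$shift_scale * (params$n_levels - lvl)
      lo <- floor(delay)
      frac <- delay - lo
      delay_bins <- lo + (stats::runif(length(ev)) < frac)
      ev <- ev + delay_bins
      ev <- ev[ev <= n]
    }
    tabulate(ev, nbins = n)
  })
  out <- binned_spikes(counts)
  attr(out, "rate") <- rate
  out
}

#' Simulate the spike-feedback threshold model
#'
#' Per bin, the feedback signal first decays by `exp(-dt/tau)`, the net
#' drive `g(t) = (filter * s)(t) - f(t)` is compared to the threshold, and
#' a spike (at most one per bin) increments the feedback by the fixed
#' amount. The model is deterministic given the stimulus; `seed` is
#' accepted for interface symmetry and ignored.
#'
#' @inheritParams simulate_ln
#' @param params [spike_feedback_params()].
#' @return A `binned_spikes` train (0/1 counts); attribute `feedback` holds
#'   the feedback signal after each bin.
#' @export
simulate_spike_feedback <- function(trace, params = spike_feedback_params(),
                                    seed = NULL) {
  stopifnot(inherits(trace, "stim_trace"))
  drive <- filter_stimulus(trace$samples, params$filter, pad0 = TRUE)
  n <- length(drive)
  decay <- exp(-trace$dt / (params$tau_ms / 1000))
  counts <- integer(n)
  fb <- numeric(n)
  f <- 0
  for (t in seq_len(n)) {
    f <- f * decay
    if (drive[t] - f > params$threshold) {
      counts[t] <- 1L
      f <- f + params$increment
    }
    fb[t] <- f
  }
  out <- binned_spikes(counts)
  attr(out, "feedback") <- fb
  out
}

#' Simulate the linear-nonlinear-kinetic (LNK) model
#'
#' Integrates the four-state kinetic block (forward Euler, `n_substeps`
#' per stimulus bin with the kinetic input held constant within a bin)
#' driven by the sigmoid output `u(t)` and draws spikes as an
#' inhomogeneous Poisson process on the supra-threshold active-state
#' occupancy.
#'
#' @inheritParams simulate_ln
#' @param params [lnk_params()].
#' @param init Initial occupancies `c(R, A, I1, I2)`; default all-resting.
#' @return A list with `spikes` (`binned_spikes`), `occupancy` (n x 4
#'   matrix with columns R, A, I1, I2), `u` (kinetic input) and `rate`
#'   (Hz).
#' @export
simulate_lnk <- function(trace, params = lnk_params(), seed = 1L,
                         init = c(1, 0, 0, 0)) {
  stopifnot(inherits(trace, "stim_trace"))
  g <- params$input_gain *
    filter_stimulus(trace$samples, params$filter, pad0 = TRUE)
  u <- 1 / (1 + exp(-params$gain * (g - params$offset)))
  ns <- max(1L, params$n_substeps)
  dt <- trace$dt / ns
  if (max(u) * max(params$r_activate, params$r_cascade) * dt > 1 ||
      max(params$r_inactivate, params$r_recover_i1, params$r_recover_i2) * dt > 1)
    stop("kinetic rates too fast for the integration step ",
         "(per-step transition probability exceeds 1)", call. = FALSE)
  n <- length(u)
  occ <- matrix(0, n, 4, dimnames = list(NULL, c("R", "A", "I1", "I2")))
  R <- init[1]; A <- init[2]; I1 <- init[3]; I2 <- init[4]
  ka <- params$r_activate; kai <- params$r_inactivate
  kc <- params$r_cascade; k1r <- params$r_recover_i1; k2r <- params$r_recover_i2
  for (t in seq_len(n)) {
    ut <- u[t]
    for (k in seq_len(ns)) {
      fRA <- ka * ut * R * dt
      fAI <- kai * A * dt
      fI12 <- kc * ut * I1 * dt
      fI1R <- k1r * I1 * dt
      fI2R <- k2r * I2 * dt
      R <- R - fRA + fI1R + fI2R
      A <- A + fRA - fAI
      I1 <- I1 + fAI - fI12 - fI1R
      I2 <- I2 + fI12 - fI2R
    }
    occ[t, ] <- c(R, A, I1, I2)
  }
  if (min(occ) < -1e-12 || max(occ) > 1 + 1e-12)
    stop("state occupancy left [0, 1]; reduce rates or step size",
         call. = FALSE)
  A <- occ[, "A"]
  if (params$spike_mode == "threshold_crossing") {
    above <- A > params$spike_threshold
    counts <- as.integer(above & !c(FALSE, above[-n]))
    rate <- counts / trace$dt
  } else {
    rate <- params$rate_scale * pmax(A - params$spike_threshold, 0)
    counts <- with_local_seed(seed, stats::rpois(n, rate * trace$dt))
  }
  list(spikes = binned_spikes(counts), occupancy = occ, u = u, rate = rate)
}

#' Steady state of the LNK kinetic block for constant input
#'
#' Solves the linear balance equations of the four-state scheme for a fixed
#' kinetic input `u`, under the occupancy constraint `R + A + I1 + I2 = 1`.
#'
#' @param params [lnk_params()].
#' @param u Constant kinetic input in `[0, 1]`.
#' @return Named occupancy vector `c(R, A, I1, I2)`.
#' @export
lnk_steady_state <- function(params, u) {
  ka <- params$r_activate * u
  kai <- params$r_inactivate
  kc <- params$r_cascade * u
  k1r <- params$r_recover_i1
  k2r <- params$r_recover_i2
  # rows: dA = 0, dI1 = 0, dI2 = 0, conservation
  M <- rbind(c(ka, -kai, 0, 0),
             c(0, kai, -(kc + k1r), 0),
             c(0, 0, kc, -k2r),
             c(1, 1, 1, 1))
  sol <- solve(M, c(0, 0, 0, 1))
  stats::setNames(sol, c("R", "A", "I1", "I2"))
}

#' Simulate a two-pathway On/Off mixture cell
#'
#' Test generator for On/Off cluster separation: two threshold-linear LN
#' pathways with an On-type and an Off-type filter drive independent
#' Poisson processes whose spikes are summed. The true source pathway of
#' every spike is recorded, providing ground truth for evaluating
#' [split_on_off()].
#'
#' @inheritParams simulate_ln
#' @param on_filter,off_filter Unit-norm temporal filters; the On filter
#'   must have a positive extreme tap, the Off filter a negative one.
#' @param gains Named vector `c(on =, off =)` of threshold-linear gains in
#'   Hz; the Off pathway should dominate (`off >= on`).
#' @param threshold Shared threshold `theta` (default 0.08).
#' @return A `binned_spikes` train with attributes `on_counts` and
#'   `off_counts` (per-bin ground-truth source counts).
#' @export
simulate_two_pathway <- function(trace, on_filter, off_filter,
                                 gains = c(on = 12, off = 20),
                                 threshold = 0.08, seed = 1L) {
  stopifnot(inherits(trace, "stim_trace"))
  on_filter <- as.numeric(on_filter); off_filter <- as.numeric(off_filter)
  if (on_filter[which.max(abs(on_filter))] <= 0)
    stop("on_filter must have a positive extreme tap", call. = FALSE)
  if (off_filter[which.max(abs(off_filter))] >= 0)
    stop("off_filter must have a negative extreme tap", call. = FALSE)
  g_on <- filter_stimulus(trace$samples, on_filter, pad0 = TRUE)
  g_off <- filter_stimulus(trace$samples, off_filter, pad0 = TRUE)
  r_on <- gains[["on"]] * pmax(g_on - threshold, 0)
  r_off <- gains[["off"]] * pmax(g_off - threshold, 0)
  n <- length(r_on)
  cts <- with_local_seed(seed, {
    on <- stats::rpois(n, r_on * trace$dt)
    off <- stats::rpois(n, r_off * trace$dt)
    list(on = on, off = off)
  })
  out <- binned_spikes(cts$on + cts$off)
  attr(out, "on_counts") <- as.integer(cts$on)
  attr(out, "off_counts") <- as.integer(cts$off)
  out
}

#' Write / read binned spike trains as CSV
#'
#' Two columns: `bin_index`, `count`.
#'
#' @param spikes A `binned_spikes` vector (or plain integer counts).
#' @param path File path.
#' @return `write_spikes_csv` returns `path` invisibly; `read_spikes_csv`
#'   returns a `binned_spikes` vector.
#' @export
write_spikes_csv <- function(spikes, path) {
  df <- data.frame(bin_index = seq_along(spikes),
                   count = as.integer(spikes))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @param n_bins Optional total bin count (defaults to the largest index in
#'   the file).
#' @export
read_spikes_csv <- function(path, n_bins = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("bin_index", "count") %in% names(df)))
    stop("spike CSV lacks required columns", call. = FALSE)
  n <- if (is.null(n_bins)) max(df$bin_index) else n_bins
  counts <- integer(n)
  counts[df$bin_index] <- as.integer(df$count)
  binned_spikes(counts)
}
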