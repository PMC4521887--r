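# Shared fixtures, built once per test run. The "medium" recording is 30
# episode pairs (one hour of stimulation) of the standard contrast-
# alternating stimulus with a plain LN-Poisson cell; enough spikes for
# stable spike-triggered estimates while keeping the suite fast.

fx <- new.env()

fx_trace <- function() {
  if (is.null(fx$tr)) {
    fx$tr <- generate_stimulus(stim_config(n_episode_pairs = 30, seed = 42))
    fx$ntr <- normalize_per_contrast(fx$tr)
  }
  fx$tr
}

fx_ntrace <- function() {
  fx_trace()
  fx$ntr
}

fx_ln_high <- function() {
  if (is.null(fx$ln_high)) {
    tr <- fx_trace()
    fx$ln <- simulate_ln(tr, seed = 7)
    fx$ln_high <- select_condition(tr, fx$ln, "high")
  }
  fx$ln_high
}

fx_ln_spectrum <- function() {
  if (is.null(fx$ln_spec)) {
    fx$ln_spec <- suppressWarnings(
      compute_stc(fx_ntrace(), fx_ln_high()))
  }
  fx$ln_spec
}

fx_latency <- function() {
  if (is.null(fx$lat)) fx$lat <- simulate_latency_shift(fx_trace(), seed = 7)
  fx$lat
}

fx_two_pathway <- function() {
  if (is.null(fx$tp)) {
    off <- make_canonical_filter()
    fx$tp <- simulate_two_pathway(fx_trace(), on_filter_from(off), off,
                                  seed = 9)
  }
  fx$tp
}

# slope of the shift-vs-activation line for one simulated train
fx_timing_slope <- function(spikes, lab = "high") {
  tr <- fx_trace(); ntr <- fx_ntrace()
  sp <- select_condition(tr, spikes, lab)
  sta <- normalize_filter(compute_sta(ntr, sp))
  act <- activation_signal(ntr, sta)
  timing_profile(act, sp, dt = tr$dt, contrast_label = lab,
                 bins_use = tr$label == lab)
}
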