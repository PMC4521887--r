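# Orchestration: configuration, end-to-end pipeline runs
# (simulate -> analyze -> classify -> fit -> timing), and report output.

#' Configuration of an end-to-end pipeline run
#'
#' Collects every parameter of a simulate-analyze-classify-fit-timing run;
#' all stochastic stages carry explicit seeds so reruns are bit-identical.
#'
#' @param stimulus A [stim_config()].
#' @param model Generative model: `"ln"`, `"latency"`, `"feedback"`,
#'   `"lnk"` or `"two_pathway"`.
#' @param model_params Optional parameter object matching the model
#'   (defaults are constructed from [make_canonical_filter()]).
#' @param n_lags,n_repeats,ci,tail Spike-triggered analysis settings, see
#'   [test_significance()].
#' @param analysis_window `"full"` or `"second_half"` (control analysis
#'   dropping the first half of each episode).
#' @param train_fraction Episode fraction for the feature/STA split.
#' @param model_seed,analysis_seed Seeds for spike generation and for the
#'   shuffle/split/subsampling streams.
#' @param info_threshold Bits/spike for the Type II rule (default 0.8).
#' @return A `run_config` list.
#' @export
run_config <- function(stimulus = stim_config(),
                       model = c("ln", "latency", "feedback", "lnk",
                                 "two_pathway"),
                       model_params = NULL,
                       n_lags = 20L, n_repeats = 1000L, ci = 0.95,
                       tail = "outer",
                       analysis_window = c("full", "second_half"),
                       train_fraction = 0.8,
                       model_seed = 1L, analysis_seed = 1L,
                       info_threshold = 0.8) {
  model <- match.arg(model)
  analysis_window <- match.arg(analysis_window)
  stopifnot(inherits(stimulus, "stim_config"))
  structure(list(stimulus = stimulus, model = model,
                 model_params = model_params, n_lags = as.integer(n_lags),
                 n_repeats = as.integer(n_repeats), ci = ci, tail = tail,
                 analysis_window = analysis_window,
                 train_fraction = train_fraction,
                 model_seed = as.integer(model_seed),
                 analysis_seed = as.integer(analysis_seed),
                 info_threshold = info_threshold),
            class = "run_config")
}

default_model_params <- function(model) {
  switch(model,
         ln = ln_params(),
         latency = latency_shift_params(),
         feedback = spike_feedback_params(),
         lnk = lnk_params(),
         two_pathway = NULL)
}

#' Simulate spikes for a pipeline configuration
#'
#' @param config A [run_config()].
#' @param trace A raw `stim_trace` generated from `config$stimulus`.
#' @return A `binned_spikes` train.
#' @export
simulate_model <- function(config, trace) {
  p <- config$model_params
  if (is.null(p)) p <- default_model_params(config$model)
  switch(config$model,
         ln = simulate_ln(trace, p, seed = config$model_seed),
         latency = simulate_latency_shift(trace, p, seed = config$model_seed),
         feedback = simulate_spike_feedback(trace, p),
         lnk = simulate_lnk(trace, p, seed = config$model_seed)$spikes,
         two_pathway = {
           if (is.null(p))
             p <- list(on_filter = on_filter_from(make_canonical_filter()),
                       off_filter = make_canonical_filter(),
                       gains = c(on = 12, off = 20), threshold = 0.08)
           simulate_two_pathway(trace, p$on_filter, p$off_filter,
                                gains = p$gains, threshold = p$threshold,
                                seed = config$model_seed)
         })
}

#' An On-type filter derived from an Off-type filter
#'
#' Sign-flips and slightly delays an Off filter (one bin), giving the
#' characteristic polarity and relative delay of the On pathway.
#'
#' @param off_filter Unit-norm Off-type filter.
#' @param delay_bins Delay of the On filter in bins (default 1).
#' @return A unit-norm `temporal_filter` with positive extreme tap.
#' @export
on_filter_from <- function(off_filter, delay_bins = 1L) {
  f <- -as.numeric(off_filter)
  n <- length(f)
  normalize_filter(c(numeric(delay_bins), f)[seq_len(n)])
}

#' Run the full spike-triggered analysis pipeline
#'
#' Simulates (or accepts) a spike train on the contrast-alternating
#' stimulus and produces, per contrast condition: the test-set STA, the
#' STC spectrum with nested shuffle significance, the nonlinearity, the
#' per-eigenvector information table and the timing profile; plus the
#' cell-type label from the high-contrast information values, four STA
#' fits (high/low basis x high/low STA) and the two STA-difference
#' coefficients of determination.
#'
#' @param config A [run_config()].
#' @param spikes Optional pre-computed spike train (skips simulation).
#' @param out_dir Optional directory; when given, all reports are written
#'   there as JSON/CSV together with a manifest.
#' @return A `pipeline_result` list with elements `trace`, `spikes`,
#'   `conditions` (per-contrast analyses), `classification`, `fits`,
#'   `difference_r2`, `config`.
#' @export
run_pipeline <- function(config, spikes = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  trace <- generate_stimulus(config$stimulus)
  if (is.null(spikes)) spikes <- simulate_model(config, trace)
  ntr <- normalize_per_contrast(trace)
  aseed <- config$analysis_seed

  conditions <- list()
  for (lab in c("high", "low")) {
    sp_c <- select_condition(trace, spikes, lab, config$analysis_window)
    if (sum(sp_c) == 0)
      stop("pipeline stage 'analyze' failed: no spikes in ", lab,
           "-contrast condition", call. = FALSE)
    split <- split_train_test(ntr, sp_c, config$train_fraction, seed = aseed)
    spec <- test_significance(ntr, split$train, n_repeats = config$n_repeats,
                              ci = config$ci, seed = aseed,
                              n_lags = config$n_lags, tail = config$tail)
    sta_test <- compute_sta(ntr, split$test, config$n_lags)
    info <- vapply(seq_len(config$n_lags), function(i)
      suppressWarnings(
        corrected_information(ntr, split$train, spec$vectors[, i],
                              contrast_label = lab,
                              seed = aseed + i)$bits),
      numeric(1))
    nl <- estimate_nonlinearity(ntr, sp_c, normalize_filter(sta_test),
                                contrast_label = lab)
    act <- activation_signal(ntr, normalize_filter(sta_test))
    tim <- timing_profile(act, sp_c, dt = trace$dt, contrast_label = lab,
                          bins_use = trace$label == lab)
    conditions[[lab]] <- list(spikes = sp_c, split = split,
                              spectrum = spec, sta = sta_test,
                              info = info, nonlinearity = nl, timing = tim)
  }

  cls <- classify_cell(conditions$high$info, config$info_threshold)
  pick_basis <- function(cond, contrast) {
    top <- order(cond$info, decreasing = TRUE)[1:2]
    feature_basis(list(k1 = cond$spectrum$vectors[, top[1]],
                       k2 = cond$spectrum$vectors[, top[2]]),
                  source_contrast = contrast, source_indices = top)
  }
  bases <- list(high = pick_basis(conditions$high, "high"),
                low = pick_basis(conditions$low, "low"))
  fits <- list()
  diff_r2 <- c(high = NA_real_, low = NA_real_)
  for (b in c("high", "low")) {
    f_h <- fit_sta(bases[[b]], normalize_filter(conditions$high$sta))
    f_l <- fit_sta(bases[[b]], normalize_filter(conditions$low$sta))
    fits[[paste0("basis_", b, "_sta_high")]] <- f_h
    fits[[paste0("basis_", b, "_sta_low")]] <- f_l
    diff_r2[b] <- sta_difference_r2(f_h, f_l)
  }

  out <- structure(
    list(trace = trace, spikes = spikes, conditions = conditions,
         classification = cls, bases = bases, fits = fits,
         difference_r2 = diff_r2, config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: model '%s', %d spikes\n",
              x$config$model, sum(x$spikes)))
  for (lab in c("high", "low")) {
    sp <- x$conditions[[lab]]$spectrum
    cat(sprintf("  %s contrast: %d sig. positive / %d sig. negative eigenvalues\n",
                lab, sp$n_sig_pos, sp$n_sig_neg))
  }
  cat(sprintf("  classification: %s\n", x$classification$label))
  cat(sprintf("  STA-fit R^2: high basis %.3f/%.3f, low basis %.3f/%.3f (high/low STA)\n",
              x$fits$basis_high_sta_high$r2, x$fits$basis_high_sta_low$r2,
              x$fits$basis_low_sta_high$r2, x$fits$basis_low_sta_low$r2))
  invisible(x)
}

#' Write all pipeline reports to a directory
#'
#' Produces JSON reports (spectra with significance flags, information
#' tables, fits, timing profiles, classification), CSV dumps (stimulus,
#' spikes, filters) and a `manifest.json` holding every parameter needed
#' to regenerate the outputs.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jw <- function(x, file)
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  write_stimulus_csv(result$trace, file.path(out_dir, "stimulus.csv"))
  write_spikes_csv(result$spikes, file.path(out_dir, "spikes.csv"))
  for (lab in c("high", "low")) {
    cond <- result$conditions[[lab]]
    jw(spectrum_report(cond$spectrum), sprintf("spectrum_%s.json", lab))
    jw(list(bits_per_eigenvector = cond$info), sprintf("info_%s.json", lab))
    jw(list(slope_ms_per_unit = cond$timing$slope,
            intercept_ms = cond$timing$intercept,
            bins = cond$timing$bins), sprintf("timing_%s.json", lab))
    utils::write.csv(cond$nonlinearity,
                     file.path(out_dir, sprintf("nonlinearity_%s.csv", lab)),
                     row.names = FALSE)
  }
  filters <- list(sta_high = as.numeric(result$conditions$high$sta),
                  sta_low = as.numeric(result$conditions$low$sta))
  for (b in c("high", "low")) {
    filters[[paste0("k1_", b)]] <- result$bases[[b]]$filters$k1
    filters[[paste0("k2_", b)]] <- result$bases[[b]]$filters$k2
  }
  write_filters_csv(filters, file.path(out_dir, "filters.csv"),
                    dt = result$trace$dt)
  jw(list(label = result$classification$label,
          k1_source = result$classification$k1_source,
          k2_source = result$classification$k2_source,
          fits = lapply(result$fits, fit_report),
          sta_difference_r2 = as.list(result$difference_r2)),
     "fits_and_classification.json")
  jw(manifest(result$config), "manifest.json")
  invisible(out_dir)
}

spectrum_report <- function(spec) {
  list(eigenvalues = spec$values,
       significant = spec$significant,
       n_sig_pos = spec$n_sig_pos,
       n_sig_neg = spec$n_sig_neg,
       n_spikes = spec$n_spikes,
       shuffle = if (!is.null(spec$shuffle))
         spec$shuffle[c("n_repeats", "ci", "seed", "tail")],
       eigenvectors = apply(spec$vectors, 2L, identity, simplify = FALSE))
}

fit_report <- function(fit) {
  list(alpha = as.list(fit$alpha), r2 = fit$r2,
       basis_contrast = fit$basis$source_contrast)
}

manifest <- function(config) {
  list(schema = "stcadapt/pipeline-manifest/1",
       stimulus = unclass(config$stimulus),
       model = config$model,
       model_params = if (!is.null(config$model_params))
         lapply(unclass(config$model_params), function(x) unname(x)),
       analysis = config[c("n_lags", "n_repeats", "ci", "tail",
                           "analysis_window", "train_fraction",
                           "model_seed", "analysis_seed",
                           "info_threshold")])
}
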