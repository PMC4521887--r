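#' Configuration of a contrast-alternating white-noise flicker stimulus
#'
#' Describes the spatially uniform Gaussian flicker used for contrast
#' adaptation experiments: intensity values are drawn at `update_rate` Hz
#' around a mean intensity `M`, with the contrast level `C = sigma/M`
#' alternating between episodes of high contrast (default 32%, 20 s) and low
#' contrast (default 12%, 100 s).
#'
#' @param mean_intensity Mean light intensity `M` (arbitrary intensity
#'   units; the default 39.5 corresponds to mW/m^2 in the photopic range).
#' @param contrast_low,contrast_high Contrast `C = sigma/M` of the low and
#'   high episodes (dimensionless, in (0, 1]; a contrast of exactly 0 is
#'   accepted only as a degenerate test case).
#' @param update_rate Stimulus update rate in Hz (default 30, i.e. bin width
#'   `dt = 1/30 s`).
#' @param episode_low_duration,episode_high_duration Episode durations in
#'   seconds; must be integer multiples of the bin width.
#' @param n_episode_pairs Number of high/low episode pairs.
#' @param seed Integer seed for the stimulus random stream.
#' @return An object of class `stim_config` (a named list).
#' @seealso [generate_stimulus()]
#' @export
stim_config <- function(mean_intensity = 39.5,
                        contrast_low = 0.12,
                        contrast_high = 0.32,
                        update_rate = 30,
                        episode_low_duration = 100,
                        episode_high_duration = 20,
                        n_episode_pairs = 10L,
                        seed = 1L) {
  if (contrast_low < 0 || contrast_high < 0 ||
      contrast_low > 1 || contrast_high > 1)
    stop("contrasts must lie in [0, 1]", call. = FALSE)
  if (episode_low_duration <= 0 || episode_high_duration <= 0)
    stop("episode durations must be positive", call. = FALSE)
  if (update_rate <= 0)
    stop("update_rate must be positive", call. = FALSE)
  if (n_episode_pairs < 1)
    stop("need at least one episode pair", call. = FALSE)
  dt <- 1 / update_rate
  for (d in c(episode_low_duration, episode_high_duration)) {
    nb <- d * update_rate
    if (abs(nb - round(nb)) > 1e-9)
      stop("episode durations must be integer multiples of the bin width",
           call. = FALSE)
  }
  structure(
    list(mean_intensity = mean_intensity,
         contrast_low = contrast_low,
         contrast_high = contrast_high,
         update_rate = update_rate,
         episode_low_duration = episode_low_duration,
         episode_high_duration = episode_high_duration,
         n_episode_pairs = as.integer(n_episode_pairs),
         seed = as.integer(seed)),
    class = "stim_config")
}

#' @export
print.stim_config <- function(x, ...) {
  cat("Contrast-alternating white-noise stimulus configuration\n")
  cat(sprintf("  contrast: high %.0f%% (%g s) / low %.0f%% (%g s), %d pairs\n",
              100 * x$contrast_high, x$episode_high_duration,
              100 * x$contrast_low, x$episode_low_duration,
              x$n_episode_pairs))
  cat(sprintf("  update rate: %g Hz (dt = %.4g ms), mean intensity %g, seed %d\n",
              x$update_rate, 1000 / x$update_rate, x$mean_intensity, x$seed))
  invisible(x)
}

#' Generate a contrast-alternating white-noise stimulus trace
#'
#' Draws independent Gaussian contrast values (deviation from the mean light
#' intensity divided by the mean, so the per-bin standard deviation equals
#' the episode contrast) for an alternating schedule of high- and
#' low-contrast episodes. One episode pair is a high-contrast episode
#' followed by a low-contrast episode.
#'
#' @param config A [stim_config()] object.
#' @return An object of class `stim_trace`: a list with elements
#'   `samples` (contrast-valued sequence, one value per bin), `episode`
#'   (integer episode index per bin), `label` (factor `"high"`/`"low"` per
#'   bin), `dt` (bin width in s), `norm_sd` (per-label scale currently
#'   divided out; 1 for a raw trace) and `config`.
#' @examples
#' tr <- generate_stimulus(stim_config(n_episode_pairs = 2, seed = 7))
#' table(tr$label)
#' @export
generate_stimulus <- function(config) {
  stopifnot(inherits(config, "stim_config"))
  n_high <- as.integer(round(config$episode_high_duration * config$update_rate))
  n_low <- as.integer(round(config$episode_low_duration * config$update_rate))
  n_pairs <- config$n_episode_pairs
  len <- rep(c(n_high, n_low), n_pairs)
  lab <- rep(rep(c("high", "low"), n_pairs), len)
  episode <- rep(seq_len(2L * n_pairs), len)
  sd_bin <- ifelse(lab == "high", config$contrast_high, config$contrast_low)
  samples <- with_local_seed(config$seed, stats::rnorm(length(lab), 0, sd_bin))
  structure(
    list(samples = samples,
         episode = episode,
         label = factor(lab, levels = c("high", "low")),
         dt = 1 / config$update_rate,
         norm_sd = c(high = 1, low = 1),
         config = config),
    class = "stim_trace")
}

# run expr under a local RNG seed without touching the caller's RNG state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.stim_trace <- function(x, ...) {
  cat(sprintf("White-noise stimulus trace: %d bins (%.1f s), %d episodes\n",
              length(x$samples), length(x$samples) * x$dt,
              max(x$episode)))
  cat(sprintf("  empirical SD: high %.4f, low %.4f (normalisation %s)\n",
              stats::sd(x$samples[x$label == "high"]),
              stats::sd(x$samples[x$label == "low"]),
              if (all(x$norm_sd == 1)) "raw" else "per-contrast"))
  invisible(x)
}

#' Normalize stimulus bins of one contrast condition to unit SD
#'
#' Spike-triggered analysis assumes a unit-variance white-noise prior, so
#' that the prior covariance matrix is the identity. This rescales all bins
#' carrying the requested contrast label by their empirical standard
#' deviation; the scale is retained in `norm_sd` so [denormalize_stimulus()]
#' can recover the raw trace.
#'
#' @param trace A `stim_trace`.
#' @param contrast_label `"high"`, `"low"`, or both (the default) to
#'   normalize each condition separately.
#' @return The trace with selected bins at unit empirical SD.
#' @export
normalize_per_contrast <- function(trace,
                                   contrast_label = c("high", "low")) {
  stopifnot(inherits(trace, "stim_trace"))
  contrast_label <- match.arg(contrast_label, several.ok = TRUE)
  for (lab in contrast_label) {
    sel <- trace$label == lab
    if (!any(sel)) stop("no bins with label '", lab, "'", call. = FALSE)
    s <- stats::sd(trace$samples[sel])
    if (s == 0) stop("zero variance in condition '", lab, "'", call. = FALSE)
    trace$samples[sel] <- trace$samples[sel] / s
    trace$norm_sd[lab] <- trace$norm_sd[lab] * s
  }
  trace
}

#' Undo per-contrast normalization
#'
#' @param trace A `stim_trace` previously passed through
#'   [normalize_per_contrast()].
#' @return The trace on the raw contrast scale.
#' @export
denormalize_stimulus <- function(trace) {
  stopifnot(inherits(trace, "stim_trace"))
  for (lab in names(trace$norm_sd)) {
    sel <- trace$label == lab
    trace$samples[sel] <- trace$samples[sel] * trace$norm_sd[[lab]]
    trace$norm_sd[lab] <- 1
  }
  trace
}

#' Bin ranges of every episode in a trace
#'
#' @param trace A `stim_trace`.
#' @return A data frame with one row per episode: `episode`, `label`,
#'   `first`, `last` (bin indices, inclusive).
#' @export
episode_table <- function(trace) {
  ep <- trace$episode
  first <- which(c(TRUE, diff(ep) != 0))
  last <- c(first[-1] - 1L, length(ep))
  data.frame(episode = ep[first],
             label = as.character(trace$label[first]),
             first = first, last = last,
             stringsAsFactors = FALSE)
}

#' Write / read a stimulus trace as CSV
#'
#' Columns: `bin_index`, `time_s`, `value`, `episode`, `contrast_label`.
#' The stimulus configuration can be stored alongside as a YAML key/value
#' file with [write_stim_config()].
#'
#' @param trace A `stim_trace`.
#' @param path File path.
#' @return `write_stimulus_csv` returns `path` invisibly;
#'   `read_stimulus_csv` returns a `stim_trace` (with `config = NULL` unless
#'   supplied).
#' @param config Optional [stim_config()] to attach on reading.
#' @export
write_stimulus_csv <- function(trace, path) {
  stopifnot(inherits(trace, "stim_trace"))
  df <- data.frame(bin_index = seq_along(trace$samples),
                   time_s = (seq_along(trace$samples) - 1) * trace$dt,
                   value = trace$samples,
                   episode = trace$episode,
                   contrast_label = as.character(trace$label))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path, config = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("bin_index", "time_s", "value", "episode", "contrast_label")
  if (!all(needed %in% names(df)))
    stop("stimulus CSV lacks required columns", call. = FALSE)
  dt <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else 1 / 30
  structure(
    list(samples = df$value,
         episode = as.integer(df$episode),
         label = factor(df$contrast_label, levels = c("high", "low")),
         dt = dt,
         norm_sd = c(high = 1, low = 1),
         config = config),
    class = "stim_trace")
}

#' @rdname write_stimulus_csv
#' @export
write_stim_config <- function(config, path) {
  stopifnot(inherits(config, "stim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(stim_config, vals)
}
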