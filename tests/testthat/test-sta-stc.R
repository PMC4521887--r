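test_that("STA is the count-weighted mean of spike-preceding windows", {
  tr <- generate_stimulus(stim_config(n_episode_pairs = 1, seed = 8))
  n <- length(tr$samples)
  # single spike: STA equals the stimulus window itself
  sp <- integer(n); sp[100] <- 1L
  sta <- compute_sta(tr, sp)
  expect_equal(as.numeric(sta), tr$samples[100 - 0:19], tolerance = 1e-14)

  # a double-count bin weighs its window twice
  sp2 <- integer(n); sp2[100] <- 2L; sp2[200] <- 1L
  sta2 <- compute_sta(tr, sp2)
  manual <- (2 * tr$samples[100 - 0:19] + tr$samples[200 - 0:19]) / 3
  expect_equal(as.numeric(sta2), manual, tolerance = 1e-14)

  # spikes without a full history are dropped; none usable is an error
  sp3 <- integer(n); sp3[5] <- 1L; sp3[100] <- 1L
  expect_equal(as.numeric(compute_sta(tr, sp3)),
               tr$samples[100 - 0:19], tolerance = 1e-14)
  expect_error(compute_sta(tr, sp3 * 0L), "no spike")
})

test_that("STA of stimulus-independent spikes obeys the CLT bound", {
  cfg <- stim_config(episode_high_duration = 17000, episode_low_duration = 1,
                     n_episode_pairs = 1, contrast_high = 1, seed = 14)
  tr <- generate_stimulus(cfg)  # 510k unit-SD bins
  set.seed(91)
  sp <- binned_spikes(stats::rpois(length(tr$samples), 0.2))
  sta <- compute_sta(tr, sp)
  n_spk <- attr(sta, "n_spikes")
  expect_gte(n_spk, 1e5)
  expect_lt(max(abs(as.numeric(sta))), 4 / sqrt(n_spk))
})

test_that("STC matches brute-force summation on a tiny example", {
  tr <- generate_stimulus(stim_config(n_episode_pairs = 1, seed = 2))
  tr$samples <- tr$samples[1:12]; tr$episode <- tr$episode[1:12]
  tr$label <- tr$label[1:12]
  spikes <- integer(12); spikes[c(3, 7, 11)] <- 1L
  st <- suppressWarnings(compute_stc(tr, spikes, n_lags = 2L))
  # explicit enumeration oracle
  W <- rbind(tr$samples[c(3, 2)], tr$samples[c(7, 6)], tr$samples[c(11, 10)])
  mu <- colMeans(W)
  C <- matrix(0, 2, 2)
  for (i in 1:3) C <- C + tcrossprod(W[i, ] - mu) / 3
  expect_equal(st$delta_c, C - diag(2), tolerance = 1e-12)
  expect_equal(sum(st$values), sum(diag(st$delta_c)), tolerance = 1e-12)
})

test_that("STC spectrum satisfies its linear-algebra invariants", {
  st <- fx_ln_spectrum()
  expect_equal(sum(st$values), sum(diag(st$delta_c)), tolerance = 1e-8)
  expect_lt(max(abs(crossprod(st$vectors) - diag(20))), 1e-8)
  expect_equal(st$values, sort(st$values, decreasing = TRUE))
  # Off-dominant sign convention
  ext <- apply(st$vectors, 2, function(v) v[which.max(abs(v))])
  expect_true(all(ext < 0))
  # the eigenbasis is complete: the STA reconstructs exactly
  recon <- st$vectors %*% crossprod(st$vectors, st$sta)
  expect_equal(drop(recon), st$sta, tolerance = 1e-10)
  expect_error(compute_stc(fx_ntrace(),
                           integer(length(fx_ntrace()$samples))),
               "rank deficient")
})

test_that("stimulus-independent spikes give a near-zero spectrum", {
  ntr <- fx_ntrace()
  set.seed(17)
  sp <- binned_spikes(stats::rpois(length(ntr$samples),
                                   0.06 * (ntr$label == "high")))
  st <- suppressWarnings(compute_stc(ntr, sp))
  expect_lt(max(abs(st$values)), 5 * sqrt(20 / st$n_spikes))
})

test_that("LN-Poisson control shows exactly one significant eigenvalue, negative", {
  sg <- suppressWarnings(
    test_significance(fx_ntrace(), fx_ln_high(), fx_ln_spectrum(),
                      n_repeats = 600, seed = 3))
  expect_equal(sg$n_sig_pos, 0L)
  expect_equal(sg$n_sig_neg, 1L)
  expect_true(sg$significant[20] && !any(sg$significant[1:19]))
})

test_that("latency-shift simulation yields a significant positive eigenvalue", {
  sp <- select_condition(fx_trace(), fx_latency(), "high")
  sg <- suppressWarnings(
    test_significance(fx_ntrace(), sp, n_repeats = 600, seed = 3))
  expect_gte(sg$n_sig_pos, 1L)
})

test_that("pre-shuffled spike trains pass the null calibration", {
  tr <- fx_trace(); ntr <- fx_ntrace()
  sp <- fx_ln_high()
  et <- episode_table(tr)
  ev <- spike_events(as.integer(sp))
  n_zero <- 0L
  for (s in 1:3) {
    set.seed(400 + s)
    lo <- pmax(et$first, 20L)[tr$episode[ev]]
    span <- et$last[tr$episode[ev]] - lo + 1L
    shuffled <- events_to_counts(lo + floor(stats::runif(length(ev)) * span),
                                 length(tr$samples))
    sg <- suppressWarnings(
      test_significance(ntr, shuffled, n_repeats = 500, seed = s))
    if (sg$n_sig_pos + sg$n_sig_neg == 0L) n_zero <- n_zero + 1L
  }
  expect_gte(n_zero, 2L)
})

test_that("second-half analysis window leaves eigenvalue counts intact", {
  tr <- fx_trace(); ntr <- fx_ntrace()
  fx_ln_high()
  sp_half <- select_condition(tr, fx$ln, "high", analysis_window = "second_half")
  expect_lt(sum(sp_half), sum(fx_ln_high()))
  sg_full <- suppressWarnings(
    test_significance(ntr, fx_ln_high(), n_repeats = 500, seed = 6))
  sg_half <- suppressWarnings(
    test_significance(ntr, sp_half, n_repeats = 500, seed = 6))
  n_full <- sg_full$n_sig_pos + sg_full$n_sig_neg
  n_half <- sg_half$n_sig_pos + sg_half$n_sig_neg
  expect_lte(abs(n_full - n_half), 1L)
})

test_that("spike-count matching discards surplus spikes reproducibly", {
  set.seed(31)
  a <- integer(500); a[sample.int(480, 90) + 20] <- 1L; a[30] <- 3L
  b <- integer(500); b[sample.int(480, 60) + 20] <- 1L
  expect_identical(match_spike_counts(a, a, seed = 1),
                   list(a = binned_spikes(a), b = binned_spikes(a)))
  m <- match_spike_counts(a, b, seed = 4)
  expect_equal(sum(m$a), sum(b))
  expect_equal(sum(m$b), sum(b))
  expect_true(all(as.integer(m$a) <= as.integer(a)))
  expect_identical(match_spike_counts(a, b, seed = 4)$a, m$a)
  expect_error(match_spike_counts(a, integer(500)), "non-empty")
})

test_that("identical conditions give a zero eigenvalue-count difference", {
  ntr <- fx_ntrace()
  sp <- fx_ln_high()
  d <- suppressWarnings(
    count_significant_delta(ntr, sp, sp, n_repeats = 400, seed = 5))
  expect_equal(d$delta_ev, 0L)
  expect_error(count_significant_delta(ntr, sp,
                                       integer(length(ntr$samples))),
               "must contain spikes")
})

test_that("nonlinearity estimation bins equally and recovers the generator", {
  tr <- fx_trace(); ntr <- fx_ntrace()
  # independent spikes: flat curve within sampling noise
  set.seed(23)
  flat_sp <- binned_spikes(stats::rpois(length(tr$samples), 0.1))
  nl <- estimate_nonlinearity(ntr, flat_sp, make_canonical_filter())
  expect_lte(diff(range(nl$n)), 1L)          # equal occupancy
  expect_true(all(diff(nl$generator) > 0))   # monotone bin centres
  se <- sqrt(mean(nl$rate) / (nl$n[1] * tr$dt))
  expect_lt(diff(range(nl$rate)), 6 * se)

  # threshold-linear LN model: supra-threshold branch is recovered
  nl2 <- estimate_nonlinearity(ntr, fx_ln_high(),
                               make_canonical_filter(),
                               contrast_label = "high")
  sd_raw <- stats::sd(tr$samples[tr$label == "high"])
  pred <- 20 * pmax(nl2$generator * sd_raw - 0.08, 0)
  sel <- pred > 2
  expect_lt(mean(abs(nl2$rate[sel] - pred[sel]) / pred[sel]), 0.2)
  expect_error(estimate_nonlinearity(ntr, flat_sp, rep(1, 20)),
               "unit-normalized")
})
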