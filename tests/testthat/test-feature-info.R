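test_that("feature information matches the closed-form Gaussian divergence", {
  # exponential-rate modulation along f makes the spike-conditional
  # projection N(1, 1) against an N(0, 1) prior: KL = 1/(2 ln 2) bits
  ntr <- fx_ntrace()
  f <- make_canonical_filter()
  g <- filter_stimulus(ntr$samples, f); g[is.na(g)] <- 0
  rate <- exp(g); rate <- rate / mean(rate) * 5
  set.seed(5)
  sp <- binned_spikes(stats::rpois(length(g), rate * ntr$dt))
  ci <- suppressWarnings(corrected_information(ntr, sp, f, seed = 6))
  expect_lt(abs(ci$bits - 1 / (2 * log(2))), 0.05)
  expect_true(ci$bias_corrected)
})

test_that("feature information is sign-invariant and zero for random spikes", {
  ntr <- fx_ntrace()
  sp <- fx_ln_high()
  f <- make_canonical_filter()
  i_pos <- suppressWarnings(feature_information(ntr, sp, f))
  i_neg <- suppressWarnings(feature_information(ntr, sp, -as.numeric(f)))
  expect_equal(i_pos$bits, i_neg$bits, tolerance = 1e-12)
  expect_gt(i_pos$bits, 0.5)  # the generating feature is informative

  set.seed(12)
  rnd <- binned_spikes(stats::rpois(length(ntr$samples), 0.05))
  raw <- suppressWarnings(feature_information(ntr, rnd, f))
  corrected <- suppressWarnings(corrected_information(ntr, rnd, f, seed = 2))
  expect_lt(corrected$bits, 0.02)
  expect_lt(corrected$bits, raw$bits)  # correction removes upward bias
  expect_error(feature_information(ntr, rnd, rep(0.5, 20)), "unit-norm")
})

test_that("halving the histogram bin width barely moves corrected values", {
  ntr <- fx_ntrace()
  sp <- fx_ln_high()
  f <- make_canonical_filter()
  i1 <- suppressWarnings(
    corrected_information(ntr, sp, f, bin_width = 0.1,
                          contrast_label = "high", seed = 1))$bits
  i2 <- suppressWarnings(
    corrected_information(ntr, sp, f, bin_width = 0.05,
                          contrast_label = "high", seed = 1))$bits
  expect_lt(abs(i2 - i1) / i1, 0.1)
})

test_that("two-feature information dominates marginals and ignores noise axes", {
  ntr <- fx_ntrace()
  sp <- fx_ln_high()
  k1 <- make_canonical_filter()
  k2 <- rep(0, 20); k2[c(15, 18)] <- c(1, -1) / sqrt(2)
  k2 <- k2 - sum(k2 * k1) * as.numeric(k1)
  k2 <- k2 / sqrt(sum(k2^2))
  j_raw <- suppressWarnings(two_feature_information(ntr, sp, k1, k2))
  m1_raw <- suppressWarnings(feature_information(ntr, sp, k1))
  expect_gte(j_raw$bits, m1_raw$bits - 0.05)  # joint dominates the marginal
  # after bias correction an irrelevant second axis adds nothing; the
  # joint histogram uses a coarser grid to keep its sampling bias linear
  j <- suppressWarnings(corrected_information(ntr, sp, list(k1, k2),
                                              bin_width = 0.2, seed = 3))
  m1 <- suppressWarnings(corrected_information(ntr, sp, k1,
                                               bin_width = 0.2, seed = 3))
  m2 <- suppressWarnings(corrected_information(ntr, sp, k2,
                                               bin_width = 0.2, seed = 3))
  expect_gte(j$bits, max(m1$bits, m2$bits) - 0.05)
  expect_lt(abs(j$bits - m1$bits), 0.2)
  expect_lt(m2$bits, 0.05)
  expect_error(two_feature_information(ntr, sp, k1, as.numeric(k1)),
               "orthogonal")
  # no modulation at all: zero bits
  none <- integer(length(ntr$samples)); none[30:40] <- 0L
  expect_equal(suppressWarnings(two_feature_information(ntr, none, k1,
                                                        k2))$bits, 0)
})

test_that("single-spike information handles flat, binary and rescaled rates", {
  expect_equal(single_spike_information(rep(4.2, 100))$bits, 0)
  two_level <- rep(c(0, 8), each = 50)
  expect_equal(single_spike_information(two_level)$bits, 1)
  expect_equal(single_spike_information(rep(two_level, each = 3))$bits, 1)
  expect_error(single_spike_information(rep(0, 10)), "all-zero")
  skewed <- c(rep(0, 75), rep(16, 25))  # p log p with p = 4
  expect_equal(single_spike_information(skewed)$bits, 2)
})

test_that("trial rate averages repeated spike trains", {
  sp <- list(c(0L, 2L, 1L), c(1L, 0L, 1L))
  r <- trial_rate(sp, dt = 1 / 30)
  expect_equal(as.numeric(r), c(0.5, 1, 1) * 30)
  expect_error(trial_rate(sp[1]), "2 trials")
})

test_that("bias correction extrapolates to infinite sample size", {
  fr <- c(0.8, 0.85, 0.9, 0.95, 1)
  flat <- bias_correct(fr, rep(1.3, 5))
  expect_equal(flat$bits, 1.3, tolerance = 1e-10)
  # synthetic info(N) = I_inf + c/N sampled at the standard fractions
  n_total <- 2000
  bits <- 0.9 + 35 / (fr * n_total)
  est <- bias_correct(fr, bits)
  expect_equal(est$bits, 0.9, tolerance = 1e-6)
  # negative intercepts are floored
  expect_equal(bias_correct(fr, -0.05 + 0.1 / fr)$bits, 0)
  expect_error(bias_correct(c(0.9, 1), c(1, 1)), "3 data fractions")
  expect_error(bias_correct(c(0.9, 0.95, 1), c(1, 1, 1)), "span")
})

test_that("plain LN information concentrates on the last eigenvector", {
  st <- fx_ln_spectrum()
  ntr <- fx_ntrace()
  sp <- fx_ln_high()
  info <- vapply(c(1, 19, 20), function(i)
    suppressWarnings(feature_information(ntr, sp, st$vectors[, i],
                                         contrast_label = "high"))$bits,
    numeric(1))
  expect_gt(info[3], 5 * info[2])
  expect_gt(info[3], 5 * info[1])
})

test_that("cell classification applies the QC and type rules", {
  base <- rep(0.05, 20)

  i1 <- base; i1[20] <- 1.4; i1[19] <- 0.9
  c1 <- classify_cell(i1)
  expect_equal(c1$label, "TypeI")
  expect_equal(c(c1$k1_source, c1$k2_source), c("v20", "v19"))

  i2 <- base; i2[1] <- 1.2; i2[20] <- 1.0
  c2 <- classify_cell(i2)
  expect_equal(c2$label, "TypeII")
  expect_equal(c(c2$k1_source, c2$k2_source), c("v1", "v20"))

  i3 <- base; i3[20] <- 1.1; i3[1] <- 0.5
  c3 <- classify_cell(i3)
  expect_equal(c3$label, "TypeIII")
  expect_equal(c(c3$k1_source, c3$k2_source), c("v20", "v1"))

  # QC: nothing informative enough
  expect_equal(classify_cell(base + 0.4)$label, "discarded")
  # QC: second-most informative in the bulk of the spectrum
  i4 <- base; i4[20] <- 1.2; i4[7] <- 0.9
  expect_equal(classify_cell(i4)$label, "discarded")
  # QC: most informative not at a spectrum end
  i5 <- base; i5[19] <- 1.2; i5[20] <- 0.9
  expect_equal(classify_cell(i5)$label, "TypeI")  # {v19, v20} is Type I
  i6 <- base; i6[19] <- 1.2; i6[1] <- 0.9
  expect_equal(classify_cell(i6)$label, "discarded")

  expect_error(classify_cell(c(1, NA, 0.2)), "complete")
})
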