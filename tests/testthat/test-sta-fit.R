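test_that("episode split is an 80/20 partition per contrast", {
  tr <- generate_stimulus(stim_config(n_episode_pairs = 5, seed = 4))
  sp <- simulate_ln(tr, seed = 1)
  s <- split_train_test(tr, sp, seed = 3)
  expect_length(s$train_episodes, 8)
  expect_length(s$test_episodes, 2)
  expect_setequal(c(s$train_episodes, s$test_episodes), 1:10)
  et <- episode_table(tr)
  for (lab in c("high", "low"))
    expect_equal(sum(et$episode[et$label == lab] %in% s$train_episodes), 4)
  expect_identical(as.integer(s$train) + as.integer(s$test), as.integer(sp))
  s2 <- split_train_test(tr, sp, seed = 3)
  expect_identical(s2$train_episodes, s$train_episodes)
  tr4 <- generate_stimulus(stim_config(n_episode_pairs = 4, seed = 4))
  expect_error(split_train_test(tr4, integer(length(tr4$samples))),
               "5 episodes")
})

test_that("least-squares STA fit matches the normal-equation oracle", {
  set.seed(77)
  k1 <- normalize_filter(rnorm(20))
  k2r <- rnorm(20); k2r <- k2r - sum(k2r * k1) * as.numeric(k1)
  k2 <- normalize_filter(k2r)
  basis <- feature_basis(list(k1 = as.numeric(k1), k2 = as.numeric(k2)))

  # member of the basis: exact weights and perfect fit
  f1 <- fit_sta(basis, k1)
  expect_equal(unname(f1$alpha), c(1, 0), tolerance = 1e-12)
  expect_equal(f1$r2, 1, tolerance = 1e-12)

  # orthogonal to the span and to the constant vector: nothing explained
  Q <- qr.Q(qr(cbind(as.numeric(k1), as.numeric(k2), 1, rnorm(20))))
  y <- normalize_filter(Q[, 4])
  f0 <- fit_sta(basis, y)
  expect_lt(abs(f0$r2), 1e-8)

  # random target: weights equal projections; brute-force normal equations
  z <- normalize_filter(rnorm(20))
  fz <- fit_sta(basis, z)
  expect_equal(unname(fz$alpha),
               c(sum(z * k1), sum(z * k2)), tolerance = 1e-10)
  A <- cbind(as.numeric(k1), as.numeric(k2))
  oracle <- solve(t(A) %*% A, t(A) %*% as.numeric(z))
  expect_equal(unname(fz$alpha), drop(oracle), tolerance = 1e-10)
  # orthonormal basis, zero-time-mean target: R^2 = alpha1^2 + alpha2^2
  zc <- normalize_filter(z - mean(z))
  fzc <- fit_sta(basis, zc)
  expect_equal(fzc$r2, sum(fzc$alpha^2), tolerance = 1e-10)

  expect_error(feature_basis(list(k1 = as.numeric(k1), k2 = as.numeric(k1))),
               "orthonormal")
  expect_error(fit_sta(feature_basis(list(k1 = as.numeric(k1),
                                          k2 = as.numeric(k1)),
                                     check_orthogonal = FALSE), z),
               "collinear")
  expect_error(fit_sta(basis, rnorm(20)), "unit-norm")
})

test_that("STA-difference R^2 follows its defining formula", {
  set.seed(13)
  k1 <- normalize_filter(rnorm(20))
  k2r <- rnorm(20); k2r <- k2r - sum(k2r * k1) * as.numeric(k1)
  k2 <- normalize_filter(k2r)
  basis <- feature_basis(list(k1 = as.numeric(k1), k2 = as.numeric(k2)))

  # both fits exact: perfect difference capture
  a <- normalize_filter(0.8 * as.numeric(k1) + 0.6 * as.numeric(k2))
  b <- normalize_filter(0.3 * as.numeric(k1) - 0.95 * as.numeric(k2))
  expect_equal(sta_difference_r2(fit_sta(basis, a), fit_sta(basis, b)), 1,
               tolerance = 1e-10)

  # random targets: direct re-evaluation of the formula
  y1 <- normalize_filter(rnorm(20)); y2 <- normalize_filter(rnorm(20))
  f1 <- fit_sta(basis, y1); f2 <- fit_sta(basis, y2)
  d <- as.numeric(y1) - as.numeric(y2)
  dh <- f1$fitted - f2$fitted
  direct <- 1 - sum((d - dh)^2) / sum((d - mean(d))^2)
  expect_equal(sta_difference_r2(f1, f2), direct, tolerance = 1e-12)

  # identical fitted difference with a mean-zero STA difference: baseline 0
  u <- rnorm(20); u <- u - mean(u)
  u <- u - sum(u * k1) * as.numeric(k1) - sum(u * k2) * as.numeric(k2)
  u <- u - mean(u)
  u <- u - sum(u * k1) * as.numeric(k1) - sum(u * k2) * as.numeric(k2)
  u <- u / sqrt(sum(u^2))
  y <- normalize_filter(as.numeric(k1))
  ydiff <- normalize_filter((as.numeric(k1) * sqrt(1 - sum((0.1 * u)^2)) +
                               0.1 * u))
  fh <- fit_sta(basis, ydiff); fl <- fit_sta(basis, y)
  # fits agree up to numerical noise; the unexplained difference is u
  expect_lt(abs(sta_difference_r2(fh, fl)), 0.05)

  other <- feature_basis(list(k1 = as.numeric(k2), k2 = as.numeric(k1)))
  expect_error(sta_difference_r2(f1, fit_sta(other, y2)), "same basis")
})

test_that("fitting with more significant features never lowers R^2", {
  st <- fx_ln_spectrum()
  ntr <- fx_ntrace()
  sta <- normalize_filter(compute_sta(ntr, fx_ln_high()))
  info <- vapply(1:20, function(i)
    suppressWarnings(feature_information(ntr, fx_ln_high(),
                                         st$vectors[, i],
                                         contrast_label = "high"))$bits,
    numeric(1))
  ord <- order(info, decreasing = TRUE)
  b2 <- feature_basis(list(k1 = st$vectors[, ord[1]],
                           k2 = st$vectors[, ord[2]]))
  b4 <- feature_basis(stats::setNames(
    lapply(ord[1:4], function(i) st$vectors[, i]), paste0("k", 1:4)))
  expect_gte(fit_sta(b4, sta)$r2, fit_sta(b2, sta)$r2 - 1e-10)
})

test_that("k-means separation recovers the two generating pathways", {
  tr <- fx_trace(); ntr <- fx_ntrace()
  tp <- fx_two_pathway()
  sp <- select_condition(tr, tp, "high")
  st <- suppressWarnings(compute_stc(ntr, sp))
  info <- vapply(1:20, function(i)
    suppressWarnings(feature_information(ntr, sp, st$vectors[, i],
                                         contrast_label = "high"))$bits,
    numeric(1))
  top <- order(info, decreasing = TRUE)[1:2]
  so <- split_on_off(ntr, sp, st$vectors[, top[1]], st$vectors[, top[2]],
                     seed = 5)

  # pathway filters match the generating On and Off filters
  off_f <- make_canonical_filter()
  expect_gt(cor(as.numeric(so$kOFF), as.numeric(off_f)), 0.9)
  expect_gt(cor(as.numeric(so$kON), as.numeric(on_filter_from(off_f))), 0.9)

  # cluster labels agree with the ground-truth spike sources
  on_true <- attr(tp, "on_counts"); off_true <- attr(tp, "off_counts")
  mask <- tr$label == "high"
  agree <- sum(pmin(as.integer(so$on_spikes), on_true * mask)) +
    sum(pmin(as.integer(so$off_spikes), off_true * mask))
  expect_gt(agree / (sum(so$on_spikes) + sum(so$off_spikes)), 0.95)

  # the full STA is the count-weighted mean of the cluster STAs
  w <- so$cluster_sizes
  recon <- (w[["on"]] * so$kON_raw + w[["off"]] * so$kOFF_raw) / sum(w)
  expect_equal(recon, so$sta_raw, tolerance = 1e-10)
  expect_equal(so$on_fraction, w[["on"]] / sum(w), tolerance = 1e-12)
  expect_error(split_on_off(ntr, integer(length(ntr$samples)),
                            st$vectors[, 1], st$vectors[, 2]),
               "at least 200")
})

test_that("Off-pathway reanalysis looks like a pure Off cell", {
  tr <- fx_trace(); ntr <- fx_ntrace()
  tp <- fx_two_pathway()
  sp <- select_condition(tr, tp, "high")
  st <- suppressWarnings(compute_stc(ntr, sp))
  info <- vapply(1:20, function(i)
    suppressWarnings(feature_information(ntr, sp, st$vectors[, i],
                                         contrast_label = "high"))$bits,
    numeric(1))
  top <- order(info, decreasing = TRUE)[1:2]
  so <- split_on_off(ntr, sp, st$vectors[, top[1]], st$vectors[, top[2]],
                     seed = 5)
  rr <- suppressWarnings(
    off_pathway_reanalysis(ntr, so$off_spikes, n_repeats = 400, seed = 5,
                           contrast_label = "high"))
  expect_equal(rr$spectrum$n_sig_pos, 0L)
  expect_gte(rr$spectrum$n_sig_neg, 1L)
  expect_gt(rr$fit$r2, 0.9)
  expect_error(off_pathway_reanalysis(ntr, integer(length(ntr$samples))),
               "empty Off cluster")
})
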