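test_that("make_basis_signal places resonances where asked", {
  sp <- to_spectrum(cr_only_basis())
  bin_ppm <- (1 / default_axis()$dwell_s) / 2048 / 400
  expect_close(sp$ppm[which.max(Mod(sp$values))], 3.027, tol = bin_ppm)
  # linearity: two peaks = sum of single-peak FIDs
  ax <- default_axis()
  p1 <- data.frame(ppm = 2.0, amp = 1, lw_hz = 8)
  p2 <- data.frame(ppm = 3.2, amp = 0.5, lw_hz = 10)
  expect_equal(make_basis_signal(rbind(p1, p2), ax)$samples,
               make_basis_signal(p1, ax)$samples +
                 make_basis_signal(p2, ax)$samples, tolerance = 1e-12)
  # phantom table: every resonance resolvable as a local maximum
  ph <- phantom_peak_table()
  sp <- to_spectrum(make_basis_signal(ph))
  mag <- Mod(sp$values)
  for (i in seq_len(nrow(ph))) {
    near <- which(abs(sp$ppm - ph$ppm[i]) < 0.05)
    j <- near[which.max(mag[near])]
    expect_true(mag[j] >= mag[j - 1] && mag[j] >= mag[j + 1],
                label = paste("local max at", ph$ppm[i], "ppm"))
  }
})

test_that("make_nuisance_peak matches its closed form", {
  ax <- small_axis(128L)
  expect_true(all(make_nuisance_peak(nuisance_params(0, 10, 50), ax)$samples
                  == 0))
  expect_equal(make_nuisance_peak(nuisance_params(1, 0, 0, 0), ax)$samples,
               rep(1 + 0i, 128L))
  set.seed(5)
  for (rep in 1:5) {
    p <- nuisance_params(runif(1, 0.1, 3), runif(1, 0, 200),
                         runif(1, -2000, 2000), runif(1, 0, 360))
    s <- make_nuisance_peak(p, ax)$samples
    t <- time_axis(ax)
    expect_equal(Mod(s), p$amp * exp(-p$damping * t), tolerance = 1e-12)
    # printed sign convention: phase decreases with +freq
    expect_equal(Arg(s[2] / s[1]),
                 mrsfpc:::wrap_deg((-2 * pi * p$freq_hz * t[2]) * 180 / pi) *
                   pi / 180,
                 tolerance = 1e-9)
  }
})

test_that("add_noise hits the target SNR and is Gaussian", {
  b <- make_basis_signal()
  # near-infinite SNR: output ~ input
  set.seed(6)
  x <- add_noise(b, 1e12)
  expect_lt(max(Mod(x$samples - b$samples)), 1e-9)
  expect_error(add_noise(b, -3), "target_snr")
  # round trip
  set.seed(7)
  est <- replicate(20, estimate_snr(add_noise(b, 15)))
  expect_lt(abs(mean(est) - 15) / 15, 0.15)
  # normality of the injected noise across seeds
  pvals <- sapply(1:100, function(sd) {
    set.seed(sd)
    noisy <- add_noise(b, 10)
    noise <- noisy$samples - b$samples
    min(stats::shapiro.test(Re(noise))$p.value,
        stats::shapiro.test(Im(noise))$p.value)
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("degenerate augmentation config reproduces the basis", {
  b <- make_basis_signal()
  cfg <- aug_config(amp_sd = 0, lw_mean_hz = 2, lw_sd_hz = 0,
                    freq_range_hz = 0, phase_range_deg = 0,
                    snr_range = c(Inf, Inf), p_lipid = 0, p_water = 0,
                    n_signals = 8L, split_fracs = c(1, 0, 0), seed = 1L)
  s <- make_simulated_set(b, cfg)
  expected <- normalize(apodize(b, 2))$samples
  for (j in 1:8)
    expect_equal(s$samples[, j], expected, tolerance = 1e-12)
  expect_true(all(s$label == "Free"))
  expect_true(all(s$true_freq_hz == 0))
})

test_that("simulated set has the stated label and shift distributions", {
  b <- make_basis_signal()
  cfg <- aug_config(n_signals = 1000L, seed = 42L)
  s <- make_simulated_set(b, cfg)
  # independent 0.5/0.5 coin flips: each label ~25% (+/- 5 points)
  props <- table(factor(s$label, levels = c("Free", "LC", "UW", "UW&LC"))) /
    1000
  expect_true(all(abs(props - 0.25) < 0.05))
  # uniform shift ground truth
  expect_gt(stats::ks.test(s$true_freq_hz, "punif", -20, 20)$p.value, 0.01)
  expect_gt(stats::ks.test(s$true_phase_deg, "punif", -90, 90)$p.value, 0.01)
  # splits follow the configured fractions
  expect_equal(as.integer(table(factor(s$split,
                                       c("train", "val", "test")))),
               c(900L, 90L, 10L))
  # reproducibility: same seed, identical bytes
  s2 <- make_simulated_set(b, cfg)
  expect_identical(s2$samples, s$samples)
  expect_identical(s2$label, s$label)
})

test_that("nuisance components agree with the labels", {
  b <- make_basis_signal()
  cfg <- aug_config(n_signals = 40L, seed = 9L)
  s <- make_simulated_set(b, cfg, keep_components = TRUE)
  diff <- attr(s, "pre_noise") - attr(s, "clean")
  has_nuis <- colSums(Mod(diff)) > 1e-9
  expect_identical(has_nuis, s$label != "Free")
  # water-only config labels everything UW
  cfg2 <- aug_config(n_signals = 12L, p_lipid = 0, p_water = 1, seed = 9L)
  s2 <- make_simulated_set(b, cfg2)
  expect_true(all(s2$label == "UW"))
})

test_that("ground truth is exact: truth-correction restores the Cr line", {
  b <- make_basis_signal()
  cfg <- aug_config(n_signals = 150L, split_fracs = c(1, 0, 0), seed = 10L)
  s <- make_simulated_set(b, cfg)
  lw_corrected <- cr_linewidth(truth_correct(s))
  lw_expected <- cr_linewidth(mrs_set(matrix(apodize(b, 2)$samples,
                                             ncol = 1), b$axis))
  expect_close(lw_corrected, lw_expected, tol = 0.5)
  # misaligned average is much broader
  expect_gt(cr_linewidth(s), lw_corrected + 5)
})

test_that("phantom set drifts smoothly within the stated SNR range", {
  b <- make_basis_signal(phantom_peak_table())
  cfg <- aug_config(snr_range = c(7, 70), seed = 12L)
  s <- make_phantom_set(b, n = 200L, cfg = cfg)
  expect_true(all(s$snr_nominal >= 7 & s$snr_nominal <= 70))
  drift <- attr(s, "drift_hz")
  span <- max(drift) - min(drift)
  expect_close(span, cfg$drift_span_hz, tol = 1e-6)
  expect_lt(max(abs(diff(drift))), 0.1 * span)
  # degenerate: no drift, no randomness -> identical normalized copies
  cfg0 <- aug_config(lw_sd_hz = 0, freq_range_hz = 0, phase_range_deg = 0,
                     snr_range = c(Inf, Inf), drift_span_hz = 0, seed = 1L)
  s0 <- make_phantom_set(b, n = 5L, cfg = cfg0)
  for (j in 2:5) expect_equal(s0$samples[, j], s0$samples[, 1],
                              tolerance = 1e-12)
})
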