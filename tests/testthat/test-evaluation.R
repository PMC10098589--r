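test_that("accuracy_precision computes wrapped error statistics", {
  est <- data.frame(freq_hz = c(1, 2, 3), phase_deg = c(10, 20, 30))
  ap <- accuracy_precision(est, c(1, 2, 3), c(10, 20, 30))
  expect_equal(unlist(ap[c("mean_f", "sd_f", "mean_phi", "sd_phi")]),
               c(mean_f = 0, sd_f = 0, mean_phi = 0, sd_phi = 0))
  # errors {-1, +1}: mean 0, sample SD sqrt(2)
  est2 <- data.frame(freq_hz = c(-1, 1), phase_deg = c(-1, 1))
  ap2 <- accuracy_precision(est2, c(0, 0), c(0, 0))
  expect_equal(ap2$mean_f, 0)
  expect_equal(ap2$sd_f, sqrt(2))
  # phase wrap: 179 vs -179 is a 2-degree error, not 358
  ap3 <- accuracy_precision(data.frame(freq_hz = 0, phase_deg = c(179, 0)),
                            c(0, 0), c(-179, 0))
  expect_equal(ap3$errors$phase_deg[1], -2)
  # reference shift subtraction for relative methods
  ap4 <- accuracy_precision(data.frame(freq_hz = c(0, 5),
                                       phase_deg = c(0, 10)),
                            c(3, 8), c(20, 30), ref_truth = c(3, 20))
  expect_equal(ap4$mean_f, 0)
  expect_equal(ap4$mean_phi, 0)
  expect_error(accuracy_precision(data.frame(freq_hz = numeric(),
                                             phase_deg = numeric()),
                                  numeric(), numeric()), "no estimates")
})

test_that("similarity index is 1 for identical sets and 0 at 90 degrees", {
  b <- make_basis_signal()
  s_id <- mrs_set(matrix(rep(b$samples, 4), ncol = 4), b$axis)
  expect_equal(similarity_index(s_id), 1, tolerance = 1e-12)
  # global 90-degree phase: Re<u, iu> = 0
  s90 <- mrs_set(cbind(b$samples, 1i * b$samples), b$axis)
  expect_lt(abs(similarity_index(s90)), 1e-12)
  # symmetry, boundedness, permutation invariance
  set.seed(40)
  cfg <- aug_config(n_signals = 12L, split_fracs = c(1, 0, 0), seed = 40L)
  s <- make_simulated_set(b, cfg)
  sm <- similarity_index(s, return_matrix = TRUE)
  expect_equal(sm$matrix, t(sm$matrix))
  expect_true(all(abs(sm$matrix) <= 1 + 1e-12))
  perm <- sample.int(12L)
  expect_equal(similarity_index(set_subset(s, perm)), sm$si,
               tolerance = 1e-12)
  # correcting by the true shifts increases the SI
  expect_gt(similarity_index(truth_correct(s)), sm$si)
})

test_that("cr_linewidth measures the FWHM of the averaged Cr peak", {
  b <- cr_only_basis(lw = 10)
  s1 <- mrs_set(matrix(b$samples, ncol = 1), b$axis)
  expect_close(cr_linewidth(s1), 10, tol = 0.2)
  # a set misaligned by +/-20 Hz is much broader than after correction
  set.seed(41)
  cfg <- aug_config(n_signals = 60L, p_lipid = 0, p_water = 0,
                    split_fracs = c(1, 0, 0), seed = 41L)
  s <- make_simulated_set(make_basis_signal(), cfg)
  expect_gt(cr_linewidth(s), cr_linewidth(truth_correct(s)) + 5)
  # empty spectrum: NaN sentinel with a warning
  z <- mrs_set(matrix(rep(0 + 0i, 2048 * 2), ncol = 2), b$axis)
  expect_warning(lw <- cr_linewidth(z), "peak|crossing")
  expect_true(is.nan(lw))
})

test_that("snr_sweep exposes the precision-versus-noise trend of SR", {
  b <- make_basis_signal()
  est_sr <- function(x) sr_align(x, b)
  tab <- snr_sweep(est_sr, b, n_levels = 20L, seed = 2L)
  expect_equal(nrow(tab), 20L)
  expect_true(all(diff(tab$snr) > 0))
  # errors at the noisiest levels dominate errors at the cleanest
  lo <- mean(abs(tab$freq_err_hz[1:5]))
  hi <- mean(abs(tab$freq_err_hz[16:20]))
  expect_gte(lo, hi)
  # near-noiseless limit: tiny error
  tab2 <- snr_sweep(est_sr, b, n_levels = 3L, snr_range = c(1e5, 1e6),
                    seed = 2L)
  expect_lt(max(abs(tab2$freq_err_hz)), 0.01)
  expect_lt(max(abs(tab2$phase_err_deg)), 0.1)
})

test_that("monte_carlo reproduces its own summary statistics", {
  b <- make_basis_signal()
  est_sr <- function(x) sr_align(x, b)
  # sigma -> 0 limit recovers the injected shift
  mc0 <- monte_carlo(est_sr, b, n = 1L, snr = 1e6, seed = 3L)
  expect_close(mc0$draws$freq_hz[1], 5, tol = 0.01)
  expect_close(mc0$draws$phase_deg[1], 45, tol = 0.1)
  mc <- monte_carlo(est_sr, b, n = 40L, snr = 15, seed = 3L)
  expect_equal(mc$summary$sd_f, stats::sd(mc$draws$freq_hz))
  expect_equal(mc$summary$mean_f, mean(mc$draws$freq_hz))
  # SR at SNR 15 keeps ~Hz-order frequency precision
  expect_lt(mc$summary$sd_f, 2)
})

test_that("bland_altman_r2 quantifies agreement", {
  set.seed(42)
  truth_f <- runif(50, -20, 20); truth_p <- runif(50, -90, 90)
  perfect <- data.frame(freq_hz = truth_f, phase_deg = truth_p)
  ba <- bland_altman_r2(perfect, truth_f, truth_p)
  expect_equal(ba$r2_freq, 1)
  expect_equal(ba$bias_f, 0)
  shifted <- data.frame(freq_hz = truth_f + 2, phase_deg = truth_p - 5)
  ba2 <- bland_altman_r2(shifted, truth_f, truth_p)
  expect_equal(ba2$r2_freq, 1)
  expect_equal(ba2$bias_f, 2)
  expect_equal(ba2$bias_phi, -5)
  # white-noise estimates carry no agreement
  noise <- data.frame(freq_hz = rnorm(500), phase_deg = rnorm(500))
  ba3 <- bland_altman_r2(noise, runif(500, -20, 20), runif(500, -90, 90))
  expect_lt(ba3$r2_freq, 0.1)
  expect_lt(ba3$r2_phase, 0.1)
  expect_error(bland_altman_r2(perfect, rep(1, 50), truth_p), "variance")
})

test_that("evaluation_report bundles the quality metrics", {
  set.seed(43)
  b <- make_basis_signal()
  cfg <- aug_config(n_signals = 25L, split_fracs = c(1, 0, 0), seed = 43L)
  s <- make_simulated_set(b, cfg)
  est <- data.frame(freq_hz = s$true_freq_hz, phase_deg = s$true_phase_deg)
  rep <- evaluation_report(s, truth_correct(s), est)
  expect_equal(rep$freq_precision_hz, 0)
  expect_gt(rep$si_after, rep$si_before)
  expect_equal(rep$r2_freq, 1)
  expect_true(is.finite(rep$cr_linewidth_hz))
})
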