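test_that("decoders match their closed forms to 1e-12", {
  ax <- small_axis(256L)
  t <- time_axis(ax)
  set.seed(30)
  x <- mrs_transient(complex(real = rnorm(256), imaginary = rnorm(256)), ax)
  p <- lorentzian_params(A_M = 0.7, d_M = 35, f_M = 650, phi_M = 0.4)
  got <- decode_lorentzian(p, x)$samples
  want <- 0.7 * exp(-35 * t) * exp(-1i * (2 * pi * 650 * t + 0.4)) +
    x$samples * exp(-500 * t)
  expect_lt(max(Mod(got - want)), 1e-12)
  # A_M = 0: pure apodized-input baseline
  p0 <- lorentzian_params(0, 35, 650, 0.4)
  expect_lt(max(Mod(decode_lorentzian(p0, x)$samples -
                    x$samples * exp(-500 * t))), 1e-15)
  # x = 0: pure Lorentzian magnitude
  z <- mrs_transient(rep(0 + 0i, 256), ax)
  expect_equal(Mod(decode_lorentzian(p, z)$samples), 0.7 * exp(-35 * t),
               tolerance = 1e-12)
  # reference-shift decoder
  ref <- cr_only_basis(ax)
  got2 <- decode_sr(12.5, -0.9, ref)$samples
  want2 <- ref$samples * exp(-1i * (2 * pi * 12.5 * t - 0.9))
  expect_lt(max(Mod(got2 - want2)), 1e-12)
  expect_equal(decode_sr(0, 0, ref)$samples, ref$samples)
  expect_equal(Mod(got2), Mod(ref$samples), tolerance = 1e-12)
  # modulation inverse: apply_shift with (+f, +phi) undoes the decoder
  back <- apply_shift(decode_sr(12.5, -0.9, ref), 12.5, -0.9 * 180 / pi)
  expect_lt(max(Mod(back$samples - ref$samples)), 1e-10)
  expect_error(decode_sr(1, 0, NULL), "reference")
})

test_that("latent gradients match central finite differences", {
  ax <- small_axis(128L)
  t <- time_axis(ax)
  set.seed(31)
  Xc <- matrix(complex(real = rnorm(256, 0, 0.3),
                       imaginary = rnorm(256, 0, 0.3)), 128, 2)
  env <- new.env()
  env$t <- t
  env$base_kernel <- exp(-500 * t)
  env$ref_mat <- matrix(cr_only_basis(ax)$samples, ncol = 1)
  W <- mrsfpc:::window_dft(ax, fit_window())$mat
  envW <- new.env()
  envW$t <- t; envW$base_kernel <- env$base_kernel
  envW$ref_mat <- env$ref_mat
  envW$W <- W; envW$WH <- Conj(t(W))
  for (variant in c("dCrR", "dCrRF", "dSR", "dSRF")) {
    e <- if (variant %in% c("dCrRF", "dSRF")) envW else env
    nz <- if (variant %in% c("dCrR", "dCrRF")) 4L else 2L
    z <- matrix(rnorm(nz * 2, 0, 0.5), nz, 2)
    res <- mrsfpc:::dae_batch(z, Xc, variant, e)
    h <- 1e-6
    for (i in seq_len(nz)) for (j in 1:2) {
      zp <- z; zp[i, j] <- zp[i, j] + h
      zm <- z; zm[i, j] <- zm[i, j] - h
      num <- (mrsfpc:::dae_batch(zp, Xc, variant, e)$loss -
              mrsfpc:::dae_batch(zm, Xc, variant, e)$loss) / (2 * h)
      denom <- max(abs(num), abs(res$dz[i, j]), 1e-8)
      expect_lt(abs(num - res$dz[i, j]) / denom, 1e-5)
    }
  }
})

test_that("the reconstruction loss behaves as an MSE should", {
  b <- truncate_fid(make_basis_signal(), 512L)
  expect_equal(dae_loss(b, b), 0)
  expect_equal(dae_loss(b, b, window = fit_window()), 0)
  # invariance of the time-domain loss under a common rigid shift
  xh <- apply_shift(b, 3, 20)
  l0 <- dae_loss(b, xh)
  expect_equal(dae_loss(apply_shift(b, 7, 55), apply_shift(xh, 7, 55)), l0,
               tolerance = 1e-10)
  # signals differing only outside the window have ~zero windowed loss:
  # add an on-grid complex exponential far from 2.5-3.5 ppm
  bin_hz <- (1 / b$axis$dwell_s) / b$axis$n_points
  f_out <- round(ppm_to_hz(1.0, b$axis) / bin_hz) * bin_hz
  t <- time_axis(b$axis)
  y <- b
  y$samples <- y$samples + 0.5 * exp(1i * 2 * pi * f_out * t)
  expect_gt(dae_loss(b, y), 1e-4)
  expect_lt(dae_loss(b, y, window = fit_window()), 1e-6)
})

test_that("training reduces the loss and is seed-deterministic", {
  set.seed(32)
  b <- make_basis_signal()
  cfg <- aug_config(n_signals = 180L, p_lipid = 0, p_water = 0,
                    split_fracs = c(0.8, 0.2, 0), seed = 32L)
  s <- make_simulated_set(b, cfg)
  tr <- set_subset(s, s$split == "train")
  va <- set_subset(s, s$split == "val")
  tc <- train_config(max_epochs = 5L, lr = 5e-4, seed = 3L)
  m1 <- train_dae("dCrR", tr, va, tc)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  # same seed + same data -> identical training history
  m2 <- train_dae("dCrR", tr, va, tc)
  expect_equal(m2$history$val_loss, m1$history$val_loss, tolerance = 1e-4)
})

test_that("early stopping halts a run that cannot improve", {
  b <- make_basis_signal()
  cfg <- aug_config(n_signals = 48L, p_lipid = 0, p_water = 0,
                    split_fracs = c(0.75, 0.25, 0), seed = 33L)
  s <- make_simulated_set(b, cfg)
  # learning rate so small that validation loss is flat
  tc <- train_config(max_epochs = 40L, lr = 1e-30, patience = 3L, seed = 3L)
  m <- train_dae("dSR", set_subset(s, s$split == "train"),
                 set_subset(s, s$split == "val"), tc,
                 ref = set_transient(s, 1L))
  expect_lte(nrow(m$history), 1L + 3L)
})

test_that("a trained dSR recovers shifts of noiseless reference copies", {
  set.seed(34)
  b <- make_basis_signal()
  n <- 360L
  fs <- runif(n, -20, 20); ps <- runif(n, -90, 90)
  s <- shifted_copy_set(b, fs, ps)
  tr <- set_subset(s, 1:320)
  va <- set_subset(s, 321:360)
  m <- train_dae("dSR", tr, va,
                 train_config(max_epochs = 110L, lr = 2e-3,
                              schedule = "cosine", seed = 4L),
                 ref = b)
  ests <- estimates_df(predict_shift(m, va))
  err_f <- ests$freq_hz - va$true_freq_hz
  err_p <- mrsfpc:::wrap_deg(ests$phase_deg - va$true_phase_deg)
  expect_lt(stats::sd(err_f), 0.5)
  expect_lt(stats::sd(err_p), 3)
  # self-consistency: the reference itself maps to ~(0, 0)
  e0 <- predict_shift(m, b)
  expect_lt(abs(e0$freq_hz), 1)
  expect_lt(abs(e0$phase_deg), 5)
  # evaluation-mode determinism and batch/single equivalence
  p1 <- encode(m, set_transient(va, 1L))
  p2 <- encode(m, set_transient(va, 1L))
  expect_identical(p1, p2)
  batch <- predict_shift(m, va)
  single <- predict_shift(m, set_transient(va, 3L))
  expect_equal(batch[[3]]$freq_hz, single$freq_hz, tolerance = 1e-10)
  expect_equal(batch[[3]]$phase_deg, single$phase_deg, tolerance = 1e-10)
})

test_that("untrained encoders emit finite latents in range", {
  set.seed(35)
  enc <- encoder_config(latent_dim = 4L)
  params <- mrsfpc:::nn_init(enc, c(0, 0, 6.7, 0))
  geo <- mrsfpc:::nn_geometry(enc)
  b <- truncate_fid(normalize(make_basis_signal()), 512L)
  z <- mrsfpc:::nn_forward(params, enc, geo,
                           mrsfpc:::as_channels(
                             matrix(b$samples, ncol = 1)))$z
  expect_true(all(is.finite(z)))
  p <- mrsfpc:::latent_map(z, "dCrR")
  expect_gte(p$A, 0)
  expect_gte(p$d, 0)
  # mismatched input length is rejected
  m_fake <- structure(list(variant = "dCrR", enc = enc, params = params,
                           axis = default_axis(), d_L = 500,
                           trained = FALSE),
                      class = "mrs_dae")
  expect_error(encode(m_fake, truncate_fid(b, 100L)), "shorter")
})

test_that("a model trained on mixed ON/OFF-like shapes corrects both", {
  set.seed(36)
  ax <- default_axis()
  on_basis <- make_basis_signal(axis = ax)   # edited-like
  off_tab <- default_peak_table()
  off_tab$amp[off_tab$name == "NAA"] <- 0.4  # unedited-like variant shape
  off_basis <- make_basis_signal(off_tab, ax)
  n <- 150L
  mk <- function(basis) {
    fs <- runif(n, -20, 20); ps <- runif(n, -90, 90)
    shifted_copy_set(basis, fs, ps)
  }
  s_on <- mk(on_basis); s_off <- mk(off_basis)
  mixed <- mrs_set(cbind(s_on$samples, s_off$samples), ax,
                   true_freq_hz = c(s_on$true_freq_hz, s_off$true_freq_hz),
                   true_phase_deg = c(s_on$true_phase_deg,
                                      s_off$true_phase_deg))
  perm <- sample.int(2L * n)
  mixed <- set_subset(mixed, perm)
  tr <- set_subset(mixed, 1:260)
  va <- set_subset(mixed, 261:300)
  m <- train_dae("dSR", tr, va,
                 train_config(max_epochs = 40L, lr = 2e-3,
                              schedule = "cosine", seed = 5L),
                 ref = on_basis)
  is_on <- perm <= n
  for (grp in list(which(is_on), which(!is_on))) {
    sub <- set_subset(mixed, grp[1:40])
    res <- dae_align_set(m, sub)
    expect_gt(similarity_index(res$set), similarity_index(sub))
  }
})
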