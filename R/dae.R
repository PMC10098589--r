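# Physics-informed autoencoder for FPC: a convolutional encoder maps a
# complex FID (2 real channels) to a handful of interpretable latent
# parameters; the decoder is an ANALYTIC signal model with no free
# parameters, so minimizing the reconstruction error makes the latent
# space the estimate itself.
#
# Variants:
#   dCrR  - decoder = Lorentzian creatine line + 500/s-apodized input
#           (baseline proxy); latent (A_M, d_M, f_M, phi_M); time-domain MSE.
#   dCrRF - same decoder, MSE on windowed spectra (2.5-3.5 ppm).
#   dSR   - decoder = reference FID modulated by e^{-i(2 pi f_M t + phi_M)};
#           latent (f_M, phi_M); time-domain MSE.
#   dSRF  - dSR with windowed spectral MSE.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

# Latent head maps (package design choice; keeps raw encoder outputs O(1)
# and encodes physical priors):
#   A_M   = softplus(z)                  -- nonnegative amplitude
#   d_M   = D_MIN + D_RANGE sigmoid(z)   -- damping bounded away from the
#            degenerate broad-line solution that would act as a baseline
#   f_M   = f_center + F_BOUND tanh(z)   -- the fitted line cannot lock
#            onto a neighbouring resonance outside +/-F_BOUND of its
#            nominal position (f_center = nominal Cr offset for the
#            Lorentzian variants, 0 for reference-shift variants)
#   phi_M = pi z                         -- unbounded phase (wrapped later)
D_MIN <- 10
D_RANGE <- 80
F_BOUND <- 45

#' Training configuration for the autoencoder
#'
#' Defaults are the published recipe: Adam, batch size 16, learning rate
#' 4e-5, up to 150 epochs with early stopping after 10 epochs without
#' validation improvement.
#'
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience (epochs).
#' @param seed integer RNG seed controlling initialization, dropout and
#'   shuffling.
#' @param schedule `"constant"` keeps `lr` fixed; `"cosine"` anneals it
#'   from `lr` to `lr / 20` over `max_epochs` (useful for short,
#'   scaled-down runs, where a flat small learning rate cannot both move
#'   quickly early and settle precisely late).
#' @param ema_decay per-step decay of a Polyak (exponential moving)
#'   average of the weights, maintained over the second half of training
#'   and used for the returned model; averaging suppresses the mini-batch
#'   noise floor that otherwise limits precision in short runs.  0
#'   disables it.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, lr = 4e-5, max_epochs = 150L,
                         patience = 10L, seed = 1L,
                         schedule = c("constant", "cosine"),
                         ema_decay = 0) {
  stopifnot(batch_size >= 1, lr > 0, max_epochs >= 1, patience >= 1,
            ema_decay >= 0, ema_decay < 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 schedule = match.arg(schedule), ema_decay = ema_decay),
            class = "train_config")
}

# elementwise EMA update over the (conv, fc) parameter tree
ema_update <- function(ema, params, decay) {
  walk <- function(e, p) {
    if (is.list(p)) {
      for (i in seq_along(p)) e[[i]] <- walk(e[[i]], p[[i]])
      e
    } else decay * e + (1 - decay) * p
  }
  walk(ema, params)
}

# learning rate for a given epoch under the configured schedule; a short
# linear warmup guards the high peak rates of compressed runs
epoch_lr <- function(cfg, epoch, warmup = 3L) {
  if (!identical(cfg$schedule, "cosine") || cfg$max_epochs <= 1)
    return(cfg$lr)
  if (epoch <= warmup && cfg$max_epochs > 2 * warmup)
    return(cfg$lr * epoch / warmup)
  e0 <- if (cfg$max_epochs > 2 * warmup) warmup else 0L
  lr_min <- cfg$lr / 20
  lr_min + 0.5 * (cfg$lr - lr_min) *
    (1 + cos(pi * (epoch - 1 - e0) / (cfg$max_epochs - 1 - e0)))
}

#' Lorentzian model-decoder parameters
#'
#' @param A_M amplitude (a.u., >= 0).
#' @param d_M damping in 1/s (>= 0); Lorentzian FWHM is `d_M / pi` Hz.
#' @param f_M resonance frequency in Hz (decoder convention
#'   \eqn{e^{-i 2\pi f_M t}}).
#' @param phi_M zero-order phase in radians.
#' @param d_L fixed kernel damping of the baseline term in 1/s (default
#'   500).
#' @return an object of class `lorentzian_params`.
#' @export
lorentzian_params <- function(A_M, d_M, f_M, phi_M, d_L = 500) {
  stopifnot(A_M >= 0, d_M >= 0)
  structure(list(A_M = A_M, d_M = d_M, f_M = f_M, phi_M = phi_M, d_L = d_L),
            class = "lorentzian_params")
}

#' Lorentzian model-decoder (creatine-referencing variants)
#'
#' Reconstructs
#' \eqn{\hat{x}(t) = A_M e^{-d_M t} e^{-i(2\pi f_M t + \phi_M)} +
#' x(t) e^{-d_L t}}: a single Lorentzian line plus the input apodized by a
#' broad Lorentzian kernel, which serves as a rough baseline estimate and
#' stops the fit from inflating the linewidth.
#'
#' @param p a [lorentzian_params()].
#' @param x the input [mrs_transient()] (supplies `x(t)` and the axis).
#' @return the reconstructed [mrs_transient()].
#' @export
decode_lorentzian <- function(p, x) {
  t <- time_axis(x$axis)
  m <- p$A_M * exp(-p$d_M * t) *
    complex(modulus = 1, argument = -(2 * pi * p$f_M * t + p$phi_M))
  x$samples <- m + x$samples * exp(-p$d_L * t)
  x
}

#' Reference-shift model-decoder (spectral-registration variants)
#'
#' Reconstructs \eqn{\hat{x}(t) = R(t) e^{-i(2\pi f_M t + \phi_M)}}: the
#' reference scan modulated by a unit-magnitude frequency/phase term.
#'
#' @param f_M frequency in Hz, `phi_M` phase in radians.
#' @param phi_M zero-order phase in radians.
#' @param ref the reference [mrs_transient()].
#' @return the reconstructed [mrs_transient()].
#' @export
decode_sr <- function(f_M, phi_M, ref) {
  if (is.null(ref)) stop("the reference-shift decoder needs a reference")
  t <- time_axis(ref$axis)
  ref$samples <- ref$samples *
    complex(modulus = 1, argument = -(2 * pi * f_M * t + phi_M))
  ref
}

#' Reconstruction loss
#'
#' Mean squared error between two equal-length complex signals: without a
#' window, over the time-domain samples (real and imaginary parts); with a
#' [fit_window()], over the complex spectra restricted to the window (the
#' "limited frequency range" loss of the F-variants).
#'
#' @param x,xhat [mrs_transient()]s on the same axis.
#' @param window optional [fit_window()].
#' @return scalar loss.
#' @export
dae_loss <- function(x, xhat, window = NULL) {
  stopifnot(x$axis$n_points == xhat$axis$n_points)
  if (is.null(window)) {
    r <- x$samples - xhat$samples
    mean(Re(r)^2 + Im(r)^2)
  } else {
    W <- window_dft(x$axis, window)$mat
    r <- W %*% (x$samples - xhat$samples)
    mean(Re(r)^2 + Im(r)^2)
  }
}

# normalize + truncate a set into the network input representation:
# complex matrix (input_len x n)
prep_inputs <- function(s, input_len) {
  stopifnot(input_len <= s$axis$n_points)
  X <- s$samples
  X <- sweep(X, 2, apply(Mod(X), 2, max), "/")
  X[seq_len(input_len), , drop = FALSE]
}

# complex matrix (len x n) -> flat real input matrix (2*len x n),
# channel fastest (row of sample p, channel c = (p-1)*2 + c)
as_channels <- function(Xc) {
  n <- nrow(Xc)
  out <- matrix(0, 2L * n, ncol(Xc))
  out[seq.int(1L, 2L * n, 2L), ] <- Re(Xc)
  out[seq.int(2L, 2L * n, 2L), ] <- Im(Xc)
  out
}

# map raw latents (latent_dim x B) to physical parameters
latent_map <- function(z, variant, f_center = 0) {
  if (is.null(f_center)) f_center <- 0
  if (variant %in% c("dCrR", "dCrRF"))
    list(A = softplus(z[1, ]), d = D_MIN + D_RANGE * sigmoid(z[2, ]),
         f = f_center + F_BOUND * tanh(z[3, ]), phi = pi * z[4, ])
  else
    list(f = f_center + F_BOUND * tanh(z[1, ]), phi = pi * z[2, ])
}

# decoder + loss + gradient wrt raw latents, vectorized over a batch.
# Xc: complex input matrix (len x B); env holds precomputed constants.
dae_batch <- function(z, Xc, variant, env) {
  B <- ncol(Xc)
  n <- nrow(Xc)
  p <- latent_map(z, variant, env$f_center)
  t <- env$t
  phase <- -(2 * pi * outer(t, p$f) + rep(p$phi, each = n))
  Emod <- complex(modulus = 1, argument = phase)
  if (variant %in% c("dCrR", "dCrRF")) {
    decay <- exp(-outer(t, p$d))
    M <- decay * Emod * rep(p$A, each = n)
    xhat <- M + Xc * env$base_kernel
  } else {
    M <- env$ref_mat[, rep(1L, B), drop = FALSE] * Emod
    xhat <- M
  }
  r <- xhat - Xc
  if (is.null(env$W)) {
    loss <- mean(Re(r)^2 + Im(r)^2)
    q <- r
    scale <- 2 / (n * B)
  } else {
    rw <- env$W %*% r
    loss <- mean(Re(rw)^2 + Im(rw)^2)
    q <- env$WH %*% rw
    scale <- 2 / (nrow(env$W) * B)
  }
  G <- Conj(q) * M
  gf <- scale * colSums(2 * pi * t * Im(G))
  gphi <- scale * colSums(Im(G))
  dz <- matrix(0, nrow(z), B)
  if (variant %in% c("dCrR", "dCrRF")) {
    gA <- scale * colSums(Re(G)) / p$A
    gd <- -scale * colSums(t * Re(G))
    sg <- sigmoid(z[2, ])
    dz[1, ] <- gA * sigmoid(z[1, ])
    dz[2, ] <- gd * D_RANGE * sg * (1 - sg)
    dz[3, ] <- F_BOUND * (1 - tanh(z[3, ])^2) * gf
    dz[4, ] <- pi * gphi
  } else {
    dz[1, ] <- F_BOUND * (1 - tanh(z[1, ])^2) * gf
    dz[2, ] <- pi * gphi
  }
  list(loss = loss, dz = dz)
}

# loss only (validation / monitoring)
dae_batch_loss <- function(z, Xc, variant, env) {
  dae_batch(z, Xc, variant, env)$loss
}

#' Train a physics-informed FPC autoencoder
#'
#' Unsupervised mini-batch training: each FID is encoded to the latent
#' parameters of the analytic decoder and the mean squared reconstruction
#' error (time-domain, or windowed-spectrum for the F-variants) is
#' minimized with Adam.  Early stopping monitors the validation loss; the
#' weights of the best validation epoch are returned.
#'
#' @param variant one of `"dCrR"`, `"dCrRF"`, `"dSR"`, `"dSRF"`.
#' @param trainset,valset [mrs_set()]s (the generator's `split` tags are
#'   NOT consulted; pass the subsets you want).
#' @param cfg a [train_config()].
#' @param ref reference [mrs_transient()], required for dSR/dSRF.
#' @param window [fit_window()] used by the F-variants (default
#'   2.5-3.5 ppm).
#' @param enc an [encoder_config()]; latent dimension is forced to match
#'   the variant.
#' @param d_L fixed baseline-kernel damping in 1/s (default 500).
#' @param verbose print one line per epoch.
#' @return an object of class `mrs_dae` (trained model state).
#' @export
train_dae <- function(variant = c("dCrR", "dCrRF", "dSR", "dSRF"),
                      trainset, valset, cfg = train_config(),
                      ref = NULL, window = fit_window(),
                      enc = NULL, d_L = 500, verbose = FALSE) {
  variant <- match.arg(variant)
  is_cr <- variant %in% c("dCrR", "dCrRF")
  windowed <- variant %in% c("dCrRF", "dSRF")
  if (!is_cr && is.null(ref))
    stop("variant ", variant, " requires a reference transient")
  set.seed(cfg$seed)

  if (is.null(enc))
    enc <- encoder_config(latent_dim = if (is_cr) 4L else 2L)
  if (enc$latent_dim != (if (is_cr) 4L else 2L))
    stop("encoder latent_dim does not match the variant")

  axis <- trainset$axis
  tax <- axis; tax$n_points <- enc$input_len
  t <- time_axis(tax)

  env <- new.env(parent = emptyenv())
  env$t <- t
  env$base_kernel <- exp(-d_L * t)
  if (!is_cr) {
    rr <- truncate_fid(normalize(ref), enc$input_len)
    env$ref_mat <- matrix(rr$samples, ncol = 1)
  }
  if (windowed) {
    env$W <- window_dft(tax, window)$mat
    env$WH <- Conj(t.default(env$W))
  } else env$W <- NULL

  # the f head is centred on the nominal Cr offset (decoder sign
  # convention) for Lorentzian variants, on 0 for reference-shift variants
  env$f_center <- if (is_cr) -ppm_to_hz(3.027, axis) else 0
  # warm-start head biases: a line of moderate amplitude and width (~30/s,
  # i.e. ~10 Hz) sitting at the centre of the frequency window
  head_bias <- if (is_cr) {
    c(softplus_inv(0.3), stats::qlogis((30 - D_MIN) / D_RANGE), 0, 0)
  } else c(0, 0)

  geo <- nn_geometry(enc)
  params <- nn_init(enc, head_bias)
  opt <- adam_init(params)

  Xtr <- prep_inputs(trainset, enc$input_len)
  Xva <- prep_inputs(valset, enc$input_len)
  n_tr <- ncol(Xtr)

  val_loss_of <- function(params) {
    tot <- 0; cnt <- 0
    idx <- seq_len(ncol(Xva))
    for (b in split(idx, ceiling(idx / 256))) {
      fw <- nn_forward(params, enc, geo, as_channels(Xva[, b, drop = FALSE]))
      tot <- tot + dae_batch_loss(fw$z, Xva[, b, drop = FALSE],
                                  variant, env) * length(b)
      cnt <- cnt + length(b)
    }
    tot / cnt
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  ema <- NULL
  ema_from <- ceiling(cfg$max_epochs / 2)
  for (epoch in seq_len(cfg$max_epochs)) {
    lr_now <- epoch_lr(cfg, epoch)
    perm <- sample.int(n_tr)
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      Xb <- Xtr[, b, drop = FALSE]
      fw <- nn_forward(params, enc, geo, as_channels(Xb), train = TRUE)
      bk <- dae_batch(fw$z, Xb, variant, env)
      if (!is.finite(bk$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      grads <- nn_backward(params, enc, geo, fw, bk$dz)
      up <- adam_step(params, grads, opt, lr = lr_now)
      params <- up$params; opt <- up$state
      if (cfg$ema_decay > 0 && epoch >= ema_from) {
        ema <- if (is.null(ema)) params
          else ema_update(ema, params, cfg$ema_decay)
      }
      ep_loss <- ep_loss + bk$loss * length(b)
    }
    ep_loss <- ep_loss / n_tr
    vl <- val_loss_of(if (is.null(ema)) params else ema)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss,
                                         val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.6g  val %.6g", epoch, ep_loss, vl))
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl,
                   params = if (is.null(ema)) params else ema,
                   epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }

  structure(list(variant = variant, enc = enc, params = best$params,
                 axis = axis, input_axis = tax, d_L = d_L,
                 f_center = env$f_center,
                 window = if (windowed) window else NULL,
                 reference = if (!is_cr) ref else NULL,
                 history = history, best_epoch = best$epoch,
                 train_cfg = cfg, trained = TRUE),
            class = "mrs_dae")
}

#' @export
print.mrs_dae <- function(x, ...) {
  cat(sprintf("<mrs_dae:%s> %strained, %d epochs (best %d), val loss %.4g\n",
              x$variant, if (x$trained) "" else "un",
              nrow(x$history), x$best_epoch,
              if (nrow(x$history)) min(x$history$val_loss) else NA))
  invisible(x)
}

#' Encode a transient into the latent model parameters
#'
#' Deterministic evaluation-mode forward pass (dropout off).
#'
#' @param m a trained `mrs_dae`.
#' @param x an [mrs_transient()] on the model's acquisition axis (longer
#'   FIDs are normalized then truncated to the network input length).
#' @return for Lorentzian variants a [lorentzian_params()]; for
#'   reference-shift variants a list `(f_M, phi_M)` (Hz, radians).
#' @export
encode <- function(m, x) {
  if (x$axis$n_points < m$enc$input_len)
    stop("input shorter than the network input length")
  xs <- normalize(x)$samples[seq_len(m$enc$input_len)]
  z <- nn_forward(m$params, m$enc, nn_geometry(m$enc),
                  as_channels(matrix(xs, ncol = 1)))$z
  p <- latent_map(z, m$variant, m$f_center)
  if (m$variant %in% c("dCrR", "dCrRF"))
    lorentzian_params(p$A, p$d, p$f, p$phi, d_L = m$d_L)
  else list(f_M = p$f, phi_M = p$phi)
}

#' Predict the frequency/phase shift of transients
#'
#' Runs the trained encoder and converts the latent parameters into a
#' [shift_estimate()] in the package-wide [apply_shift()] convention (so
#' that [correct()] undoes the shift):
#' reference-shift variants return the relative shift versus the
#' reference; Lorentzian variants return the absolute deviation of the
#' fitted creatine line from its nominal 3.027 ppm position.
#'
#' @param m a trained `mrs_dae`.
#' @param x an [mrs_transient()] or an [mrs_set()].
#' @param cr_ppm nominal creatine position for the Lorentzian variants.
#' @return a [shift_estimate()] (or a list of them for a set).
#' @export
predict_shift <- function(m, x, cr_ppm = 3.027) {
  if (inherits(x, "mrs_set")) {
    Xc <- prep_inputs(x, m$enc$input_len)
    geo <- nn_geometry(m$enc)
    idx <- seq_len(ncol(Xc))
    ests <- vector("list", ncol(Xc))
    for (b in split(idx, ceiling(idx / 256))) {
      z <- nn_forward(m$params, m$enc, geo,
                      as_channels(Xc[, b, drop = FALSE]))$z
      p <- latent_map(z, m$variant, m$f_center)
      est <- latent_to_shift(p, m, cr_ppm)
      for (i in seq_along(b))
        ests[[b[i]]] <- shift_estimate(est$f[i], est$phi[i],
                                       converged = m$trained,
                                       method = m$variant)
    }
    return(ests)
  }
  p <- encode(m, x)
  if (inherits(p, "lorentzian_params"))
    p <- list(A = p$A_M, d = p$d_M, f = p$f_M, phi = p$phi_M)
  est <- latent_to_shift(p, m, cr_ppm)
  shift_estimate(est$f, est$phi, converged = m$trained, method = m$variant)
}

# latent physical params -> shift in the apply_shift (+) convention.
# The decoders modulate with e^{-i(2 pi f_M t + phi_M)}, so an input
# shifted by (+df, +dphi) fits f_M = -df (+ nominal Cr offset for the
# Lorentzian variants) and phi_M = -dphi.
latent_to_shift <- function(p, m, cr_ppm) {
  if (m$variant %in% c("dCrR", "dCrRF")) {
    f <- -(p$f + ppm_to_hz(cr_ppm, m$axis))
  } else {
    f <- -p$f
  }
  list(f = f, phi = wrap_deg(-p$phi * 180 / pi))
}

#' Correct a whole set with a trained autoencoder
#'
#' @param m a trained `mrs_dae`.
#' @param s an [mrs_set()].
#' @return list with `set` (corrected) and `estimates`.
#' @export
dae_align_set <- function(m, s) {
  ests <- predict_shift(m, s)
  out <- s
  for (j in seq_len(length(s)))
    out$samples[, j] <- correct(set_transient(s, j), ests[[j]])$samples
  list(set = out, estimates = ests)
}
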