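# Minimal 1-D convolutional network with hand-written backprop.
#
# The encoder is small enough (6 conv blocks, kernel 3, stride 2, ReLU,
# one FC layer) that forward/backward can be expressed as row-index
# gathers (im2col) + BLAS matrix products; no autodiff framework is
# available or needed.  Layout conventions (all flat matrices, channel
# index fastest):
#   activations : matrix (channels * length, batch);
#                 row of sample p, channel c = (p - 1) * channels + c
#   im2col      : matrix (in_ch * kernel, out_len * batch), built by one
#                 precomputed row-gather from the zero-padded activations
#   conv weights: matrix (out_ch, in_ch * kernel), bias (out_ch)
#   fc weights  : matrix (latent_dim, features), bias (latent_dim)

#' Encoder architecture configuration
#'
#' Six strided convolution blocks (kernel 3, stride 2, zero padding 1,
#' ReLU) followed by a single fully connected layer mapping to the latent
#' heads.  Channel widths double per block.  Dropout acts on the input
#' layer during training only.
#'
#' @param input_len FID points fed to the network (default 512).
#' @param latent_dim 4 for Lorentzian-decoder variants (amplitude, damping,
#'   frequency, phase), 2 for reference-shift variants.
#' @param channels integer vector of per-block output channels.
#' @param kernel,stride convolution kernel size (odd) and stride.
#' @param dropout_p input dropout probability.
#' @param fc_hidden width of an optional hidden fully connected layer
#'   (with ReLU) between the flattened convolution features and the latent
#'   heads; 0 for a single direct FC layer.
#' @param input_gain fixed scalar applied to the encoder input channels
#'   (the decoder always sees the physical signal); lifts the small
#'   amplitudes of a normalized, decaying FID into a range where ReLU
#'   units switch.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(input_len = 512L, latent_dim = 4L,
                           channels = c(8L, 16L, 32L, 64L, 128L, 256L),
                           kernel = 3L, stride = 2L, dropout_p = 0.05,
                           fc_hidden = 0L, input_gain = 1) {
  stopifnot(latent_dim %in% c(2L, 4L), kernel >= 1, kernel %% 2 == 1,
            stride >= 1, dropout_p >= 0, dropout_p < 1,
            fc_hidden >= 0, input_gain > 0)
  pad <- kernel %/% 2L
  len <- input_len
  for (i in seq_along(channels)) {
    len <- (len + 2L * pad - kernel) %/% stride + 1L
    if (len < 1) stop("network depth too large for input_len")
  }
  structure(list(input_len = as.integer(input_len),
                 latent_dim = as.integer(latent_dim),
                 channels = as.integer(channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 dropout_p = dropout_p, out_len = as.integer(len),
                 fc_hidden = as.integer(fc_hidden),
                 input_gain = input_gain),
            class = "encoder_config")
}

# per-layer geometry: lengths, gather indices into the padded flat
# activation matrix, and the row range of the interior (non-pad) samples
nn_geometry <- function(cfg) {
  geo <- vector("list", length(cfg$channels))
  in_ch <- 2L
  L <- cfg$input_len
  pad <- cfg$kernel %/% 2L
  for (i in seq_along(cfg$channels)) {
    out_len <- (L + 2L * pad - cfg$kernel) %/% cfg$stride + 1L
    # padded position of (tap t, output o): p = stride*(o-1) + t,
    # 1..L+2*pad
    pos <- outer(seq_len(cfg$kernel), seq_len(out_len),
                 function(t, o) cfg$stride * (o - 1L) + t)
    idx <- as.vector(outer(seq_len(in_ch),
                           as.vector((pos - 1L) * in_ch), `+`))
    geo[[i]] <- list(in_ch = in_ch, out_ch = cfg$channels[i],
                     in_len = L, out_len = out_len, idx = idx,
                     interior = seq.int(in_ch * pad + 1L,
                                        in_ch * (L + pad)),
                     pad_rows = in_ch * (L + 2L * pad))
    L <- out_len
    in_ch <- cfg$channels[i]
  }
  geo
}

# He-initialized parameters; fc bias taken from `head_bias` (warm start)
nn_init <- function(cfg, head_bias = NULL) {
  geo <- nn_geometry(cfg)
  layers <- lapply(geo, function(g) {
    fan_in <- g$in_ch * cfg$kernel
    list(W = matrix(stats::rnorm(g$out_ch * fan_in, 0, sqrt(2 / fan_in)),
                    g$out_ch, fan_in),
         b = numeric(g$out_ch))
  })
  feat <- cfg$channels[length(cfg$channels)] * cfg$out_len
  if (is.null(head_bias)) head_bias <- numeric(cfg$latent_dim)
  stopifnot(length(head_bias) == cfg$latent_dim)
  if (cfg$fc_hidden > 0) {
    h <- cfg$fc_hidden
    list(conv = layers,
         fch = list(W = matrix(stats::rnorm(h * feat, 0, sqrt(2 / feat)),
                               h, feat),
                    b = numeric(h)),
         fc = list(W = matrix(stats::rnorm(cfg$latent_dim * h, 0, 0.01),
                              cfg$latent_dim, h),
                   b = as.numeric(head_bias)))
  } else {
    list(conv = layers,
         fc = list(W = matrix(stats::rnorm(cfg$latent_dim * feat, 0, 0.01),
                              cfg$latent_dim, feat),
                   b = as.numeric(head_bias)))
  }
}

# forward pass. X: matrix (2 * input_len, batch), channel fastest.
# Returns latent z (latent_dim x batch) and, if `train`, the caches needed
# for backprop (im2col matrices, relu masks, dropout mask).
nn_forward <- function(params, cfg, geo, X, train = FALSE) {
  B <- ncol(X)
  if (cfg$input_gain != 1) X <- X * cfg$input_gain
  cache <- if (train) vector("list", length(geo)) else NULL
  drop_mask <- NULL
  if (train && cfg$dropout_p > 0) {
    keep <- 1 - cfg$dropout_p
    drop_mask <- matrix(stats::rbinom(length(X), 1, keep) / keep,
                        nrow(X), B)
    X <- X * drop_mask
  }
  A <- X
  for (i in seq_along(geo)) {
    g <- geo[[i]]
    Ap <- matrix(0, g$pad_rows, B)
    Ap[g$interior, ] <- A
    col <- Ap[g$idx, , drop = FALSE]
    dim(col) <- c(g$in_ch * cfg$kernel, g$out_len * B)
    Y <- params$conv[[i]]$W %*% col + params$conv[[i]]$b
    mask <- Y > 0
    Y[!mask] <- 0
    if (train) cache[[i]] <- list(col = col, mask = mask)
    dim(Y) <- c(g$out_ch * g$out_len, B)
    A <- Y
  }
  hmask <- NULL
  flat <- A
  if (!is.null(params$fch)) {
    H <- params$fch$W %*% A + params$fch$b
    hmask <- H > 0
    H[!hmask] <- 0
    A <- H
  }
  z <- params$fc$W %*% A + params$fc$b
  list(z = z, flat = flat, hidden = if (is.null(hmask)) NULL else A,
       hmask = hmask, cache = cache, drop_mask = drop_mask)
}

# backward pass: dz (latent_dim x batch) -> gradients for all parameters
nn_backward <- function(params, cfg, geo, fw, dz) {
  B <- ncol(dz)
  grads <- list(conv = vector("list", length(geo)))
  if (!is.null(params$fch)) {
    grads$fc <- list(W = dz %*% t(fw$hidden), b = rowSums(dz))
    dH <- crossprod(params$fc$W, dz) * fw$hmask
    grads$fch <- list(W = dH %*% t(fw$flat), b = rowSums(dH))
    dA <- crossprod(params$fch$W, dH)              # features x B
  } else {
    grads$fc <- list(W = dz %*% t(fw$flat), b = rowSums(dz))
    dA <- crossprod(params$fc$W, dz)               # features x B
  }
  for (i in rev(seq_along(geo))) {
    g <- geo[[i]]
    dY <- dA
    dim(dY) <- c(g$out_ch, g$out_len * B)
    dY <- dY * fw$cache[[i]]$mask
    grads$conv[[i]] <- list(W = tcrossprod(dY, fw$cache[[i]]$col),
                            b = rowSums(dY))
    dcol <- crossprod(params$conv[[i]]$W, dY)
    dim(dcol) <- c(g$in_ch * cfg$kernel * g$out_len, B)
    rs <- rowsum(dcol, group = g$idx)              # scatter-add by target row
    dAp <- matrix(0, g$pad_rows, B)
    dAp[as.integer(rownames(rs)), ] <- rs
    dA <- dAp[g$interior, , drop = FALSE]
  }
  if (!is.null(fw$drop_mask)) dA <- dA * fw$drop_mask
  grads$input <- dA
  grads
}

# Adam optimizer state and update (standard bias-corrected moments)
adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 4e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {   # positional: conv is an unnamed list
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^state$t)
      vhat <- v / (1 - beta2^state$t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  # every named element of `params` carries weights; grads$input is not one
  r <- walk(params, grads[names(params)], state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
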