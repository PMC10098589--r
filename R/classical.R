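#' Spectral fit window
#'
#' The limited frequency range used by windowed methods; default 2.5-3.5
#' ppm brackets the creatine CH3 singlet.
#'
#' @param lo_ppm,hi_ppm window bounds, `lo_ppm < hi_ppm`.
#' @return an object of class `fit_window`.
#' @export
fit_window <- function(lo_ppm = 2.5, hi_ppm = 3.5) {
  if (!(lo_ppm < hi_ppm)) stop("lo_ppm must be < hi_ppm")
  structure(list(lo_ppm = lo_ppm, hi_ppm = hi_ppm), class = "fit_window")
}

# complex DFT rows for the bins of `window` on an axis of n points:
# returns list(mat = m x n complex matrix, ppm = bin positions)
window_dft <- function(axis, window) {
  f <- fft_freqs_hz(axis)
  ppm <- hz_to_ppm(f, axis)
  keep <- which(ppm >= window$lo_ppm & ppm <= window$hi_ppm)
  if (length(keep) == 0) stop("ppm window does not overlap the axis")
  keep <- keep[order(ppm[keep])]
  t <- time_axis(axis)
  mat <- exp(outer(f[keep], t, function(fr, tt) {
    complex(real = 0, imaginary = -2 * pi * fr * tt)
  }))
  list(mat = mat, ppm = ppm[keep])
}

#' Time-domain spectral registration (SR / SRF)
#'
#' Estimates the frequency and zero-order phase shift of `x` relative to
#' `ref` by nonlinear least squares: minimize
#' \eqn{\sum_k | x_k - ref_k e^{i(2\pi f t_k + \phi)} |^2}
#' over the first `max_points` samples.  With a `window` (the SRF variant)
#' the residual is instead the difference of the complex spectra of `x` and
#' the shifted reference restricted to the window.
#'
#' A derivative-based optimizer is multi-started over f in {-15, 0, 15} Hz
#' to escape the local minima that plain SR hits at large shifts, and the
#' frequency is box-constrained to `f_bound` (default +/-60 Hz): spectral
#' registration is a local alignment method, and letting the fit wander
#' hundreds of Hz (e.g. matching a residual-water peak of the input onto an
#' unrelated resonance of the reference) produces physically meaningless
#' shifts.
#'
#' @param x,ref [mrs_transient()]s sharing an axis.
#' @param window optional [fit_window()]; supplying it selects SRF.
#' @param max_points number of initial FID points used (default 512).
#' @param f_bound half-width (Hz) of the frequency search box.
#' @return a [shift_estimate()]; `freq_hz`/`phase_deg` are the shift OF `x`
#'   RELATIVE TO `ref` in the [apply_shift()] convention.
#' @export
sr_align <- function(x, ref, window = NULL, max_points = 512L,
                     f_bound = 60) {
  stopifnot(x$axis$n_points == ref$axis$n_points)
  m <- min(max_points, x$axis$n_points)
  xs <- x$samples[seq_len(m)]
  rs <- ref$samples[seq_len(m)]
  tax <- x$axis; tax$n_points <- m
  t <- time_axis(tax)

  if (is.null(window)) {
    obj <- function(p) {
      r <- xs - rs * complex(modulus = 1,
                             argument = 2 * pi * p[1] * t + p[2])
      sum(Re(r)^2 + Im(r)^2)
    }
    method_id <- "SR"
  } else {
    W <- window_dft(tax, window)$mat
    ux <- as.vector(W %*% xs)
    obj <- function(p) {
      u <- as.vector(W %*% (rs * complex(modulus = 1,
                                         argument = 2 * pi * p[1] * t + p[2])))
      r <- ux - u
      sum(Re(r)^2 + Im(r)^2)
    }
    method_id <- "SRF"
  }

  best <- NULL
  conv <- FALSE
  for (f0 in c(-15, 0, 15)) {
    fit <- tryCatch(
      stats::optim(c(f0, 0), obj, method = "L-BFGS-B",
                   lower = c(-f_bound, -pi), upper = c(f_bound, pi),
                   control = list(maxit = 500, factr = 10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence == 0
    }
  }
  if (is.null(best))
    return(shift_estimate(0, 0, converged = FALSE, method = method_id))
  shift_estimate(best$par[1], wrap_deg(best$par[2] * 180 / pi),
                 converged = conv, method = method_id)
}

#' Frequency-domain correlation alignment (Corr / CorrF)
#'
#' The frequency shift is the arg-max of the cross-correlation of the
#' magnitude spectra of `x` and `ref` (sub-bin resolution by three-point
#' parabolic interpolation); the phase is then read from the complex inner
#' product of the reference spectrum with the frequency-corrected spectrum.
#' With a `window` (CorrF) both steps are restricted to the window.
#'
#' @param x,ref [mrs_transient()]s sharing an axis.
#' @param window optional [fit_window()].
#' @return a [shift_estimate()] (shift of `x` relative to `ref`).
#' @export
corr_align <- function(x, ref, window = NULL) {
  stopifnot(x$axis$n_points == ref$axis$n_points)
  sx <- to_spectrum(x); sr <- to_spectrum(ref)
  if (!is.null(window)) {
    sx_w <- ppm_window(sx, window$lo_ppm, window$hi_ppm)
    sr_w <- ppm_window(sr, window$lo_ppm, window$hi_ppm)
  } else {
    sx_w <- sx; sr_w <- sr
  }
  a <- Mod(sx_w$values); b <- Mod(sr_w$values)
  if (sum(a) == 0 || sum(b) == 0) stop("flat spectrum: cannot correlate")

  # circular cross-correlation c(lag) = sum_i a(i + lag) b(i) via FFT
  n <- length(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / n
  lags <- seq_len(n) - 1L
  lags[lags >= n / 2] <- lags[lags >= n / 2] - n
  i0 <- which.max(cc)
  lag <- lags[i0]
  # parabolic sub-bin refinement on the wrapped neighbours
  im <- if (i0 == 1L) n else i0 - 1L
  ip <- if (i0 == n) 1L else i0 + 1L
  denom <- cc[im] - 2 * cc[i0] + cc[ip]
  delta <- if (denom != 0) 0.5 * (cc[im] - cc[ip]) / denom else 0
  bin_hz <- (1 / x$axis$dwell_s) / x$axis$n_points
  f_hat <- (lag + delta) * bin_hz

  xc <- apply_shift(x, -f_hat, 0)
  sxc <- to_spectrum(xc)
  if (!is.null(window)) sxc <- ppm_window(sxc, window$lo_ppm, window$hi_ppm)
  ph <- Arg(sum(Conj(sr_w$values) * sxc$values))
  shift_estimate(f_hat, wrap_deg(ph * 180 / pi), converged = TRUE,
                 method = if (is.null(window)) "Corr" else "CorrF")
}

#' Creatine referencing (CrR)
#'
#' Absolute FPC from a complex Lorentzian fit of the creatine CH3 singlet:
#' the windowed complex spectrum is fitted with
#' \eqn{A e^{i\phi} / (d + i 2\pi(\nu - \nu_0))} plus a complex linear
#' baseline; the frequency shift is the fitted line position minus the
#' nominal 3.027 ppm, the phase shift is the fitted phase.  The linear
#' parameters are profiled out by complex least squares; only
#' \eqn{(\nu_0, d)} are optimized, initialized at the window's magnitude
#' maximum.
#'
#' A second, narrower pass refits around the first-pass line position so
#' that neighbouring resonances (choline at 3.20 ppm) outside the refined
#' sub-window reduce to a near-linear background the baseline can absorb.
#'
#' @param x an [mrs_transient()].
#' @param window a [fit_window()] containing the Cr peak (default 2.5-3.5
#'   ppm).
#' @param cr_ppm nominal creatine position (default 3.027 ppm).
#' @param refine_hz half-width (Hz) of the second-pass sub-window; 0
#'   disables the refinement.
#' @return an absolute [shift_estimate()].
#' @export
cr_referencing <- function(x, window = fit_window(), cr_ppm = 3.027,
                           refine_hz = 45) {
  sp <- ppm_window(to_spectrum(x), window$lo_ppm, window$hi_ppm)
  nu_all <- ppm_to_hz(sp$ppm, x$axis)    # Hz offsets, ascending
  y_all <- sp$values

  fit_on <- function(nu, y, par0) {
    nu_c <- mean(nu)
    lin_fit <- function(nu0, d) {
      M <- cbind(1 / (d + 1i * 2 * pi * (nu - nu0)), 1 + 0i,
                 (nu - nu_c) + 0i)
      co <- tryCatch(qr.solve(M, y), error = function(e) rep(NA_complex_, 3))
      r <- y - as.vector(M %*% co)
      list(coef = co, rss = sum(Re(r)^2 + Im(r)^2))
    }
    fit <- tryCatch(
      stats::optim(par0, function(p) lin_fit(p[1], exp(p[2]))$rss,
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(nu0 = fit$par[1], d = exp(fit$par[2]),
         coef = lin_fit(fit$par[1], exp(fit$par[2]))$coef,
         ok = fit$convergence == 0)
  }

  par0 <- c(nu_all[which.max(Mod(y_all))], log(pi * 10))
  f1 <- fit_on(nu_all, y_all, par0)
  if (is.null(f1))
    return(shift_estimate(0, 0, converged = FALSE, method = "CrR"))
  best <- f1
  if (refine_hz > 0) {
    keep <- abs(nu_all - f1$nu0) <= refine_hz
    if (sum(keep) >= 8) {
      f2 <- fit_on(nu_all[keep], y_all[keep], c(f1$nu0, log(f1$d)))
      if (!is.null(f2)) best <- f2
    }
  }
  shift_estimate(best$nu0 - ppm_to_hz(cr_ppm, x$axis),
                 wrap_deg(Arg(best$coef[1]) * 180 / pi),
                 converged = best$ok && all(is.finite(Mod(best$coef))),
                 method = "CrR")
}

#' Undo an estimated shift
#'
#' Applies the negated estimate, the inverse of [apply_shift()].
#'
#' @param x an [mrs_transient()].
#' @param est a [shift_estimate()].
#' @return the corrected transient.
#' @export
correct <- function(x, est) {
  stopifnot(is.finite(est$freq_hz), is.finite(est$phase_deg))
  apply_shift(x, -est$freq_hz, -est$phase_deg)
}

#' Pick a reference transient by strategy
#'
#' @param s an [mrs_set()].
#' @param strategy `"first"`, `"median"` (transient closest to the median
#'   magnitude spectrum) or `"kmeans"` (see [select_reference()]).
#' @param seed seed forwarded to the k-means strategy.
#' @return index of the reference transient.
#' @export
pick_reference <- function(s, strategy = c("kmeans", "first", "median"),
                           seed = NULL) {
  strategy <- match.arg(strategy)
  switch(strategy,
    first = 1L,
    median = {
      mags <- Mod(apply(s$samples, 2, stats::fft))
      med <- apply(mags, 1, stats::median)
      which.min(colSums((mags - med)^2))
    },
    kmeans = select_reference(s, seed = seed)$index
  )
}

#' Align a whole set with one method
#'
#' Runs one FPC method over every transient of a set and corrects each by
#' its estimate.  Relative methods (SR, SRF, Corr, CorrF) align to a single
#' reference chosen by `ref_strategy`; CrR is absolute and ignores the
#' reference.  A failing transient is passed through uncorrected with
#' `converged = FALSE`.
#'
#' @param s an [mrs_set()].
#' @param method one of `"SR"`, `"SRF"`, `"Corr"`, `"CorrF"`, `"CrR"`.
#' @param ref_strategy `"kmeans"`, `"first"` or `"median"`.
#' @param window [fit_window()] for the windowed variants (default
#'   2.5-3.5 ppm).
#' @param max_points FID points used by SR/SRF.
#' @param seed seed for the k-means reference selection.
#' @return list with `set` (corrected [mrs_set()]), `estimates` (list of
#'   [shift_estimate()]), `ref_index` (`NA` for CrR).
#' @export
align_set <- function(s, method = c("SR", "SRF", "Corr", "CorrF", "CrR"),
                      ref_strategy = "kmeans", window = fit_window(),
                      max_points = 512L, seed = NULL) {
  method <- match.arg(method)
  n <- length(s)
  ref_index <- NA_integer_
  ref <- NULL
  if (method != "CrR") {
    ref_index <- pick_reference(s, ref_strategy, seed = seed)
    ref <- set_transient(s, ref_index)
  }
  ests <- vector("list", n)
  out <- s
  for (j in seq_len(n)) {
    x <- set_transient(s, j)
    est <- tryCatch(
      switch(method,
        SR = sr_align(x, ref, window = NULL, max_points = max_points),
        SRF = sr_align(x, ref, window = window, max_points = max_points),
        Corr = corr_align(x, ref, window = NULL),
        CorrF = corr_align(x, ref, window = window),
        CrR = cr_referencing(x, window = window)),
      error = function(e) shift_estimate(0, 0, converged = FALSE,
                                         method = method))
    ests[[j]] <- est
    if (is.finite(est$freq_hz) && is.finite(est$phase_deg))
      out$samples[, j] <- correct(x, est)$samples
  }
  list(set = out, estimates = ests, ref_index = ref_index)
}

#' Tabulate shift estimates
#'
#' @param estimates list of [shift_estimate()]s.
#' @return data.frame with columns `index`, `method`, `freq_hz`,
#'   `phase_deg`, `converged`.
#' @export
estimates_df <- function(estimates) {
  data.frame(
    index = seq_along(estimates),
    method = vapply(estimates, `[[`, "", "method"),
    freq_hz = vapply(estimates, `[[`, 0, "freq_hz"),
    phase_deg = vapply(estimates, `[[`, 0, "phase_deg"),
    converged = vapply(estimates, `[[`, TRUE, "converged")
  )
}
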