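#' Accuracy and precision of shift estimates
#'
#' Error = estimate - truth, per axis; phase errors are wrapped to
#' (-180, 180] before statistics.  Accuracy is the mean error, precision
#' the sample (n-1) standard deviation.  For relative methods the
#' reference transient's own true shift must first be subtracted from all
#' truths: pass it as `ref_truth` and the expected estimate becomes
#' `truth - ref_truth`.
#'
#' @param estimates list of [shift_estimate()]s or a data.frame with
#'   columns `freq_hz`, `phase_deg`.
#' @param truth_freq_hz,truth_phase_deg numeric vectors of true shifts.
#' @param ref_truth optional length-2 numeric `(freq_hz, phase_deg)` of the
#'   reference's own true shift.
#' @return list `(mean_f, sd_f, mean_phi, sd_phi, errors)`.
#' @export
accuracy_precision <- function(estimates, truth_freq_hz, truth_phase_deg,
                               ref_truth = NULL) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- estimates_df(estimates)
  n <- nrow(estimates)
  if (n == 0) stop("no estimates supplied")
  stopifnot(length(truth_freq_hz) == n, length(truth_phase_deg) == n)
  tf <- truth_freq_hz; tp <- truth_phase_deg
  if (!is.null(ref_truth)) {
    tf <- tf - ref_truth[1]
    tp <- tp - ref_truth[2]
  }
  ef <- estimates$freq_hz - tf
  ep <- wrap_deg(estimates$phase_deg - tp)
  list(mean_f = mean(ef), sd_f = stats::sd(ef),
       mean_phi = mean(ep), sd_phi = stats::sd(ep),
       errors = data.frame(freq_hz = ef, phase_deg = ep))
}

#' Similarity index of a transient set
#'
#' Each pair of transients contributes the real part of the normalized
#' complex scalar product of their spectra over a limited frequency range
#' (default 2.5-3.5 ppm); the similarity index is the mean of the
#' off-diagonal elements of this matrix.  Identical, perfectly aligned
#' spectra give SI = 1; a 90-degree relative phase gives 0.
#'
#' @param s an [mrs_set()] with >= 2 transients.
#' @param window a [fit_window()].
#' @param return_matrix also return the full similarity matrix.
#' @return the scalar SI, or `list(si, matrix)` if `return_matrix`.
#' @export
similarity_index <- function(s, window = fit_window(),
                             return_matrix = FALSE) {
  n <- length(s)
  if (n < 2) stop("similarity_index needs at least 2 transients")
  W <- window_dft(s$axis, window)$mat
  U <- W %*% s$samples                       # window bins x n
  nrm <- sqrt(colSums(Mod(U)^2))
  ok <- nrm > 0
  if (!all(ok)) {
    warning(sum(!ok), " transient(s) with zero windowed norm skipped")
    U <- U[, ok, drop = FALSE]; nrm <- nrm[ok]; n <- sum(ok)
    if (n < 2) stop("fewer than 2 nonzero transients in the window")
  }
  U <- sweep(U, 2, nrm, "/")
  E <- Re(Conj(t.default(U)) %*% U)
  si <- (sum(E) - sum(diag(E))) / (n * (n - 1))
  if (return_matrix) list(si = si, matrix = E) else si
}

#' Creatine linewidth of the averaged spectrum
#'
#' Averages all transients of the set, takes the magnitude spectrum,
#' locates the creatine peak near 3.027 ppm (largest magnitude in
#' 2.9-3.1 ppm by default) and measures its full width at half maximum via
#' linear interpolation of the half-maximum crossings.  The magnitude of a
#' complex Lorentzian is wider than its absorption mode by a factor
#' sqrt(3), so the measured width is divided by sqrt(3) to report the
#' conventional (absorption-mode) linewidth in Hz; phase errors across the
#' set cannot bias the peak location this way.  Misalignment across the
#' set broadens this line, so the linewidth is a ground-truth-free quality
#' measure.
#'
#' The averaged FID is zero-filled (8x) before the transform so that the
#' half-maximum crossings are found by interpolation on a fine grid.
#'
#' @param s an [mrs_set()].
#' @param search_ppm length-2 ppm range in which to look for the peak.
#' @param zerofill zero-filling factor for the interpolation grid.
#' @return linewidth in Hz, or `NaN` with a warning when no peak is found.
#' @export
cr_linewidth <- function(s, search_ppm = c(2.9, 3.1), zerofill = 8L) {
  pad_axis <- s$axis
  pad_axis$n_points <- s$axis$n_points * as.integer(zerofill)
  avg <- mrs_transient(c(rowMeans(s$samples),
                         rep(0 + 0i, pad_axis$n_points - s$axis$n_points)),
                       pad_axis)
  sp <- to_spectrum(avg)
  mag <- Mod(sp$values)
  in_win <- which(sp$ppm >= search_ppm[1] & sp$ppm <= search_ppm[2])
  if (length(in_win) == 0) { warning("no bins in search window"); return(NaN) }
  ipk <- in_win[which.max(mag[in_win])]
  if (ipk == 1L || ipk == length(mag)) { warning("peak at axis edge"); return(NaN) }
  if (mag[ipk] <= 0) { warning("no peak found in search window"); return(NaN) }
  half <- mag[ipk] / 2
  # walk outward to the half-maximum crossings
  iL <- ipk
  while (iL > 1 && mag[iL] > half) iL <- iL - 1
  iR <- ipk
  while (iR < length(mag) && mag[iR] > half) iR <- iR + 1
  if (mag[iL] > half || mag[iR] > half) {
    warning("half-maximum crossing not found"); return(NaN)
  }
  interp <- function(i0, i1) {
    # ppm where mag crosses `half` between bins i0 (below) and i1 (above)
    p0 <- sp$ppm[i0]; p1 <- sp$ppm[i1]
    m0 <- mag[i0]; m1 <- mag[i1]
    p0 + (half - m0) / (m1 - m0) * (p1 - p0)
  }
  ppm_l <- interp(iL, iL + 1L)
  ppm_r <- interp(iR, iR - 1L)
  w <- abs(ppm_r - ppm_l) * s$axis$f0_mhz / sqrt(3)
  if (!is.finite(w)) { warning("no well-defined peak width"); return(NaN) }
  w
}

#' Precision versus SNR sweep
#'
#' Shifts the basis signal by a fixed (frequency, phase) offset, then adds
#' one realization of complex Gaussian noise per level with linearly
#' increasing noise SD spanning the requested SNR range, and records each
#' estimator error.
#'
#' @param estimator function mapping an [mrs_transient()] to a
#'   [shift_estimate()] (wrap SR, the DAE, etc. in a closure).
#' @param basis noiseless basis [mrs_transient()].
#' @param freq_hz,phase_deg the injected shift (defaults 5 Hz, 45 deg).
#' @param n_levels number of SNR levels (default 20).
#' @param snr_range approximate SNR range covered (default 8-110).
#' @param seed RNG seed.
#' @return data.frame with columns `snr`, `sigma`, `freq_err_hz`,
#'   `phase_err_deg` in ascending SNR order.
#' @export
snr_sweep <- function(estimator, basis, freq_hz = 5, phase_deg = 45,
                      n_levels = 20L, snr_range = c(8, 110), seed = 1L) {
  set.seed(seed)
  shifted <- apply_shift(basis, freq_hz, phase_deg)
  s0 <- Mod(shifted$samples[1])
  sigmas <- seq(s0 / snr_range[2], s0 / snr_range[1], length.out = n_levels)
  out <- lapply(sigmas, function(sg) {
    x <- shifted
    x$samples <- x$samples +
      complex(real = stats::rnorm(length(x$samples), 0, sg),
              imaginary = stats::rnorm(length(x$samples), 0, sg))
    x <- normalize(x)
    est <- estimator(x)
    data.frame(snr = s0 / sg, sigma = sg,
               freq_err_hz = est$freq_hz - freq_hz,
               phase_err_deg = wrap_deg(est$phase_deg - phase_deg))
  })
  res <- do.call(rbind, out)
  res[order(res$snr), , drop = FALSE]
}

#' Monte Carlo study at fixed SNR
#'
#' Shifts the basis by a fixed offset and adds `n` independent noise
#' realizations with the same SD (targeting the given SNR); returns the
#' per-realization estimates and their summary.
#'
#' @inheritParams snr_sweep
#' @param n number of realizations (default 256).
#' @param snr target SNR (default 15).
#' @return list with `draws` (data.frame of estimates) and `summary`
#'   (mean/SD of frequency and phase estimates and errors).
#' @export
monte_carlo <- function(estimator, basis, freq_hz = 5, phase_deg = 45,
                        n = 256L, snr = 15, seed = 1L) {
  set.seed(seed)
  shifted <- apply_shift(basis, freq_hz, phase_deg)
  sg <- Mod(shifted$samples[1]) / snr
  draws <- lapply(seq_len(n), function(i) {
    x <- shifted
    x$samples <- x$samples +
      complex(real = stats::rnorm(length(x$samples), 0, sg),
              imaginary = stats::rnorm(length(x$samples), 0, sg))
    x <- normalize(x)
    est <- estimator(x)
    data.frame(freq_hz = est$freq_hz, phase_deg = est$phase_deg)
  })
  d <- do.call(rbind, draws)
  list(draws = d,
       summary = data.frame(
         mean_f = mean(d$freq_hz), sd_f = stats::sd(d$freq_hz),
         mean_phi = mean(wrap_deg(d$phase_deg)),
         sd_phi = stats::sd(wrap_deg(d$phase_deg)),
         mean_f_err = mean(d$freq_hz - freq_hz),
         mean_phi_err = mean(wrap_deg(d$phase_deg - phase_deg))))
}

#' Evaluate a trained model beyond its trained shift range
#'
#' Generates noisy transients with shifts drawn uniformly over an extended
#' box (default +/-40 Hz, +/-180 deg), predicts with the model, and
#' compares the precision of the errors inside versus outside the trained
#' box (default +/-20 Hz, +/-90 deg).
#'
#' @param m a trained `mrs_dae`.
#' @param basis noiseless basis [mrs_transient()].
#' @param f_range,phi_range half-ranges of the extended box.
#' @param n number of transients (default 400).
#' @param snr_range SNR range of the added noise.
#' @param trained_box length-2 `(f_half_range, phi_half_range)` of the
#'   training distribution.
#' @param lw_mean_hz,lw_sd_hz apodization distribution, as in training.
#' @param seed RNG seed.
#' @return list with per-region precision (`sd_f`, `sd_phi`), counts and
#'   the error table.
#' @export
beyond_range_eval <- function(m, basis, f_range = 40, phi_range = 180,
                              n = 400L, snr_range = c(9, 27),
                              trained_box = c(20, 90),
                              lw_mean_hz = 2, lw_sd_hz = 0.2, seed = 1L) {
  n <- as.integer(n)
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  t <- time_axis(basis$axis)
  np <- basis$axis$n_points
  fs <- stats::runif(n, -f_range, f_range)
  ps <- stats::runif(n, -phi_range, phi_range)
  samples <- matrix(complex(real = 0), np, n)
  for (j in seq_len(n)) {
    lw <- max(0, stats::rnorm(1, lw_mean_hz, lw_sd_hz))
    s <- basis$samples * exp(-pi * lw * t) *
      complex(modulus = 1, argument = 2 * pi * fs[j] * t + ps[j] * pi / 180)
    sg <- Mod(s[1]) / stats::runif(1, snr_range[1], snr_range[2])
    s <- s + complex(real = stats::rnorm(np, 0, sg),
                     imaginary = stats::rnorm(np, 0, sg))
    samples[, j] <- s / max(Mod(s))
  }
  set <- mrs_set(samples, basis$axis, true_freq_hz = fs, true_phase_deg = ps)
  ests <- estimates_df(predict_shift(m, set))
  ef <- ests$freq_hz - fs
  ep <- wrap_deg(ests$phase_deg - ps)
  inside <- abs(fs) <= trained_box[1] & abs(ps) <= trained_box[2]
  prec <- function(idx) if (sum(idx) >= 2)
    c(sd_f = stats::sd(ef[idx]), sd_phi = stats::sd(ep[idx]))
  else c(sd_f = NA_real_, sd_phi = NA_real_)
  list(inside = as.list(prec(inside)), outside = as.list(prec(!inside)),
       n_inside = sum(inside), n_outside = sum(!inside),
       errors = data.frame(freq_true = fs, phase_true = ps,
                           freq_err = ef, phase_err = ep,
                           inside = inside))
}

#' Agreement of estimates with truth
#'
#' Coefficient of determination (R squared) of the linear regression of
#' estimate on truth, per axis, plus the mean bias.
#'
#' @param estimates data.frame (or list of [shift_estimate()]) with
#'   `freq_hz`, `phase_deg`.
#' @param truth_freq_hz,truth_phase_deg true shifts (>= 3 points, nonzero
#'   variance).
#' @return list `(r2_freq, r2_phase, bias_f, bias_phi)`.
#' @export
bland_altman_r2 <- function(estimates, truth_freq_hz, truth_phase_deg) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- estimates_df(estimates)
  if (nrow(estimates) < 3) stop("need at least 3 points")
  if (stats::var(truth_freq_hz) == 0 || stats::var(truth_phase_deg) == 0)
    stop("zero-variance truths: R^2 undefined")
  # R^2 of a simple linear regression is the squared correlation
  r2 <- function(est, truth)
    if (stats::sd(est) == 0) 0 else stats::cor(est, truth)^2
  list(r2_freq = r2(estimates$freq_hz, truth_freq_hz),
       r2_phase = r2(estimates$phase_deg, truth_phase_deg),
       bias_f = mean(estimates$freq_hz - truth_freq_hz),
       bias_phi = mean(wrap_deg(estimates$phase_deg - truth_phase_deg)))
}

#' Assemble an evaluation report for one method
#'
#' Bundles precision/accuracy, similarity index before/after, creatine
#' linewidth and R-squared agreement into one machine-readable list.
#'
#' @param uncorrected,corrected [mrs_set()]s before and after FPC.
#' @param estimates the method's estimates (list or data.frame).
#' @param ref_truth optional reference true shift for relative methods.
#' @param window [fit_window()] for the SI.
#' @return a list of class `fpc_report`.
#' @export
evaluation_report <- function(uncorrected, corrected, estimates,
                              ref_truth = NULL, window = fit_window()) {
  ap <- accuracy_precision(estimates, uncorrected$true_freq_hz,
                           uncorrected$true_phase_deg, ref_truth = ref_truth)
  ba <- tryCatch(
    bland_altman_r2(estimates, uncorrected$true_freq_hz,
                    uncorrected$true_phase_deg),
    error = function(e) list(r2_freq = NA, r2_phase = NA,
                             bias_f = NA, bias_phi = NA))
  structure(list(
    freq_accuracy_hz = ap$mean_f, freq_precision_hz = ap$sd_f,
    phase_accuracy_deg = ap$mean_phi, phase_precision_deg = ap$sd_phi,
    si_before = similarity_index(uncorrected, window),
    si_after = similarity_index(corrected, window),
    cr_linewidth_hz = cr_linewidth(corrected),
    r2_freq = ba$r2_freq, r2_phase = ba$r2_phase), class = "fpc_report")
}

#' @export
print.fpc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<fpc_report> precision %.3f Hz / %.3f deg; accuracy %.3f Hz / ",
    "%.3f deg\n  SI %.3f -> %.3f; Cr linewidth %.2f Hz; R2 %.3f / %.3f\n"),
    x$freq_precision_hz, x$phase_precision_deg,
    x$freq_accuracy_hz, x$phase_accuracy_deg,
    x$si_before, x$si_after, x$cr_linewidth_hz, x$r2_freq, x$r2_phase))
  invisible(x)
}
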