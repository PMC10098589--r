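#' A single MRS transient (FID)
#'
#' One complex free-induction decay plus its acquisition axis, the optional
#' ground-truth frequency/phase offset (known for synthetic data), a
#' contamination label and a nominal SNR.
#'
#' @param samples complex vector of length `axis$n_points`.
#' @param axis an [mrs_axis()].
#' @param true_freq_hz,true_phase_deg ground-truth shift, `NA` if unknown.
#' @param label one of `"Free"`, `"LC"`, `"UW"`, `"UW&LC"`, `"unknown"`
#'   (lipid-contaminated, unstable-water, both).
#' @param snr_nominal nominal SNR injected by the generator, `NA` if unknown.
#' @return an object of class `mrs_transient`.
#' @export
mrs_transient <- function(samples, axis, true_freq_hz = NA_real_,
                          true_phase_deg = NA_real_, label = "unknown",
                          snr_nominal = NA_real_) {
  samples <- as.complex(samples)
  if (length(samples) != axis$n_points)
    stop("length(samples) must equal axis$n_points")
  label <- match.arg(label, transient_labels())
  structure(
    list(samples = samples, axis = axis,
         true_freq_hz = true_freq_hz, true_phase_deg = true_phase_deg,
         label = label, snr_nominal = snr_nominal),
    class = "mrs_transient"
  )
}

#' @export
print.mrs_transient <- function(x, ...) {
  cat(sprintf("<mrs_transient> %d pts, label %s, true shift (%s Hz, %s deg)\n",
              x$axis$n_points, x$label,
              format(x$true_freq_hz, digits = 4),
              format(x$true_phase_deg, digits = 4)))
  invisible(x)
}

#' Valid contamination labels
#' @return character vector of the five labels.
#' @export
transient_labels <- function() c("Free", "LC", "UW", "UW&LC", "unknown")

#' A set of transients sharing one acquisition axis
#'
#' Stored column-wise: `samples[, j]` is the j-th FID.  Per-transient
#' metadata (label, split, true shifts, nominal SNR) are parallel vectors.
#'
#' @param samples complex matrix, `n_points x n_signals`.
#' @param axis an [mrs_axis()].
#' @param label character vector of contamination labels.
#' @param split character vector, each `"train"`, `"val"` or `"test"`.
#' @param true_freq_hz,true_phase_deg numeric vectors of ground-truth shifts.
#' @param snr_nominal numeric vector of injected SNRs.
#' @return an object of class `mrs_set`.
#' @export
mrs_set <- function(samples, axis, label = NULL, split = NULL,
                    true_freq_hz = NULL, true_phase_deg = NULL,
                    snr_nominal = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "complex"
  dimnames(samples) <- NULL
  if (nrow(samples) != axis$n_points)
    stop("nrow(samples) must equal axis$n_points")
  n <- ncol(samples)
  fill <- function(x, default) {
    if (is.null(x)) rep(default, n)
    else if (length(x) == n) x
    else stop("metadata length must match the number of transients")
  }
  label <- fill(label, "unknown")
  stopifnot(all(label %in% transient_labels()))
  split <- fill(split, "train")
  stopifnot(all(split %in% c("train", "val", "test")))
  structure(
    list(samples = samples, axis = axis, label = label, split = split,
         true_freq_hz = fill(true_freq_hz, NA_real_),
         true_phase_deg = fill(true_phase_deg, NA_real_),
         snr_nominal = fill(snr_nominal, NA_real_)),
    class = "mrs_set"
  )
}

#' @export
length.mrs_set <- function(x) ncol(x$samples)

#' @export
print.mrs_set <- function(x, ...) {
  cat(sprintf("<mrs_set> %d transients x %d pts; labels: %s\n",
              length(x), x$axis$n_points,
              paste(names(table(x$label)), table(x$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Extract one transient from a set
#' @param s an [mrs_set()].
#' @param j index of the transient.
#' @return an [mrs_transient()].
#' @export
set_transient <- function(s, j) {
  mrs_transient(s$samples[, j], s$axis,
                true_freq_hz = s$true_freq_hz[j],
                true_phase_deg = s$true_phase_deg[j],
                label = s$label[j], snr_nominal = s$snr_nominal[j])
}

#' Subset an mrs_set
#' @param s an [mrs_set()].
#' @param idx integer or logical index of transients to keep.
#' @return an [mrs_set()].
#' @export
set_subset <- function(s, idx) {
  mrs_set(s$samples[, idx, drop = FALSE], s$axis,
          label = s$label[idx], split = s$split[idx],
          true_freq_hz = s$true_freq_hz[idx],
          true_phase_deg = s$true_phase_deg[idx],
          snr_nominal = s$snr_nominal[idx])
}

#' A shift estimate produced by any FPC method
#' @param freq_hz estimated frequency offset in Hz.
#' @param phase_deg estimated zero-order phase in degrees.
#' @param converged did the estimator converge.
#' @param method identifier of the producing method.
#' @return an object of class `shift_estimate`.
#' @export
shift_estimate <- function(freq_hz, phase_deg, converged = TRUE,
                           method = "unknown") {
  if (isTRUE(converged) && !(is.finite(freq_hz) && is.finite(phase_deg)))
    stop("a converged estimate must be finite")
  structure(list(freq_hz = freq_hz, phase_deg = phase_deg,
                 converged = converged, method = method),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate:%s> %.3f Hz, %.2f deg%s\n", x$method,
              x$freq_hz, x$phase_deg,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Normalize a transient to unit maximum magnitude
#'
#' Rescales the complex signal by the maximum of its magnitude so that
#' \eqn{\max_k |S(t_k)| = 1}.  Metadata are unchanged.  Idempotent.
#'
#' @param x an [mrs_transient()].
#' @return the rescaled transient.
#' @export
normalize <- function(x) {
  m <- max(Mod(x$samples))
  if (m == 0) stop("cannot normalize an all-zero signal")
  x$samples <- x$samples / m
  x
}

#' Apply a frequency and zero-order phase shift
#'
#' Multiplies the FID by \eqn{\exp(+i(2\pi f t_k + \phi))}.  The package-wide
#' sign convention: a positive `freq_hz` moves spectral peaks toward higher
#' Hz offset (higher ppm); `correct()` undoes an estimate by applying the
#' negated shift.  Recorded ground truth accumulates.
#'
#' @param x an [mrs_transient()].
#' @param freq_hz frequency shift in Hz.
#' @param phase_deg zero-order phase shift in degrees.
#' @return the shifted transient.
#' @export
apply_shift <- function(x, freq_hz, phase_deg) {
  stopifnot(is.finite(freq_hz), is.finite(phase_deg))
  t <- time_axis(x$axis)
  ph <- 2 * pi * freq_hz * t + phase_deg * pi / 180
  x$samples <- x$samples * complex(modulus = 1, argument = ph)
  x$true_freq_hz <- ifelse(is.na(x$true_freq_hz), freq_hz,
                           x$true_freq_hz + freq_hz)
  x$true_phase_deg <- ifelse(is.na(x$true_phase_deg), phase_deg,
                             x$true_phase_deg + phase_deg)
  x
}

#' Lorentzian apodization
#'
#' Multiplies the FID by \eqn{\exp(-\pi \cdot lw \cdot t_k)}, which broadens
#' every Lorentzian line by `lw_hz` (FWHM convention: a damping \eqn{d}
#' gives linewidth \eqn{d/\pi}).
#'
#' @param x an [mrs_transient()].
#' @param lw_hz added Lorentzian linewidth in Hz (>= 0).
#' @return the apodized transient.
#' @export
apodize <- function(x, lw_hz) {
  if (!is.finite(lw_hz) || lw_hz < 0) stop("lw_hz must be >= 0")
  x$samples <- x$samples * exp(-pi * lw_hz * time_axis(x$axis))
  x
}

#' Frequency-domain view of a transient
#'
#' Discrete Fourier transform of the FID with bins mapped to ppm through the
#' axis and reordered to ascending ppm.  A time-domain component
#' \eqn{e^{+i 2\pi f t}} appears at Hz offset \eqn{+f}, i.e. at
#' \eqn{ref_{ppm} + f / f0}.
#'
#' @param x an [mrs_transient()].
#' @return an object of class `mrs_spectrum` with fields `values` (complex)
#'   and `ppm` (ascending).
#' @export
to_spectrum <- function(x) {
  v <- stats::fft(x$samples)
  ppm <- hz_to_ppm(fft_freqs_hz(x$axis), x$axis)
  o <- order(ppm)
  structure(list(values = v[o], ppm = ppm[o]), class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d bins, %.2f..%.2f ppm\n",
              length(x$values), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Restrict a spectrum to a ppm window
#'
#' Keeps the contiguous bins with `lo_ppm <= ppm <= hi_ppm` (closed
#' interval).
#'
#' @param s an `mrs_spectrum`.
#' @param lo_ppm,hi_ppm window bounds in ppm, `lo_ppm < hi_ppm`.
#' @return the windowed `mrs_spectrum`.
#' @export
ppm_window <- function(s, lo_ppm, hi_ppm) {
  if (!(lo_ppm < hi_ppm)) stop("lo_ppm must be < hi_ppm")
  keep <- s$ppm >= lo_ppm & s$ppm <= hi_ppm
  if (!any(keep)) stop("ppm window does not overlap the spectrum axis")
  structure(list(values = s$values[keep], ppm = s$ppm[keep]),
            class = "mrs_spectrum")
}

#' Estimate the SNR of a transient
#'
#' SNR is defined as the magnitude of the FID at the time origin divided by
#' the noise standard deviation; the noise SD is estimated from the real
#' part of the last quarter of the FID, where the signal has decayed.
#'
#' @param x an [mrs_transient()] with at least 64 points.
#' @return estimated SNR; `Inf` when the tail is exactly constant.
#' @export
estimate_snr <- function(x) {
  n <- x$axis$n_points
  if (n < 64) stop("estimate_snr needs at least 64 points")
  tail_idx <- seq.int(n - floor(n / 4) + 1L, n)
  s <- stats::sd(Re(x$samples[tail_idx]))
  if (s == 0) return(Inf)
  Mod(x$samples[1]) / s
}

#' Truncate a transient to its initial points
#'
#' Noise dominates the late FID; estimation typically uses only the first
#' 512 points.  The dwell time is unchanged, so truncation coarsens spectral
#' resolution.
#'
#' @param x an [mrs_transient()].
#' @param n number of initial samples to keep (1 <= n <= n_points).
#' @return the truncated transient.
#' @export
truncate_fid <- function(x, n = 512L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > x$axis$n_points)
    stop("n must be in [1, n_points]")
  x$samples <- x$samples[seq_len(n)]
  x$axis$n_points <- n
  x
}

#' Read a single FID from a two-column CSV
#'
#' Plain-text reader for one FID: a CSV whose first two columns are the real
#' and imaginary parts, one row per time point.
#'
#' @param path CSV file path.
#' @param axis an [mrs_axis()] describing the acquisition; its `n_points`
#'   must match the row count.
#' @return an [mrs_transient()].
#' @export
read_fid_csv <- function(path, axis) {
  d <- data.table::fread(path)
  if (ncol(d) < 2) stop("FID csv needs two columns (real, imag)")
  if (nrow(d) != axis$n_points)
    stop("row count does not match axis$n_points")
  mrs_transient(complex(real = d[[1]], imaginary = d[[2]]), axis)
}

# wrap phases (degrees) to (-180, 180]
wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}
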