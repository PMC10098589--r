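#' Acquisition axis of an MRS transient
#'
#' Bundles the sampling parameters that define the time and frequency axes of
#' a free-induction decay (FID): number of complex points, dwell time,
#' spectrometer frequency and the chemical shift assigned to a frequency
#' offset of 0 Hz (the carrier, usually water at 4.7 ppm).
#'
#' The time axis is \eqn{t_k = k \cdot dwell_s, k = 0, \dots, n-1}.  The
#' ppm/Hz map is \eqn{ppm(f) = ref_{ppm} + f / f0_{MHz}}, so a resonance at
#' chemical shift \eqn{p} sits at the Hz offset \eqn{(p - ref_{ppm}) f0_{MHz}}.
#'
#' @param n_points number of complex samples (>= 2).
#' @param dwell_s sampling interval in seconds (> 0).
#' @param f0_mhz spectrometer frequency in MHz (> 0).
#' @param ref_ppm chemical shift (ppm) mapped to 0 Hz offset.
#' @return an object of class `mrs_axis`.
#' @export
mrs_axis <- function(n_points, dwell_s, f0_mhz, ref_ppm = 4.7) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) stop("n_points must be an integer >= 2")
  if (!is.finite(dwell_s) || dwell_s <= 0) stop("dwell_s must be > 0")
  if (!is.finite(f0_mhz) || f0_mhz <= 0) stop("f0_mhz must be > 0")
  structure(
    list(n_points = n_points, dwell_s = dwell_s,
         f0_mhz = f0_mhz, ref_ppm = ref_ppm),
    class = "mrs_axis"
  )
}

#' Default simulated acquisition axis
#'
#' 4400 Hz spectral width, 2048 complex points, 400 MHz spectrometer
#' frequency (9.4 T proton), water reference at 4.7 ppm — the acquisition
#' emulated by the synthetic generator.
#'
#' @return an `mrs_axis`.
#' @export
default_axis <- function() mrs_axis(2048L, 1 / 4400, 400, 4.7)

#' @export
print.mrs_axis <- function(x, ...) {
  cat(sprintf("<mrs_axis> %d pts, sw %.1f Hz, f0 %.1f MHz, ref %.2f ppm\n",
              x$n_points, 1 / x$dwell_s, x$f0_mhz, x$ref_ppm))
  invisible(x)
}

#' Time vector of an axis
#' @param axis an `mrs_axis`.
#' @return numeric vector \eqn{t_k = k \cdot dwell}, length `n_points`.
#' @export
time_axis <- function(axis) (seq_len(axis$n_points) - 1) * axis$dwell_s

#' Convert a chemical shift to a frequency offset
#' @param ppm chemical shift(s) in ppm.
#' @param axis an `mrs_axis`.
#' @return offset(s) in Hz relative to the carrier.
#' @export
ppm_to_hz <- function(ppm, axis) (ppm - axis$ref_ppm) * axis$f0_mhz

#' Convert a frequency offset to a chemical shift
#' @param hz offset(s) in Hz relative to the carrier.
#' @param axis an `mrs_axis`.
#' @return chemical shift(s) in ppm.
#' @export
hz_to_ppm <- function(hz, axis) axis$ref_ppm + hz / axis$f0_mhz

# Spectral bin frequencies in acquisition (FFT) order, Hz, wrapped to
# [-sw/2, sw/2).
fft_freqs_hz <- function(axis) {
  n <- axis$n_points
  sw <- 1 / axis$dwell_s
  f <- (seq_len(n) - 1) * sw / n
  f[f >= sw / 2] <- f[f >= sw / 2] - sw
  f
}
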