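#' Default metabolite peak table for the synthetic basis signal
#'
#' A parametric sum-of-Lorentzians stand-in for an averaged short-TE rodent
#' brain acquisition.  Positions are textbook singlet/centroid chemical
#' shifts; relative amplitudes give a dominant NAA peak and a clearly
#' dominant creatine CH3 singlet near 3 ppm so creatine-referencing methods
#' have a target.  Linewidths are a plausible 9.4 T in vivo shim.
#'
#' @return data.frame with columns `name`, `ppm`, `amp`, `lw_hz`.
#' @export
default_peak_table <- function() {
  data.frame(
    name  = c("NAA", "Glu", "Cr", "Cho", "mI", "Cr2"),
    ppm   = c(2.008, 2.35, 3.027, 3.20, 3.56, 3.913),
    amp   = c(1.00, 0.60, 0.80, 0.30, 0.50, 0.55),
    lw_hz = c(8, 10, 8, 8, 9, 8)
  )
}

#' Phantom peak table
#'
#' Relative amplitudes proportional to the metabolite concentrations of a
#' standard quality-assurance phantom (NAA 17.5, Glu 26.2, mI 17.5,
#' Cr 12.7, Tau 10.1 mmol/L), narrow lines.
#'
#' @return data.frame with columns `name`, `ppm`, `amp`, `lw_hz`.
#' @export
phantom_peak_table <- function() {
  data.frame(
    name  = c("NAA", "Glu", "mI", "Cr", "Tau", "Cr2"),
    ppm   = c(2.008, 2.35, 3.56, 3.027, 3.42, 3.913),
    amp   = c(17.5, 26.2, 17.5, 12.7, 10.1, 12.7) / 26.2,
    lw_hz = c(4, 5, 4.5, 4, 4.5, 4)
  )
}

#' Build a noiseless sum-of-Lorentzians basis FID
#'
#' \eqn{S(t) = \sum_j a_j e^{-\pi lw_j t} e^{+i 2\pi f(ppm_j) t}} where
#' \eqn{f(ppm)} is the Hz offset of the resonance on the given axis.
#'
#' @param peaks data.frame with columns `ppm`, `amp`, `lw_hz` (one row per
#'   resonance); defaults to [default_peak_table()].
#' @param axis an [mrs_axis()]; defaults to [default_axis()].
#' @return a noiseless [mrs_transient()] with `true_shift = (0, 0)` and
#'   label `"Free"`.
#' @export
make_basis_signal <- function(peaks = default_peak_table(),
                              axis = default_axis()) {
  stopifnot(nrow(peaks) >= 1, all(peaks$amp > 0), all(peaks$lw_hz > 0))
  t <- time_axis(axis)
  s <- complex(real = numeric(axis$n_points))
  for (j in seq_len(nrow(peaks))) {
    f <- ppm_to_hz(peaks$ppm[j], axis)
    s <- s + peaks$amp[j] * exp(-pi * peaks$lw_hz[j] * t) *
      complex(modulus = 1, argument = 2 * pi * f * t)
  }
  mrs_transient(s, axis, true_freq_hz = 0, true_phase_deg = 0,
                label = "Free")
}

#' Parameters of one nuisance peak
#'
#' A nuisance resonance (residual water or lipid) is a damped complex
#' exponential \eqn{A_a e^{-d_a t} e^{-i(2\pi f_a t + \phi_a)}}.  Note the
#' negative sign of the complex exponent: with the package's display
#' convention a peak intended at chemical shift `p` needs
#' `freq_hz = -ppm_to_hz(p, axis)`.
#'
#' @param amp amplitude \eqn{A_a \ge 0} (a.u.).
#' @param damping damping \eqn{d_a \ge 0} in 1/s (Lorentzian FWHM
#'   \eqn{d_a/\pi} Hz).
#' @param freq_hz precession frequency \eqn{f_a} in Hz.
#' @param phase_deg phase \eqn{\phi_a} in degrees.
#' @return an object of class `nuisance_params`.
#' @export
nuisance_params <- function(amp, damping, freq_hz, phase_deg = 0) {
  stopifnot(amp >= 0, damping >= 0)
  structure(list(amp = amp, damping = damping, freq_hz = freq_hz,
                 phase_deg = phase_deg), class = "nuisance_params")
}

#' Generate a nuisance-peak FID
#'
#' @param p a [nuisance_params()].
#' @param axis an [mrs_axis()].
#' @return an [mrs_transient()] holding only the nuisance component.
#' @export
make_nuisance_peak <- function(p, axis = default_axis()) {
  t <- time_axis(axis)
  s <- p$amp * exp(-p$damping * t) *
    complex(modulus = 1,
            argument = -(2 * pi * p$freq_hz * t + p$phase_deg * pi / 180))
  mrs_transient(s, axis)
}

#' Add complex Gaussian white noise at a target SNR
#'
#' Adds i.i.d. circular complex Gaussian noise with per-channel standard
#' deviation \eqn{|S(0)| / SNR_{target}} (SNR = time-origin magnitude over
#' noise SD).  Uses R's global RNG stream; seed upstream for
#' reproducibility.
#'
#' @param x an [mrs_transient()].
#' @param target_snr positive target SNR.
#' @return the noisy transient with `snr_nominal` set.
#' @export
add_noise <- function(x, target_snr) {
  if (!is.finite(target_snr) || target_snr <= 0)
    stop("target_snr must be > 0")
  n <- x$axis$n_points
  sigma <- Mod(x$samples[1]) / target_snr
  x$samples <- x$samples +
    complex(real = stats::rnorm(n, 0, sigma),
            imaginary = stats::rnorm(n, 0, sigma))
  x$snr_nominal <- target_snr
  x
}

#' Augmentation configuration for the synthetic sets
#'
#' Defaults are the stated in vivo-like simulation recipe: amplitude factor
#' N(1, 0.1); Lorentzian apodization with linewidth N(2, 0.2) Hz; frequency
#' offsets U(-20, 20) Hz; phase offsets U(-90, 90) degrees; noise to SNR
#' U(9, 27); independent lipid / unstable-residual-water nuisance peaks with
#' probability 0.5 each; 24000 signals split 90/9/1 into train/val/test.
#'
#' The nuisance distributions (their exact table is not public) are: lipid
#' at 1.3 ppm, linewidth U(20, 50) Hz, amplitude U(0.1, 0.5) x basis
#' maximum; residual water at 4.7 ppm with a per-transient U(-5, 5) Hz
#' position jitter ("unstable"), linewidth U(10, 30) Hz, amplitude
#' U(0.5, 2) x basis maximum, phase U(0, 360) degrees.
#'
#' @param amp_mean,amp_sd amplitude-factor distribution.
#' @param lw_mean_hz,lw_sd_hz apodization linewidth distribution (Hz).
#' @param freq_range_hz half-range of the uniform frequency offsets (Hz).
#' @param phase_range_deg half-range of the uniform phase offsets (deg).
#' @param snr_range length-2 ascending positive SNR range.
#' @param p_lipid,p_water independent nuisance probabilities in [0, 1].
#' @param n_signals number of transients to generate.
#' @param split_fracs length-3 train/val/test fractions summing to 1.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param lipid,water lists overriding the nuisance distributions
#'   (`ppm`, `lw_range`, `amp_range`, and for water `jitter_hz`).
#' @param drift_span_hz full span (Hz) of the phantom temperature-drift
#'   random walk.
#' @return an object of class `aug_config`.
#' @export
aug_config <- function(amp_mean = 1, amp_sd = 0.1,
                       lw_mean_hz = 2, lw_sd_hz = 0.2,
                       freq_range_hz = 20, phase_range_deg = 90,
                       snr_range = c(9, 27),
                       p_lipid = 0.5, p_water = 0.5,
                       n_signals = 24000L,
                       split_fracs = c(0.90, 0.09, 0.01),
                       seed = NULL,
                       lipid = list(ppm = 1.3, lw_range = c(20, 50),
                                    amp_range = c(0.1, 0.5)),
                       water = list(ppm = 4.7, jitter_hz = 5,
                                    lw_range = c(10, 30),
                                    amp_range = c(0.5, 2)),
                       drift_span_hz = 30) {
  stopifnot(p_lipid >= 0, p_lipid <= 1, p_water >= 0, p_water <= 1,
            length(snr_range) == 2, all(snr_range > 0),
            snr_range[1] <= snr_range[2],
            length(split_fracs) == 3, abs(sum(split_fracs) - 1) < 1e-8)
  structure(list(amp_mean = amp_mean, amp_sd = amp_sd,
                 lw_mean_hz = lw_mean_hz, lw_sd_hz = lw_sd_hz,
                 freq_range_hz = freq_range_hz,
                 phase_range_deg = phase_range_deg,
                 snr_range = snr_range, p_lipid = p_lipid,
                 p_water = p_water, n_signals = as.integer(n_signals),
                 split_fracs = split_fracs, seed = seed,
                 lipid = lipid, water = water,
                 drift_span_hz = drift_span_hz),
            class = "aug_config")
}

# uniform draw that tolerates a collapsed (or infinite) range
runif1 <- function(lo, hi) if (lo == hi) lo else stats::runif(1, lo, hi)

# draw one nuisance FID (complex vector) for a given spec entry
draw_nuisance <- function(spec, axis, jitter_hz = 0) {
  f_ppm_hz <- ppm_to_hz(spec$ppm, axis)
  if (jitter_hz > 0)
    f_ppm_hz <- f_ppm_hz + stats::runif(1, -jitter_hz, jitter_hz)
  lw <- stats::runif(1, spec$lw_range[1], spec$lw_range[2])
  amp <- stats::runif(1, spec$amp_range[1], spec$amp_range[2])
  ph <- stats::runif(1, 0, 360)
  # Eq-style negative exponent: peak lands at `ppm` when f_a = -offset
  p <- nuisance_params(amp = amp, damping = pi * lw,
                       freq_hz = -f_ppm_hz, phase_deg = ph)
  make_nuisance_peak(p, axis)$samples
}

#' Generate the simulated training/validation/test set
#'
#' Per transient, in order: scale the basis by an amplitude factor; add the
#' lipid and/or unstable-water nuisance peaks (independent coin flips,
#' setting the label Free / LC / UW / UW&LC); apodize; apply a random
#' frequency/phase shift (recorded as ground truth); add noise to a random
#' target SNR; normalize to unit maximum magnitude.  The set is then
#' shuffled and split into train/val/test.
#'
#' @param basis a noiseless basis [mrs_transient()], e.g.
#'   [make_basis_signal()].
#' @param cfg an [aug_config()].
#' @param keep_components if `TRUE`, attach attributes `pre_noise` (complex
#'   matrix of the signals before noise/normalization) and `clean`
#'   (the same signals without their nuisance component) for testing.
#' @return an [mrs_set()] with ground truth, labels, splits and nominal SNR.
#' @export
make_simulated_set <- function(basis, cfg = aug_config(),
                               keep_components = FALSE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  axis <- basis$axis
  n <- cfg$n_signals
  np <- axis$n_points
  t <- time_axis(axis)
  basis_max <- max(Mod(basis$samples))

  samples <- matrix(complex(real = 0), np, n)
  if (keep_components) {
    pre_noise <- matrix(complex(real = 0), np, n)
    clean <- matrix(complex(real = 0), np, n)
  }
  label <- character(n)
  tf <- numeric(n); tp <- numeric(n); snr <- numeric(n)

  for (j in seq_len(n)) {
    amp <- stats::rnorm(1, cfg$amp_mean, cfg$amp_sd)
    s <- amp * basis$samples
    s_clean <- s
    has_lip <- stats::runif(1) < cfg$p_lipid
    has_wat <- stats::runif(1) < cfg$p_water
    lip_spec <- within(cfg$lipid, amp_range <- amp_range * basis_max)
    wat_spec <- within(cfg$water, amp_range <- amp_range * basis_max)
    if (has_lip) s <- s + draw_nuisance(lip_spec, axis)
    if (has_wat) s <- s + draw_nuisance(wat_spec, axis,
                                        jitter_hz = cfg$water$jitter_hz)
    label[j] <- if (has_lip && has_wat) "UW&LC"
      else if (has_lip) "LC" else if (has_wat) "UW" else "Free"

    lw <- max(0, stats::rnorm(1, cfg$lw_mean_hz, cfg$lw_sd_hz))
    fshift <- stats::runif(1, -cfg$freq_range_hz, cfg$freq_range_hz)
    pshift <- stats::runif(1, -cfg$phase_range_deg, cfg$phase_range_deg)
    mod <- exp(-pi * lw * t) *
      complex(modulus = 1,
              argument = 2 * pi * fshift * t + pshift * pi / 180)
    s <- s * mod
    s_clean <- s_clean * mod
    tf[j] <- fshift; tp[j] <- pshift

    snr[j] <- runif1(cfg$snr_range[1], cfg$snr_range[2])
    sigma <- if (is.finite(snr[j])) Mod(s[1]) / snr[j] else 0
    if (keep_components) { pre_noise[, j] <- s; clean[, j] <- s_clean }
    if (sigma > 0)
      s <- s + complex(real = stats::rnorm(np, 0, sigma),
                       imaginary = stats::rnorm(np, 0, sigma))
    samples[, j] <- s / max(Mod(s))
  }

  perm <- sample.int(n)
  n_train <- round(cfg$split_fracs[1] * n)
  n_val <- round(cfg$split_fracs[2] * n)
  split <- rep("test", n)
  split[seq_len(n_train)] <- "train"
  if (n_val > 0 && n_train < n)
    split[seq.int(n_train + 1L, min(n, n_train + n_val))] <- "val"

  out <- mrs_set(samples[, perm, drop = FALSE], axis,
                 label = label[perm], split = split,
                 true_freq_hz = tf[perm], true_phase_deg = tp[perm],
                 snr_nominal = snr[perm])
  if (keep_components) {
    attr(out, "pre_noise") <- pre_noise[, perm, drop = FALSE]
    attr(out, "clean") <- clean[, perm, drop = FALSE]
  }
  out
}

# smooth bounded random walk of length n, rescaled to [-1, 1]
smooth_walk <- function(n) {
  w <- cumsum(stats::rnorm(n))
  k <- max(1L, min(25L, n %/% 3L))
  w <- as.numeric(stats::filter(w, rep(1 / k, k), sides = 2))
  # fill the filter's edge NAs by nearest valid value
  ok <- which(!is.na(w))
  w[seq_len(ok[1] - 1)] <- w[ok[1]]
  w[seq.int(ok[length(ok)] + 1L, length.out = n - ok[length(ok)])] <-
    w[ok[length(ok)]]
  span <- max(w) - min(w)
  if (span == 0) return(rep(0, n))
  2 * (w - min(w)) / span - 1
}

#' Generate a phantom-like set with slow temperature drift
#'
#' Emulates a phantom acquired while the magnet temperature drifts: a slow,
#' smooth frequency drift (bounded random walk with full span
#' `cfg$drift_span_hz`) plus a small smooth amplitude and linewidth
#' modulation stand in for the temperature change.  On top of that each
#' transient gets the in vivo-style augmentation without amplitude factor
#' and without nuisance peaks, and noise to SNR U(7, 70) by default.
#'
#' Ground truth `true_freq_hz` records drift + applied shift (the total
#' displacement an FPC method should undo); `true_phase_deg` records the
#' applied phase.
#'
#' @param basis a noiseless basis [mrs_transient()], e.g.
#'   `make_basis_signal(phantom_peak_table())`.
#' @param n number of transients.
#' @param cfg an [aug_config()]; its `snr_range` defaults here to (7, 70).
#' @return an [mrs_set()]; the drift curve is attached as attribute
#'   `drift_hz`.
#' @export
make_phantom_set <- function(basis, n = 1648L,
                             cfg = aug_config(snr_range = c(7, 70))) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  axis <- basis$axis
  np <- axis$n_points
  t <- time_axis(axis)
  n <- as.integer(n)

  # amplitude/linewidth modulation scales with the drift span so a
  # zero-drift configuration degenerates to exact copies
  temp_scale <- cfg$drift_span_hz / 30
  drift <- smooth_walk(n) * cfg$drift_span_hz / 2
  amp_mod <- 1 + 0.03 * temp_scale * smooth_walk(n)
  lw_mod <- 0.3 * temp_scale * (smooth_walk(n) + 1)  # extra linewidth, Hz

  samples <- matrix(complex(real = 0), np, n)
  tf <- numeric(n); tp <- numeric(n); snr <- numeric(n)
  for (j in seq_len(n)) {
    lw <- max(0, stats::rnorm(1, cfg$lw_mean_hz, cfg$lw_sd_hz)) + lw_mod[j]
    fshift <- stats::runif(1, -cfg$freq_range_hz, cfg$freq_range_hz)
    pshift <- stats::runif(1, -cfg$phase_range_deg, cfg$phase_range_deg)
    ftot <- fshift + drift[j]
    s <- amp_mod[j] * basis$samples * exp(-pi * lw * t) *
      complex(modulus = 1,
              argument = 2 * pi * ftot * t + pshift * pi / 180)
    tf[j] <- ftot; tp[j] <- pshift
    snr[j] <- runif1(cfg$snr_range[1], cfg$snr_range[2])
    sigma <- if (is.finite(snr[j])) Mod(s[1]) / snr[j] else 0
    if (sigma > 0)
      s <- s + complex(real = stats::rnorm(np, 0, sigma),
                       imaginary = stats::rnorm(np, 0, sigma))
    samples[, j] <- s / max(Mod(s))
  }
  out <- mrs_set(samples, axis, label = rep("Free", n),
                 split = rep("test", n), true_freq_hz = tf,
                 true_phase_deg = tp, snr_nominal = snr)
  attr(out, "drift_hz") <- drift
  out
}
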