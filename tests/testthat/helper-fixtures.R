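# Shared fixtures and independent oracles for the test suite.

# small axis for cheap tests (keeps the same spectral width / ppm map as
# the default acquisition)
small_axis <- function(n = 512L) mrs_axis(n, 1 / 4400, 400, 4.7)

# single-resonance creatine basis (ground truth by construction)
cr_only_basis <- function(axis = default_axis(), lw = 8) {
  make_basis_signal(data.frame(ppm = 3.027, amp = 1, lw_hz = lw), axis)
}

# a set of noiseless shifted copies of a basis with known truths
shifted_copy_set <- function(basis, freqs, phases) {
  samples <- vapply(seq_along(freqs), function(j) {
    apply_shift(basis, freqs[j], phases[j])$samples
  }, complex(basis$axis$n_points))
  mrs_set(samples, basis$axis, true_freq_hz = freqs,
          true_phase_deg = phases)
}

# Brute-force spectral-registration oracle: profile the phase in closed
# form per candidate frequency and scan a fine grid.  For the time-domain
# SR objective sum |x - ref e^{i(2 pi f t + phi)}|^2, the optimal phase at
# fixed f is phi = Arg(sum x conj(ref) e^{-i 2 pi f t}) and the objective
# reduces to maximizing |v(f)|, v(f) = sum_k x_k conj(ref_k) e^{-i2pi f t_k}.
# Completely independent of the package's optimizer path.
sr_grid_oracle <- function(x, ref, f_lo = -20, f_hi = 20, step = 0.01,
                           max_points = 512L) {
  m <- min(max_points, x$axis$n_points)
  t <- (seq_len(m) - 1) * x$axis$dwell_s
  w <- x$samples[seq_len(m)] * Conj(ref$samples[seq_len(m)])
  fgrid <- seq(f_lo, f_hi, by = step)
  E <- exp(outer(fgrid, t, function(f, tt) {
    complex(real = 0, imaginary = -2 * pi * f * tt)
  }))
  v <- as.vector(E %*% w)
  i <- which.max(Mod(v))
  list(freq_hz = fgrid[i], phase_deg = Arg(v[i]) * 180 / pi)
}

# correct every transient of a set by its recorded ground truth
truth_correct <- function(s) {
  out <- s
  for (j in seq_len(length(s)))
    out$samples[, j] <- apply_shift(set_transient(s, j),
                                    -s$true_freq_hz[j],
                                    -s$true_phase_deg[j])$samples
  out
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", actual, expected, tol))
}
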