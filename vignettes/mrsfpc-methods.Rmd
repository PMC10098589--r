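---
title: "Frequency and phase correction of MRS transients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency and phase correction of MRS transients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsfpc)
```

## The problem

In single-voxel MR spectroscopy (MRS), hundreds of individual transients
(free-induction decays, FIDs) are acquired and averaged to beat the low SNR
of metabolite signals.  Hardware drift, subject motion and physiology give
every transient its own small frequency offset $\Delta f$ and zero-order
phase offset $\Delta\phi$:

$$ S_j(t) = S_0(t)\, e^{\,i(2\pi \Delta f_j t + \Delta\phi_j)} + \varepsilon_j(t). $$

Averaging without correcting these offsets broadens and distorts every
spectral line, and in spectral-editing experiments (e.g. MEGA-PRESS GABA
editing) misalignment leaks large singlets into the edited difference
spectrum.  Frequency-and-phase correction (FPC) therefore estimates
$(\Delta f_j, \Delta\phi_j)$ per transient and removes them before
averaging.

`mrsfpc` implements, on a common set of containers and conventions:

* the classical estimators — time-domain spectral registration (SR), SR on
  a restricted spectral window (SRF), magnitude-spectrum cross-correlation
  (Corr/CorrF) and creatine referencing (CrR);
* an unsupervised, physics-informed autoencoder family (dCrR, dCrRF, dSR,
  dSRF) whose decoder is an analytic signal model, so the latent space *is*
  the estimate;
* a k-means procedure that picks a nuisance-free reference scan;
* a synthetic-data generator with exact ground truth; and
* the evaluation protocol (precision, similarity index, creatine linewidth,
  SNR sweeps, Monte Carlo studies, beyond-range tests).

## Conventions

* The ppm axis follows `ppm(f) = ref_ppm + f / f0_mhz`; the default axis is
  4400 Hz spectral width, 2048 complex points, 400 MHz (9.4 T proton) with
  water at 4.7 ppm on carrier.
* `apply_shift(x, f, phi)` multiplies the FID by
  $e^{+i(2\pi f t + \phi)}$; a positive `f` moves peaks to higher ppm.
  `correct()` applies the negated estimate.  Every estimator returns shifts
  in this one convention, which round-trip tests pin down.
* Phases are degrees at API boundaries, radians internally; phase errors
  are wrapped to $(-180°, 180°]$ before statistics.
* Apodization by `lw_hz` multiplies by $e^{-\pi \cdot lw \cdot t}$; a
  damping $d$ corresponds to a Lorentzian FWHM of $d/\pi$.
* All signals are normalized to unit maximum magnitude
  ($S / \max_\tau |S(\tau)|$) before they enter an estimator or network —
  MRS amplitudes are physically meaningful, so only this linear rescaling
  is allowed.

## The synthetic world

The real acquisitions this methodology was developed on (an averaged rat
hippocampus PRESS signal, a temperature-drifted phantom series, public
GABA-edited human data) are not shipped here.  The generator replaces the
measured basis signal with a parametric sum of Lorentzians,

$$ S_{\text{basis}}(t) = \sum_j a_j\, e^{-\pi\, lw_j t}\, e^{\,i 2\pi f(p_j) t}, $$

with default resonances NAA 2.008, Glu 2.35, Cr 3.027, Cho 3.20, mI 3.56
and Cr 3.913 ppm, amplitudes (1.0, 0.6, 0.8, 0.3, 0.5, 0.55) and ~8–10 Hz
linewidths — a plausible 9.4 T rodent brain spectrum whose creatine CH3
singlet clearly dominates its neighbourhood, so creatine-referencing
methods have a well-defined target.  A phantom table with amplitudes
proportional to known concentrations (NAA 17.5, Glu 26.2, mI 17.5,
Cr 12.7, Tau 10.1 mmol/L) and narrower lines is also provided.

The augmentation recipe is the stated one: per transient, an amplitude
factor $\mathcal N(1, 0.1)$; independent residual-water and lipid nuisance
peaks with probability 0.5 each (see below); Lorentzian apodization with
linewidth $\mathcal N(2, 0.2)$ Hz; frequency offsets
$\mathcal U(-20, 20)$ Hz and phase offsets $\mathcal U(-90°, 90°)$
(recorded as ground truth); complex white Gaussian noise to an SNR
$\mathcal U(9, 27)$ (SNR = first-point magnitude over noise SD); then
normalization, a shuffle, and a 90/9/1 train/val/test split.  The phantom
emulation adds a smooth bounded-random-walk frequency drift (default full
span 30 Hz — the drift magnitude of the original temperature experiment is
not published) with proportional slow amplitude/linewidth modulation, no
nuisance peaks, no amplitude factor, and SNR $\mathcal U(7, 70)$.

Nuisance peaks follow the damped-complex-exponential model (note the
negative exponent, kept exactly as the model is usually printed):

$$ S_{\text{nuis}}(t) = A_a e^{-d_a t} e^{-i(2\pi f_a t + \phi_a)}, $$

so a peak intended at chemical shift $p$ needs $f_a = -\,(p -
\text{ref}_{ppm}) f_0$.  The exact nuisance parameter table of the source
experiments is not public; the defaults — lipid at 1.3 ppm with linewidth
$\mathcal U(20, 50)$ Hz and amplitude $\mathcal U(0.1, 0.5)\times$ basis
maximum; "unstable" residual water at 4.7 ppm jittered by
$\mathcal U(\pm 5)$ Hz with linewidth $\mathcal U(10, 30)$ Hz, amplitude
$\mathcal U(0.5, 2)\times$ basis maximum and uniform phase — reproduce the
qualitative picture: water contamination can dominate the FID and derails
naive time-domain registration, lipid contamination is milder.

What a green test on this world does **not** establish: performance on
measured data with macromolecule baselines, eddy-current lineshape
distortion, frequency-dependent phase, or vendor-specific filtering.  The
surrogate basis is also "easier" than a real crowded spectrum (six clean
Lorentzians), so classical estimators reach somewhat better absolute
precision here than the published full-scale numbers; comparisons across
methods, and all trends, are meaningful.

## Classical estimators

**SR** minimizes
$\sum_k |x_k - r_k e^{i(2\pi f t_k + \phi)}|^2$ over the first 512 FID
points with a multi-start (f ∈ {−15, 0, 15} Hz) box-constrained
quasi-Newton search.  The box (±60 Hz by default) encodes that spectral
registration is a *local* method: without it, a residual-water peak in the
input can be matched onto an unrelated resonance of the reference,
producing "shifts" of hundreds of Hz.  **SRF** evaluates the same residual
on the complex spectra restricted to a window (default 2.5–3.5 ppm).
A brute-force oracle (0.01 Hz grid with the phase profiled out in closed
form) verifies the optimizer in the test suite.

**Corr/CorrF** take the frequency from the arg-max (with three-point
parabolic sub-bin refinement) of the circular cross-correlation of
magnitude spectra — magnitude makes the frequency step phase-blind — and
then read the phase from the complex inner product of the reference
spectrum with the frequency-corrected spectrum.

**CrR** fits the windowed complex spectrum with a single complex
Lorentzian $A e^{i\phi}/(d + i2\pi(\nu-\nu_0))$ plus a complex linear
baseline (linear parameters profiled out by least squares, only
$(\nu_0, \log d)$ optimized).  A second pass refits on a ±45 Hz
sub-window around the first-pass position so the choline resonance
69 Hz away reduces to a near-linear background.  The estimate is absolute:
$\hat{\Delta f} = \nu_0 - f(3.027\,\text{ppm})$, $\hat{\Delta\phi} =
\phi$.  CrR needs no reference but inherits the noise of a handful of
spectral bins, which is why it is the least precise method at low SNR.

Relative methods need a reference scan.  `select_reference()` clusters the
magnitude FIDs with k-means (k = 2, seeded, 10 restarts), identifies the
cluster whose mean signal has the lower average over its first 10 points
as nuisance-free (contaminating peaks are strong and coherent early in the
FID), and returns its highest-SNR member.  Clustering uses only the first
100 magnitude points: the late FID is noise whose amplitude scales with
the (normalized) nuisance content, and including it makes k-means cluster
by noise level rather than contamination.

## The physics-informed autoencoder

A conventional autoencoder compresses and reconstructs; its latent space
is not interpretable.  Here the decoder is replaced by an analytic model
with **no trainable parameters**, so the encoder is forced to output the
model's physical parameters.  The encoder is a small 1-D convolutional
network: input dropout (p = 0.05), six convolution blocks
(kernel 3, stride 2, ReLU, channels 8→256 doubling), and one fully
connected layer onto the latent heads (`encoder_config()` also offers a
hidden FC layer and other widths/kernels; the defaults are sufficient at
every scale exercised here).  The complex FID enters as two real
channels, truncated to its first 512 points (the late FID is
noise-dominated).

Two decoder families:

* **Lorentzian (dCrR/dCrRF)**, four latents $(A_M, d_M, f_M, \phi_M)$:
  $$ \hat{x}(t) = A_M e^{-d_M t} e^{-i(2\pi f_M t + \phi_M)}
     + x(t)\, e^{-d_L t}, $$
  a single creatine line plus the input apodized with a broad Lorentzian
  kernel ($d_L = 500\,s^{-1}$, fixed).  The second term is a rough
  baseline: without it, the lone Lorentzian would inflate its linewidth to
  soak up the other metabolites.
* **Reference-shift (dSR/dSRF)**, two latents $(f_M, \phi_M)$:
  $\hat{x}(t) = R(t) e^{-i(2\pi f_M t + \phi_M)}$ with $R$ the selected
  reference scan.

Training minimizes the mean squared reconstruction error, in the time
domain or — for the F-variants — between the complex spectra restricted to
2.5–3.5 ppm (computed with an exact windowed DFT matrix on the truncated
axis, so the loss stays differentiable and cheap).  After training the
decoder is discarded; the encoder alone maps a transient to its shift
estimate in milliseconds (`predict_shift()` converts the decoder-sign
latents into the package's `apply_shift` convention; for dCrR the
frequency estimate is the deviation of the fitted line from nominal
3.027 ppm, i.e. the method is absolute).

### Numerical and design choices

The published work does not disclose the exact layer table or
hyper-parameter search, so the following are this package's own choices:

* **Latent head maps.** $A_M = \mathrm{softplus}(z)$;
  $d_M = 10 + 80\,\sigma(z)\ s^{-1}$; $f_M = f_c + 45\tanh(z)$ Hz, where
  $f_c$ is the nominal creatine offset (Lorentzian variants) or 0
  (reference-shift variants); $\phi_M = \pi z$.  The bounded damping and
  frequency heads encode physical priors: the damping cannot degenerate
  into a baseline absorber, and the fitted line cannot lock onto a
  *neighbouring* resonance (glutamate/NAA sit a few hundred Hz away —
  exactly the failure mode observed with an unbounded head).
* **Warm start.** The head biases start the line at the window centre with
  $A_M \approx 0.3$, $d_M \approx 30\,s^{-1}$ ($\approx$ 10 Hz linewidth).
* **Backprop.** The network is small enough that forward/backward are
  written directly as im2col gathers plus BLAS products; the decoder
  gradients are analytic (verified against central differences to
  $10^{-5}$ relative in the tests).
* **Optimizer.** Adam with the published batch size 16 and, by default,
  the published learning rate $4\times10^{-5}$ over up to 150 epochs with
  early stopping (patience 10).  Scaled-down runs (a few thousand signals,
  ≤ 40 epochs, i.e. ~5% of the full-scale gradient steps) cannot both
  travel and settle at a flat $4\times10^{-5}$; for them
  `train_config(schedule = "cosine", lr = 2e-3)` (3-epoch linear warmup,
  annealed to `lr/20`) recovers full-scale precision in minutes on a
  single CPU core.  The time-domain loss profile around the optimum is
  shallow (±1 Hz changes the loss by ~0.2% at SNR 15), so the annealed
  tail — many steps at a small rate — is what converts a fitted network
  into a sub-Hz estimator.  Optional Polyak weight averaging
  (`ema_decay`) is available for even shorter runs.
* **Determinism.** One integer seed fixes initialization, dropout masks
  and shuffling; identical seeds reproduce training histories to floating
  tolerance.

## Evaluation protocol

* **Accuracy/precision**: mean and sample (n−1) SD of
  (estimate − truth), phase wrapped; for relative methods the reference's
  own true shift is subtracted from the truths first.
* **Similarity index (SI)**: mean off-diagonal entry of the matrix of
  normalized real scalar products of windowed complex spectra
  (2.5–3.5 ppm).  The mean (rather than the raw sum of all matrix
  elements) makes the index size-invariant and 1 for a perfectly aligned
  identical set; absolute values can therefore differ from reports that
  sum the matrix.
* **Creatine linewidth**: FWHM of the creatine peak of the averaged
  magnitude spectrum (8× zero-filled, half-maximum crossings
  interpolated), divided by $\sqrt3$ because the magnitude of a complex
  Lorentzian is $\sqrt3$ wider than its absorption mode.  Misalignment
  broadens the average, so this is a ground-truth-free quality measure
  robust to overall phase.
* **SNR sweep**: one noise realization per level, 20 levels with linearly
  spaced noise SD spanning SNR ≈ 8–110, on the basis shifted by (5 Hz,
  45°).  **Monte Carlo**: 256 realizations at fixed SNR ≈ 15.
  **Beyond-range**: shifts drawn over ±40 Hz / ±180° compare precision
  inside vs outside the trained ±20 Hz / ±90° box — encoder estimates
  degrade sharply outside the training distribution, which is the main
  operational caveat of learned FPC.

## Container format and pipeline

Transient sets round-trip through a plain-text directory container
(`meta.json` with `dwell_s`, `f0_mhz`, `ref_ppm`, plus one CSV holding
labels, split tags, true shifts, nominal SNR and the full-precision
real/imaginary sample matrix).  No binary dependency is required, and the
schema mirrors the obvious HDF5 layout should one want to swap the
backend.  `run_pipeline()` executes simulate → reference → train →
correct → evaluate from a JSON config, validates stage consistency before
computing, and writes a manifest with seeds and a config hash so identical
configs reproduce identical metrics.  A thin command-line wrapper
(`exec/mrsfpc`) exposes the same stages.

## Known limitations

* Zero-order phase only; no frequency-dependent (first-order) phase and no
  eddy-current correction.
* The surrogate basis has no macromolecular baseline and no J-coupled
  multiplet structure; density-matrix simulation is out of scope.
* CrR uses a single Lorentzian plus linear baseline, not the Cho–Cr
  double-Lorentzian of some toolboxes; SR is not bit-compatible with any
  specific toolbox implementation.
* The encoder generalizes only within its training distribution (see
  beyond-range evaluation); retraining is expected when the acquisition
  changes.
* Training on 1 CPU core takes minutes at desk scale; no GPU path is
  provided.

## A worked example

```{r example, eval = FALSE}
library(mrsfpc)

basis <- make_basis_signal()
cfg <- aug_config(n_signals = 2400, split_fracs = c(0.85, 0.10, 0.05),
                  seed = 1)
s <- make_simulated_set(basis, cfg)
tr <- set_subset(s, s$split == "train")
va <- set_subset(s, s$split == "val")
te <- set_subset(s, s$split == "test")

# classical spectral registration against a k-means reference
res_sr <- align_set(te, method = "SR", ref_strategy = "kmeans", seed = 1)

# unsupervised Lorentzian-decoder autoencoder, scaled-down schedule
m <- train_dae("dCrR", tr, va,
               train_config(max_epochs = 40, lr = 2e-3,
                            schedule = "cosine", seed = 2))
res_dae <- dae_align_set(m, te)

ap <- accuracy_precision(res_dae$estimates,
                         te$true_freq_hz, te$true_phase_deg)
c(sd_f = ap$sd_f, sd_phi = ap$sd_phi,
  si_before = similarity_index(te),
  si_after = similarity_index(res_dae$set))
```
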