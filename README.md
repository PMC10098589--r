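# mrsfpc — frequency and phase correction of MRS transients

In MR spectroscopy, hundreds of individual transients (FIDs) are averaged
to build up SNR. Each transient carries its own small frequency and
zero-order phase offset (scanner drift, motion, physiology); averaging
without removing them broadens every line and, in spectral editing,
contaminates the difference spectrum. Correcting each transient,

S_j(t) = S_0(t) · exp(i(2π·Δf_j·t + Δφ_j)) + noise,

means estimating (Δf_j, Δφ_j) per transient. `mrsfpc` is for spectroscopy
methodologists who want those estimators — classical and learned — behind
one set of containers, conventions, and evaluation metrics:

* **Classical methods** — time-domain spectral registration (SR), windowed
  SR (SRF), magnitude-spectrum cross-correlation (Corr/CorrF), and
  creatine referencing (CrR: complex Lorentzian fit of the Cr singlet at
  3.027 ppm with a linear baseline).
* **Physics-informed autoencoders** (dCrR, dCrRF, dSR, dSRF) — a small 1-D
  convolutional encoder whose decoder is an *analytic signal model* with
  no trainable parameters, either a single Lorentzian plus an
  apodized-input baseline term,
  `x̂(t) = A·e^(−d·t)·e^(−i(2πf·t+φ)) + x(t)·e^(−500t)`,
  or a reference-shift model `x̂(t) = R(t)·e^(−i(2πf·t+φ))`.
  Trained unsupervised (MSE between input and reconstruction, Adam,
  batch 16, early stopping), the latent space *is* the shift estimate; no
  ground-truth labels are ever needed, and inference is a single forward
  pass. The network and its backprop are implemented directly in R
  (im2col + BLAS), so there is no deep-learning dependency.
* **Reference selection** — k-means (k = 2) on initial magnitude FIDs
  identifies the nuisance-free cluster (residual water / lipid peaks are
  strong and coherent early in the FID) and picks its highest-SNR member.
* **Synthetic data** — a sum-of-Lorentzians basis spectrum with the full
  augmentation recipe (amplitude jitter, nuisance water/lipid peaks,
  apodization, uniform shift offsets, Gaussian noise to a target SNR) and
  a phantom-like generator with a smooth temperature-style frequency
  drift; ground truth is exact by construction.
* **Evaluation** — accuracy/precision of shift errors, pairwise spectral
  similarity index over 2.5–3.5 ppm, creatine linewidth of the averaged
  spectrum, SNR sweeps, Monte Carlo studies, beyond-trained-range tests.

## Worked example

```r
library(mrsfpc)

basis <- make_basis_signal()                      # synthetic brain-like FID
cfg   <- aug_config(n_signals = 2400, split_fracs = c(0.85, 0.10, 0.05),
                    seed = 1)
s  <- make_simulated_set(basis, cfg)              # shifts/noise/nuisance, truth recorded
tr <- set_subset(s, s$split == "train")
va <- set_subset(s, s$split == "val")
te <- set_subset(s, s$split == "test")

# classical spectral registration against a k-means-selected reference
res_sr <- align_set(te, method = "SR", ref_strategy = "kmeans", seed = 1)

# unsupervised Lorentzian-decoder autoencoder (scaled-down schedule)
m <- train_dae("dCrR", tr, va,
               train_config(max_epochs = 40, lr = 2e-3,
                            schedule = "cosine", seed = 2))
res <- dae_align_set(m, te)
ap  <- accuracy_precision(res$estimates, te$true_freq_hz, te$true_phase_deg)

round(c(sd_f = ap$sd_f, sd_phi = ap$sd_phi,
        si_before = similarity_index(te),
        si_after  = similarity_index(res$set)), 3)
```

On this 2400-signal run (a few minutes on one CPU core) the output is

```
     sd_f    sd_phi si_before  si_after
    0.734     4.814     0.135     0.652
```

i.e. the trained encoder recovers per-transient frequency shifts with a
precision (SD of error) of ≈0.7 Hz and phases to ≈5°, and correcting the
test transients with its estimates raises the mean pairwise spectral
similarity in the creatine window from 0.14 (badly misaligned) to 0.65 —
essentially the ceiling attained by correcting with the exact simulated
shifts.

`exec/mrsfpc` exposes the stages (`simulate`, `reference`, `correct`,
`evaluate`, `pipeline`) as a thin command-line wrapper, and
`run_pipeline()` drives them from a JSON config with a reproducibility
manifest. See the vignette `vignettes/mrsfpc-methods.Rmd` for the models,
conventions, parameter choices and limitations.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the synthetic world from scratch at desk scale (4800 signals;
240-signal test subset), runs spectral registration against the
k-means-selected reference, trains the dCrR and dSRF autoencoders on the
training split, and writes the headline quantities (frequency/phase error
SDs per method and the post-correction similarity index) as JSON. It takes
roughly 10 minutes on one CPU core.
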