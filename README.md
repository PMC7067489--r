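# itpcflow

Spectral profiling of impulse-evoked intracranial auditory responses.

`itpcflow` is an R implementation of an analysis pipeline for stereotactic
EEG (SEEG) recordings of auditory cortex responding to brief acoustic
impulses. Its central statistic is **intertrial phase coherence (ITPC)**:
at each time–frequency point, the mean resultant length of the trials'
unit phase vectors,

```
ITPC(f, t) = | (1/n) Σ_k  c_k(f,t) / |c_k(f,t)| |   ∈ [0, 1],
```

with `c_k` complex Morlet coefficients (7 cycles per frequency, 100
log-spaced frequencies from 2–250 Hz). Averaging the ITPC map over one
oscillatory cycle per frequency — the window `[0, 1/f)` from stimulus
onset: 500 ms at 2 Hz, 20 ms at 50 Hz — yields the **ITPC spectrum**,
which is z-scored across frequencies. On top of this the package provides:

- a **synthetic cohort generator** (phase-locked damped oscillations with
  von Mises phase jitter over 1/f noise; region- and hemisphere-specific
  frequency pairs such as theta/gamma 5/45 Hz on the left vs delta/beta
  2.5/16 Hz on the right association cortex), because no patient
  recordings are publicly deposited;
- SEEG-style **preprocessing**: bipolar referencing of adjacent
  within-electrode contacts, amplitude-based epoch rejection, auditory
  evoked potentials (AEPs) with per-trial baseline z-scoring, and
  selection of the most responsive contact (≥ 40 µV);
- extraction of the **two highest noncontiguous spectral peaks**
  (minimum distance 22 grid points, prominence ≥ 0.01);
- **leave-one-out hemisphere classification** of individual spectra by
  inverse-squared-MSE similarity to group-level templates;
- **non-negative matrix factorization** (`V ≈ W H`, squared Frobenius
  objective, k = 4) of the frequency × contact spectrum matrix into
  prototypical spectral components, with cross-validated variance
  explained and delta/beta vs theta/gamma component classification;
- the **group statistics** used throughout (exact/approximate
  Mann–Whitney U, pooled-variance t tests).

## Worked example

Simulate one left-association-cortex patient and recover its spectral
profile:

```r
library(itpcflow)

profile <- default_profiles()$AAC.left
profile
#> <spectral_profile> 2 components, kappa = 5, noise 1/f^1 @ 100 uV RMS
#>   freq amp n_cycles_duration onset
#> 1    5 250                 2     0
#> 2   45 250                 2     0

ep <- generate_evoked_epochs(profile, n_trials = 60, sampling_rate = 1000,
                             epoch_window = c(-2.5, 2.5), seed = 1)
ep
#> <epoch_array> 60 trials x 1 contacts x 5001 samples (monopolar montage)
#>   time: -2.500 .. 2.500 s @ 1000 Hz; electrodes: E1

spec <- itpc_spectrum(ep, frequency_grid())
spec
#> <itpc_spectrum> 100 frequencies 2..250 Hz, 60 trials (normalized)

find_two_peaks(spec)
#> <peak_set> 2 peak(s): 6.14 Hz (h=1.29), 39.2 Hz (h=0.958)
```

The two recovered peaks sit at the grid bins near the injected 5 and
45 Hz components. (Single-patient peaks scatter by a bin or two around
the injected frequency — at 60 trials the coherence floor is ≈ 0.13 —
and group averaging tightens them; the methods vignette quantifies the
residual displacement intrinsic to one-cycle-window averaging of
transient responses.)

A full cohort analysis — simulate → preprocess → ITPC → peaks → LOOCV →
NMF → statistics, with every table written as CSV/JSON:

```r
cfg <- run_config(groups = default_profiles()[c("AAC.left", "AAC.right")],
                  n_patients_per_group = 12, n_trials = 110,
                  n_contacts = 3, epoch_window = c(-2.5, 2.5), seed = 1)
res <- run_pipeline(cfg, "run1")
res$loocv
#> <loocv_report> 24 patients, accuracy 1.000 (left 1.00, right 1.00)
report("run1")           # group spectra, peak box data, scatter, weights
```

There is also a thin CLI wrapper:

```sh
Rscript inst/cli/itpcflow.R run-all --config cfg.json --out run1 --seed 1
```

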