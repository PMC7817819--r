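# ccistiff

Tools for evaluating how well EMG-based **co-contraction indices (CCIs)**
approximate sagittal-plane **joint stiffness** during gait.

## The problem

Co-contraction — simultaneous activity of muscles on opposite sides of a
joint — stiffens the joint. Joint stiffness in the strict sense,

    K_joint = -∂M_j/∂θ_j

(the elastic response of the net joint moment to a change in joint angle at
fixed activation), matters clinically — post-stroke gait, orthosis and
exoskeleton design — but is hard to measure and expensive to compute: it
needs a calibrated musculoskeletal model. Co-contraction indices computed
from surface EMG are nearly free. This package implements both sides of the
comparison and the statistics joining them, for researchers in
neuromuscular biomechanics and motor control:

* **EMG processing** — the standard linear-envelope pipeline (40 Hz
  zero-phase Butterworth high-pass, demean, rectify, low-pass at
  3.5/cycle-period Hz), gait-cycle segmentation onto the 0–100% grid
  (101 points), and the four signal variants: `basic`, `scaled` (× a
  muscle-specific calibration factor), `delayed` (shifted by the leg's
  electromechanical delay, ~80–115 ms), `calibrated` (both).
* **CCIs** — the two standard formulations over antagonist pairs, applied
  pointwise with L = min, H = max:
  `CCI1 = (L/H)(L+H)` (agonist-weighted, scale-dependent) and
  `CCI2 = 2L/(L+H)` (common-activity fraction, scale-invariant).
* **Model-based joint stiffness** — rigid-tendon Hill-type muscles over
  polynomial musculotendon geometry, assembled analytically as
  `K_mus = r² ∂F/∂l − (∂r/∂θ) F`, summed over spanning muscles, validated
  against a finite-difference oracle on the defining derivative.
* **Statistics** — per-gait-cycle Pearson correlation between CCI and
  stiffness series, strength classes (weak/moderate/strong at
  0.3/0.5/0.7), best-pair reports, and exact Wilcoxon rank-sum comparisons.
* **A synthetic virtual subject** — 16 muscles per leg, seeded, with known
  ground-truth envelopes, activations and stiffness, and a controllable
  coupling between antagonist co-activation and joint stiffness — so the
  whole chain is testable without laboratory data.

## A worked example

```r
library(ccistiff)

subject <- make_subject(seed = 1)           # two legs, delays 82 / 93 ms
sim <- make_gait_trial(subject, n_cycles = 10, coupling = "coupled",
                       seed = 1)
fit <- cci_stiffness(subject, sim$trial, legs = "non-paretic",
                     variants = c("basic", "delayed"))
summary(fit)
```

The best-pair table for CCI1 (one row per DOF and EMG variant) prints:

```
                dof formulation variant           pair r_mean  r_sd strength
        hip_flexion        CCI1   basic   addlong+bflh  0.627 0.019 moderate
        hip_flexion        CCI1 delayed recfem+semiten  0.933 0.009   strong
       knee_flexion        CCI1   basic semiten+vasmed  0.606 0.022 moderate
       knee_flexion        CCI1 delayed semiten+vasmed  0.796 0.022   strong
 ankle_dorsiflexion        CCI1   basic  tibant+soleus  0.636 0.025 moderate
 ankle_dorsiflexion        CCI1 delayed  tibant+soleus  0.943 0.009   strong
```

Read: with antagonist co-activation genuinely coupled to stiffness in the
simulation, the Rudolph-style CCI1 computed from **delayed** envelopes
tracks joint stiffness strongly (mean per-cycle r of 0.80–0.94 across the
three joints), while the same index from undelayed `basic` envelopes is
only moderate — the electromechanical delay aligns the EMG with the force
it produces. The accompanying contrast table shows CCI1 beating CCI2 at
every joint (difference in best mean r ≈ 0.5–0.6, rank-sum p ≈ 1e-5).

`plot(fit, leg = "non-paretic", dof = "ankle_dorsiflexion")` overlays the
mean ± SD stiffness profile with the best pair's mean CCI1.

`run_pipeline(run_config(seed = 1))` runs the same analysis end to end and
writes every intermediate — subject JSON, kinematics/EMG/events,
per-variant envelopes, stiffness, correlations, reports — as
provenance-stamped delimited text. A thin command-line wrapper with
`simulate | process | stiffness | cci | correlate | report | run`
subcommands lives at `inst/cli/ccistiff.R`.

## Documentation

The methods vignette (`vignettes/cci-joint-stiffness.Rmd`) describes the
models and their assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, the
numerical choices (filter padding, normalisation order, degenerate guards,
tie-breaks), and known limitations.
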