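---
title: "Co-contraction indices as surrogates for joint stiffness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-contraction indices as surrogates for joint stiffness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccistiff)
```

## The scientific question

Muscles on opposite sides of a joint can fire simultaneously
(co-contraction). Doing so stiffens the joint — useful for stability and
accuracy, costly in energy, and elevated in many neurological conditions
such as stroke. Joint stiffness in the strict sense,

$$K_{joint} = -\frac{\partial M_j}{\partial \theta_j},$$

the elastic response of the net joint moment $M_j$ to a change in joint
angle $\theta_j$ at fixed activation, is hard to measure and requires a
calibrated musculoskeletal model to compute. (It is *not* the slope of the
measured torque–angle loop — that "quasi-stiffness" mixes in activation and
velocity changes and is deliberately out of scope here.) Co-contraction
indices (CCIs) computed from surface EMG are, by contrast, trivial to
obtain in a clinic. This package implements the full analysis chain needed
to ask: *how well do the two standard EMG-based CCIs track model-based
sagittal-plane joint stiffness over the gait cycle?*

The chain is: raw EMG → linear envelopes in four processing variants →
CCIs over antagonist muscle pairs, and, in parallel, envelopes → Hill-type
muscle activations → analytic joint stiffness; then per-gait-cycle Pearson
correlation between the two, summarised over pairs, variants and
formulations. A synthetic virtual subject with known ground truth makes
every stage testable without laboratory data.

## EMG processing and the four signal variants

`emg_envelope()` applies the standard surface-EMG protocol: a 4th-order
zero-phase Butterworth high-pass at 40 Hz, demeaning, full-wave
rectification, and a 4th-order zero-phase Butterworth low-pass at a
gait-cycle-dependent cutoff of $3.5/T$ Hz (2.5 Hz for the default
$T = 1.4$ s cycle). "4th-order zero-phase" is read as a 4th-order design
applied forward–backward (an effective 8th-order magnitude response); the
alternative reading (2nd-order design) is available through the `order`
argument.

`segment_normalize()` then resamples each heel-strike-to-heel-strike
interval to 101 points (0–100% of the gait cycle in 1% steps), subtracts
each cycle's minimum, and divides all cycles by the maximum over the
analysed cycles. Because subtraction and division commute, performing the
normalisation after resampling (rather than before, on the continuous
record) changes the result only by a constant factor ≈ 1 while making two
contracts exact on the analysed grid: every cycle's minimum is exactly 0,
and the basic variant's global maximum is exactly 1. Nothing downstream can
tell the difference: CCI1 is degree-1 homogeneous, CCI2 is scale-invariant,
and Pearson correlation is invariant to positive affine maps.

`make_variants()` produces the four signal variants from one continuous
record:

* **basic** — envelope → segment → normalise, as above;
* **delayed** — the same pipeline applied to the record shifted by the
  leg's electromechanical delay (`delay_shift()`; output at time $t$ equals
  input at $t - d$);
* **scaled** — basic × muscle-specific scale factor in (0, 1];
* **calibrated** — delayed × scale factor, so calibrated / scale = delayed
  by construction.

The electromechanical delay (the lag between muscle electrical activity
and force production; 82 and 93 ms for the two default legs, order
80–115 ms generally) is applied to the continuous record *before*
segmentation, with the leading gap held at the first value; trials should
provide at least one delay-length of lead-in before the first analysed
heel strike, and the synthetic generator provides 0.5 s.

Numerical details that matter: zero-phase filtering pads the record by
even (mirror) reflection over 6 cutoff-periods at each end, which keeps the
zero-initial-condition transients of both filter passes away from analysed
samples and preserves the local mean of the non-negative rectified signal;
at very low normalised cutoffs the designed low-pass coefficients lose
their unit DC gain to floating-point cancellation, so the gain is restored
explicitly; small negative ripple left by the low-pass is clamped to zero
before segmentation because envelopes are physically non-negative and the
per-cycle offset step would otherwise shift whole cycles by the ripple
magnitude; resampling uses linear interpolation (monotone, artifact-free).

## Musculotendon mechanics and analytic joint stiffness

Each muscle is a rigid-tendon Hill-type actuator. With tendon length fixed
at the slack length $l_s$, the fibre state follows kinematically from the
musculotendon length $l^{MT}$ under constant-thickness pennation:
$l_f\cos\alpha = l^{MT} - l_s$, $l_f \sin\alpha = l_{opt}\sin\alpha_{opt}$.
Tendon force is

$$F^T = F_{max}\,\bigl[a\,e^{-(\tilde l - 1)^2 / w} + f_{pas}(\tilde l)\bigr]\cos\alpha,$$

with normalised fibre length $\tilde l = l_f / l_{opt}$, Gaussian active
force–length of width $w$ (default 0.45), and an exponential passive curve
that is zero below optimal length. Excitation-to-activation dynamics are
first-order with an activation-dependent time constant (fast activation
$\tau_{act} = 15$ ms, slow deactivation $\tau_{deact} = 50$ ms), integrated
by backward Euler at the EMG rate, followed by an exponential shape
nonlinearity $a' = (e^{Aa}-1)/(e^{A}-1)$ with $A = -2$. These closed forms
are the field's standard choices; each is a parameter of
`muscle_params()`, so alternates can be swapped without touching the
stiffness assembly.

Musculotendon geometry is a polynomial surrogate: $l^{MT}(\boldsymbol\theta)$
is a multivariate polynomial in the spanned joint angles, so the moment arm
$r_j = -\partial l^{MT}/\partial\theta_j$ and its gradient
$\partial r_j/\partial\theta_j$ are available analytically
(`moment_arm()`, `moment_arm_gradient()`). The sign convention is fixed and
validated: hip flexion, knee flexion, and ankle dorsiflexion are positive,
and a muscle with role FLEX/DF must have $r > 0$ at the neutral pose
(EXT/PF: $r < 0$) — a mismatch is a configuration error, which prevents
silent sign bugs in the stiffness assembly.

Joint stiffness is assembled per muscle as

$$K_{mus} = r_j^2\,\frac{\partial F^T}{\partial l^{MT}} -
  \frac{\partial r_j}{\partial\theta_j}\,F^T, \qquad
  K_{joint} = \sum_i K_{mus,i},$$

with the force–length slope in closed form and the force–velocity
multiplier held at 1: stiffness is the response to a change in *position
only*, so velocity (and activation) are frozen in the partial derivative.
The expansion's overall sign is anchored to the definition
$K = -\partial M/\partial\theta$ rather than transcribed from any printed
intermediate: the package's core correctness gate is a central-difference
oracle ($h = 10^{-5}$ rad) that checks the analytic assembly against the
differentiated joint moment on random models at every grid point (relative
error below $10^{-4}$; in practice ~$10^{-5}$). A muscle "spans" a DOF iff
its geometry polynomial depends on that angle; biarticular muscles
contribute to each spanned DOF independently (the partial derivative is
single-DOF, so there are no cross-joint terms).

## CCI formulations and pair selection

For an antagonist pair with envelope values $L \le H$ at a time point:

* **CCI1** (agonist-weighted): $(L/H)\,(L+H)$ — degree-1 homogeneous, so
  EMG scaling changes it;
* **CCI2** (common-activity fraction): $2L/(L+H) \in [0,1]$ —
  scale-invariant.

Both are applied pointwise on the 101-point grid, with the lower/higher
assignment made independently at every point. When both inputs are zero the
value is defined as 0 (no activity means no co-contraction; the per-cycle
minimum offset guarantees such points exist in every cycle). These
algebraic facts — symmetry, bounds, CCI1 homogeneity and CCI2 scale
invariance — are property-tested, and they are the formal root of why
scaling the EMG affects CCI1-based correlations but not CCI2-based ones.

`build_pair_catalog()` enumerates pairs per DOF as (agonist = FLEX or DF
role) × (antagonist = EXT or PF role), excluding muscles recorded with
fine-wire electrodes (the analysis is restricted to clinically practical
surface EMG) and muscles whose mean fractional contribution to joint
stiffness is below 2%. The contribution fraction is the time-average of
$|K_{mus,i}| / \sum_m |K_{mus,m}|$ over grid points with nonzero total,
averaged over cycles. Only individual-muscle pairs are formed (no group
averages). `best_pair_report()` selects, per (DOF, formulation, variant),
the pair with the highest mean per-cycle correlation; ties are broken by
the lexicographically first pair name and logged.

## Statistics

`pearson_r()` is the product-moment coefficient, computed per gait cycle
between the 101-point CCI and stiffness series; a zero-variance series
yields NA with a warning, never a fabricated 0. Summaries report the mean
and sample (n−1) standard deviation over cycles, with a strength class on
the magnitude of the mean: negligible [0, 0.3), weak [0.3, 0.5), moderate
[0.5, 0.7), strong [0.7, 1]. The half-open intervals make boundary values
deterministic; a negative mean is classified by its magnitude with the sign
carried by the mean itself. `rank_sum_test()` is the two-sided Wilcoxon
rank-sum (Mann–Whitney) test: exact null distribution when there are no
ties and the combined sample size is at most 20 (the regime of two sets of
10 per-cycle correlations), normal approximation with tie and continuity
correction otherwise; significance at $\alpha = 0.05$. The exact path is
verified against a full enumeration oracle for all combined sizes up to 12.

## The synthetic virtual subject

`make_subject()` builds a two-legged subject ("non-paretic", "paretic")
with 16 muscles per leg mirroring a standard lower-limb EMG montage,
including three deep muscles flagged fine-wire (iliacus, psoas, tibialis
posterior) so the surface-only restriction is exercised. Per-leg
electromechanical delays default to 82 / 93 ms. EMG scale factors are drawn
uniformly from [0.05, 1] per muscle (seeded), matching the range of
calibrated values in this literature. Geometry is quadratic per spanned DOF
(the lowest degree that gives a nonzero moment-arm gradient, so the
geometric stiffness term is genuinely exercised) with a small bilinear
cross-term for biarticular muscles; fibres sit at $\tilde l = 0.95$ at the
neutral pose, on the ascending limb.

`make_gait_trial()` generates, per leg: two-harmonic joint-angle
trajectories with the reduced sagittal excursions typical of slow
hemiparetic gait (cycle period 1.4 s); per-muscle envelopes as per-cycle
Gaussian bursts (σ = 5% of the cycle, i.e. ~165 ms full width at half
maximum) with multiplicative lognormal amplitude jitter (σ = 0.15); raw
EMG synthesized by amplitude-modulating a zero-mean 40–450 Hz Gaussian
carrier (scaled to unit mean absolute value so demodulation recovers
amplitude) with a 2% noise floor; and ground-truth activations and
stiffness computed from excitations that are genuinely delayed by the
leg's electromechanical delay and scaled by the muscle's scale factor — so
both calibration parameters are physically present in the synthetic
mechanics and recoverable downstream.

The burst width is a deliberate compromise dictated by the envelope
low-pass: much narrower bursts have spectral content above the 2.5 Hz
cutoff and acquire deterministic ringing side-lobes; much wider bursts
overlap their antagonists' tails. Both artifacts are faithful consequences
of the processing protocol, but they add structural CCI–stiffness
correlation that has nothing to do with co-activation coupling, so the
default sits where gait-like burst shapes pass the filter cleanly.

Coupling between co-activation and stiffness is the generator's key
control. Under `coupling = "coupled"` (strength 1) every muscle of a leg
bursts in a common window (30% of the cycle) with a shared per-cycle
amplitude factor: antagonists genuinely co-contract, and total antagonist
activity tracks stiffness within each cycle. Under `"independent"`
(strength 0) each muscle keeps its own roster phase — extensors in early
stance, plantarflexors at push-off, flexors in swing, hamstrings in late
swing, every opposing group separated by at least a quarter cycle — with
per-cycle phase jitter (±5% of the cycle) and independent amplitudes.
Intermediate strengths interpolate both mechanisms.

What the generator does *not* emulate: motion-capture kinematics and
inverse dynamics (angles are idealised harmonics), ground-reaction forces,
frontal/transverse DOFs, motor-unit-level EMG physiology, inter-leg phase
offsets, and the EMG-driven calibration optimisation itself (calibrated
parameters are inputs here). Passing tests on this generator therefore
demonstrate the correctness of the *pipeline* — filters, mechanics,
indices, statistics — and the recoverability of designed-in effects; they
do not certify performance on real hemiparetic data.

## The end-to-end verification experiment

The headline check runs the full pipeline at the study conditions (10 gait
cycles, 1 kHz EMG, 101-point grid) under both coupling scenarios with the
same subject. Under coupling, the best antagonist pair per DOF for
CCI1 computed from delayed envelopes correlates strongly with joint
stiffness (mean per-cycle r ≈ 0.8–0.95 per DOF, well above 0.7). The
independent scenario is evaluated as a *matched control*: the same pairs
identified under coupling are re-measured, and their scenario-level mean
correlation falls near zero (|mean r| < 0.3), with a rank-sum p-value far
below 0.05 between the two scenarios' per-cycle correlation sets. The
matched-pair design is deliberate: re-maximising over all ~28 pairs under
independence would reward selection noise and the residual
envelope-processing structure described above, which is not the question —
the question is whether the association found under co-activation coupling
vanishes when the coupling is removed. With delays present in the
ground-truth mechanics, delay-aware variants (delayed, calibrated) beat
the basic variant for CCI1, reproducing the expected ordering.

Problem sizes throughout the test suite are chosen for speed at full
fidelity: trials of 2–10 cycles at 1 kHz, oracle sweeps of 15–25 random
models × 101 grid points, 1000+ random CCI pairs, and rank-sum enumeration
to combined n = 12. The complete suite runs in well under a minute.

## Known limitations

* The rigid-tendon assumption makes fibre kinematics algebraic; compliant
  tendons would lower stiffness estimates, and no equilibrium solve is
  provided.
* The force–velocity multiplier is fixed at 1 in the stiffness partial
  derivative (position-only elasticity). Freezing it at measured velocity
  instead would scale forces but is not the default.
* The passive force–length slope has a kink at optimal fibre length (zero
  below, exponential above); the stiffness slope is therefore
  discontinuous exactly at $\tilde l = 1$.
* Activation integration is first-order (backward Euler); its agreement
  with a fine-step oracle is ~10⁻³ for envelope-like smooth excitation but
  degrades for step-like inputs.
* Pair enumeration is exhaustive over individual muscles; muscle-group
  averaging (e.g. a pooled quadriceps channel) is not implemented.

## A worked run

```{r run, eval = FALSE}
subject <- make_subject(seed = 1)
sim <- make_gait_trial(subject, n_cycles = 10, coupling = "coupled",
                       seed = 1)
fit <- cci_stiffness(subject, sim$trial, legs = "non-paretic")
summary(fit)
plot(fit, leg = "non-paretic", dof = "ankle_dorsiflexion")
```

`run_pipeline(run_config(seed = 1))` performs the same analysis end to end
and writes every intermediate (subject JSON, kinematics/EMG/event files,
per-variant envelopes, stiffness, correlations, best-pair report) as
provenance-stamped delimited text under one output directory.
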