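---
title: "Quantitative saturation-transfer MR fingerprinting: model, networks and schedule optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative saturation-transfer MR fingerprinting: model, networks and schedule optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stmrf)
```

# The physical model

`stmrf` simulates saturation-transfer (ST) MRI with a three-pool
Bloch–McConnell exchange model: free bulk water (w), a mobile solute pool
of amide protons (s, resonating at +3.5 ppm from water), and a semisolid
macromolecular pool (m) with a microsecond-scale T2. RF irradiation at
frequency offset Ω with amplitude B1 saturates the solute and semisolid
pools; proton exchange transfers that saturation to water, attenuating the
measurable water signal (CEST and MTC contrast respectively). Direct
exchange between the solute and semisolid pools is neglected, as is
standard.

The state vector has seven components — x, y, z magnetization for water
and solute, z only for the semisolid pool, whose transverse coherence
lifetime (T2m of order 10 µs) is far shorter than any other timescale and
is absorbed into an RF absorption *rate*

$$R_{rf}^m = \pi\,\omega_1^2\, g(\Delta_m, T_2^m), \qquad
\omega_1 = \gamma\, rB_1\, B_1,$$

where $g$ is the super-Lorentzian lineshape evaluated at the offset
$\Delta_m$ of the RF from the semisolid resonance. Each dynamic scan of
duration $T_s$, preceded by a relaxation delay $T_d$, is simulated
independently with the exact transient closed form

$$M = \left(M_0\,(1 - e^{-R_1^w T_d}) + A^{-1}B\right) e^{A T_s} - A^{-1}B,$$

where $A$ is the 7×7 evolution matrix (relaxation, precession, RF
nutation, exchange), $B$ the thermal-recovery drive, and the initial
condition applies the post-readout saturation recovery to the longitudinal
components only (transverse magnetization is spoiled by the crusher at the
end of saturation and by the readout). The matrix exponential uses
scaling-and-squaring with Padé approximation. The recorded, S0-normalized
signal is $|M_z^w|/M_0^w$: magnitude reconstruction makes the sign
unobservable, which only matters for near-resonance water-band scans where
strong RF can nutate water Mz through zero.

Conventions fixed in the implementation:

* pool fractions relative to water protons at 111 M: $f_s = M_0^s
  [\mathrm{mM}]/111000$, $f_m = M_0^m[\mathrm{M}]/111$, with reverse
  exchange rates from detailed balance ($k_{ws} = k_{sw} f_s$, $k_{wm} =
  k_{mw} f_m$);
* 3 T field: 1 ppm = 127.73 Hz; $\gamma$ = 267.522 rad s⁻¹ µT⁻¹;
* the static-field offset ΔB0 (Hz) shifts every pool resonance; the
  semisolid resonance sits *upfield* of water by Δmw ppm (the sign is not
  observable from the magnitude of far-offset scans alone, but upfield
  placement reproduces the usual negative MT asymmetry: stronger semisolid
  saturation at negative offsets);
* solute and semisolid longitudinal rates are fixed at $R_1^s = R_1^m =
  1\ \mathrm{s^{-1}}$, the customary assumption for parameters the data
  cannot resolve;
* solute transverse dynamics are simulated in full, so the solute line is
  implicitly Lorentzian with width $1/T_2^s$.

## Super-Lorentzian lineshape and its extrapolation

The semisolid absorption lineshape is the orientation average

$$g(\Delta) = \int_0^1 \sqrt{\frac{2}{\pi}}\;
\frac{T_2^m}{|3u^2 - 1|}\,
\exp\!\left(-2\left(\frac{2\pi \Delta\, T_2^m}{3u^2-1}\right)^2\right) du,$$

which diverges at $\Delta = 0$. Away from resonance
($|\Delta| \ge 1$ kHz) the integral is evaluated by 256-point
Gauss–Legendre quadrature split at the magic-angle orientation
$u = 1/\sqrt 3$, where the integrand has sharp structure (the split keeps
the rule accurate to better than $10^{-6}$ relative wherever the lineshape
has physical magnitude). Inside 1 kHz the value is taken from a natural
cubic spline through quadrature anchors at ±(1, 1.5, 2, 3, 5, 8, 12, 20,
30, 50, 100) kHz — the standard "extrapolated super-Lorentzian", which
removes the on-resonance singularity and, because the resulting
signal-versus-parameter map is only piecewise defined, also removes any
closed-form derivative: this non-differentiability is exactly why a neural
surrogate is used for schedule optimization.

## Tissue parameters and sampling bounds

Eleven quantities describe a voxel (`tissue_bounds()`):

| parameter | meaning | range | unit |
|---|---|---|---|
| T1w | water longitudinal relaxation | 0.2–3.0 | s |
| T1w/T2w | relaxation-time ratio (T2w derived) | 1–30 | – |
| kmw | semisolid→water exchange rate | 5–100 | Hz |
| M0m | semisolid pool concentration | 0–27.5 | M |
| T2m | semisolid transverse relaxation | 1–100 | µs |
| Δmw | semisolid shift from water | 0–5 | ppm |
| ksw | solute→water exchange rate | 5–500 | Hz |
| M0s | solute concentration | 0–550 | mM |
| T2s | solute transverse relaxation | 1–100 | ms |
| ΔB0 | static field offset | ±128 (±64 during schedule optimization) | Hz |
| rB1 | relative transmit field | 0.5–1.5 | – |

T2s has no tabulated range in the source protocol; 1–100 ms spans mobile
solutes and is configurable. The quantifier estimates eight of these
(T1w, kmw, M0m, T2m, Δmw, ksw, M0s, ΔB0); T2s, the ratio and rB1 act as
nuisance dimensions, with the measured rB1 supplied to the quantifier as
an input.

# Acquisition schedules

A protocol is 63 dynamic scans of $(B_1, \Omega, T_s, T_d)$ split into
three bands: 3 water/B0 scans (±1 ppm), 20 MTC scans (8–40 ppm, both
signs, probing the asymmetric semisolid spectrum) and 40 APT scans (3–4
ppm around the amide resonance). Parameter ranges are 0.5–2.4 µT, 0.3–2.5 s
and 1.5–5.0 s, under the SAR feasibility constraint $B_1 \times T_s \le 4$.

* `linear_schedule()` sweeps each parameter monotonically across its range
  within each band (SAR-violating combinations are clipped by shortening
  Ts to the feasible boundary) — the deliberately redundant comparator.
* `pseudo_random_schedule(seed)` samples uniformly with a round-robin
  stratification over the four B1×Ts quadrants per band (high/low B1
  crossed with long/short Ts, with a seeded starting phase so every
  quadrant is visited in every band across seeds) and rejects
  SAR-infeasible draws.
* `loas_optimize()` produces the optimized schedule (below).

# The networks

Both networks are fully connected, ReLU-activated, sigmoid-bounded
multilayer perceptrons trained with Adam on an L1 loss with a step
learning-rate decay and lowest-validation-loss checkpointing (90/10
split). All inputs and outputs are normalized to [0, 1] by the sampling
bounds.

**dBES** (deep Bloch-equation simulator, `train_dbes()`) maps the 15
normalized tissue + scan values to one signal value. It serves two
purposes: fast batch synthesis, and — because a network is exactly
differentiable — a gradient path through the otherwise non-differentiable
forward model. The reference architecture is 7×256 trained on 10⁸
samples; desk presets are recorded in the model metadata:

* `small`: 5×128, 45 epochs, initial learning rate 10⁻³ (decay 0.1 every
  18 epochs). The reference configuration pairs its 10⁻⁴ rate with two
  orders of magnitude more optimizer steps; at desk scale the larger rate
  is needed to reach the converged regime.
* `slice`: 4×64 on the two-parameter (ksw, M0s) slice with all other
  tissue parameters fixed (T1w = T2w = 1 s, remaining at bound midpoints,
  ΔB0 = 0, rB1 = 1) and the scan fixed at 1.5 µT / 3.5 ppm / 2 s / 5 s —
  the surrogate-fidelity benchmark setting.

Out-of-range prediction inputs are clamped to the training bounds with a
warning; a sigmoid network extrapolates smoothly and silently, which is
the dangerous failure mode.

**dTPQ** (tissue-parameter quantifier, `train_dtpq()`) maps a 63-scan
signal vector plus the measured rB1 to the eight normalized parameters.
Training signals come from a selectable forward model (exact simulator or
a trained surrogate; the metadata records which) and are corrupted afresh
every pass with white Gaussian noise at a per-example SNR drawn uniformly
from 40–46 dB. The SNR is defined against the unit S0 reference:
$\sigma = 10^{-\mathrm{SNR}/20}$, so 40 dB means σ = 0.01 on the
normalized signal scale. A trained quantifier is hard-bound to its
schedule by a content hash — quantifying signals from a different
schedule would be silently wrong, so it is an error instead. ΔB0 is both
an output and, optionally, an input to `b0_shift_correction()`, which
re-interpolates the APT band onto offsets shifted by −ΔB0; the default
pipeline feeds raw signals, matching the optimization loop.

# Schedule optimization (LOAS)

`loas_optimize()` treats the 63×4 scan parameters as free variables. Each
parameter is an unconstrained logit decoded through a sigmoid into its
physical range — bound feasibility holds by construction at every
iterate. Offsets are decoded within their band only, and MTC scans keep
the sign of their initial offset; the band structure (3/20/40) is fixed.

Each step synthesizes signals for a minibatch of tissue samples through
the *frozen* surrogate, adds 40–46 dB noise, quantifies with a co-trained
dTPQ, and evaluates

$$L_{total} = \big|p_t - \mathrm{dTPQ}(\mathrm{dBES}(p_t, p_s; \eta),
rB_1)\big|_1 + \big|\max(B_1 \times T_s - 4,\, 0)\big|_1 .$$

The loss is backpropagated simultaneously into the dTPQ weights (Adam,
10⁻⁴) and — through the surrogate's input gradient — into the schedule
logits (Adam, 10⁻²). ΔB0 is sampled in ±64 Hz here (field inhomogeneity
the protocol must tolerate, not the full quantifier training range).
Choices made where the design was open: logits are initialized from a
seeded pseudo-random schedule; the SAR hinge enters with weight 1; the
returned schedule is the lowest-validation-loss iterate, with any residual
SAR excess (the hinge drives it to ~0 but not exactly 0) clipped to the
feasible boundary; the co-trained quantifier is returned for inspection,
but the deployed quantifier is retrained from scratch on the frozen
optimized schedule so that all schedules are compared with identically
trained quantifiers.

# Digital phantoms and evaluation

`build_digital_phantoms()` constructs eight 64×64 maps, one per estimated
parameter, each with five disk compartments (radius 10 px; the geometry is
cosmetic, metrics use only the labels) carrying fixed values — e.g. 50,
150, 250, 350, 500 Hz for ksw and −80…80 Hz for ΔB0 — while the remaining
parameters are drawn once per phantom (seeded) and held constant; rB1 is
fixed at 1. `build_precision_phantom()` builds the fine ladders (ksw 50 →
500 Hz and M0s 10 → 500 mM in steps of 10) with per-compartment random
nuisance parameters, for adjacent-compartment two-sided t-tests of
discrimination power.

Accuracy metrics: nRMSE = 100 · RMSE / (sampling-range width) — the
range normalizer keeps phantoms with different truth spreads comparable
(a truth-spread normalizer is available via `norm = "truth"`) — and MAE
in native units.

`run_schedule_comparison()` executes the full study: surrogate training,
schedule optimization from a pseudo-random initialization, per-schedule
quantifier retraining (exact-simulator forward model, for fairness and to
keep surrogate error out of the comparison), and phantom scoring at 46 dB
SNR.

# Numerical choices and problem sizes

* Matrix exponential: Padé scaling-and-squaring (7×7, machine accuracy).
* Quadrature: 256 Gauss–Legendre nodes split at $u = 1/\sqrt{3}$;
  spline anchors as listed; the cutoff at 1 kHz.
* Logits are clamped to ±6 when encoding an existing schedule (values on
  a range boundary would otherwise be infinite); decoded values are
  asserted inside their bounds every epoch.
* Schedule files render numbers with 12 significant digits, which makes
  the text → double → text round trip exact.
* Desk-scale study sizes (the package's default study conditions, recorded
  in every model's metadata): 1.5×10⁵ surrogate training samples, 10⁵ for
  the slice benchmark, 3072 tissue samples × 32 epochs for schedule
  optimization, 1.2×10⁴ samples per quantifier, 12 680 phantom voxels.
  The reference pipeline uses 10⁸/4×10⁷ samples and 100 epochs throughout;
  desk-scale results are therefore noisier in absolute terms, and the
  meaningful desk-scale claims are relative ones (schedule orderings,
  convergence behavior), not the reference pipeline's absolute error
  levels.

# What the synthetic data does and does not emulate

The generator reproduces the *simulation* conditions: uniform parameter
draws inside the sampling box, ideal continuous-wave saturation, white
Gaussian measurement noise at 40–46 dB, and field inhomogeneities as a
per-voxel (ΔB0, rB1) pair. It does not emulate pulsed or shaped
saturation, relaxation during the readout train, inter-scan magnetization
carry-over, motion, spatially correlated noise, partial-volume mixtures,
or parameter correlations found in tissue. Tests passing on this
generator therefore validate the algorithmic pipeline, not in vivo
performance.

# Known limitations

* Exchange saturates the labeling efficiency at the fast end of the ksw
  range ($\omega_1$-limited), so the signal-versus-ksw curve flattens by
  ~10⁻³ near 500 Hz at 1.5 µT rather than decreasing strictly — visible
  as a tolerance in the monotonicity checks, and a genuine identifiability
  limit for fast-exchanging solutes at clinical B1.
* The sign of Δmw is a convention (upfield), not an estimate.
* A 5×128 surrogate trained on 1.5×10⁵ samples carries ≈0.9% mean
  absolute signal error — an order of magnitude above the measurement
  noise floor it is asked to optimize through; schedule optimization
  still works because it needs gradients, not absolute accuracy, but the
  co-trained loss values should not be read as absolute error estimates.
* Quantifier accuracy at desk scale is sample-limited; bound-respecting
  sigmoid outputs shrink estimates toward the interior of the box when
  information is weak.
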