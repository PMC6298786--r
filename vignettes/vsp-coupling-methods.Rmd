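---
title: "Methods: quantifying VSP domain-membrane coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying VSP domain-membrane coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vspkit)
library(dplyr)
```

## The scientific problem

Voltage-sensing phosphatases (VSPs) couple a transmembrane voltage-sensor
domain (VSD) to a cytoplasmic catalytic region (CCR) — a PTEN-like
phosphatase domain (PD) plus a C2 domain — that dephosphorylates membrane
phosphoinositides when the VSD moves. Whether and how the PD engages the
bilayer, and how that engagement translates into enzyme activity, are
quantified through three very different kinds of measurement, each with its
own bespoke analysis:

1. **Molecular-dynamics trajectories** of the CCR near a planar bilayer,
   classified frame-by-frame into membrane-bound / unbound states of each
   domain and into a "productive" orientation of the whole region;
2. **Episodic voltage-clamp recordings** in which the decay of a
   PI(4,5)P2-dependent Kir current across repeated depolarizations reports
   phosphatase activity as a rate constant;
3. **Voltage-clamp fluorometry (VCF)** sweeps whose fluorescence-voltage
   (F-V) relations decompose into one or two Boltzmann components, revealing
   one- versus two-step activation.

vspkit implements all three analyses as composable, tibble-in / tibble-out
functions, plus synthetic-data generators that produce every input with
recorded ground truth, so the full pipeline is testable without simulation
or recording hardware.

## Membrane binding and productive orientation

### Depth reference and binding rule

All depths are measured along the membrane normal (+z points from the
cytoplasmic side toward the proximal monolayer, so the protein sits at
negative relative z) against the **phosphorus layer**: the per-frame mean z
of the proximal monolayer's lipid phosphorus atoms (a median option exists
for robustness; the mean is the default estimator since the lattice of
phosphorus atoms is approximately symmetric about its plane).

A domain is **bound** when its *top atom* — the selection's highest-z atom —
sits at or above a cutoff relative to that layer. The cutoff depends on
resolution and bilayer composition, because bulky PIP3 headgroups hold
protein atoms further from the phosphocholine phosphates:

| system | cutoff (Å) |
|---|---|
| atomistic / POPC | 0 |
| atomistic / POPC + PIP3 | −4 |
| coarse-grained / POPC | −2 |
| coarse-grained / POPC + PIP3 | −12 |

Equality counts as bound ("at the cutoff or higher"). Coarse-grained times
are reported as effective times (raw × 4), the usual convention for dynamics
on a smoothed energy landscape.

### Orientation

Two vectors are rooted at the PD's Arg-281 Cα: **v1** to the midpoint of the
Lys-516/Arg-520 Cα pair (the CBR3-like loop of the C2 domain) and **v2** to
the midpoint of the Lys-555/Lys-558 Cα pair (the β8–9 loop). The pose is
**productive** when the cross product v1 × v2 lies within 0–30° of +z, the
band closed at both ends (the conservative reading of "0–30°"; the bound is
configurable). As a diagnostic, the His-332 Cβ / Lys-367 Cα depth asymmetry
is reported — in the productive pose the catalytic center sits level, with a
difference below about 0.3 Å.

Two genuinely open conventions are exposed rather than guessed:

* **Cross-product order.** v1 × v2 versus v2 × v1 differ by reflection
  (θ versus 180° − θ), and the z-axis sign convention interacts with the
  same choice. The default is v1 × v2 against the +z axis defined above;
  `classifier_config(cross_order = "v2xv1")` selects the mirror convention.
* **Equilibration.** Time fractions use the whole trajectory by default;
  callers can drop an equilibration prefix by filtering the trace tibble
  before `summarize_binding()`.

Frames with collinear anchor vectors (zero cross product) are flagged
degenerate, counted non-productive, and reported with a warning. Time
fractions are frame counts over total frames under uniform sampling;
trapezoidal time weighting is available for non-uniform frame spacing.

```{r binding-demo}
sch <- schedule_block(200, f_pd = 0.4, f_c2 = 0.6, f_productive = 0.3)
traj <- sim_membrane_trajectory(sch, resolution = "at", bilayer = "popc")
trace <- analyze_trajectory(traj, "at", "popc")
summarize_binding(trace)
```

### What the trajectory generator emulates — and what it does not

`sim_membrane_trajectory()` builds planar phosphorus lattices for both
monolayers, rigid pseudo-atom blobs for the PD and C2 domain whose top atoms
sit a fixed margin (default 5 Å) above or below the system's cutoff
according to a schedule, spine atoms riding on the PD, and anchors on a
rigid internal frame rotated to 10° (productive) or 90° (non-productive).
Occupancy schedules are either exact deterministic blocks or a stationary
two-state telegraph process whose occupancy is prescribed in closed form.
Gaussian jitter may be added; a guard refuses jitter whose 3-SD envelope
(for the angle, via a conservative linearized bound) could flip any
scheduled state, which is what makes "scheduled occupancies are reproduced
exactly" a provable property rather than a statistical one.

The generator is deliberately minimal: rigid bodies, a flat bilayer, no
lipid dynamics, no gradual approach/detachment, no correlation between
binding and orientation. Passing tests therefore certify the *classifiers*
(geometry, cutoffs, bookkeeping), not any ability to cope with soft-matter
realism — force-field artifacts, membrane undulations, or partial
insertions lie outside what these tests can show about real trajectories.
Real structure/trajectory data enter through the documented long-format CSV
(columns `frame, time_ps, atom_id, role, monolayer, x_nm, y_nm, z_nm,
mass_amu`); single PDB structures can be adapted with
`read_structure_frame()`. Binary trajectory containers are out of scope for
this package's I/O; upstream tools export the CSV.

## Phosphatase activity from Kir current decay

The readout protocol repeats, per episode: a 50 ms ramp, a 50 ms test pulse
at −120 mV whose end-point current amplitude reports the PI(4,5)P2 level,
and a depolarization (300 ms standard, 50 ms for fast constructs) at +50 mV
that activates the enzyme; holding potential −60 mV, 20 episodes.
Amplitudes are extracted as the mean over the final 2 ms of the test pulse
(more noise-robust than the literal last sample; the window is
configurable, and one sample period reproduces the end-point reading),
normalized to episode 1, and laid out against accumulated depolarization
time (episode i at (i − 1) × depolarization duration).

The decay is fit with `I(t) = (1 − C)·e^{−kt} + C` by Levenberg–Marquardt
least squares. The plateau `C` is free in [0, 1) by default, because
normalized Kir currents visibly approach non-zero floors; a pure
exponential (`plateau = "zero"`) is available, and the choice is recorded in
the fit object. The raw LM routine is used rather than an `nls`-style
wrapper because for slow decays over a short accumulated-time span the
(k, C) Jacobian columns are nearly collinear and `nls`-family fitters
reject the start; damping handles that regime, and noiseless recovery holds
across k from 0.05 to 15 s⁻¹.

**Capping rule.** When the second episode's normalized amplitude falls
below 1% of the first, the decay is too fast for the protocol to resolve;
fitting is skipped and the result is the conventional capped pair
τ = 0.065 s, k = 15.4 s⁻¹ (the pair as conventionally reported; 15.4 equals
1/0.065 at that precision), flagged `capped = TRUE`. The rule looks only at
episode 2, so later noise cannot un-cap a saturated recording.

```{r decay-demo}
rec <- sim_kir_recording(k = 2, C = 0.1, noise_sd = 0.02, seed = 1)
fit <- fit_decay(build_decay_series(rec))
glance(fit)
```

Sign conventions: inward currents are negative, amplitudes are compared by
magnitude through the normalization, and k is reported positive. No
multiple-comparison correction is applied by `compare_groups()` (raw
pairwise two-tailed t-tests, equal-variance by default with a Welch
option).

### Off-sensing charge

Gating charge is integrated from a repolarization step (150 mV to the
−60 mV holding potential). The P/N subsweeps — assumed to be same-polarity
1/N-amplitude steps — are summed, rescaled by N over the subsweep count, and
subtracted; the residual is baseline-corrected by the mean of the 5 ms
before the step and integrated by trapezoid (1 µA·ms = 1 nC) from the step
onset until the transient decays below 1% of its peak (or a fixed window,
by option). Linear leak and constant offsets cancel exactly by
construction, which the tests assert as invariances. The adaptive 1% stop
truncates at most 1% of an exponential transient's area, within the 2%
recovery budget the generator-recovery test enforces.

## F-V decomposition and kinetics

### Extraction

`extract_fv()` reduces per-voltage ΔF/F sweeps to an F-V curve by one of
three strategies used for the three probes: the mean of the last 1 ms of
the 500 ms pulse (slow probes, e.g. TMRM at position 214), the end-point
sample (non-plateauing probes, e.g. Anap at position 555), or the sample at
the peak time of a designated reference trace (transient probes, e.g. TMRM
at position 208, referenced to the 200 mV trace), with linear interpolation
between samples. Normalization to the reference-voltage value is applied on
request even when the curve has not saturated there (as is done for
non-saturating mutants); the choice is recorded in the result's attributes.
The peak-time reference is the per-dataset reference trace, since a
cross-cell reference is not transferable between recordings.

### Boltzmann fits

F-V curves are fit with `F(V) = Σᵢ Aᵢ / (1 + exp((V − V½,ᵢ)/sᵢ))`, one or
two components. Slopes are constrained positive via log-parametrization;
the direction of each fluorescence change is carried by the sign of Aᵢ.
Half-maximum potentials are seeded from half-amplitude crossings of the
data, and a deterministic grid of 16 start variants (V½ offsets ±15–40 mV,
amplitude splits 10–75%, slope scalings) guards against local minima — a
deterministic grid rather than seeded random jitter, so reproducibility
needs no RNG state. Components are reported ordered V½,1 < V½,2 with the
amplitude-share ratio Aᵢ/(A₁+A₂)·100 when the amplitudes share a sign.
Flat data raise a degenerate-fit error; fewer than 4 points per component
are refused.

```{r boltzmann-demo}
fv <- sim_fv_dataset(wt_boltzmann_components())
fit_boltzmann(fv, 2)$params |> select(component, A, v_half_mV, slope_mV, ratio_pct)
```

### Model selection and its statistical limits

`select_model()` fits both models and chooses by small-sample-corrected AIC
(default) or the extra-sum-of-squares F-test; both criteria are always
reported. With the default generator truth (ratio 24.3/75.7, V½ 27.1/82.7
mV, slopes 10/15 mV — the slopes are this package's choice of realistic
steepness, as published decompositions report ratio and V½ but not slope),
the best-fitting *single* Boltzmann deviates from the two-component curve
by only ~1.7% RMS of the total amplitude on a 20 mV voltage grid. Model
selection is therefore only reliable when the noise is clearly below that
structural residual: at 0.5% noise the default criterion selects correctly
in ≳95% of replicates for both truths, while at 3% noise *no* decision rule
can reach that figure on this grid (the optimal likelihood-ratio detector's
signal-to-noise ratio, ‖d‖/σ ≈ 2.2, is below the ≈3.3 needed for 95% power
at 95% specificity). The practical reading: distinguishing one- from
two-step activation at realistic single-cell noise requires averaging
across cells or denser voltage sampling, which is exactly why published
work fits averaged F-V curves.

### Kinetics

`compute_t_half()` returns the first linear-interpolated crossing of
baseline + ½(extremum − baseline) within the analysis window (the window
start's value is the default baseline). `fit_fluorescence_kinetics()` fits
`ΔF(t) = Σᵢ Aᵢ (1 − e^{−t/τᵢ})` with one or two components
(log-parametrized τ, τ_fast < τ_slow, slow fraction = |A_slow| / Σ|Aᵢ| ×
100). On a pure single exponential the two-component fit degenerates
gracefully (vanishing second amplitude or coincident τs), which is tested.

The sweep generator scales its relaxation so that the final sample equals
the generating F(V) exactly, making end-point extraction an exact inverse
at zero noise — a construction chosen so generator/extractor consistency is
an identity, not a tolerance.

## Numerical and design choices, in one place

* Units: coordinates in nm in, depths in Å out; currents µA, charge nC
  (1 µA·ms = 1 nC); times ps (trajectories), ms (sweeps), s (decay fits);
  voltages mV.
* Boundary conventions: binding cutoff inclusive; productive band [0°, 30°]
  closed; cap threshold strict (`< 1%`).
* Estimators: phosphorus plane mean (median optional); center of mass
  mass-weighted when masses are present, uniform otherwise (coarse-grained
  beads often carry none).
* Fitting: Levenberg–Marquardt throughout; decay fit via raw `nls.lm` with
  box constraints; Boltzmann/kinetics via `nlsLM` with log-positive scale
  parameters and deterministic multi-starts; AICc uses p = parameters + 1.
* Degenerate inputs: empty selections, missing anchors (named in the
  error), flat F-V data, non-crossing traces, and mismatched P/N timebases
  all raise classed errors; non-decaying series warn and return k ≈ 0.
* Determinism: every generator takes a seed, restores the caller's RNG
  state, and attaches a `ground_truth()` attribute (generator name, seed,
  all parameters, and closed-form expectations) sufficient to regenerate
  the dataset bit-identically.
* Problem sizes used by the test-suite and the acceptance script — 1000
  oracle-checked frames, 100-recording and 100-dataset Monte-Carlo
  batches, 200-frame scheduled trajectories — were chosen to make
  recovery statistics stable at desk scale.

## Known limitations

* The trajectory generator's rigidity means classifier robustness to
  partial insertion, tilt drift, or bilayer undulation is untested here.
* The F-V model has no additive offset term; curves that do not decay to
  zero at depolarized potentials must be baseline-referenced before
  fitting.
* Capped decay results carry no uncertainty (nothing was fit).
* Model selection near the identifiability boundary (noise comparable to
  the single-component structural residual) favours the simpler model by
  construction; report both criteria, or average replicates first.
* `compare_groups()` deliberately applies no multiplicity correction.
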