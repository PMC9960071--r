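---
title: "Models and methods behind kosens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kosens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kosens` implements the quantitative analyses used to characterize the
inhibition of KCNQ1-type potassium channels by external K⁺: dose–response
fitting with driving-force correction, tail-current inactivation analysis,
single-channel amplitude analysis, and ion-permeation analysis of molecular
dynamics (MD) trajectories. This vignette documents the models, the tunable
parameters and their defaults, the numerical conventions, and what the
synthetic-data validation does and does not demonstrate.

## The biophysical models

### GHK flux and the driving-force correction

Outward current through an open K⁺ channel in the constant-field
approximation is

$$I = P\,\frac{V_m F^2}{RT}\,
      \frac{K_i - K_o e^{-V_m F/RT}}{1 - e^{-V_m F/RT}},$$

with permeability $P$ (cm/s), concentrations in mM (≡ mol/m³) and voltage in
mV at the interface (converted internally; `F = 96485` C/mol, `R = 8.314`
J/(mol·K), `T = 293` K by default). The expression has a removable
singularity at $V_m = 0$; `ghk_flux()` switches to the second-order series
$(K_i-K_o)(1 + u/2 + u^2/12) + K_o u$, $u = V_mF/RT$, for $|u| < 10^{-4}$,
keeping the function continuous (the limit at 0 is $P F (K_i - K_o)$). The
absolute scale is a current density (A/m²) per unit area; every analysis in
the package uses either ratios of GHK currents or a fitted amplitude, so this
scale convention never reaches the user.

Raising external K⁺ reduces outward current even for a channel that is not
modulated at all, simply by loss of driving force. The expected size of that
trivial effect relative to a reference concentration $C_{ref}$ is the GHK
current ratio

$$I_{th}(C) = \frac{K_{in} - C\,e^{-V_mF/RT}}{K_{in} - C_{ref}\,e^{-V_mF/RT}},$$

implemented in `ghk_current_ratio()` and applied by `ghk_correct()`. At the
standard test-pulse conditions ($V_m$ = +60 mV, $K_{in}$ = 108 mM,
$C_{ref}$ = 0.2 mM) the ratio at 100 mM K⁺ₒ is 0.914: an unmodulated channel
loses 8.6% of its current from driving force alone.

**Correction mode.** Experimental descriptions of this correction commonly
say the theoretical values were "subtracted", which taken literally
($obs - I_{th}$) cannot yield values near 1 at the reference concentration.
We read it as subtracting the theoretical *reduction*:
$corrected = obs + (1 - I_{th})$, the additive default. Because the
physically generative relation is multiplicative
($obs = \text{modulation} \times I_{th}$), a multiplicative mode
($obs / I_{th}$) is provided as well. The two agree to first order while
$|1 - I_{th}| \ll 1$ (below ~20 mM K⁺ₒ at these conditions they differ by
< 0.01; at 100 mM they differ by ~0.04). Internal K⁺ defaults to 108 mM —
the conventional oocyte value; published work alternates between 108 and
109 mM, and the parameter is exposed.

### Hill inhibition curve

Normalized current as a function of inhibitor (external K⁺) concentration is

$$I(C) = (1 - I_{max}) + \frac{I_{max}}{1 + (C/IC_{50})^{n_H}},$$

so $I(0) = 1$ and $I(\infty) = 1 - I_{max}$. `fit_hill()` estimates
$(I_{max}, IC_{50}, n_H)$ by Levenberg–Marquardt least squares
(`minpack.lm`), with box constraints $I_{max} \in [0,1]$, $IC_{50} > 0$,
$n_H \in [0.05, 10]$. Starting values are heuristic: $IC_{50}$ at the
geometric midpoint of the concentration range, $I_{max}$ from the response
span, $n_H = 1$; the first converged optimum from that start is reported.
Standard errors come from the Jacobian-based covariance
($\sigma^2 (J^TJ)^{-1}$); there is no bootstrap, because experimental
reporting aggregates per cell (see below). A flat response drives $I_{max}$
to 0 and leaves $IC_{50}$ and $n_H$ unidentifiable; such fits are flagged
`converged = FALSE` and excluded from aggregation.

Like all nonlinear least-squares estimators these fits carry an $O(\sigma^2)$
finite-sample bias (for the 5-concentration design at noise SD 0.02 the
$IC_{50}$ bias is about +3%); the test suite verifies unbiasedness at low
noise where the Monte-Carlo SEM dominates, and verifies accuracy at the
working noise level at the ensemble tolerances appropriate there.

### Per-cell aggregation

`fit_series()` fits each cell separately and reports the parameter means with
SEM over cells, matching the way dose–response tables report
mean ± SEM with $n$ = cells. A pooled fit over all points is available
(`aggregate = "pooled"`) but is not the default: per-cell fitting keeps the
between-cell variance visible and is robust to cell-to-cell amplitude scale
differences. Normalization inside `build_series()` uses the mean of the three
retained reference-concentration points, not the first pulse.

### Boltzmann activation with offset

Channels with a voltage-independent conductance component are described by

$$G/G_{max} = \frac{1 - G_{min}}{1 + e^{(V_{1/2} - V)ZF/RT}} + G_{min}.$$

`fit_boltzmann()` fits $(V_{1/2}, Z, G_{min})$ with $Z$ free by default;
whether the original analysis fitted or fixed $Z$ is not documented, so
`fix_z` exposes both modes (fixing $Z$ changes the $V_{1/2}$ sampling
variance only marginally). Saturated data (no lower asymptote in range) are
flagged unidentifiable via the covariance and a $V_{1/2}$-uncertainty bound.

### Permeability ratios

Bi-ionic substitution shifts the reversal potential by
$\Delta E_{rev} = (RT/ZF)\ln(P_X/P_K)$; `permeability_ratio()` inverts this.
`estimate_reversal()` interpolates the zero-current crossing linearly between
the bracketing voltages of an instantaneous IV relation; on noiseless GHK
data with ≤ 10 mV grid spacing the interpolation error is below 0.5 mV.

## Tail currents and fractional fast inactivation

Repolarization tails of fast-inactivating KCNQ1 show a "hook": current first
grows as channels recover from inactivation, then deactivates.
`fit_tail_multiexp()` fits

$$I(t) = a_0 + \sum_{i=1}^{k} a_i e^{-(t - t_0)/\tau_i}, \qquad k \in \{2,3\}$$

between two cursors, with the time origin $t_0$ at the tail-segment start so
that extrapolation to the segment beginning is evaluation at $t_0$. Defaults:
cursor 1 at $t_0 + 7.5$ ms — the midpoint of the conventional 5–10 ms
clearance after the capacitive transient — and cursor 2 at 97% of the
segment. The capacitive transient is excluded by the cursor, never by
filtering. Time constants are fitted on a log scale; amplitudes are
initialized by linear least squares at each of three geometric $\tau$ seeds
and the best converged optimum is kept. With $k = 3$ the fit falls back to
two components when the smallest amplitude is below its standard error
(slow tails genuinely have 2–3 resolvable components, not more).

The inactivation statistic is $1 - X/Y$:

* $Y$ — total tail amplitude if all channels were conducting: $a_0$ plus the
  *deactivating* components, evaluated at the segment start.
* $X$ — open-channel current just after the capacitive transient: the fitted
  model value at cursor 1 (default), or the raw sample there
  (`x_source = "raw"`) for users who prefer the literal convention. The
  fitted value is the default because it is noise-robust; the raw sample on a
  single trace inherits the full sample noise.

"Deactivating" is decided in fitted-model space: components whose amplitude
has the same sign as the tail's displacement from baseline at cursor 1; the
recovering hook component opposes that direction. Since $X/Y$ is a ratio,
the statistic is identical for inward and outward tails. With no recovering
component the fraction is 0; values outside $[0,1)$ are clipped with a
warning, and $Y = 0$ is an error.

## Single-channel analysis

All-point histograms (`all_point_histogram()`, default bin width 0.01 pA,
edges aligned to 0) pool every sample of the baseline-subtracted sweeps.
Baseline subtraction defaults to the mode of the per-sweep amplitude density
(the closed state dominates these slow channels); a constant override exists
because the mode is wrong when open probability approaches 1.
`fit_gaussian_peaks()` fits a sum of $k$ Gaussians to the *histogram counts*
by least squares — the standard treatment of all-point histograms — with $k$
chosen by a BIC-type criterion up to `k_max`. The "largest peak" used for
conductance curves is the non-baseline component with the largest mixture
weight (area rather than height, for bin-width invariance); the baseline is
the component nearest 0 pA. The 200 Hz analysis bandwidth of the source
recordings is modeled in the generator (a 4-pole digital low-pass), not in
the analyzer, which takes filtered data as given.

Conductance comes from linear regression of amplitude on voltage
(`conductance_from_iv()`, slope × 1000 = pS), and slope equality between two
conditions is tested by the classical two-line ANCOVA F test
(`compare_slopes()`: interaction vs common-slope model). Absolute
permeability at each K⁺ₒ comes from `fit_ghk_permeability()`; since the GHK
current is linear in $P$, this is an exact linear projection with a
closed-form standard error. The cell-attached internal K⁺ is not measurable
and defaults to 135 mM (the bath solution, which sets the resting cell K⁺
in these recordings); it is a required, documented parameter.
`permeability_reduction()` converts a low/high-K⁺ permeability pair into a
percent reduction.

## Trajectory analysis

The core contract is a long-format table of ion axial positions
(`time_ns, ion_id, z_A`) with all ions on one uniform frame grid; adapters
from MD trajectory formats are deliberately out of scope (any tool that can
write a z-table can feed the analysis).

**Site map.** z = 0 is the substate reference (center of mass of the four
G314 carbonyl carbons). The filter sites S_cav, S4, S3, S2, S1, S0 are
contiguous bands of width 3.1 Å — a canonical inter-site spacing for K⁺
channels, *not* a measured value — with S2 centered at 0; everything is
configurable via `site_map()` JSON. The permeation completion criterion uses
a separate exit reference (the analysis that defines completion references
the G316 carbonyl oxygens, two residues above the substate reference):
by default +6 Å above the substate reference, with completion when an ion
rises more than 4 Å above it, i.e. z ≥ 10 Å. Both references are parameters
because the two conventions are genuinely distinct in the source analyses.

**Substates.** `classify_substates()` assigns each ion a band per frame with
a 2-frame debounce (a band change must persist two frames, suppressing
boundary chatter from thermal jitter) and renders each frame as a label such
as `"Scav-S3-S2"` (occupied sites, internal to external). Two ions in one
band is physically suspect; such frames are retained but flagged.

**Permeation events.** `detect_permeations()` tracks each ion's last
definitive side (internal bulk: below the S_cav band; external: beyond the
completion coordinate) and emits one event per side change — an ion that
re-enters and exits again yields multiple events, and net flux is conserved
per ion. `current_from_flux()` converts net outward counts to pA
($I = n e / t$; 10 events per 100 ns ≡ 16.02 pA).

**Conduction modes.** An outward event is classified from S_cav occupancy in
a window $w$ before the permeating ion's release from S0 (release = last
frame in the S0 band before completion): *canonical* (knock-on) if S_cav
becomes newly occupied within the window — the intracellular ion binding
below the filter triggers the release above; *spontaneous S0* if S_cav is
vacant throughout the window; *other* for everything else (e.g. S_cav
occupied continuously since before the window). The mechanistic description
gives no operational window; $w$ defaults to 1.0 ns and is exposed, and the
generator's coupling delay (0.3 ns) is set well inside it.

**S0 occupancy by origin.** `s0_occupancy_by_origin()` counts S0 dwell
episodes longer than 0.4 ns — we read the published "0.4 nS" threshold as a
units typo for ns — and attributes each to the site occupied just before
entry (S1 → from the filter; above → from the external solution), reporting
occupied-time fractions.

**Dihedral flips.** `dihedral_flip_stats()` reduces a χ (C–Cα–Cβ–Cγ)
dihedral series to two rotamers (~55° and ~160°) with a boundary at 110° and
a ±10° hysteresis band, returning per-subunit state probabilities and flip
counts. The boundary is configurable per residue because the two rotamer
angles are only approximately known.

## Synthetic data: what it emulates, and what passing tests show

Every generator is deterministic given (configuration, seed), restores the
global RNG state, and logs complete ground truth.

* `gen_dose_response()` — normalized triplets per concentration per cell:
  Hill curve + Gaussian noise (SD 0.02 by default), optionally multiplied by
  $I_{th}(C)$ so the correction step can be exercised, with optional
  amplitude scale, cell-to-cell lognormal spread and additive leak for the
  blank-subtraction path.
* `gen_tevc_trace()` — one depolarize/repolarize sweep: saturating
  activation with a sag to $(1-f)$, and a tail built from a capacitive
  spike (τ 0.8 ms), a recovery hook (τ 12 ms), two deactivating components
  (τ 150 and 700 ms, 35/65 amplitude split) and an offset. The hook
  amplitude is calibrated in closed form so that the analysis statistic
  $1 - X/Y$ at the default cursors equals the programmed fraction exactly on
  noiseless data — the generator defines ground truth *at the measurement
  convention*, which is what makes recovery a well-posed test. Default noise
  is 1.5% of the tail amplitude (≈ 36 dB).
* `gen_single_channel()` — k-level telegraph signal with exponential dwells,
  Gaussian noise, 4-pole low-pass at 200 Hz.
* `gen_iv_ghk()`, `gen_gv_data()`, `gen_reversal_shifts()` — closed-form
  curves plus noise (multiplicative for IV data, additive otherwise).
* `gen_ion_trajectory()` — a scripted continuous-time hopping process on the
  site ladder, rendered onto frames (0.05 ns step) with 0.35 Å Gaussian
  jitter. Permeation events are constructed mode by mode with exact
  largest-remainder counts of the programmed mixture; ascent dwells are
  honest exponentials (rate 2/ns per edge), and external S0 binding is a
  Poisson process with rate ∝ [K⁺]ₒ. It is a validation instrument: the
  generator and analyzer share one site definition, so classification tests
  are well-posed.

What passing recovery tests on these fixtures shows: the analyzers invert
the data-generating conventions they claim to invert, at realistic noise.
What it does not show: that real recordings satisfy those conventions. Real
tails have drifting baselines and imperfectly exponential kinetics; real
single-channel records flicker below the filter corner; real MD ions diffuse
continuously rather than hopping, sites are not rigid bands, and genuine
mode classification is sensitive to the window and band choices in ways the
matched generator cannot probe. The trajectory generator also makes no
physical claims about rates or voltages (no force fields, no CompEL-scale
potentials, no microsecond sampling).

## Problem sizes and numerical conventions

The test and acceptance suites run desk-scale versions of each experiment:
8-cell dose–response ensembles, 8 GV datasets, 10 IV replicates, 20
trajectories of 20 permeations each (400 events pooled for mode-fraction
recovery), and 150-replicate fit-bias ensembles — sizes chosen to give
useful statistical power in seconds of CPU. Levenberg–Marquardt runs with
`ftol = ptol = 1e-12` and up to 200–400 iterations; positive parameters
(τ, mixture SDs and weights) are fitted on the log scale; ties in
model-order selection go to the smaller model via the BIC penalty. Degenerate
inputs follow explicit contracts: empty segments, zero denominators,
non-bracketed reversals and never-stabilizing pulse trains raise errors or
flags rather than returning silent numbers.

## Known limitations

* The dose–response normalization divides by the reference-concentration
  mean; at IC₅₀ ≈ 8 mM the true curve is already ~1.3% below 1 at 0.2 mM,
  a bias inherited from the experimental convention itself.
* Multi-exponential tail fitting is ill-conditioned when time constants are
  within a factor of ~3; the hook statistic is accurate when recovery is
  fast relative to deactivation, as it is for this channel family.
* The Boltzmann $V_{1/2}$ of a shallow-offset curve is information-limited:
  at noise SD 0.03 on a 9-point GV curve its per-dataset SD is ~1.7 mV
  regardless of estimator, so means over small ensembles scatter accordingly.
* `compare_slopes()` tests slope equality only; it is not a full ANCOVA
  table.
* No idealization/event detection for single-channel kinetics (open times,
  Po): amplitude analysis only.
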