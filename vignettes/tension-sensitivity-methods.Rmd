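---
title: "Quantifying membrane-tension sensitivity of mechanosensitive channels"
author: "piezotension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-tension sensitivity of mechanosensitive channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezotension)
```

## The measurement problem

Mechanosensitive channels such as Piezo1 and Piezo2 open in response to
lateral tension in the lipid bilayer. In a cell-attached pressure-clamp
experiment, suction applied through the patch pipette both stretches the
membrane and pulls it into a curved dome. The applied pressure is a poor
proxy for the stimulus the channel actually senses, because the same
suction produces different tensions depending on the dome geometry.
Laplace's law resolves this: for a spherical cap,

$$T = \frac{|P|\, r}{2},$$

with $P$ the applied pressure (converted at 133.322 Pa/mmHg) and $r$ the
dome's radius of curvature. Measuring $r$ per pressure step — by imaging
the dome with DIC microscopy while recording the evoked current — converts
a pressure-response experiment into a tension-response experiment. This
package implements that conversion and everything downstream of it.

## Dome radius from a micrograph

The dome appears as a dark band inside the pipette. Radius estimation has
three stages, each an explicit function:

1. **Column scan** (`columnBandScan`): within a user-supplied ROI, each
   pixel column is scanned with 5-pixel segment means; the darkest
   segment's centre seeds a 25-pixel window (shifted inward at ROI edges
   so it always holds 25 pixels; ties go to the lowest row index).
2. **Sub-pixel localisation** (`fitColumnGaussian`): the window is fit
   with an inverted Gaussian plus a baseline offset,
   $y = b + a\,e^{-(x-c_1)^2/2\sigma_1^2}$ with $a<0$. The offset term is
   essential: a pure (negative) Gaussian cannot represent a dark band on a
   bright background, so without it the noiseless fit would be ill-posed.
   $c_1$ is the band centre at sub-pixel precision, $\sigma_1$ its width.
   Columns whose fit fails, pins the width at its lower bound
   (0.5 px — narrower bands are optically implausible at 0.0325 µm/px),
   or yields a depth under three residual RMS are dropped: a single noisy
   pixel can otherwise masquerade as an implausibly sharp "band" and, with
   weight $1/\sigma_1^2$, dominate the circle fit.
3. **Weighted circle fit** (`fitCircleWeighted`): the half-circle
   $y = c_y \pm \sqrt{r^2 - (x-h)^2}$ is fit to the $(x, c_1)$ points by
   nonlinear least squares with weights $1/\sigma_1^2$ (the standard
   inverse-variance choice; the localisation uncertainty grows where the
   arc runs oblique to the columns, and the weights down-rank exactly
   those columns). The fit is initialised from an unweighted algebraic
   (Kåsa) circle fit, and one trimming pass removes columns whose
   residual exceeds six times the median — the automated analogue of
   inspecting the fitted arc overlaid on the image and discarding columns
   that are not part of the dome. $\sigma_r$ is read from the fit
   covariance; resampling would be a defensible alternative, covariance
   was chosen as the cheaper and deterministic option.

Orientation: the dome apex points toward the pipette tip, i.e. toward
smaller row indices by default (`apex = "up"`), with a flip available.
Pixel coordinates are 0-based and ROI bounds half-open, matching how
coordinates read off an image viewer.

Quality control mirrors standard practice: an image is excluded when
$\sigma_r / r > 10\%$, except at 0 mmHg, where the membrane is nearly flat,
the radius ill-constrained, and the tension zero regardless; a patch is
excluded when more than two of its images fail.

## Response curves

Per sweep, the pre-stimulus mean is subtracted and the peak is the mean of
the absolute extremum and its two neighbours on each side (five samples,
shifted inward at window edges). Sweeps are excluded for rundown when
their peak drops below 70% of the running maximum of earlier unflagged
peaks; flagged sweeps do not update the reference, so everything after the
onset of rundown is judged against the pre-rundown maximum. The running
maximum is the more conservative reading of ">30% reduction in subsequent
peaks" (the immediately-preceding-peak reading is available as
`reference = "previous"`). Patches qualify with a maximal peak of at least
20 pA — the threshold is deliberately inclusive at the boundary and
configurable, since "at least 20 pA" and "> 20 pA" both circulate as
phrasings of this rule — plus a seal above 1 GΩ and leak below 50 pA
(whole-cell: series resistance < 15 MΩ, leak < 100 pA, capacitance
< 40 pF).

All dose-response fitting uses the three-parameter Boltzmann
$I = A / (1 + e^{-k(x - x_{50})})$ with stimulus magnitudes (suction and
inward current positive). The normalisation order matters and follows the
two-stage convention: the raw peaks are first fit against *pressure*, and
that fit's plateau $A$ divides every peak; the normalised currents are
then fit against *tension*, unbinned, giving per-patch $(T_{50}, k)$.
Cohort curves instead pool all patches' normalised points, bin tension in
1 mN/m increments (left-closed $[m, m+1)$, labelled at the midpoint — the
convention had to be fixed somewhere, and left-closed bins keep 0 mmHg
points in the first bin), and fit the bin means weighted by $1/SD^2$,
single-point bins borrowing the median SD of the multi-point bins.

Fits that never approach a plateau are untrustworthy: when the maximum
normalised response stays below 0.8, or the points lie on one side of the
inflection, the fit is flagged low-confidence. Flagged patches are still
reported but excluded from cohort averages. This flag matters: without it,
patches whose $T_{50}$ sits near the top of the achievable tension range
bias cohort means upward (their plateau is extrapolated), and with
aggressive exclusion they bias it downward (survivorship); reporting both
the flag and the per-patch table keeps the trade-off visible.

## Tuning curves and thermodynamics

The tension-tuning curve is the derivative of the response Boltzmann,

$$y(T) = \frac{A\,k\,e^{-k(T-T_{50})}}{(1 + e^{-k(T-T_{50})})^2},$$

peaking at $A k / 4$ at $T_{50}$ with FWHM $2\ln(3+2\sqrt{2})/k$: its peak
marks the tension of maximal incremental sensitivity and its width the
dynamic range over which the channel encodes tension gradations.

With $T_{50}$ in mN/m and $k$ in m/mN the product $T_{50} \cdot k$ is
dimensionless, and the gating free energy is
$\Delta G = k_B T_{abs} \cdot T_{50} \cdot k$ (reported in $k_B T$ units),
while the in-plane area expansion on opening is
$\Delta A = k \cdot k_B T_{abs}$, reported in nm² at $T_{abs}$ = 300 K
(configurable). `thermodynamics()` reports both the mean of patch-wise
products and the product of means: the two differ whenever $T_{50}$ and
$k$ covary across patches (they are negatively correlated in practice),
and published per-construct values follow the patch-wise convention.

## Single channels, kinetics, indentation

Unitary currents come from histograms of current samples across 3–5
manually isolated opening events per voltage, fit with a two-Gaussian
mixture; $i_u = |c_2 - c_1|$. The histogram bin width defaults to the
within-level spread divided by three (a pooled Freedman–Diaconis width
straddles both modes and is too coarse); bimodality is enforced by
requiring the level separation to exceed three within-level SDs plus a
genuine dip between the modes, since a unimodal cloud split by 2-means
always yields two "levels" about 1.6 pooled SDs apart. Signed unitary
currents against voltage give the slope conductance $g$ (pS) by ordinary
least squares; signs are kept so an ohmic inward channel has positive $g$.

Inactivation kinetics fit $I(t) = I_b + I_p e^{-t/\tau}$ from the peak
sample to stimulus offset (time re-zeroed at the peak; the window start is
a choice — the peak is the natural origin once the rising phase is over).
Estimates with $\tau \le 0$ or beyond ten window lengths are rejected as
non-decaying.

Indentation analysis aligns depths to the externally supplied contact
step (in the source experiments, contact is read off video by a blinded
observer; here it is an explicit input), then reports the first
post-contact depth whose peak exceeds 10 pA — strictly, per the
responsiveness histogram that motivated the criterion. A supra-threshold
response followed by sub-threshold ones still sets $d$ at the first
crossing but flags the series non-monotone. Construct labels are joined
only at reporting, never inside threshold computation, mirroring the
blinded protocol structurally.

## The synthetic-data module

Every estimator above is validated by recovery from synthetic data with
known ground truth; the generators are first-class, tested code.

- **Dome images** (`genDomeImage`): a dark arc over a uniform background
  (level 200, depth 60 by default), rendered per column as a Gaussian
  centred exactly on the circle with width scaled by the local arc slope,
  so the cross-section perpendicular to the arc has the nominal width
  (2 px default) and the noiseless image realises exactly the
  column-Gaussian + circle model the estimator fits — making noiseless
  recovery a sharp correctness test rather than a model-mismatch
  measurement. Additive Gaussian pixel noise on top. Pixel size defaults
  to 0.0325 µm (2×2-binned acquisition at 100× with a 4× relay); the
  pipette half-width defaults to 0.9 µm, consistent with the saturating
  dome geometry below.
- **Stretch cohorts** (`genStretchPatch`/`genStretchCohort`): 17 pressure
  steps (0…−80 mmHg); per-patch $(T_{50}, k, A, \tau)$ drawn from normal
  distributions with defaults $T_{50}$ = 3.7 ± 0.8 mN/m, $k$ = 1.2 ±
  0.4 m/mN (SDs consistent with published SEMs at n ≈ 17), $A$ = 100 ±
  40 pA. The dome radius follows $r(P) = r_{min}(1 + P_{half}/|P|)$ —
  monotone, saturating at $r_{min}$, divergent (flat membrane) at
  $P = 0$ — with $r_{min}$ = 1.33 µm and $P_{half}$ = 10 mmHg so tension
  spans ~0–8 mN/m across the protocol, the range over which published
  binned tension-response curves are fit and the minimum needed for a
  $T_{50} \approx 4$ mN/m patch to reach a fittable plateau. Rundown, when
  drawn (probability 0.1), halves amplitudes from a random sweep in the
  plateau region onward; restricting the onset to the plateau guarantees
  the ×0.5 drop violates the 70% rule (during the rising phase a halved
  peak can still exceed 70% of the running maximum, which would make the
  "filter must fire" recovery test vacuous). The +5 mmHg pre-step and
  10 s inter-step recovery are protocol metadata, not simulated time.
  Full 10 kHz traces (100 ms baseline, 300 ms step, exponential decay)
  are built on request; cohort-scale recovery experiments run at the
  peak-table level, which is where the noise condition (peak SD as a
  fraction of $A$) is defined.
- **Single-channel sweeps** (`genSingleChannel`): two-state Markov
  telegraph at each voltage, open level $gV + b$, Gaussian noise; the
  ground truth carries the true state sequence and isolated-opening
  windows standing in for manual event isolation.
- **Indentation series** (`genIndentationSeries`): 1 µm steps, no current
  below the threshold depth, peak growing linearly above it, exponential
  decay, additive noise.

What the generators deliberately do not model: 1/f and seal-drift noise,
capacitance transients, slow rundown (only the step form), focus drift and
uneven illumination in images, and correlated pixel noise. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated noise model, not robustness to every artefact of real
recordings; the QC rules (σr/r, rundown, low-confidence flags) are the
defence against those artefacts and are exercised by their own tests.

## Numerical choices and degenerate inputs

- All nonlinear fits use Levenberg–Marquardt (minpack.lm) with analytic
  model expressions and data-driven starts: Boltzmann fits start at
  $A = \max y$, $x_{50}$ from linear interpolation at half-maximum,
  $k = 4/\text{range}$; the circle fit starts at the algebraic solution;
  the exponential at the tail mean and a fifth of the window.
- Boltzmann fits require ≥ 3 points and non-constant response; `A` and `k`
  are bounded positive. The half-circle square root is clamped at a small
  positive value so the optimiser can cross configurations where a point
  falls outside the current radius.
- Two exactly discrete current levels (a noiseless telegraph) make the
  two-Gaussian histogram fit degenerate; the level centres are then the
  cluster means, which is the correct limit.
- Collinear band centres, all-equal responses, windows shorter than
  25 px (scan) or 5 samples (peak), flat post-peak currents, and contact
  indices outside the protocol all raise immediate, named errors rather
  than propagating NaN.
- Seeding: every generator takes an explicit seed and is bit-reproducible;
  cohort patches derive per-patch seeds as `seed + 7919 * index` so
  patches are independent but individually reproducible.

## Problem sizes used in the validation suite

The recovery experiments in the test suite use 20-seed medians for image
recovery (at 25% band-depth noise), a 5×5 $(T_{50}, k)$ grid × 20 patches
for cohort recovery at 5%-of-$A$ peak noise, 7–9 seeds per condition for
conductance and τ, and 100 seeds for the sub-pixel localisation and
threshold-reliability checks — sizes at which the medians are stable
across reruns while the whole suite stays quick enough to run on every
change.

## Known limitations

- The radius estimator assumes one dome band per column inside the ROI;
  pipette-wall reflections must be excluded via `excludedColumns` (as in
  manual practice). Columns whose Gaussian fit fails are dropped silently
  from the circle fit (by design — the paper trail lives in the returned
  per-column table).
- Whether cohort averages should weight patches or points equally is
  genuinely open; pooled points ("binning tension values" reads as
  pooling) is the default, and per-patch weighting can be composed from
  the per-patch fits the pipeline already returns.
- Event isolation for single-channel analysis is an input, not an
  idealisation algorithm; HMM-style idealisation is out of scope.
- Proprietary acquisition formats are not parsed; the ingestion boundary
  is the documented columnar interchange format.
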