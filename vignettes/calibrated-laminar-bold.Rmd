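---
title: "Calibrated laminar BOLD: model, estimation, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated laminar BOLD: model, estimation, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

BOLD fMRI signals across cortical depth are dominated by where the
contributing vessels sit: gradient-echo (GE) acquisitions are sensitive to
the whole venous tree, including the large pial veins at the cortical
surface, while spin-echo (SE) acquisitions weight the micro-vasculature.
This package quantifies that difference with two respiratory gas
challenges. Hypercapnia (raised end-tidal CO2) dilates vessels and probes
cerebrovascular reactivity (CVR); hyperoxia (raised end-tidal O2) raises
venous oxygenation without dilating vessels and calibrates the maximum
attainable BOLD change (the M-value). Combining the two inverts the
calibrated-BOLD model for the relative change in venous cerebral blood
volume (CBV) at each hypercapnic level, per voxel, per cortical depth bin.

## The physiological model

Oxygen transport uses the Severinghaus dissociation curve
$S(P) = 1/(23400/(P^3 + 150P) + 1)$ and the arterial content
$C_aO_2 = \varphi\,[\mathrm{Hb}]\,S(P) + \varepsilon P$ (bound plus
dissolved oxygen). Mild hyperoxia is assumed to leave cerebral blood flow
and oxygen metabolism unchanged, so the arterio-venous content difference
stays at its baseline value $\mathrm{OEF}_0 \cdot C_aO_2^{(0)}$; venous
saturation follows from the venous content (dissolved venous O2 neglected,
saturation capped at 1), and the venous deoxyhemoglobin ratio is
$r = (1 - S_vO_2^{\mathrm{hyper}})/(1 - S_vO_2^{(0)})$.

The hyperoxic BOLD response then calibrates
$M = \Delta\mathrm{BOLD}/\mathrm{BOLD}_0 \,/\, (1 - r^\beta)$, and the
hypercapnic response follows the Davis model with Grubb flow-volume
coupling $v = f^{\alpha}$ folded in:

$$\frac{\Delta \mathrm{BOLD}}{\mathrm{BOLD}_0}
  = M\left(1 - v^{\,1-\beta/\alpha}\, q^{\beta}\right),
\qquad
v = \left[\frac{1 - \Delta\mathrm{BOLD}/(M\,\mathrm{BOLD}_0)}{q^{\beta}}
    \right]^{1/(1-\beta/\alpha)},$$

with $v = \mathrm{CBV}/\mathrm{CBV}_0$ and
$q = \mathrm{CMRO}_2/\mathrm{CMRO}_{2,0}$. The exponent is written as
$1-\beta/\alpha$, the algebraic consequence of substituting Grubb's law
into the Davis model; forward and inverse are exact inverses of each other
(tested to $10^{-9}$ over a broad parameter grid).

### Parameters, units, defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `alpha` | venous flow-volume coupling exponent | 0.2 | – |
| `beta` | dHb relaxation exponent (7 T) | 1.0 | – |
| `oef0` | assumed baseline O2 extraction fraction | 0.30 | – |
| `hb` | hemoglobin concentration | 15 | g/dL |
| `phi` | O2 capacity of hemoglobin | 1.34 | mL O2/g |
| `eps` | plasma O2 solubility | 0.0031 | mL O2/dL/mmHg |
| `cmro2_ratio` | metabolic scaling per CO2 step (+3/+5/+8/+10 mmHg) | 0.97 / 0.95 / 0.92 / 0.90 | – |

All are configurable through `calib_params()` and serialize to flat JSON;
every run record embeds them, because the calibrated estimates depend
directly on these assumptions. The metabolic scaling is a per-condition
lookup, not an interpolation in measured CO2: each breathing condition
carries a fixed assumed value. Arterial O2 tension is taken equal to the
measured end-tidal value. Internally all BOLD changes are fractions;
user-facing outputs are percent — one internal unit avoids factor-100
bugs.

## The breathing protocol

A 697 s task sampled at TR = 0.85 s (exactly 820 volumes): 200 s baseline,
a gas-transition buffer, 120 s at each hypercapnic step (+5 then +10 mmHg
in the default session, +3 then +8 in the alternative session, connected
without intermediate return to baseline), a second transition buffer in
which the CO2 washes out, and a terminal 120 s hyperoxic block
(+350 mmHg). Two 68.5 s buffers reconcile the named block durations with
the scan duration; placing the hyperoxia last and ending the scan with it
matters for estimation, because a post-hyperoxia washout tail inside the
scan would be unmodeled signal (see below).

## The synthetic generator

The generator exists so that every downstream stage can be validated by
parameter recovery: it draws per-voxel ground truth, pushes it through the
same forward model the estimator inverts, and emits the full input bundle
(4D NIfTI series, label volumes, gas/respiration/pulse/motion traces with
JSON sidecars, and the ground-truth record).

**Slab and labels.** A rectangular slab with 20 equivolumetric depth
layers along one axis (one out-of-cortex slice on each face), three ROI
stripes standing in for visual areas V1-V3, and vein flags on the
superficial face. A single grid serves both sequences: the GE/SE
acquisition differences (voxel size, SNR strategy) are deliberately not
emulated — sequence differences are encoded purely in the ground-truth
parameters and the temporal SNR.

**Ground truth.** Within the included layers (2-19), the M-value rises
linearly with depth from 9% to 21% for GE-like contrast and 9% to 16% for
SE-like; CVR rises 0.39 to 0.64 %BOLD/mmHg (GE) and 0.18 to 0.25 (SE); the
+10 mmHg volume change is depth-constant at 12.5% (GE) and 8.5% (SE).
These anchors are the group depth profiles reported for human visual
cortex at 7 T. The three anchors cannot be simultaneously exact if the
volume change is forced to be proportional to the CO2 step, so the
generator anchors the +10 mmHg condition at the stated volume change and
places the per-condition BOLD plateaus on a straight line in the CO2 step
with slope equal to the voxel's CVR; the remaining conditions' volume
ratios follow by exact model inversion. Every anchor then holds exactly,
and the implied volume change still grows monotonically with the CO2
step. Optional log-normal voxel jitter (default sd 0.05) decorrelates
neighbors.

**Signal model.** Per voxel,
$s(t) = s_0\,(1 + f_{hc}(t) + f_{ho}(t)) + d(t) + \epsilon(t)$. The
hypercapnic response $f_{hc}$ is a square plateau per block at the
forward-model value — the vasodilatory response is modeled at block level,
which is exactly what binary-regressor fitting estimates. The hyperoxic
response $f_{ho}(t) = m\,(1 - r(t))$ tracks the simulated end-tidal O2
trace sample by sample, carrying its settling dynamics and noise. Gas
traces approach their targets as a first-order exponential (default time
constant 15 s) with breath-to-breath Gaussian noise. Drift is a half-cycle
cosine (default 1% of $s_0$), which lies below the high-pass cutoff and is
removed exactly by the filter. Noise is white Gaussian with sd
$s_0/\mathrm{tSNR}$. Respiration (~16 breaths/min) and pulse (~66 bpm)
traces are quasi-periodic oscillations with slow rate and amplitude
modulation; motion is six small-amplitude AR(1) random walks.

What the generator does *not* emulate: partial-volume mixing between
layers, vascular network geometry and draining-vein biases, T2/T2*
biophysics, temporally autocorrelated or physiologically coupled noise,
motion effects in the images themselves, and registration error. Passing
recovery on this generator therefore demonstrates correctness of the
estimation chain under the stated forward model — not robustness to every
artifact of real laminar data.

## Estimation choices

**Processing order** is smooth, then high-pass, then percent signal
change. Smoothing (FWHM 2.35 mm) is a renormalized masked convolution
restricted to voxels sharing a (depth bin, ROI) cell, so no signal crosses
depth bins or areas; kernels are truncated at 3 sd and computed on each
cell's bounding box. The high-pass regresses out the mean and the
$K = \lfloor 2\,T\,f_c \rfloor$ lowest discrete-cosine vectors
($f_c = 0.003$ Hz, so $K = 4$ for the 697 s run) and re-adds the mean so
percent signal change stays well defined.

**The GLM** uses one binary regressor per gas condition (1 during the
block), an intercept, and mean-centered nuisance columns (6 motion
parameters, respiration volume per time, beats per minute). Three choices
here deserve explanation:

1. *The design is projected through the same DCT filter as the data.*
   Filtering only the data removes low-frequency energy that the block
   regressors still contain and biases every beta; projecting the design
   too is algebraically identical to adding the DCT basis to the model
   (Frisch-Waugh) and leaves noiseless plateaus exactly recoverable.
2. *Condition betas are rescaled to percent of baseline.* Percent signal
   change is taken against the whole-series mean, which includes the
   activation blocks; the model's quantities are fractions of the
   *baseline* signal. Dividing by $(100 + \hat\beta_0)/100$, with
   $\hat\beta_0$ the intercept, converts exactly — without it, estimates
   are biased low by several percent in proportion to the session's mean
   activation.
3. *The hyperoxic response is calibrated through its trace-derived
   shape.* The hyperoxic response follows the measured O2 trace, so a
   binary regressor captures only part of it, and the captured fraction
   depends on the settling dynamics and the filter. The package computes
   the response shape implied by the measured trace,
   $h(t) = 1 - r(\mathrm{PetO}_2(t))$, fits it through the *same* filtered
   design, and uses its fitted condition coefficient as the effective
   deoxyhemoglobin contrast: $\hat M = \hat\beta_{ho}/\hat g$. For an
   ideal step trace this reduces to the textbook block-mean form; for
   realistic ramps it is unbiased where the block-mean pairing
   underestimates M by tens of percent. The same fit also yields, per
   unit M, the leakage of the trace-locked hyperoxic component into the
   hypercapnia betas, which is subtracted exactly.

**Voxel selection** applies the Holm step-down procedure (via
`stats::p.adjust`) at familywise level 0.05 to the per-voxel omnibus F
test over the gas conditions, the simplest reading of "voxels responding
significantly to the gas challenges"; per-condition selection and the
test's sidedness are configurable. Tests are two-sided by convention.
Transition volumes are not excluded: block boundaries follow the protocol
timing exactly, and the binary regressors fit the average plateau.

**Gas pairing.** Measured CO2 steps for the CVR regression are plateau
means over the last half of each hypercapnic block minus the baseline-block
mean: the binary beta estimates the settled plateau response, and pairing
it with a full-block mean that includes the exponential approach would
overstate CVR by ~12% at the default settling constant. The hyperoxic
block keeps its full-block mean PetO2 where it appears in summaries, since
the deoxyhemoglobin ratio is nearly affine in PetO2 above arterial
saturation.

**CVR** is the least-squares slope (with intercept) of the per-condition
%BOLD against the measured CO2 steps; an intercept is included because
forcing the line through zero would bias slopes under any baseline offset.
Sessions missing the +3/+8 conditions contribute fits on their available
points only. **Depth profiles** average voxels within (subject, bin)
first, then report mean and SEM across subjects; GE/SE ratios propagate
the SEMs to first order. Voxels with non-positive M or a saturated
inversion ($\Delta\mathrm{BOLD} \ge M$) are excluded from profiles and
counted in the QC log.

## Numerical choices and degenerate inputs

Exact fits (zero residual variance, as in noiseless simulation) would make
t ill-defined; such voxels get p = 0 for nonzero effects and p = 1
otherwise. Venous saturation is capped at 1, and a fully saturated
baseline (no baseline deoxyhemoglobin) raises a degenerate-state error, as
does a deoxyhemoglobin ratio of 1 (an uninformative hyperoxia challenge).
Peak detection for the respiratory and cardiac regressors keeps strict
local maxima separated by at least half the expected period, larger peak
winning ties. A session without a hyperoxia block fails fast, naming the
M-value calibration requirement. All randomness flows from one master
seed through a deterministic seed-derivation chain, so outputs are
bit-reproducible.

## Problem sizes used in validation

The test suite and the acceptance script validate at desk scale, chosen so
the full suite runs in a few minutes on one CPU while every depth bin
still contains thousands of voxels: noiseless identifiability on a
10x10x22 slab (machine-precision recovery, spatial smoothing disabled —
smoothing deliberately pools voxels whose ground truth varies across the
six layers inside a bin, so per-voxel exactness is a property of the
estimator chain, not the smoother); and a group study of 8 synthetic
subjects, GE and SE sessions each, on a 24x24x22 slab at temporal SNR 50,
with two subjects on the alternative +3/+8 session to exercise the
unbalanced design. At those settings the group depth-bin means of M, CVR
and the volume changes recover their ground truth within ~4%, the GE/SE
CVR ratio rises from ~2.24 (deep) to ~2.52 (superficial), and the GE/SE
volume-change ratio is depth-flat — the study's qualitative fingerprint.

## Known limitations

The calibration inherits every parameter assumption ($\alpha$, $\beta$,
OEF$_0$, the metabolic scalings); errors in them move M and the volume
changes multiplicatively, and plausibly differ between vascular
compartments and depths. The square-plateau hypercapnic response ignores
vasodilatory onset dynamics; the binary-regressor design absorbs, but does
not model, them. No prewhitening is applied, so single-voxel p-values are
anticonservative under autocorrelated noise (selection in the validation
studies is insensitive to this; real-data use should treat per-voxel
inference cautiously). Linear mixed-model group inference is out of scope:
profiles report subject-level means with SEM.
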