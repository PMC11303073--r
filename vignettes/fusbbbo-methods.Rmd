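---
title: "Methods: cavitation dosimetry, passive acoustic mapping, and opening quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cavitation dosimetry, passive acoustic mapping, and opening quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fusbbbo` implements the computational analysis of a microbubble-mediated
focused-ultrasound (FUS) blood-brain-barrier-opening (BBBO) treatment
session: spectral cavitation dosimetry from passive cavitation detector (PCD)
recordings, coherence-factor passive acoustic mapping (PAM) from multichannel
array RF, contrast-MRI opening quantification, amyloid-PET SUVR asymmetry,
skull insertion-loss/derating arithmetic, and the descriptive statistics a
small clinical cohort is summarized with. Because patient data from such
trials are not publicly deposited, the package ships a synthetic-data module
that generates every input with the statistical structure the analysis
assumes, so the full pipeline is exercised end to end by the test suite.

This vignette records the models, the tunable parameters, the numerical
choices, and the limitations.

## Sonication protocol

A treatment session is a pulse train: center frequency $f_0$ = 0.25 MHz,
pulse length 10 ms, pulse repetition frequency 2 Hz, duration 120 s (240
bursts), targeting a derated in-situ peak-negative pressure of 200 kPa
(mechanical index $\mathrm{MI} = p_\mathrm{MPa}/\sqrt{f_\mathrm{MHz}} =
0.4$). A microbubble bolus is injected during the sonication and followed by
a saline flush; emissions rise after the bolus reaches the brain. The
synthetic bolus model is a hard onset at a configurable burst index followed
by an exponential rise (time constant 5 s by default) — enough structure to
give the dose series its characteristic step without modeling perfusion
kinetics. Defaults place the onset at burst 50 ($t$ = 24.5 s) with the
protocol's injection marker at 25 s and flush marker at 30 s.

## Cavitation dose

Each burst trace is Hann-tapered, zero-padded to the next power of two, and
converted to a single-sided amplitude spectrum compensated for the taper's
coherent gain (`burst_spectrum()`). Three per-burst doses are computed
(`cavitation_doses()`):

* **harmonic** $CD_h$: sum over orders $n \in \{3,4,5,6\}$ of the *peak*
  magnitude within $n f_0 \pm 25$ kHz;
* **ultraharmonic** $CD_u$: the same at $(n + 0.5) f_0$;
* **broadband** $CD_b$: the *mean* magnitude over $[2.5 f_0,\, 6.5 f_0]$
  excluding every harmonic and ultraharmonic tone window.

Peaks for tones and means for broadband follow the usual stable/inertial
cavitation split; the 25 kHz half-width leaves guard bands between tone
windows at a 0.25 MHz fundamental, and the broadband band covers orders 3-6
with half-order margins. The exact dose normalization is immaterial because
every reported quantity is baseline-normalized: per band,
$CD^{dB}_i = 20\log_{10}(CD_i / \overline{CD}_\mathrm{baseline})$, with the
baseline window defaulting to all bursts before the injection time. Summation
(not averaging) across orders is used for $CD_h$/$CD_u$; any fixed affine
choice cancels in the normalization.

The cumulative cavitation dose sums the normalized doses over the post-flush
bursts on a log scale,
$CCD = 10\log_{10} \sum_{i \ge \mathrm{flush}} CD_i/\overline{CD}_\mathrm{baseline}$,
treating the dimensionless normalized amplitudes as energy-like (hence
$10\log_{10}$ for the sum but $20\log_{10}$ for per-burst amplitudes). One
hundred unit-normalized post-flush bursts therefore give exactly 20 dB. An
all-zero post-flush sum returns `NA` — "not a dose" — never 0 dB.

## Passive acoustic mapping

Cavitation sources emit; the array only listens. Delays are therefore one-way
(`travel_delays()`): Euclidean pixel-to-element distance over an assumed
sound speed of 1540 m/s, with no skull aberration correction. For each pixel
the channels are aligned with sub-sample linear interpolation and combined as
coherence-factor-weighted delay-and-sum (`pam_burst_map()`):

$$E(\mathbf{r}) = \sum_t \mathrm{cf}(\mathbf{r}, t)\,
  \Big[\sum_i s_i(t + \tau_i(\mathbf{r}))\Big]^2,\qquad
  \mathrm{cf} = \frac{|\sum_i s_i|^2}{N \sum_i s_i^2},$$

with $\mathrm{cf} \in [0,1]$ defined as 0 where the denominator vanishes.
The coherence factor is computed per time sample after alignment — burst-level
weighting would blur off-target energy. Apodization is uniform (none); the
0.5 mm default pixel size is below the array's lateral resolution. A naive
triple-loop reference (`pam_burst_map_naive()`) implements the identical
arithmetic and is used in the tests to pin the optimized implementation to
$10^{-9}$ relative agreement. Final maps average the linear energy maps over
post-injection bursts, apply the brain mask, and convert to dB relative to
the map maximum (`average_and_mask()`).

Two numerical properties are worth knowing. First, the axial (depth) response
of a passive map is a broad ridge — receive-only delay curvature is the only
depth cue — so depth localization is much softer than lateral localization.
Second, for off-axis sources the point-spread ridge tilts along the
source-to-array radial direction, so the raw arg-max can slide along the
ridge by more than a pixel when the source sits between lateral grid nodes;
`map_peak_centroid()` (energy-weighted centroid of the half-maximum region)
is centered on the source in that situation. The monitoring array of the
emulated system is coaxial with the FUS transducer, so sources of interest
are near the beam axis where the arg-max itself is grid-limited.

Pixel-wise agreement between a cavitation map and a projected opening mask is
quantified by ROC and precision-recall curves from an explicit threshold
sweep with trapezoidal AUCs (`roc_pr_pixelwise()`); pixels can be pooled
across subjects before the sweep. Degenerate references (all one class) are
rejected; a constant map yields AUROC 0.5 and AUPR equal to the positive
prevalence by construction.

## Opening quantification from paired contrast MRI

The opening volume is measured on the voxelwise difference of the day-0 and
day-3 post-contrast T1 volumes (`subtract_volumes()`; grids and affines must
match — registration is upstream of this package). The threshold is selected
under the assumption that the background of the subtraction image is
Gaussian (`auto_threshold()`):

1. Fit the background robustly (median and MAD) over the search region.
2. Sweep descending intensity percentiles (99.9 to 90 in 0.1 steps) and take
   as candidate the lowest percentile that still exceeds the one-sided
   Gaussian confidence bound $\hat\mu + z_{0.98}\,\hat\sigma$ (confidence
   0.98 by default).
3. Validate the candidate: the largest 26-connected suprathreshold component
   is tested (one-sided z) against the *truncated-Gaussian selection null*,
   with background mean and sd estimated from a 3-voxel dilation shell
   around the suprathreshold region. If the test does not reject, the result
   is the sentinel `NA`: no opening.

The selection correction in step 3 is essential. Thresholding pure noise at
any percentile produces a suprathreshold set whose mean exceeds the
surrounding mean by construction, so a direct inside-versus-shell comparison
rejects on noise with probability near one. Testing against the expectation
of that selection effect ($\mu + \sigma\lambda(z_T)$ with $\lambda$ the
inverse Mills ratio, and the truncated variance in the standard error)
controls the false-positive rate at roughly the test level: across 100
pure-noise simulations the suite requires at most 5 detections. The
candidate-threshold rule is monotone in the confidence level: raising the
confidence never lowers the threshold.

`quantify_opening()` binarizes at the threshold, keeps 26-connected
components of at least 10 voxels whose centroid falls within a 15 mm
cylinder around the beam trajectory (openings concentrate along the beam
axis; the radius bounds the off-axis spread seen in practice and is
configurable), and reports volume (voxel count times voxel volume from the
affine determinant, hence invariant under rigid re-orientation),
intensity-weighted centroid in world mm, Euclidean distance to the focus,
and gray/white-matter fractions from supplied masks. Sulcal or perivascular
extravasation connected to the main component is counted if it passes the
gate — a documented limitation, not a separate class.

## PET SUVR and asymmetry

SUVR is the mean uptake in a target region over the mean uptake in the
reference region (cerebellar gray matter in the emulated design); the
asymmetry SUVR divides the treated-side SUVR by that of the contralateral
region obtained by mirroring the mask across the mid-sagittal grid plane
(synthetic grids are mid-plane symmetric by construction; MNI-space
normalization is out of scope). Percent changes are
$100(\mathrm{f/u} - \mathrm{base})/\mathrm{base}$. Centiloid conversion is
the affine map $\mathrm{CL} = a \cdot \mathrm{SUVR} + b$ whose calibration
constants are configuration inputs — they come from external calibration
pipelines and are deliberately not hard-coded.

## Skull acoustics

Full wave propagation is out of scope; the package implements the
property-map construction and the scalar derating algebra around it. CT
Hounsfield units map linearly from the water anchor (0 HU: 1000 kg/m³,
1500 m/s, 0 dB/cm) to the stated skull maxima (1850 kg/m³, 4000 m/s,
0.68 dB/cm at $f_0$) at the volume's maximum HU, clipped below at water;
absorption scales linearly with frequency. Insertion loss is
$\alpha = 1 - P_\mathrm{skull}/P_\mathrm{freefield}$; the free-field pressure
required for a derated in-situ target is $p/(1-\alpha)$; the post-hoc
correction for a revised loss estimate is
$p\,(1-\alpha_\mathrm{new})/(1-\alpha_\mathrm{old})$, which composes
consistently.

## Statistics

Two divisor conventions coexist in small-cohort reporting and both are
explicit flags in `summarize_values()`: "mean ± std" table aggregates use
the population (N) divisor — this convention reproduces the emulated study's
printed aggregates exactly — while paired t-tests recomputed from printed
summary rows (`paired_t_from_summary()`) use the sample (N−1) convention:
$t = \bar d / (s_d/\sqrt{n})$, $df = n - 1$, two-sided. Simple regression
(`linreg()`) is OLS via `lm()` with $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$
and the slope's F-test p-value. Motion is summarized by the mean absolute
Euclidean deviation from the trace centroid and the maximum distance from
the initial location; transducer positioning error by the Euclidean distance
between planned and treated targets and the angle between the trajectory
directions.

## The synthetic-data module as study conditions

The generators define the conditions every downstream claim is tested under:

| quantity | default | rationale |
|---|---|---|
| $f_0$, pulse, PRF, duration | 0.25 MHz, 10 ms, 2 Hz, 120 s | the emulated protocol |
| PCD / RF sampling | 4 MHz / 10 MHz | ≥ Nyquist for 6.5 $f_0$ = 1.625 MHz with margin |
| broadband synthesis | band-limited white noise on $[2.5 f_0, 6.5 f_0]$ | matches the dose bands without out-of-band leakage |
| bolus onset | burst 50, exponential rise $\tau$ = 5 s | step-plus-rise shape of post-injection emissions |
| array | 64 elements, 0.5 mm pitch, coaxial with the beam | monitoring-array geometry |
| point sources | 25-35 mm depth, near-axis | the focal region of the coaxial system |
| MRI phantom | constant background 100, noise sd 10, contrast 70, 1 mm voxels | Gaussian background assumed by the threshold; CNR ≈ 5 in the subtraction image |
| opening ellipsoid | 983 mm³, 3:1 axial elongation along the beam | cohort-mean volume; axially elongated focus |
| PET | baseline SUVR 1.4, asymmetry factor 0.9853, zero noise | amyloid-positive target; the −1.47 % frontal-lobe-scale effect |

Deliberately not emulated: anatomical texture and bias fields in MRI, skull
aberration and refraction in the acoustics, subject motion, registration
error between modalities (synthetic fixtures carry exact transforms), and
PET kinetics. Passing tests therefore demonstrate correctness of the
computations under the stated statistical assumptions — not robustness to
the full messiness of clinical data.

## Numerical choices and problem sizes

FFT lengths are the next power of two above the trace length; tapers are
Hann; quantiles use R's default type 7; arg-max ties resolve to the first
index in column-major order; sentinel results propagate as `NA` with a
`reason` attribute rather than as magic numbers. The test suite and the
acceptance script run on one CPU in a few minutes using 64³ MRI volumes
(40³ for the 100-seed false-positive sweep), 48³ PET volumes, 33 × 33 map
grids with every 10th post-injection burst beamformed, and 16-channel /
16 × 16-pixel configurations for the triple-loop oracle comparison; these
sizes keep every statistical check well-powered while staying desk-scale.

## Known limitations

* Depth localization in PAM is ridge-limited and biased along the tilted
  point-spread function for off-axis sources (see above).
* The opening threshold assumes a Gaussian background; heavy-tailed
  artifacts (motion, ringing) would inflate the robust scale estimate and
  make the threshold conservative.
* Connected extravasation along sulci is not distinguished from
  parenchymal opening.
* The acoustics module treats simulated skull pressures as inputs; it does
  not propagate waves.
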