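# fusbbbo

Analysis pipeline for microbubble-mediated focused-ultrasound (FUS)
blood-brain-barrier-opening (BBBO) studies, for researchers running or
evaluating FUS neurotherapy experiments: real-time treatment monitoring
quantities (cavitation doses and passive acoustic maps), post-treatment
outcome quantities (contrast-MRI opening volumes, amyloid-PET SUVR
asymmetry), treatment-planning arithmetic (skull insertion loss and
derating), and the small-cohort statistics used to report them. A
synthetic-data module generates every input — burst RF, paired T1 volumes,
PET pairs — with the statistical structure the analysis assumes, so the
whole pipeline runs and is tested without any patient data.

## Core quantities

**Cavitation dose.** Per sonication burst, from the single-sided amplitude
spectrum: harmonic dose `CD_h` (sum of peak magnitudes at `n·f0 ± 25 kHz`,
`n = 3..6`), ultraharmonic dose `CD_u` (same at `(n+0.5)·f0`), broadband
dose `CD_b` (mean magnitude over `[2.5·f0, 6.5·f0]` excluding the tone
windows). Doses are reported normalized to the pre-injection baseline in dB,
and accumulated after the microbubble flush as the cumulative cavitation
dose `CCD = 10·log10( Σ CD/CD_baseline )`.

**Passive acoustic map.** Coherence-factor-weighted delay-and-sum over
one-way (receive-only) delays:

    E(r) = Σ_t cf(r,t) · [ Σ_i s_i(t + τ_i(r)) ]²,
    cf   = |Σ_i s_i|² / (N · Σ_i s_i²)

with sub-sample linear interpolation, uniform apodization, c = 1540 m/s.
Burst maps are averaged over post-injection bursts, brain-masked, and
dB-scaled. Map-vs-opening agreement is scored by pixel-wise ROC/PR AUCs.

**Opening quantification.** Day-0 minus day-3 post-contrast T1, thresholded
at the lowest descending-percentile threshold exceeding the one-sided
Gaussian 98 %-confidence bound of the robust background fit, validated by a
z-test of the largest 26-connected component against the truncated-Gaussian
selection null; components are gated to a 15 mm cylinder around the beam
trajectory. Reports volume (mm³), intensity-weighted centroid, distance to
focus, and GM/WM fractions.

**PET.** Regional SUVR against a reference region, asymmetry SUVR against
the mirrored contralateral region, percent changes, and a configurable
Centiloid conversion.

**Acoustics.** CT-HU to density/speed/absorption maps (linear between water
and skull maxima), insertion loss `α = 1 − P_skull/P_freefield`, derating
`p/(1−α)`, post-hoc re-derating `p·(1−α_new)/(1−α_old)`, mechanical index.

## Worked example

The numbered drivers under `analysis/` run the full synthetic study; each is
a thin script over the package functions and writes its tables under
`results/`.

```sh
Rscript analysis/01_simulate.R        # synthetic PCD, RF, MRI, PET inputs
Rscript analysis/02_cavitation_dose.R
Rscript analysis/03_cavitation_map.R
Rscript analysis/04_opening_quant.R
Rscript analysis/05_pet_suvr.R
Rscript analysis/06_stats_summary.R
```

Output of a run at seed 1:

```
broadband dose rises 35.4 dB after the flush
CCD (dB): harmonic 56.1, ultraharmonic 56.1, broadband 40.3
map peak (0.0, 30.0) mm; true source (0.0, 30.0) mm
selected threshold 29.5 (validation z = 259.1)
opening volume 1003 mm^3 (truth 981), Dice 0.99, 0.0 mm from focus
SUVR 1.400 -> 1.379; asymmetry 1.0000 -> 0.9853 (-1.47%)
asymmetry change, frontal_lobe: t = -4.27, p = 0.013
CCD_h vs opening volume: R^2 = 0.94, p = 0.032 (n = 4)
```

Reading: the microbubble bolus raises broadband emissions ~35 dB above the
pre-injection baseline and the post-flush accumulation gives the per-band
CCDs; the cavitation map localizes the synthetic source exactly; the
adaptive threshold recovers the 983 mm³ truth ellipsoid to within ~2 % with
Dice 0.99 centered on the focus; the PET follow-up reproduces the configured
−1.47 % asymmetry change exactly at zero noise; and across a four-subject
synthetic cohort the harmonic CCD predicts opening volume (R² = 0.94), the
relationship the monitoring is designed to exploit. The per-subject
aggregates of the study table (`trial_subject_table()`) summarize to
983.6 ± 626.2 mm³ opening volume, 5.7 ± 1.4 mm / 11.2 ± 2.5° positioning
error, 12.3 ± 6.1 mm centroid-to-focus distance, and 0.3 / 1.2 mm motion
MAD/max with the head rest.

In code, the single-subject pipeline is one call:

```r
library(fusbbbo)
report <- run_pipeline(default_config(seed = 1))
report$dose$ccd_h          # cumulative harmonic dose (dB)
report$opening$volume_mm3  # quantified opening volume
report$pet$pct_change_asym # percent change in asymmetry SUVR
```

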