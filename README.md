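# dixonfgt

Volumetric breast density from two-point Dixon MRI, end to end and fully
testable without patient data.

MRI measures breast density as **%FGT**: the volume of fibroglandular
tissue relative to total breast volume, the 3D analogue of mammographic
percent density and a major breast-cancer risk factor. Dixon sequences
acquire in-phase and opposed-phase echoes and separate them into water-only
(W) and fat-only (F) images; because pure fibroglandular tissue and pure
fat do not reach equal intensities in those images, a per-breast
calibration factor `c = F_max / W_max` - measured in a standardized
30 x 30 mm ROI at the breast centre - rescales the water image before the
per-voxel water fraction is formed:

    WF = c W / (c W + F),     FGT volume = sum(WF) x voxel volume,
    %FGT = 100 x FGT volume / mask volume

The package implements this measurement pipeline (segmentation with a
pectoral coronal cut, calibration, water-fraction quantification, a ±15%
calibration sensitivity analysis) together with the statistics used to
characterise it (Bland-Altman coefficients of repeatability and variation,
paired t, Pearson, repeated-measures ANOVA, cohort comparison reports) and
a digital breast phantom + Dixon acquisition simulator (SPGR and spin-echo
signal equations, six-peak triglyceride fat spectrum, Rician noise, coil
bias, thick-slice reformatting). Ground truth is known exactly for every
phantom, so sequence-dependent biases - in particular the large spin-echo
%FGT overestimate caused by single-peak separation of a multi-peak fat
spectrum - are reproducible as properties rather than anecdotes. See the
methods vignette (`vignettes/dixon-fgt-methods.Rmd`) for the model and
design notes.

## Worked example

Simulate a noise-free phantom with 30% true fibroglandular fraction,
acquire it with the proton-density gradient-echo preset, and quantify:

```r
library(dixonfgt)

ph <- generate_phantom(phantom_spec(
  composition = list(type = "blobs", fraction = 0.3, scale_mm = 8),
  noise_sd = 0, rng_seed = 7))
tis <- tissue_properties(fat_spectrum = fat_spectrum_single_peak())
out <- acquire_and_quantify(ph, "hr_gre_pd", tissues = tis)
out$results
#>   subject   dataset laterality  fgt_cm3 total_cm3  pct_fgt        c
#> 1 phantom hr_gre_pd          L 19.12941  63.68258 30.03869 1.285936
#> 2 phantom hr_gre_pd          R 19.12941  63.68258 30.03869 1.285936
ph$true_fgt_percent
#>        L        R
#> 30.00106 30.00106
```

Each breast of 63.7 cm³ contains 19.1 cm³ of fibroglandular tissue, i.e.
30.04 %FGT against a ground truth of 30.00 - the calibrated pipeline
recovers the known composition to within a twentieth of a percentage
point, and the correction factor 1.286 matches the analytic
pure-fat/pure-water signal ratio of this sequence. Acquiring the same
phantom with the spin-echo preset and the six-peak fat model instead
yields ~43.7 %FGT: the fat signal that one-peak separation misassigns to
water, the central sequence-selection hazard this package quantifies.

The `analysis/` scripts run the full studies and write tables under
`results/`: `01_simulate_phantom.R` (volumes + ground truth),
`02_parameter_recovery.R`, `03_sequence_comparison.R` (five datasets per
subject: high/low resolution x PD/T1 weighting + spin echo, shared
registered masks), `04_repeatability.R` (test-retest with repositioning
jitter), `05_sensitivity.R` (±15% calibration perturbation).

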