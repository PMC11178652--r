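# hsitta — test-time augmentation for perfusion shifts in hyperspectral tissue imaging

Segmentation networks for intraoperative hyperspectral imaging (HSI) are
trained almost exclusively on well-perfused organs. Surgical maneuvers
change perfusion — arterial clamping desaturates an organ, venous clamping
pools deoxygenated blood in it — and because tissue reflectance is dominated
by blood content, such pixels fall far outside the training distribution and
a frozen classifier can fail outright on them. `hsitta` is for researchers
in biomedical optics and surgical data science who want to study and
mitigate this failure mode *without retraining the model*.

## Method

The package builds a synthetic tissue-spectra database with a forward model
and a digital twin of a 100-band camera (500–995 nm at 5 nm), then applies
three test-time steps to each incoming image:

1. **Digital twin**: every pixel spectrum is matched by exact
   nearest-neighbor search (Euclidean, on L1-normalized spectra) to a
   database record, annotating the pixel with tissue oxygen saturation
   StO2 and blood volume fraction VHb.
2. **OOD filtering**: a pixel is out-of-distribution iff its StO2 *or* VHb
   falls outside percentile bounds (the (25, 75) or (5, 95) setting) fitted
   on physiological reference data.
3. **Hybrid generation**: each OOD pixel becomes the L1-normalized mean of
   its real spectrum and the spectrally nearest synthetic record whose
   StO2/VHb lie within box tolerances of the physiological medians
   (|ΔStO2| ≤ 0.05, |ΔVHb| ≤ 0.02). In-distribution pixels pass through
   bit-exactly. The hybrid image goes to the frozen model.

The forward model is a closed-form diffusion approximation for a
semi-infinite layer: absorption
μa(λ) = VHb·C_Hb·ln10·[s·ε_HbO2 + (1−s)·ε_Hb] + w·μa_water, scattering
μs′(λ) = μs′(500)·(λ/500)^−b, reflectance
R_d = a′ / (1 + 2A(1−a′) + (1 + 2A/3)√(3(1−a′))) with albedo
a′ = μs′/(μa+μs′) and internal-reflection parameter A(n). Database records
sample the full parameter space uniformly — including implausible perfusion
states (StO2 0–100%, VHb 0–30%) that labeled training data never shows.

Because no in vivo data ships with the package, a scene simulator generates
the full study: 12 subjects split 7/5 into validation/test, four perfusion
states (physiological, avascular, arterial ischemia, venous congestion),
multi-organ scenes, and a frozen pixel-wise discriminant classifier trained
on physiological scenes only. Evaluation uses the Dice similarity
coefficient (DSC), aggregated hierarchically (images within subject, then
subjects), plus a PCA/KDE domain-gap diagnostic on per-image median organ
spectra. See `vignettes/tta-methods.Rmd` for models, parameters, and design
rationale.

## Worked example

```r
library(hsitta)
db     <- build_database(20000, seed = 7, keep_raw = FALSE)
scenes <- make_dataset(n_subjects = 12, images_per_subject = 2, seed = 11)
sp     <- split_subjects(scenes, n_val = 7, n_test = 5, seed = 11)

train  <- Filter(function(s) s$state == "physiological", sp$validation)
model  <- train_segmenter(train, seed = 3)
twins  <- lapply(train, function(s) generate_twin(s$cube, db))
stats  <- fit_physio_stats(twins, c(25, 75))
print(stats)
#> <physio_stats> (25, 75) percentiles over 8064 pixels
#>   StO2: median 0.642, in-distribution [0.500, 0.752]
#>   VHb : median 0.020, in-distribution [0.012, 0.035]

s      <- Filter(function(x) x$state == "venous_congestion", sp$test)[[1]]
tw     <- generate_twin(s$cube, db)
ood    <- detect_ood(tw, stats)
print(ood)
#> <ood_mask> 24 x 24, 77.8% OOD
hybrid <- augment_image(s$cube, tw, ood, db, stats)
dsc(predict(model, s$cube), s$mask, 1)   # 0     — congestion collapses the kidney DSC
dsc(predict(model, hybrid), s$mask, 1)   # 0.867 — augmentation restores it
```

The physiological statistics say half the reference pixels sit inside each
parameter's interquartile band; on the congested test scene 77.8% of pixels
are flagged OOD, and replacing them lifts the kidney-analog Dice score from
0 to 0.867 with the model untouched. The summary arithmetic mirrors how
such results are reported: `relative_decrease(0.73, 0.05)` ≈ 93% and
`improvement_factor(0.05, 0.23)` = 4.6.

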