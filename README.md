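# prostadss

Decision support for prostate-cancer detection and staging from two
routinely available inputs: a six-marker serum panel (TPSA, RBC, HB,
FPSA, PAP, PSMA) and a medical image of the lesion. The package is aimed
at settings where specialist time is scarce and a reproducible
first-pass stage estimate plus treatment suggestion is valuable.

## What it computes

1. **Lesion quantification.** A Canny-style pipeline (grayscale
   conversion `P = αR + βG + γB`, Gaussian smoothing, 2×2
   finite-difference gradient, non-maximum suppression, hysteresis
   thresholding) finds the lesion edge; the boundary is traced with an
   eight-direction Freeman chain code and the enclosed pixel area is
   computed by the discrete Green's theorem with the Pick correction
   `A + N/2 + 1`. Outputs: lesion area `P_Area` (px) and mean gray level
   `P_Gray-level`.
2. **Input model.** Marker panels are validated against normal reference
   ranges (TPSA 0–4 ng/ml, FPSA 4–20 µg/L, HB 120–165 g/L, RBC
   12–15 g/100 ml, PAP 0–3.5 ng/ml, PSMA 0–4 ng/ml) with plausibility
   caps, then min–max scaled to [0, 1] and split into the disease vector
   `ACP(t)` (6 markers) and image vector `AHP(t)` (2 features).
3. **Two sigmoid perceptrons** (default 6-4-1 and 2-3-1), trained
   from scratch by batch gradient descent with momentum (dynamic
   coefficient 0.7) and bold-driver rate adaptation, weights initialised
   uniformly on [0, 0.5). Targets are the stage-band midpoints.
4. **Rule-based fusion.** A four-case weight table combines the two
   scores: `DPC = w_d · s_disease + w_i · s_image`, `w_i = 1 − w_d`,
   with `w_d` = 0.6 / 0.4 / 0.8 / 0.2 depending on whether each channel
   looks early (stages I–II) or late (III–IV). The DPC score maps to a
   clinical stage by the bands (0, 0.25] → I, (0.25, 0.50] → II,
   (0.50, 0.75] → III, (0.75, 1] → IV, each with a treatment
   recommendation, and classifiers are scored by TPR/FPR/ROC.
5. **Synthetic cohorts.** A generator produces stage-conditioned marker
   panels (log-normal; TPSA rising, FPSA/TPSA falling below 0.1 by stage
   IV) and lesion images (one bright ellipse, noisy background) with
   exact rasterised ground truth, so the whole pipeline is testable
   without patient data.

## Worked example

```r
library(prostadss)

# 1. synthetic cohort with ground truth
spec  <- cohort_spec(800, seed = 1001)
train <- generate_cohort(spec)$cohort
test  <- generate_cohort(cohort_spec(200, seed = 2002))$cohort

# 2. train the two channels on stage-midpoint targets
cfg     <- default_run_config(seed = 1)
scaled  <- prostadss:::.scale_cohort(train, default_ranges())
targets <- stage_target(train$stage)
mcfg <- prostadss:::.config_net(cfg$marker_net)
icfg <- prostadss:::.config_net(cfg$image_net)
mnet <- train_network(init_network(mcfg), scaled[, 1:6], targets, mcfg)$net
inet <- train_network(init_network(icfg), scaled[, 7:8], targets, icfg)$net

# 3. diagnose the held-out cohort
out <- diagnose_cohort(test, mnet, inet)
mean(out$reports$stage == test$stage)
#> [1] 0.995

out$reports[1, c("disease_score", "image_score", "dpc", "stage")]
#>   disease_score image_score       dpc stage
#> 1     0.6563157   0.6535639 0.6546646   III
```

The first patient's marker score 0.656 and image score 0.654 both fall
in the late band, so the rule engine picks `w_disease = 0.4`, the fused
DPC 0.655 lands in (0.50, 0.75] and the patient is staged III
(endocrine-therapy recommendation), matching the generator's true
stage. On this 200-patient held-out cohort the
fused stage matches the generator's true stage 99.5% of the time.

The same flow is available from the command line
(`inst/cli/prostadss`): `simulate`, `preprocess`, `train`, `diagnose`,
`evaluate`.

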