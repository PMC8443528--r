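# tmshift

Analysis pipeline for protein melting-temperature change (ΔTm, °C) upon
single point mutation: dataset characterization, structure-derived
featurization, a shallow neural baseline predictor, a full prediction
grid over the structural-feature space, per-substitution linear
regression, and a forward/reverse symmetry experiment — exercised end to
end on synthetic data with known ground truth.

## The scientific problem

Predicting how a point mutation shifts a protein's melting temperature
is unsolved even for small, soluble, monomeric two-state folders.
Curated ΔTm compilations are dominated by a few protein families, skewed
toward destabilization (~47% of entries below −2 °C versus ~12% above
+2 °C), and truncated to |ΔTm| < 20 °C. A useful working decomposition
is

    ΔTm  =  baseline(substitution, RSA, B, SS)  +  structure-specific deviation

where the baseline is a smooth function of the substitution type and
three wild-type structural descriptors — relative solvent accessibility
(RSA ∈ [0, 1]), the mean B-factor of the residue's C/N/O atoms (Å²), and
a ternary secondary-structure code (−1 sheet-like: DSSP B/E/S; +1
helical: H/G/I; 0 otherwise) — while the deviations arise from fine
structural detail that these descriptors cannot see.

The baseline predictor is a 19 → 64 → 1 feed-forward network. Its 19
inputs are 8 physicochemical descriptor values of the wild-type amino
acid, the 8 mutant-minus-wild-type changes, and the 3 structural
features; inputs are z-scored on the training split only, except the
secondary-structure and charge slots which keep their categorical
coding. Training minimizes mean-square error with validation-driven
early stopping; the protocol augments the dataset with 15 mock
wild-type→wild-type rows (ΔTm = 0) per protein, splits 60/30/10, and
replicates over independent random splits, selecting the final model by
best validation RMSE. The package also fits, per ordered substitution,
the multiple linear regression ΔTm = β₀ + β₁·RSA + β₂·B + β₃·SS, and
ships two transcribed Val→Ala reference equations, a linear one
(12.63·RSA − 0.089·B + 1.95·SS − 5.81) and a symbolic one
(SS − SS/(8.58·RSA − 0.89) + 13.56·RSA − 7.35), as evaluable fixtures.

This package is intended for developers of stability predictors and
structural bioinformaticians who need a tested, reproducible harness for
ΔTm dataset analysis and baseline modeling.

## Worked example

```r
library(tmshift)

# a synthetic dataset under the default study conditions
sim <- simulate_dataset(synthetic_config(), seed = 1)
ds  <- sim$dataset
summarize_dataset(ds)
#> dTm dataset summary: 1626 entries, 90 proteins
#> categories: destabilizing 53.5%, neutral 35.2%, stabilizing 11.3%, within_1 18.4%

# baseline training protocol: augment, split, replicate
aug  <- augment_with_wt(ds, n_per_protein = 15, seed = 1)
reps <- replicate_training(aug, n_replicates = 5,
                           cfg = net_config(max_epochs = 1500,
                                            early_stop_patience = 100))
reps
#> 5 replicate networks; test RMSE min/median/max = 2.25/2.44/2.62 C; selected replicate 3

best <- reps$models[[reps$selected]]
reps$test_metrics[[reps$selected]]
#> RMSE 2.62 C, Pearson r 0.55, n = 299
#> |error| bands: <1 C 57%, 1-4 C 30%, >5 C 8%, >=10 C 1%

# full baseline grid: 380 substitutions x 462 feature combinations
grid <- generate_grid(best)
nrow(grid)
#> [1] 175560

# the transcribed Val->Ala reference equations at the origin
eval_reference_equation("val_ala_linear",   rsa = 0, b = 0, ss = 0)
#> [1] -5.81
eval_reference_equation("val_ala_symbolic", rsa = 0, ss = 0)
#> [1] -7.35
```

The summary says the simulated compilation reproduces the destabilizing
skew; the replicate table shows the five split/train cycles agree to a
few tenths of a degree; the selected network's held-out metrics (RMSE
2.62 °C, r 0.55, 57% of predictions within 1 °C but 1% off by ≥ 10 °C)
show a baseline that captures the smooth trend while missing the large
structure-specific deviations — exactly the decomposition the generator
encodes.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
dataset and write their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | draw the 1626-entry dataset + ground truth |
| `02_characterize.R` | composition summary, substitution matrix, binned ΔTm profiles |
| `03_structure_features.R` | toy PDB/DSSP fixtures through the feature pipeline |
| `04_train_baseline.R` | augmentation, 60/30/10 splits, replicate training, model JSON |
| `05_grid_regression.R` | 175,560-row grid, per-substitution OLS, reference equations, web-app JSON export |
| `06_symmetry.R` | forward vs forward+reversed training over 5 seeds |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

## Package documentation

The methods vignette (`vignettes/tmshift-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, the
numerical edge-case rules, and known limitations.
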