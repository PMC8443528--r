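#!/usr/bin/env Rscript
# Train the replicated baseline dTm networks.
#
# Follows the baseline training protocol: extend the dataset with 15 mock
# wild-type "mutations" per protein (dTm = 0), split 60/30/10 into
# train / early-stop / test, train the 19 -> 64 -> 1 network on MSE with
# early stopping, and repeat over independent random splits. Replicates
# are kept to 5 here (the dispersion table shows they behave alike; the
# protocol supports 20). The final model is the best-validation-RMSE
# replicate, serialized as JSON.

suppressPackageStartupMessages(library(tmshift))

ds <- load_dataset("results/synthetic_s1626_like.tsv")
aug <- augment_with_wt(ds, n_per_protein = 15, seed = 1)
cat(sprintf("augmented: %d entries (%d mock wild-type rows)\n",
            nrow(aug), nrow(aug) - nrow(ds)))

cfg <- net_config(max_epochs = 1500, early_stop_patience = 100, seed = 1)
reps <- replicate_training(aug, n_replicates = 5, cfg = cfg)
print(reps)
readr::write_tsv(reps$metrics, "results/replicate_metrics.tsv")

best <- reps$models[[reps$selected]]
write_model_json(best, "results/baseline_model.json")

sel <- reps$test_metrics[[reps$selected]]
cat("\nselected network, held-out test part:\n")
print(sel)
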