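#!/usr/bin/env Rscript
## Stage 3: quality control, normative modelling and deviation scoring.
##
## Applies the Euler-index MAD filter and the per-diagnosis/sex eTIV
## Tukey-fence filter, fits one distributional regression per region on
## the reference controls (age + age^2 + sex location, age-dependent
## log-scale, partially pooled site offsets, Gaussian/SHASH residuals by
## AIC), scores everyone else as deviation Z-scores, and residualizes the
## Z-scores against eTIV within sex-by-diagnosis cells.

library(mindev)

data_dir <- "results/data"
manifest <- read_manifest(file.path(data_dir, "manifest.csv"))
degrees <- read_tsv_matrix(file.path("results", "degrees.tsv"))

ef <- euler_mad_filter(manifest, n_mad = 2)
vf <- etiv_iqr_filter(ef$manifest, fence_multiplier = 1.5)
qc <- vf$manifest
cat("QC: excluded", nrow(ef$exclusions), "subjects by Euler index,",
    nrow(vf$exclusions), "by eTIV fences;", nrow(qc), "remain\n")

train <- qc$diagnosis == "NC_train"
model <- fit_normative(degrees[qc$subject_id[train], , drop = FALSE],
                       qc[train, ], normative_config(min_site_n = 5))
print(model)

test_man <- qc[!train, ]
z <- compute_deviation_z(model,
                         degrees[test_man$subject_id, , drop = FALSE],
                         test_man)
z <- residualize_etiv(z, test_man)

ev <- evaluate_model(model,
                     degrees[test_man$subject_id[
                       test_man$diagnosis == "NC_test"], , drop = FALSE],
                     test_man[test_man$diagnosis == "NC_test", ])
write.csv(ev, "results/model_eval.csv", row.names = FALSE)
cat(sprintf(
  "Held-out controls: Z mean %.3f, sd %.3f; tails %.2f%% / %.2f%%\n",
  mean(ev$z_mean), mean(ev$z_sd), 100 * mean(ev$pos_rate),
  100 * mean(ev$neg_rate)))

df <- data.frame(id = rownames(z), z, check.names = FALSE)
write.table(df, "results/zscores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_manifest(test_man, "results/test_manifest.csv")
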