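#!/usr/bin/env Rscript
## Stage 4: extreme deviations, overlap/difference maps, effect sizes,
## heterogeneity.
##
## Binarizes deviations at |Z| > 1.96, counts per-subject burden, maps
## group overlap minus held-out-control overlap per region with
## label-permutation inference, contrasts diagnostic groups with Cohen's d
## maps, and summarises within-group heterogeneity by pairwise Hamming
## distances.

library(mindev)

z <- read_tsv_matrix("results/zscores.tsv")
tm <- read_manifest("results/test_manifest.csv")

bin <- threshold_deviations(z, 1.96)
counts <- count_deviations(bin)
write.csv(counts, "results/counts.csv", row.names = FALSE)
agg <- merge(counts, tm[, c("subject_id", "diagnosis")])
cat("Median negative deviation count by group:\n")
print(tapply(agg$negative_count, agg$diagnosis, median))

ov <- permutation_overlap_test(bin, tm, n_perm = 10000, seed = 20260924)
write.csv(ov, "results/overlap_regions.csv", row.names = FALSE)
sig <- ov[ov$q_greater < 0.05 & ov$direction == "negative", ]
cat("Regions with FDR-significant excess negative deviations:\n")
print(table(sig$group))

pairs <- list(c("MCI_stable", "MCI_progressive"),
              c("MCI_stable", "AD"), c("MCI_progressive", "AD"))
dmaps <- do.call(rbind, lapply(pairs, function(p)
  cbind(pair = paste(p, collapse = "_vs_"),
        cohens_d_map(z, tm, p, n_perm = 10000, seed = 20260925))))
write.csv(dmaps, "results/cohens_d.csv", row.names = FALSE)
cat("FDR-significant regions per contrast:\n")
print(tapply(dmaps$q < 0.05, dmaps$pair, sum))

het <- hamming_heterogeneity(bin, tm)
write.csv(het, "results/heterogeneity.csv", row.names = FALSE)
cat("Within-group heterogeneity (negative deviations):\n")
print(het[het$direction == "negative", ])
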