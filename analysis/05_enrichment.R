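#!/usr/bin/env Rscript
## Stage 5: functional-network enrichment under two null families.
##
## For each network and group: the proportion of subjects with at least
## one extreme deviation in the network, versus held-out controls, tested
## against (a) diagnostic-label permutations and (b) spatially constrained
## rotation nulls (Hungarian assignment of rotated spherical centroids).

library(mindev)

z <- read_tsv_matrix("results/zscores.tsv")
tm <- read_manifest("results/test_manifest.csv")
parc <- read_parcellation("results/data/parcellation.tsv")
bin <- threshold_deviations(z, 1.96)

gl <- group_label_null(bin, parc, tm, n_perm = 10000, seed = 20260926)
sp <- spatial_rotation_null(bin, parc, tm, n_perm = 10000,
                            seed = 20260927)
gl$null_family <- "group_label"
sp$null_family <- "spatial_rotation"
enr <- rbind(gl, sp)
write.csv(enr, "results/enrichment.csv", row.names = FALSE)

negAD <- enr[enr$direction == "negative" & enr$group == "AD", ]
cat("AD negative-deviation network enrichment (delta vs controls):\n")
print(negAD[order(-negAD$delta),
            c("network", "delta", "q_greater", "null_family")])
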