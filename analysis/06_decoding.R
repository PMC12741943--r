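#!/usr/bin/env Rscript
## Stage 6: spatial decoding of group-average deviation maps.
##
## Bilaterally averages each group's mean deviation map and correlates it
## with synthetic regional reference maps (Gaussian-process surrogates for
## receptor-density maps), with spin-permutation p-values from rotation
## nulls of the deviation map.

library(mindev)

z <- read_tsv_matrix("results/zscores.tsv")
tm <- read_manifest("results/test_manifest.csv")
parc <- read_parcellation("results/data/parcellation.tsv")

maps <- generate_reference_maps(parc, n_maps = 4, length_scale = 0.8,
                                seed = 20260928)
left <- parc[parc$hemisphere == "L", ]
cents <- as.matrix(left[, c("cx", "cy", "cz")])

rows <- list()
for (g in c("MCI_stable", "MCI_progressive", "AD")) {
  gz <- colMeans(z[tm$diagnosis == g, , drop = FALSE])
  bz <- bilateral_average(gz, parc)
  for (m in colnames(maps)) {
    st <- spin_correlation(bz, maps[, m], cents, n_perm = 5000,
                           seed = 20260929)
    rows[[length(rows) + 1]] <- data.frame(group = g, map = m, r = st$r,
                                           p_spin = st$p)
  }
}
dec <- do.call(rbind, rows)
write.csv(dec, "results/decoding.csv", row.names = FALSE)
cat("Spin-test correlations between deviation maps and reference maps:\n")
print(dec)
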