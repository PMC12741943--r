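# mindev

Individual-level deviation mapping for structural brain networks.

Alzheimer's disease is heterogeneous: group-average contrasts hide which
regions are abnormal in *which* patients. `mindev` implements a pipeline
that (1) builds each subject's **MIND** (Morphometric Inverse Divergence)
structural similarity network from vertex-level cortical features,
(2) fits **normative models** of regional network degree on reference
controls, (3) scores every test subject's regions as deviation
**Z-scores** against those norms, and (4) runs the downstream clinical
analyses: extreme-deviation overlap and difference maps with permutation
inference, functional-network enrichment under group-label and spatial
rotation nulls, spin-test decoding against regional reference maps, and
models of deviation burden against diagnosis, APOE genotype, mortality
and post mortem neuropathology. A synthetic multi-site cohort generator
with injectable, network-targeted disease effects makes every stage
testable end to end.

It is written for neuroimaging methodologists who want a transparent,
fully seeded reference implementation of this analysis family at desk
scale.

## The model in brief

Similarity between cortical regions $a$ and $b$ is

$$\mathrm{MIND}(a,b) = \frac{1}{1+\mathrm{KL}(a,b)} \in (0, 1],$$

where $\mathrm{KL}(a,b)$ is the symmetric Kullback–Leibler divergence
between the regions' multivariate vertex-feature distributions (five
standardized features per vertex), estimated by a k-nearest-neighbour
density-ratio estimator. A region's **weighted degree** — its mean
similarity to all other regions — is modelled per region on reference
controls with a distributional regression:
location $\mu = \beta_0+\beta_1\mathrm{age}+\beta_2\mathrm{age}^2+\beta_3\mathrm{sex}+u_{site}$,
scale $\log\sigma = \gamma_0+\gamma_1\mathrm{age}+v_{site}$, sinh–arcsinh
(SHASH) or Gaussian residuals chosen by AIC, and site offsets partially
pooled by a quadratic penalty. Deviations are Gaussianized quantile
residuals $Z=\sinh(\delta\,\mathrm{asinh}\,r-\epsilon)$, $r=(y-\mu)/\sigma$;
regions with $|Z|>1.96$ are **extreme deviations**, counted per subject
and direction.

## Worked example

```r
library(mindev)

parc   <- generate_parcellation(n_regions = 60, n_networks = 7, seed = 1)
spec   <- cohort_spec(n_nc_train = 100, n_nc_test = 30, n_mci_stable = 0,
                      n_mci_progressive = 0, n_ad = 30,
                      vertices_per_region = 60, targeted_networks = 7,
                      seed = 501)
cohort <- generate_cohort(spec, parc)
deg    <- cohort_degrees(cohort, k = 3, seed = 601)

train  <- cohort$manifest$diagnosis == "NC_train"
model  <- fit_normative(deg[train, ], cohort$manifest[train, ],
                        normative_config(min_site_n = 5))
z      <- compute_deviation_z(model, deg[!train, ],
                              cohort$manifest[!train, ])
bin    <- threshold_deviations(z, 1.96)
tm     <- cohort$manifest[!train, ]

enr <- group_label_null(bin, parc, tm, n_perm = 500, seed = 701)
subset(enr, direction == "negative" & network == 7,
       select = c(group, network, prop, prop_control, delta, q_greater))
```

```
   group network      prop prop_control     delta   q_greater
14    AD       7 0.9666667          0.3 0.6666667 0.004657352
```

97% of synthetic AD subjects — versus 30% of held-out controls — have at
least one extreme negative deviation in the degraded network, and the
group-label permutation null rejects at FDR q = 0.005: the pipeline
recovers the network that the generator degraded. The full desk-scale
study (≈600 subjects, all stages, ~10 minutes) is scripted under
`analysis/01_simulate.R` … `analysis/07_clinical.R`; each script prints
what it found and writes its tables under `results/`.

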