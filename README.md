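# rhizonet

Linking rhizosphere soil multi-nutrient cycling to microbial community
assembly and cross-kingdom co-occurrence networks in pure versus mixed
plantations.

## What this package is for

Mixed conifer–broadleaf plantations tend to carry more fertile soils than
conifer monocultures, and the leading mechanistic explanation runs through
the rhizosphere microbiome: mixing changes soil conditions, which change
bacterial and fungal diversity, the balance of deterministic versus
stochastic community assembly, and the architecture of bacteria–fungi
interaction networks — and those, in turn, drive nutrient cycling.
`rhizonet` implements the full analysis chain needed to test that story on
a standard design (two stand types × two stand ages × replicate plots,
one 16S-like and one ITS-like OTU table, rooted phylogenies, per-plot soil
chemistry), for soil ecologists and microbiome researchers who want each
step reproducible, seeded and unit-tested:

- **SMC index** — soil multi-nutrient cycling as the mean of z-scored
  SOC, NO3, NH4, TN, TP, AP, AK; Wilcoxon group tests; OLS against pH and
  SWC.
- **Diversity** — Shannon/Simpson/Pielou/Chao1, Bray–Curtis, PCoA,
  one-factor PERMANOVA (seeded permutations).
- **Assembly** — βMNTD/βNTI with a tip-shuffling phylogenetic null,
  Bray–Curtis Raup–Crick, the five-process partition
  (|βNTI| > 2 selection; RC ± 0.95 dispersal; drift otherwise), the
  modified stochasticity ratio (MST), and the Sloan neutral community
  model with migration rate `m` and fit `R²`.
- **Networks** — prevalence-filtered Spearman edge screen with BH FDR,
  signed cross-kingdom networks, topology summary, per-sample cohesion,
  natural-connectivity robustness curves, Zi–Pi keystone roles, GraphML
  export.
- **Drivers** — random-forest %IncMSE with permutation significance, and
  a recursive standardized path model giving direct/indirect/total
  effects (STE) on SMC.
- **Synthetic studies** — a generator that assembles two-kingdom
  communities by a seeded death–birth (Moran) process with controllable
  migration `m`, Gaussian-kernel environmental filtering `s` on a
  Brownian trait, and cooperative co-fluctuation factors, plus
  group-shifted correlated soil chemistry. It provides ground truth for
  every stage.

The core quantities, in the field's notation: βNTI is the z-score of
observed βMNTD against a taxa-label null (|βNTI| > 2 ⇒ deterministic
assembly); RCBray ∈ [−1, 1] with |RC| > 0.95 ⇒ dispersal-driven; MST ∈
[0, 1] with values > 0.5 read as stochasticity-dominated; the Sloan NCM
predicts occurrence frequency from mean relative abundance via a
beta(-binomial) law governed by `Nm`; natural connectivity is
ln(mean(exp(λᵢ))) over adjacency eigenvalues; cohesion is the
abundance-weighted sum of each taxon's mean retained positive (negative)
correlation; STE is the sum over directed paths of products of
standardized coefficients.

## Worked example

```r
library(rhizonet)

study <- generate_study(simulation_spec(seed = 1))   # 2 x 2 x 6 design
#> synthetic_study: 24 samples; 300 bacterial and 150 fungal taxa

cfg <- rhizo_config(n_null = 99, n_perm = 199, rf_trees = 300,
                    rf_perm = 99, seed = 1)
res <- run_pipeline(study, cfg)

res$smc
#> SMC index over 24 samples (mean 5.17e-17 )
#> group means: M =  0.466, P = -0.466
#> Wilcoxon (P vs M): W = 11 , p = 0.000429
#> OLS SMC ~ pH: slope 1.110, R2 0.445, p 0.000367
#> OLS SMC ~ SWC: slope 6.620, R2 0.475, p 0.000196

res$assembly$bacteria$ncm$M
#> Sloan NCM fit: m = 0.9024 (Nm = 4512.0), R2 = 0.965 over 284 taxa

res$assembly$bacteria$partition$stochastic_share
#>         P         M
#> 0.3636364 0.9848485

res$assembly$bacteria$mst[c("P", "M")]
#>         P         M
#> 0.6739568 0.7707026

res$networks$M$network
#> co-occurrence network: 37 nodes, 26 edges (88% positive)
#>   avg degree 1.41, path length 1.20, clustering 0.65, Q 0.856

head(res$drivers$importance[order(-res$drivers$importance$inc_mse), ], 3)
#>       predictor  inc_mse    p
#> 10 cohesion_neg 7.709080 0.02
#> 1     B_shannon 4.764486 0.05
#> 9  cohesion_pos 4.519225 0.05
```

Reading the output: the SMC index is higher in mixed stands (+0.47 vs
−0.47 z-units, Wilcoxon p < 0.001) and rises with pH and soil water
content. Bacterial assembly in mixed stands is dominated by stochastic
processes — 98% of within-M pairs have |βNTI| < 2, versus 36% in pure
stands — with MST telling the same story (0.77 vs 0.67), and the
mixed-stand NCM fit recovers a migration rate near the generating value
(m = 0.90 at a simulated 0.9) with R² = 0.97. The mixed-stand network is
88% positive edges. These are exactly the contrasts the generator plants
(mixed stands: higher migration, weaker filtering, stronger cooperative
covariance), so the run doubles as an end-to-end correctness check.

## Layout

| Path | Contents |
| --- | --- |
| `R/data_io.R` | OTU table / Newick / metadata IO, validation, alignment |
| `R/synthetic.R` | the study generator |
| `R/smc.R` | SMC index, Wilcoxon, OLS |
| `R/diversity.R` | alpha/beta diversity, PCoA, PERMANOVA |
| `R/assembly.R` | βMNTD/βNTI, RCBray, process partition, MST, NCM |
| `R/network.R` | edge screen, topology, cohesion, robustness, Zi–Pi |
| `R/drivers.R` | RF importance, path model, driver table |
| `R/pipeline.R` | configuration and the `run_pipeline()` orchestrator |
| `vignettes/rhizonet-methods.Rmd` | the methods vignette |

See the methods vignette for the statistical definitions, the generator's
assumptions, and known limitations.
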