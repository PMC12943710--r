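---
title: "Methods: assembly, networks and soil multi-nutrient cycling in rhizonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly, networks and soil multi-nutrient cycling in rhizonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rhizonet is an analysis pipeline for a common study design in forest soil
microbial ecology: rhizosphere communities of one tree species sampled in
pure versus mixed plantations, profiled with two markers (a 16S-like
bacterial table and an ITS-like fungal table), accompanied by rooted
phylogenies and per-plot soil chemistry. The package asks how soil
multi-nutrient cycling relates to microbial diversity, to the balance of
deterministic and stochastic community assembly, and to the structure of
the cross-kingdom co-occurrence network. This vignette explains each
statistical component, the choices behind its defaults, and what the
bundled synthetic-data generator does and does not emulate.

## The soil multi-nutrient cycling (SMC) index

SMC is an averaging multifunctionality index: exactly seven nutrient
variables — SOC, NO3, NH4, TN, TP, AP and AK — are z-scored (sample SD,
denominator $n-1$) and averaged per sample. Standardization is performed
jointly across *all* samples, both stand types and both ages, so that group
contrasts of the index are interpretable; standardizing within groups would
remove the very signal being tested. pH and SWC are deliberately not part
of the index; they are retained as covariates, and `smc_index()` reports
ordinary-least-squares fits of SMC against each. Group differences use the
Wilcoxon rank-sum test: exact two-sided p by enumeration when
$n_A + n_B \le 12$ without ties, otherwise the tie-corrected normal
approximation. Because z-scores absorb affine changes of units, SMC is
invariant to rescaling any input variable, and swapping the group labels
flips the sign of the group difference exactly.

## Diversity

Alpha diversity reports Shannon $H = -\sum p_i \ln p_i$ (natural log; the
base is a convention and is stated here because downstream comparisons only
need consistency), Simpson $1 - \sum p_i^2$, Pielou $H / \ln S_{obs}$
(defined as 1 for a single-taxon sample, the evenness of a singleton), and
Chao1 $S_{obs} + F_1^2 / (2 F_2)$ with the bias-corrected fallback
$S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))$ when no doubletons exist. Beta
diversity is Bray–Curtis on counts; principal coordinates come from the
eigendecomposition of the double-centred Gower matrix, with negative
eigenvalues (Bray–Curtis is semi-metric) reported rather than hidden.
PERMANOVA is the one-factor form: pseudo-F from among/within sums of
squared dissimilarities, $R^2 = SS_{among}/SS_{total}$, and
$p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + B)$ under label permutation
with a fixed seed, so $p \ge 1/(B+1)$ by construction. The implementation
is checked against `vegan::adonis2` in the test suite; only the one-factor
contrast the pipeline reports is supported.

## Community assembly

The assembly module follows the null-model framework that partitions
pairwise community turnover into five processes.

**βMNTD and βNTI.** βMNTD is the abundance-weighted mean patristic
distance from each taxon to its nearest neighbour in the partner
community, averaged over both directions; a taxon shared by both samples
contributes zero. βNTI is the z-score of the observed βMNTD against a
null distribution obtained by shuffling taxon labels across the tips of
the phylogeny ("taxa.labels" null). One shared tip relabeling per
replicate is applied to all sample pairs, which preserves cross-pair
correlation structure and makes the computation one patristic-lookup pass
per replicate. At least 99 replicates are required (z-scores from fewer
are unstable); the default is 999. Pairs with zero null SD (e.g.
self-comparisons) are flagged degenerate and assigned βNTI = 0 rather
than NaN. |βNTI| > 2 is read as deterministic assembly: > 2 heterogeneous
selection, < −2 homogeneous selection.

**RCBray and the five-process partition.** For pairs not assigned to
selection, the Bray–Curtis Raup–Crick index compares observed
dissimilarity with null communities assembled by drawing each sample's
observed richness (taxa chosen with probability proportional to occurrence
frequency) and filling to its observed total (probability proportional to
mean relative abundance). Ties count half,
$RC = 2[(\#null < obs) + 0.5(\#null = obs)]/B - 1 \in [-1, 1]$.
RC > 0.95 is dispersal limitation, RC < −0.95 homogenizing dispersal, and
|RC| ≤ 0.95 drift/undominated. The ±0.95 cut-offs follow the standard
framework; they and the βNTI cut-off are configuration keys, not
constants, because published variants differ.

**MST.** The modified stochasticity ratio uses the same null scheme:
per within-group pair, $\min(D_{obs}, \bar D_{null}) / \max(D_{obs},
\bar D_{null})$, averaged within groups — 1 means observed turnover is
exactly null-like (fully stochastic), and values shrink whenever observed
turnover is either much smaller (homogenizing selection) or much larger
(heterogeneous selection, dispersal limitation) than the null. The
symmetric min/max form is used; exact published variants differ and the
choice is recorded here rather than hidden. Both stochasticity summaries —
the |βNTI| < 2 share and MST — are reported; they are related but need not
agree numerically.

**The Sloan neutral community model.** The NCM predicts a taxon's
occurrence frequency from its mean relative abundance $p$ under island
dynamics with migration probability $m$. Two prediction forms are
implemented. The default is the exact stationary occupancy of a finite
Moran community of size $N$: counts follow a beta-binomial with shapes
$Ap$ and $A(1-p)$, $A = m(N-1)/(1-m)$, and the predicted frequency is the
probability of at least one individual. The classical continuous
approximation $1 - \mathrm{BetaCDF}(d;\; Nmp,\; Nm(1-p))$ with detection
limit $d = 1/N$ is available as `method = "beta"`. The exact form is the
default because, against communities simulated by the package's own
death–birth process, the continuous approximation misstates rare-taxon
occupancy and inflates $\hat m$ by roughly a factor of two, whereas the
beta-binomial form recovers the generating $m$ to within ~10% across
$m \in [0.1, 0.7]$ — a direct numerical check, reproduced in the test
suite. $m$ is estimated by least squares of predicted against observed
frequency on a logit-transformed 1-D search, constrained to (0, 1]; note
that field estimates quoted as $m > 1$ arise from the $Nm/N$ convention
and are not representable under this constraint. $R^2 = 1 - SSE/SST$ can
be negative when the neutral curve fits worse than a constant — expected
for strongly filtered communities, and itself informative.

## Co-occurrence networks

Edges are screened by Spearman correlation on relative abundances among
taxa passing a prevalence filter (default: present in ≥ 1/3 of samples),
keeping pairs with $|\rho| \ge 0.6$ and Benjamini–Hochberg $q \le 0.05$.
Spearman rather than Pearson resists the skew of compositional abundance
data; compositionality-aware estimators (SparCC-type) are out of scope and
the thresholds are configuration keys because published screens vary
widely. Networks are built per stand type from that group's samples only.
On the signed weighted graph the package reports node/edge counts, average
degree, clustering coefficient, average path length (largest connected
component), modularity (greedy agglomeration on unsigned weights), and the
positive-edge fraction. Cohesion summarises each sample's connectivity:
per taxon, the mean of its retained positive (negative) correlations; per
sample, the relative-abundance-weighted sum of those connectedness values,
giving a non-negative positive component and a non-positive negative
component. The null-model-corrected connectedness of the original cohesion
formulation is a noted extension point; the uncorrected form is
implemented. Robustness uses natural connectivity,
$\bar\lambda = \ln\left(\frac{1}{N}\sum_i e^{\lambda_i}\right)$ over
adjacency eigenvalues of the unsigned, unweighted graph, tracked as nodes
are removed in decreasing-degree order or at random (averaged over
repeats). Keystone roles follow the within-module degree z-score $Z_i$ and
participation coefficient $P_i = 1 - \sum_s (k_{is}/k_i)^2$ with the
conventional 2.5/0.62 cut-offs; isolated nodes get $P_i = 0$ and a flag.

## Driver models

Random-forest importance is %IncMSE (out-of-bag permutation importance,
scaled) from a regression forest of SMC on the microbial predictors
(B_/F_-prefixed alpha diversity, cohesion components, per-sample mean
βNTI, group MST). Significance does not reuse the forest's internal
scores: the response is permuted, the forest refit, and each predictor's
observed importance compared with its null distribution,
$p = (1 + \#\{null \ge obs\})/(1 + B)$.

The structural model is deliberately a *recursive path analysis with
observed variables*, not latent-variable SEM: each endogenous variable is
regressed by OLS on its declared parents after z-scoring, coefficients are
standardized path weights, and the standardized total effect (STE) of a
variable on the outcome is the sum over all directed paths of the products
of the coefficients along them (direct + indirect), computed by dynamic
programming over the DAG and satisfying the path-tracing identity to
1e-10. Everything such a model reports — standardized coefficients,
per-equation $R^2$, STE — is what the pipeline needs, and nothing requires
covariance-matrix ML fitting. STE values can exceed 1 when several
indirect channels reinforce each other. The diagram is user-declared
configuration; the shipped default routes stand type through soil (pH),
both kingdoms' diversity, bacterial assembly and network complexity
(operationalized per-sample as positive cohesion, since topology metrics
are per-network, not per-sample) into SMC, with diversity also acting on
complexity.

## The synthetic-data generator

No public data accompany the motivating study design, so the generator is
a first-class module: every downstream method is tested against data whose
generating process is known.

A study is a 2 × 2 × 6 factorial (two stand ages, stand types P and M,
six replicate plots; 24 samples), with 300 bacterial and 150 fungal taxa
at 5,000 reads per sample. Communities are assembled per sample by a
death–birth (Moran) local community process: initialization by a
multinomial draw from a source pool, then ten death–birth events per
individual in which the replacement is a pool migrant with probability
$m$, otherwise a copy of a random local individual. Ten generations was
chosen after checking that occupancy spectra and across-sample variance
stop changing at desk scale (the island-Moran stationary variance is
reproduced to a few percent). The source pool is a log-normal
metacommunity (shape `sdlog = 2`, a realistic steep rank-abundance curve)
reweighted by three per-sample factors:

- **Environmental filtering.** A trait evolved by Brownian motion on a
  coalescent-topology tree with exponential branch lengths (standardized
  to SD 1) and a Gaussian kernel $\exp(-s (trait - env)^2)$. P samples
  are strongly filtered ($s = 6$) toward an optimum at −0.8 SD that
  differs by 1.6 SD between the two stand ages; M samples are nearly
  neutral ($s = 0.1$, age shift 0.2). The age-split optimum in P is what
  produces heterogeneous selection across ages — observed turnover far
  above the null — alongside homogeneous selection within an age, which
  jointly lower P's stochastic share and MST.
- **Migration.** $m = 0.15$ in P versus $0.9$ in M: mixed-stand
  communities track the metacommunity (null-like, high NCM fit), pure
  stands drift.
- **Cooperation.** A per-sample "fertility" factor loading on ~60% of
  taxa and four abundance-biased interaction guilds (~10% of taxa each)
  with log-normal multipliers. Factor SDs are larger in M (0.7/0.5)
  than in P (0.2/0.3). These shared fluctuations are what a correlation
  screen can detect at $n = 12$; making them stronger in M encodes the
  target contrast of a more cooperative mixed-stand network, while P's
  filter supplies its sign-mixed edges.

Soil chemistry is drawn per sample in SD units with stand-type shifts
(+1 SD for SOC, TN, NH4, AP; +0.8 for TP, AK, pH, SWC; −0.8 for NO3), a
+0.2 SD age effect on nutrients, a common 0.3 correlation among nutrients
and 0.3 between pH/SWC and the nutrients, then mapped to realistic units.
The pH direction deserves a note: the emulated study reports lower pH in
mixed stands in one place but a strong *positive* SMC–pH relationship in
another; the generator defaults to the direction consistent with the
positive SMC–pH association and exposes the sign as an ordinary parameter
(`soil_effects["pH"]`) rather than resolving the contradiction.

What the generator does **not** emulate: sequencing error, chimeras and
PCR bias (counts are exact multinomial/Moran draws); taxonomy; spatial
autocorrelation among plots; temporal dynamics; compositional biases of
extraction. Passing tests therefore demonstrate that the estimators
recover known structure from idealized count data of realistic size and
shape — not that they are robust to every artefact of real amplicon data.

## Numerical choices and degenerate inputs

Seeds: every randomized operation takes one integer seed; the pipeline
derives per-stage child seeds deterministically (`derive_seed`), so
results are bit-reproducible and stages are independent of each other's
draw counts. RNG state is restored after each operation. βNTI with zero
null SD → 0 with a degeneracy flag; MST pairs with zero observed and null
distance are excluded with a flag; Pielou of a singleton community is 1;
Chao1 falls back to the bias-corrected form at $F_2 = 0$; natural
connectivity of an edgeless graph is 0 (all eigenvalues zero); empty edge
sets yield an explicitly flagged all-zero topology summary; `fit_ncm`
clips $\hat m$ into (0, 1]; constant variables are a hard error in
z-scoring rather than silent NaN. Rarefaction is off by default (analyses
use counts or relative abundances as each method dictates) and available
as `rhizo_config(rarefy = depth)`.

Problem sizes in the shipped tests — 99–999 null replicates, 24 samples,
up to a few hundred taxa per kingdom, five replicate studies for
directional checks — were chosen as the smallest sizes at which the
directional contrasts of the default design are stable across seeds; all
scale up by configuration.

## Known limitations

One-factor PERMANOVA only; no UniFrac; no compositionality-corrected
correlation; no latent-variable SEM; migration rates above 1 (the $Nm/N$
convention) are not representable; the cohesion null-model correction is
not implemented; networks at $n = 12$ samples per group detect only
strong associations regardless of screen settings, and the BH screen's
FDR control is nominal under the dependence structure of relative
abundances.
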