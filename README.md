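# mnQTL

Host genetics shapes not only *which* microbes live in the gut but *how
they interact*. `mnQTL` is an R package for reconstructing microbial
interaction networks from ordinary cross-sectional abundance data and
mapping the host genetic variants that control their emergent properties
— microbial-network QTLs (mnQTLs) — for researchers working at the
intersection of microbiome GWAS, community ecology and systems genetics.

## What it computes

**Interaction descriptors.** For a pair of microbes with snapshot
abundances `x_u > x_v > 0` (u the more abundant):

    Z_mu = x_u x_v / (x_u − x_v)        mutualism   (symmetric)
    Z_ag = x_u / x_v                    aggression  (directed u → v)
    Z_al = 1 − x_v / x_u                altruism    (directed u → v)

plus an antagonism descriptor whose two published renderings are both
available (`anForm`). When co-culture/monoculture data exist, the realized
strengths `M_u`, `A_n`, `A_g`, `A_l` are computed from co/mono abundance
ratios (with `A_g · A_l = 1` identically) and correlated against the
descriptors within growth phases segmented from fitted Gompertz /
logistic / Richards curves.

**Networks and emergent properties.** Edges are significance-filtered
against a within-host permutation null with BH-FDR control; per-host
networks use a descriptor-quantile rule. Six indices are computed per
network — connectivity, closeness `C(u) = 1/Σ D(u,v)`, betweenness
`B(u) = Σ g_vw(u)/g_vw`, eccentricity `E(u) = 1/max D(u,v)`, eigenvector
centrality (`AG = λG`), and PageRank
`P(u) = (1−d) + d Σ a_vu P(v)/K_v`, `d = 0.85` — along with hub/keystone
detection (hawk / dove / hawk–dove roles in aggression networks) and a
discrete power-law test of scale-freeness.

**QTL mapping.** Each per-host property summary, residualized on
covariates, is scanned with a genotype-class normal likelihood: class
means AA/Aa/aa (coded 1/0/−1), pooled ML variance, and
`LRT = n·ln(σ̂₀²/σ̂₁²)`, with genome-wide significance from the
permutation max-LRT distribution.

**Path analysis.** SNP-to-phenotype correlations are decomposed into a
direct path and indirect paths through network-perturbation mediators
(winter−summer property differences), screened at the 10% level:
`r_gz = P_z←g + Σ P_z←y·r_gy`, `R² = b'Rb`, residual path `√(1−R²)`,
with a mutual-information option for genotype correlations.

**Monte Carlo power study.** A synthetic-cohort generator (127 hosts,
8 microbes, HWE SNPs, big/moderate/small variance-explained schemes)
compares abundance-QTL scans with interaction-QTL scans on the same data.

## Worked example

Simulate a cohort in which one SNP (19% of phenotypic variance) modulates
the abundance ratio of a dominant–subordinate microbe pair, then scan the
per-host aggression strength `log Z_ag`:

```r
library(mnQTL)
cfg  <- simConfig(scheme = "big", scenario = "aggression", seed = 7)
sim  <- simulateCohort(cfg, seed = 42)
scan <- scanQTL(sim$networkPhenotype, sim$genotypes,
                nPerm = 200, alpha = 0.05, seed = 7,
                phenotypeName = "log Z_ag (dominant pair)")
scan
#> ScanResult [ log Z_ag (dominant pair) ]: 100 SNPs
#>   genome-wide threshold (alpha = 0.05 , 200 permutations): 14.193
#>   significant SNPs: 1
subset(scanTable(scan), significant)[c("snp", "muAA", "muAa", "muaa", "lrt", "n")]
#>       snp  muAA  muAa   muaa   lrt   n
#> snp1 snp1 1.463 1.042 0.3975 34.53 127
```

The one declared SNP is the causal one: its genotype classes differ in
mean log abundance ratio (1.46 vs 1.04 vs 0.40 — an additive allele
dosage effect on who dominates whom), its LRT of 34.5 clears the
genome-wide permutation threshold of 14.2, and all 127 hosts carried
complete genotypes. A full power comparison at any scheme is one call:
`powerStudy(cfg)` returns power ± binomial SE and the false-positive
rate for both the abundance scan and the interaction scan.

Real data enter through `loadCohort()` (tab-delimited abundance /
covariate / phenotype tables, coded genotype matrices or VCF), and every
pipeline stage is also reachable from the command line via
`inst/scripts/mnqtl` (`descriptors`, `validate`, `network`, `centrality`,
`scan`, `path`, `simulate`).

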