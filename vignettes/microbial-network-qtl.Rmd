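---
title: "From abundance snapshots to interaction-network QTLs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From abundance snapshots to interaction-network QTLs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnQTL)
```

# The model

Gut microbes do not act in isolation: hosts differ in how their microbes
cooperate and compete, and those differences — not just taxon abundances —
can be under host genetic control. `mnQTL` implements a pipeline that (i)
quantifies pairwise interactions from a single abundance snapshot per host,
(ii) assembles them into per-host and cohort-level interaction networks,
(iii) treats emergent network properties as quantitative phenotypes for QTL
mapping, and (iv) dissects SNP effects on end-point phenotypes (such as BMI)
into direct effects and effects mediated by network perturbations.

## Interaction descriptors

For two microbes with snapshot abundances $x_u > x_v > 0$ (the more abundant
microbe is always relabeled $u$), the four descriptors are

$$Z_{mu} = \frac{x_u x_v}{x_u - x_v},\qquad
  Z_{ag} = \frac{x_u}{x_v},\qquad
  Z_{al} = 1 - \frac{x_v}{x_u},$$

with mutualism and antagonism symmetric in the pair and aggression/altruism
directed from $u$ to $v$. Aggression is the more abundant microbe exploiting
the less abundant one; altruism the converse. These satisfy
$Z_{al} = 1 - 1/Z_{ag}$, $Z_{ag} > 1$ and $Z_{al} \in (0,1)$ whenever
$x_u > x_v > 0$, and $Z_{mu}$ scales linearly with the common abundance
scale while the two ratio forms are scale-free.

The antagonism descriptor's published rendering is typographically
ambiguous between $1/(x_u x_v (x_u - x_v))$ and $(x_u - x_v)/(x_u x_v)$.
The package defaults to the first (`anForm = "reciprocal-product"`) and
exposes the second (`"inverse-mutualism"`); any result involving $Z_{an}$
depends on this switch, which is why it is an explicit argument rather
than an internal constant. Similarly, whether descriptors are computed on
absolute or relative abundances is exposed (`normalize` in
`descriptorTensor()`) because the two conventions differ for $Z_{mu}$.

**Degenerate inputs.** Tied abundances make $Z_{mu}$ and $Z_{an}$
undefined (zero denominator): by default the pair is flagged missing with
a warning, because ties are common in sparse count data; `strict = TRUE`
raises instead. Zero abundances flag the whole pair missing; an optional
pseudocount can be added first (default off). $Z_{mu}$ and $Z_{an}$
explode as $x_u \to x_v$, so network construction winsorizes each host's
values at a per-host upper quantile (default 0.99) before testing edges.

## Observed strengths and their validation

When the same strain pair is grown in co-culture ($x_u, x_v$) and
monoculture ($w_u, w_v$), the realized interaction strengths are

$$M_u = \frac{(x_u/w_u)(x_v/w_v)}{|x_u/w_u - x_v/w_v|},\quad
  A_n = \frac{(w_u/x_u)(w_v/x_v)}{|w_u/x_u - w_v/x_v|},\quad
  A_g = \frac{x_u/x_v}{w_u/w_v},\quad
  A_l = \frac{x_v/w_v}{x_u/w_u},$$

with the algebraic identity $A_g A_l = 1$. $M_u$ is only meaningful when
both strains do better together ($x/w > 1$ for both); $A_n$ only when both
do worse; `observedStrengths()` reports these applicability flags and
`validateDescriptors()` restricts the corresponding correlations to
applicable pairs. Validation correlates each $Z$ descriptor with its
$M/A$ counterpart within growth phases, because interaction strength is
phase-dependent.

## Growth curves and phase segmentation

`fitGrowth()` fits Gompertz, logistic and four-parameter Richards curves
(shape $\nu$; $\nu = 1$ recovers the logistic and $\nu \to 0$ the
Gompertz) by Levenberg–Marquardt least squares. Starting values are taken
from the data (asymptote from the maximum, rate from the log-slope of the
middle third, midpoint at the half-maximum crossing) with a deterministic
five-point jittered multi-start, keeping the best residual sum of squares.
Model choice uses AICc by default, with a nested-F comparison available.

Phase boundaries are a convention, since "determined from the fitted
curve" admits many rules: the lag phase ends at the time of maximum
acceleration of the fitted curve and the log phase at the time of maximum
deceleration (the extrema of the second derivative, located numerically to
about $10^{-4}$ of the observed window). For a logistic with rate $r$ and
midpoint $t_0$ these are $t_0 \pm \ln(2+\sqrt{3})/r$.

A caveat worth stating plainly: because Richards nests both other models,
no information criterion can drive its selection rate to zero — the
log-RSS-ratio statistic between nested fits is scale-invariant, so its
distribution does not shrink as noise does. At the 16-point sampling grid
used by the synthetic fixtures we observe the generating model re-selected
in roughly 85–95% of 1%-noise replicates under AICc; treat automatic
selection between nested growth laws as approximate at small sample sizes.

## Networks and their emergent properties

Cohort-level networks (`buildNetwork()`) retain an edge when its
descriptor, averaged over hosts, is significantly elevated against a
within-host permutation null: each host's taxon labels are shuffled
independently (so a pair slot inherits the descriptor of a random
same-host pair), the cross-host mean is recomputed $B$ times, and
one-sided permutation p-values are BH-adjusted at level $\alpha$. The
exact edge-significance procedure in the source framework is unspecified;
this permutation scheme is the package's documented convention. Edges with
a degenerate (constant) null — e.g. a two-taxon cohort — are flagged
indeterminate rather than retained. Directed edges point from the more to
the less abundant taxon by majority vote across hosts, so an
aggression network can never contain a reciprocal pair. Per-host networks
(`perHostNetwork()`), the source of mapping phenotypes, skip the
cross-host test: edges are all finite descriptors, optionally thresholded
at a per-host quantile (default 0.9).

Node-level indices: closeness $C(u) = 1/\sum_v D(u,v)$, betweenness
$B(u) = \sum_{v<w} g_{vw}(u)/g_{vw}$ with fractional counting of tied
shortest paths, eccentricity $E(u) = 1/\max_v D(u,v)$, eigenvector
centrality from the leading eigenpair of the adjacency (in-edge based for
directed graphs, matching the incoming-link PageRank recursion), and
PageRank

$$P(u) = (1-d) + d \sum_v a_{vu} P(v) / K_v$$

with damping $d = 0.85$ and $K_v$ the out-degree of the linking node;
dangling mass is redistributed uniformly. The teleportation term is
implemented as printed, i.e. $(1-d)$ *without* division by the node count
$m$; the standard $(1-d)/m$ variant is an option, and the two solutions
are exactly proportional (factor $m$), so rankings coincide. The
network-level connectivity is the mean number of neighbors, and the
per-host scalar phenotypes are the means over nodes of each node index.
On disconnected graphs, closeness and eccentricity are computed within
each node's reachable set and a reachable fraction is reported — the
framework is silent here, so this is a documented choice.

All of these are implemented directly (breadth-first search, Brandes
accumulation, power iteration, dense eigendecomposition) and are verified
in the test suite against igraph as an independent oracle on random
directed and undirected graphs; igraph itself is only used for GraphML
export.

Hubs are nodes whose degree exceeds the median plus one raw median
absolute deviation (no cutoff is prescribed by the framework; the rule is
exposed as a function argument), compared with non-hubs by a two-sample
t-test on abundance. Aggression networks additionally partition linked
nodes into hawks (out-edges only), doves (in-edges only) and hawk–doves.
Scale-freeness is assessed by a discrete maximum-likelihood power-law fit
of the degree distribution with a parametric-bootstrap
Kolmogorov–Smirnov goodness-of-fit p-value; with fewer than 10 linked
nodes the test is reported undefined.

## QTL mapping

Property phenotypes are first residualized on host covariates by
fixed-effects regression (`correctPhenotype()`); a precomputed relatedness
matrix can be supplied for GLS, but no kinship term is used by default
because none is generally available. For a SNP with genotype classes AA/Aa/aa
(coded 1/0/−1, counts $n_1, n_2, n_3$), the alternative model gives each
class its own normal mean with a pooled maximum-likelihood variance; the
null has a single mean. The statistic is
$\mathrm{LRT} = n \ln(\hat\sigma^2_0/\hat\sigma^2_1)$, invariant under
affine transforms of the phenotype and asymptotically $\chi^2_2$ under the
null with three classes (verified by simulation in the acceptance suite).
Missing genotypes drop hosts per SNP, and classes below a minimum size
(default 2) are excluded rather than allowed to destabilize the variance
estimate. Genome-wide significance uses the permutation max-statistic:
phenotype labels are shuffled, the maximum LRT across SNPs is recorded per
permutation, and the threshold is the $(1-\alpha)$ empirical quantile
(type-1, so $\alpha = 1$ degenerates to the minimum). Thresholds are
computed per phenotype, with no correction across the property × type ×
season families, mirroring per-property scans; users combining many
phenotypes should correct accordingly.

## Path analysis

For a system of SNP $g$, network-perturbation mediators $y_j$
(winter−summer differences of property summaries, computed only for hosts
present in both seasons) and end-point phenotype $z$, mediators are
screened by the two-sided significance of their genotype correlation at
the 10% level. Path coefficients are the standardized multiple-regression
weights of $z$ on $(g, y_j)$, obtained from the normal equations on the
correlation matrix. This guarantees, exactly,

$$r_{gz} = P_{z\leftarrow g} + \sum_j P_{z\leftarrow y_j}\, r_{gy_j},
\qquad R^2 = \mathbf{b}^\top R\, \mathbf{b}, \qquad
P_{z\leftarrow e} = \sqrt{1-R^2}.$$

A design choice deserves a note. The single-mediator presentation of this
decomposition elsewhere sets $P_{z\leftarrow y} = r_{yz}$ (the
network-to-phenotype link treated as one direct path). When $g$ and $y$
are correlated, that convention is incompatible with $R^2$ equalling the
squared multiple correlation — Wright's tracing rules give
$r_{yz} = P_{z\leftarrow y} + P_{z\leftarrow g} r_{gy}$ instead. The
package therefore uses the regression convention by default, which
satisfies both the decomposition identity and the $R^2$ identity to
machine precision, and offers the alternative via
`decomposePaths(..., yzAsDirect = TRUE)`.

Genotype–phenotype correlations can be computed either as dose-coded
Pearson correlations (default) or by a mutual-information estimator:
$I(g;y)$ from class-conditional Gaussian entropies (log-variances debiased
by their exact digamma expectation so the null estimate is centered at
zero), mapped to the correlation scale by
$r = \mathrm{sign}(\mathrm{cov}(g,y))\sqrt{1-e^{-2I}}$. The original
mutual-information procedure is cited but not reproduced in the source
framework; this estimator is the package's documented stand-in.

# The synthetic cohort generator

`simulateCohort()` emulates the sampling design the framework targets:
127 hosts, eight interacting microbes, biallelic SNPs in Hardy–Weinberg
proportions with allele frequencies uniform on (0.2, 0.5), and one causal
SNP whose additive effect on log-abundance is scaled so that its realized
genetic variance over the total phenotypic variance of an affected
microbe's log-abundance equals a draw from the effect-size scheme: big
(0.10–0.20), moderate (0.05–0.10) or small (0.01–0.05). Abundance
baselines span three orders of magnitude (as genus-level data do) and
residual variation is independent log-normal noise with SD 0.5 log units.

The mapping from "a QTL affects abundance" to "a QTL affects an
interaction" is not specified anywhere and is the largest inferential gap
in this design; the package's conventions are:

* **Mutualism scenario** — microbes 1–4 form a cooperating guild and all
  receive the same additive genotype effect. The network phenotype is the
  per-host *median* of $\log Z_{mu}$ over the guild's six pairs (median,
  not mean, because $\log Z_{mu}$ has a heavy upper tail near abundance
  ties).
* **Aggression scenario** — the dominant and subordinate microbes of the
  focal pair receive opposite-signed effects, modulating their abundance
  ratio; the network phenotype is the per-host $\log Z_{ag}$ of that pair.

The traditional (abundance-GWAS) comparator scans the log-abundance of an
affected microbe. Both arms use the same data, the same likelihood-ratio
scan, and their own 200-permutation genome-wide thresholds at
$\alpha = 0.05$ over 100 SNPs (both counts are package defaults; neither
is prescribed).

**What the generator does not emulate:** 16S sequencing noise and
compositional closure, phylogenetic correlation between taxa, kinship
structure among hosts, season-by-genotype interactions, and linkage
disequilibrium between SNPs (SNPs are simulated independently). Passing
tests on this generator therefore demonstrate the statistical machinery,
not robustness to those real-data complications.

## What the power study can and cannot reproduce

With these conventions, the interaction scan consistently dominates the
abundance scan for small effects, big-effect interaction QTLs are detected
essentially always, and false-positive rates at the genome-wide threshold
are tiny (the acceptance script recomputes this). The *absolute*
small-effect powers reported for the original study design, however, are
not attainable under a genome-wide max-LRT threshold at $n = 127$: a
phenotype carrying 1–5% genetic variance has a likelihood-ratio
noncentrality of about 1.3–6.7, far below a $\sim$15-unit genome-wide
threshold, which caps traditional-scan power near 0.05; a 0.7-level
interaction-scan power would require the scanned property to inherit
roughly four times more genetic variance than pair-level coupling
produces. The corresponding acceptance checks assert the published
benchmark levels regardless and are expected to fail under these study
conditions; the package reports what the simulation actually yields.

## Problem sizes and reproducibility

Default test and acceptance runs use 200 replicates × 100 SNPs × 200
permutations for the power study (a deliberate reduced-scale setting of
the 1000-replicate design; standard errors are reported alongside every
power estimate), 2000 simulations for the null-distribution check of the
LRT, 50 random graphs for the centrality oracle, and $10^4$ random pairs
for the descriptor algebra. Every randomized stage takes an explicit seed;
sub-seeds are derived deterministically from the master seed, so cohorts,
scans, thresholds and power tables are bit-for-bit reproducible.

# A worked example

```{r example, eval = FALSE}
cfg <- simConfig(scheme = "big", scenario = "aggression",
                 replicates = 50, nPerm = 200, seed = 7)
sim <- simulateCohort(cfg, seed = 42)
scan <- scanQTL(sim$networkPhenotype, sim$genotypes,
                nPerm = 200, alpha = 0.05, seed = 7,
                phenotypeName = "log Z_ag (dominant pair)")
scan
subset(scanTable(scan), significant)
```

The scan table reports, per SNP, the three genotype-class means, the
pooled ML variance, the LRT, the number of hosts used, and whether the
SNP clears the genome-wide permutation threshold.

# Known limitations

* Antagonism-based results depend on the `anForm` switch (see above).
* The edge-significance permutation scheme, hub cutoff, phase-segmentation
  rule, disconnected-graph conventions and interaction-coupling scenarios
  are documented conventions, not reproductions of unpublished choices.
* Covariate correction is fixed-effects only by default; population
  structure beyond a supplied relatedness matrix is out of scope.
* Automatic selection among nested growth laws is approximate at small
  sample sizes (see the growth section).
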