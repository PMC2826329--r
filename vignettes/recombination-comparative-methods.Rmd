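---
title: "Methods: comparative analysis of plant recombination rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of plant recombination rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `recombevol`, the assumptions they
make, the tunable parameters and the numerical and design choices that were
genuinely open, so that a user can judge what a passing test suite does and
does not establish.

## Genome-wide recombination rates

The genome-wide recombination rate of a species is its total genetic map
length (cM) divided by its physical genome size (Mb). Published maps
underestimate the true map length — terminal markers rarely reach the
telomeres and marker densities differ between studies — so
`correct_map_length()` applies, by default, the additive correction:
with per-chromosome lengths $L_c$ and marker counts $m_c$, the mean
inter-marker spacing is $s = \sum L_c / \sum (m_c - 1)$ and the corrected
length is $\sum L_c + 2sC$ over $C$ chromosomes. The multiplicative
Chakravarti correction $\sum L_c (m_c+1)/(m_c-1)$ is available as an
alternative; the two give different totals, which is why the method used is
recorded in the output. Genome sizes given as haploid C-values are converted
at 1 pg = 978 Mb, the standard equivalence.

Inclusion filters: maps covering less than 60% of the genome and
heterozygosities estimated from fewer than five SSR loci are excluded, with
a per-record reason in the exclusion log. The coverage filter is applied
before correction, since the correction needs the retained per-chromosome
data. Rates are analysed on the natural-log scale; the log base is a
convention, and all fitted coefficients in this package are natural-log
units of cM/Mb.

Domesticated species can be pooled with their wild relatives after
`domestication_check()`, a paired Wilcoxon signed-rank test on log rates
(pooling recommended at p > 0.05). A paired nonparametric comparison is a
design choice: several chi-square-distributed constructions exist for the
same question, and they are not equivalent; the signed-rank test was chosen
because it makes the fewest distributional assumptions at the small number
of pairs typical here. When every paired difference is exactly zero the test
degenerates and p = 1 is reported directly.

## Tree handling and age calibration

Trees are `ape::phylo` objects. `bladj_calibrate()` assigns ages to undated
nodes by even interpolation: each maximal chain of undated nodes between a
dated ancestor and its *nearest* dated descendant (fewest intervening
undated nodes) receives evenly spaced ages. When several dated descendants
tie for nearest, the chain descends through the child subtree containing the
lexicographically smallest tip label. This tie-break is a documented
convention of this package — reference implementations do not specify
theirs — chosen because it is deterministic and independent of input order.
Chains are resolved in preorder, and interpolated nodes become dated for all
later chains, so re-running the calibration with the same constraints is a
no-op. Ages are in Myr; branch lengths are always recomputed from ages and
never stored independently after calibration.

The phylogenetic covariance is $V_{ij}$ = depth of the MRCA of tips $i, j$;
the correlation matrix used by the regressions is $R = V / \text{depth}$,
which requires an ultrametric tree. Ultrametricity is checked at a relative
tolerance of $10^{-6}$ on root-to-tip depths: calibrated trees are
ultrametric by construction and the tolerance only absorbs floating-point
rounding. Non-ultrametric input is rejected rather than silently
normalized, because silently rescaling $V$ would change the model.

## Phylogenetic signal

Independent contrasts follow Felsenstein's pruning algorithm; polytomies are
resolved on the fly into left-deep bifurcations with zero-length internal
branches, children ordered by their smallest subtree tip label. This
resolution leaves $V$ exactly unchanged and makes the contrast count
well-defined ($n-1$ for $n$ tips).

The "variance of the contrasts" is the mean of the squared standardized
contrasts without centering, $\sum c_k^2/(n-1)$. This definition is the one
that satisfies the algebraic identity
$\sum c_k^2 = (x-\hat a\mathbf 1)^\top V^{-1}(x-\hat a\mathbf 1)$
with $\hat a$ the GLS phylogenetic mean, which ties the contrast machinery
to the matrix form of Blomberg's $K$ and is verified to $10^{-8}$ in the
test suite. $K$ itself is implemented twice — the explicit matrix formula
and an $O(n)$ contrast route — and the two agree to $10^{-10}$.

The permutation test reshuffles trait values across tips. Significance at
$\alpha = 0.05$ follows the rule that the observed contrast variance must be
lower than 95% of the null values; a one-tailed Monte-Carlo p-value with the
plus-one correction $(1 + \#\{\text{null} \le \text{obs}\})/(1 + B)$ is
reported alongside, so p is never exactly 0. Two p-values are reported: one
from the contrast-variance ranking and one from the ranking of $K$ itself.
The two orderings coincide in direction but not necessarily in tail counts,
and which of them a given reference analysis used is usually not stated; we
expose both. An exact mode enumerates all $n!$ assignments for $n \le 8$.
The null summary printed is the mean of the null variances ("expected by
chance").

## The three comparative models

`fit_rate_models()` fits, on the same rate table: an uncorrected Gaussian
model of log rate on He and life-form (baseline: trees); the same design
with the phylogenetic correlation matrix; and a third model in which conifer
trees are split from angiosperm trees into their own level. Column order is
fixed (intercept, He, herb, shrub, conifer tree) and a level absent from the
data is dropped with a warning rather than an error, so degenerate synthetic
inputs still fit.

For a Gaussian identity-link model with a *fixed* working correlation the
generalized estimating equations reduce to generalized least squares, so the
fit is a single closed-form step — no working-correlation iteration. With
the identity matrix the fit reproduces OLS to $10^{-10}$, which is both a
unit test and the reason model 1 and models 2–3 are directly comparable.

Degrees of freedom are $n - p$. GEE software often uses a different
(phylogenetically discounted) df heuristic, so p-values — not estimates —
from such software can differ on identical data; any comparison of p-values
across implementations should keep this in mind. Fitted per-life-form means
are intercept + level coefficient, with the delta-method SE
$\sqrt{\operatorname{var}(b_0) + \operatorname{var}(b_l) + 2\operatorname{cov}(b_0,b_l)}$.
Kruskal–Wallis comparisons use the tie-corrected $H$ with the chi-square
approximation; the approximation is good in the significance tail but can be
off by ~0.1 in the mid-range at very small group sizes, as the exact
enumeration test documents.

## Within-gene estimation

From a phased haplotype alignment, columns with gaps or ambiguity codes are
discarded ("indels"), as are columns with more than two states; diversity
($\theta_\pi = \sum 2p(1-p)\frac{n}{n-1}/L$, $\theta_W = S/(a_n L)$) is
computed on all biallelic gap-free columns, while $R_m$ and $\rho$ use only
parsimony-informative columns (minor allele count $\ge 2$). The major
allele is coded 0, ties broken by first occurrence — this affects nothing
downstream and is recorded only for reproducibility. Genes enter the survey
when $L \ge 800$ bp, $S \ge 10$ and $n > 20$ chromosomes (strictly).

$R_m$ is the Hudson–Kaplan bound: incompatible site pairs (all four gametes
observed) define open intervals; intervals containing another incompatible
interval are removed and the rest greedily selected left to right.
Recombination events live strictly between sites, so intervals sharing an
endpoint count as disjoint. The greedy count equals the exhaustive
minimum-breakpoint solution (verified against a brute-force oracle on 500
random matrices).

$\hat\rho$ is a pairwise composite-likelihood estimate in the spirit of the
LDhat implementation of Hudson's method. A Monte-Carlo two-locus table
(compiled code, $10^4$ replicates per grid point by default, grid
$\{0, 0.5, 1, 2, 5, 10, 20, 50, 100\}$) stores
$P(\text{configuration} \mid \rho, n)$ conditional on both loci
segregating, folded over allele relabelling and locus exchange. Per-pair
rates scale with physical distance, $\rho_{ij} = \hat\rho\, d_{ij}/d_{total}$
(column indices are used if no physical positions are available; the genes
this targets are contiguous amplicons). Interpolation is linear in
$\log\rho$ between positive grid points and linear in $\rho$ below the first
positive point; configurations never seen in the table are floored at
$1/(\text{reps}+1)$ so the composite log-likelihood stays finite. The
maximizer is found on a deterministic candidate grid (0 plus 60 log-spaced
points up to twice the table maximum), ties resolved toward the smaller
value — perfect linkage disequilibrium therefore yields the boundary
estimate 0. The estimate is per gene, not per bp, and the
$\hat\rho/\hat\theta$ ratio uses the per-gene Watterson estimator computed
from all segregating sites; which $\theta$ enters such ratios is a
convention that published analyses rarely state, so it is fixed and
documented here.

## The synthetic-data module

The generators define the conditions under which the pipeline is validated;
every one is a pure function of (parameters, seed).

* `sim_yule_tree()`: pure-birth trees with an Exp($n\lambda$) tail after the
  last split, so the expected depth is $\sum_{k=2}^{n} 1/(k\lambda)$.
* `sim_bm()`: Brownian increments per branch; the bivariate mode takes a
  $2\times2$ per-Myr covariance.
* `sim_life_forms()`: a symmetric continuous-time Markov switch (uniform
  stationary distribution), plus clade painting for taxa that are coherent
  clades in reality — conifers are emulated this way, as a painted clade of
  roughly 10% of tips.
* `sim_species_table()`: He is a logistic transform of a Brownian trait
  scaled to [0.3, 0.9] — a deliberately arbitrary but realistic SSR range;
  log rate is `intercept + slope_He * He + group effect + Brownian
  deviation`. Defaults are the generating values used throughout the tests:
  intercept −1.5, slope 0.8, herb −0.9, shrub −0.7, conifer −1.1, matching
  the magnitudes such comparative analyses report for these quantities. Map
  lengths, marker counts and genome sizes (lognormal, conifers drawn ~20×
  larger) are back-solved so that `build_rate_table()` returns the latent
  log rate to machine precision — the round trip is an exact construction
  contract, not an approximation.
* `sim_coalescent()`: an ancestral-recombination-graph simulation;
  coalescence at rate $k(k-1)/2$, recombination at rate $\rho/2$ per unit of
  ancestral span (material outside ancestral segments is not tracked, the
  standard ms economy), infinite-sites mutations at $\theta/2$ per unit
  branch length on segregating material. Positions on the unit interval are
  mapped to distinct integer bp in $1..L$, collisions resampled ($L$ is
  always much larger than the expected $S$ at the scales used). The output
  distribution of $S$ is cross-checked against an independent
  community-standard coalescent simulator in the test suite
  (Kolmogorov–Smirnov), and against the Watterson closed form.

What the generators do *not* emulate: selection, demography, gene
conversion, sequencing error, alignment error, missing data patterns, and
non-Brownian trait evolution. Passing tests therefore demonstrate that the
estimators recover truth under the neutral, correctly specified conditions
they assume — they say nothing about robustness to model violations in real
compilations.

## Problem sizes and numerical choices

The validation suite uses the sizes at which the statistical properties are
informative yet the whole suite stays interactive: 200 random trees for the
contrast/GLS identity; 200 Brownian replicates on 50-tip trees and 1,000
white-noise datasets (199 reshuffles each) for the size of the permutation
test; 300 end-to-end replicates at 200 tips for coverage of the GLS
intervals; 500 random matrices for the $R_m$ oracle; 2,000 coalescent
replicates for the Watterson check; and 200 replicates per true
$\rho \in \{0, 5, 20, 50\}$ (n = 30, $\theta = 10$) for the monotonicity of
the composite-likelihood estimator, sharing one cached two-locus table.
The acceptance script runs the same machinery at moderately smaller
replicate counts and reports point summaries.

Known limitations: the two-locus table is Monte-Carlo, so $\hat\rho$
inherits table noise (the floor on unseen configurations biases very sparse
genes toward the interior of the grid); the GLS standard errors condition on
the tree being known without error; BLADJ interpolation is a convention,
not an estimate, and different tie-breaks give different (equally
defensible) calibrations; and K's permutation p-values are resolution-
limited by the number of reshuffles.
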