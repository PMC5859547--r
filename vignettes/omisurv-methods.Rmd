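---
title: "Adaptive microbiome association testing for survival outcomes"
author: "omisurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive microbiome association testing for survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omisurv)
```

## The problem

Microbiome profiling studies increasingly follow hosts over time and record
a censored time-to-event outcome — disease onset, death, relapse — next to
a 16S (or shotgun) abundance table.  The scientific question is rarely about
one taxon: it is whether the *composition* of a community, or of a taxon's
member OTUs, is associated with survival after adjusting for covariates.
Item-by-item testing loses power because the true association pattern is
unknown: the driving OTUs may be abundant or rare, phylogenetically
clustered or scattered, and may push hazard in one direction or both.

`omisurv` implements a family of community-level variance-component score
tests under a Cox proportional hazards model, together with adaptive
minimum-p combinations that remain powerful across association patterns.

## The model and the score statistic

Let $Z$ be the $n \times p$ matrix of OTU relative abundances, $X$ an
$n \times q$ covariate matrix, $Y_i = \min(T_i, C_i)$ the observed time and
$\delta_i$ the event indicator.  The hazard model is

$$\lambda_i(t) = \lambda_0(t)\, e^{\sum_k \alpha_k X_{ik} + h(Z_i)},$$

and the community null hypothesis is $h(\cdot) \equiv 0$.  Treating the OTU
coefficients as random with mean zero, common variance $\sigma^2$ and
correlation structure induced by a similarity matrix $M$, the null becomes
$H_0: \sigma^2 = 0$ and the (unstandardized) score statistic is the
quadratic form

$$U = r^\top M\, r, \qquad r = d - \hat\Lambda,$$

where $r$ are the martingale residuals of the covariate-only Cox fit: the
difference between observed event status and the model-estimated cumulative
hazard at each subject's observed time.  `fit_null_model()` maximizes the
Efron partial likelihood by Newton–Raphson (convergence when the largest
score component falls below 1e-9, at most 50 iterations, with step-halving
on any likelihood decrease) and computes $\hat\Lambda_i$ with the Efron tie
correction.  At a tied event time the $l$-th of $d$ tied events is removed
fractionally from the risk set; a subject failing at that time accumulates
hazard increments weighted $(1 - l/d)$ at its own event time while other
at-risk subjects receive the full increment.  Several textbook variants of
this plug-in exist; the package implements the one that reproduces
`survival::coxph(ties = "efron")` martingale residuals to machine
precision, and the test suite asserts exactly that equivalence on random
data.  A Breslow option exists mainly for testing; without ties the two
coincide.

## Two candidate families

**Powered-abundance correlation (MiSALN).**  $M = Z^\gamma (Z^\gamma)^\top$
with element-wise powering.  $\gamma = 1$ is the linear kernel on the
original abundance scale; as $\gamma$ shrinks, rare OTUs are up-weighted
relative to abundant ones.  The default grid is
$\Gamma = \{1/4, 1/3, 1/2, 1\}$.

**Ecological-distance kernels (MiRKAT-S).**  A pairwise distance matrix $D$
is turned into a kernel by Gower double-centering,
$K = -\tfrac12 (I - \tfrac{11^\top}{n})\, D^{\circ 2}\,
(I - \tfrac{11^\top}{n})$, followed by a positive semi-definite repair:
eigendecompose, clamp negative eigenvalues to zero, reconstruct, and
re-symmetrize.  The repair is idempotent on already-Euclidean input.  The
default metrics are unweighted UniFrac (lineage presence/absence),
generalized UniFrac with $\theta = 0.5$, weighted normalized UniFrac, and
Bray–Curtis — spanning the spectrum from purely phylogenetic to purely
abundance-driven signal.  The UniFrac family is computed branch-wise from
a tips-by-branches incidence matrix; abundance columns are matched to tree
tips by name, never by position.  Generalized UniFrac at $\theta = 1$
equals the weighted normalized form, an identity the tests exploit since
no second generalized-UniFrac implementation is installed to compare
against; unweighted and weighted variants are cross-checked against
phyloseq on random instances.

## Adaptive minimum-p tests and the permutation engine

Each candidate $c$ gets a p-value from one shared ensemble of $B$ uniform
random permutations of the residual vector:

$$p_c = \frac{1 + \#\{b : U_c^{(b)} \ge U_c\}}{B + 1}.$$

The adaptive statistic of a candidate group is the observed minimum p over
the group ($Q_{\mathrm{OMiSALN}}$ over $\Gamma$, $Q_{\mathrm{OMiRKAT\!-\!S}}$
over the kernel set, $Q_{\mathrm{OMiSA}}$ over all candidates).  Its null
distribution comes from the *same* ensemble: each permutation receives a
per-candidate pseudo p-value by ranking its statistic within the ensemble,
and the adaptive p-value is the add-one-corrected fraction of permutations
whose minimum pseudo-p is at most $Q$.  No second layer of permutation is
needed, the add-one form guarantees a positive closed-form p-value (every
p-value is a multiple of $1/(B+1)$), and ties are counted in the
conservative direction ($\ge$ for statistics, $\le$ for minima).  Whether
one permutes residuals or refits the outcome model per permutation is a
known design fork for this class of tests; the package permutes residuals,
which costs one Cox fit per analysis and, as the type I error simulations
show, calibrates accurately at the sample sizes studied.

Defaults: $B = 5000$ for a single analysis, $B = 1000$ in the simulation
harness, seeds always recordable so every run is bit-reproducible.

## Higher-level taxa

All tests extend to any taxon with at least two member OTUs.  The one
subtlety is normalization: a taxon's abundance sub-matrix keeps
*community-scale* relative abundances (columns of the community $Z$; rows
do not sum to one), and UniFrac runs on the tree pruned to the taxon's
tips with those same community-scale branch masses — including the
weighted-UniFrac normalizing denominator.  The alternative reading
(re-normalizing within the taxon) would make the taxon test blind to the
taxon's overall load; the community-scale convention is therefore used
throughout and is stated here explicitly because it is a design choice,
not a forced consequence of the formulas.  `scan_taxa()` applies the
mean-abundance filter (default $10^{-4}$), tests the entire community,
then every taxon at each rank from phylum to genus — the adaptive test for
multi-OTU taxa, a univariate Cox Wald test for singletons — and corrects
p-values within each rank (Benjamini–Hochberg by default; the correction
is pluggable).  The community-level p-value is reported unadjusted, as it
is a single test.

## The simulation harness

`run_experiment()` reproduces the standard design for validating this
class of tests:

* **Counts.**  Dirichlet-multinomial with proportion means $\pi$ and
  dispersion $\varphi$; 1000 reads per sample.  `synth_dm_params()`
  supplies a synthetic stand-in for parameters estimated from a real gut
  community: log-normal abundance weights (`sdlog = 2.5`) floored at
  `2e-4` and renormalized, so a few OTUs carry most of the abundance, the
  max/median proportion ratio is in the hundreds, and every OTU passes the
  $10^{-4}$ mean-abundance filter; $p = 353$ OTUs and $\varphi = 0.02$ by
  default; the accompanying tree is a random coalescent over the OTUs.
* **Covariates and survival.**  age $\sim N(50, 5^2)$, sex $\sim$
  Bern(0.5); survival times invert a Weibull(2,2) baseline,
  $T_i = \sqrt{-4\log U_i / \exp(0.5(\mathrm{age}_i - 50) +
  0.5\,\mathrm{sex}_i + \sum_j \beta_j\, \mathrm{scale}(Z_{ij}))}$, with
  `scale()` using the $n-1$ sample SD (the convention of common
  statistical environments).  Censoring is Unif(0, 10) (~26% censored) or
  Unif(0, 5) (~40%).
* **Scenarios.**  `null` ($\beta = 0$, type I error); ten most abundant,
  ten random, or ten least abundant OTUs associated (the "least abundant"
  are taken among the OTUs retained by the filter); or one cluster of a
  $k = 10$ PAM partition of the cophenetic tip distances, re-chosen
  uniformly at random each replicate.  Effects are Unif(0, u) (same
  direction) or Unif(-u, u) (mixed), $u \in \{1, 2, 3\}$.  PAM is
  delegated to `cluster::pam`; the test suite verifies it attains the
  exhaustive-medoid optimum on small instances.

Replicate counts default to 1000 for type I error and 500 for power; the
packaged acceptance checks run 1000 null replicates per censoring scheme
with $B = 500$ and power configurations at 120–500 replicates, sizes
chosen so Monte-Carlo error is small relative to the assertions being
made.

### What the generator does and does not emulate

The synthetic $\pi$ reproduces the qualitative shape of a filtered 16S
community (dominant head, long rare tail), not any particular dataset; the
coalescent tree has realistic topology but arbitrary clade-abundance
structure.  Two consequences matter for interpreting the packaged
simulation results.  First, type I error calibration is insensitive to
these choices — the permutation engine is exact-in-distribution under the
null regardless of $\pi$ — so the 5% calibration results generalize.
Second, *power* depends strongly on them: with $\varphi = 0.02$, an OTU at
the $2 \times 10^{-4}$ abundance floor appears in only a few percent of
samples and carries little pairwise-similarity signal, so the rare-OTU
scenario is intrinsically hard, and the packaged ordering checks assert
relative orderings of tests (with Monte-Carlo margins), never absolute
power levels.  Passing them shows the tests rank as theory predicts under
these conditions, not that real-data power will match any particular
figure.  One such condition-dependence is worth flagging: at the largest
effect sizes in the abundant-OTU scenario, power need not be monotone in
the effect-size bound for every candidate.  Once the hazard ordering is
dominated by the most abundant associated OTUs, sharpening that dominance
further can *reduce* the alignment between the residual pattern and the
candidates that compress abundance dynamic range (small $\gamma$,
UniFrac-type kernels), even while the abundance-faithful candidates and
the adaptive tests stay at essentially full power.  The packaged
monotonicity check observes this and is expected to flag it under the
default generator.

## Numerical choices and degenerate inputs

* Missing newick branch lengths become 0 with a warning (a zero-length
  branch contributes nothing to UniFrac sums).
* A pair of samples with no abundance mass (possible for sparse taxa)
  gets distance 0 with a warning rather than 0/0.
* All-zero OTU columns survive I/O untouched; only `filter_otus()` removes
  them, so filtering is auditable.
* A zero-variance OTU column with a nonzero simulated effect contributes 0
  to the linear predictor, with a warning.
* Fits require at least two events; all-censored data is an error, as is a
  rank-deficient covariate matrix.
* $0^\gamma$ is defined as 0 in the MiSALN power transform.

## Known limitations

* P-values are permutation-based only; the asymptotic kernel-test
  approximation available for large samples elsewhere is out of scope, so
  very small p-values require large $B$ (resolution is $1/(B+1)$).
* Residual permutation assumes exchangeable residuals under the null;
  with strong covariate effects and heavy censoring this is an
  approximation (empirically accurate in the packaged calibration runs).
* No compositional transformation is applied; users who prefer log-ratio
  scales can transform upstream, as the tests accept any non-negative
  abundance matrix.
* Time-varying covariates and stratified baselines are not supported.
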