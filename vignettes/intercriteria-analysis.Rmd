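---
title: "InterCriteria analysis: model, thresholds, and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{InterCriteria analysis: model, thresholds, and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(InterCriteria)
```

## The model

InterCriteria analysis (ICrA) asks, for every pair of criteria evaluated
over a common set of objects, *how consistently do the two criteria order
the objects?* Its input is an index matrix: `m` objects in rows, `n`
criteria in columns, a real evaluation in every cell. For one pair of
criteria $(C_k, C_l)$, all $m(m-1)/2$ unordered object pairs are visited.
On each object pair the relation $R$ = "greater than" either holds or its
dual holds within each criterion; the pair is *concordant* when the same
relation holds in both criteria and *discordant* when they oppose. Two
counters accumulate these cases, $S^{\mu}_{k,l}$ and $S^{\nu}_{k,l}$, and
are normalized into the intuitionistic fuzzy pair

$$\mu_{C_k,C_l} = \frac{2\,S^{\mu}_{k,l}}{m(m-1)}, \qquad
  \nu_{C_k,C_l} = \frac{2\,S^{\nu}_{k,l}}{m(m-1)},$$

the *degrees of agreement and disagreement*, with
$0 \le \mu + \nu \le 1$. The residual $\pi = 1 - \mu - \nu$ is the
*degree of uncertainty*. The collected pairs form a symmetric
criteria-by-criteria index matrix with $\langle 1, 0\rangle$ on the
diagonal — this is what `runICrA()` returns.

Because only orderings enter the counters, $\mu$ and $\nu$ are invariant
under any strictly increasing transform of a column and under any
permutation of the objects. That is the property that lets ICrA compare
criteria living on incommensurable scales — docking scores in kcal/mol,
RMSDs in Å, $-\log K$ affinities — without normalization. On tie-free data
the degrees tie back to classical rank statistics:
$\mu - \nu$ equals Kendall's $\tau_a$, so $\mu = (1+\tau_a)/2$. Unlike a
correlation coefficient, however, the pair $\langle\mu, \nu\rangle$ keeps
disagreement and *uncertainty* apart rather than folding both into a
single number.

### Ties

An object pair where either criterion's two evaluations are equal (within
`epsilon`, default 0) carries no order information. The default
`tieMode = "unbiased"` counts such pairs in neither counter; they surface
as uncertainty $\pi$, preserving the intuitionistic interpretation. The
alternative `"mu_biased"` credits pairs tied in *both* criteria to
$S^\mu$ (agreement by shared indifference) and is available because some
ICrA implementations behave this way; the two modes coincide on tie-free
data. `epsilon` exists for noisy floating-point inputs and should remain
0 for exact data. The conservation identity
`sMu + sNu + sTie = m(m-1)/2` holds in every mode and is asserted in the
tests.

## Consonance classification and threshold schemes

Given thresholds $\alpha > \beta$, a pair of criteria is in

* **positive consonance** when $\mu \ge \alpha$ and $\nu \le \beta$,
* **negative consonance** when $\mu \le \beta$ and $\nu \ge \alpha$,
* **dissonance** otherwise,

and, under the *thirds* scale only, **uncertainty** when $\mu$, $\nu$ and
$\mu + \nu$ all fall below $\alpha$ — the corner of the intuitionistic
triangle where $\pi$ dominates. The *quarters* scale
($\alpha = 0.75, \beta = 0.25$, the conventional software default) keeps
the classical three classes; the *thirds* scale
($\alpha = 0.67 \approx 2/3$, $\beta = 0.33 \approx 1/3$) restores the
symmetry of the triangle while admitting the fourth class.

Two numerical choices deserve explanation:

* **Boundary convention.** The default is *inclusive*: $\mu = \alpha$
  qualifies, on both the $\mu$ and the $\nu$ condition. Published
  agreement tables are printed at two decimals, and only the inclusive
  convention makes a printed $\mu = 0.60$ count at $\alpha = 0.60$; a
  strict inequality presumably operated on unrounded values upstream.
  Making the $\nu$ condition inclusive too ($\nu \le \beta$) is what
  collapses the two-condition rule to the one-dimensional test
  $\mu \ge \alpha$ whenever $\beta = 1 - \alpha$ and $\nu = 1 - \mu$ —
  an equivalence the test suite asserts.
* **Threshold tolerance.** Comparisons against $\alpha$ and $\beta$ carry
  a tolerance of $10^{-9}$. When $\nu$ is completed as $1 - \mu$ in
  floating point, $1 - 0.70$ exceeds $0.30$ by one ulp; without the
  tolerance a boundary pair would be misclassified by representation
  noise. $10^{-9}$ is far below the two-decimal resolution of any
  realistic threshold and far above accumulated rounding error.

When a table reports only $\mu$, classification takes $\nu = 1 - \mu$
(`ifPairs(mu)`). This is exact whenever $\alpha + \beta = 1$ (the only
regime the sweep explores) and is the worst case consistent with
$\mu + \nu \le 1$ otherwise; reports relying on it should state the
assumption.

### Threshold sweeps

`thresholdSweep()` varies $\alpha$ keeping $\alpha + \beta = 1$, over the
default grid $\{0.75, 0.70, 0.67, 0.65, 0.60\}$, and produces the two
standing summaries: pairs in positive consonance per evaluation block
(how threshold-sensitive each block is) and blocks in positive consonance
per pair (how consistently comparable two criteria are). Per block the
counts are provably non-increasing in $\alpha$. Alphas at or below 0.5
are rejected since they would violate $\alpha > \beta$.

```{r sweep}
sw <- thresholdSweep(table1Fixture())
perBlockCounts(sw)
perPairCounts(sw)["Alpha HB-London dG", ]
```

The packaged `table1Fixture()` holds the published degrees of agreement
for the five MOE docking scoring functions (plus the experimental
$-\log K_d$/$-\log K_i$ column) across four docking outputs over 195
protein–ligand complexes. The raw docking evaluations behind it are not
public, so the table is a given input here, never a recomputation target.
The sweep above regenerates the published per-block counts exactly, and
the `Alpha HB-London dG` row shows that pair positive in all four docking
outputs from $\alpha = 0.67$ downward — the study's headline result.

## Correlation juxtaposition

`juxtapose()` reports the Pearson coefficient $r$ (via `stats::cor`) next
to $\mu$ for every pair and block, with no combined score: the two
measures answer different questions ($r$ is invariant only under positive
affine maps, $\mu$ under all strictly increasing maps), and the interest
lies in where they diverge. Constant columns are an error rather than an
`NA`, and missing data are rejected upstream, keeping both analyses on
identical inputs.

## The synthetic generator

Raw docking outputs being unavailable, `generateBlock()` provides
evaluation matrices with *controllable pairwise concordance*: latent
vectors are drawn from a zero-mean Gaussian with correlation matrix
`targetRho`, then pushed through strictly increasing, block-appropriate
marginal transforms — shifted negative score-like values for score
blocks (lower = better), lognormal Å-scale values for RMSD blocks,
affinity-like values around 6 pK units for an experimental column. The
Gaussian copula was chosen because its rank concordance has a closed
form, $\tau = \frac{2}{\pi}\arcsin\rho$, so the expected agreement degree
is $\mu = \frac12 + \frac{\arcsin\rho}{\pi}$ and `rhoForTargetMu()`
inverts it exactly. Continuous marginals make ties a null event, so the
identity holds without tie corrections. Defaults mirror the study
conditions: 195 objects per block, five scoring-function columns plus one
experimental column, four block kinds.

What the generator does *not* emulate: the structural content of the
benchmark (protein clusters, chemotypes), any particular joint dependence
among five real scoring functions (only marginal pairwise concordance is
controlled), heteroscedastic or heavy-tailed score noise, and tied
evaluations. Tests passing on synthetic blocks therefore validate the
counting, classification and calibration machinery — not any claim about
real docking data.

Degenerate and edge inputs are handled explicitly: `targetRho` entries of
exactly $\pm 1$ are realized by copying (or negating) latent columns, so
comonotone pairs reach $\mu = 1$ exactly rather than approximately;
non-PSD matrices are rejected with the offending eigenvalue named; and
`calibrateRho()`, which assembles a full matrix from 15 independent
pairwise targets, projects to the nearest correlation matrix
(`Matrix::nearPD`) when the assembly is not PSD and reports achieved
versus requested $\mu$ for every pair.

```{r synth}
rho <- rhoForTargetMu(0.84)
spec <- syntheticSpec(m = 1000, criteriaLabels = c("X", "Y"),
                      targetRho = matrix(c(1, rho, rho, 1), 2), seed = 42)
agreement(runICrA(generateBlock(spec)))["X", "Y"]
```

## Problem sizes and verification strategy

The test suite checks the implementation against an independently written
brute-force double loop on random 10×4 matrices, against
`stats::cor(method = "kendall")` on tie-free columns (agreement to
$10^{-12}$), and against the published count tables (exactly). Simulation
sizes were chosen where the analytic error bounds make the assertions
sharp at desk scale: $m = 200$ for the independence check (3 standard
errors of $\tau$), $m = 500$–$1000$ for concordance recovery within 0.02,
and 20 seeds of paired $m = 195$ blocks for the end-to-end emulation of
the published sweep (counts within ±1 in at least 90% of cells). The
full suite runs in well under a minute on one CPU.

## Known limitations

* Only the two-dimensional index matrix is supported — no
  multi-dimensional index-matrix algebra.
* Only the unbiased and mu-biased tie variants are implemented; other
  weighting variants found in ICrA software are out of scope.
* Threshold selection is the user's: no algorithmic choice of
  $(\alpha, \beta)$ is attempted.
* The triangle viewer is export-only (`triangleCoordinates()`); plotting
  is left to the caller.
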