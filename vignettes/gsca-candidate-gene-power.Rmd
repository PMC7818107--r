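---
title: "Gene-level association by structured components: model, simulation design, and power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level association by structured components: model, simulation design, and power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscapower)
```

## The problem

Candidate-gene studies of quantitative traits face an awkward trade-off.
Testing every SNP against every phenotype multiplies the number of tests,
and the multiple-testing correction that keeps false positives in check
also destroys power in the small samples typical of deeply phenotyped
clinical cohorts (a few hundred individuals, as in studies of
developmental language disorder). A gene-level test that pools the modest
signals of several SNPs against a composite of several correlated
phenotypes can recover that power, because the multiplicity it must pay
for is the number of *genes*, not the number of SNP-by-phenotype pairs.

`gscapower` implements such a test — generalized structured component
analysis (GSCA) restricted to the formative genes-to-pathway design — next
to the conventional per-SNP regression comparator, and a Monte-Carlo
engine that estimates the power and false-positive rate of both under
controlled synthetic data.

## The model

Let $X_1, \dots, X_J$ be standardized SNP dosages mapped to $G$ genes and
$X_{J+1}, \dots, X_K$ standardized phenotypes. Every latent component is an
exact weighted sum of its block,
$$\gamma_l = \sum_{i \in S_l} w_{il} X_i,$$
held at unit sample variance, where $S_l$ indexes the block of latent $l$:
one component per gene, and one *clinical pathway* component over the
phenotypes. The structural part links components through path coefficients
$b$:
$$\gamma_{\text{pathway}} = \sum_{g} b_g \gamma_g + \epsilon .$$

Estimation minimizes the total squared structural residual
$$\phi(W, B) = \sum_{\text{sinks}} \big\lVert \gamma_{\text{sink}} -
  \textstyle\sum_{\text{sources}} b \, \gamma_{\text{source}} \big\rVert^2$$
subject to $\operatorname{var}(\gamma_l) = 1$ for every component. There is
no reflective measurement model: indicators are formative only, and
cross-loadings, multiple pathway latents and fit indices are deliberately
out of scope.

### The alternating least squares scheme

`fit_gsca()` alternates two exact conditional solves:

1. **Paths.** Given all weights, each sink component is regressed on its
   source components by ordinary least squares.
2. **Weights.** Given all paths and the other blocks, the criterion as a
   function of one block's weight vector $w$ is
   $b^2\, w^\top C_{ll} w - 2\, w^\top c + \text{const}$ under the
   constraint $w^\top C_{ll} w = 1$ (with $C$ the sample covariance of the
   standardized indicators), so the constrained minimizer is
   $w \propto C_{ll}^{-1} c$, rescaled to unit component variance, with the
   sign fixed so $w^\top c \ge 0$.

Because every step is an exact minimization given the other parameters,
the criterion is non-increasing across cycles — a property the test suite
asserts on a thousand randomly drawn models rather than takes on faith. A
common alternative scheme solves the weight update without the variance
constraint and renormalizes afterwards; that variant has the same fixed
points but no monotonicity guarantee, which is why the constrained solve
is used here.

Everything runs on the $K \times K$ covariance matrix rather than the
$N \times K$ data, which makes each ALS cycle independent of the sample
size and keeps the permutation loop cheap.

Numerical choices:

* **Convergence** is declared when the relative criterion change falls
  below `tol` (default $10^{-5}$), with the denominator floored at
  $10^{-4}$ so near-perfect fits (criterion near zero) do not grind to
  `max_iter` (default 200) over meaningless relative changes. Hitting
  `max_iter` returns the best iterate with a warning.
* **Starts.** ALS can stop in local minima, so `n_starts` (default 5) runs
  are fitted: equal weights first, standard-normal draws after, best final
  criterion wins. For a single gene-to-pathway path the problem is a
  canonical-correlation problem whose equal-weight start essentially
  always reaches the global optimum, which is why the simulation engine
  uses one start (see below).
* **Signs.** Weight vectors are flipped so each component's weight sum is
  non-negative. Only $|b|$ is stable under this convention and only $|b|$
  is compared across fits.
* **Degenerate blocks.** Exactly collinear indicators within a block make
  the unit-variance constraint unsatisfiable in some directions; the fit
  refuses them and points to `filter_snps()`, which always prunes
  perfectly correlated SNP pairs.

For a model with a single gene and the pathway, the fitted $|b|$ equals
the first canonical correlation between the two blocks; the tests exploit
this as an independent oracle (via the canonical-correlation
eigenproblem), and on tiny models the final criterion is checked against a
derivative-free optimizer over the weight parameterization.

### Permutation inference

The null hypothesis of no gene-phenotype association leaves the rows of
the phenotype block exchangeable against the genotype blocks.
`permutation_test()` therefore permutes the phenotype-block rows jointly
(preserving within-block correlation on both sides), refits, and records
each $|b^*|$. P-values use the add-one estimator
$$p = \frac{1 + \#\{|b^*| \ge |\hat b|\}}{1 + n_{\text{perm}}},$$
a two-sided test bounded below by $1/(n_{\text{perm}}+1)$. The per-path
significance level divides the family alpha by the number of structural
paths — $0.05/4 = 0.0125$ in a four-gene model — never by the number of
SNPs or phenotypes; that milder correction is the method's selling point.

The permutation refits reuse the observed fit's settings (tolerance,
iteration cap, number of starts). This matters: giving the observed
statistic a more thorough optimization than the permuted ones would
inflate it relative to its permutation distribution and bias the test
anticonservatively. For the same reason the simulation engine fits both
with a single equal-weight start.

## The comparator

`regress_all()` fits the conventional model: every phenotype on every SNP
dosage (additive coding), slope, $t$ statistic with $N-2$ degrees of
freedom, two-sided p. `adjust_pvalues()` wraps `stats::p.adjust`
(Bonferroni, Holm, BH, BY) and adds Sidak. The trial-level rule
`any_significant()` adjusts jointly across all SNP-by-phenotype tests and
declares a positive if any adjusted p-value clears the family alpha —
exactly the decision rule whose power the simulation compares against the
gene-level test.

## The synthetic-data generator

The generator reproduces the statistical structure the analysis assumes,
directly as a correlation matrix — no haplotype or coalescent model:

* **LD blocks.** One correlation block per gene. In `random` mode,
  off-diagonal magnitudes are drawn from a binned frequency distribution —
  70% in $[0, 0.2)$, 25% in $[0.2, 0.5)$, 5% in $[0.5, 0.8)$, uniform
  within bin, random sign — a sparse-LD look with occasional strong pairs.
  In `template` mode a principal submatrix of a supplied empirical
  correlation matrix is sampled, inheriting a real panel's LD. Genes are
  mutually uncorrelated.
* **Phenotypes.** Three phenotypes with a common intercorrelation
  `pheno_corr` (0, 0.25 and 0.5 in the default grid).
* **Planted effects.** `n_effect_snps` SNPs — drawn from the first gene by
  default (effects clustered within a gene), or from all genes with
  `spread_across_genes` — each receive correlation `effect_r` with one
  uniformly chosen phenotype (`one_phenotype_each`; an `all_phenotypes`
  switch exists). Canonical effect sizes are $r = 0.1, 0.15, 0.2$. Both
  the LD pattern and the effect allocation are re-drawn in every
  Monte-Carlo replicate, so power estimates average over patterns rather
  than condition on one.

### Positive-definiteness repair

A matrix assembled from random off-diagonals need not be positive
semi-definite. `nearest_pd()` repairs it by alternating projections —
eigenvalue clipping, then unit-diagonal restoration — the standard
approach for nearest-correlation problems (the test suite cross-checks it
against the independent Higham implementation in the Matrix package).

One consequence deserves emphasis. Random-sign LD blocks of realistic size
are usually *strongly* non-PSD, and projecting them onto the boundary of
the PSD cone (eigenvalues clipped at essentially zero) produces a
near-singular target. Sampling from such a target makes the phenotypes
near-exact linear combinations of the SNPs whenever effects mix the
blocks — the in-sample canonical correlation saturates at 1 regardless of
the planted effect size, and "power" becomes an artifact of matrix rank
rather than of association strength. `sample_dataset()` therefore repairs
targets with an eigenvalue floor of 0.05 (`eig_floor`), keeping them
well-conditioned; the floor is a property of the generator, not of
`nearest_pd()`, whose default still projects onto the cone. The repair
moves planted entries — typically by 0.03–0.10 under the default magnitude
distribution — and a warning reports any drift beyond 0.02 (the replicate
engines collect these and report the maximum once per scenario). Planted
effect sizes after repair are therefore nominal labels for scenario
conditions, not exact population correlations; since the repair shrinks
effects more often than it inflates them, power estimates err on the
conservative side.

SNPs are continuous multivariate-normal columns by default, matching a
simulation defined directly on correlations; Hardy-Weinberg discretization
to 0/1/2 dosages from supplied allele frequencies is available behind
`discretize` for users who want genotype-shaped data.

## The power engine

`run_scenario_gsca()` and `run_scenario_univariate()` replicate a scenario
(draw target, sample data, analyze, decide), and `run_grid()` sweeps
scenario lists with per-row checkpointing. Decisions:

* GSCA replicate: positive iff a causal gene's path clears the per-path
  alpha (`family_alpha` / number of paths; 0.05 for single-gene
  scenarios). Under a null scenario any path counts, so the estimate is
  the false-positive rate.
* Comparator replicate: positive iff any BH-adjusted p-value over all
  SNP-by-phenotype tests clears `family_alpha`.
* Replication defaults follow the study design: 100 replicates for the
  permutation-tested fit, 1000 for the cheap comparator; 200 permutations
  inside grid replicates (1000 for standalone analyses).
* Reproducibility: each scenario seeds a deterministic stream of
  per-replicate seeds, so any row can be recomputed in isolation and
  reruns are bit-identical.

`scenario_grid()` enumerates the full design: total SNPs $\{20, 40\}$
$\times$ effect size $\{0.1, 0.15, 0.2\}$ $\times$ phenotype correlation
$\{0, 0.25, 0.5\}$ $\times$ effect SNPs $\{0, 5, 10\}$ — 54 combinations
of the five varied factors, at the headline sample size $N = 100$ (power
saturates well before $N = 500$ in all conditions, so the grid
concentrates on the regime where the methods differ).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run, among smaller unit checks:
a null calibration of the gene test (20 SNPs, $\rho = 0.5$, $N = 100$;
100 replicates $\times$ 200 permutations), the matching power scenario
(5 of 20 SNPs at $r = 0.2$), the comparator's null calibration
(1000 replicates, BH over 60 tests), ALS monotonicity over 1000 random
small models, and empirical-correlation convergence at $n = 10^5$. The
`analysis/` drivers run a reduced grid slice (30 replicates $\times$ 100
permutations per GSCA row) chosen to finish in minutes; replicate counts
are arguments, and the full-replication grid is a matter of patience, not
of different code.

## What the generator does and does not emulate

Passing tests on synthetic data show that the estimator, the permutation
test and the decision rules behave correctly when the data are
multivariate normal with the assumed block structure. Real genotype data
differ in ways the generator does not model: integer dosages with
MAF-dependent variance, LD decaying with physical distance, phenotypes
with skew and kurtosis, relatedness and population structure, and
missingness. The io module's filters (MAF threshold, greedy $r^2$ pruning
at 0.8, listwise deletion) address the first line of those concerns for
real tables, but no synthetic result here certifies robustness to, e.g.,
ancestry confounding — that is out of scope by design.

## Design choices where the design was open

* **LD pruning metric** for hard-called genotypes: squared correlation
  $r^2 \ge 0.8$ by default, with `ld_metric = "abs"` as a switch, since
  imputation-era pipelines state the $R^2$ form explicitly while
  hard-call descriptions often just say "LD $< 0.8$". Pruning is greedy,
  keep-first, in input column order — deterministic and documented.
* **MAF** is computed from dosages as mean/2 (folded) when no frequency
  table is supplied.
* **Missing data**: listwise deletion with a reported drop count;
  imputation is deliberately not offered as a default path.
* **Permutation scheme**: phenotype-block rows are permuted jointly; the
  alternative (permuting each phenotype independently) would break the
  phenotype correlation that the pathway component exists to exploit, and
  tests a different null.
* **Effect re-allocation per replicate** (rather than fixed per scenario)
  makes a scenario's power an average over effect placements, which is
  the quantity a study planner wants.
* **Single-start fits inside the engine**, for the exchangeability reason
  above; multi-start remains the default for one-off data analyses where
  the permutation refits inherit the same setting.

## Known limitations

Only single-sink structural designs (genes to one pathway) are supported;
latents may not be both source and sink, so chained or cross-loaded
structures are rejected at model construction. The permutation test refits
the full model per draw, which is exact but costly for many genes with
many permutations. Planted effects drift under PD repair as discussed
above. Component weights are not interpretable as per-SNP effect sizes —
they are the joint solution of a gene-level optimization — and only
$|b|$ with its permutation p-value should be reported.
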