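---
title: "Causal trait networks, yield interventions and ideotype optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal trait networks, yield interventions and ideotype optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ideonet)
```

## The problem

Crop yield decomposes into interacting component traits — branch and flower
counts, pod number and length, seed number and size — linked by development
and by competition for resources. Treating those links as a causal directed
acyclic graph (DAG) changes the answer to three practical questions:

1. *Which traits should a breeder change?* Modifying a trait propagates only
   to its DAG descendants; correlated but non-causal traits are unaffected,
   and compensatory pathways (more flowers, but shorter pods with fewer
   seeds) can buffer yield against changes that look promising in isolation.
2. *Which trait combinations define a better plant (an ideotype)?* Yield
   depends only on its direct parent traits, so optimisation can run in that
   smaller space — but it must respect physiological trade-offs such as the
   negative seed-number/seed-weight relationship, which cannot simply be
   selected away.
3. *How much of a trait's heritability and genetic association signal is its
   own?* Variation flowing in from heritable parent traits inflates
   broad-sense heritability and makes association scans flag loci that act
   on the parents (mediated pleiotropy). Conditioning on the parents via
   model residuals isolates the direct component.

`ideonet` implements this whole chain as testable, reusable functions, with
a synthetic-data module providing ground-truth panels shaped like a
glasshouse diversity panel (about a hundred varieties, a handful of
replicates each, a tiered trait hierarchy, missing cells).

## Structure learning

The trait table (after normalising transforms and imputation) is modelled as
a Gaussian Bayesian network: every node is a linear function of its parents
plus Gaussian noise. Structures are scored by BIC — each node contributes its
maximised Gaussian log-likelihood under ordinary least squares minus
$\tfrac{k}{2}\log n$ with $k$ counting that node's coefficients, intercept
and variance — and the score's additive decomposition over nodes makes local
search cheap: a single-edge move re-scores only the touched families, which
`ideonet` computes from a pre-accumulated cross-product matrix and memoises
per (node, parent-set).

`tabu_search()` climbs over single-edge additions, deletions and reversals
under constraints: a whitelist of links that must be present, a blacklist,
and a tier map that forbids edges running down the biological hierarchy. A
tabu list of the last 10 moves (with the usual aspiration exception) lets
the search step through score plateaus; it stops after 15 non-improving
moves. Both defaults are conventional for this search and exposed as
arguments. Orientation ties between score-equivalent edge directions are
broken toward the hierarchy direction, then lexicographically.

Two layers of resampling control overfitting, mirroring standard practice
for small panels:

* `bootstrap_arc_probabilities()` reruns the search on row resamples
  (500 replicates at reference scale) and reports each link's recovery
  frequency; whitelisted links have probability exactly 1 by construction.
* `average_across_folds()` splits plants into five folds — stratified by
  variety, so replicates of one variety never straddle folds — reruns the
  bootstrap per fold, and keeps links found consistently across folds. The
  shipped consensus rule requires probability ≥ 0.5 in a majority of folds;
  a pooled-mean-probability mode is available behind the `consensus` flag
  because "consistently across folds" admits both readings.

On the package's 8-node reference network (strong effects, noise sd 0.5,
500 plants), the consensus skeleton attains F1 near 1 against the
generating graph; the test suite asserts F1 ≥ 0.8 averaged over ten seeds
at 100 bootstrap replicates per fold, a deliberate desk-scale reduction of
the 500-replicate reference setting.

## Per-node Gaussian processes

Relationships between traits saturate, so each node is regressed on its DAG
parents with a Gaussian process under the automatic relevance determination
(ARD) kernel

$$K_{ij} = \alpha^2 \exp\!\Big(-\tfrac12 \sum_{k=1}^q
\big(\tfrac{x_{ik}-x_{jk}}{\rho_k}\big)^2\Big) + \delta_{ij}\,\sigma^2 ,$$

one length-scale per parent, so irrelevant parents are suppressed
automatically. Inputs and response are standardised to zero mean and unit
variance before fitting — necessary for fixed priors to be sensible across
traits measured in different units. Priors are half-normal(0, 1) on
$\alpha$ and $\sigma$ (stated as normal priors on scale parameters, which
must be folded onto the positive half-line to be proper) and
inverse-gamma(shape 5, scale 5) on each $\rho_k$; the shape–scale reading
follows the convention of the sampling platforms this model class is
usually fitted with, and is config-exposed. $\sigma$ is a single
homoscedastic noise scale per node model; the per-observation subscript in
the kernel above indexes the Kronecker delta, not distinct noise levels.

Hyperparameters are estimated by MAP-initialised gradient-based MCMC: a
static-metric Hamiltonian sampler with dual-averaging step-size adaptation,
run with 4 chains and 1000 warm-up plus 1000 sampling iterations by
default. Convergence is declared when split-$\hat R \le 1.05$ on every
hyperparameter; non-converged fits are returned flagged, with the policy
left to the caller. A deterministic multi-start MAP mode
(`gp_sampler_config("map")`) exists for pipelines and tests where full
posteriors are not needed; the test suite uses it throughout to stay fast,
and exercises the sampler itself on a small fixture.

Numerical choices: Cholesky factorisations add a jitter of $10^{-8}$ times
the mean diagonal, escalating tenfold up to $10^{-4}$ before failing;
predictive draws for distinct plants use marginal variances (plants are
independent backgrounds, so cross-plant predictive covariance is not
needed); the full predictive covariance is available from
`gp_posterior()` and is checked against the textbook formulae to $10^{-8}$
in the tests.

## Interventions

`do_intervene()` fixes one trait to each value of a grid spanning its
observed range (20 points by default; an explicit grid can be supplied),
uses every plant of the panel as an intervention background, and propagates
sampled predictions through the DAG in topological order: descendants are
drawn from their GPs, non-descendant parents keep their observed in-planta
values, and non-descendants are untouched. Draws are pooled over plants,
hyperparameter draws and any number of candidate networks (e.g. the five
per-fold models), and per-descendant decile curves are reported. The
default of 1000 pooled draws per grid point and network keeps the
Monte-Carlo error of the outer deciles below a few hundredths of a standard
deviation on the test fixtures.

Two analytic fixtures pin the semantics down: on a linear chain
$x \to y \to z$ with coefficients 2 and 3, the median $z$ curve at
$do(x{=}1)$ must sit at 6; on a compensation motif ($x$ raises one yield
parent and lowers the other equally) the median yield curve must stay flat
while each arm responds strongly.

## Ideotype proposals

The yield surrogate is the yield node's own GP on its direct parents.
Candidates are scored by Expected Improvement over the best observed plant,
$\mathrm{EI}(x) = \mathbb E[\max(f(x) - f(x^+), 0)]$, maximised by 50
Latin-hypercube starts refined with bounded quasi-Newton steps, always
inside the observed per-trait box. Batches of $q = 10$ ranked proposals use
the Constant Liar heuristic: each accepted proposal is appended to the
training set with its response set to the maximum observed yield, and the
predictive equations are refit with hyperparameters frozen at their
posterior medians (refitting hyperparameters per lie is expensive and not
part of the heuristic).

Two design choices deserve emphasis:

* **Lies are exact.** Pending lie rows enter the refit with negligible
  observation noise. Under the fitted noise level a lie leaves residual
  predictive uncertainty at its own location — and because the lie value is
  the incumbent maximum, it can even raise the local predictive mean — so
  batches collapse onto a single basin. Treating pending proposals as exact
  pseudo-observations restores the repulsion the heuristic exists to
  provide. When every basin already carries a lie and improvement mass is
  numerically exhausted, the proposer falls back to the most uncertain
  candidate (pure exploration) rather than duplicating a point.
* **Correlation constraints are conservative.** `build_pc_basis()`
  eigendecomposes the correlation matrix of the yield parents, keeps the
  components explaining > 95 % of variance, and optimisation runs over the
  observed score ranges before back-transforming and clipping to the trait
  box. Note a geometric consequence: for two standardised traits the
  principal axes always sit at ±45°, so the score box truncates the trait
  box's corners even when sample correlation is negligible. The constraint
  therefore only ever restricts the search — proposals stay within the
  spread of plants actually observed, which is the point: combinations that
  break a physiological trade-off (many *and* heavy seeds) should not be
  proposed, however attractive the surrogate finds them.

Proposals are ranked by exceedance probability — the chance of beating the
best observed plant under the lie-free surrogate — because that is the
quantity a breeder acts on; EI is kept as metadata.

## Heritability and mediated pleiotropy

`estimate_h2()` estimates broad-sense heritability from one-way ANOVA mean
squares: $\sigma_g^2 = \max(0, (MS_G - MS_E)/\bar r)$ with $\bar r$ the
harmonic-mean replicate count (the standard unbalanced-design correction),
$\sigma_e^2 = MS_E$, $H^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$. In
residual mode the response is the trait minus its GP posterior-mean
prediction from its parents — "direct" heritability; parentless traits fall
back to raw mode, mirroring the dash convention of per-trait summary
tables.

The mediated-pleiotropy simulation draws SNPs as independent Bernoulli(0.5)
0/1 codes; the parent trait is a weighted sum of its causal SNPs plus
noise, the child adds its own SNPs plus $\gamma$ times the parent.
`association_scan()` drops SNPs with minor-allele frequency ≤ 0.05 and
Bonferroni-controls the family-wise error at 0.1 across the SNPs actually
tested. `power_experiment()` contrasts scanning the child directly with
scanning the child-on-parent regression residual: at $\gamma = 0$ the two
agree; when $\gamma$ dominates the noise (e.g. $\gamma = 3$,
$\sigma = 0.1$) the raw scan preferentially flags parent SNPs while the
residual scan recovers the child SNPs, with null SNPs staying within the
Bonferroni budget in both modes. SNP-class sizes (20/20/460 over 200
plants) and the weight scale (0.5) are package defaults chosen to put
signals at detectable-but-not-saturated effect sizes; they are arguments,
not constants.

## The synthetic panel, and what passing tests do not show

`generate_scm_table()` draws from a tiered structural causal model: traits
in topological order, each the sum of parent-edge contributions, a
variety-level intercept shared across replicates (this is what gives ANOVA
a genotype signal), and Gaussian noise. Saturating edges contribute
`coef * tanh(z(parent))` — smooth, bounded and monotone, the simplest shape
matching observed saturation; the functional form of real trait links is
unknown. Missingness is injected completely at random, the weakest
mechanism predictive mean matching handles. A two-group split with
perturbed coefficients emulates crop-type contrasts. Draws are made
per node in a canonical topological order, so declaring nodes in a
different order yields bitwise-identical columns.

The generator deliberately does **not** reproduce the measured distributions
of a real 27-trait panel, glasshouse spatial design effects, non-MCAR
missingness, genotype-by-environment interaction, or linkage disequilibrium
between SNPs. Green tests therefore certify the machinery — score algebra,
search behaviour, GP posteriors, propagation semantics, estimator
calibration — under the stated generative assumptions, not the biology of
any particular panel.

## Imputation and transforms

`select_transforms()` picks, per trait, the transform (identity, log, sqrt,
logit; automatic offsets for zero-containing columns) minimising absolute
sample skewness, with ties broken in that order; a user-supplied
`transform_spec()` always overrides it. `impute_pmm()` is chained-equations
predictive mean matching with the method's conventional settings (5 donors,
5 sweeps, ridge-stabilised regressions with posterior-perturbed
coefficients); it returns a single completed table — multiple imputation
and the propagation of imputation uncertainty into structure learning are
out of scope and acknowledged as a limitation. Imputation runs on
transformed values; whether to impute before or after transformation is a
genuinely open choice, flagged for sensitivity analysis.

## Problem sizes

The reference analysis scale is 94 varieties × 5 replicates, 500 bootstrap
replicates, five folds, and 4 × (1000 + 1000) MCMC iterations per node. The
test suite and the acceptance script run the same code paths at desk scale —
100 bootstrap replicates per fold, MAP-mode GPs, panels of 100–500 plants,
50-replicate power cells — sizes chosen so the full suite completes on a
single CPU in minutes while every statistical assertion retains comfortable
Monte-Carlo margins.

## Known limitations

* Edges are interpreted causally on the uncounfoundedness assumption; a
  latent common cause (e.g. a pleiotropic locus) can masquerade as a direct
  trait-trait link. The framework quantifies consequences of the assumed
  DAG; it cannot validate the assumption.
* Single imputation; no CPDAG/equivalence-class output; no multi-trait
  simultaneous interventions (the optimiser covers that use case); no
  population-structure correction in the association scan — that belongs to
  real-data GWAS tooling, not to this simulation framework.
* The exceedance ranking degenerates when the incumbent best plant is an
  off-constraint outlier: every constrained proposal then has essentially
  zero probability of beating it, and ranks carry little information. The
  proposal table exposes the probabilities, so this situation is visible
  rather than hidden.
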