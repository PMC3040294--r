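---
title: "Multiple-testing-adjusted disease mapping with tri-level mixture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-testing-adjusted disease mapping with tri-level mixture models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

A disease map reports, for each of a few hundred small areas, an observed
count of cases $Y_i$ and an expected count $E_i$ obtained by indirect
standardization (reference age-specific rates applied to the area's
population). The standardized mortality ratio $\mathrm{SMR}_i = Y_i/E_i$
estimates the area's relative risk $\theta_i$, with variance $1/E_i$ on the
ratio scale. Because population sizes vary over orders of magnitude, raw
SMRs from small areas spread wildly around the null $\theta_i = 1$, and
deciding which areas truly diverge is a multiple-testing problem: with
$m \approx 300$ areas, per-area tests at 5% would flag a dozen areas on a
completely null map.

`trimix` provides the two standard answers side by side.

* A **frequentist screen**: exact Poisson p-values per area, corrected by
  Bonferroni (family-wise control), the Benjamini--Hochberg step-up (FDR
  control, plain and adaptive), and Storey q-values, with funnel-plot
  control limits for display.
* A **tri-level hierarchical Bayesian mixture model** whose per-area
  posterior *classification probability* — the probability of belonging to
  the null set — is a fully Bayesian local-FDR-like quantity that adjusts
  for multiplicity through its prior.

## The tri-level model

The first level is the Poisson likelihood,
$Y_i \sim \mathrm{Poisson}(E_i\,\theta_i)$. At the second level the log
relative risk is a two-component mixture,

$$\log \theta_i = r_i\,\mu_{0i} + (1 - r_i)\,\mu_{1i},$$

where $r_i \in \{0,1\}$ indicates membership of the null set. Under the
null all mass sits at a point, $\mu_{0i} = 0$: the area is exactly at the
reference and only Poisson noise remains. Under the alternative,
extra-Poisson variability is modelled in one of the two classical ways:

* **Poisson-Gamma (PG)**: $e^{\mu_{1i}} \sim \mathrm{Gamma}(k, \nu)$, with
  exponential hyperpriors on $k$ and $\nu$. Divergent risks shrink toward
  the global mean $k/\nu$.
* **BYM (convolution)**: $\mu_{1i} = u_i + v_i$ with unstructured
  heterogeneity $u_i \sim N(0, \lambda_u^{-1})$ and a clustering term $v_i$
  following an intrinsic CAR prior: given its neighbours,
  $v_i \mid v_{j \in S_i} \sim N(\bar v_{S_i},\, (\lambda_v n_i)^{-1})$,
  where $S_i$ is the neighbour set and $n_i = |S_i|$. Divergent risks
  shrink toward local and global means; Gamma hyperpriors sit on both
  precisions.

The third level is the testing layer: $r_i \sim \mathrm{Bernoulli}(\pi_i)$
with $\pi_i \sim \mathrm{Beta}(c, d)$, exchangeable across areas. The
posterior mean of $r_i$ is the classification probability
$\Pr(r_i = 1 \mid \mathbf{Y})$; its complement is the inclusion
probability. Because the prior carries genuine mass on the null, posterior
inference is adjusted for multiple testing in the sense of Scott and
Berger: flagging areas with low classification probability does not
degenerate as $m$ grows.

### Why the prior on $\pi$ matters

The default hyperprior is $\mathrm{Beta}(9.7, 0.3)$: mean $0.97$, 10th
percentile $0.91$, median $0.99$ (`beta_prior_summary(9.7, 0.3)`). It
encodes the surveillance-typical belief that only a few percent of areas
diverge. This choice is load-bearing. On an all-null map a uniform
$\mathrm{Beta}(1,1)$ prior — mean $0.5$ — drags classification
probabilities down wholesale and flags areas spuriously, while the
moderately weaker $\mathrm{Beta}(9,1)$ (mean $0.90$, first decile $0.77$,
median $0.93$) preserves the area ranking almost perfectly. The
`sensitivity_sweep()` function automates exactly this comparison, refitting
under a list of $(c,d)$ pairs with shared chain randomness and reporting
sorted classification probabilities and their Spearman rank correlations;
the acceptance suite runs it on a synthetic null map and checks both the
wholesale drop under the uniform prior and rank correlation $\ge 0.9$
between the two informative choices.

A related open choice is whether $\pi$ is area-specific or shared. The
exchangeable area-specific form ($\pi_i$ per area) is the default; a
`pi_sharing = "common"` option pools $\sum r_i$ into a single Beta update.
With the informative default prior the two behave similarly; the common
form tightens the coupling between areas and is provided for users who
want the Scott--Berger-style shared mixing weight.

## The sampler

All updates are Metropolis-within-Gibbs, vectorized over areas:

1. $r_i$ from its two-point full conditional with odds
   $\pi_i \mathrm{Pois}(y_i \mid E_i e^{\mu_0})$ against
   $(1-\pi_i)\mathrm{Pois}(y_i \mid E_i e^{\mu_{1i}})$, computed on the log
   scale throughout.
2. $\pi_i \sim \mathrm{Beta}(c + r_i,\, d + 1 - r_i)$ conjugately (or the
   pooled form under a common $\pi$).
3. PG: $e^{\mu_{1i}} \sim \mathrm{Gamma}(k + y_i,\, \nu + E_i)$ for areas
   currently in the alternative; areas at the null refresh $\mu_{1i}$ from
   the $\mathrm{Gamma}(k, \nu)$ prior, which keeps the chain irreducible
   without reversible-jump machinery. $k$ and $\nu$ move by random-walk
   Metropolis on the log scale — componentwise steps plus a *joint scale
   move* along $(\log k, \log\nu)$, because the posterior pins the Gamma
   mean $k/\nu$ much harder than the scale and componentwise walks crawl
   along that ridge.
4. BYM: $u_i$ is Gibbs-drawn from its prior where the likelihood is
   inactive ($r_i = 1$) and random-walk updated otherwise; $v_i$ likewise,
   with its ICAR full conditional (neighbour-average mean, precision
   $\lambda_v n_i$) as the prior part. $v$ updates sweep over a greedy
   coloring of the adjacency graph so each color class updates as one
   vectorized block. After each sweep $v$ is re-centred to sum zero and the
   level is absorbed by $u$ (the model has no separate intercept).
   $\lambda_u$ and $\lambda_v$ get conjugate Gamma updates, the latter via
   the ICAR pairwise-difference quadratic form with rank $m - (\#$connected
   components$)$.

Random-walk step sizes adapt only during burn-in (Robbins--Monro toward
0.44 componentwise acceptance) and are frozen afterwards, preserving
detailed balance in the sampling phase. Chain seeds are derived from the
master seed, so a fixed seed makes the entire draw store bit-reproducible;
chain labels are exchangeable.

Degenerate and edge cases: $\pi_i$ draws are clamped away from 0 and 1
before entering log-odds; Gamma draws are floored at the smallest positive
double; islands (areas with no neighbours) keep $v_i = 0$ with a warning
and are excluded from the centering — their fit rests on $u_i$ alone.
The re-centering transformation is exact for connected maps; on maps with
islands it perturbs the island likelihood by the (per-sweep tiny) centering
shift, which is the standard practical treatment.

### Validation oracles

Three closed-form checks pin the sampler down, and run in the test suite:

* **Conjugacy**: with the null component disabled (`fix_r = 0`) and $k,
  \nu$ fixed, the PG posterior means must equal $(k + y_i)/(\nu + E_i)$;
  since the draws are then iid, the Monte-Carlo standard error is exact and
  the test asserts agreement within 3 of them.
* **ICAR conditional**: on a 3-node path the middle node's full
  conditional must have the neighbour average as mean and precision
  $2\lambda_v$; moments over $10^5$ conditional draws confirm it.
* **Prior recovery**: with the likelihood masked (`prior_only = TRUE`), the
  across-draw mean of $\pi_i$ must return $c/(c+d)$.

## Frequentist screen: numerical choices

* The two-sided exact Poisson p-value doubles the smaller tail, capped at
  1. The doubling rule is monotone in each tail and matches the usual
  surveillance convention; the minimum-likelihood two-sided construction is
  deliberately not implemented.
* Storey's $\hat\pi_0$ uses a fixed $\lambda = 0.5$ (configurable); the
  smoother variant is out of scope. With a few hundred tests the estimator
  is noisy, which is precisely the regime where the Bayesian route with an
  informative prior earns its keep.
* q-values are computed by the tail-minimization
  $q_{(i)} = \min_{k \ge i} \hat\pi_0 m p_{(k)}/k$; thresholding them at
  $\gamma$ provably rejects exactly the adaptive BH set at level $\gamma$
  with the same $\hat\pi_0$, and the test suite asserts the identity on
  hundreds of random vectors. Ties in p-values share a fate because
  rejection is decided by p-value, never by sort position.
* Funnel-plot control limits use conservative discrete Poisson quantiles
  (achieved coverage at least nominal, no randomized tests). Being
  discrete, the limit curves carry a sawtooth: they do **not** narrow
  monotonically in $E$, and the tests check tail coverage and a large-$E$
  normal cross-check ($1 \pm 1.96/\sqrt{E}$ within 5%) instead of
  monotonicity. The multiplicity-adjusted curves convert a q-value
  threshold into the implied per-test p cut-off (the largest observed p
  with $q \le$ threshold) — a data-dependent rule, recorded per curve in
  the output. When the lower tail is unrejectable even at $Y = 0$ the
  lower limit is reported as 0.

## The synthetic-map generator

Real municipal mortality registers are rarely shareable, so the package
ships a seeded generator that emulates their structure: a rook-contiguity
lattice (neighbour counts 2--4, like municipal contiguity), expected counts
drawn log-uniformly over $[0.5, 200]$ to reproduce the funnel geometry of
small-area maps, a configurable proportion of truly divergent areas
(default $\pi_0 = 0.97$, i.e. around 3% divergent), two-sided fixed effects
by default (half at $RR$, half at $1/RR$), and an optional spatially
contiguous divergent patch to exercise the BYM variant. A 17×17 lattice
minus 2 cells gives 287 areas, the scale of a regional municipal map.

What it does *not* emulate: real adjacency geometry (lattices have no
coastline, enclaves or size-dependent contiguity), demographic age
structure (expected counts are drawn, not standardized from stratum
rates), spatially varying $\pi_0$, and risk surfaces smoother than the
two-component truth. Tests passing on these maps therefore demonstrate
algorithmic correctness and honest operating characteristics under the
stated generating model — not performance guarantees for any particular
registry.

## Default settings and problem sizes

The fitting defaults mirror conservative production practice: 2 chains,
100&nbsp;000 burn-in, 50&nbsp;000 stored draws. The package's own test and
acceptance runs use reduced settings — 2 chains × 2&nbsp;000 stored after
2&nbsp;000 burn-in, thinning 2, on 287-area maps — which we chose as the
smallest configuration at which the Gelman--Rubin diagnostic on the
monitored scalars ($k$, $\nu$ or $\lambda_u$, $\lambda_v$, and
$\sum r_i$) sits reliably below 1.1; convergence is asserted, not assumed,
in every such test. Simulation studies use 200 replicates (FDR control)
and 5 seeds (parameter recovery), sizes at which Monte-Carlo standard
errors are small relative to the margins being tested.

Hyperprior defaults that the data source does not dictate are conventions,
stated once: $\mathrm{Exponential}(0.1)$ on $k$ and $\nu$ (weakly
informative on the positive half-line, in the Clayton--Kaldor lineage) and
$\mathrm{Gamma}(0.5, 0.0005)$ on $\lambda_u, \lambda_v$ (the widely used
WinBUGS-era precision prior). Both are configurable through `hyper =`.

## Known limitations

* The BYM variant's per-area Metropolis updates mix more slowly than the
  PG variant's conjugate draws; budget longer chains for spatially
  structured maps, and always check the reported PSRFs.
* Classification probabilities are reported as posterior means of $r_i$;
  the posterior mean of $\pi_i$ is exposed separately
  (`pi_posterior_mean()`) and the two should not be conflated.
* No decision-theoretic layer is provided: thresholds such as 0.2
  (classification) and 0.9 (inclusion) are conventional screen settings,
  not loss-minimizing cut-offs.
* Alternative spatial priors (Leroux, proper CAR), model comparison
  (DIC/WAIC), and empirical-Bayes estimation of $\pi$ inside the model are
  out of scope.

## A minimal session

```{r, eval = FALSE}
library(trimix)

map <- generate_map(17, 17, drop = 2, pi0 = 0.97, effect_size = 2,
                    e_range = c(20, 200), seed = 1)

# frequentist screen
scr <- poisson_screen(map$table)
sum(scr$reject_bh)

# Bayesian classification
fit <- trimix(map$table, chains = 2, burnin = 2000, store = 2000,
              thin = 2, seed = 2)
summary(fit)

# agreement between the two routes at the 0.2 cut-offs
cp <- classification_probs(fit)
ct <- cross_tabulate(as.integer(cp$prob_null <= 0.2), scr$reject_q,
                     labels = c("PG prob", "q-value"))
specific_agreement(ct)
```
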