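# trimix

Multiple-testing-adjusted disease mapping: a frequentist screen and a
tri-level hierarchical Bayesian mixture model, side by side.

## The problem

Disease maps report, for each of a few hundred small areas, an observed
count of cases *Y&#7522;* and an expected count *E&#7522;* from indirect
standardization, so every area shares the implicit null hypothesis
RR&#7522; = 1. The standardized mortality ratio SMR&#7522; = *Y&#7522;/E&#7522;*
estimates the relative risk with variance 1/*E&#7522;*: tiny areas produce
wildly unstable SMRs, and deciding which areas *truly* diverge from the
reference is a multiple-testing problem. Classical family-wise control
(Bonferroni) is too strict for exploratory surveillance; false-discovery-
rate ideas fit better, and a hierarchical Bayesian model with a genuine
point-mass null gives the fully Bayesian version of the same adjustment.

`trimix` is for epidemiologists and biostatisticians running small-area
screens. It implements:

- **Exact Poisson per-area tests** (no normal approximation) with
  Bonferroni, plain and adaptive Benjamini–Hochberg, Storey's π₀ estimate
  and q-values, and exact conservative funnel-plot control limits
  (including multiplicity-adjusted curves from a q-value threshold).
- **The tri-level mixture model.** Level 1:
  *Y&#7522;* ~ Poisson(*E&#7522;θ&#7522;*). Level 2:
  log θ&#7522; = *r&#7522;*·μ₀&#7522; + (1 − *r&#7522;*)·μ₁&#7522;, a point
  mass at μ₀ = 0 (the null) versus an alternative with extra-Poisson
  variability — Poisson-Gamma (exp(μ₁) ~ Gamma(*k*, ν)) or BYM
  (μ₁ = *u* + *v*, unstructured plus intrinsic-CAR spatial effects).
  Level 3: *r&#7522;* ~ Bernoulli(π&#7522;), π&#7522; ~ Beta(*c*, *d*).
  The posterior mean of *r&#7522;* is the per-area **classification
  probability** of belonging to the null set; its complement is the
  inclusion probability. Fitting is by Metropolis-within-Gibbs MCMC with
  Gelman–Rubin diagnostics.
- **A seeded synthetic-map generator** (lattice adjacency, heterogeneous
  expected counts, a small configurable fraction of divergent areas,
  optionally spatially clustered) with truth-based evaluation: false
  discovery proportion, sensitivity, replicated operating-characteristic
  studies.
- **Comparison reports**: 2×2 cross-tabulations, Fleiss' proportion of
  specific agreement, exponential Q-Q data for p-values, q-value versus
  classification-probability rank agreement, and an end-to-end pipeline
  with a reproducibility manifest.

## Worked example

```r
library(trimix)

# 287 areas on a 17x17 lattice minus 2 cells; 3% divergent at RR 2 (two-sided)
map <- generate_map(17, 17, drop = 2, pi0 = 0.97, effect_size = 2,
                    e_range = c(20, 200), seed = 1)

scr <- poisson_screen(map$table)
fit <- trimix(map$table, chains = 2, burnin = 2000, store = 2000,
              thin = 2, seed = 2)

cp <- classification_probs(fit)
ct <- cross_tabulate(as.integer(cp$prob_null <= 0.2), scr$reject_q,
                     labels = c("PG prob", "q-value"))
```

This prints (seed-for-seed reproducible):

```
> map
synthetic_map: 287 areas (17x17 lattice - 2 cells), 7 truly divergent (fixed)
> sum(scr$p_value < 0.05); sum(scr$reject_bonferroni); sum(scr$reject_q)
[1] 17
[1] 6
[1] 8
> fit
Tri-level Bayesian mixture model (Poisson-Gamma alternative)
  287 areas; Beta(9.7, 0.3) null-probability hyperprior (area-specific pi)
  2 chain(s) x 2000 stored draws (burn-in 2000, thin 2)
  areas with classification probability <= 0.2: 5
> ct
            q-value yes q-value no
PG prob yes           5          0
PG prob no            3        279
> round(specific_agreement(ct))
[1] 77
```

Reading the numbers: 17 of 287 areas have raw p < 0.05 — mostly
multiplicity noise, since only 7 are truly divergent. The q-value screen
at 0.20 flags 8; the Bayesian classification probability at the same 0.20
cut-off flags 5, all of which the q-value screen also flags, for a
proportion of specific agreement of 77%. All 5 Bayesian flags are truly
divergent areas. `summary(fit)` adds smoothed relative risks with credible
intervals and per-parameter Gelman–Rubin statistics; `plot(fit)` draws the
funnel plot with flagged areas highlighted.

The same workflow is scriptable from a shell via `exec/trimix`
(`simulate`, `screen`, `fit`, `compare`, `report` subcommands), and
`run_pipeline()` drives everything from one YAML configuration.

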