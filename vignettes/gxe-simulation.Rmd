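---
title: "Simulating gene-environment interactions in case-control data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating gene-environment interactions in case-control data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxesim)
```

## The penetrance model

Complex diseases arise from genetic variants interacting with environmental
exposures. To benchmark statistical methods that hunt for such interactions
— logistic regression screens, multifactor dimensionality reduction, and the
like — one needs case-control samples in which the generating mechanism is
fully known. `gxesim` produces them.

Each individual carries `G` biallelic SNP genotypes and `E` environmental
exposures. For the causal gene, the three genotypes are indexed `i = 1`
(reference homozygote AA), `i = 2` (heterozygote Aa) and `i = 3` (high-risk
homozygote aa). The disease risk of an individual with genotype `i` and
exposure `x` is a logistic function whose coefficients are set by the
genotype:

$$R(i, x) = \frac{1}{1 + e^{-(\alpha_i + \beta_i x)}}$$

so the model is a bundle of logistic curves, one per genotype: `alpha_i` is
the basal (exposure-free) log-odds of disease and `beta_i` the log odds
ratio per one unit of exposure — the genotype's susceptibility to the
environment. The logit-linear form is forced by the requirement that a
covariate's coefficient be interpretable as a log odds ratio, the standard
epidemiological reading. In the general multi-factor form (`coef_table()`,
`general_risk()`) every multi-locus genotype combination owns an intercept
and a slope vector over the exposures, which permits epistasis and any
non-linear gene-environment pattern; the packaged solver, however, covers
the one gene-one environment case, and multi-factor models are driven by
user-supplied coefficient tables.

Marginalizing a genotype's risk curve over the exposure distribution gives
its *total risk*

$$TR_i = E_x\!\left[R(i, x)\right],$$

and ratios of total risks are the familiar relative risks,
`RR_kl = TR_k / TR_l`. The overall disease frequency decomposes as

$$m = \sum_{i=1}^{3} P_i \, TR_i,$$

with `P_i` the genotype frequencies. This conservation identity is the
anchor of the whole parametrization and is what the test suite checks most
aggressively.

## From epidemiological inputs to coefficients

Users rarely know `alpha_i` and `beta_i`; they know prevalences and risk
ratios. `solve_coefficients()` therefore accepts:

| parameter | meaning | default |
|---|---|---|
| `m` | overall disease frequency, in (0, 1) | — |
| `rr31` | relative risk of aa vs AA, ≥ 1 | 1 |
| `w` | inheritance weight in [0, 1] | 0 |
| `env_or` | odds ratio per unit of exposure, > 0 | 1 |
| genotype frequencies | `(P_1, P_2, P_3)`, e.g. Hardy-Weinberg from an allele frequency | — |
| exposure distribution | normal, uniform, or empirical discrete | — |

The heterozygote's relative risk is placed between the homozygotes on the
relative-risk scale, `RR21 = 1 + w (RR31 - 1)`: `w = 0` is recessive
(heterozygote behaves like the reference homozygote), `w = 1` dominant,
intermediate values co-dominant. This is the unique linear interpolation
with those endpoint semantics, and it guarantees `1 ≤ RR21 ≤ RR31`. (Some
descriptions of the co-dominant case state it as `0 < RR21 < 1`; that is
inconsistent with `RR21 ≥ 1`, and we read the condition as `0 < w < 1`.)

Substituting `TR_2 = RR21 · TR_1` and `TR_3 = RR31 · TR_1` into the
conservation identity yields the closed-form targets

$$TR_1 = \frac{m}{P_1 + P_2\,RR21 + P_3\,RR31}, \qquad
  TR_2 = RR21 \cdot TR_1, \qquad TR_3 = RR31 \cdot TR_1 .$$

If any target reaches 1 the request is infeasible (the prevalence is too
large for the requested relative risks) and the solver stops before any
simulation, naming the offending quantity.

The remaining freedom — six coefficients against three targets — is removed
by a qualitative description of the interaction, a set of equalities and
inequalities over the coefficients:

| model | constraint pattern | reading |
|---|---|---|
| `GM` | `α₁ ≤ α₂ ≤ α₃`, `β = 0` | genetics only; flat risk in the exposure |
| `EM` | shared `α`, shared `β ≠ 0` | environment only; one curve for all genotypes |
| `AM` | `α₁ ≤ α₂ ≤ α₃`, shared `β ≠ 0` | additive: same slope, genotype-specific shift |
| `GEM` | shared `α`, `β₁ ≤ β₂ ≤ β₃` | the gene modulates the response to the exposure |

Given the pattern, each model reduces to monotone one-dimensional
root-finding problems:

* **GM** — closed form, `alpha_i = logit(TR_i)`.
* **EM** — `beta = log(env_or)` shared; one intercept solved so the marginal
  risk equals `m`. Because equal coefficients force equal total risks, an EM
  request with `rr31 != 1` is contradictory and is rejected rather than
  silently ignoring `rr31`.
* **AM** — `beta = log(env_or)` shared; three independent intercept solves,
  one per target `TR_i`. The intercept ordering then follows the total-risk
  ordering automatically.
* **GEM** — the user's odds ratio anchors the *reference* genotype's slope,
  `beta_1 = log(env_or)` (all relative risks are defined against genotype 1,
  which makes it the natural anchor; only one slope can be taken from the
  user without over-determining the system). The shared intercept is solved
  against `TR_1`, then `beta_2` and `beta_3` against `TR_2` and `TR_3`. The
  `beta` ordering is verified after solving.

Every solve is validated against its constraint pattern
(`validate_constraints()`, absolute tolerance 1e-9 on equalities — far above
the solver residual) and returns the achieved total risks and the maximum
residual for provenance.

## Numerical choices

* **Marginalization.** Discrete exposure laws are summed exactly. Continuous
  laws use fixed 256-node Gauss-Legendre quadrature — over `[min, max]` for
  the uniform, over `mean ± 8 sd` for the normal (truncated tail mass below
  1e-15). A fixed deterministic scheme, rather than adaptive integration,
  keeps solves bit-reproducible; an independent Monte Carlo estimator
  (`mc_total_risk()`) cross-checks it in the test suite.
* **Root finding.** Intercept solves run Brent's bracketed search on
  `[-50, 50]` log-odds with tolerance 1e-13 on the root; the residual
  `|TR - target|` lands near machine precision and is always below 1e-10.
  Total risk is strictly increasing in the intercept, so the bracket either
  contains exactly one root or the request is reported infeasible.
* **Slope solves and support.** The marginal risk is monotone in the slope
  only when the exposure support is nonnegative. GEM slope derivation
  therefore requires `min(support) ≥ 0`; distributions straddling zero (the
  unshifted normal, for instance) are rejected with a suggestion to shift
  the exposure scale. Exposure-like variables (doses, pack-years, BMI
  classes) are naturally nonnegative, so this is rarely restrictive.
* **Degenerate inputs.** A point-mass exposure admits closed forms
  (`alpha = logit(TR) - beta x₀`), which the solvers use directly — with a
  point mass at 0 every solver returns `alpha_i = logit(TR_i)` exactly. Equal
  total-risk targets (within 1e-14) short-circuit the slope solve to
  `beta_i = beta_1`, so a GEM request with `rr31 = 1` degrades gracefully to
  EM rather than relying on the root-finder to find an exact tie.

## The generator

`simulate_population()` runs the pipeline: solve the coefficients (failing
before any sampling if infeasible), assign genotypes, assign exposures,
compute risks, draw statuses.

* Genotypes are sampled i.i.d. per gene from the genotype-frequency triples;
  when only an allele frequency is known, `hwe_genotype_freqs()` applies the
  Hardy-Weinberg law `(p², 2p(1-p), (1-p)²)`, and `sample_allele_freqs()`
  draws frequencies uniformly in [0.1, 0.9] when the user wants them chosen
  at random.
* Exposures are sampled i.i.d. per factor; environmental variables are
  assumed independent of each other and of the genotypes.
* Disease status is a Bernoulli draw per individual: affected exactly when a
  uniform [0, 1] number is *strictly less* than the individual's risk.
* Only the causal gene/environment pair enters the risk; any further factors
  in the specification are noise background, mimicking the many unassociated
  covariates of real studies.
* One root seed is expanded into independent named sub-streams for the
  genotype, exposure and status draws, so adding a factor to one stage
  cannot perturb the others and identical `(spec, seed)` pairs give
  identical datasets.

`m` is an *expected* prevalence: the affected count is binomial, not fixed.
`sample_case_control()` is provided as plumbing for users who need an exact
cases-to-controls design, but it is deliberately outside the generative
model.

## Validation and what it does (not) show

`summarize_dataset()` recomputes the empirical prevalence, per-genotype
affected fractions and their ratios, and per-genotype maximum-likelihood
logistic slopes of status on the causal exposure (a self-contained
Newton-Raphson fit with Wald standard errors, cross-checked against
`glm()` in the tests), reporting each discrepancy in standard-error units.

The test suite verifies, among others: exact conservation of `m` by the
solved coefficients (tolerance 1e-8, with discrete environments re-checked
by exhaustive summation independent of the quadrature code); recovery of
`m`, `RR21` and `RR31` from simulated samples within three binomial standard
errors at n = 200,000; 95% Wald-interval coverage of the generating GEM
slopes in at least 90% of 100 replicates at n = 50,000; the qualitative
signatures of all four interaction models; and byte-identical outputs under
repeated runs. These problem sizes keep the full suite in the minutes range
while leaving Monte Carlo noise well below the tested effects.

Passing these checks shows that the generator delivers the populations it
promises — it does not make the samples real. The simulation omits, by
design: linkage disequilibrium and haplotype structure between loci (loci
are sampled independently), gene-environment *correlation* (exposures are
independent of genotypes), measurement error in exposures, time-varying
exposure, family structure, and non-logistic penetrance. Results obtained on
these datasets transfer to real data only to the extent that these
assumptions are tolerable for the question at hand.

## Worked example

```{r}
spec <- population_spec(
  n = 50000,
  genotype_freqs = hwe_genotype_freqs(0.5),
  env = env_uniform(0, 4),
  m = 0.1, model = "GEM", rr31 = 3, w = 0.5, env_or = 1.5
)
sol <- solve_coefficients(spec)
sol

sim <- simulate_population(spec, seed = 42)
summarize_dataset(sim)
```

File-driven runs (`load_run_config()` + `run_simulation()`, or the
`inst/cli/gxesim.R` script with subcommands `solve`, `simulate` and
`summarize`) write the dataset TSV, the solved coefficients, the validation
summary and an echoed configuration, so every dataset carries its full
provenance.
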