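---
title: "Measurement-error-free genetic resemblance between partners, siblings and in-laws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement-error-free genetic resemblance between partners, siblings and in-laws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgensi)
```

## The problem

Assortative mating — non-random partner choice on heritable traits — makes
partners, and in later generations siblings, siblings-in-law and
co-siblings-in-law, genetically more alike than random pairs. Correlations
between relatives' polygenic scores (PGS) understate this resemblance,
because a PGS is a noisy indicator of the latent genetic factor behind a
trait: if only a share $s^2$ of PGS variance is genetic signal, a latent
genetic correlation $r_g$ surfaces as a PGS correlation of only
$s^2 r_g$. `rgensi` implements a structural-equation model that separates
signal from noise using family-linked data, and two simulators that
validate it.

## The model

Each person contributes two observed variables, a polygenic score and a
phenotype, both standardized. The structural layer per person is

* a latent genetic factor $G$ loading $s$ on the PGS ($s^2$ = genetic
  signal) and $h$ on a latent phenotype ($h^2$ = heritability),
* a latent *mated* phenotype $LP$ on which partner selection operates,
  loading $a$ on the observed phenotype ($a = 1$: direct, primary
  phenotypic assortment; $a < 1$: indirect assortment on a correlated
  trait),
* a sibling-shared environment loading $c$,
* residuals $E_g = 1 - s^2$, $E_l$, $E_p$ completing each variance to 1.

Partners are connected by a *co-path* $m$ between their latent mated
phenotypes: a non-causal bond that contributes to covariances but not
variances, so any traced chain crossing a couple bond picks up one factor
of $m$. Siblings' genetic factors correlate $r_s$, their PGS residuals
correlate $g_0$ (0.50 by default, the random-mating value; freeing $g_0$
is only identified when $c$ is fixed at 0). Path tracing with co-paths then
gives the measurement-error-free genetic correlations

$$r_{g,\mathrm{partner}} = m h^2,\quad
  r_{g,\mathrm{sibling}} = r_s,\quad
  r_{g,\mathrm{in\text{-}law}} = r_s\, m h^2,\quad
  r_{g,\mathrm{co\text{-}in\text{-}law}} = r_s (m h^2)^2 ,$$

and an $8\times 8$ implied covariance over (PGS, phenotype) for the four
family roles (two siblings A1, A2 and their partners Q1, Q2), computed by
`implied_family_covariance()`. Two orientation-asymmetric in-law entries
($s h a m r_s$ vs $s h^3 a m r_s$) fall out of the tracing and are a sharp
test of any implementation.

### Where does the shared environment load?

Two conventions are implemented. Under `c_target = "observed"` (default)
the shared environment loads the observed phenotype and does not transmit
through the co-path; the co-in-law genetic correlation is then exactly
$r_s (m h^2)^2$, which matches the published derived values even when
$\hat c > 0$. Under `c_target = "latent"` (cascade-style) it loads the
latent mated phenotype, so $c^2$ propagates through $m$ and, e.g., the
sibling phenotype covariance becomes $a^2(h^2 r_s + c^2)$. The observed
placement is the default because the derived co-in-law arithmetic only
holds there; the latent placement fits higher in-law phenotypic
correlations and is retained as an explicit option. Note a structural
consequence: with `c_target = "observed"` the phenotype residual is
$1 - a^2 - c^2$, so a model with $a$ fixed at 1 cannot carry $c > 0$; the
ladder's `c_free` variant is then a boundary fit ($\hat c \to 0$). Under
the latent placement `c_free` with $a = 1$ is a regular model.

Loadings $s, h, a, c$ are restricted to $[0, 1]$ (their sign is not
identified for standardized factors); $m$ and $r_s$ may be negative to
admit disassortative mating.

## Fitting

`fit_model()` minimizes the full-information maximum-likelihood deviance
over families with arbitrary missingness: a family with observed subvector
$x$ of dimension $k$ and implied submatrix $\Sigma_{\mathrm{sub}}$
contributes $k\log 2\pi + \log|\Sigma_{\mathrm{sub}}| +
x'\Sigma_{\mathrm{sub}}^{-1}x$ (means fixed at 0 and variances at 1; the
preprocessing layer standardizes the data, and a residualization step
removes principal-component and batch structure beforehand). Families are
grouped by missingness pattern so each deviance evaluation costs one
$8\times 8$ Cholesky per pattern. Optimization is quasi-Newton
(`nlminb`) on logit-transformed coordinates with Latin-hypercube
multistart (10 starts by default; deviance tolerance $10^{-10}$); the
joint residual-variance constraints are enforced by a penalty so boundary
solutions such as $\hat c = 0$ are reachable. Estimates within $10^{-3}$
of a bound are flagged.

Confidence intervals are likelihood-based: `profile_confidence_interval()`
bisects for the parameter value where the profiled deviance rises by
$\chi^2_1(0.95) = 3.841$, to $10^{-4}$ in the parameter, clipping (and
flagging) at parameter-space limits. `fit_model_ladder()` fits the basic
model ($s, h, m, r_s$ free; $a = 1$, $c = 0$), the $a$-free, $c$-free and
$a{+}c$-free extensions, and each with the intergenerational-equilibrium
constraint $r_s = \tfrac12(1 + m h^2)$; nested variants are compared by
likelihood-ratio tests at the 5% level, preferring the more restricted
model on ties. Testing $c = 0$ or $a = 1$ tests a boundary value, so the
plain $\chi^2_1$ p-values are conservative; this is documented rather than
corrected, mirroring standard practice.

`pgs_equilibrium_test()` applies the same equilibrium logic directly to
polygenic scores: it fits bivariate-normal models to partner and sibling
PGS pairs and tests $r_{\mathrm{sib}} = \tfrac12(1 + r_{\mathrm{partner}})$
with 1 df. With $g_0 = 0.5$ the latent constraint implies exactly this
PGS-level constraint, since
$r_{\mathrm{sib,PGS}} = s^2 r_s + \tfrac12(1 - s^2)$ and
$r_{\mathrm{partner,PGS}} = s^2 m h^2$.

Non-independence of overlapping pairs (one person appearing in several
family units, sibships larger than two) is ignored in the likelihood and
flagged in the outputs; descriptive Fisher-z intervals likewise treat
pairs as independent.

## The simulators

`sample_families()` draws family 8-vectors from the implied covariance
(eigen square root) and applies per-variable missingness masks, emulating
register-linked cohorts where genotyped and phenotyped pair counts differ.

`mate_matching_oracle()` is the independent validation route: it builds
sibling pairs and partner pools mechanically from the factor model and
couples them by Gaussian-rank matching on the latent mated phenotype so
the realized couple correlation equals $m$. It never touches the
closed-form cross-partner algebra, so agreement of its empirical
covariance with `implied_family_covariance()` (within Monte-Carlo error)
validates the co-path tracing, including the asymmetric in-law entries.
The suite runs this comparison at $2\times 10^5$ couples for five
parameter points covering $c > 0$, $a < 1$, negative $m$ and both
shared-environment conventions. With roughly 180 simultaneous entrywise
checks at a 3-standard-error criterion, a single marginal exceedance is
expected occasionally under a correct model; replicated diagnostics at
such an entry show an unbiased statistic.

`forward_simulate()` is an infinitesimal-model, forward-in-time process:
founders carry genetic values with variance $V_0$; each generation is
paired by Gaussian-rank matching to a target partner correlation (on the
mated phenotype, or directly on genetic values for constant-$r$ dynamics);
offspring receive mid-parent values plus a segregation deviate of constant
variance $V_0/2$ (no inbreeding adjustment, constant population size, two
offspring per couple, no selective fertility). Under constant partner
genetic correlation $r$,

$$V_{t+1} = \tfrac12 V_t (1 + r) + \tfrac12 V_0,
  \qquad V_\infty = \frac{V_0}{1 - r},$$

so the deviation from equilibrium contracts by $(1+r)/2$ per generation.
At $r = 0.25$ the fraction of the eventual variance increase attained by
generation 2 is $1 - 0.625^2 \approx 0.61$, while the variance itself is
within 5% of $V_\infty$ by generation 5 ($V_5/V_\infty \approx 0.98$).
`equilibrium_summary()` reports both series — the fraction of the
eventual *increase* and the ratio $V_t/V_\infty$ — because "60% of the
increase after two generations" is a statement about the former and
"close to equilibrium after five generations" about the latter: under the
contraction above the fraction of the increase at generation 5 is only
$1 - 0.625^5 \approx 0.90$ for $r = 0.25$, so the five-generation claim is
read as proximity of the variance to its equilibrium value. The summary
also checks the equilibrium identity
$r_{g,\mathrm{sibling}} = \tfrac12(1 + r_{g,\mathrm{partner}})$ against
the final generation on the Monte-Carlo standard-error scale.

## Numerical choices and problem sizes

* Covariance validity: symmetrized eigenvalues $\ge -10^{-10}$; residual
  variances may undershoot 0 by at most $10^{-9}$ (boundary arithmetic).
* Likelihood-ratio deltas more negative than a small tolerance (0.01 by
  default, 0.05 in the ladder where deviances are $\sim 10^5$) raise an
  error instead of being truncated; smaller negatives are optimizer noise
  and are clamped to 0.
* The test suite sizes its simulations to run on one CPU in minutes:
  recovery uses 50 replicates of 5,000 fully observed families
  (education-like generating values $s=0.55$, $h=0.75$, $m=0.60$,
  $r_s=0.60$); test calibration uses 200 replicates of 2,000 families;
  oracle comparisons use $2\times 10^5$ couples; forward runs use 25,000
  couples for 15 generations at partner genetic correlations
  $\{0.20, 0.25, 0.30\}$, bracketing the education-like value.

## What the synthetic data do and do not show

The generative sampler and the mate-matching oracle produce exactly
multivariate-normal, missing-completely-at-random data with one partner
per person and clean links. Real register-linked cohorts add selective
participation, non-normal phenotypes (ordinal education levels, skewed
symptom scores), genotyping batch and population structure (handled here
only via upstream residualization), overlapping extended families, and
possibly informative missingness. Passing tests therefore establish the
correctness of the algebra, the likelihood and the estimator under the
model's own assumptions — not robustness to these violations. Vertical
transmission (gene–environment covariance) and multi-trait assortment are
outside the model by construction; PGS construction itself is upstream of
this package.

## Worked example

```{r example, eval = FALSE}
theta <- gensi_parameters(s = 0.55, h = 0.75, m = 0.6, a = 1, c = 0,
                          r_s = 0.685)
dat <- sample_families(theta, 5000, seed = 1)
ladder <- fit_model_ladder(dat, seed = 1)
ladder
genetic_signal_correlations(ladder$fits[[ladder$selected]]$theta)
```
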