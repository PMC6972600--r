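---
title: "Benchmark-dose modelling and risk characterization for continuous genotoxicity endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-dose modelling and risk characterization for continuous genotoxicity endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmdrisk)
```

## The problem

In vivo genotoxicity endpoints such as the frequency of micronucleated
reticulocytes (MN-RET, in %) are continuous, strictly positive and
approximately lognormal across animals. A quantitative risk assessment of a
genotoxic chemical like benzene proceeds in two stages: (i) estimate from a
dose-response study the benchmark concentration (BMC) — the air
concentration producing a predefined fractional increase, the critical
effect size (CES), over background — together with its confidence limits
(BMCL/BMCU), and (ii) carry that animal point of departure (PoD) through
deterministic extrapolation arithmetic (exposure-regimen correction,
assessment factors) to an acceptable human daily exposure range that can be
compared with measured exposure. `bmdrisk` implements both stages as a
tested pipeline, plus a simulator that generates data with exactly the
statistical structure the analysis assumes, so every stage can be validated
without access to the original animal data (which are not publicly
deposited).

## Dose-response model

Two standard four-parameter families for continuous, monotone increasing
endpoints are fitted, parameterised directly in the critical effect dose
(CED = BMC):

* exponential: $y(x) = a\,[c - (c-1)\,e^{-b x^d}]$
* Hill: $y(x) = a\,[1 + (c-1)\,x^d/(b^d + x^d)]$

with background $a > 0$ (response units), maximum fold change $c > 1$,
log-steepness $d > 0$, and $b$ eliminated by solving $y(\mathrm{CED}) =
a(1+\mathrm{CES})$:

* exponential: $b = -\log\!\big((c-1-\mathrm{CES})/(c-1)\big)/\mathrm{CED}^d$
* Hill: $b = \mathrm{CED}\,\big((c-1-\mathrm{CES})/\mathrm{CES}\big)^{1/d}$

so the reported quantity is a model parameter and profile likelihood acts
on it directly — numerically better behaved than profiling a derived
function of $(b, c, d)$. The CES for micronucleus data is set to 50%
(`ces = 0.5`): smaller values (the 5% continuous-data default, or the 10%
used early in quantitative genotoxicity work) sit well inside the noise of
MN assays, and subsequent method work converged on 50% as appropriate for
this endpoint. `ces` is a plain argument everywhere, so other conventions
are one keystroke away.

Residual variation is lognormal: $\log y_{ij} \sim N(\log
\mu(x_i), \sigma^2)$. For group-summary data (dose, n, arithmetic mean m,
arithmetic SD s) the log-scale moments are recovered by the
method-of-moments transform $\sigma_g^2 = \log(1+s^2/m^2)$, $\mu_g = \log m
- \sigma_g^2/2$, and enter the likelihood as sufficient statistics with
$SS = n\,\sigma_g^2$. Individual data are reduced to the same per-group
sufficient statistics (exactly, by the normal factorisation), which makes
likelihood evaluation O(number of groups) regardless of group size — the
property that keeps the simulation studies in the test suite affordable.
Zero or negative responses are rejected rather than silently shifted; an
explicit `offset` can be supplied and is recorded, because a silent offset
changes the potency estimate.

## Fitting, covariate structure, confidence limits

Maximisation is by box-constrained quasi-Newton (`optim` L-BFGS-B) on
log-transformed parameters, from 20 Latin-hypercube start points plus the
box centre, deterministic given the seed. The steepness is constrained to
$d \in [0.25, 4]$: on sparse designs (four dose groups) an unconstrained
$d$ can run to degenerate step-function fits; the bound is recorded in the
fit object. The bound on $c-1-\mathrm{CES}$ is $[10^{-3}, 10^{3}]$ — on
designs whose top dose sits below the plateau, $c$ is weakly identified
and may rest on its bound; this is harmless for the CED because the profile
re-optimises $c$ at every step.

When several comparable studies (same endpoint, tissue, route, units) are
available, they are fitted jointly with study/strain as a covariate. The
lattice of structures — all shared; background $a$ split; $a$ + CED split;
$a$ + CED + residual SD split — is fitted and the lowest AIC wins, with
ties (ΔAIC < 2) resolved toward fewer free parameters. Shape parameters
$c$ and $d$ are always shared: that is what makes the studies mutually
informative, and per-strain backgrounds with a common shape is the
structure under which combining improves BMD precision. All candidate AICs
are kept in the returned fit for audit.

Confidence limits are profile-likelihood based: BMCL and BMCU at two-sided
level $1-\alpha$ are the CED values where the profile log-likelihood drops
by $\chi^2_1(1-\alpha)/2$ (1.3528 at 90%) below its maximum, found by a
geometric walk (factor 4/3) to bracket the crossing and bisection on the
log-dose scale to a relative tolerance of $10^{-4}$, warm-starting each
inner re-optimisation from its neighbour. A limit not bracketed within
CED/1000 .. CED×1000 is reported as an open interval flag, never a number.
Monotonicity of the profile along the search path is checked and flagged.
The default level is two-sided 90% (one-sided 95% bounds), the convention
of regulatory BMD practice; it is configurable.

## The simulator and what it does (not) show

`generate_study()` draws per-animal responses as $\mu(x)\,e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$ — exactly the fitted likelihood, with no
overdispersion, litter effects or cytotoxicity-driven dropout. This is
deliberate: it makes parameter recovery, interval coverage and
precision-gain experiments well-posed (nominal behaviour is the correct
expectation). Passing those tests shows the estimator and intervals are
correct under the model; it does not show the lognormal model is correct
for any particular real assay.

`benzene_like_fixture()` emulates the two study designs of the benzene
literature: a Diversity Outbred (DO)-like study (0/1/10/100 ppm, 75 per
group, 6 h/day, 5 days/week, 4 weeks) and a B6C3F1-like study
(0/1/5/10/100/200 ppm, 10 per group). The defaults — backgrounds 0.25 and
0.15 MN-RET%, shared $c = 15$, $d = 1$, $\sigma = 0.4$, true CEDs 10 ppm
(DO) and 8 ppm (B6C3F1) — are stated choices of this package: background
and fold-change are typical of mouse MN-RET benzene responses, the CEDs
match the order of magnitude of published benzene potency (~10 ppm), and
$\sigma = 0.4$ gives a realistic ~40% coefficient of variation between
animals. They are not estimates of the unpublished study parameters.

The test suite exercises the engine at these problem sizes: 200 simulated
two-strain studies for 90%-interval coverage (assessed on the DO-level CED
against the central 99% binomial band), 50 replicates each for
covariate-structure recovery and for the combined-fit precision gain, a
200-replicate parametric bootstrap against the profile interval on a
reduced design, and a ~10k-point grid-search oracle for the MLE.

## Risk-characterization arithmetic

The deterministic chain is intentionally plain arithmetic, but two
conventions matter and are fixed package-wide:

* **Rounding.** Every reported intermediate is rounded half-up to two
  significant figures, and the rounded value feeds the next reported step
  (`signif_half_up()`). This is the only convention that reproduces all
  published chains simultaneously (e.g. $14.2 \times 6/24 = 3.55 \to 3.6$,
  then $3.6/450 \to 8$ ppb, not 7.9). Half-up is implemented with a small
  relative guard so decimal halves that fall just below the half in binary
  floating point still round up. Full precision is kept internally;
  rounding happens only at the reporting layer.
* **Gas conversions** use 20 °C / 101.3 kPa (molar volume 24.04 L/mol)
  with benzene defaults (MW 78.11 g/mol); this temperature convention, not
  25 °C, reproduces the published conversions (0.05 ppm → 0.16 mg/m³ and
  5 µg/m³ → 1.5 ppb).

The human-equivalent PoD multiplies by the exposure-hours ratio and
inhaled-volume ratio: workers $6/8 \times 6.7/10$ (animals exposed 6 h/day
vs an 8-h shift, light-activity 6.7 m³ scaled to 10 m³ for working
activity); general population $6/24$ with volume ratio 1 (continuous
exposure, activity like the animals). Assessment factors are user-supplied
configuration, never hard-coded policy: the worker preset (2.5 interspecies
TK/TD × 6 duration × 5 intraspecies × 3 severity = 225) and
general-population preset (2.5 × 6 × 10 × 3 = 450) ship as illustrative
configurations, with the caveat that they should not be read as precedent
echoed into every report. The margin of exposure helper exists but the
benzene chain reports the acceptable-range comparison instead, as the case
study does. The verdict rule is: "above" only if the exposure lower bound
exceeds the acceptable upper bound, "below" only if the exposure upper
bound is under the acceptable lower bound, otherwise overlapping — an
exposure exactly at a boundary counts as overlapping.

## Design decisions that were genuinely open

* **Which family is the headline?** The published analysis shows both
  exponential and Hill panels without naming one. Both are fitted and
  reported; the headline PoD comes from the lower-AIC family. On the
  synthetic fixture the two families agree on the CED to well within the
  interval width, so nothing downstream hinges on this.
* **CI level.** Not stated in the source narrative; two-sided 90% is the
  regulatory BMD convention and is the default, configurable.
* **Summary vs individual entry of the second study.** Unknown for the
  original analysis; both dialects are first-class here and give identical
  likelihoods up to the moments transform.
* **Plateau behaviour.** The Hill family approaches its plateau
  hyperbolically, so "the curve reaches $a\,c$" is only an asymptotic
  statement; tests check the plateau at family-appropriate doses rather
  than pretending both families converge equally fast.

## Limitations

* The engine covers monotone increasing continuous endpoints only — no
  quantal models, no model averaging, no Bayesian fitting, no
  litter/clustered random effects.
* The covariate lattice is the fixed four-structure set; $c$ and $d$ never
  split.
* Unit conversions live in the risk layer only; the fitting layer treats
  dose as ppm throughout and refuses to mix unit labels rather than
  guessing.
* The synthetic fixture validates the machinery, not the published potency:
  the real MN-RET data are not public, so the published BMC50 of 11.4
  (9.6–14.2) ppm cannot be recomputed here, only the chain downstream of it.

## A worked chain

```{r}
pod <- pod_range(9.6, 14.2, basis = "BMCL50/BMCU50, MN-RET, DO mouse")
he <- human_equivalent_pod(pod, worker_adjustment())
c(he$lower, he$upper)
af <- compose_afs(benzene_worker_afs())
acc <- acceptable_range(he, af)
unlist(acc[1:2])
characterize_risk(acc, c(50, 100))
```
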