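---
title: "Methods: probabilistic fluoride risk assessment from brewed tea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic fluoride risk assessment from brewed tea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorisk)
```

## The problem and the model

Tea plants hyperaccumulate fluoride from soil into mature leaves; brewing
releases a fraction of it into the infusion. For habitual drinkers the
resulting intake can approach the doses associated with dental fluorosis in
children and teenagers and skeletal fluorosis in adults. `fluorisk`
implements the standard probabilistic (Monte Carlo) form of the
non-carcinogenic risk assessment for this exposure route.

The dose model is the conventional ingestion equation,

$$\mathrm{CDI} = \frac{C \cdot DI \cdot EF \cdot ED}{BW \cdot AT},
\qquad \mathrm{HQ} = \frac{\mathrm{CDI}}{\mathrm{RfD}},$$

with $C$ the fluoride concentration in the infusion (mg/L), $DI$ the daily
tea intake (L/day), $EF$ the exposure frequency (days/year), $ED$ the
exposure duration (years), $BW$ body weight (kg) and $AT$ the averaging
time (days). An HQ above 1 flags a potential non-carcinogenic health impact.

**Averaging time.** For non-carcinogenic endpoints risk is averaged over the
exposure period, so the default rule is $AT = ED \times 365$ days. A direct
consequence — documented and tested — is that the $ED$ draw cancels exactly
out of CDI. A fixed $AT$ (in days) is available for users who want the
alternative convention; under it $ED$ matters again.

**Reference doses.** Defaults are 0.06 mg/kg/day for children (0–10 y) and
teenagers (11–20 y), the dental-fluorosis threshold, and 0.12 mg/kg/day for
adults (21–70 y), the skeletal-fluorosis threshold; both overridable per
scenario.

## Distribution specifications

Every stochastic input is a `dist_spec`: one of five families (point,
uniform, triangular, normal, lognormal) with an optional truncation
interval. Design choices that matter numerically:

* **Inverse-CDF truncation.** Truncated draws map uniforms onto the
  truncated quantile range $[F(l), F(u)]$ rather than rejecting out-of-range
  samples. This guarantees exactly $n$ draws, keeps streams seed-stable
  under any truncation, and makes the truncated quantile function a true
  inverse of the truncated CDF (tested to $10^{-9}$ on the support
  interior).
* **Physical truncation at zero.** Normal-family inputs passed to a
  scenario without explicit truncation are truncated at $[0, \infty)$:
  concentrations, intakes and body weights are physical quantities, and a
  rare negative draw would silently corrupt the dose product.
* **Substream seeding.** Each parameter samples from a seed derived
  deterministically from the root seed and the parameter *name* (a 31-based
  string hash, kept below $2^{31}$). Runs are bit-reproducible, and editing
  one input's spec never perturbs another input's draws — a property the
  test suite asserts directly.
* **Closed-form moments.** Means and variances are closed-form for all
  untruncated families and for truncated uniform/normal/lognormal (via
  partial expectations). Truncated-triangular moments are deliberately not
  implemented: nothing in the pipeline needs them, and a silent
  approximation would be worse than an explicit error.

## Triangular fitting

Commercial risk software fits sparse environmental concentration data with a
triangular distribution; the estimator it uses is not published. The
package's fitter is deterministic moment matching: endpoints pinned at the
sample minimum and maximum, mode solved from the sample mean via
$c = 3\bar{x} - a - b$ (the triangular mean is $(a+c+b)/3$), clamped into
$[a, b]$. It needs no optimizer, is exactly reproducible, and recovers
$(a, c, b) = (0, 0.7, 2)$ from $10^4$ draws within $(0.05, 0.1, 0.05)$ in
the acceptance suite. Its known bias: sample min/max underestimate the true
support for small $n$, so fitted tails are slightly short — acceptable here
because the analysis uses central percentiles (5th/95th) of a product of
several inputs.

## Descriptive and nonparametric statistics

The published form of the study data is type-level: per product type and
brewing time, the brand count, mean and SD. Two reconstructions operate on
that form:

* the size-weighted overall mean $\sum n_i \bar{x}_i / \sum n_i$, and
* the pooled sample SD via the within/between sum-of-squares decomposition
  $\sqrt{(\sum (n_i{-}1) s_i^2 + \sum n_i(\bar{x}_i - \bar{x})^2)/(N-1)}$.

A subtlety the tests encode: with the sample-SD ($n-1$) convention, pooling
$k$ groups with identical means and SDs does *not* return the common SD
$s$ but $\sqrt{\sum(n_i-1)/(N-1)}\, s < s$, because the pool spends degrees
of freedom on group means that happen to coincide. The test asserts the
value obtained by brute-force reconstruction of raw-value multisets with
matching moments, which is what the decomposition reproduces exactly.

Pairwise comparisons use the two-sided Mann–Whitney U test: the exact null
distribution when the combined sample is at most 20 with no ties (the
regime of 2–5 brands per type; cross-checked in tests against complete
enumeration of all labelings), otherwise the tie-corrected normal
approximation *without* continuity correction — the convention of the major
statistical packages, and the choice under which two identical samples give
$p = 1$ exactly. No multiple-testing correction is applied by default (the
source analysis applied none); a Holm adjustment is available by flag.

## Censoring policy for rank correlation

Water-chemistry fluoride below the 0.02 mg/L detection limit is carried as
a first-class censored state, never silently substituted. At analysis time
`spearman_censored()` applies one of three policies: substitute the
detection limit (default), substitute half of it, or drop censored pairs.
Substitution creates ties at the substituted value, which average ranks
share.

Under the default policy, the six brewing waters give rank vectors
$(2,2,2,4,5,6)$ for initial fluoride against $(3,1,2,4,5,6)$ for mean
infusible fluoride, hence $\rho = 0.941$; initial pH orders identically to
infusible fluoride, hence $\rho = 1.0$. The source study prints the same
two numbers with the *labels swapped* (fluoride $\rho = 1$, pH
$\rho = 0.941$); its tie/censoring policy is unstated, so the package
documents its own policy, asserts the hand-rank oracle values, and does not
claim to match the published labeling.

## Monte Carlo engine and summaries

Each scenario draws all inputs independently (the source analysis states no
correlation structure; a correlation hook is an explicit non-feature rather
than a hidden default), derives $AT$ after the $ED$ draw, and evaluates CDI
and HQ per iteration. 10,000 iterations is the default, matching standard
practice for this assessment class. Summaries report the empirical 5th
percentile, mean and 95th percentile of CDI and HQ plus exceedance
probabilities, using the linear-interpolation quantile estimator (R type 7,
the spreadsheet-compatible definition, recorded in the output metadata
because other software may differ in the third decimal). By construction
$P(\mathrm{HQ} > 1) = P(\mathrm{CDI} > \mathrm{RfD})$ per draw; the tests
assert this identity exactly.

Correctness is checked against closed forms rather than against other
software: an all-point-mass scenario must propagate to the exact constant;
a lognormal concentration must shift the CDI quantiles by the scaling
property; and with all inputs lognormal, $\log \mathrm{CDI}$ is normal with
mean and variance given by the signed sums of the component log-moments
($BW$ entering negatively), so Monte Carlo percentiles at $n = 10^4$ must
sit within 2% of the analytic lognormal quantiles.

## Sensitivity analysis

The contribution-to-variance measure mirrors what the commercial tool used
in such studies computes but is defined here from first principles: for each
varying input, the Spearman rank correlation $r_i$ with the output, reported
as $\mathrm{sign}(r_i)\, r_i^2 / \sum_j r_j^2 \times 100$. Absolute
contributions sum to 100% whenever anything varies; point-mass inputs are
excluded from the normalization (contribution 0, flagged) rather than
producing NaN correlations. Sign behaviour is tested on constructed cases
($X_1 + X_2$ splits $+50/+50$, $X_1 - X_2$ splits $+50/-50$) and on the dose
model itself, where body weight's contribution is negative whenever it
varies.

## Synthetic data generator

Brand-level raw measurements are not deposited, so the generator emulates
the study's structure from its published type-level summaries: 16 brands
(5 black, 3 green, 3 oolong, 3 herbal, 2 white), triplicate measurements at
5, 10 and 20 minutes. Modeling choices:

* The published type-level SDs are treated as **between-brand** SDs; brand
  means are drawn from a normal centred on the type mean, truncated at zero.
* Each brand carries a **single latent quantile shared across brewing
  times**, so a fluoride-rich brand stays rich at every time — preserving
  the within-brand consistency visible in the study — at the cost of fewer
  effective independent draws when pooling across times.
* Within-brand replicate noise defaults to a **5% CV**, consistent with the
  small brand-level replicate SDs the study prints (type-level SD ≈ 1.10
  versus brand-level replicate SD ≈ 0.07 for black tea).

What the generator does not emulate: leaching kinetics over time beyond the
type-by-time means, leaf-size effects, analytical measurement bias, and any
brand-by-time interaction beyond the shared quantile. A green test on
synthetic data therefore establishes that the pipeline's statistics and
propagation are correct for data *shaped like* the study, not that the
study's brand-level values are recovered. Truncation at zero inflates
low-mean types slightly (about +0.03 mg/L for black tea, more for herbal
tea, whose SD is comparable to its mean); the sampling-distribution test
budgets for this explicitly.

## Reconstructed exposure scenarios

The study's exposure-factor distributions (DI, EF, ED, BW per age group)
live in supplementary tables that are not deposited. The packaged defaults
(`reference_exposure()`) are a reconstruction, and two kinds of published
information constrain it:

1. plausible national ranges for tea intake, body weight and exposure
   duration per age group (triangular, the family the study fitted); and
2. the study's *printed* sensitivity results — concentration contributing
   roughly 50–96% of output variance, exposure frequency and daily intake
   moderate shares, body weight a small negative share — which bound the
   relative spreads the unpublished distributions must have had.

An earlier draft of the defaults gave daily intake a coefficient of
variation rivaling the concentration's, contradicting (2); the spreads were
narrowed once to respect the printed constraint (DI CV ≈ 0.14–0.17, BW CV ≈
0.10–0.13) and then frozen. Because the true distributions remain unknown,
the published headline values — 95th-percentile HQ of 1.16 (children) and
1.04 (teenagers) for black tea — are *not* reproduced numerically and the
package does not claim them; tests assert only the qualitative findings
that survive any reasonable reconstruction: black tea dominates the hazard
ranking in every age group, children exceed teenagers exceed adults for the
same product, concentration ranks first in the sensitivity narrative, and
body weight's contribution is negative. The quantitative acceptance surface
is carried instead by the closed-form scenarios, where the truth is exact.

## Numerical and interface choices

* Quantiles: R type 7 everywhere, stated in outputs.
* Mode clamping in the triangular fitter guarantees a valid spec for
  heavily skewed samples.
* Degenerate inputs fail loudly with classed conditions
  (`fluorisk_error_*`): zero-variance samples for normality testing,
  all-constant inputs for sensitivity, zero-range samples for fitting.
* Scenario and distribution objects serialize to JSON (`dist_to_json()`);
  YAML is not used because no YAML parser is available in the supported
  dependency set.
* Pipeline outputs carry `#`-prefixed provenance headers (package version,
  seed, iteration count, scenario hash) and are staged in a temporary
  directory, moving into place only on success, so a failing stage never
  half-overwrites a previous report bundle.

## Known limitations

Only the ingestion route and a single fluoride source are modeled, so total
exposure is underestimated by design. Inputs are sampled independently;
correlated exposure factors (e.g. body weight with intake) would need the
correlation hook this version deliberately omits. The triangular fitter's
support estimate is biased inward for small samples. The generator's
between-brand normal-with-truncation model is a choice, not an inference —
brand-level concentration data, if they become available, should replace it.
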