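---
title: "Modeling sequential collaboration: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sequential collaboration: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcollab)
```

## The process being modeled

Sequential collaboration is the aggregation regime of collaborative online
projects: a chain of contributors, each seeing only the current entry for an
item, each deciding whether to adjust it or leave it alone. The package
provides a generative model of one such chain and of its natural competitor,
the unweighted average of independent judgments (wisdom of crowds), so that
predictions about accuracy, change behavior, and crowd size can be derived by
simulation rather than collected from participants.

The model is deliberately *not* a statistical model fitted to data. All
parameters are set a priori; simulation output is compared to empirical
phenomena at the level of qualitative patterns (which position changes most,
which chain composition ends most accurately, when averaging overtakes
chains).

## Model structure

Three building blocks generate every judgment:

1. **Plausible-value distribution.** Person $i$ holds, for item $k$, an
   internal distribution of answers they consider plausible. In the normal
   family this is $\mathrm{Normal}(T_k,\, D_k E_i)$: truth $T_k$, item
   difficulty $D_k > 0$ scaling everyone's dispersion on that item, and
   expertise $E_i = \mathrm{logistic}(E^*_i) \in (0,1)$ with latent
   $E^*_i \sim \mathrm{Normal}(0, \sigma_{E^*})$. Low values of $E_i$ mean
   *high* expertise. Independent judgments — crowd members and the first
   chain position — are single draws from this distribution.

2. **Adjust-or-maintain decision.** A presented judgment $y$ is evaluated
   through the baseline CDF $F$: the change probability is
   $P = G_i + (1-G_i)\, 4 (F(y) - \tfrac12)^2$, a parabola in cumulative
   probability that bottoms out at the personal change tendency
   $G_i = \mathrm{logistic}(G^*_i)$ exactly at the distribution median and
   approaches 1 for implausible values. $G^*_i \sim \mathrm{Normal}(-1,
   \sigma_{G^*})$; the $-1$ default encodes that contributors maintain more
   often than they change (mean tendency $\approx 0.27$). The decision is a
   single Bernoulli draw; a maintained judgment is passed through
   bit-identically.

3. **Revision.** An adjusting contributor draws from the *updated*
   distribution: mean shifted toward the presented judgment by the anchoring
   term $A = E_i (y - T_k)$ — experts barely move, novices absorb almost the
   full discrepancy — and scale multiplied by the frame-of-reference factor
   $R \le 1$, reflecting that seeing a previous judgment sharpens one's own.

Two family variants keep the same machinery but change the distribution:
the **skew-normal** $\mathrm{SN}(\xi = T_k, \omega = D_k E_i, \alpha = S_k
E_i)$, whose CDF $\Phi(z) - 2\,T(z, \alpha)$ requires Owen's T function, and
the **biased-normal**, which shifts the mean to $T_k + B_k E_i$. In both,
expertise damps the distortion: experts are less skewed and less biased.

## Default parameters and the presets

The generator's defaults are the published study conditions, frozen as named
presets (`preset_config()`):

| preset | design | family settings |
|---|---|---|
| `baseline` | 60 items, 100 chains × 4, 100 crowds × 4 | normal; $T_k = 0$, $D_k \sim U(1,5)$, $\sigma_{E^*} = \sigma_{G^*} = 1$, $R = 0.4$ |
| `long_chain_normal` | chains and crowds extended to 20 | as baseline |
| `long_chain_skew` | as long | skew-normal, $S_k = 1$ |
| `bias_skew_normal` / `_biased` / `_skewed` | 1000 chains × 20 | $D_k = 3$, $R = 0.5$; $B_k = 0.6$ or $S_k = 0.25$ |

The `bias_skew` trio is calibrated so the biased and skewed families share
the same plausible-value mean $0.6$ at $E_i = 1$ ($0.6 \approx 3 \cdot 0.2425
\cdot \sqrt{2/\pi}$ for $\alpha = 0.25$), i.e. a 20% bias in SD units —
which is what lets the simulation separate *where the mass sits* (bias)
from *how it is shaped* (skew). The published description of this design
does not state the chain length; we use 20, the long-chain design, since the
comparison is about long-run behavior, and expose the length in the
configuration.

## Numerical choices

* **Owen's T.** No installed R package provides it, so it is implemented
  from its defining integral: a fixed 64-node Gauss–Legendre rule on the
  reduced range $|a| \le 1$ (where the integrand is analytic, so the rule is
  accurate to ~1e-15) plus the standard reduction identity
  $T(h,a) = \tfrac12[\Phi(h) + \Phi(ah)] - \Phi(h)\Phi(ah) - T(ah, 1/a)$
  for $|a| > 1$, and the symmetries in $h$ and $a$. The accuracy budget
  (1e-10 in tests, observed ~1e-16) is chosen so that model-level assertions
  are limited by Monte-Carlo error, never by special-function error.
* **Skew-normal sampling** uses the exact representation
  $X = \xi + \omega(\delta |Z_0| + \sqrt{1-\delta^2} Z_1)$ — no
  accept–reject, so the RNG consumption per call is deterministic and seeded
  substreams stay aligned.
* **Scale parameter reading.** The skew-normal item rule sets
  $\omega = D_k E_i$ directly (the scale parameter, not the standard
  deviation). The alternative reading — treat $D_k E_i$ as the SD and derive
  $\omega$ — is available as `population_config(scale_rule = "sd")` for
  sensitivity checks; both reproduce the 0.6-mean calibration to one
  decimal.
* **Biased-normal change probability.** Only the distribution is specified
  for this extension; we evaluate the decision CDF as the normal centered at
  $T_k + B_k E_i$ with scale $D_k E_i$, i.e. the same "evaluate against your
  own baseline distribution" rule as the other families. Its floor therefore
  sits at the *biased* median, which is the behaviorally consistent reading.
* **Clamping.** Latent person parameters are clamped to $\pm 50$ before the
  logistic so transformed values never equal 0 or 1 in double precision
  (either would zero a scale). Under the default priors the clamp has
  probability $\sim 10^{-550}$ of binding.
* **Seeding.** One master seed generates the item set and one integer
  sub-seed per chain and per crowd; each chain runs under its own sub-seed,
  so any chain is reproducible in isolation and results are independent of
  execution order. Identical configurations give bit-identical tables.
* **Tabular output** is comma-separated UTF-8 with doubles printed at 17
  significant digits, so a write/read round trip is bit-exact.

## Dependent variables and analysis conventions

* *Accuracy* is the absolute error $|y - T_k|$ (with $T_k = 0$, just
  $|y|$); *relative accuracy* is $100\,|y - T_k| / T_k$ for positive truths.
* *Change magnitude* $|y_{rev} - y_{pres}|$ and *improvement*
  $|y_{pres} - T_k| - |y_{rev} - T_k|$ are computed **only** over trials
  where the contributor adjusted; maintained trials are excluded by
  contract, and the summary layer enforces this.
* Aggregation is items-within-contributor first, then across contributors;
  dispersion is the across-contributor SD plus a 99% normal-theory CI of
  the mean.
* The *expertise proxy* is the mean absolute error of a contributor's first
  20 independent judgments. Classification standardizes the proxy:
  "high" expertise is an error more than 1 SD *better* than the mean,
  "average" within ±1 SD, "low" beyond. (The published classification rule
  contains a typographical inequality; we read it so that the high-expertise
  group is the accurate one, which is the only reading consistent with the
  error-scaled proxy.) Labels are affine-invariant in the proxies.
* Single-step probes present $T_k + d$ for fixed offsets $d$ and record the
  deterministic change probability plus Monte-Carlo improvement conditional
  on adjusting; offset-level summaries replace any curve smoothing.
* Composed chains default to a sampled position-1 contributor; a fixed
  starting value per item is available to mirror designs that seed chains
  with preselected values.

## What the generator does and does not emulate

The simulator reproduces the structural conditions of the published designs:
population heterogeneity in expertise and change tendency, item
heterogeneity in difficulty, chain dependence through presented judgments,
and the crowd-size dynamics of averaging. It does **not** emulate features
of real collaborative data such as two-dimensional (map) judgments, opt-out
behavior, participant dropout, correlated expertise across items, or
fitted person parameters — so green tests certify the model's internal
predictions, not agreement with any human dataset. Predictions are
one-dimensional and symmetric in the normal family by construction.

## Problem sizes

Test and script runs use the published design sizes where they are cheap
(the 24,000-trial baseline runs in about a second) and the full long-chain
designs (100 chains × 20 positions × 60 items). The composition analysis
uses 200 chains per composition from a classified pool of 8,000
contributors, enough that the 99% CIs of the extreme compositions do not
overlap; the probe uses 1,000 contributors at five offsets. The 1000-chain
`bias_skew` presets are exposed at full size but exercised at reduced size
in the test suite, since their headline quantity (the 0.6 mean, 20% of SD)
is analytic.

## Known limitations

* $P$ saturates at 1 in double precision for extreme presented judgments;
  monotonicity in the offset is strict only below the saturation point.
* The skew-normal median used by the floor property has no closed form and
  is located numerically where needed.
* Change probability for the biased-normal family is a modeling decision
  (see above), as the extension's decision rule is not fully specified in
  the source design.
* Crowd members are exchangeable; running averages use sampling order, and
  any other exchangeable order is statistically equivalent.
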