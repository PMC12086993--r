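---
title: "Yield–density models for addition-series competition experiments"
author: "addseries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Yield–density models for addition-series competition experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addseries)
```

## The design and the model

An addition series crosses planting density and species proportion in a
single greenhouse experiment: monocultures of each species over a density
ladder (here 1, 2, 4, 8, 16 plants per pot), plus two-species pots at all
pairs of intermediate densities (2, 4, 8), replicated (4 times by default).
Because density and proportion vary simultaneously, per-plant ("per
capita") biomass can be decomposed into intraspecific and interspecific
density dependence — something neither a pure density series nor a
replacement series can do.

`addseries` implements this analysis for the two-species case, with species
codes `BRTE` (*Bromus tectorum*, downy brome) and `VEDU` (*Ventenata
dubia*, ventenata), two co-occurring invasive winter annual grasses; the
machinery is generic for any two annual plants measured the same way.

Mean per-plant biomass in monoculture follows the hyperbolic yield–density
law

$$ w = w_m \, (1 + aN)^{-b}, $$

where $w_m$ (g) is the biomass of an isolated plant, $N$ is the *realized*
density at harvest (plants per pot, counting the focal plant), $a$ is the
per-plant crowding coefficient (interpretable as the area a plant needs to
reach $w_m$), and $b$ is a dimensionless exponent often read as a species'
resource-use efficiency. In a two-species stand the crowding term splits
into conspecific and allospecific parts:

$$ w_B = w_{mB}\,(1 + \beta_B N_B + \alpha_{BV} N_V)^{-b_B}, $$

and symmetrically for the second species. $\beta$ is the intraspecific and
$\alpha$ the interspecific competition coefficient, both per plant.

All fitting happens on the natural-log scale (the multiplicative-error
form), by nonlinear least squares:

$$ \ln w = \ln w_m - b \ln(1 + aN) + \varepsilon, \qquad
   \varepsilon \sim \mathcal N(0, \sigma^2). $$

The analysis is two-stage: the monoculture data determine $(w_m, a, b)$ per
species; the biculture data are then fit for $(w_m, \beta, \alpha)$ with
the exponent $b$ *fixed* at the focal species' monoculture estimate, so the
shape of the density response is shared between stand types. Wald standard
errors, $t$ statistics and two-sided $p$ values (Student-$t$, residual df)
are reported on the natural scale, matching the conventional coefficient
tables for this design.

Two derived quantities summarise the fits:

* the **decline threshold** $N^\ast = ((1-f)^{-1/b} - 1)/c$, the neighbour
  density at which per-capita biomass has fallen by a fraction $f$ (50% and
  75% by default), computed one coefficient $c \in \{\beta, \alpha\}$ at a
  time with the other species held at zero density;
* the **relative competitive ability** $\mathrm{RCA} = \beta/\alpha$, whose
  reciprocal is the *density equivalence*: the number of allospecific
  plants whose effect equals one conspecific. $\mathrm{RCA} < 1$ means a
  species suffers more from the other species than from itself.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `wm` | g | 0.113 (BRTE), 0.02808 (VEDU) | isolated-plant biomass at published magnitudes |
| `b` | — | 0.96848, 0.96730 | published exponents, both close to the classical value 1 |
| `beta` | per plant | 0.1309, 0.57514 | published intraspecific coefficients |
| `alpha` | per plant | 5.6387, 1.88184 | published interspecific coefficients |
| `sigma_log` | log-g | 0.5 | calibrated so simulated pseudo-$r^2$ spans ~0.2–0.6, the realistic range for such fits |
| `survival_p` | — | 0.9 | per-plant survival to harvest; makes full 16-plant pots rare, as observed in practice |
| `k` (fences) | — | 1.5 | conventional Tukey multiplier |
| `n_boot` | — | 10000 | percentile bootstrap resolution |

## What the generator emulates — and what it does not

`simulate_addition_series()` draws one pot per composition and replicate,
kills each planted plant independently with probability `1 - survival_p`
(so realized density is Binomial), and gives each surviving plant biomass
equal to the two-species model mean at the pot's *realized* densities times
$e^\varepsilon$ with $\varepsilon \sim \mathcal N(0, \sigma_{\log}^2)$ —
multiplicative lognormal noise, the conjugate assumption for a log-scale
fit. Biomass is kept at full precision in memory and quantized to 0.001 g
(floored at 0.001) only when written to CSV, mirroring balance accuracy.

Conventions worth stating explicitly:

* $N$ counts the focal plant. The generator and the fitters agree on this;
  any mismatch would break the exact-recovery property below.
* Taken literally, the model gives an isolated plant
  $w(N{=}1) = w_m (1+\beta)^{-b} \ne w_m$; $w_m$ is the $N \to 0$
  intercept, not the observed mean of singletons. The generator follows
  the algebra.
* Not emulated: germination-timing differences, spatial arrangement within
  pots, density-dependent mortality, belowground interactions. Tests that
  pass on generated data therefore validate the *estimation machinery*
  under the stated stochastic model, not the field realism of that model.

With `sigma_log = 0` and `survival_p = 1` the pipeline is an exact inverse
of the generator: every fitted parameter returns the generating value to
within $10^{-6}$ relative error. This is the package's core correctness
property and is enforced in the test suite for 20 random parameter draws.

## Identifiability: where this likelihood degenerates

The hyperbola's least-squares surface has well-known soft directions, and
at realistic noise they are not rare corner cases:

* **Monoculture ridge.** As $a \to 0$, $b \to \infty$ with $ab$ constant,
  the model tends to the log-linear limit $\ln w = \ln w_m - (ab)N$. When
  the data do not resolve curvature, the SSE decreases monotonically along
  this ridge and no interior optimum exists. `fit_monoculture()` detects
  this by profiling: for fixed $a$ the model is linear in the remaining
  parameters, so a grid over $\log a$ maps the whole profile cheaply. On a
  ridge the bare fitter raises a rank-deficiency error;
  `on_degenerate = "fix_b"` instead falls back to the reciprocal-yield
  special case $b = 1$ (the classical constant-final-yield exponent, and
  close to both published estimates), re-fits the crowding coefficient, and
  flags the fit.
* **Biculture zero boundary.** The coefficients are constrained
  non-negative; when a weak coefficient's optimum is at zero the fit holds
  it on the boundary, reports it as exactly 0 with `NA` inference, and
  re-estimates the rest (`boundary` field). The corresponding decline
  threshold is reported as an explicit infinity.
* **Biculture scale ridge.** With a free intercept, multiplying
  $(\beta, \alpha)$ by $k$ and $w_m$ by $k^{\,b}$ changes the fit only
  through the "+1" of the crowding term. When every pot is strongly
  crowded that term is unresolved and the optimum runs to the power-law
  limit with only coefficient ratios identified; this raises a
  rank-deficiency error.

The profiled grid start matters even away from these boundaries: a plain
single start frequently stalls on the monoculture ridge when an interior
global optimum exists.

### The intercept convention

Two conventions for $w_m$ are supported. `wm_mode = "estimate"` (default)
treats it as a free parameter — the generative-model reading, required for
exact zero-noise recovery. `wm_mode = "mean"` fixes the intercept at the
group's mean observed biomass (a plug-in, reported with zero variance).
The plug-in convention is common in practice — published intercepts for
this design typically equal the printed group means — and it anchors the
model's overall scale, which removes the biculture scale ridge entirely;
its cost is that the plug-in is a biased estimate of the true $w_m$
whenever plants are crowded, which propagates into the coefficients. The
pipeline exposes the choice as `fit$wm_mode`.

## Outlier screening

Extreme values (attributable to recording or collection mistakes in real
data) are screened per group — species crossed with experiment type
(monoculture vs biculture), classification by *planted* composition — with
Tukey fences $[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ on the
raw gram scale, quartiles by linear interpolation (type 7, recorded in the
report so counts can be sensitivity-checked under other conventions).
Fences are pooled across densities within each group.

On *synthetic* lognormal data this pooled raw-scale filter is aggressive:
group biomass spans several-fold between density classes, so the upper
fence preferentially removes high-biomass records from low-density pots
and measurably attenuates fitted coefficients (on deterministic data it
can remove entire density classes). The pipeline therefore exposes
`filter$enabled`; it defaults to on (the field procedure), but simulation
studies in this package run unfiltered, since generated records contain no
recording mistakes. This divergence is a deliberate, documented choice,
not an accident of the tests.

## Uncertainty propagation for thresholds

The threshold point estimate is the analytic plug-in inversion at the
fitted coefficients. Its confidence interval is a parametric bootstrap:
parameter vectors are drawn from a multivariate normal centred at the
*internal* (log-scale) estimates with the fitted covariance — so every
draw yields positive coefficients — the threshold is recomputed per draw,
and the 2.5% and 97.5% percentiles are reported. Percentile intervals
accommodate the strong right skew of a reciprocal of a small coefficient.
For biculture fits the fixed exponent is held constant across draws: the
two-stage procedure conditions on $b$, and its monoculture-stage
uncertainty is deliberately not propagated (a stated limitation, see
below).

## What the simulation studies show

The test suite includes a coverage study at the default study conditions
(4 replicates, $\sigma_{\log} = 0.5$, survival 0.9): 500 simulated
experiments, biculture fits with the exponent at its generative value,
unfiltered data, coverage evaluated conditionally on interior fits
(boundary and ridge outcomes — a substantial fraction at these conditions
— are tallied separately). Estimation-scale Wald intervals for $\beta$ and
$\alpha$ and percentile-bootstrap intervals for the 50%-decline thresholds
all attain empirical coverage within [0.90, 0.99] there.

Two honest negative results, found while building the package and worth
knowing before trusting any single fit:

* **Two-stage $b$ is fragile at these conditions.** When the monoculture
  stage's $b$ is noisy (its identifiability is weak whenever intraspecific
  crowding is mild), fixing the biculture exponent at that estimate biases
  $\beta$ and $\alpha$ and collapses their Wald coverage far below
  nominal. The procedure is faithful to field practice, but its inference
  should be read conditionally on a well-determined exponent.
* **Joint recovery of all six competition parameters in one default-sized
  experiment is unreliable**: boundary and ridge outcomes plus the above
  interact so that a single 76-pot experiment at realistic noise often
  cannot support the full two-stage analysis. Larger replication or an
  anchored intercept mitigate this.

## Numerical choices

Levenberg–Marquardt (with analytic Jacobians) on log-parameterized
internals; convergence tolerances $10^{-12}$ on relative SSE and parameter
change, at most 1024 iterations and 10 deterministic jittered restarts;
profiled grid starts over $\log a \in [-14, 8]$ (step 0.25) and
$\log\beta, \log\alpha \in [-13, 7]$ (step 0.5), with the grid edges
doubling as degeneracy detectors. Covariances come from the Jacobian at
the optimum scaled by residual variance; natural-scale standard errors by
the delta method. All randomness flows from one master seed split
deterministically per pipeline stage, so identical configurations produce
byte-identical result bundles. Problem sizes in the test suite (500
coverage replicates, 300 bootstrap-coverage replicates with 1000 draws
each, 20 oracle datasets) were chosen to keep the full suite within a few
minutes while leaving Monte-Carlo error well inside the asserted bands.

## Limitations

No mixed-effects structure (pot or replicate random effects) — fits pool
plants within pots, as is conventional for this design; no raw-scale
heteroscedastic fitting; no more-than-two-species stands; no spatial or
phenological structure. The pseudo-$r^2$ is $1 - \mathrm{SSE}/\mathrm{SST}$
on the log scale; other definitions exist and would give different values
for the same fit.
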