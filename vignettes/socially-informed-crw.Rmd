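---
title: "Inferring social interaction rules with socially informed correlated random walks"
author: "socialcrw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring social interaction rules with socially informed correlated random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Collectively moving animals — migrating ungulate herds are the motivating
system — make fine-scale movement decisions under three kinds of influence:
where they were already going (directional persistence), features of the
environment such as trails or obstacles, and the positions and headings of
their neighbours. `socialcrw` implements a discrete-time, continuous-space
framework for separating these influences from trajectory data alone and for
deciding *which mathematical form* of social interaction best describes a
group.

Trajectories are discretised into movement steps of fixed duration $\Delta t$
(2 s by default). The heading $\theta_t$ of each step is modelled as a draw
from a wrapped Cauchy distribution,

$$f(\theta_t \mid \lambda_t, \rho) \;=\; \frac{1}{2\pi}\,
  \frac{1-\rho^2}{1+\rho^2-2\rho\cos(\theta_t-\lambda_t)},$$

whose concentration $\rho \in [0,1)$ measures how predictable movement is
($\rho = 0$ is a uniform heading, $\rho \to 1$ deterministic). The expected
heading $\lambda_t$ is a weighted circular average of three unit vectors,

$$\lambda_t \;=\; \arg\big[\,\alpha\,\hat u(\psi_t) + \beta\,\hat u(\phi_t)
  + \gamma\,\hat u(\theta_{t-1})\,\big], \qquad \alpha+\beta+\gamma = 1,$$

where $\psi_t$ is the heading indicated by neighbours (the *social* heading),
$\phi_t$ an estimate of environmental pathways, and $\theta_{t-1}$ the
previous heading. Taking $\alpha=\beta=0$ recovers the plain correlated
random walk.

The averaging rule for angles is a genuine design choice: arithmetic
averaging of angles is ill-defined across the $\pm\pi$ cut, so we take the
argument of the convex combination of unit vectors — the standard circular
weighted mean. A social or environmental term that is missing or degenerate
at a given step hands its weight to persistence (which is always defined)
rather than renormalising over the remaining terms; this keeps the
combination convex without inventing signal, and is switchable in principle
because it is isolated in one function (`expectedHeading()`).

### Candidate interaction rules

Eight models are compared, named by their specification strings:

| spec | social | env | neighbour weighting |
|------|--------|-----|---------------------|
| `rw` | – | – | none (correlated random walk) |
| `env` | – | yes | none |
| `metric`, `metric+align` | yes | yes | equal within a range $r$ |
| `topo`, `topo+align` | yes | yes | equal for the $K$ nearest |
| `expdecay`, `expdecay+align` | yes | yes | $e^{-d/\ell}$ ("local crowded horizon") |

With weights $w_i$ from the chosen kernel, the attraction resultant is
$A=\sum_i w_i \hat u(x_i - x_f)$ and the alignment resultant
$G=\sum_i w_i \hat u(\theta_i)$. Alignment models blend the two as
$V = (1-a)\hat A + a\hat G$ with a single *alignment strength*
$a \in [0,1]$; $\psi = \arg V$. This convex combination of the
**normalised** resultants is the key structural reconstruction in the
package: it makes $a$ interpretable as the relative reliance on copying
headings versus maintaining proximity, applies one distance kernel to both
terms, and is deliberately confined to `socialHeading()` so alternative
compositions can be swapped in. Distance ties in the topological rule are
broken lexicographically by individual id, making the rule deterministic.

### The environmental heading

Environmental features are not observed directly. Following the
track-derived approach used for this class of data, $\phi_t$ is estimated
as the average heading of all herd members crossing each fixed cell of
space (5 m cells by default, roughly 2–3 body lengths), always excluding
the focal individual (`attachEnvGrid()`). The field is static over the
observation period — tracks here are minutes long, so time-windowing would
only thin the estimate. Whether cells pool across herds is configurable
(`pool`); herd-specific fields are the default since herds may use
different pathways.

## Inference

Priors are flat on the constrained scale: $(\alpha,\beta,\gamma)$ uniform on
the simplex, $\rho$ and $a$ uniform on the unit interval, $r$ and $\ell$
uniform on $(0, 100)$ m. The source data for this kind of analysis never
constrains these parameters near their bounds, so the bounds are just
numerical guard rails; all are configurable through `priorSpec()`.

Sampling is adaptive random-walk Metropolis on an unconstrained scale
(additive log-ratio for the simplex, logit for $\rho$ and $a$, scaled logit
for $r$ and $\ell$), targeting an acceptance rate of about 0.23. Each fit
first locates the posterior mode with a restarted Nelder–Mead search and
starts every chain from a jittered copy of the mode: at the data sizes of
interest the posterior is extremely concentrated, and without this step a
chain initialised in a flat tail can spend its whole budget travelling.
Per-coordinate proposal widths are re-estimated from the chain history at
three points during burn-in (with a floor, so a slow coordinate can never
freeze itself) and adaptation stops at the end of burn-in, so retained draws
target the exact posterior. Convergence is summarised by split-$\hat R$ per
parameter and **flagged, not enforced** (a warning at $\hat R > 1.1$).

The topological neighbour count $K$ is a small integer, so it is profiled
over a grid (default $1,\dots,10$) rather than sampled trans-dimensionally;
`fitCompare()` fits each $K$ and keeps the WAIC-best. Per-class fits
(`fitByClass()`) partition steps by the *focal* individual's demographic
class — calf, adult, large bull — keeping neighbours of every class, and are
fully independent (no partial pooling), so class posteriors can be compared
directly.

## Model comparison

Models are ranked with two predictive information criteria computed from the
stored draws-by-steps log-likelihood matrix: WAIC, with the sample-variance
penalty ($p_{\text{WAIC}2}$), and DIC, with the deviance evaluated at the
posterior mean of the parameters taken on the unconstrained sampling scale
(the mean of simplex weights taken naively need not respect the simplex).
The data-point unit for both is one movement step — the natural
exchangeable unit given the per-step likelihood. `compareModels()` reports
both criteria side by side, differenced against the `rw` baseline, with a
flag wherever the two rankings disagree.

## The simulator and what validation shows

Because the step-heading model is generative, the package ships an
agent-based simulator (`simHerds()`) that draws each agent's heading from
exactly the distribution the likelihood evaluates, records every expected
heading in a ground-truth sidecar, and emits fixes on the $\Delta t$ grid so
that discretisation reconstructs each decision context exactly (the test
suite verifies the recorded $\lambda_t$ to $10^{-9}$).

Default conditions mirror the structure of observed migrating-herd track
data: herds of 15 individuals (up to ~50 supported), 2 s steps at a constant
1.2 m/s (so ~2.4 m displacements against ~2 m nearest-neighbour spacings),
strongly aligned line-forming motion, and the reference parameter set
$\alpha=0.5$, $\beta=0.2$, $\gamma=0.3$, $\rho=0.8$, $\ell=5$ m, $a=0.6$
under `expdecay+align`. Speed is *not* part of the likelihood (heading-only,
as in the modelling tradition this follows), so a constant speed loses
nothing. Initial conditions place agents uniformly in a disc of radius
$2\sqrt{n}$ m with headings spread around a common direction; the plane is
boundary-free (a migration context, not an arena) and there is no body-size
exclusion zone.

The default environmental field is a smooth random vector field with a 50 m
correlation length, built from random Fourier modes (`makeEnvField()`; a
uniform direction and a circular trail are also available). A *spatially
varying* field is what makes $\alpha$, $\beta$ and $\gamma$ separately
identifiable in validation: under a uniform field an aligned herd's social,
environmental and persistence headings all coincide and the weights are
confounded.

Validation experiments in the test suite (problem sizes chosen as a
practical single-CPU budget):

* **Parameter recovery** at the reference conditions (20 herds × 15 agents
  × 150 steps, ~44,000 usable steps): posterior means of all six parameters
  land within ±0.1 of truth in at least 9 of 10 seeded replicates — in
  practice within ±0.03. These fits attach the generator's *true*
  environmental headings, isolating the estimator from the quality of the
  track-derived field reconstruction (which carries a social confound: herd
  members' tracks are what define the field).
* **Model-selection recovery** (4 herds × 12 agents × 110 steps, $K$ grid
  1–3): the generating `expdecay+align` model is WAIC-best among all eight
  in ≥7/10 replicates, and on persistence-only data the random walk stays
  in the top two in ≥7/10.
* **Class variation** (~5,000 steps per class): simulated calves
  (high $\alpha$, low $a$) and adults (lower $\alpha$, higher $a$) yield
  correctly ordered, non-overlapping 95% credible intervals, while an
  identical-class negative control shows overlapping intervals in ≥8/10
  replicates.
* **Interval robustness**: the full eight-model comparison runs at
  $\Delta t = 1,\dots,10$ s and is byte-reproducible under a fixed seed.

What passing these tests does **not** show: real tracks contain detection
gaps, position noise, fission–fusion events, time-varying behaviour and
unmodelled speed variation, none of which the generator emulates. The
validation demonstrates that the estimator is correct *under the model*,
not that the model is correct for any particular species.

## Numerical choices and degenerate inputs

* Angles are radians in $(-\pi,\pi]$ throughout; degrees appear only in
  reporting surfaces such as `headingChangeDist()`.
* Displacements below 0.05 m (below typical position-noise scale) define no
  heading; such intervals leave the likelihood but the individual still
  appears in neighbour snapshots. Gaps longer than $2\Delta t$ split a
  track rather than bridging through an occlusion; resampling is linear
  with no extrapolation. Track starts have no $\theta_{t-1}$ and are
  excluded, not imputed.
* A social resultant shorter than $10^{-9}$ (no neighbours, or opposing
  neighbours cancelling) is treated as "no social signal"; similarly a
  heading-grid cell with no non-focal contributions, or a cancelling
  resultant, returns a missing $\phi_t$.
* `headingChangeDist()` requires ≥30 steps and reports a degeneracy flag
  with the fitted spread at its lower bound when all changes are identical.
* The wrapped Cauchy sampler uses the closed-form inverse CDF; the density
  is evaluated in log space via `log1p`.

## Known limitations

Parameters are constant over time and (except for class partitions) over
individuals; there are no random effects, no speed model, no repulsion
zone, no occlusion or blind-angle weighting, and no cross-herd
interactions. The track-derived environmental field inherits a social
signal by construction — where the herd goes is partly where neighbours
went — so $\beta$ on real data should be read as "use of shared pathways",
not purely abiotic influence.
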