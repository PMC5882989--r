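# socialcrw

Inferring the rules of social interaction from trajectories of collectively
moving animals.

Groups of migrating animals — ungulate herds are the motivating system —
make movement decisions under three influences: directional persistence,
environmental pathways, and their neighbours. Given simultaneous tracks of
every individual in a group, `socialcrw` separates these influences and asks
*which mathematical form* of social interaction best describes the group:
a **metric** zone (all neighbours within a radius count equally), a
**topological** rule (the K nearest neighbours count), or an
**exponentially decaying** weighting with distance, each with or without an
**alignment** force on top of attraction.

## The model

Trajectories are discretised into movement steps of duration Δt (default
2 s). Each step heading θ_t is a draw from a wrapped Cauchy distribution

    f(θ_t | λ_t, ρ) = (1/2π) · (1 − ρ²) / (1 + ρ² − 2ρ·cos(θ_t − λ_t)),

centred on an expected heading composed as a weighted circular mean

    λ_t = arg[ α·û(ψ_t) + β·û(φ_t) + γ·û(θ_{t−1}) ],   α + β + γ = 1,

where ψ_t is the social heading under one of the candidate interaction
rules, φ_t is a track-derived environmental heading (the leave-one-out
average heading of herd members crossing each cell of space), and θ_{t−1}
is the previous heading. α = β = 0 recovers the plain correlated random
walk. Eight candidate models (`rw`, `env`, `metric`, `topo`, `expdecay`,
and the three `+align` variants) are fitted by adaptive Metropolis MCMC
under flat priors and ranked by WAIC and DIC against the `rw` baseline.

A built-in agent-based herd simulator draws each agent's heading from
exactly the distribution the likelihood evaluates and records the ground
truth, so the whole pipeline is validated by parameter recovery and
model-selection recovery on synthetic herds. See the vignette
(`vignettes/socially-informed-crw.Rmd`) for the full account.

## Worked example

Simulate four herds under the exponential-decay + alignment rule
(α = 0.5, β = 0.2, γ = 0.3, ρ = 0.8, ℓ = 5 m, a = 0.6), discretise, and
refit the generating model:

```r
library(socialcrw)

cfg   <- simConfig(nHerds = 4, herdSize = 12, nSteps = 120, seed = 11)
sim   <- simHerds(cfg)
steps <- attachEnvTruth(discretize(sim$traj, dt = 2), sim)
steps
#> Discretised movement steps (dt = 2 s)
#>   5760 steps, 5712 usable for likelihood (theta and theta_prev defined)
#>   4 herd(s), 48 individuals, 63360 neighbour records
#>   environmental heading: 5760 steps

fitModel(steps, "expdecay+align",
         mcmc = mcmcControl(chains = 2, iter = 1200, burn = 500, seed = 1))
#> Movement model fit: 'expdecay+align'
#>   5712 steps, 700 stored draws, 2 chain(s); mean acceptance 0.32
#>   alpha  mean   0.503   95% CrI [  0.494,   0.513]
#>   beta   mean   0.194   95% CrI [  0.184,   0.202]
#>   gamma  mean   0.303   95% CrI [  0.294,   0.311]
#>   rho    mean   0.805   95% CrI [  0.799,   0.811]
#>   a      mean   0.602   95% CrI [  0.596,   0.608]
#>   ell    mean   5.131   95% CrI [  4.894,   5.382]
```

Every posterior mean sits on its generating value. Comparing a subset of
candidate models on the same steps ranks the generating rule first, with
the score differences reported against the random-walk baseline (lower is
better, so large negative deltas are large improvements):

```r
res <- fitCompare(steps, models = c("rw", "env", "expdecay", "expdecay+align"),
                  mcmc = mcmcControl(chains = 1, iter = 700, burn = 300,
                                     seed = 2, maxStore = 150))
res$table
#> Model comparison (lower scores better; deltas vs 'rw' baseline)
#>           model social K    waic   dWAIC rankWAIC     dic    dDIC rankDIC
#>  expdecay+align      Y    9053.8 -6561.5        1  9053.1 -6562.4       1
#>        expdecay      Y   12675.8 -2939.6        2 12674.6 -2940.9       2
#>             env      N   14062.3 -1553.1        3 14061.5 -1554.0       3
#>              rw      N   15615.4     0.0        4 15615.5     0.0       4
```

Descriptive diagnostics work on any discretised step set: per-step
heading-change distributions with a Gaussian fit (`headingChangeDist`),
heading autocorrelation (`headingAutocorrelation`), focal-frame
relative-position, circular-variance and orientation maps
(`relativePositionHeatmap`, `circularVarianceMap`,
`orientationProjectionMap`), neighbour-influence maps at the fitted
parameters (`influenceMap`), and model-performance-versus-distance curves
(`performanceVsDistance`). Real data enter through `readTrajectories()`
(CSV with columns `herd_id,individual_id,t,x,y[,class]`);
`fitByClass()` fits demographic classes separately, and `dtSweep()` checks
robustness of the ranking across discretisation intervals of 1–10 s. A
command-line wrapper lives at `inst/scripts/run_pipeline.R`.

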