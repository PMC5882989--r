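test_that("parameter container enforces the simplex and consistency", {
  expect_error(modelParams(0.5, 0.2, 0.2, 0.5), "equal 1")
  expect_error(modelParams(0, 0, 1, 1), "rho")
  # alpha = 0 iff no interaction form
  expect_error(modelParams(0.5, 0.2, 0.3, 0.5), "alpha")
  expect_error(modelParams(0, 0.5, 0.5, 0.5,
                           interactionModel("metric", r = 5)), "alpha")
  p <- modelParams(0, 0.4, 0.6, 0.3)
  expect_s3_class(p, "model_params")
})

test_that("expected heading reduces to each pure influence", {
  crw <- modelParams(0, 0, 1, 0.5)
  expect_equal(expectedHeading(crw, NA, 0, NA, 0.7), 0.7)   # persistence
  soc <- modelParams(1, 0, 0, 0.5,
                     interactionModel("metric", r = 5))
  expect_equal(expectedHeading(soc, pi / 2, 1, NA, 0), pi / 2)
  env <- modelParams(0, 1, 0, 0.5)
  expect_equal(expectedHeading(env, NA, 0, -1.2, 0), -1.2)
  # equal-weight bisector
  half <- modelParams(0.5, 0, 0.5, 0.5,
                      interactionModel("metric", r = 5))
  expect_equal(expectedHeading(half, pi / 2, 1, NA, 0), pi / 4)
})

test_that("missing terms hand their weight to persistence", {
  p <- modelParams(0.5, 0.2, 0.3, 0.5,
                   interactionModel("expdecay", ell = 5))
  # no social signal: weight goes to theta_prev, phi still counts
  lam <- expectedHeading(p, NA, 0, 0.4, 0)
  # alpha+gamma = 0.8 on heading 0, beta = 0.2 on 0.4
  expect_equal(lam, atan2(0.2 * sin(0.4), 0.8 + 0.2 * cos(0.4)))
  # both missing: pure persistence
  expect_equal(expectedHeading(p, NA, 0, NA, 1.1), 1.1)
  # degenerate social magnitude triggers the same redistribution
  expect_equal(expectedHeading(p, 2, 1e-12, NA, 1.1), 1.1)
})

test_that("step log-likelihood limits and invariances hold", {
  st <- midSteps()
  # rho = 0: uniform density regardless of all other parameters
  p0 <- modelParams(0.5, 0.2, 0.3, 0,
                    interactionModel("expdecay", alignment = TRUE,
                                     ell = 5, a = 0.6))
  ll <- stepLoglik(p0, st)
  expect_true(all(abs(ll - log(1 / (2 * pi))) < 1e-12))
  # permutation invariance of the total
  p <- midParams()
  ll1 <- sum(stepLoglik(p, st))
  set.seed(5)
  perm <- sample(nrow(st$steps))
  st2 <- herdSteps(st$steps[perm, ], st$nb, dt = st$dt)
  expect_equal(sum(stepLoglik(p, st2)), ll1, tolerance = 1e-9)
})

test_that("compiled likelihood equals the pure-R reference", {
  st <- midSteps()
  sub <- socialcrw:::.filterSteps(st, st$steps$step_id[1:300])
  for (p in list(midParams(),
                 modelParams(0, 0, 1, 0.7),
                 modelParams(0, 0.3, 0.7, 0.5),
                 modelParams(0.6, 0.1, 0.3, 0.9,
                             interactionModel("metric", r = 4)),
                 modelParams(0.4, 0.2, 0.4, 0.6,
                             interactionModel("topological", K = 2)))) {
    expect_equal(stepLoglik(p, sub), socialcrw:::.stepLoglikR(p, sub),
                 tolerance = 1e-12)
  }
})

test_that("total log-likelihood is invariant under global rotation", {
  sim <- midSim()
  p <- midParams()
  st <- attachEnvTruth(discretize(sim$traj, dt = 2), sim)
  ll0 <- sum(stepLoglik(p, st))
  phi <- 0.83
  st2 <- discretize(rotateTraj(sim$traj, phi), dt = 2)
  st2$steps$phi <- wrapAngle(st$steps$phi + phi)   # rotate the field too
  expect_equal(sum(stepLoglik(p, st2)), ll0, tolerance = 1e-9)
})

test_that("the likelihood peaks at the generating parameters", {
  st <- midSteps()
  p <- midParams()
  ll0 <- sum(stepLoglik(p, st))
  perturb <- list(
    modelParams(0.7, 0.1, 0.2, 0.8, p$interaction),
    modelParams(0.3, 0.3, 0.4, 0.8, p$interaction),
    modelParams(0.5, 0.2, 0.3, 0.6, p$interaction),
    modelParams(0.5, 0.2, 0.3, 0.95, p$interaction),
    modelParams(0.5, 0.2, 0.3, 0.8,
                interactionModel("expdecay", alignment = TRUE,
                                 ell = 10, a = 0.6)),
    modelParams(0.5, 0.2, 0.3, 0.8,
                interactionModel("expdecay", alignment = TRUE,
                                 ell = 5, a = 0.4)))
  for (q in perturb) expect_lt(sum(stepLoglik(q, st)), ll0)
})

test_that("profile likelihood in rho is maximised near the generating value", {
  st <- rwSteps()
  rhos <- seq(0.6, 0.95, by = 0.025)
  prof <- vapply(rhos, function(r)
    sum(stepLoglik(modelParams(0, 0, 1, r), st)), 0)
  expect_lt(abs(rhos[which.max(prof)] - 0.8), 0.05)
})
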