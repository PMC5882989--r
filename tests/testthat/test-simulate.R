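test_that("environment fields honour their definitions", {
  f <- makeEnvField("uniform", direction = 0)
  expect_equal(f(c(0, 100, -3), c(5, -2, 0)), c(0, 0, 0))
  g <- makeEnvField("trail", centre = c(0, 0))
  expect_equal(g(10, 0), pi / 2)      # counterclockwise tangent at (r, 0)
  expect_equal(g(0, 10), pi)
  expect_error(makeEnvField("volcano"), "unknown")
  # deterministic given seed, and does not disturb the global RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1)
  h <- makeEnvField("smooth", L = 50, seed = 7)
  expect_equal(runif(1), x1)
  h2 <- makeEnvField("smooth", L = 50, seed = 7)
  pts <- cbind(runif(20, -100, 100), runif(20, -100, 100))
  expect_equal(h(pts[, 1], pts[, 2]), h2(pts[, 1], pts[, 2]))
  expect_true(all(is.finite(h(pts[, 1], pts[, 2]))))
})

test_that("smooth fields decorrelate beyond their correlation length", {
  # headings at two points 10 L apart, compared across 200 field seeds
  h1 <- h2 <- numeric(200)
  for (s in 1:200) {
    f <- makeEnvField("smooth", L = 5, seed = 3000 + s)
    h1[s] <- f(0, 0); h2[s] <- f(50, 0)
  }
  expect_lt(abs(mean(cos(h1 - h2))), 0.1)
  # and correlate strongly well inside it
  h3 <- h4 <- numeric(200)
  for (s in 1:200) {
    f <- makeEnvField("smooth", L = 5, seed = 3000 + s)
    h3[s] <- f(0, 0); h4[s] <- f(0.25, 0)
  }
  expect_gt(mean(cos(h3 - h4)), 0.9)
})

test_that("persistence-only limits behave as expected", {
  # rho near 1: near-straight lines, autocorrelation ~ 1 at all lags
  sim1 <- simHerds(simConfig(nHerds = 1, herdSize = 5, nSteps = 100,
                             model = "rw",
                             params = list(alpha = 0, beta = 0, gamma = 1,
                                           rho = 0.999),
                             envField = NULL, seed = 5))
  ac <- headingAutocorrelation(discretize(sim1$traj, dt = 2), maxLag = 20)
  expect_true(all(ac$correlation > 0.98))
  # rho = 0: i.i.d. uniform headings
  sim0 <- simHerds(simConfig(nHerds = 1, herdSize = 5, nSteps = 500,
                             model = "rw",
                             params = list(alpha = 0, beta = 0, gamma = 1,
                                           rho = 0),
                             envField = NULL, seed = 6))
  st <- discretize(sim0$traj, dt = 2)
  dth <- wrapAngle(st$steps$theta - st$steps$theta_prev)
  expect_lt(abs(mean(cos(dth), na.rm = TRUE)), 0.05)
})

test_that("social interaction raises group polarization over the matched control", {
  polSoc <- polCtl <- numeric(20)
  for (r in 1:20) {
    simS <- simHerds(simConfig(nHerds = 1, herdSize = 12, nSteps = 80,
                               model = "expdecay+align",
                               params = list(alpha = 0.8, beta = 0,
                                             gamma = 0.2, rho = 0.8,
                                             ell = 5, a = 0.6),
                               envField = NULL, seed = 400 + r,
                               initHeadingRho = 0))
    simC <- simHerds(simConfig(nHerds = 1, herdSize = 12, nSteps = 80,
                               model = "rw",
                               params = list(alpha = 0, beta = 0,
                                             gamma = 1, rho = 0.8),
                               envField = NULL, seed = 400 + r,
                               initHeadingRho = 0))
    # polarization over the final quarter of the run
    lastQ <- function(sim) {
      th <- sim$truth$perStep
      polarization(th$theta[th$t_start >= max(th$t_start) * 0.75])
    }
    polSoc[r] <- lastQ(simS); polCtl[r] <- lastQ(simC)
  }
  expect_gt(mean(polSoc > polCtl), 0.8)
  expect_gt(mean(polSoc), mean(polCtl))
})

test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- simConfig(nHerds = 2, herdSize = 6, nSteps = 30, seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  writeSim(simHerds(cfg), d1)
  writeSim(simHerds(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("sidecar lambda agrees with the likelihood's expected heading", {
  # the generator's recorded expected headings must be reproducible from
  # the discretised steps plus the true environmental heading: the
  # simulator and the likelihood share one model
  sim <- midSim()
  st <- attachEnvTruth(discretize(sim$traj, dt = 2), sim)
  p <- midParams()
  s <- st$steps
  ev <- which(!is.na(s$theta_prev))[1:400]
  ts <- sim$truth$perStep
  m <- match(paste(s$herd_id[ev], s$individual_id[ev], s$t_start[ev]),
             paste(ts$herd_id, ts$individual_id, ts$t_start))
  lam <- vapply(ev, function(i) {
    nb <- st$nb[st$nb$step_id == s$step_id[i], ]
    sh <- socialHeading(p$interaction, nb$rel_x, nb$rel_y, nb$heading,
                        rank = nb$rank)
    expectedHeading(p, sh$psi, sh$magnitude, s$phi[i], s$theta_prev[i])
  }, 0)
  expect_equal(wrapAngle(lam - ts$lambda[m]), rep(0, length(ev)),
               tolerance = 1e-9)
})

test_that("simulated data are most likely under the generating parameters", {
  st <- midSteps()
  base <- midParams()
  ll0 <- sum(stepLoglik(base, st))
  for (coord in c("alpha", "rho", "a")) {
    for (dlt in c(-0.2, 0.2)) {
      p <- list(alpha = 0.5, beta = 0.2, gamma = 0.3, rho = 0.8,
                ell = 5, a = 0.6)
      p[[coord]] <- p[[coord]] + dlt
      if (p[[coord]] < 0 || p[[coord]] >= 1) next
      if (coord == "alpha") p$gamma <- 1 - p$alpha - p$beta
      q <- modelParams(p$alpha, p$beta, p$gamma, p$rho,
                       interactionModel("expdecay", alignment = TRUE,
                                        ell = p$ell, a = p$a))
      expect_lt(sum(stepLoglik(q, st)), ll0)
    }
  }
})

test_that("solitary herds and class assignment plumbing", {
  sim <- simHerds(simConfig(nHerds = 1, herdSize = 1, nSteps = 40,
                            model = "rw",
                            params = list(alpha = 0, beta = 0, gamma = 1,
                                          rho = 0.8),
                            envField = NULL, seed = 9))
  st <- discretize(sim$traj, dt = 2)
  expect_equal(nrow(st$nb), 0L)
  simC <- simHerds(simConfig(nHerds = 2, herdSize = 20, nSteps = 10,
                             seed = 10,
                             classMix = c(calf = 0.4, adult = 0.6),
                             classParams = list(calf = list(alpha = 0.7))))
  expect_setequal(unique(simC$traj$class), c("calf", "adult"))
  # class overrides renormalise the remaining weights proportionally
  p <- socialcrw:::.classParams(list(alpha = 0.5, beta = 0.2, gamma = 0.3,
                                     rho = 0.8, ell = 5, a = 0.6),
                                list(alpha = 0.7))
  expect_equal(p$alpha + p$beta + p$gamma, 1)
  expect_equal(p$beta / p$gamma, 2 / 3)
})
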