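test_that("relative-position heatmap normalises and respects symmetry", {
  hm <- relativePositionHeatmap(midSteps())
  expect_equal(sum(hm$values), 1, tolerance = 1e-12)
  # mirror-symmetric configuration: neighbours at +-x (cell centres, so
  # the pair lands in mirror-image cells)
  st <- stepsFromConfigs(theta = rep(pi / 2, 50),
                         thetaPrev = rep(pi / 2, 50),
                         nbList = replicate(50, data.frame(
                           nb_id = c("l", "r"), rel_x = c(-1.5, 1.5),
                           rel_y = 0.5, heading = pi / 2),
                           simplify = FALSE))
  hm2 <- relativePositionHeatmap(st, extent = 5, cell = 1)
  expect_equal(hm2$values, hm2$values[nrow(hm2$values):1, ],
               tolerance = 1e-12)
})

test_that("line formations concentrate neighbour mass on the body axis", {
  # single-file herd moving east, 2 m spacings, with slight lateral jitter
  set.seed(61)
  tt <- seq(0, 40, by = 2)
  rows <- do.call(rbind, lapply(1:5, function(i)
    data.frame(herd_id = "h", individual_id = sprintf("i%d", i),
               t = tt, x = 2 * i + 1.2 * tt,
               y = 0.2 * sin(tt / 7 + i))))
  st <- discretize(herdTrajectory(rows), dt = 2)
  hm <- relativePositionHeatmap(st, extent = 10, cell = 0.5)
  centralCol <- abs(hm$mids) < 1
  frac <- sum(hm$values[centralCol, ])
  expect_gt(frac, 2 / 20 * 1.5)   # well above the isotropic share
})

test_that("circular variance map hits its anchor cases", {
  mk <- function(headings) stepsFromConfigs(
    theta = rep(pi / 2, length(headings)),
    thetaPrev = rep(pi / 2, length(headings)),
    nbList = lapply(headings, function(h)
      data.frame(nb_id = "n", rel_x = 0, rel_y = 3, heading = h)))
  # identical headings -> 0
  cv <- circularVarianceMap(mk(rep(1, 30)), extent = 5, cell = 1, nMin = 10)
  expect_equal(min(cv$values, na.rm = TRUE), 0, tolerance = 1e-12)
  # antipodal headings -> 1
  cv2 <- circularVarianceMap(mk(rep(c(0, pi), 15)), extent = 5, cell = 1,
                             nMin = 10)
  expect_equal(max(cv2$values, na.rm = TRUE), 1, tolerance = 1e-12)
  # uniform headings -> ~ 1
  set.seed(55)
  cv3 <- circularVarianceMap(mk(runif(1e4, -pi, pi)), extent = 5,
                             cell = 1, nMin = 10)
  expect_equal(max(cv3$values, na.rm = TRUE), 1, tolerance = 0.02)
  # bounds on real data
  cv4 <- circularVarianceMap(midSteps(), nMin = 5)
  v <- cv4$values[!is.na(cv4$values)]
  expect_true(all(v >= 0 & v <= 1 + 1e-12))
})

test_that("orientation projection is signed by approach direction", {
  # cell size 2 puts a cell centre exactly on the body axis at (0, -4)
  mk <- function(nbHeading) stepsFromConfigs(
    theta = rep(pi / 2, 30), thetaPrev = rep(pi / 2, 30),
    nbList = replicate(30, data.frame(nb_id = "n", rel_x = 0, rel_y = -4,
                                      heading = nbHeading),
                       simplify = FALSE))
  # focal heads +y; neighbour sits behind (focal-frame (0,-4))
  # moving straight at the focal: +1
  om <- orientationProjectionMap(mk(pi / 2), extent = 5, cell = 2, nMin = 10)
  expect_equal(max(om$values, na.rm = TRUE), 1, tolerance = 1e-12)
  # moving away: -1
  om2 <- orientationProjectionMap(mk(-pi / 2), extent = 5, cell = 2,
                                  nMin = 10)
  expect_equal(min(om2$values, na.rm = TRUE), -1, tolerance = 1e-12)
  # perpendicular: 0
  om3 <- orientationProjectionMap(mk(0), extent = 5, cell = 2, nMin = 10)
  v <- om3$values[!is.na(om3$values)]
  expect_equal(v, rep(0, length(v)), tolerance = 1e-12)
})

test_that("influence maps trace their kernels and stay isotropic", {
  im <- influenceMap(interactionModel("expdecay", ell = 5), extent = 10,
                     cell = 0.5)
  d <- sqrt(outer(im$mids^2, im$mids^2, "+"))
  expect_equal(im$values, exp(-d / 5) / max(exp(-d / 5)), tolerance = 1e-9)
  # value at distance ell is e^{-1} of the near-origin value
  iNear <- which.min(abs(im$mids))
  near <- im$values[iNear, iNear]
  at5 <- im$values[iNear, which.min(abs(im$mids - 5))]
  expect_equal(at5 / near,
               exp(-d[iNear, which.min(abs(im$mids - 5))] / 5) /
                 exp(-d[iNear, iNear] / 5), tolerance = 1e-9)
  im2 <- influenceMap(interactionModel("metric", r = 4), extent = 10,
                      cell = 0.5)
  expect_setequal(unique(as.numeric(im2$values)), c(0, 1))
  expect_equal(im2$values, (d <= 4) * 1)
})

test_that("performance curves vanish for identical models and ignore order", {
  st <- midSteps()
  p <- midParams()
  pv <- performanceVsDistance(st, p, p)
  expect_true(all(abs(pv$mean[!is.na(pv$mean)]) < 1e-15))
  # against a rank-1 topological rule the generating kernel wins on average
  pTopo <- modelParams(0.5, 0.2, 0.3, 0.8,
                       interactionModel("topological", alignment = TRUE,
                                        K = 1, a = 0.6))
  llA <- stepLoglik(p, st); llB <- stepLoglik(pTopo, st)
  expect_gt(mean(exp(llA) - exp(llB)), 0)
  # shuffling step order leaves bin means unchanged
  set.seed(3)
  perm <- sample(nrow(st$steps))
  st2 <- herdSteps(st$steps[perm, ], st$nb, dt = st$dt)
  pv2 <- performanceVsDistance(st2, p, pTopo)
  pv1 <- performanceVsDistance(st, p, pTopo)
  expect_equal(pv2$mean, pv1$mean, tolerance = 1e-12)
})

test_that("focal-frame maps are invariant under rigid motions of the data", {
  sim <- midSim()
  st <- discretize(sim$traj, dt = 2)
  tr2 <- rotateTraj(sim$traj, 1.13)
  tr2$x <- tr2$x + 40; tr2$y <- tr2$y - 17
  st2 <- discretize(tr2, dt = 2)
  expect_equal(relativePositionHeatmap(st2)$values,
               relativePositionHeatmap(st)$values, tolerance = 1e-9)
  expect_equal(circularVarianceMap(st2)$values,
               circularVarianceMap(st)$values, tolerance = 1e-9)
  expect_equal(orientationProjectionMap(st2)$values,
               orientationProjectionMap(st)$values, tolerance = 1e-9)
})
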