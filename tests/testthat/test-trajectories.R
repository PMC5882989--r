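test_that("straight-line motion discretises to constant zero headings", {
  st <- discretize(eastTraj(), dt = 2)
  expect_true(all(st$steps$theta == 0))
  expect_true(all(st$steps$theta_prev[!is.na(st$steps$theta_prev)] == 0))
})

test_that("a two-individual herd gives exactly one neighbour per step", {
  st <- discretize(pairTraj(), dt = 2)
  expect_true(all(table(st$nb$step_id) == 1L))
  expect_equal(nrow(st$nb), nrow(st$steps))
  # neighbour symmetry: a sees b at +3 in y, b sees a at -3
  a <- st$nb[st$nb$nb_id == "b", ]
  b <- st$nb[st$nb$nb_id == "a", ]
  expect_true(all(a$rel_y == 3) && all(b$rel_y == -3))
  expect_true(all(a$rel_x == 0) && all(b$rel_x == 0))
})

test_that("interval counts on a hand-counted track", {
  # 60 fixes at 1 Hz spanning 0..59 s: the 2 s grid has points 0,2,...,58,
  # hence 29 displacement intervals, 28 of which also have a previous
  # heading (counted by hand for this convention)
  tt <- 0:59
  tr <- herdTrajectory(data.frame(herd_id = "h", individual_id = "a",
                                  t = tt, x = 1.2 * tt, y = 0))
  st <- discretize(tr, dt = 2)
  expect_equal(nrow(st$steps), 29L)
  expect_equal(sum(!is.na(st$steps$theta_prev)), 28L)
})

test_that("duplicate or non-increasing timestamps are rejected by name", {
  df <- data.frame(herd_id = "h", individual_id = c("a", "a", "b", "b"),
                   t = c(0, 0, 0, 1), x = 1:4, y = 0)
  expect_error(herdTrajectory(df), "'a'")
})

test_that("discretisation is idempotent on already-gridded data", {
  sim <- midSim()
  st <- discretize(sim$traj, dt = 2)
  # re-gridding the resampled positions reproduces displacement vectors
  pos <- st$steps
  tr2 <- herdTrajectory(data.frame(herd_id = pos$herd_id,
                                   individual_id = pos$individual_id,
                                   t = pos$t_start, x = pos$x, y = pos$y))
  st2 <- discretize(tr2, dt = 2)
  m <- match(paste(st2$steps$individual_id, st2$steps$t_start),
             paste(pos$individual_id, pos$t_start))
  expect_equal(st2$steps$theta, pos$theta[m], tolerance = 1e-12)
})

test_that("all returned angles lie in (-pi, pi]", {
  st <- midSteps()
  th <- c(st$steps$theta, st$steps$theta_prev, st$nb$heading)
  th <- th[!is.na(th)]
  expect_true(all(th > -pi & th <= pi))
})

test_that("neighbour snapshots are symmetric at shared instants", {
  st <- midSteps()
  s <- st$steps
  nb <- st$nb
  m <- match(nb$step_id, s$step_id)
  key1 <- paste(s$herd_id[m], s$individual_id[m], nb$nb_id, s$t_start[m])
  key2 <- paste(s$herd_id[m], nb$nb_id, s$individual_id[m], s$t_start[m])
  back <- match(key2, key1)
  ok <- !is.na(back)
  expect_gt(mean(ok), 0.9)  # partners missing only at track edges
  expect_equal(nb$rel_x[ok], -nb$rel_x[back[ok]], tolerance = 1e-12)
  expect_equal(nb$rel_y[ok], -nb$rel_y[back[ok]], tolerance = 1e-12)
})

test_that("gaps longer than twice dt split tracks instead of bridging", {
  tt <- c(0:5, 11:16) * 2                    # 12 s hole in the middle
  tr <- herdTrajectory(data.frame(herd_id = "h", individual_id = "a",
                                  t = tt, x = 1.2 * tt, y = 0))
  st <- discretize(tr, dt = 2)
  # no step interval spans the gap; heading chains restart afterwards
  expect_false(any(st$steps$t_start >= 10 & st$steps$t_start < 22))
  expect_true(is.na(st$steps$theta_prev[st$steps$t_start == 22]))
})

test_that("sub-threshold displacements define no heading", {
  tt <- seq(0, 20, by = 2)
  x <- c(0, 2.4, 4.8, 4.81, 4.82, 4.83, seq(7.2, by = 2.4,
                                            length.out = 5))
  tr <- herdTrajectory(data.frame(herd_id = "h", individual_id = "a",
                                  t = tt, x = x, y = 0))
  st <- discretize(tr, dt = 2, minDisp = 0.05)
  expect_false(any(st$steps$t_start %in% c(4, 6, 8)))  # stationary spell
})

test_that("trajectory CSV IO round-trips bit-exactly", {
  sim <- midSim()
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeTrajectories(sim$traj, f1)
  tr <- readTrajectories(f1)
  writeTrajectories(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(tr), nrow(sim$traj))
})

test_that("heading autocorrelation is exact for constant and uniform headings", {
  st <- discretize(eastTraj(nFix = 31), dt = 2)
  ac <- headingAutocorrelation(st, maxLag = 10)
  expect_equal(ac$correlation, rep(1, nrow(ac)))
  expect_equal(ac$correlation[ac$lag == 0], 1)

  set.seed(8)
  trs <- lapply(1:20, function(i)
    headingTraj(runif(500, -pi, pi), id = sprintf("i%02d", i)))
  tr <- herdTrajectory(do.call(rbind, trs))
  ac <- headingAutocorrelation(discretize(tr, dt = 2), maxLag = 6)
  expect_equal(ac$correlation[ac$lag == 0], 1)
  expect_true(all(abs(ac$correlation[ac$lag > 0]) < 0.02))

  expect_warning(
    headingAutocorrelation(discretize(eastTraj(nFix = 3), dt = 2),
                           maxLag = 100) -> ac2, NA)
  expect_true(all(ac2$n > 0))
})

test_that("heading-change fit recovers generating Gaussians", {
  set.seed(12)
  # N(0 deg, 6.54 deg) changes
  ch <- rnorm(1e5, 0, 6.54) * pi / 180
  fit <- headingChangeDist(ch)
  expect_gt(fit$sigma, 6.4); expect_lt(fit$sigma, 6.7)
  expect_lt(abs(fit$mu), 0.2)
  # N(5 deg, 10 deg)
  fit2 <- headingChangeDist(rnorm(1e5, 5, 10) * pi / 180)
  expect_gt(fit2$mu, 4.5); expect_lt(fit2$mu, 5.5)
  # degenerate: all-zero changes
  fit3 <- headingChangeDist(rep(0, 100))
  expect_true(fit3$degenerate)
  expect_equal(fit3$mu, 0)
  expect_equal(fit3$sigma, 1e-3)
  expect_error(headingChangeDist(rnorm(10)), "at least 30")
})
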