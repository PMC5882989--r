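# Shared fixtures, built in code and cached for the duration of a test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# A straight-line mover: due east at constant speed.
eastTraj <- function(nFix = 11, dt = 2, speed = 1.2, id = "a", herd = "h") {
  tt <- seq(0, by = dt, length.out = nFix)
  herdTrajectory(data.frame(herd_id = herd, individual_id = id, t = tt,
                            x = speed * tt, y = 0))
}

# Two-individual herd moving east, 3 m apart in y.
pairTraj <- function(nFix = 11, dt = 2) {
  tt <- seq(0, by = dt, length.out = nFix)
  herdTrajectory(data.frame(
    herd_id = "h", individual_id = rep(c("a", "b"), each = nFix),
    t = rep(tt, 2), x = rep(2.4 * tt / 2, 2), y = rep(c(0, 3), each = nFix)))
}

# Build a single-individual trajectory realising a given heading sequence
# (unit speed steps of duration dt).
headingTraj <- function(theta, dt = 2, step = 2.4, id = "a", herd = "h") {
  x <- c(0, cumsum(step * cos(theta)))
  y <- c(0, cumsum(step * sin(theta)))
  herdTrajectory(data.frame(herd_id = herd, individual_id = id,
                            t = seq(0, by = dt, length.out = length(x)),
                            x = x, y = y))
}

# Moderate simulated dataset under the reference generating model
# (exponential decay + alignment), reused across test files.
midSim <- function() cached("midSim",
  simHerds(simConfig(nHerds = 4, herdSize = 12, nSteps = 120, seed = 11)))

midSteps <- function() cached("midSteps", {
  sim <- midSim()
  attachEnvTruth(discretize(sim$traj, dt = 2), sim)
})

midParams <- function() modelParams(
  0.5, 0.2, 0.3, 0.8,
  interactionModel("expdecay", alignment = TRUE, ell = 5, a = 0.6))

# Persistence-only (plain correlated random walk) simulation.
rwSim <- function() cached("rwSim",
  simHerds(simConfig(nHerds = 2, herdSize = 10, nSteps = 150,
                     model = "rw",
                     params = list(alpha = 0, beta = 0, gamma = 1,
                                   rho = 0.8),
                     envField = NULL, seed = 21)))

rwSteps <- function() cached("rwSteps",
  discretize(rwSim()$traj, dt = 2))

# Build a herd_steps object directly from a list of neighbour
# configurations for one synthetic focal step each: used by diagnostics
# tests where full trajectories are unnecessary.
stepsFromConfigs <- function(theta, thetaPrev, nbList, dt = 2) {
  n <- length(theta)
  steps <- data.frame(step_id = seq_len(n), herd_id = "h",
                      individual_id = sprintf("f%03d", seq_len(n)),
                      class = "unknown", t_start = 0,
                      x = 0, y = 0, theta = theta, theta_prev = thetaPrev,
                      phi = NA_real_, stringsAsFactors = FALSE)
  nb <- do.call(rbind, lapply(seq_along(nbList), function(i) {
    b <- nbList[[i]]
    if (is.null(b) || nrow(b) == 0L) return(NULL)
    d <- sqrt(b$rel_x^2 + b$rel_y^2)
    o <- order(d, b$nb_id)
    rk <- integer(nrow(b)); rk[o] <- seq_len(nrow(b))
    data.frame(step_id = i, nb_id = b$nb_id, rel_x = b$rel_x,
               rel_y = b$rel_y, dist = d, heading = b$heading,
               class = "unknown", rank = rk, stringsAsFactors = FALSE)
  }))
  if (is.null(nb))
    nb <- data.frame(step_id = integer(0), nb_id = character(0),
                     rel_x = numeric(0), rel_y = numeric(0),
                     dist = numeric(0), heading = numeric(0),
                     class = character(0), rank = integer(0))
  herdSteps(steps, nb, dt = dt)
}

# Rotate a trajectory table about the origin (for invariance checks).
rotateTraj <- function(traj, phi) {
  x <- cos(phi) * traj$x - sin(phi) * traj$y
  y <- sin(phi) * traj$x + cos(phi) * traj$y
  traj$x <- x; traj$y <- y
  traj
}
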