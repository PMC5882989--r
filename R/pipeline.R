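# End-to-end pipelines: fit the full candidate set and rank it, sweep the
# discretisation interval, and run simulate-fit-compare recovery
# experiments.  A thin command-line wrapper over these functions ships in
# inst/scripts/run_pipeline.R.

#' Fit all candidate models and rank them
#'
#' Discretises trajectories if needed, attaches the track-derived
#' environmental heading grid (unless `phi` is already present), fits
#' every requested model, profiles topological models over the `K` grid
#' (keeping the WAIC-best `K`), and returns the ranked comparison table
#' against the random-walk baseline.
#'
#' @param x `herd_traj` or `herd_steps`.
#' @param models character vector of model specification strings; default
#'   all eight candidates.
#' @param dt discretisation interval, seconds (used when `x` is a
#'   trajectory table).
#' @param envCell heading-grid cell size, metres.
#' @param priors `prior_spec` (its `kGrid` drives the topological profile).
#' @param mcmc `mcmc_control`; the seed fans out deterministically over
#'   models, so a re-run from the same inputs reproduces the table.
#' @param minDisp minimum displacement defining a heading, metres.
#' @return list with `table` (`crw_comparison`), `fits` (named list of
#'   `crw_fit`, topological entries at their best `K`), `kOpt` (named
#'   integer vector of selected `K` per topological model) and `steps`.
#' @export
fitCompare <- function(x, models = MODEL_SPECS, dt = 2, envCell = 5,
                       priors = priorSpec(), mcmc = mcmcControl(),
                       minDisp = 0.05) {
  steps <- if (inherits(x, "herd_traj")) {
    st <- discretize(x, dt = dt, minDisp = minDisp)
    attachEnvGrid(st, cell = envCell)
  } else {
    stopifnot(inherits(x, "herd_steps"))
    if (all(is.na(x$steps$phi))) attachEnvGrid(x, cell = envCell) else x
  }
  fits <- list()
  kOpt <- integer(0)
  for (mi in seq_along(models)) {
    m <- models[mi]
    spec <- parseModelSpec(m)
    mc <- mcmc
    mc$seed <- mcmc$seed + 131L * mi      # deterministic per-model seeds
    if (spec$form == "topological") {
      kFits <- lapply(priors$kGrid, function(k)
        fitModel(steps, m, K = k, priors = priors, mcmc = mc))
      scores <- vapply(kFits, function(f) waic(f$loglikMatrix)$waic, 0)
      best <- which.min(scores)
      fits[[m]] <- kFits[[best]]
      kOpt[m] <- priors$kGrid[best]
    } else {
      fits[[m]] <- fitModel(steps, m, priors = priors, mcmc = mc)
    }
  }
  list(table = compareModels(fits), fits = fits, kOpt = kOpt,
       steps = steps)
}

#' Robustness sweep over the discretisation interval
#'
#' Re-runs the full fit-and-compare pipeline at a range of step durations
#' to check that the model ranking is not an artefact of the chosen
#' interval.
#'
#' @param traj `herd_traj`.
#' @param dts numeric vector of step durations, seconds.
#' @param ... passed to [fitCompare()].
#' @return named list of `crw_comparison` tables, one per `dt`.
#' @export
dtSweep <- function(traj, dts = 1:10, ...) {
  stopifnot(inherits(traj, "herd_traj"), all(dts > 0))
  out <- lapply(dts, function(d) fitCompare(traj, dt = d, ...)$table)
  names(out) <- paste0("dt=", dts)
  out
}

#' Simulate-fit-compare recovery experiment
#'
#' For each generating model, repeatedly simulates herd data with known
#' parameters, runs the full comparison pipeline, and records which model
#' each criterion selects, together with the posterior means of the
#' generating model's own fit.  Summarises selection performance as a
#' confusion matrix (rows: generating model; columns: WAIC-selected
#' model).
#'
#' @param genModels character vector of generating model specs.
#' @param genParams named list (by model spec) of true-parameter lists as
#'   accepted by [simConfig()]; entries missing from the list fall back to
#'   [simConfig()]'s defaults with weights moved to the terms the model
#'   carries.
#' @param nReplicates replicates per generating model.
#' @param config base `sim_config`; its model/params/seed are overridden
#'   per replicate (seeds fan out deterministically from `config$seed`).
#' @param fitModels candidate set passed to [fitCompare()].
#' @param priors,mcmc passed to [fitCompare()].
#' @param useTrueEnv attach the generator's true environmental headings
#'   (default) instead of the track-derived grid estimate.
#' @return object of class `crw_recovery`: list with `confusion` (matrix),
#'   `details` (one row per replicate: generating model, selected model by
#'   each criterion, posterior means of the matched fit) and `nReplicates`.
#' @export
recoveryExperiment <- function(genModels, genParams = list(),
                               nReplicates = 5, config = simConfig(),
                               fitModels = MODEL_SPECS,
                               priors = priorSpec(), mcmc = mcmcControl(),
                               useTrueEnv = TRUE) {
  details <- list()
  for (gm in genModels) {
    spec <- parseModelSpec(gm)
    pars <- genParams[[gm]]
    if (is.null(pars)) {
      pars <- config$params
      if (!spec$social) {
        pars$gamma <- pars$gamma + pars$alpha; pars$alpha <- 0
      }
      if (!spec$env) {
        pars$gamma <- pars$gamma + pars$beta; pars$beta <- 0
      }
      if (spec$form == "topological" && is.null(pars$K)) pars$K <- 1L
      if (spec$form == "metric" && is.null(pars$r)) pars$r <- 10
    }
    for (rep in seq_len(nReplicates)) {
      cfg <- config
      cfg$model <- spec
      cfg$params <- pars
      cfg$seed <- config$seed + 7919L * match(gm, genModels) + rep
      sim <- simHerds(cfg)
      st <- discretize(sim$traj, dt = cfg$dt)
      st <- if (useTrueEnv) attachEnvTruth(st, sim) else attachEnvGrid(st)
      mc <- mcmc
      mc$seed <- mcmc$seed + 17L * rep
      res <- fitCompare(st, models = fitModels, priors = priors, mcmc = mc)
      tab <- res$table
      selW <- tab$model[tab$rankWAIC == 1L]
      selD <- tab$model[tab$rankDIC == 1L]
      pm <- if (gm %in% names(res$fits)) res$fits[[gm]]$postMean else NULL
      details[[length(details) + 1L]] <- data.frame(
        generating = gm, replicate = rep, selectedWAIC = selW,
        selectedDIC = selD,
        alpha = if (!is.null(pm)) pm[["alpha"]] else NA_real_,
        rho = if (!is.null(pm)) pm[["rho"]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  details <- do.call(rbind, details)
  confusion <- table(factor(details$generating, levels = genModels),
                     factor(details$selectedWAIC, levels = fitModels))
  structure(list(confusion = unclass(confusion), details = details,
                 nReplicates = nReplicates),
            class = "crw_recovery")
}

#' @export
print.crw_recovery <- function(x, ...) {
  cat("Model-selection recovery (", x$nReplicates,
      " replicates per generating model)\n", sep = "")
  cat("Confusion matrix (rows: generating; cols: WAIC-selected):\n")
  print(x$confusion)
  invisible(x)
}
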