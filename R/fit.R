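# Bayesian inference for the movement model: adaptive random-walk
# Metropolis on an unconstrained parameter space (additive log-ratio for
# the simplex weights, logit for rho and the alignment strength, scaled
# logit for the interaction range/length), flat priors on the constrained
# scale.

#' Prior specification
#'
#' All priors are flat on the constrained scale: the composite weights
#' `(alpha, beta, gamma)` uniform on the 2-simplex, `rho` uniform on
#' \code{[0, 1)}, the alignment strength `a` uniform on \code{[0, 1]}, the
#' metric range `r` and decay length `ell` uniform on \code{(0, rMax)} and
#' \code{(0, ellMax)}.  The topological neighbour count `K` is profiled
#' over an integer grid rather than sampled.
#'
#' @param rMax upper bound for the metric range (metres).
#' @param ellMax upper bound for the decay length (metres).
#' @param kGrid integer grid of candidate `K` values for topological
#'   models.
#' @return object of class `prior_spec`.
#' @export
priorSpec <- function(rMax = 100, ellMax = 100, kGrid = 1:10) {
  stopifnot(rMax > 0, ellMax > 0, all(kGrid >= 1), all(kGrid == round(kGrid)))
  structure(list(rMax = rMax, ellMax = ellMax, kGrid = as.integer(kGrid)),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param chains number of independent chains (run sequentially).
#' @param iter iterations per chain.
#' @param burn burn-in iterations discarded per chain (adaptation happens
#'   here and stops afterwards, so the kept draws target the exact
#'   posterior).
#' @param thin thinning of kept draws; `NULL` picks the smallest thinning
#'   that stores at most `maxStore` draws in total.
#' @param seed integer seed; identical settings give identical draws.
#' @param maxStore cap on stored posterior draws across chains.
#' @return object of class `mcmc_control`.
#' @export
mcmcControl <- function(chains = 4, iter = 2000, burn = floor(iter / 2),
                        thin = NULL, seed = 1, maxStore = 1000) {
  stopifnot(chains >= 1, iter > burn, burn >= 1)
  if (is.null(thin))
    thin <- max(1L, ceiling(chains * (iter - burn) / maxStore))
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burn = as.integer(burn), thin = as.integer(thin),
                 seed = as.integer(seed), maxStore = maxStore),
            class = "mcmc_control")
}

# ---- parameter transforms ------------------------------------------------

# Which parameters a model spec carries, and where they sit in z.
.paramSpec <- function(spec, K = NULL) {
  simplex <- if (spec$social) "full" else if (spec$env) "env" else "none"
  if (spec$form == "topological" && is.null(K))
    stop("topological models are fitted at a requested K (profile over the ",
         "K grid with fitCompare())")
  nms <- c(switch(simplex, full = c("z_alpha", "z_beta"), env = "z_beta",
                  none = NULL),
           "z_rho",
           if (spec$alignment) "z_a",
           if (spec$form == "metric") "z_r",
           if (spec$form == "expdecay") "z_ell")
  list(spec = spec, simplex = simplex, K = K, names = nms, d = length(nms))
}

# Back-transform an unconstrained vector; returns the parameter list the
# likelihood consumes plus the log Jacobian of the transform (the log
# target is loglik + logJ under the flat priors).
.zToParams <- function(z, ps, priors) {
  logJ <- 0; i <- 1L
  if (ps$simplex == "full") {
    m <- max(0, z[1L], z[2L])
    e0 <- exp(-m); e1 <- exp(z[1L] - m); e2 <- exp(z[2L] - m)
    s <- e0 + e1 + e2
    alpha <- e1 / s; beta <- e2 / s; gamma <- e0 / s
    logJ <- logJ + log(alpha) + log(beta) + log(gamma)
    i <- 3L
  } else if (ps$simplex == "env") {
    p <- stats::plogis(z[1L])
    alpha <- 0; beta <- p; gamma <- 1 - p
    logJ <- logJ + log(p) + log1p(-p)
    i <- 2L
  } else {
    alpha <- 0; beta <- 0; gamma <- 1
  }
  rho <- stats::plogis(z[i]); logJ <- logJ + log(rho) + log1p(-rho); i <- i + 1L
  a <- r <- ell <- NULL
  if (ps$spec$alignment) {
    a <- stats::plogis(z[i]); logJ <- logJ + log(a) + log1p(-a); i <- i + 1L
  }
  if (ps$spec$form == "metric") {
    p <- stats::plogis(z[i]); r <- priors$rMax * p
    logJ <- logJ + log(p) + log1p(-p); i <- i + 1L
  }
  if (ps$spec$form == "expdecay") {
    p <- stats::plogis(z[i]); ell <- priors$ellMax * p
    logJ <- logJ + log(p) + log1p(-p); i <- i + 1L
  }
  params <- list(alpha = alpha, beta = beta, gamma = gamma, rho = rho,
                 interaction = list(form = ps$spec$form,
                                    alignment = ps$spec$alignment,
                                    r = r, K = ps$K, ell = ell, a = a))
  list(params = params, logJ = logJ)
}

.paramsToZ <- function(p, ps, priors) {
  z <- numeric(0)
  if (ps$simplex == "full")
    z <- c(log(p$alpha / p$gamma), log(p$beta / p$gamma))
  else if (ps$simplex == "env")
    z <- stats::qlogis(p$beta)
  z <- c(z, stats::qlogis(p$rho))
  if (ps$spec$alignment) z <- c(z, stats::qlogis(p$a))
  if (ps$spec$form == "metric") z <- c(z, stats::qlogis(p$r / priors$rMax))
  if (ps$spec$form == "expdecay")
    z <- c(z, stats::qlogis(p$ell / priors$ellMax))
  z
}

# Draw an initial constrained parameter set from (slightly interiorised)
# priors, returned on the unconstrained scale.
.initZ <- function(ps, priors) {
  w <- stats::rgamma(3, 1)
  w <- w / sum(w)
  p <- list(alpha = w[1L], beta = w[2L], gamma = w[3L],
            rho = runif(1, 0.05, 0.95), a = runif(1, 0.05, 0.95),
            r = runif(1, 0.05, 0.95) * priors$rMax,
            ell = runif(1, 0.05, 0.95) * priors$ellMax)
  if (ps$simplex == "env") { p$beta <- runif(1, 0.05, 0.95); }
  .paramsToZ(p, ps, priors)
}

# ---- sampler -------------------------------------------------------------

# Adaptive random-walk Metropolis.  During burn-in a global proposal scale
# is tuned by Robbins-Monro toward the target acceptance rate and, halfway
# through burn-in, per-coordinate proposal widths are set from the history;
# adaptation is frozen afterwards.
.runMetropolis <- function(logpost, zInit, iter, burn, target = 0.234) {
  d <- length(zInit)
  z <- zInit
  lp <- logpost(z)
  if (!is.finite(lp)) stop("non-finite log posterior at initial value")
  s <- 0.3
  sig <- rep(1, d)
  draws <- matrix(NA_real_, iter, d)
  lps <- numeric(iter)
  nAcc <- 0L
  hist <- matrix(NA_real_, burn, d)
  for (t in seq_len(iter)) {
    zProp <- z + s * sig * rnorm(d)
    lpProp <- logpost(zProp)
    acc <- if (is.finite(lpProp)) min(1, exp(lpProp - lp)) else 0
    if (runif(1) < acc) {
      z <- zProp; lp <- lpProp; nAcc <- nAcc + 1L
    }
    if (t <= burn) {
      s <- s * exp((acc - target) / max(1, t)^0.6)
      hist[t, ] <- z
      if (t > 20L && t %in% floor(burn * c(0.25, 0.5, 0.75))) {
        win <- seq(max(1L, floor(t / 2)), t)
        sds <- apply(hist[win, , drop = FALSE], 2L, sd)
        if (all(is.finite(sds)) && any(sds > 0))
          sig <- pmax(sds, max(sds) * 0.05, 1e-3)
      }
    }
    draws[t, ] <- z
    lps[t] <- lp
  }
  list(draws = draws[(burn + 1L):iter, , drop = FALSE],
       logpost = lps[(burn + 1L):iter],
       acceptance = nAcc / iter)
}

# Split-Rhat per column across a list of equally sized chain matrices.
.splitRhat <- function(chainList) {
  half <- lapply(chainList, function(m) {
    n <- nrow(m)
    if (n < 4L) return(NULL)
    h <- floor(n / 2)
    list(m[seq_len(h), , drop = FALSE], m[(n - h + 1L):n, , drop = FALSE])
  })
  half <- unlist(half[!vapply(half, is.null, TRUE)], recursive = FALSE)
  if (length(half) < 2L) return(rep(NA_real_, ncol(chainList[[1L]])))
  vapply(seq_len(ncol(half[[1L]])), function(j) {
    xs <- lapply(half, function(m) m[, j])
    n <- length(xs[[1L]]); m <- length(xs)
    mus <- vapply(xs, mean, 0)
    vars <- vapply(xs, var, 0)
    W <- mean(vars)
    B <- n * var(mus)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

# ---- fitting -------------------------------------------------------------

#' Fit a movement model by MCMC
#'
#' Samples the posterior of the movement-model parameters for one
#' candidate interaction rule, given discretised steps.  Priors are flat
#' (see [priorSpec()]); sampling is adaptive random-walk Metropolis on the
#' unconstrained scale, multiple chains, with split-R-hat convergence
#' flags.  Topological models are fitted at a single requested `K`; use
#' [fitCompare()] to profile `K` over a grid.
#'
#' @param steps `herd_steps` with at least 100 likelihood-usable steps.
#' @param model model specification string (see [parseModelSpec()]).
#' @param K neighbour count for `"topo"` / `"topo+align"`.
#' @param priors `prior_spec`.
#' @param mcmc `mcmc_control`.
#' @param keepLoglik keep the draws-by-steps log-likelihood matrix needed
#'   for WAIC/DIC?  Set `FALSE` to save memory when only posterior
#'   summaries are needed.
#' @return object of class `crw_fit`: list with the posterior draws on the
#'   constrained scale (`draws`, one row per stored draw, with `logpost`
#'   and `chain`), the maximum a posteriori draw (`map`, a
#'   [modelParams()] object; `mapIndex` its row), posterior means
#'   (`postMean`), the per-draw per-step log-likelihood matrix
#'   (`loglikMatrix`), the deviance at the posterior mean of the
#'   unconstrained parameters (`devAtMean`), sampler diagnostics
#'   (`diagnostics$acceptance`, `diagnostics$rhat`,
#'   `diagnostics$converged`), and bookkeeping (`modelName`, `K`,
#'   `nEval`, `stepIds`, `priors`, `mcmc`).
#' @examples
#' \dontrun{
#' sim <- simHerds(simConfig(nHerds = 2, nSteps = 80, seed = 1))
#' st <- attachEnvTruth(discretize(sim$traj), sim)
#' fit <- fitModel(st, "expdecay+align",
#'                 mcmc = mcmcControl(chains = 2, iter = 1200, seed = 1))
#' fit$postMean
#' }
#' @export
fitModel <- function(steps, model, K = NULL, priors = priorSpec(),
                     mcmc = mcmcControl(), keepLoglik = TRUE) {
  stopifnot(inherits(steps, "herd_steps"), inherits(priors, "prior_spec"),
            inherits(mcmc, "mcmc_control"))
  spec <- parseModelSpec(model)
  prep <- .prepLoglikData(steps)
  if (prep$n < 100L)
    stop("need at least 100 likelihood-usable steps (got ", prep$n, ")")
  ps <- .paramSpec(spec, K = K)
  logpost <- function(z) {
    tp <- .zToParams(z, ps, priors)
    if (!is.finite(tp$logJ)) return(-Inf)
    sum(.cppLoglik(prep, tp$params)) + tp$logJ
  }
  # posterior-mode search shared by all chains: best of several random
  # starts, polished by restarted Nelder-Mead.  Chains start jittered
  # around the mode, so burn-in is spent adapting proposals rather than
  # travelling long transients (the posterior is typically very
  # concentrated at these data sizes).
  set.seed(mcmc$seed)
  zStarts <- list()
  for (tryI in seq_len(30L)) {
    cand <- .initZ(ps, priors)
    if (is.finite(logpost(cand))) zStarts[[length(zStarts) + 1L]] <- cand
    if (length(zStarts) >= 5L) break
  }
  if (!length(zStarts))
    stop("non-finite likelihood at initialisation after 30 attempts")
  zMode <- zStarts[[which.max(vapply(zStarts, logpost, 0))]]
  lpMode <- logpost(zMode)
  for (round in 1:3) {
    opt <- tryCatch(
      if (ps$d == 1L)
        optim(zMode, function(z) -logpost(z), method = "Brent",
              lower = -20, upper = 20)
      else
        optim(zMode, function(z) -logpost(z), method = "Nelder-Mead",
              control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) break
    improved <- -opt$value - lpMode
    zMode <- opt$par; lpMode <- -opt$value
    if (improved < 0.5) break
  }

  chainsZ <- list(); chainsLp <- list(); accs <- numeric(mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 1000L * (ch - 1L))
    z0 <- zMode
    for (jit in c(0.3, 0.1, 0.02, 0)) {
      cand <- zMode + jit * rnorm(length(zMode))
      if (is.finite(logpost(cand))) { z0 <- cand; break }
    }
    run <- .runMetropolis(logpost, z0, mcmc$iter, mcmc$burn)
    keep <- seq(1L, nrow(run$draws), by = mcmc$thin)
    chainsZ[[ch]] <- run$draws[keep, , drop = FALSE]
    chainsLp[[ch]] <- run$logpost[keep]
    accs[ch] <- run$acceptance
  }
  zDraws <- do.call(rbind, chainsZ)
  lp <- unlist(chainsLp)
  chainId <- rep(seq_len(mcmc$chains), vapply(chainsZ, nrow, 0L))
  S <- nrow(zDraws)

  # constrained-scale draws
  cols <- c("alpha", "beta", "gamma", "rho", "a", "r", "ell")
  dm <- matrix(NA_real_, S, length(cols), dimnames = list(NULL, cols))
  for (si in seq_len(S)) {
    p <- .zToParams(zDraws[si, ], ps, priors)$params
    dm[si, "alpha"] <- p$alpha; dm[si, "beta"] <- p$beta
    dm[si, "gamma"] <- p$gamma; dm[si, "rho"] <- p$rho
    if (!is.null(p$interaction$a)) dm[si, "a"] <- p$interaction$a
    if (!is.null(p$interaction$r)) dm[si, "r"] <- p$interaction$r
    if (!is.null(p$interaction$ell)) dm[si, "ell"] <- p$interaction$ell
  }
  draws <- as.data.frame(dm)
  draws$logpost <- lp
  draws$chain <- chainId

  rhat <- .splitRhat(chainsZ)
  names(rhat) <- ps$names
  converged <- all(is.na(rhat) | rhat <= 1.1)
  if (!converged)
    warning("split-Rhat > 1.1 for model '", spec$name,
            "': chains may not have converged")

  mapIndex <- which.max(lp)
  pMap <- .zToParams(zDraws[mapIndex, ], ps, priors)$params
  imMap <- if (pMap$interaction$form == "none") interactionModel("none") else
    interactionModel(pMap$interaction$form,
                     alignment = pMap$interaction$alignment,
                     r = pMap$interaction$r, K = pMap$interaction$K,
                     ell = pMap$interaction$ell, a = pMap$interaction$a)
  map <- modelParams(pMap$alpha, pMap$beta, pMap$gamma, pMap$rho, imMap)

  zBar <- colMeans(zDraws)
  pBar <- .zToParams(zBar, ps, priors)$params
  devAtMean <- -2 * sum(.cppLoglik(prep, pBar))

  loglikMatrix <- NULL
  if (keepLoglik) {
    loglikMatrix <- matrix(NA_real_, S, prep$n)
    for (si in seq_len(S)) {
      p <- .zToParams(zDraws[si, ], ps, priors)$params
      loglikMatrix[si, ] <- .cppLoglik(prep, p)
    }
  }

  present <- !vapply(draws[cols], function(x) all(is.na(x)), TRUE)
  postMean <- colMeans(draws[cols][present])

  structure(list(modelName = spec$name, spec = spec, K = K,
                 draws = draws, zDraws = zDraws,
                 map = map, mapIndex = mapIndex, postMean = postMean,
                 loglikMatrix = loglikMatrix, devAtMean = devAtMean,
                 diagnostics = list(acceptance = accs, rhat = rhat,
                                    converged = converged),
                 nEval = prep$n, stepIds = prep$stepId,
                 priors = priors, mcmc = mcmc),
            class = "crw_fit")
}

#' @export
print.crw_fit <- function(x, ...) {
  cat("Movement model fit: '", x$modelName, "'",
      if (!is.null(x$K)) paste0(" (K = ", x$K, ")"), "\n", sep = "")
  cat("  ", x$nEval, " steps, ", nrow(x$draws), " stored draws, ",
      length(unique(x$draws$chain)), " chain(s); mean acceptance ",
      sprintf("%.2f", mean(x$diagnostics$acceptance)), "\n", sep = "")
  q <- function(v) quantile(v, c(0.025, 0.975), names = FALSE)
  for (nm in names(x$postMean)) {
    ci <- q(x$draws[[nm]])
    cat(sprintf("  %-6s mean %7.3f   95%% CrI [%7.3f, %7.3f]\n",
                nm, x$postMean[[nm]], ci[1L], ci[2L]))
  }
  if (!x$diagnostics$converged)
    cat("  WARNING: split-Rhat > 1.1; treat results with caution\n")
  invisible(x)
}

# Restrict a step set to the given step ids (neighbour snapshots kept).
.filterSteps <- function(steps, ids) {
  keep <- steps$steps$step_id %in% ids
  herdSteps(steps$steps[keep, , drop = FALSE],
            steps$nb[steps$nb$step_id %in% ids, , drop = FALSE],
            dt = steps$dt, minDisp = steps$minDisp)
}

#' Fit a movement model separately per demographic class
#'
#' Partitions steps by the class of the FOCAL individual (neighbour
#' snapshots keep all classes) and fits the model independently in each
#' partition, enabling comparisons of social weighting and alignment
#' strength across life stages.
#'
#' @inheritParams fitModel
#' @param minStepsPerClass classes with fewer usable steps are skipped
#'   with a warning.
#' @return named list of `crw_fit` objects, one per fitted class.  If the
#'   class column is absent (all `"unknown"`), a single pooled fit is
#'   returned under the name `"pooled"`, with a warning.
#' @export
fitByClass <- function(steps, model, K = NULL, priors = priorSpec(),
                       mcmc = mcmcControl(), keepLoglik = TRUE,
                       minStepsPerClass = 100) {
  stopifnot(inherits(steps, "herd_steps"))
  s <- steps$steps
  usable <- !is.na(s$theta) & !is.na(s$theta_prev)
  cls <- s$class
  if (all(is.na(cls) | cls == "unknown")) {
    warning("no class labels present; returning a single pooled fit")
    return(list(pooled = fitModel(steps, model, K = K, priors = priors,
                                  mcmc = mcmc, keepLoglik = keepLoglik)))
  }
  out <- list()
  for (cl in sort(unique(cls[usable]))) {
    ids <- s$step_id[usable & cls == cl]
    if (length(ids) < minStepsPerClass) {
      warning("class '", cl, "' has only ", length(ids),
              " usable steps; skipped")
      next
    }
    out[[cl]] <- fitModel(.filterSteps(steps, s$step_id[cls == cl]),
                          model, K = K, priors = priors, mcmc = mcmc,
                          keepLoglik = keepLoglik)
  }
  if (!length(out)) stop("no class had enough steps to fit")
  out
}
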