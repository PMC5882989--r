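# Movement model likelihood: wrapped Cauchy step density around a
# composite expected heading (weighted circular average of social,
# environmental and persistence headings).

#' Movement model parameters
#'
#' The composite weights `alpha` (social), `beta` (environment) and
#' `gamma` (persistence) must be a point on the 2-simplex
#' (`alpha + beta + gamma = 1`); `rho` is the wrapped Cauchy concentration
#' governing step-heading predictability; `interaction` houses the social
#' rule and its parameters (`r` / `K` / `ell` / `a`).  A model with no
#' social rule (`interaction$form == "none"`) must have `alpha = 0`, and
#' vice versa.
#'
#' @param alpha,beta,gamma non-negative weights summing to 1 (tol 1e-9).
#' @param rho wrapped Cauchy concentration in \code{[0, 1)}.
#' @param interaction `interaction_model` (default: none).
#' @return object of class `model_params`.
#' @export
modelParams <- function(alpha, beta, gamma, rho,
                        interaction = interactionModel("none")) {
  stopifnot(inherits(interaction, "interaction_model"))
  w <- c(alpha, beta, gamma)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("alpha, beta, gamma must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stop("alpha + beta + gamma must equal 1 (got ", format(sum(w)), ")")
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)")
  if ((alpha == 0) != (interaction$form == "none"))
    stop("alpha = 0 if and only if the interaction form is 'none'")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, rho = rho,
                 interaction = interaction),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "Movement model parameters: alpha = %.3f, beta = %.3f, gamma = %.3f, rho = %.3f\n",
    x$alpha, x$beta, x$gamma, x$rho))
  print(x$interaction)
  invisible(x)
}

#' Composite expected heading
#'
#' The expected step heading is the direction of the convex combination of
#' unit vectors
#' \deqn{\alpha\,\hat u(\psi_t) + \beta\,\hat u(\phi_t) +
#'       \gamma\,\hat u(\theta_{t-1}),}
#' the standard circular weighted mean of the social heading \eqn{\psi_t},
#' the environmental heading \eqn{\phi_t} and the previous heading
#' \eqn{\theta_{t-1}}.  A missing or degenerate social/environmental term
#' hands its weight to persistence, which is always defined, so the
#' combination stays convex.  If the composite vector is numerically zero
#' the previous heading is returned.
#'
#' @param params `model_params`.
#' @param psi social heading (radians); `NA` when absent.  Vectorised.
#' @param psiMag social signal magnitude; values below `1e-9` are treated
#'   as degenerate (default 1, i.e. trust `psi` when non-`NA`).
#' @param phi environmental heading (radians); `NA` when missing.
#' @param thetaPrev previous step heading (radians); must be defined.
#' @return expected headings, wrapped to \code{(-pi, pi]}.
#' @examples
#' p <- modelParams(0, 0, 1, 0.8)
#' expectedHeading(p, NA, 0, NA, 0.3)   # pure persistence: 0.3
#' @export
expectedHeading <- function(params, psi, psiMag = 1, phi, thetaPrev) {
  stopifnot(inherits(params, "model_params"))
  n <- max(length(psi), length(phi), length(thetaPrev))
  psi <- rep_len(psi, n); phi <- rep_len(phi, n)
  thetaPrev <- rep_len(thetaPrev, n); psiMag <- rep_len(psiMag, n)
  if (any(is.na(thetaPrev))) stop("'thetaPrev' must be defined for every step")
  aEff <- rep(params$alpha, n); bEff <- rep(params$beta, n)
  gEff <- rep(params$gamma, n)
  noPsi <- is.na(psi) | psiMag < 1e-9
  gEff[noPsi] <- gEff[noPsi] + aEff[noPsi]; aEff[noPsi] <- 0
  noPhi <- is.na(phi)
  gEff[noPhi] <- gEff[noPhi] + bEff[noPhi]; bEff[noPhi] <- 0
  psi0 <- ifelse(noPsi, 0, psi); phi0 <- ifelse(noPhi, 0, phi)
  vx <- aEff * cos(psi0) + bEff * cos(phi0) + gEff * cos(thetaPrev)
  vy <- aEff * sin(psi0) + bEff * sin(phi0) + gEff * sin(thetaPrev)
  lam <- atan2(vy, vx)
  tiny <- sqrt(vx^2 + vy^2) < 1e-9
  lam[tiny] <- thetaPrev[tiny]
  wrapAngle(lam)
}

# Flatten a herd_steps object into the arrays the C++ likelihood consumes.
# Only steps with both theta and theta_prev defined enter the likelihood.
.prepLoglikData <- function(steps) {
  s <- steps$steps
  ev <- which(!is.na(s$theta) & !is.na(s$theta_prev))
  if (length(ev) == 0L) stop("no steps with both theta and theta_prev defined")
  nb <- steps$nb
  nb <- nb[nb$step_id %in% s$step_id[ev], , drop = FALSE]
  # nb already ordered by (step_id, rank); align offsets with ev order
  pos <- match(nb$step_id, s$step_id[ev])
  o <- order(pos, nb$rank)
  nb <- nb[o, , drop = FALSE]
  cnt <- tabulate(pos[o], nbins = length(ev))
  off <- c(0L, cumsum(cnt))
  hx <- cos(nb$heading); hy <- sin(nb$heading)
  list(theta = s$theta[ev], thetaPrev = s$theta_prev[ev], phi = s$phi[ev],
       nbOff = as.integer(off),
       d = nb$dist, ux = nb$rel_x / nb$dist, uy = nb$rel_y / nb$dist,
       hx = hx, hy = hy, rank = as.integer(nb$rank),
       stepId = s$step_id[ev], n = length(ev))
}

.formCode <- function(form) {
  switch(form, none = 0L, metric = 1L, topological = 2L, expdecay = 3L)
}

.cppLoglik <- function(prep, params) {
  im <- params$interaction
  cpp_step_loglik(prep$theta, prep$thetaPrev, prep$phi, prep$nbOff,
                  prep$d, prep$ux, prep$uy, prep$hx, prep$hy, prep$rank,
                  .formCode(im$form),
                  if (is.null(im$r)) 0 else im$r,
                  if (is.null(im$K)) 0L else im$K,
                  if (is.null(im$ell)) 1 else im$ell,
                  if (is.null(im$a)) 0 else im$a,
                  as.integer(im$alignment),
                  params$alpha, params$beta, params$gamma, params$rho)
}

#' Per-step log-likelihood
#'
#' Evaluates the wrapped Cauchy log density of each observed step heading
#' around its composite expected heading.  Only steps with both `theta`
#' and `theta_prev` defined contribute; the full-data log-likelihood is
#' the sum of the returned vector.
#'
#' @param params `model_params`.
#' @param steps `herd_steps` object (with `phi` attached if the model has
#'   `beta > 0`; missing `phi` redistributes `beta` to persistence).
#' @return numeric vector of per-step log-likelihood contributions, named
#'   by `step_id`.
#' @export
stepLoglik <- function(params, steps) {
  stopifnot(inherits(params, "model_params"), inherits(steps, "herd_steps"))
  prep <- .prepLoglikData(steps)
  ll <- .cppLoglik(prep, params)
  names(ll) <- prep$stepId
  ll
}

# Pure-R reference implementation of the per-step log-likelihood, used as
# an independent second route in the tests.  Deliberately written from the
# model definition (socialHeading / expectedHeading / dwrpcauchy), not
# from the flattened arrays.
.stepLoglikR <- function(params, steps) {
  s <- steps$steps
  ev <- which(!is.na(s$theta) & !is.na(s$theta_prev))
  nbAll <- steps$nb
  out <- numeric(length(ev))
  im <- params$interaction
  for (k in seq_along(ev)) {
    i <- ev[k]
    nb <- nbAll[nbAll$step_id == s$step_id[i], , drop = FALSE]
    if (im$form != "none" && nrow(nb) > 0L) {
      sh <- socialHeading(im, nb$rel_x, nb$rel_y, nb$heading, rank = nb$rank)
    } else {
      sh <- list(psi = NA_real_, magnitude = 0)
    }
    lam <- expectedHeading(params, sh$psi, sh$magnitude, s$phi[i],
                           s$theta_prev[i])
    out[k] <- dwrpcauchy(s$theta[i], lam, params$rho, log = TRUE)
  }
  names(out) <- s$step_id[ev]
  out
}
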