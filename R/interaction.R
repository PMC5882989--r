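# Candidate social interaction rules: metric, topological and
# exponential-decay neighbour weighting, each with or without alignment.

MODEL_SPECS <- c("rw", "env", "metric", "metric+align", "topo", "topo+align",
                 "expdecay", "expdecay+align")

#' Interaction model specification
#'
#' Describes one candidate rule for how neighbours influence a focal
#' individual:
#' \describe{
#'   \item{metric}{all neighbours within a fixed range `r` weigh equally;}
#'   \item{topological}{the `K` nearest neighbours weigh equally,
#'     regardless of distance;}
#'   \item{expdecay}{influence decays exponentially with distance with
#'     length scale `ell` (a "local crowded horizon" rule);}
#'   \item{none}{no social term (used by the plain correlated random walk
#'     and the environment-only model).}
#' }
#' With `alignment = TRUE` the social heading blends attraction (steering
#' toward neighbour positions) with alignment (copying neighbour headings)
#' with strength `a` in \code{[0, 1]}.
#'
#' @param form one of `"none"`, `"metric"`, `"topological"`, `"expdecay"`.
#' @param alignment logical; include an alignment component?
#' @param r metric interaction range, metres (`form = "metric"`).
#' @param K number of nearest neighbours (`form = "topological"`).
#' @param ell decay length, metres (`form = "expdecay"`).
#' @param a alignment strength in \code{[0, 1]} (`alignment = TRUE`).
#' @return object of class `interaction_model`.
#' @export
interactionModel <- function(form = c("none", "metric", "topological",
                                      "expdecay"),
                             alignment = FALSE, r = NULL, K = NULL,
                             ell = NULL, a = NULL) {
  form <- match.arg(form)
  if (form == "metric") {
    if (is.null(r) || is.na(r) || r <= 0)
      stop("metric form requires a range 'r' > 0 (Inf allowed)")
  }
  if (form == "topological") {
    if (is.null(K) || K < 1 || K != round(K))
      stop("topological form requires an integer 'K' >= 1")
    K <- as.integer(K)
  }
  if (form == "expdecay") {
    if (is.null(ell) || ell <= 0) stop("expdecay form requires 'ell' > 0")
  }
  if (alignment) {
    if (form == "none") stop("alignment requires a social form")
    if (is.null(a) || a < 0 || a > 1)
      stop("alignment requires strength 'a' in [0, 1]")
  } else {
    a <- NULL
  }
  structure(list(form = form, alignment = isTRUE(alignment),
                 r = r, K = K, ell = ell, a = a),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  par <- switch(x$form,
                none = "",
                metric = sprintf(" (r = %g m)", x$r),
                topological = sprintf(" (K = %d)", x$K),
                expdecay = sprintf(" (ell = %g m)", x$ell))
  al <- if (x$alignment) sprintf(" + alignment (a = %g)", x$a) else ""
  cat("Interaction rule: ", x$form, par, al, "\n", sep = "")
  invisible(x)
}

#' Parse a model specification string
#'
#' The eight candidate movement models are named `"rw"` (correlated random
#' walk), `"env"` (environment-following, no direct interactions),
#' `"metric"`, `"topo"`, `"expdecay"` and their `"+align"` variants.
#'
#' @param spec one of the strings above.
#' @return list with elements `name`, `form` (interaction form), `alignment`
#'   (logical), `social` (does the model carry a social weight `alpha`?) and
#'   `env` (does it carry an environment weight `beta`?).
#' @export
parseModelSpec <- function(spec) {
  if (is.list(spec) && !is.null(spec$form)) return(spec)
  spec <- match.arg(spec, MODEL_SPECS)
  form <- switch(sub("\\+align$", "", spec),
                 rw = "none", env = "none", metric = "metric",
                 topo = "topological", expdecay = "expdecay")
  list(name = spec,
       form = form,
       alignment = grepl("\\+align$", spec),
       social = form != "none",
       env = spec != "rw")
}

#' Neighbour interaction weights
#'
#' Unnormalised non-negative weights given to each neighbour under an
#' interaction rule: metric \eqn{w_i = 1\{d_i \le r\}}; topological
#' \eqn{w_i = 1} for the `K` smallest distances (ties broken by individual
#' id so the rule is deterministic); exponential decay
#' \eqn{w_i = e^{-d_i/\ell}}.
#'
#' @param model `interaction_model`.
#' @param dist numeric vector of neighbour distances (metres), all > 0.
#' @param rank optional integer vector of precomputed distance ranks
#'   (1 = nearest); required tie-breaking information for the topological
#'   rule when `ids` is not given.
#' @param ids optional character vector of neighbour ids used to break
#'   distance ties when `rank` is not supplied.
#' @return numeric vector of weights, same length as `dist` (empty input
#'   gives an empty vector).
#' @export
neighbourWeights <- function(model, dist, rank = NULL, ids = NULL) {
  stopifnot(inherits(model, "interaction_model"))
  n <- length(dist)
  if (n == 0L) return(numeric(0))
  switch(model$form,
         none = rep(0, n),
         metric = as.numeric(dist <= model$r),
         topological = {
           if (is.null(rank)) {
             o <- if (is.null(ids)) order(dist) else order(dist, ids)
             rank <- integer(n); rank[o] <- seq_len(n)
           }
           as.numeric(rank <= model$K)
         },
         expdecay = exp(-dist / model$ell))
}

#' Social heading
#'
#' Composite heading indicated by the neighbours of a focal individual.
#' With weights \eqn{w_i} from [neighbourWeights()], the attraction
#' resultant is \eqn{A = \sum_i w_i\,\hat u_i} (unit vectors toward
#' neighbour positions) and the alignment resultant is
#' \eqn{G = \sum_i w_i\,\hat h_i} (neighbour heading unit vectors,
#' neighbours with undefined heading contribute only to attraction).  The
#' combined vector is \eqn{V = (1-a)\hat A + a \hat G} where hats denote
#' normalisation to unit length when non-zero and \eqn{a = 0} without
#' alignment.  The social heading is \eqn{\psi = \mathrm{atan2}(V_y, V_x)}.
#'
#' The returned `magnitude` (\eqn{|V|}) lets the caller detect a degenerate
#' social signal (no neighbours, or opposing neighbours cancelling); the
#' movement model then redistributes the social weight to persistence.
#'
#' @param model `interaction_model`.
#' @param relX,relY world-frame neighbour offsets from the focal individual
#'   (metres).
#' @param heading neighbour headings (radians); `NA` allowed.
#' @param ids optional neighbour ids for deterministic topological ties.
#' @param rank optional precomputed distance ranks.
#' @return list with `psi` (radians, `NA` when degenerate), `magnitude`
#'   and `degenerate` (logical; `magnitude < 1e-9`).
#' @export
socialHeading <- function(model, relX, relY, heading = NULL, ids = NULL,
                          rank = NULL) {
  d <- sqrt(relX^2 + relY^2)
  w <- neighbourWeights(model, d, rank = rank, ids = ids)
  if (length(w) == 0L || sum(w) == 0)
    return(list(psi = NA_real_, magnitude = 0, degenerate = TRUE))
  ax <- sum(w * relX / d); ay <- sum(w * relY / d)
  na <- sqrt(ax^2 + ay^2)
  if (na > 0) { ax <- ax / na; ay <- ay / na }
  a <- if (model$alignment) model$a else 0
  gx <- gy <- 0
  if (a > 0 && !is.null(heading)) {
    ok <- !is.na(heading)
    if (any(ok)) {
      gx <- sum(w[ok] * cos(heading[ok]))
      gy <- sum(w[ok] * sin(heading[ok]))
      ng <- sqrt(gx^2 + gy^2)
      if (ng > 0) { gx <- gx / ng; gy <- gy / ng }
    }
  }
  vx <- (1 - a) * ax + a * gx
  vy <- (1 - a) * ay + a * gy
  mag <- sqrt(vx^2 + vy^2)
  if (mag < 1e-9)
    return(list(psi = NA_real_, magnitude = mag, degenerate = TRUE))
  list(psi = atan2(vy, vx), magnitude = mag, degenerate = FALSE)
}
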