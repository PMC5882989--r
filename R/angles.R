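# Circular helpers.  All internal angles are radians, counterclockwise from
# the +x axis, wrapped to (-pi, pi]; degrees appear only at reporting
# surfaces such as heading-change histograms.

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length, each angle reduced modulo
#'   \code{2*pi} into the half-open interval \code{(-pi, pi]}.
#' @examples
#' wrapAngle(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrapAngle <- function(x) {
  w <- x %% (2 * pi)
  i <- !is.na(w) & w > pi
  w[i] <- w[i] - 2 * pi
  w
}

#' Wrapped Cauchy density
#'
#' Density of the wrapped Cauchy distribution with location \code{mu} and
#' concentration \code{rho},
#' \deqn{f(\theta) = \frac{1}{2\pi}\,
#'   \frac{1 - \rho^2}{1 + \rho^2 - 2\rho\cos(\theta - \mu)}.}
#' At \code{rho = 0} this is the uniform density \code{1/(2*pi)}; as
#' \code{rho} approaches 1 it concentrates on \code{mu}.  This is the
#' step-heading distribution of the movement model: each observed step
#' heading is a draw centred on the composite expected heading (see
#' [expectedHeading()]).
#'
#' @param theta angles (radians) at which to evaluate the density.
#' @param mu location parameter (radians).
#' @param rho concentration in \code{[0, 1)}.
#' @param log logical; return the log density?
#' @return numeric vector of (log) densities; the function is periodic in
#'   both \code{theta} and \code{mu}.
#' @examples
#' dwrpcauchy(0, 0, 0)            # 1 / (2 * pi)
#' dwrpcauchy(0, 0, 0.5)          # 3 / (2 * pi)
#' @export
dwrpcauchy <- function(theta, mu = 0, rho = 0, log = FALSE) {
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho >= 1))
    stop("'rho' must lie in [0, 1)")
  ld <- log1p(-rho^2) - log(2 * pi) - log1p(rho^2 - 2 * rho * cos(theta - mu))
  if (log) ld else exp(ld)
}

#' Draw from a wrapped Cauchy distribution
#'
#' Inverse-CDF sampler: \code{mu + 2*atan(((1-rho)/(1+rho)) * tan(pi*(u - 0.5)))}
#' with \code{u} uniform on (0, 1), wrapped to \code{(-pi, pi]}.
#'
#' @param n number of draws.
#' @param mu location (radians); recycled.
#' @param rho concentration in \code{[0, 1)}; recycled.
#' @return numeric vector of \code{n} angles in \code{(-pi, pi]}.
#' @export
rwrpcauchy <- function(n, mu = 0, rho = 0) {
  if (any(rho < 0) || any(rho >= 1)) stop("'rho' must lie in [0, 1)")
  u <- runif(n)
  wrapAngle(mu + 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5))))
}

#' Circular mean and mean resultant length
#'
#' @param x angles in radians.
#' @param w optional non-negative weights.
#' @return list with \code{mean} (circular mean, radians; \code{NA} if the
#'   resultant is shorter than \code{1e-9}) and \code{rbar} (mean resultant
#'   length in \code{[0, 1]}).
#' @export
circMean <- function(x, w = NULL) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(list(mean = NA_real_, rbar = NA_real_))
  if (is.null(w)) w <- rep(1, length(x))
  sx <- sum(w * cos(x))
  sy <- sum(w * sin(x))
  sw <- sum(w)
  r <- sqrt(sx^2 + sy^2)
  list(mean = if (r < 1e-9) NA_real_ else atan2(sy, sx), rbar = r / sw)
}

#' Polarization of a set of headings
#'
#' Length of the mean heading unit vector: 1 for perfectly aligned headings,
#' near 0 for isotropic headings.  Accepts a numeric vector of angles or a
#' discretised step set (all defined step headings are used).
#'
#' @param x numeric vector of headings (radians) or a `herd_steps` object.
#' @return scalar in \code{[0, 1]}.
#' @export
polarization <- function(x) {
  if (inherits(x, "herd_steps")) x <- x$steps$theta
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean(cos(x))^2 + mean(sin(x))^2)
}
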