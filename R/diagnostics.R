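# Focal-frame descriptive diagnostics: where neighbours sit relative to a
# focal individual, how variable their headings are, whether they move
# toward or away from it, how a fitted rule weights them, and where one
# model outperforms another.

# Rotate every neighbour record into its focal individual's frame: the
# focal heading points along +y ("front" up).  Returns focal-frame
# offsets, the neighbour heading in the same frame, and the step index.
.focalFrame <- function(steps) {
  s <- steps$steps
  nb <- steps$nb
  ok <- !is.na(s$theta)
  m <- match(nb$step_id, s$step_id)
  keep <- ok[m]
  nb <- nb[keep, , drop = FALSE]; m <- m[keep]
  delta <- pi / 2 - s$theta[m]
  cd <- cos(delta); sdl <- sin(delta)
  data.frame(step_id = nb$step_id,
             fx = cd * nb$rel_x - sdl * nb$rel_y,
             fy = sdl * nb$rel_x + cd * nb$rel_y,
             fh = wrapAngle(nb$heading + delta),
             stringsAsFactors = FALSE)
}

.gridIndex <- function(v, extent, cell) {
  n <- round(2 * extent / cell)
  i <- floor((v + extent) / cell) + 1L
  i[i < 1L | i > n] <- NA_integer_
  i
}

.newFocalGrid <- function(values, extent, cell, type, n = NULL) {
  mids <- seq(-extent + cell / 2, extent - cell / 2, by = cell)
  structure(list(values = values, n = n, extent = extent, cell = cell,
                 mids = mids, type = type),
            class = "focal_grid")
}

#' @export
print.focal_grid <- function(x, ...) {
  cat("Focal-frame grid (", x$type, "): ", nrow(x$values), " x ",
      ncol(x$values), " cells of ", x$cell, " m, extent +/-", x$extent,
      " m\n", sep = "")
  invisible(x)
}

#' Plot a focal-frame grid
#'
#' Simple image rendering; the focal individual sits at the origin and
#' faces up (+y).
#'
#' @param x `focal_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.focal_grid <- function(x, ...) {
  graphics::image(x$mids, x$mids, x$values, xlab = "left-right (m)",
                  ylab = "back-front (m)", main = x$type, ...)
  invisible(x)
}

#' Relative-position heatmap
#'
#' Probability that a neighbour occupies each focal-frame cell (focal
#' individual at the origin, facing +y).  Cells sum to 1.  Line-forming
#' herds concentrate mass on the front-back axis.
#'
#' @param steps `herd_steps`.
#' @param extent half-width of the focal frame, metres.
#' @param cell cell size, metres.
#' @return `focal_grid` whose `values` sum to 1 (neighbours outside the
#'   extent are dropped before normalisation).
#' @export
relativePositionHeatmap <- function(steps, extent = 10, cell = 0.5) {
  ff <- .focalFrame(steps)
  nc <- round(2 * extent / cell)
  ix <- .gridIndex(ff$fx, extent, cell)
  iy <- .gridIndex(ff$fy, extent, cell)
  ok <- !is.na(ix) & !is.na(iy)
  cnt <- matrix(0, nc, nc)
  tb <- table(factor(ix[ok], levels = 1:nc), factor(iy[ok], levels = 1:nc))
  cnt <- matrix(as.numeric(tb), nc, nc)
  if (sum(cnt) == 0) stop("no neighbours inside the focal-frame extent")
  .newFocalGrid(cnt / sum(cnt), extent, cell, "relative position", n = cnt)
}

#' Circular-variance map
#'
#' Per focal-frame cell, the circular variance \eqn{1 - \bar R} of the
#' headings of neighbours observed there (headings measured relative to
#' the focal heading): 0 when all occupants head the same way, up to 1
#' for fully dispersed headings.
#'
#' @inheritParams relativePositionHeatmap
#' @param nMin cells with fewer heading observations are masked (`NA`).
#' @return `focal_grid` with values in \code{[0, 1]}.
#' @export
circularVarianceMap <- function(steps, extent = 10, cell = 0.5, nMin = 10) {
  ff <- .focalFrame(steps)
  ff <- ff[!is.na(ff$fh), , drop = FALSE]
  nc <- round(2 * extent / cell)
  ix <- .gridIndex(ff$fx, extent, cell)
  iy <- .gridIndex(ff$fy, extent, cell)
  ok <- !is.na(ix) & !is.na(iy)
  idx <- (iy[ok] - 1L) * nc + ix[ok]
  sx <- rowsum(cos(ff$fh[ok]), idx)
  sy <- rowsum(sin(ff$fh[ok]), idx)
  n <- rowsum(rep(1, sum(ok)), idx)
  vals <- matrix(NA_real_, nc, nc)
  cnt <- matrix(0, nc, nc)
  ii <- as.integer(rownames(sx))
  vals[ii] <- 1 - sqrt(sx^2 + sy^2) / n
  cnt[ii] <- n
  vals[cnt < nMin] <- NA_real_
  .newFocalGrid(vals, extent, cell, "circular variance", n = cnt)
}

#' Orientation-projection map
#'
#' Per focal-frame cell, the mean heading unit vector of occupants
#' projected onto the unit vector pointing from the cell centre toward the
#' focal individual: +1 for neighbours moving straight at the focal
#' animal, -1 for neighbours moving directly away, 0 for perpendicular
#' motion.
#'
#' @inheritParams circularVarianceMap
#' @return `focal_grid` with values in \code{[-1, 1]} (masked below
#'   `nMin`).
#' @export
orientationProjectionMap <- function(steps, extent = 10, cell = 0.5,
                                     nMin = 10) {
  ff <- .focalFrame(steps)
  ff <- ff[!is.na(ff$fh), , drop = FALSE]
  nc <- round(2 * extent / cell)
  ix <- .gridIndex(ff$fx, extent, cell)
  iy <- .gridIndex(ff$fy, extent, cell)
  ok <- !is.na(ix) & !is.na(iy)
  idx <- (iy[ok] - 1L) * nc + ix[ok]
  mx <- rowsum(cos(ff$fh[ok]), idx)
  my <- rowsum(sin(ff$fh[ok]), idx)
  n <- rowsum(rep(1, sum(ok)), idx)
  vals <- matrix(NA_real_, nc, nc)
  cnt <- matrix(0, nc, nc)
  ii <- as.integer(rownames(mx))
  mids <- seq(-extent + cell / 2, extent - cell / 2, by = cell)
  cx <- mids[(ii - 1L) %% nc + 1L]
  cy <- mids[(ii - 1L) %/% nc + 1L]
  rr <- sqrt(cx^2 + cy^2)
  ux <- ifelse(rr > 0, -cx / rr, 0)
  uy <- ifelse(rr > 0, -cy / rr, 0)
  vals[ii] <- (mx / n) * ux + (my / n) * uy
  cnt[ii] <- n
  vals[cnt < nMin] <- NA_real_
  .newFocalGrid(vals, extent, cell, "orientation projection", n = cnt)
}

#' Neighbour-influence map
#'
#' Evaluates the interaction weight a fitted rule gives a (lone) neighbour
#' at each focal-frame cell centre, normalised to a maximum of 1.  All
#' three rules depend on distance only, so the map is isotropic; for the
#' exponential-decay rule the value at distance `ell` is `exp(-1)` times
#' the near-origin value.
#'
#' @param model `interaction_model` (typically at the maximum a posteriori
#'   parameters of the best-fitting model).
#' @param extent half-width of the map, metres.
#' @param cell cell size, metres.
#' @return `focal_grid` of normalised weights.
#' @export
influenceMap <- function(model, extent = 10, cell = 0.5) {
  stopifnot(inherits(model, "interaction_model"))
  mids <- seq(-extent + cell / 2, extent - cell / 2, by = cell)
  nc <- length(mids)
  d <- sqrt(outer(mids^2, mids^2, "+"))
  w <- matrix(neighbourWeights(model, pmax(as.numeric(d), 1e-12),
                               rank = rep(1L, nc * nc)), nc, nc)
  mx <- max(w)
  .newFocalGrid(if (mx > 0) w / mx else w, extent, cell,
                "neighbour influence")
}

# Gaussian smoothing over unmasked bins (sd in bins).
.gaussSmooth <- function(v, sigma) {
  n <- length(v)
  out <- rep(NA_real_, n)
  ok <- !is.na(v)
  for (i in which(ok)) {
    w <- exp(-((seq_len(n) - i)^2) / (2 * sigma^2))
    w[!ok] <- 0
    out[i] <- sum(w * v, na.rm = TRUE) / sum(w)
  }
  out
}

#' Model performance as a function of neighbour distance
#'
#' For each likelihood-usable step, the difference in the wrapped Cauchy
#' step-heading probability density under two parameterisations,
#' \eqn{\Delta p = p_A(\theta_t) - p_B(\theta_t)} (both typically at their
#' maximum a posteriori values), binned by the distance to the nearest or
#' second-nearest neighbour.  Positive values mean model A assigned the
#' observed step a higher probability.  Binned means are smoothed with a
#' Gaussian filter; the standard error of the mean is reported per bin.
#'
#' @param steps `herd_steps`.
#' @param paramsA,paramsB `model_params` objects.
#' @param whichNeighbour 1 (nearest) or 2 (second nearest).
#' @param binWidth bin width in metres.
#' @param smoothSigma Gaussian smoothing standard deviation, in bins.
#' @param minPerBin bins with fewer steps are masked.
#' @return data frame with columns `dist` (bin midpoint), `mean`, `se`,
#'   `n`, `smoothed`; masked bins carry `NA` means.
#' @export
performanceVsDistance <- function(steps, paramsA, paramsB,
                                  whichNeighbour = 1, binWidth = 1,
                                  smoothSigma = 1, minPerBin = 5) {
  stopifnot(whichNeighbour %in% c(1, 2))
  llA <- stepLoglik(paramsA, steps)
  llB <- stepLoglik(paramsB, steps)
  dp <- exp(llA) - exp(llB)
  nb <- steps$nb[steps$nb$rank == whichNeighbour, , drop = FALSE]
  d <- nb$dist[match(as.integer(names(llA)), nb$step_id)]
  ok <- !is.na(d)
  dp <- dp[ok]; d <- d[ok]
  if (!length(d)) stop("no steps with a rank-", whichNeighbour, " neighbour")
  bin <- floor(d / binWidth)
  binsAll <- seq(0L, max(bin))
  f <- factor(bin, levels = binsAll)
  n <- as.integer(table(f))
  mu <- tapply(dp, f, mean)
  s2 <- tapply(dp, f, var)
  se <- sqrt(s2 / n)
  mu[n < minPerBin] <- NA_real_
  se[n < minPerBin] <- NA_real_
  data.frame(dist = (binsAll + 0.5) * binWidth,
             mean = as.numeric(mu), se = as.numeric(se), n = n,
             smoothed = .gaussSmooth(as.numeric(mu), smoothSigma))
}
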