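# Trajectory data model: raw fixes, CSV IO, and discretisation into
# movement steps with neighbour and heading context.

CLASS_LEVELS <- c("calf", "adult", "large_bull", "unknown")

#' Construct a trajectory table
#'
#' Validates a data frame of time-stamped positions (fixes) and returns a
#' `herd_traj` object.  One row per fix, columns `herd_id`, `individual_id`,
#' `t` (seconds), `x`, `y` (metres) and optionally `class` (one of
#' `"calf"`, `"adult"`, `"large_bull"`, `"unknown"`).
#'
#' @param df data frame with the columns above.
#' @return `herd_traj` data frame, sorted by herd, individual and time.
#' @details Within each individual, times must be strictly increasing;
#'   duplicate timestamps are rejected with a diagnostic naming the
#'   individual.  Positions must be finite planar metres (no geographic
#'   coordinates).
#' @export
herdTrajectory <- function(df) {
  need <- c("herd_id", "individual_id", "t", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory table is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$herd_id <- as.character(df$herd_id)
  df$individual_id <- as.character(df$individual_id)
  for (cc in c("t", "x", "y")) df[[cc]] <- as.numeric(df[[cc]])
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("non-finite x/y positions in trajectory table")
  if (any(!is.finite(df$t)) || any(df$t < 0))
    stop("'t' must be finite and non-negative (seconds)")
  if (is.null(df$class)) {
    df$class <- "unknown"
  } else {
    df$class <- as.character(df$class)
    df$class[is.na(df$class) | df$class == ""] <- "unknown"
    bad <- setdiff(unique(df$class), CLASS_LEVELS)
    if (length(bad))
      stop("unknown class label(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(CLASS_LEVELS, collapse = ", "), ")")
  }
  df <- df[order(df$herd_id, df$individual_id, df$t), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$herd_id, df$individual_id, sep = "\r")
  dup <- tapply(df$t, key, function(tt) any(diff(tt) <= 0))
  if (any(unlist(dup))) {
    who <- names(dup)[which(unlist(dup))[1L]]
    stop("non-increasing or duplicate timestamps for individual '",
         sub(".*\r", "", who), "' in herd '", sub("\r.*", "", who), "'")
  }
  class(df) <- c("herd_traj", "data.frame")
  df
}

#' Read a trajectory CSV
#'
#' Reads the package's trajectory dialect: header row, UTF-8, `.` decimal
#' separator, columns `herd_id,individual_id,t,x,y[,class]`.
#'
#' @param file path to the CSV file.
#' @return `herd_traj` data frame (see [herdTrajectory()]).
#' @seealso [writeTrajectories()] for the inverse; the pair round-trips
#'   bit-exactly at the text level for files produced by the writer.
#' @export
readTrajectories <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  herdTrajectory(df)
}

#' Write a trajectory CSV
#'
#' @param traj `herd_traj` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTrajectories <- function(traj, file) {
  stopifnot(inherits(traj, "herd_traj"))
  out <- data.frame(herd_id = traj$herd_id,
                    individual_id = traj$individual_id,
                    t = as.character(traj$t),
                    x = as.character(traj$x),
                    y = as.character(traj$y),
                    class = traj$class,
                    stringsAsFactors = FALSE)
  write.csv(out, file, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Low-level step-set constructor
#'
#' Assembles a `herd_steps` object from already-computed step and neighbour
#' tables.  Most users obtain steps from [discretize()]; this constructor is
#' for pipelines with their own discretisation (or for building small test
#' configurations by hand).
#'
#' @param steps data frame with columns `step_id` (unique integer),
#'   `herd_id`, `individual_id`, `class`, `t_start`, `x`, `y`, `theta`,
#'   `theta_prev` (radians, `NA` allowed) and optionally `phi`.
#' @param neighbours data frame with columns `step_id`, `nb_id`, `rel_x`,
#'   `rel_y`, `dist`, `heading` (`NA` allowed), `class`, `rank` (1 =
#'   nearest; ties broken by id).  Relative positions are world-frame.
#' @param dt step duration, seconds.
#' @param minDisp minimum displacement (m) used to define a heading.
#' @return `herd_steps` object: a list with elements `steps`, `nb`, `dt`,
#'   `minDisp`.
#' @export
herdSteps <- function(steps, neighbours, dt, minDisp = 0.05) {
  stopifnot(is.data.frame(steps), is.data.frame(neighbours), dt > 0)
  if (anyDuplicated(steps$step_id)) stop("duplicate step_id")
  if (is.null(steps$phi)) steps$phi <- NA_real_
  if (!all(neighbours$step_id %in% steps$step_id))
    stop("neighbour rows reference unknown step_id")
  ok <- is.na(steps$theta) | (steps$theta > -pi & steps$theta <= pi + 1e-12)
  if (!all(ok)) stop("step headings must be wrapped to (-pi, pi]")
  nb <- neighbours[order(neighbours$step_id, neighbours$rank), , drop = FALSE]
  rownames(steps) <- rownames(nb) <- NULL
  structure(list(steps = steps, nb = nb, dt = dt, minDisp = minDisp),
            class = "herd_steps")
}

#' @export
print.herd_steps <- function(x, ...) {
  s <- x$steps
  cat("Discretised movement steps (dt = ", x$dt, " s)\n", sep = "")
  cat("  ", nrow(s), " steps, ", sum(!is.na(s$theta) & !is.na(s$theta_prev)),
      " usable for likelihood (theta and theta_prev defined)\n", sep = "")
  cat("  ", length(unique(s$herd_id)), " herd(s), ",
      length(unique(paste(s$herd_id, s$individual_id))), " individuals, ",
      nrow(x$nb), " neighbour records\n", sep = "")
  cat("  environmental heading: ",
      if (all(is.na(s$phi))) "not attached" else
        paste0(sum(!is.na(s$phi)), " steps"), "\n", sep = "")
  invisible(x)
}

# Split an individual's fixes into segments at gaps > maxGapFactor * dt.
.splitSegments <- function(t, maxGap) {
  brk <- c(0L, which(diff(t) > maxGap), length(t))
  lapply(seq_len(length(brk) - 1L),
         function(i) (brk[i] + 1L):brk[i + 1L])
}

#' Discretise trajectories into movement steps
#'
#' Resamples each track onto a regular time grid (grid points at integer
#' multiples of `dt`, linear interpolation between fixes, no extrapolation)
#' and emits one step record per grid interval whose displacement defines a
#' heading.  Each record carries the step heading `theta` (the direction of
#' the displacement over \code{[t_start, t_start + dt]}), the previous
#' heading `theta_prev` (`NA` at track starts and after gaps), and a
#' snapshot of all other herd members present at `t_start`: their
#' world-frame relative position, distance, heading over the interval
#' ending at `t_start` (`NA` if undefined), demographic class and distance
#' rank (1 = nearest, ties broken by individual id).
#'
#' Displacements shorter than `minDisp` define no heading (below position
#' noise); such intervals yield no step record, but the individual still
#' appears in neighbour snapshots.  Gaps longer than `maxGapFactor * dt`
#' are not bridged: the track is split and headings are not carried across.
#'
#' @param traj `herd_traj` object (see [herdTrajectory()]).
#' @param dt step duration in seconds (default 2).
#' @param minDisp minimum displacement in metres defining a heading.
#' @param maxGapFactor gaps longer than `maxGapFactor * dt` split a track.
#' @return `herd_steps` object (see [herdSteps()]).
#' @examples
#' tr <- herdTrajectory(data.frame(
#'   herd_id = "h", individual_id = rep(c("a", "b"), each = 6),
#'   t = rep(seq(0, 10, by = 2), 2),
#'   x = c(seq(0, 10, by = 2), seq(0, 10, by = 2)),
#'   y = rep(c(0, 3), each = 6)))
#' st <- discretize(tr, dt = 2)
#' st$steps$theta        # all 0: both individuals move due east
#' @export
discretize <- function(traj, dt = 2, minDisp = 0.05, maxGapFactor = 2) {
  stopifnot(inherits(traj, "herd_traj"), dt > 0, minDisp >= 0)
  key <- paste(traj$herd_id, traj$individual_id, sep = "\r")
  pieces <- split(seq_len(nrow(traj)), key)

  posL <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    idx <- pieces[[i]]
    tt <- traj$t[idx]; xx <- traj$x[idx]; yy <- traj$y[idx]
    segs <- .splitSegments(tt, maxGapFactor * dt)
    segL <- list()
    for (sg in segs) {
      if (length(sg) < 2L) next
      t1 <- tt[sg[1L]]; t2 <- tt[sg[length(sg)]]
      ks <- seq(ceiling(t1 / dt - 1e-9), floor(t2 / dt + 1e-9))
      if (length(ks) < 2L) next
      gt <- ks * dt
      gx <- approx(tt[sg], xx[sg], xout = gt, ties = "ordered")$y
      gy <- approx(tt[sg], yy[sg], xout = gt, ties = "ordered")$y
      dxy <- cbind(diff(gx), diff(gy))
      disp <- sqrt(rowSums(dxy^2))
      hh <- ifelse(disp >= minDisp, atan2(dxy[, 2L], dxy[, 1L]), NA_real_)
      # heading "arriving" at grid point j is the heading over the interval
      # ending there; undefined at the segment start
      segL[[length(segL) + 1L]] <- data.frame(
        t = gt, x = gx, y = gy,
        h_arr = c(NA_real_, hh),           # heading over [t - dt, t]
        h_dep = c(hh, NA_real_),           # heading over [t, t + dt]
        stringsAsFactors = FALSE)
    }
    if (!length(segL)) next
    seg <- do.call(rbind, segL)
    seg$herd_id <- traj$herd_id[idx[1L]]
    seg$individual_id <- traj$individual_id[idx[1L]]
    seg$class <- traj$class[idx[1L]]
    posL[[i]] <- seg
  }
  pos <- do.call(rbind, posL[!vapply(posL, is.null, TRUE)])
  if (is.null(pos) || nrow(pos) == 0L)
    stop("no resampled positions: tracks too short for dt = ", dt)
  pos <- pos[order(pos$herd_id, pos$t, pos$individual_id), , drop = FALSE]
  rownames(pos) <- NULL

  # step records: grid points with a departing heading
  si <- which(!is.na(pos$h_dep))
  steps <- data.frame(step_id = seq_along(si),
                      herd_id = pos$herd_id[si],
                      individual_id = pos$individual_id[si],
                      class = pos$class[si],
                      t_start = pos$t[si],
                      x = pos$x[si], y = pos$y[si],
                      theta = pos$h_dep[si],
                      theta_prev = pos$h_arr[si],
                      phi = NA_real_,
                      stringsAsFactors = FALSE)

  # neighbour snapshots: all other herd members with a position at t_start
  posKey <- paste(pos$herd_id, pos$t, sep = "\r")
  stepKey <- posKey[si]
  grp <- split(seq_len(nrow(pos)), posKey)
  hits <- grp[stepKey]                      # list parallel to steps
  nper <- lengths(hits)
  stepRep <- rep.int(steps$step_id, nper)
  pj <- unlist(hits, use.names = FALSE)
  keep <- pos$individual_id[pj] != rep.int(steps$individual_id, nper)
  stepRep <- stepRep[keep]; pj <- pj[keep]
  relx <- pos$x[pj] - steps$x[stepRep]
  rely <- pos$y[pj] - steps$y[stepRep]
  nb <- data.frame(step_id = stepRep,
                   nb_id = pos$individual_id[pj],
                   rel_x = relx, rel_y = rely,
                   dist = sqrt(relx^2 + rely^2),
                   heading = pos$h_arr[pj],
                   class = pos$class[pj],
                   stringsAsFactors = FALSE)
  ord <- order(nb$step_id, nb$dist, nb$nb_id)
  nb <- nb[ord, , drop = FALSE]
  nb$rank <- sequence(tabulate(factor(nb$step_id, levels = steps$step_id)))
  herdSteps(steps, nb, dt = dt, minDisp = minDisp)
}

#' Heading autocorrelation
#'
#' Mean cosine of the heading change over a time lag,
#' \eqn{C(\tau) = \langle \cos(\theta(t+\tau) - \theta(t)) \rangle},
#' averaged over individuals and times; \eqn{C(0) = 1}.  Used to choose the
#' discretisation interval: persistence decays with lag, and a kink in the
#' decay suggests the natural step duration.
#'
#' @param steps `herd_steps` object.
#' @param maxLag maximum lag in seconds.
#' @return data frame with columns `lag` (seconds, multiples of the step
#'   duration starting at 0), `correlation` and `n` (number of heading
#'   pairs); lags with no pairs are dropped, with a warning if none remain.
#' @export
headingAutocorrelation <- function(steps, maxLag) {
  stopifnot(inherits(steps, "herd_steps"), maxLag >= 0)
  dt <- steps$dt
  s <- steps$steps[!is.na(steps$steps$theta), , drop = FALSE]
  byInd <- split(s[, c("t_start", "theta")],
                 paste(s$herd_id, s$individual_id, sep = "\r"))
  lags <- seq(0, maxLag, by = dt)
  sums <- numeric(length(lags)); ns <- integer(length(lags))
  for (ser in byInd) {
    tt <- ser$t_start; th <- ser$theta
    for (k in seq_along(lags)) {
      j <- match(tt + lags[k], tt)
      ok <- !is.na(j)
      if (!any(ok)) next
      sums[k] <- sums[k] + sum(cos(th[j[ok]] - th[ok]))
      ns[k] <- ns[k] + sum(ok)
    }
  }
  keep <- ns > 0L
  if (!any(keep)) {
    warning("no heading pairs available up to maxLag = ", maxLag)
    return(data.frame(lag = numeric(0), correlation = numeric(0),
                      n = integer(0)))
  }
  data.frame(lag = lags[keep], correlation = sums[keep] / ns[keep],
             n = ns[keep])
}

# Least-squares Gaussian fit to a normalised histogram of heading changes
# (degrees).  Returns mu, sigma and a degeneracy flag.
.fitGaussianHist <- function(deg, binWidth, sigmaMin) {
  breaks <- seq(-180, 180, by = binWidth)
  h <- graphics::hist(deg, breaks = breaks, plot = FALSE)
  dens <- h$density
  mids <- h$mids
  if (sd(deg) < sigmaMin) {
    return(list(mu = mean(deg), sigma = sigmaMin, degenerate = TRUE,
                mids = mids, density = dens))
  }
  obj <- function(p) sum((dens - dnorm(mids, p[1L], exp(p[2L])))^2)
  fit <- optim(c(mean(deg), log(max(sd(deg), sigmaMin))), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1L], sigma = max(exp(fit$par[2L]), sigmaMin),
       degenerate = FALSE, mids = mids, density = dens)
}

#' Distribution of per-step heading changes
#'
#' Computes the heading change \eqn{\theta_t - \theta_{t-1}} for every step
#' with both headings defined, wraps it to \code{(-180, 180]} degrees,
#' bins it into a normalised histogram, and fits a Gaussian curve (free
#' mean, positive standard deviation) to the histogram by least squares.
#' Strongly aligned herds give a narrow, zero-centred distribution (a
#' standard deviation of a few degrees per step).
#'
#' @param x `herd_steps` object, or a numeric vector of heading changes in
#'   radians.
#' @param binWidth histogram bin width in degrees.
#' @param sigmaMin lower bound for the fitted standard deviation (degrees);
#'   an all-identical sample returns this bound with `degenerate = TRUE`.
#' @return object of class `heading_change_fit`: list with `mu`, `sigma`
#'   (degrees), `degenerate`, `changes` (degrees), `mids`, `density`.
#' @export
headingChangeDist <- function(x, binWidth = 1, sigmaMin = 1e-3) {
  if (inherits(x, "herd_steps")) {
    s <- x$steps
    ch <- wrapAngle(s$theta - s$theta_prev)
    ch <- ch[!is.na(ch)]
  } else {
    ch <- wrapAngle(as.numeric(x[!is.na(x)]))
  }
  if (length(ch) < 30L)
    stop("need at least 30 heading changes for a stable fit (got ",
         length(ch), ")")
  deg <- ch * 180 / pi
  deg[deg <= -180] <- 180
  f <- .fitGaussianHist(deg, binWidth, sigmaMin)
  structure(list(mu = f$mu, sigma = f$sigma, degenerate = f$degenerate,
                 changes = deg, mids = f$mids, density = f$density),
            class = "heading_change_fit")
}

#' @export
print.heading_change_fit <- function(x, ...) {
  cat("Per-step heading change distribution (", length(x$changes),
      " steps)\n", sep = "")
  cat(sprintf("  Gaussian fit: mu = %.3f deg, sigma = %.3f deg%s\n",
              x$mu, x$sigma,
              if (x$degenerate) "  [degenerate: zero spread]" else ""))
  invisible(x)
}
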