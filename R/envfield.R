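# Track-derived environmental heading field: the average heading of all
# herd members crossing each fixed cell in space, queried leave-one-out so
# an individual's own steps never inform its environmental cue.

#' Build a heading grid from steps
#'
#' Every step with a defined heading contributes its heading unit vector to
#' the grid cell containing its start position, tagged by the contributing
#' individual so later queries can exclude the focal animal.
#'
#' @param steps `herd_steps` object, or its `$steps` data frame (typically
#'   one herd; see [attachEnvGrid()] for the per-herd pipeline).
#' @param cell grid spacing in metres (default 5, roughly 2-3 body lengths).
#' @param origin grid origin, `c(x, y)`.
#' @return object of class `heading_grid`: per (cell, individual) sums of
#'   heading unit vectors with contribution counts.
#' @export
buildHeadingGrid <- function(steps, cell = 5, origin = c(0, 0)) {
  s <- if (inherits(steps, "herd_steps")) steps$steps else steps
  s <- s[!is.na(s$theta), , drop = FALSE]
  if (nrow(s) == 0L) stop("no steps with a defined heading")
  cx <- floor((s$x - origin[1L]) / cell)
  cy <- floor((s$y - origin[2L]) / cell)
  key <- paste(cx, cy, s$individual_id, sep = "\r")
  ag <- rowsum(cbind(sx = cos(s$theta), sy = sin(s$theta), n = 1), key)
  parts <- strsplit(rownames(ag), "\r", fixed = TRUE)
  tab <- data.frame(cellKey = vapply(parts, function(p)
                      paste(p[1L], p[2L], sep = "\r"), ""),
                    individual_id = vapply(parts, `[`, "", 3L),
                    sx = ag[, "sx"], sy = ag[, "sy"], n = ag[, "n"],
                    stringsAsFactors = FALSE, row.names = NULL)
  tot <- rowsum(cbind(tx = tab$sx, ty = tab$sy, n = tab$n), tab$cellKey)
  structure(list(origin = origin, cell = cell, tab = tab,
                 totals = data.frame(cellKey = rownames(tot),
                                     tx = tot[, "tx"], ty = tot[, "ty"],
                                     n = tot[, "n"],
                                     stringsAsFactors = FALSE,
                                     row.names = NULL)),
            class = "heading_grid")
}

#' @export
print.heading_grid <- function(x, ...) {
  cat("Heading grid: cell ", x$cell, " m, ", nrow(x$totals),
      " populated cells, ", sum(x$totals$n), " contributions\n", sep = "")
  invisible(x)
}

#' Leave-one-out environmental heading
#'
#' Circular mean of all heading contributions in the cell containing a
#' queried position, excluding those of the focal individual.  Returns
#' `NA` ("missing") for unpopulated cells, cells whose only contributors
#' are the focal individual, and cells whose non-focal resultant is
#' numerically zero (opposing headings cancelling).
#'
#' @param grid `heading_grid` from [buildHeadingGrid()].
#' @param x,y query positions (metres); vectorised.
#' @param focalId focal individual id(s), recycled to the query length.
#' @return numeric vector of headings (radians) with `NA` for missing.
#' @export
envHeading <- function(grid, x, y, focalId) {
  stopifnot(inherits(grid, "heading_grid"))
  n <- max(length(x), length(y), length(focalId))
  x <- rep_len(x, n); y <- rep_len(y, n); focalId <- rep_len(focalId, n)
  cx <- floor((x - grid$origin[1L]) / grid$cell)
  cy <- floor((y - grid$origin[2L]) / grid$cell)
  ck <- paste(cx, cy, sep = "\r")
  it <- match(ck, grid$totals$cellKey)
  tx <- grid$totals$tx[it]; ty <- grid$totals$ty[it]
  nn <- grid$totals$n[it]
  io <- match(paste(ck, focalId, sep = "\r"),
              paste(grid$tab$cellKey, grid$tab$individual_id, sep = "\r"))
  own <- !is.na(io)
  tx[own] <- tx[own] - grid$tab$sx[io[own]]
  ty[own] <- ty[own] - grid$tab$sy[io[own]]
  nn[own] <- nn[own] - grid$tab$n[io[own]]
  out <- atan2(ty, tx)
  out[is.na(it) | nn <= 0 | sqrt(tx^2 + ty^2) < 1e-9] <- NA_real_
  out
}

#' Attach grid-estimated environmental headings to steps
#'
#' Builds a heading grid from the steps themselves (herd-specific by
#' default, or pooled across herds) and fills the `phi` column of the step
#' table with the leave-one-out cell average at each step's start position.
#' This is the track-derived stand-in for unobserved environmental features
#' such as trails and obstacles: where the rest of the herd consistently
#' heads the same way at a location, that direction is taken as the local
#' environmental cue.
#'
#' @param steps `herd_steps` object.
#' @param cell grid spacing in metres.
#' @param pool pool contributions across herds at shared locations?
#'   Default `FALSE` (herd-specific fields).
#' @return the `herd_steps` object with `phi` filled in.
#' @export
attachEnvGrid <- function(steps, cell = 5, pool = FALSE) {
  stopifnot(inherits(steps, "herd_steps"))
  s <- steps$steps
  phi <- rep(NA_real_, nrow(s))
  groups <- if (pool) list(seq_len(nrow(s))) else
    split(seq_len(nrow(s)), s$herd_id)
  for (idx in groups) {
    g <- buildHeadingGrid(s[idx, , drop = FALSE], cell = cell)
    phi[idx] <- envHeading(g, s$x[idx], s$y[idx], s$individual_id[idx])
  }
  steps$steps$phi <- phi
  steps
}

#' Attach environmental headings from a vector field
#'
#' Evaluates a heading field (e.g. from [makeEnvField()], or the generator's
#' true field when validating on simulated data) at each step's start
#' position and stores it in the `phi` column.
#'
#' @param steps `herd_steps` object.
#' @param field function `(x, y) -> heading` in radians.
#' @return the `herd_steps` object with `phi` filled in.
#' @export
attachEnvField <- function(steps, field) {
  stopifnot(inherits(steps, "herd_steps"), is.function(field))
  steps$steps$phi <- field(steps$steps$x, steps$steps$y)
  steps
}
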