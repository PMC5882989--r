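# Predictive information criteria from posterior samples, and the ranked
# model-comparison table against the random-walk baseline.

#' Widely applicable information criterion
#'
#' Computed from a draws-by-steps log-likelihood matrix:
#' \deqn{\mathrm{lppd} = \sum_i \log\Big(\tfrac1S \sum_s e^{\ell_{si}}\Big),
#' \qquad p_\mathrm{WAIC} = \sum_i \mathrm{Var}_s(\ell_{si}),
#' \qquad \mathrm{WAIC} = -2(\mathrm{lppd} - p_\mathrm{WAIC}).}
#' The log-mean-exp is evaluated with a max shift for stability, and the
#' penalty uses the sample-variance form (Gelman's \eqn{p_{\mathrm{WAIC}2}}).
#' The data-point unit is one movement step.
#'
#' @param loglikMatrix numeric matrix, S posterior draws by N steps, of
#'   per-step log-likelihoods; all entries must be finite.
#' @return list with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(loglikMatrix) {
  ll <- as.matrix(loglikMatrix)
  if (anyNA(ll) || any(!is.finite(ll))) {
    bad <- which(!is.finite(ll), arr.ind = TRUE)[1L, ]
    stop("non-finite log-likelihood at draw ", bad[1L], ", step ", bad[2L])
  }
  if (nrow(ll) < 2L) stop("need at least 2 posterior draws")
  m <- apply(ll, 2L, max)
  lppd <- sum(m + log(colMeans(exp(sweep(ll, 2L, m)))))
  pw <- sum(apply(ll, 2L, var))
  list(waic = -2 * (lppd - pw), lppd = lppd, p_waic = pw)
}

#' Deviance information criterion
#'
#' \deqn{p_D = \overline{D} - D(\bar\theta), \qquad
#'       \mathrm{DIC} = D(\bar\theta) + 2 p_D,}
#' where \eqn{\overline{D}} is the posterior mean deviance
#' (\eqn{-2\sum_i \ell_{si}} averaged over draws) and
#' \eqn{D(\bar\theta)} the deviance at the posterior mean of the
#' parameters (taken on the unconstrained sampling scale and
#' back-transformed, as stored by [fitModel()] in `devAtMean`).
#'
#' @param loglikMatrix draws-by-steps log-likelihood matrix.
#' @param devAtMean deviance evaluated at the posterior parameter mean.
#' @return list with `dic` and `p_d`.
#' @export
dic <- function(loglikMatrix, devAtMean) {
  ll <- as.matrix(loglikMatrix)
  if (anyNA(ll) || any(!is.finite(ll))) {
    bad <- which(!is.finite(ll), arr.ind = TRUE)[1L, ]
    stop("non-finite log-likelihood at draw ", bad[1L], ", step ", bad[2L])
  }
  if (!is.finite(devAtMean)) stop("'devAtMean' must be finite")
  meanDev <- mean(-2 * rowSums(ll))
  pd <- meanDev - devAtMean
  list(dic = devAtMean + 2 * pd, p_d = pd)
}

#' Rank candidate models against the random-walk baseline
#'
#' Computes WAIC and DIC for each fit, differences against the plain
#' correlated-random-walk fit (`"rw"`, whose delta is 0 by construction),
#' ranks the models under each criterion (rank 1 = lowest score = best)
#' and flags rows where the two criteria disagree about the rank.
#'
#' @param fits list of `crw_fit` objects over the same step set, normally
#'   including the `"rw"` baseline (a single-model list is allowed).
#' @return object of class `crw_comparison`: a data frame with columns
#'   `model`, `social`, `K`, `waic`, `dWAIC`, `rankWAIC`, `dic`, `dDIC`,
#'   `rankDIC`, `disagree`, sorted by WAIC rank, with the absolute
#'   criterion components kept in `attr(, "details")`.
#' @export
compareModels <- function(fits) {
  if (inherits(fits, "crw_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "crw_fit")))
  ids <- lapply(fits, `[[`, "stepIds")
  if (!all(vapply(ids, identical, TRUE, ids[[1L]])))
    stop("fits were not computed on the identical step set")
  nms <- vapply(fits, `[[`, "", "modelName")
  if (length(fits) > 1L && !("rw" %in% nms))
    stop("the 'rw' baseline fit is required for delta scores")
  wa <- lapply(fits, function(f) {
    if (is.null(f$loglikMatrix))
      stop("fit for '", f$modelName, "' kept no log-likelihood matrix")
    waic(f$loglikMatrix)
  })
  di <- lapply(fits, function(f) dic(f$loglikMatrix, f$devAtMean))
  waicV <- vapply(wa, `[[`, 0, "waic")
  dicV <- vapply(di, `[[`, 0, "dic")
  base <- if ("rw" %in% nms) which(nms == "rw")[1L] else 1L
  tab <- data.frame(
    model = nms,
    social = ifelse(vapply(fits, function(f) f$spec$social, TRUE), "Y", "N"),
    K = vapply(fits, function(f) if (is.null(f$K)) NA_integer_ else f$K, 0L),
    waic = waicV,
    dWAIC = waicV - waicV[base],
    rankWAIC = rank(waicV, ties.method = "first"),
    dic = dicV,
    dDIC = dicV - dicV[base],
    rankDIC = rank(dicV, ties.method = "first"),
    stringsAsFactors = FALSE)
  tab$disagree <- tab$rankWAIC != tab$rankDIC
  tab <- tab[order(tab$rankWAIC), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "details") <- data.frame(
    model = nms,
    lppd = vapply(wa, `[[`, 0, "lppd"),
    p_waic = vapply(wa, `[[`, 0, "p_waic"),
    p_d = vapply(di, `[[`, 0, "p_d"),
    devAtMean = vapply(fits, `[[`, 0, "devAtMean"))
  class(tab) <- c("crw_comparison", "data.frame")
  tab
}

#' @export
print.crw_comparison <- function(x, ...) {
  cat("Model comparison (lower scores better; deltas vs 'rw' baseline)\n")
  df <- as.data.frame(x)
  df$waic <- sprintf("%.1f", df$waic)
  df$dWAIC <- sprintf("%.1f", df$dWAIC)
  df$dic <- sprintf("%.1f", df$dic)
  df$dDIC <- sprintf("%.1f", df$dDIC)
  df$K <- ifelse(is.na(df$K), "", as.character(df$K))
  df$disagree <- ifelse(df$disagree, "*", "")
  names(df)[names(df) == "disagree"] <- "rank.mismatch"
  print(df, row.names = FALSE)
  if (any(x$disagree))
    cat("* WAIC and DIC rank this model differently\n")
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' @param x `crw_comparison`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeComparison <- function(x, file) {
  stopifnot(inherits(x, "crw_comparison"))
  write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}
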