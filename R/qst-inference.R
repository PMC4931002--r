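## Q_ST, broad-sense heritability, the nine-population heritability
## plug-in, and Q_ST-F_ST divergence calls.

#' External F_ST estimate with confidence bounds
#'
#' Neutral-marker differentiation consumed as a numeric input (estimated
#' elsewhere from molecular markers).
#'
#' @param point point estimate.
#' @param lower,upper 95\% confidence bounds.
#' @return list of class \code{"fstInterval"}.
#' @examples
#' fstInterval(0.21, 0.16, 0.26)
#' @export
fstInterval <- function(point, lower, upper) {
  if (!(lower <= point && point <= upper))
    stop("F_ST bounds must satisfy lower <= point <= upper")
  if (lower < 0 || upper > 1) stop("F_ST values must lie in [0, 1]")
  structure(list(point = point, lower = lower, upper = upper),
            class = "fstInterval")
}

.qstEstimate <- function(num, den, model) {
  bad <- den < 1e-12
  q <- num[!bad] / den[!bad]
  if (!length(q)) stop("all draws have zero total genetic variance")
  q <- pmin(pmax(q, 0), 1)
  methods::new("QstEstimate",
    draws = q, mean = mean(q), ci = credInterval(q),
    model = model, excluded = as.integer(sum(bad)))
}

#' Q_ST from posterior variance draws
#'
#' Per-draw \eqn{Q_{ST} = \sigma^2_P / (\sigma^2_P + 2\sigma^2_G)}
#' computed on the joint posterior sample, so the reported credible
#' interval reflects the full posterior distribution of the ratio rather
#' than a ratio of posterior means.  Draws in which both variances are
#' numerically zero are excluded (count reported).
#'
#' @param posterior \code{\linkS4class{HBPosterior}} containing
#'   \code{sigma2_P} and \code{sigma2_G} draws (a fit with replicated
#'   genotypes).
#' @return a \code{\linkS4class{QstEstimate}} with model tag
#'   \code{"3-population"}.
#' @export
qstFromDraws <- function(posterior) {
  d <- posteriorDraws(posterior, c("sigma2_P", "sigma2_G"))
  .qstEstimate(d[, "sigma2_P"], d[, "sigma2_P"] + 2 * d[, "sigma2_G"],
               "3-population")
}

#' Broad-sense heritability from posterior draws
#'
#' Per-draw \eqn{H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_W)} among
#' clonally replicated genotypes.  Fit with a population grouping for the
#' hierarchical (within-population) H2, or without one for the
#' collection-wide H2 (genotypes pooled across populations).
#'
#' @param posterior \code{\linkS4class{HBPosterior}} with \code{sigma2_G}
#'   and \code{sigma2_W} draws.
#' @return list with \code{draws}, posterior \code{mean} and 95\% \code{ci}.
#' @export
h2FromDraws <- function(posterior) {
  d <- posteriorDraws(posterior, c("sigma2_G", "sigma2_W"))
  den <- d[, "sigma2_G"] + d[, "sigma2_W"]
  bad <- den < 1e-12
  h <- pmin(pmax(d[!bad, "sigma2_G"] / den[!bad], 0), 1)
  list(draws = h, mean = mean(h), ci = credInterval(h),
       excluded = sum(bad))
}

#' Nine-population Q_ST with a heritability plug-in
#'
#' When genotypes are unreplicated, the within-population genetic variance
#' cannot be separated from error: the fit omits the genotype layer and
#' \code{sigma2_W} absorbs both.  The genetic fraction is recovered by
#' plugging in a broad-sense heritability point estimate from the
#' replicated-genotype analysis, giving per-draw
#' \eqn{Q_{ST} = \sigma^2_P / (\sigma^2_P + 2 H^2 \sigma^2_W)}.
#'
#' @param posterior \code{\linkS4class{HBPosterior}} from a model without
#'   genotype effects.
#' @param h2 heritability point value in [0, 1] (posterior mean from
#'   \code{\link{h2FromDraws}}).
#' @return a \code{\linkS4class{QstEstimate}} with model tag
#'   \code{"9-population plug-in"}.
#' @export
ninePopQst <- function(posterior, h2) {
  if (is.list(h2)) h2 <- h2$mean
  if (!is.finite(h2) || h2 < 0 || h2 > 1)
    stop("h2 must lie in [0, 1]")
  d <- posteriorDraws(posterior, c("sigma2_P", "sigma2_W"))
  if ("sigma2_G" %in% colnames(posteriorDraws(posterior)))
    warning("posterior includes a genotype layer; the plug-in assumes ",
            "sigma2_W absorbs genotype variance")
  .qstEstimate(d[, "sigma2_P"], d[, "sigma2_P"] + 2 * h2 * d[, "sigma2_W"],
               "9-population plug-in")
}

#' Q_ST versus F_ST divergence call
#'
#' A trait is called divergent when the Q_ST 95\% credible interval and
#' the F_ST 95\% confidence interval are disjoint; the direction states
#' whether Q_ST lies above (divergent selection) or below (uniform
#' selection) F_ST.
#'
#' @param qst a \code{\linkS4class{QstEstimate}}.
#' @param fst an \code{\link{fstInterval}}.
#' @return list with \code{call} (\code{"divergent"} or
#'   \code{"not distinguishable"}), \code{direction} (\code{"above"},
#'   \code{"below"} or \code{NA}) and both intervals.
#' @examples
#' # disjoint intervals -> divergent, Q_ST above
#' q <- new("QstEstimate", draws = runif(100, 0.55, 0.92), mean = 0.75,
#'          ci = c(0.55, 0.92), model = "3-population", excluded = 0L)
#' qstFstTest(q, fstInterval(0.21, 0.16, 0.26))$call
#' @export
qstFstTest <- function(qst, fst) {
  stopifnot(is(qst, "QstEstimate"), inherits(fst, "fstInterval"))
  qL <- qst@ci[1]; qU <- qst@ci[2]
  if (qL > fst$upper)
    list(call = "divergent", direction = "above",
         qst_ci = qst@ci, fst_ci = c(fst$lower, fst$upper))
  else if (qU < fst$lower)
    list(call = "divergent", direction = "below",
         qst_ci = qst@ci, fst_ci = c(fst$lower, fst$upper))
  else
    list(call = "not distinguishable", direction = NA_character_,
         qst_ci = qst@ci, fst_ci = c(fst$lower, fst$upper))
}
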