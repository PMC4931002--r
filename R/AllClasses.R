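#' @import methods
NULL

#' Posterior draws from a hierarchical variance-component model
#'
#' Container for the joint posterior sample returned by
#' \code{\link{fitGaussianHB}} and \code{\link{fitPoissonHB}}: scalar
#' parameters (intercept, fixed effects, variance components) as a draws
#' matrix, random-effect draws per grouping block, Metropolis acceptance
#' diagnostics for the Poisson latent layer, and convergence diagnostics.
#'
#' @slot draws numeric matrix, one row per retained draw, one column per
#'   scalar parameter (\code{alpha0}, variance components named
#'   \code{sigma2_P}, \code{sigma2_G}, \code{sigma2_garden},
#'   \code{sigma2_PxG}, \code{sigma2_W}, and any fixed-effect coefficients).
#' @slot effects named list of draw matrices (draw x level) for each
#'   random-effect block.
#' @slot effectLevels named list of character level labels per block.
#' @slot family \code{"gaussian"} or \code{"poisson"}.
#' @slot acceptance mean Metropolis acceptance rate of the latent
#'   log-mean updates (\code{NA} for Gaussian fits).
#' @slot diagnostics data.frame with split-chain Rhat and effective sample
#'   size per scalar parameter.
#' @slot mcmc list of sampler settings (burnin, samples, thin, seed).
#' @export
setClass("HBPosterior",
  representation(
    draws = "matrix",
    effects = "list",
    effectLevels = "list",
    family = "character",
    acceptance = "numeric",
    diagnostics = "data.frame",
    mcmc = "list"
  )
)

setValidity("HBPosterior", function(object) {
  msg <- character()
  if (!object@family %in% c("gaussian", "poisson"))
    msg <- c(msg, "family must be 'gaussian' or 'poisson'")
  if (is.null(colnames(object@draws)))
    msg <- c(msg, "draws matrix must have parameter names")
  vc <- grep("^sigma2_", colnames(object@draws), value = TRUE)
  if (length(vc) && any(object@draws[, vc] < 0))
    msg <- c(msg, "variance draws must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Posterior distribution of Q_ST
#'
#' Per-draw values of the quantitative-trait differentiation statistic
#' \eqn{Q_{ST} = \sigma^2_P / (\sigma^2_P + 2\sigma^2_G)} together with its
#' posterior mean and equal-tailed 95\% credible interval.
#'
#' @slot draws numeric vector of per-draw Q_ST values, each in [0, 1].
#' @slot mean posterior mean.
#' @slot ci lower and upper 95\% credible bounds.
#' @slot model \code{"3-population"} (replicated genotypes) or
#'   \code{"9-population plug-in"} (heritability plug-in).
#' @slot excluded number of draws dropped because both variances were
#'   numerically zero.
#' @export
setClass("QstEstimate",
  representation(
    draws = "numeric",
    mean = "numeric",
    ci = "numeric",
    model = "character",
    excluded = "integer"
  )
)

setValidity("QstEstimate", function(object) {
  msg <- character()
  if (length(object@draws) && (min(object@draws) < -1e-12 ||
      max(object@draws) > 1 + 1e-12))
    msg <- c(msg, "Q_ST draws must lie in [0, 1]")
  if (length(object@ci) != 2L || diff(object@ci) < 0)
    msg <- c(msg, "credible bounds must be ordered (lower, upper)")
  if (length(msg)) msg else TRUE
})

#' Climate transfer-function fit
#'
#' Result of \code{\link{transferFunction}}: posterior summaries of the
#' linear and quadratic climate-transfer-distance fixed effects, the
#' projected response curve for an idealized population (random effects at
#' zero), and the apex of that curve.
#'
#' @slot fit the underlying \code{HBPosterior}.
#' @slot coef posterior summary data.frame for the fixed effects
#'   (\code{pc_trd}, \code{pc_trd2}).
#' @slot curve data.frame with the projected response over the observed
#'   transfer-distance range.
#' @slot apex transfer distance at which the projected curve peaks.
#' @slot localAdaptation logical; quadratic term credibly negative and
#'   apex near zero.
#' @slot range observed transfer-distance range.
#' @export
setClass("TransferResult",
  representation(
    fit = "HBPosterior",
    coef = "data.frame",
    curve = "data.frame",
    apex = "numeric",
    localAdaptation = "logical",
    range = "numeric"
  )
)

setValidity("TransferResult", function(object) {
  if (nrow(object@curve) &&
      (min(object@curve$pc_trd) < object@range[1] - 1e-8 ||
       max(object@curve$pc_trd) > object@range[2] + 1e-8))
    "projected curve extends beyond the observed transfer-distance range"
  else TRUE
})
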