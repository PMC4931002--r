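## Hierarchical Bayesian variance-component samplers.
##
## Gaussian model:  y_igp = alpha0 + x'b + gamma_p + beta_g(p) [+ garden
## + population:garden] + e_igp,  e ~ N(0, sigma2_W), all random-effect
## blocks exchangeable N(0, sigma2_block).
## Poisson model:   y ~ Poisson(theta), with the same linear structure on
## ln(theta); the per-tree log-means are latent and updated by an embedded
## random-walk Metropolis step.
##
## Conjugate full conditionals: normal for the intercept, fixed
## coefficients and every random-effect level; inverse-gamma for every
## variance.  All variances share a weak IG prior, by default IG(1, 8) in
## the shape/scale parameterization (density ~ x^-2 exp(-8/x)).

#' Prior settings for the hierarchical samplers
#'
#' @param varShape,varScale inverse-gamma hyperprior for every variance
#'   component.  Defaults IG(1, 8).
#' @param parameterization \code{"scale"} (default; density proportional to
#'   \eqn{x^{-(a+1)} e^{-b/x}}) or \code{"rate"}, a sensitivity switch that
#'   reads the second hyperparameter as a rate (equivalent to scale
#'   \code{1/varScale}).
#' @param interceptVar,fixedVar normal prior variances for the intercept
#'   and fixed-effect coefficients (both N(0, 100) by default).
#' @return list of prior settings.
#' @export
hbPrior <- function(varShape = 1, varScale = 8,
                    parameterization = c("scale", "rate"),
                    interceptVar = 100, fixedVar = 100) {
  parameterization <- match.arg(parameterization)
  stopifnot(varShape > 0, varScale > 0, interceptVar > 0, fixedVar > 0)
  scale <- if (parameterization == "rate") 1 / varScale else varScale
  list(shape = varShape, scale = scale, interceptVar = interceptVar,
       fixedVar = fixedVar, parameterization = parameterization)
}

#' MCMC settings for the hierarchical samplers
#'
#' Defaults follow the long schedule used for final inference (10,000
#' burnin + 20,000 retained steps, thinning 1); simulation studies in the
#' tests use shorter chains.
#'
#' @param burnin discarded initial steps.
#' @param samples retained post-burnin steps (before thinning).
#' @param thin keep every \code{thin}-th draw.
#' @param seed integer RNG seed; fits are bit-reproducible given the seed.
#' @param proposalSd initial per-tree random-walk sd for the Poisson latent
#'   log-means (adapted during burnin toward ~30\% acceptance).
#' @return list of sampler settings.
#' @export
hbControl <- function(burnin = 10000, samples = 20000, thin = 1,
                      seed = 1, proposalSd = 0.5) {
  stopifnot(burnin >= 0, samples >= 2, thin >= 1, proposalSd > 0)
  list(burnin = as.integer(burnin), samples = as.integer(samples),
       thin = as.integer(thin), seed = as.integer(seed),
       proposalSd = proposalSd)
}

## One conjugate variance update: ss = sum of squares, k = number of
## terms.  Kept as a free function so the conditional can be checked
## against closed-form inverse-gamma quantiles.
updateVariance <- function(ss, k, prior) {
  rinvgamma(1L, prior$shape + k / 2, prior$scale + ss / 2)
}

## Core sampler shared by the Gaussian and Poisson fits.
## blocks: named list of factors (all levels observed); varNames: the
## sigma2_* label for each block.
.fitHB <- function(y, blocks, varNames, X = NULL,
                   family = c("gaussian", "poisson"),
                   prior = hbPrior(), mcmc = hbControl(),
                   keepEffects = TRUE) {
  family <- match.arg(family)
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(y) || any(!is.finite(y)))
    stop("response contains missing or non-finite values; ",
         "remove or impute before fitting")
  if (family == "poisson") {
    if (any(y < 0) || any(y != round(y)))
      stop("Poisson responses must be nonnegative integers")
  }
  blocks <- lapply(blocks, function(f) droplevels(as.factor(f)))
  for (bn in names(blocks)) {
    if (length(blocks[[bn]]) != n)
      stop("grouping '", bn, "' length does not match the response")
    if (nlevels(blocks[[bn]]) < 2L)
      stop("grouping '", bn, "' has a single level; ",
           "its variance is unidentifiable")
    if (family == "poisson") {
      zero <- tapply(y, blocks[[bn]], function(v) all(v == 0))
      if (any(zero))
        warning("all-zero counts for ", sum(zero), " level(s) of '", bn,
                "'; these levels are weakly identified")
    }
  }
  K <- length(blocks)
  idx <- lapply(blocks, as.integer)
  nlev <- vapply(blocks, nlevels, 0L)
  cnt <- lapply(idx, tabulate)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("fixed-covariate matrix has wrong row count")
    if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
    XtX <- crossprod(X)
    p <- ncol(X)
  } else p <- 0L

  set.seed(mcmc$seed)
  ## Gaussian responses are centered internally so the N(0, interceptVar)
  ## intercept prior is location-free; the mean is restored in the draws.
  center <- if (family == "gaussian") mean(y) else 0
  d <- if (family == "poisson") log(y + 0.5) else y - center
  z <- d                          # latent log-means (poisson only)
  alpha0 <- mean(d)
  beta <- numeric(p)
  eff <- lapply(nlev, numeric)
  v0 <- max(stats::var(d), 1e-3)
  s2 <- rep(v0 / (K + 1), K)
  s2W <- v0 / 2
  effmat <- matrix(0, n, max(K, 1L))   # expanded effects, one col per block
  ps <- rep(mcmc$proposalSd, n)
  accSum <- 0; accIter <- 0L

  nkeep <- mcmc$samples %/% mcmc$thin
  parNames <- c("alpha0",
                if (p) colnames(X),
                varNames, "sigma2_W")
  draws <- matrix(NA_real_, nkeep, length(parNames),
                  dimnames = list(NULL, parNames))
  effDraws <- if (keepEffects)
    lapply(seq_len(K), function(k) matrix(NA_real_, nkeep, nlev[k]))
  else NULL

  total <- mcmc$burnin + mcmc$samples
  kept <- 0L
  for (it in seq_len(total)) {
    fixpart <- if (p) drop(X %*% beta) else 0
    effsum <- if (K) rowSums(effmat[, seq_len(K), drop = FALSE]) else 0

    ## intercept
    r <- d - fixpart - effsum
    prec <- n / s2W + 1 / prior$interceptVar
    alpha0 <- stats::rnorm(1L, sum(r) / s2W / prec, sqrt(1 / prec))

    ## fixed coefficients (joint conjugate normal)
    if (p) {
      r <- d - alpha0 - effsum
      Prec <- XtX / s2W + diag(1 / prior$fixedVar, p)
      ch <- chol(Prec)
      m <- backsolve(ch, forwardsolve(t(ch), crossprod(X, r) / s2W))
      beta <- drop(m + backsolve(ch, stats::rnorm(p)))
      fixpart <- drop(X %*% beta)
    }

    ## random-effect blocks
    for (k in seq_len(K)) {
      others <- effsum - effmat[, k]
      r <- d - alpha0 - fixpart - others
      sums <- drop(rowsum(r, idx[[k]], reorder = TRUE))
      precj <- cnt[[k]] / s2W + 1 / s2[k]
      eff[[k]] <- stats::rnorm(nlev[k], sums / s2W / precj, sqrt(1 / precj))
      ## location sweep (translation-group Gibbs move): resample the
      ## split of the common level between the intercept and this block;
      ## leaves the likelihood invariant and decouples the intercept
      ## from the block mean, which otherwise mixes by random walk
      Pd <- 1 / prior$interceptVar + nlev[k] / s2[k]
      md <- (-alpha0 / prior$interceptVar + sum(eff[[k]]) / s2[k]) / Pd
      delta <- stats::rnorm(1L, md, sqrt(1 / Pd))
      alpha0 <- alpha0 + delta
      eff[[k]] <- eff[[k]] - delta
      effmat[, k] <- eff[[k]][idx[[k]]]
      effsum <- others + effmat[, k]
      s2[k] <- updateVariance(sum(eff[[k]]^2), nlev[k], prior)
    }

    ## residual variance
    resid <- d - alpha0 - fixpart - effsum
    s2W <- updateVariance(sum(resid^2), n, prior)

    ## Poisson latent log-means: elementwise random-walk Metropolis
    if (family == "poisson") {
      mu <- alpha0 + fixpart + effsum
      zp <- z + stats::rnorm(n, 0, ps)
      logr <- y * (zp - z) - (exp(zp) - exp(z)) -
        ((zp - mu)^2 - (z - mu)^2) / (2 * s2W)
      acc <- log(stats::runif(n)) < logr
      z[acc] <- zp[acc]
      if (it <= mcmc$burnin) {       # Robbins-Monro, burnin only
        ps <- ps * exp((acc - 0.3) / it^0.55)
        ps <- pmin(pmax(ps, 1e-3), 10)
      } else {
        accSum <- accSum + mean(acc); accIter <- accIter + 1L
      }
      d <- z
    }

    if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(alpha0 + center, if (p) beta, s2, s2W)
      if (keepEffects)
        for (k in seq_len(K)) effDraws[[k]][kept, ] <- eff[[k]]
    }
  }

  diag <- data.frame(
    parameter = parNames,
    rhat = apply(draws, 2, splitRhat),
    ess = apply(draws, 2, essBasic),
    row.names = NULL
  )
  if (any(diag$rhat > 1.05, na.rm = TRUE))
    warning("split-chain Rhat > 1.05 for: ",
            paste(diag$parameter[which(diag$rhat > 1.05)], collapse = ", "),
            "; consider a longer chain")
  if (keepEffects) names(effDraws) <- names(blocks)
  methods::new("HBPosterior",
    draws = draws,
    effects = if (keepEffects) effDraws else list(),
    effectLevels = lapply(blocks, levels),
    family = family,
    acceptance = if (family == "poisson" && accIter)
      accSum / accIter else NA_real_,
    diagnostics = diag,
    mcmc = mcmc
  )
}

## Assemble grouping blocks from a trait table.
.buildBlocks <- function(data, population, genotype, garden, interaction) {
  blocks <- list(); varNames <- character()
  if (!is.null(population)) {
    blocks$population <- data[[population]]
    varNames <- c(varNames, "sigma2_P")
  }
  if (!is.null(genotype)) {
    blocks$genotype <- data[[genotype]]
    varNames <- c(varNames, "sigma2_G")
  }
  if (!is.null(garden)) {
    blocks$garden <- data[[garden]]
    varNames <- c(varNames, "sigma2_garden")
  }
  if (interaction) {
    if (is.null(population) || is.null(garden))
      stop("the population x garden interaction needs both terms")
    blocks$pop_garden <- interaction(data[[population]], data[[garden]],
                                     drop = TRUE, sep = ":")
    varNames <- c(varNames, "sigma2_PxG")
  }
  ## no grouping at all collapses to the conjugate intercept-only model
  list(blocks = blocks, varNames = varNames)
}

#' Fit the Gaussian hierarchical variance-component model
#'
#' Gibbs sampler for a Gaussian trait with exchangeable random effects for
#' population (river), genotype within population, and optionally garden
#' and population x garden interaction, plus optional fixed covariates.
#' The intercept and fixed coefficients carry N(0, 100) priors and every
#' variance an IG(1, 8) prior by default.
#'
#' @param data data.frame of (typically spatially detrended) trait values.
#' @param response name of the response column.
#' @param population,genotype,garden column names of the grouping factors;
#'   set to \code{NULL} to drop a term.
#' @param interaction logical; include a population x garden block.
#' @param fixed optional character vector of numeric covariate columns to
#'   include as fixed effects.
#' @param prior see \code{\link{hbPrior}}.
#' @param mcmc see \code{\link{hbControl}}.
#' @param keepEffects store full random-effect draws (needed for
#'   genotype/population posterior-mean correlations).
#' @return an \code{\linkS4class{HBPosterior}}.
#' @examples
#' set.seed(1)
#' d <- data.frame(population = rep(letters[1:6], each = 20),
#'                 y = rep(rnorm(6, sd = 1), each = 20) + rnorm(120))
#' fit <- fitGaussianHB(d, response = "y", genotype = NULL,
#'                      mcmc = hbControl(burnin = 200, samples = 400))
#' posteriorSummary(fit)
#' @export
fitGaussianHB <- function(data, response = "value",
                          population = "population", genotype = "genotype",
                          garden = NULL, interaction = FALSE,
                          fixed = NULL,
                          prior = hbPrior(), mcmc = hbControl(),
                          keepEffects = TRUE) {
  b <- .buildBlocks(data, population, genotype, garden, interaction)
  X <- if (!is.null(fixed)) as.matrix(data[fixed]) else NULL
  .fitHB(data[[response]], b$blocks, b$varNames, X = X,
         family = "gaussian", prior = prior, mcmc = mcmc,
         keepEffects = keepEffects)
}

#' Fit the overdispersed-Poisson hierarchical model
#'
#' Metropolis-within-Gibbs sampler for count responses (e.g. arthropod
#' richness or abundance per tree): counts are conditionally Poisson with
#' per-tree log-means carrying the same hierarchical Gaussian structure as
#' \code{\link{fitGaussianHB}}, so the residual log-scale variance
#' \code{sigma2_W} captures extra-Poisson variability.  The latent
#' log-means are updated by an elementwise Gaussian random-walk Metropolis
#' step whose proposal scale is adapted during burnin toward roughly 30\%
#' acceptance.
#'
#' @inheritParams fitGaussianHB
#' @return an \code{\linkS4class{HBPosterior}}; \code{acceptance} holds the
#'   post-burnin mean Metropolis acceptance rate.
#' @examples
#' set.seed(2)
#' d <- data.frame(population = rep(letters[1:5], each = 12),
#'                 y = rpois(60, exp(2 + rep(rnorm(5, sd = 0.5), each = 12))))
#' fit <- fitPoissonHB(d, response = "y", genotype = NULL,
#'                     mcmc = hbControl(burnin = 300, samples = 600))
#' @export
fitPoissonHB <- function(data, response = "value",
                         population = "population", genotype = "genotype",
                         garden = NULL, interaction = FALSE,
                         fixed = NULL,
                         prior = hbPrior(), mcmc = hbControl(),
                         keepEffects = TRUE) {
  b <- .buildBlocks(data, population, genotype, garden, interaction)
  X <- if (!is.null(fixed)) as.matrix(data[fixed]) else NULL
  .fitHB(data[[response]], b$blocks, b$varNames, X = X,
         family = "poisson", prior = prior, mcmc = mcmc,
         keepEffects = keepEffects)
}

#' Write posterior draws and a JSON summary to disk
#'
#' @param fit an \code{\linkS4class{HBPosterior}}.
#' @param drawsFile CSV path for the scalar draws (one row per draw).
#' @param summaryFile JSON path for posterior means, 95\% CIs and
#'   diagnostics.
#' @return invisibly, the summary list.
#' @export
writePosterior <- function(fit, drawsFile = NULL, summaryFile = NULL) {
  if (!is.null(drawsFile))
    utils::write.csv(as.data.frame(fit@draws), drawsFile, row.names = FALSE)
  s <- list(
    family = fit@family,
    summary = posteriorSummary(fit),
    acceptance = fit@acceptance,
    diagnostics = fit@diagnostics,
    mcmc = fit@mcmc
  )
  if (!is.null(summaryFile))
    jsonlite::write_json(s, summaryFile, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(s)
}
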