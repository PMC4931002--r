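## Climate principal components, G x E variance partitioning, the
## quadratic climate transfer function, and differentiation-climate
## correlations.

#' Principal components of the climate/geography table
#'
#' Eigendecomposition of the correlation matrix of the climate variables
#' (plus latitude, longitude, elevation if present), yielding composite
#' environmental axes.  Constant columns are dropped with a warning.
#' Loading signs are fixed so that each component's largest-magnitude
#' loading is positive.
#'
#' @param climate data.frame with a \code{population} id column and
#'   numeric climate/geography columns.
#' @param idCol name of the id column.
#' @return list with \code{loadings} (variable x PC), \code{scores}
#'   (population x PC, unit-variance standardized data projected on the
#'   eigenvectors), \code{varFrac} (fraction of variance per PC, summing
#'   to 1) and \code{sdev}.
#' @examples
#' cl <- simulateClimateTable(9, seed = 1)
#' p <- climatePCA(cl)
#' p$varFrac[1]      # leading latitudinal/temperature axis
#' @export
climatePCA <- function(climate, idCol = "population") {
  X <- climate[, setdiff(names(climate), idCol), drop = FALSE]
  X <- X[, vapply(X, is.numeric, TRUE), drop = FALSE]
  if (nrow(X) < 2L) stop("need at least 2 populations for a PCA")
  sds <- vapply(X, stats::sd, 0)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(names(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(as.matrix(X))
  R <- stats::cor(as.matrix(X))
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  V <- e$vectors
  ## sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  pcs <- paste0("PC", seq_along(ev))
  dimnames(V) <- list(colnames(X), pcs)
  scores <- Z %*% V
  rownames(scores) <- climate[[idCol]]
  list(loadings = V, scores = scores,
       varFrac = ev / sum(ev), sdev = sqrt(ev))
}

#' Genotype-by-environment variance partitioning
#'
#' The "G x E model": the nine-population model (no genotype layer)
#' extended with garden and population x garden random-effect blocks, each
#' with its own IG(1, 8) variance.  Reports the posterior mean (and CI)
#' proportion of total variance for each component.
#'
#' @param observations detrended trait table with \code{population},
#'   \code{garden} and the response column.
#' @param response response column name.
#' @param prior,mcmc see \code{\link{hbPrior}}, \code{\link{hbControl}}.
#' @param ... passed to \code{\link{fitGaussianHB}}.
#' @return list with \code{fit} (the \code{\linkS4class{HBPosterior}}) and
#'   \code{proportions}, a data.frame of posterior mean proportions of
#'   total variance for river (population), garden, river x garden and
#'   residual.
#' @export
fitGxE <- function(observations, response = "value",
                   prior = hbPrior(), mcmc = hbControl(), ...) {
  if (length(unique(observations$garden)) < 2L)
    stop("G x E partitioning needs at least 2 gardens")
  if (length(unique(observations$population)) < 2L)
    stop("G x E partitioning needs at least 2 populations")
  fit <- fitGaussianHB(observations, response = response,
                       population = "population", genotype = NULL,
                       garden = "garden", interaction = TRUE,
                       prior = prior, mcmc = mcmc, ...)
  vc <- c("sigma2_P", "sigma2_garden", "sigma2_PxG", "sigma2_W")
  d <- posteriorDraws(fit, vc)
  prop <- d / rowSums(d)
  ci <- apply(prop, 2, credInterval)
  proportions <- data.frame(
    component = c("river", "garden", "river_x_garden", "residual"),
    variance = colMeans(d),
    proportion = colMeans(prop),
    lower = ci[1, ], upper = ci[2, ],
    row.names = NULL
  )
  list(fit = fit, proportions = proportions)
}

#' Quadratic climate transfer function
#'
#' Tests local adaptation by regressing growth on climate transfer
#' distance, \code{pc_trd} = garden PC1 - source PC1, with linear and
#' quadratic fixed effects (N(0, 100) priors) inside the G x E model.  A
#' credibly negative quadratic term with the curve's apex near zero
#' indicates that populations grow best near their home climate.  The
#' projected response curve is evaluated for an idealized population
#' (random effects at zero) over the observed transfer-distance range
#' only.
#'
#' @param observations detrended height table with \code{population} and
#'   \code{garden} columns and the response column.
#' @param sourcePC1 named vector of climate PC1 scores per population (or
#'   data.frame with \code{population}, \code{pc1}).
#' @param gardenPC1 named vector of PC1 scores per garden.
#' @param response response column name.
#' @param standardize scale the response to unit variance before fitting,
#'   making coefficients comparable across traits (disable to recover
#'   coefficients on the raw trait scale).
#' @param apexWindow half-width of the "apex near zero" window (PC1
#'   units) used for the local-adaptation flag.
#' @param prior,mcmc see \code{\link{hbPrior}}, \code{\link{hbControl}}.
#' @return a \code{\linkS4class{TransferResult}}.
#' @export
transferFunction <- function(observations, sourcePC1, gardenPC1,
                             response = "value", standardize = TRUE,
                             apexWindow = 0.5,
                             prior = hbPrior(), mcmc = hbControl()) {
  if (is.data.frame(sourcePC1))
    sourcePC1 <- stats::setNames(sourcePC1$pc1, sourcePC1$population)
  pops <- unique(observations$population)
  gards <- unique(observations$garden)
  if (!all(pops %in% names(sourcePC1)))
    stop("missing source PC1 for population(s): ",
         paste(setdiff(pops, names(sourcePC1)), collapse = ", "))
  if (!all(gards %in% names(gardenPC1)))
    stop("missing garden PC1 for garden(s): ",
         paste(setdiff(gards, names(gardenPC1)), collapse = ", "))
  obs <- observations
  obs$pc_trd <- as.numeric(gardenPC1[obs$garden] - sourcePC1[obs$population])
  if (stats::sd(obs$pc_trd) < 1e-12)
    stop("transfer distances are all equal; the function is unidentifiable")
  obs$pc_trd2 <- obs$pc_trd^2
  if (standardize)
    obs[[response]] <- obs[[response]] / stats::sd(obs[[response]])
  fit <- fitGaussianHB(obs, response = response,
                       population = "population", genotype = NULL,
                       garden = "garden", interaction = TRUE,
                       fixed = c("pc_trd", "pc_trd2"),
                       prior = prior, mcmc = mcmc)
  co <- posteriorDraws(fit, c("pc_trd", "pc_trd2"))
  ci <- apply(co, 2, credInterval)
  coef <- data.frame(
    term = c("pc_trd", "pc_trd2"),
    mean = colMeans(co), sd = apply(co, 2, stats::sd),
    lower = ci[1, ], upper = ci[2, ],
    pNegative = colMeans(co < 0),
    row.names = NULL
  )
  b <- coef$mean[1]; a <- coef$mean[2]
  apex <- if (abs(a) > 1e-12) -b / (2 * a) else NA_real_
  rng <- range(obs$pc_trd)
  grid <- seq(rng[1], rng[2], length.out = 101)
  a0 <- mean(posteriorDraws(fit, "alpha0"))
  curve <- data.frame(pc_trd = grid,
                      response = a0 + b * grid + a * grid^2)
  localAdaptation <- isTRUE(coef$pNegative[2] >= 0.975 &&
                            !is.na(apex) && abs(apex) < apexWindow)
  methods::new("TransferResult",
    fit = fit, coef = coef, curve = curve,
    apex = apex, localAdaptation = localAdaptation, range = rng)
}

#' Trait-climate correlation matrix
#'
#' Pearson correlations of population- (or genotype-) level trait values
#' -- typically posterior mean effects -- with each climate variable and
#' PC score, using pairwise-complete observations.  Cells with fewer than
#' 3 complete pairs are \code{NA}.
#'
#' @param traitMeans data.frame: id column plus one column per trait.
#' @param climate data.frame: same id column plus numeric climate
#'   variables (may include PC scores).
#' @param idCol shared id column name.
#' @return numeric matrix, traits x climate variables.
#' @export
traitClimateCorrelations <- function(traitMeans, climate,
                                     idCol = "population") {
  m <- merge(traitMeans, climate, by = idCol)
  tv <- setdiff(names(traitMeans), idCol)
  cv <- setdiff(names(climate), idCol)
  cv <- cv[vapply(m[cv], is.numeric, TRUE)]
  out <- matrix(NA_real_, length(tv), length(cv),
                dimnames = list(tv, cv))
  for (i in tv) for (j in cv) {
    ok <- stats::complete.cases(m[[i]], m[[j]])
    if (sum(ok) >= 3L)
      out[i, j] <- stats::cor(m[[i]][ok], m[[j]][ok])
  }
  out
}

#' Correlation between trait differentiation and climate association
#'
#' Across traits, correlates the absolute trait-climate correlation |r|
#' (against a chosen climate PC) with the Q_ST posterior means: a positive
#' relationship indicates that more climatically associated traits are
#' more differentiated among populations.
#'
#' @param qst numeric vector of Q_ST posterior means (one per trait x
#'   garden x year combination).
#' @param absR matching vector of |r| values.
#' @return list with Pearson \code{estimate}, two-sided \code{p.value}
#'   (t transform) and \code{n}.
#' @export
differentiationClimateCorrelation <- function(qst, absR) {
  ok <- stats::complete.cases(qst, absR)
  qst <- qst[ok]; absR <- abs(absR[ok])
  if (length(qst) < 3L) stop("need at least 3 paired values")
  if (stats::sd(qst) < 1e-12 || stats::sd(absR) < 1e-12)
    stop("zero variance in Q_ST or |r|; correlation undefined")
  ct <- stats::cor.test(absR, qst, method = "pearson")
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       n = length(qst))
}
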