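test_that("PCA of two perfectly correlated variables puts all variance on PC1", {
  cl <- data.frame(population = paste0("P", 1:6),
                   a = 1:6, b = 2 * (1:6) + 3)
  p <- climatePCA(cl)
  expect_equal(p$varFrac[1], 1, tolerance = 1e-12)
  expect_equal(p$varFrac[2], 0, tolerance = 1e-12)
})

test_that("independent standardized variables give near-equal fractions", {
  set.seed(71)
  cl <- data.frame(population = paste0("P", 1:500),
                   a = rnorm(500), b = rnorm(500), c = rnorm(500))
  p <- climatePCA(cl)
  expect_true(all(abs(p$varFrac - 1 / 3) < 0.1))
})

test_that("PCA agrees with an independent eigendecomposition and prcomp", {
  cl <- simulateClimateTable(9, seed = 72)
  p <- climatePCA(cl)
  X <- as.matrix(cl[, -1])
  ## oracle 1: direct eigen of the correlation matrix
  ev <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(p$varFrac, pmax(ev, 0) / sum(pmax(ev, 0)), tolerance = 1e-9)
  ## oracle 2: prcomp on the standardized data (rank-limited to n-1
  ## components; compare the leading, well-determined ones)
  pr <- prcomp(X, scale. = TRUE)
  expect_equal(unname(p$sdev[1:6]), unname(pr$sdev[1:6]), tolerance = 1e-9)
  expect_equal(abs(unname(p$scores[, 1])), abs(unname(pr$x[, 1])),
               tolerance = 1e-9)
  ## the synthetic gradient yields a dominant latitudinal axis
  expect_gt(p$varFrac[1], 0.5)
  expect_gt(abs(cor(p$scores[, 1], cl$latitude)), 0.95)
})

test_that("PCA reconstruction and edge cases", {
  cl <- simulateClimateTable(8, seed = 73)
  p <- climatePCA(cl)
  Z <- scale(as.matrix(cl[, -1]))
  expect_lt(max(abs(Z - p$scores %*% t(p$loadings))), 1e-8)
  expect_equal(sum(p$varFrac), 1, tolerance = 1e-12)
  ## sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  cl$flat <- 1
  expect_warning(climatePCA(cl), "constant")
  expect_error(climatePCA(cl[1, ]), "at least 2")
})

test_that("G x E partitioning recovers equal variance shares", {
  d <- simulateGardenDesign(nPopulations = 12, genotypesPerPopulation = 8,
                            nGardens = 3, localPopulations = 1,
                            nLocalGenotypes = 0, seed = 74)
  s <- simulateTraits(d, truthParams(sigma2_P = 1, sigma2_G = 0,
                                     sigma2_W = 1, sigma2_garden = 1,
                                     sigma2_GxE = 1, seed = 74),
                      micrositeAmplitude = 0)
  g <- suppressWarnings(fitGxE(s$traits, prior = weakPrior(),
                               mcmc = quickMC(74, 600, 1200),
                               keepEffects = FALSE))
  pr <- g$proportions
  expect_equal(pr$component,
               c("river", "garden", "river_x_garden", "residual"))
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-9)
  expect_true(all(pr$proportion >= 0 & pr$proportion <= 1))
  d4 <- posteriorDraws(g$fit, c("sigma2_P", "sigma2_garden",
                                "sigma2_PxG", "sigma2_W"))
  propDraws <- d4 / rowSums(d4)
  sds <- apply(propDraws, 2, sd)
  ## the posterior estimates the realized layer variances; with only 3
  ## gardens (the trial's own constraint) the realized garden variance
  ## can sit far from its generative value, so recovery is assessed
  ## against the realized proportions from the truth sidecar
  realized <- c(var(s$truth$populationEffects),
                var(s$truth$gardenEffects),
                var(s$truth$interactionEffects),
                var(s$truth$residuals))
  realProp <- realized / sum(realized)
  expect_true(all(abs(pr$proportion - realProp) < 3 * sds))
  ## layers with many levels also recover the generative share 0.25
  many <- c(1, 3, 4)                 # river, river x garden, residual
  expect_true(all(abs(pr$proportion[many] - 0.25) < 3 * sds[many]))
})

test_that("null interaction variance is estimated near zero", {
  d <- simulateGardenDesign(nPopulations = 9, genotypesPerPopulation = 12,
                            nGardens = 3, localPopulations = 1,
                            nLocalGenotypes = 0, seed = 75)
  s <- simulateTraits(d, truthParams(sigma2_P = 1, sigma2_G = 0,
                                     sigma2_W = 1, sigma2_garden = 0.5,
                                     sigma2_GxE = 0, seed = 75),
                      micrositeAmplitude = 0)
  g <- suppressWarnings(fitGxE(s$traits, prior = weakPrior(),
                               mcmc = quickMC(75, 600, 1200),
                               keepEffects = FALSE))
  pr <- g$proportions
  expect_lt(pr$proportion[pr$component == "river_x_garden"], 0.05)
  expect_error(fitGxE(s$traits[s$traits$garden == "G1", ]), "2 gardens")
})

test_that("transfer function recovers simulated curvature and apex", {
  d <- simulateGardenDesign(nPopulations = 9, genotypesPerPopulation = 15,
                            nGardens = 3, localPopulations = 1,
                            nLocalGenotypes = 0, seed = 76)
  pops <- paste0("P", 1:9)
  pc1 <- setNames(as.numeric(scale(1:9)), pops)
  gpc <- setNames(c(min(pc1), 0, max(pc1)), c("G1", "G2", "G3"))
  s <- simulateTraits(d, truthParams(alpha0 = 10, sigma2_P = 0.2,
                                     sigma2_G = 0, sigma2_W = 1,
                                     sigma2_garden = 0.2, sigma2_GxE = 0.1,
                                     quad_transfer = -2, seed = 76),
                      pc1 = pc1, gardenPC1 = gpc, micrositeAmplitude = 0)
  tf <- suppressWarnings(
    transferFunction(s$traits, pc1, gpc, standardize = FALSE,
                     prior = weakPrior(), mcmc = quickMC(76, 600, 1200)))
  quad <- tf@coef[tf@coef$term == "pc_trd2", ]
  expect_lt(abs(quad$mean - (-2)), 3 * quad$sd)
  expect_lt(abs(tf@apex), 0.3)
  ## apex identity and concavity
  b <- tf@coef$mean[1]; a <- tf@coef$mean[2]
  expect_equal(tf@apex, -b / (2 * a), tolerance = 1e-12)
  expect_true(a < 0)
  i <- which.max(tf@curve$response)
  expect_lt(abs(tf@curve$pc_trd[i] - tf@apex), 0.1)
  ## curve stays within the observed transfer-distance range
  expect_gte(min(tf@curve$pc_trd), tf@range[1])
  expect_lte(max(tf@curve$pc_trd), tf@range[2])
})

test_that("null transfer simulation yields coefficients covering zero", {
  d <- simulateGardenDesign(nPopulations = 9, genotypesPerPopulation = 15,
                            nGardens = 3, localPopulations = 1,
                            nLocalGenotypes = 0, seed = 77)
  pops <- paste0("P", 1:9)
  pc1 <- setNames(as.numeric(scale(1:9)), pops)
  gpc <- setNames(c(min(pc1), 0, max(pc1)), c("G1", "G2", "G3"))
  s <- simulateTraits(d, truthParams(sigma2_P = 0.3, sigma2_G = 0,
                                     sigma2_W = 1, sigma2_garden = 0.2,
                                     quad_transfer = 0, seed = 77),
                      pc1 = pc1, gardenPC1 = gpc, micrositeAmplitude = 0)
  tf <- suppressWarnings(
    transferFunction(s$traits, pc1, gpc, prior = weakPrior(),
                     mcmc = quickMC(77, 600, 1200)))
  expect_true(all(tf@coef$lower <= 0 & tf@coef$upper >= 0))
  expect_false(tf@localAdaptation)
})

test_that("trait-climate correlations equal the direct formula", {
  cl <- simulateClimateTable(9, seed = 78)
  tm <- data.frame(population = cl$population,
                   budset = cl$MAT,            # identical to a climate column
                   noise = rnorm(9))
  cc <- traitClimateCorrelations(tm, cl)
  expect_equal(cc["budset", "MAT"], 1, tolerance = 1e-12)
  expect_equal(cc["noise", "DD5"], cor(tm$noise, cl$DD5),
               tolerance = 1e-12)
  ## fewer than 3 complete pairs -> NA
  tm$sparse <- c(1, 2, rep(NA, 7))
  cc2 <- traitClimateCorrelations(tm, cl)
  expect_true(is.na(cc2["sparse", "MAT"]))
})

test_that("differentiation-climate meta-correlation behaves", {
  x <- seq(0.1, 0.9, length.out = 10)
  r <- differentiationClimateCorrelation(x, x)
  expect_equal(r$estimate, 1, tolerance = 1e-12)
  expect_error(differentiationClimateCorrelation(x, rep(0.5, 10)),
               "zero variance")
  expect_error(differentiationClimateCorrelation(x[1:2], x[1:2]),
               "at least 3")
  ## simulation with generative correlation 0.8 over 28 trait pairs
  set.seed(79)
  absR <- runif(28, 0.05, 0.95)
  qst <- 0.5 + 0.8 * as.numeric(scale(absR)) * 0.2 +
    sqrt(1 - 0.64) * 0.2 * rnorm(28)
  res <- differentiationClimateCorrelation(qst, absR)
  ct <- cor.test(absR, qst)
  expect_equal(res$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p.value, ct$p.value, tolerance = 1e-12)
  ## the estimate's own 95% sampling interval covers the generative value
  expect_true(ct$conf.int[1] <= 0.8 && 0.8 <= ct$conf.int[2])
})
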