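test_that("intercept-only model collapses to the conjugate normal mean", {
  set.seed(41)
  y <- rnorm(50, 5, 1)
  d <- data.frame(value = y)
  fit <- fitGaussianHB(d, population = NULL, genotype = NULL,
                       mcmc = quickMC(41))
  s <- posteriorSummary(fit)
  a <- s[s$parameter == "alpha0", ]
  expect_lt(abs(a$mean - mean(y)), 3 * a$sd)
})

test_that("variance conditional matches closed-form inverse-gamma", {
  ## one Gibbs step with everything else frozen: sigma2 | . is
  ## IG(shape + n/2, scale + SS/2); check 5000 draws against the
  ## closed-form quantile function
  prior <- hbPrior()
  n <- 120; ss <- 96.4
  set.seed(42)
  draws <- replicate(5000, gardenQst:::updateVariance(ss, n, prior))
  qs <- seq(0.05, 0.95, by = 0.05)
  theo <- gardenQst:::qinvgamma(qs, 1 + n / 2, 8 + ss / 2)
  emp <- quantile(draws, qs, names = FALSE)
  expect_lt(max(abs(emp / theo - 1)), 0.05)
})

test_that("with no data the variance conditional reduces to the prior", {
  prior <- hbPrior()
  set.seed(43)
  draws <- replicate(4000, gardenQst:::updateVariance(0, 0, prior))
  ## IG(1, 8) quantiles: q_p = 8 / qgamma(1-p, 1)
  for (p in c(0.25, 0.5, 0.75)) {
    theo <- 8 / qgamma(1 - p, shape = 1)
    expect_lt(abs(quantile(draws, p, names = FALSE) / theo - 1), 0.1)
  }
})

test_that("fits are deterministic given the seed and vary across seeds", {
  d <- replicatedDesign(seed = 44)
  s <- simulateTraits(d, truthParams(seed = 44), micrositeAmplitude = 0)
  f1 <- suppressWarnings(fitGaussianHB(s$traits, mcmc = quickMC(7)))
  f2 <- suppressWarnings(fitGaussianHB(s$traits, mcmc = quickMC(7)))
  f3 <- suppressWarnings(fitGaussianHB(s$traits, mcmc = quickMC(8)))
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))
  expect_false(identical(posteriorDraws(f1), posteriorDraws(f3)))
})

test_that("gaussian recovery: posterior means near generative truth", {
  d <- recoveryDesign(seed = 45)
  s <- simulateTraits(d, truthParams(sigma2_P = 1, sigma2_G = 0.5,
                                     sigma2_W = 1, seed = 45),
                      micrositeAmplitude = 0)
  fit <- suppressWarnings(
    fitGaussianHB(s$traits, prior = weakPrior(),
                  mcmc = quickMC(45, 800, 1600), keepEffects = TRUE))
  s2 <- posteriorSummary(fit)
  for (p in c("sigma2_P", "sigma2_G", "sigma2_W")) {
    row <- s2[s2$parameter == p, ]
    truthVal <- c(sigma2_P = 1, sigma2_G = 0.5, sigma2_W = 1)[[p]]
    expect_lt(abs(row$mean - truthVal), 3 * row$sd)
  }
  ## posterior mean population effects track the drawn effects
  pe <- effectMeans(fit, "population")
  expect_gt(cor(pe, s$truth$populationEffects[names(pe)]), 0.9)
})

test_that("posterior summaries are invariant to population relabeling", {
  d <- replicatedDesign(nPop = 4, nGeno = 10, nRep = 4, seed = 46)
  s <- simulateTraits(d, truthParams(seed = 46), micrositeAmplitude = 0)
  t1 <- s$traits
  t2 <- t1
  ## reverse the population labels (pure relabeling, same partition)
  t2$population <- factor(t1$population,
                          levels = sort(unique(t1$population)),
                          labels = rev(sort(unique(t1$population))))
  f1 <- suppressWarnings(fitGaussianHB(t1, prior = weakPrior(),
                                       mcmc = quickMC(9, 600, 1500)))
  f2 <- suppressWarnings(fitGaussianHB(t2, prior = weakPrior(),
                                       mcmc = quickMC(9, 600, 1500)))
  m1 <- colMeans(posteriorDraws(f1)); m2 <- colMeans(posteriorDraws(f2))
  sds <- apply(posteriorDraws(f1), 2, sd)
  ess <- f1@diagnostics$ess
  expect_true(all(abs(m1 - m2) < 6 * sds / sqrt(pmax(ess, 1))))
})

test_that("unidentifiable or invalid inputs are refused with diagnostics", {
  d <- data.frame(population = rep("P1", 10), genotype = rep("g1", 10),
                  value = rnorm(10))
  expect_error(fitGaussianHB(d), "single level")
  d2 <- data.frame(population = rep(c("a", "b"), 5), value = rnorm(10))
  d2$value[3] <- NA
  expect_error(fitGaussianHB(d2, genotype = NULL), "missing")
  d3 <- data.frame(population = rep(c("a", "b"), 5),
                   value = c(-1, rpois(9, 5)))
  expect_error(fitPoissonHB(d3, genotype = NULL), "nonnegative integers")
  d4 <- data.frame(population = rep(c("a", "b"), 5),
                   value = c(1.5, rpois(9, 5)))
  expect_error(fitPoissonHB(d4, genotype = NULL), "nonnegative integers")
})

test_that("poisson sampler hits the delta-method limit at large counts", {
  set.seed(47)
  d <- data.frame(population = rep(c("a", "b", "c"), each = 30),
                  value = rpois(90, 1000))
  fit <- suppressWarnings(
    fitPoissonHB(d, genotype = NULL, prior = weakPrior(),
                 mcmc = quickMC(47, 600, 1200)))
  s <- posteriorSummary(fit)
  a <- s[s$parameter == "alpha0", ]
  expect_lt(abs(a$mean - log(1000)), 3 * max(a$sd, 0.01))
  expect_gt(fit@acceptance, 0.1)
  expect_lt(fit@acceptance, 0.7)
})

test_that("all-zero count levels proceed with a warning", {
  d <- data.frame(population = rep(c("a", "b", "c"), each = 10),
                  value = c(rep(0L, 10), rpois(20, 8)))
  w <- capture_warnings(fitPoissonHB(d, genotype = NULL,
                                     mcmc = quickMC(48, 200, 300)))
  expect_true(any(grepl("all-zero", w)))
})

test_that("balanced-design posterior means agree with REML", {
  ## independent oracle: lme4 restricted maximum likelihood on the same
  ## data (the cross-check analysis style for bud set)
  skip_if_not_installed("lme4")
  d <- simulateGardenDesign(nPopulations = 40, genotypesPerPopulation = 5,
                            nGardens = 1, localPopulations = 1:40,
                            nLocalGenotypes = 5, clonalReplicatesLocal = 3,
                            seed = 49)
  s <- simulateTraits(d, truthParams(alpha0 = 100, sigma2_P = 50,
                                     sigma2_G = 30, sigma2_W = 40,
                                     seed = 49),
                      micrositeAmplitude = 0)
  fit <- suppressWarnings(
    fitGaussianHB(s$traits, prior = weakPrior(),
                  mcmc = quickMC(49, 800, 1600), keepEffects = FALSE))
  lmm <- lme4::lmer(value ~ (1 | population) + (1 | genotype),
                    data = s$traits, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  reml <- setNames(vc$vcov, vc$grp)
  post <- posteriorSummary(fit)
  getm <- function(p) post[post$parameter == p, ]
  ## agreement within 10% relative or 3 posterior sds, whichever is looser
  for (pair in list(c("sigma2_P", "population"),
                    c("sigma2_G", "genotype"),
                    c("sigma2_W", "Residual"))) {
    row <- getm(pair[1])
    expect_lt(abs(row$mean - reml[[pair[2]]]),
              max(0.1 * reml[[pair[2]]], 3 * row$sd))
  }
})
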