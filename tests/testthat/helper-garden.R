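## Shared fixture builders for the test suite.  Everything is generated
## in code with fixed seeds; no data files.

## Short chains for unit tests; longer schedules live in the acceptance
## tests.
quickMC <- function(seed = 1L, burnin = 300, samples = 600) {
  hbControl(burnin = burnin, samples = samples, seed = seed)
}

## Weak variance prior used in recovery simulations at unit scale, where
## the field-scale IG(1, 8) prior would dominate the likelihood.
weakPrior <- function() hbPrior(parameterization = "rate")

## Fully replicated small garden: 3 populations x nGeno genotypes x
## nRep clonal copies, one garden.
replicatedDesign <- function(nPop = 3, nGeno = 8, nRep = 4, seed = 1L) {
  simulateGardenDesign(nPopulations = nPop, genotypesPerPopulation = nGeno,
                       nGardens = 1, localPopulations = seq_len(nPop),
                       nLocalGenotypes = nGeno,
                       clonalReplicatesLocal = nRep - 1, seed = seed)
}

## The study-shaped recovery design: 9 populations x 20 genotypes x 6
## clonal replicates in one garden.
recoveryDesign <- function(seed = 1L, nGeno = 20) {
  simulateGardenDesign(nPopulations = 9, genotypesPerPopulation = nGeno,
                       nGardens = 1, localPopulations = 1:9,
                       nLocalGenotypes = nGeno, clonalReplicatesLocal = 5,
                       seed = seed)
}

## Minimal HBPosterior wrapping a given scalar-draw matrix (for testing
## the draw-level Q_ST / H2 arithmetic in isolation).
fakeFit <- function(draws) {
  draws <- as.matrix(draws)
  methods::new("HBPosterior",
    draws = draws,
    effects = list(), effectLevels = list(),
    family = "gaussian", acceptance = NA_real_,
    diagnostics = data.frame(parameter = colnames(draws),
                             rhat = NA_real_, ess = NA_real_),
    mcmc = list(burnin = 0L, samples = nrow(draws), thin = 1L, seed = 1L))
}

## All permutations of 1..n (small n), for the exhaustive accumulation
## oracle.
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}
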