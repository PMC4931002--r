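## Synthetic common-garden generator.
##
## Emulates a provenance trial: source populations ("rivers") on a
## latitudinal/climatic gradient, each contributing genotypes planted once
## in every replicated garden, plus a subset of "local" populations whose
## genotypes are clonally replicated within each garden.  Gaussian traits
## are built from known population / genotype / garden / interaction
## variance layers plus a smooth within-garden microsite surface;
## arthropod counts come from a Poisson-lognormal layer with a fixed taxon
## abundance profile.  Every function is deterministic given its seed and
## emits its ground truth as a sidecar, never merged into analysis inputs.

#' Ground-truth parameters for the synthetic garden
#'
#' @param alpha0 trait grand mean (trait units; log scale for counts).
#' @param sigma2_P among-population variance.
#' @param sigma2_G among-genotype (within-population) variance.
#' @param sigma2_W residual (within-genotype) variance.
#' @param sigma2_garden among-garden variance.
#' @param sigma2_GxE population x garden interaction variance.
#' @param climate_slope linear dependence of population means on climate
#'   PC1 (trait units per PC1 unit).
#' @param quad_transfer curvature of growth against climate transfer
#'   distance (trait units per squared PC1 unit; negative under local
#'   adaptation).
#' @param overdispersion_sd log-scale sd of the extra-Poisson layer for
#'   community counts.
#' @param seed integer seed.
#' @return validated list of class \code{"truthParams"}.
#' @export
truthParams <- function(alpha0 = 0, sigma2_P = 1, sigma2_G = 0.5,
                        sigma2_W = 1, sigma2_garden = 0, sigma2_GxE = 0,
                        climate_slope = 0, quad_transfer = 0,
                        overdispersion_sd = 0.5, seed = 1L) {
  v <- c(sigma2_P = sigma2_P, sigma2_G = sigma2_G, sigma2_W = sigma2_W,
         sigma2_garden = sigma2_garden, sigma2_GxE = sigma2_GxE)
  if (any(v < 0)) stop("variances must be nonnegative: ",
                       paste(names(v)[v < 0], collapse = ", "))
  if (overdispersion_sd < 0) stop("overdispersion_sd must be nonnegative")
  structure(list(alpha0 = alpha0, sigma2_P = sigma2_P, sigma2_G = sigma2_G,
                 sigma2_W = sigma2_W, sigma2_garden = sigma2_garden,
                 sigma2_GxE = sigma2_GxE, climate_slope = climate_slope,
                 quad_transfer = quad_transfer,
                 overdispersion_sd = overdispersion_sd,
                 seed = as.integer(seed)),
            class = "truthParams")
}

#' Generate a common-garden planting design
#'
#' Mirrors the field layout: every genotype planted once per garden, and
#' within a set of local populations a subset of genotypes receives
#' additional clonal replicates at every garden.  Trees get unique ids and
#' uniform random coordinates inside each garden's rectangular extent
#' (completely randomized design).
#'
#' @param nPopulations number of source populations (rivers).
#' @param genotypesPerPopulation single count or inclusive range from
#'   which each population's genotype number is drawn.
#' @param nGardens number of replicated gardens.
#' @param localPopulations indices of the populations with clonal
#'   replication (default: southern, central and northern rivers).
#' @param nLocalGenotypes genotypes per local population that are cloned.
#' @param clonalReplicatesLocal additional clonal replicates per garden for
#'   each cloned genotype (total copies per garden =
#'   \code{clonalReplicatesLocal + 1}).
#' @param gardenExtent width and height of each garden (m).
#' @param seed integer seed.
#' @return data.frame with columns \code{tree}, \code{population},
#'   \code{genotype}, \code{garden}, \code{x}, \code{y}; one row per
#'   planted tree.
#' @examples
#' d <- simulateGardenDesign(nPopulations = 3, genotypesPerPopulation = 5,
#'                           nGardens = 2, localPopulations = 1,
#'                           nLocalGenotypes = 2, seed = 1)
#' table(d$garden)
#' @export
simulateGardenDesign <- function(nPopulations = 9,
                                 genotypesPerPopulation = c(30, 60),
                                 nGardens = 3,
                                 localPopulations = NULL,
                                 nLocalGenotypes = 20,
                                 clonalReplicatesLocal = 5,
                                 gardenExtent = c(90, 90),
                                 seed = 1L) {
  if (nPopulations < 1) stop("need at least one population")
  if (clonalReplicatesLocal < 0) stop("replicate count must be >= 0")
  if (is.null(localPopulations))
    localPopulations <- unique(round(seq(1, nPopulations,
                                         length.out = min(3, nPopulations))))
  if (any(localPopulations < 1 | localPopulations > nPopulations))
    stop("localPopulations must index existing populations")
  set.seed(as.integer(seed))
  pops <- sprintf("P%d", seq_len(nPopulations))
  rng <- range(genotypesPerPopulation)
  nG <- if (rng[1] == rng[2]) rep(rng[1], nPopulations)
        else sample(seq(rng[1], rng[2]), nPopulations, replace = TRUE)
  gardens <- sprintf("G%d", seq_len(nGardens))

  rows <- lapply(seq_len(nPopulations), function(p) {
    genos <- sprintf("%s.g%02d", pops[p], seq_len(nG[p]))
    copies <- rep(1L, nG[p])
    if (p %in% localPopulations) {
      nl <- min(nLocalGenotypes, nG[p])
      copies[seq_len(nl)] <- 1L + clonalReplicatesLocal
    }
    data.frame(population = pops[p],
               genotype = rep(genos, copies))
  })
  perGarden <- do.call(rbind, rows)
  design <- do.call(rbind, lapply(gardens, function(g)
    cbind(perGarden, garden = g)))
  n <- nrow(design)
  design$tree <- sprintf("t%05d", seq_len(n))
  design$x <- round(stats::runif(n, 0, gardenExtent[1]), 2)
  design$y <- round(stats::runif(n, 0, gardenExtent[2]), 2)
  rownames(design) <- NULL
  design[, c("tree", "population", "genotype", "garden", "x", "y")]
}

#' Synthetic climate/geography table for source populations
#'
#' Builds a population x variable table shaped like a ClimateWNA extract:
#' 21 climate normals plus latitude, longitude and elevation, with the
#' temperature and degree-day variables strongly driven by a shared
#' latitudinal factor so that the leading principal component is a
#' latitude/temperature axis.
#'
#' @param nPopulations number of populations.
#' @param latRange latitudinal span of the sources (degrees N).
#' @param seed integer seed.
#' @return data.frame: \code{population}, 21 climate variables,
#'   \code{latitude}, \code{longitude}, \code{elevation}.
#' @export
simulateClimateTable <- function(nPopulations = 9, latRange = c(34, 50),
                                 seed = 1L) {
  set.seed(as.integer(seed))
  lat <- seq(latRange[1], latRange[2], length.out = nPopulations)
  f <- as.numeric(scale(lat))          # shared latitudinal factor
  vars <- c("MAT", "MWMT", "MCMT", "TD", "MAP", "MSP", "AHM", "SHM",
            "DD0", "DD5", "DD18", "DDsub18", "NFFD", "FFP", "bFFP",
            "eFFP", "PAS", "EMT", "EXT", "Eref", "CMD")
  ## temperature/degree-day variables load strongly on latitude,
  ## precipitation variables weakly
  strong <- c("MAT", "MWMT", "MCMT", "DD0", "DD5", "DD18", "DDsub18",
              "NFFD", "FFP", "bFFP", "eFFP", "EMT", "EXT", "Eref")
  out <- data.frame(population = sprintf("P%d", seq_len(nPopulations)))
  for (v in vars) {
    load <- if (v %in% strong) stats::runif(1, 0.85, 0.98)
            else stats::runif(1, 0.2, 0.5)
    sgn <- if (v %in% c("MAT", "MWMT", "MCMT", "DD5", "DD18", "NFFD",
                        "FFP", "EMT", "EXT", "Eref")) -1 else 1
    out[[v]] <- round(sgn * load * f +
                        stats::rnorm(nPopulations, 0, sqrt(1 - load^2)), 4)
  }
  out$latitude <- round(lat, 3)
  out$longitude <- round(-113 + 0.3 * f + stats::rnorm(nPopulations, 0, 0.8), 3)
  out$elevation <- round(1500 + 300 * f + stats::rnorm(nPopulations, 0, 120))
  out
}

## Smooth microsite surface: 2-3 seeded Gaussian bumps plus a planar tilt.
## Returns a function of (x, y); deterministic given seed.
micrositeSurface <- function(extent = c(90, 90), amplitude = 0.5,
                             nBumps = 3, tilt = 0.6 * amplitude, seed = 1L) {
  set.seed(as.integer(seed))
  cx <- stats::runif(nBumps, 0, extent[1])
  cy <- stats::runif(nBumps, 0, extent[2])
  w <- stats::runif(nBumps, extent[1] / 6, extent[1] / 3)
  a <- stats::runif(nBumps, 0.5, 1) * amplitude
  bx <- stats::runif(1, -1, 1) * tilt / extent[1]
  by <- stats::runif(1, -1, 1) * tilt / extent[2]
  function(x, y) {
    s <- bx * (x - extent[1] / 2) + by * (y - extent[2] / 2)
    for (k in seq_len(nBumps))
      s <- s + a[k] * exp(-((x - cx[k])^2 + (y - cy[k])^2) / (2 * w[k]^2))
    s
  }
}

#' Simulate a Gaussian trait over a planting design
#'
#' Trait value per tree:
#' \deqn{y = \alpha_0 + slope \cdot PC1_p + \gamma_p + \beta_{g(p)} +
#'   garden + interaction + microsite(x, y) + \varepsilon}
#' with each random layer drawn from its ground-truth variance.  All drawn
#' effects are returned as a sidecar list so recovery can be checked.
#'
#' @param design planting table from \code{\link{simulateGardenDesign}}.
#' @param truth \code{\link{truthParams}}.
#' @param pc1 named numeric vector of climate PC1 scores per population, or
#'   a climate table with \code{population} and \code{pc1} columns.  By
#'   default an evenly spaced, unit-variance latitudinal gradient.
#' @param gardenPC1 optional named vector of climate PC1 scores per garden;
#'   when supplied, \code{truth$quad_transfer} adds a curvature term
#'   \code{quad_transfer * (gardenPC1 - sourcePC1)^2} to each tree's mean,
#'   emulating local adaptation in growth.
#' @param micrositeAmplitude amplitude of the smooth within-garden surface
#'   (0 disables it).
#' @param seed integer seed (defaults to \code{truth$seed}).
#' @return list with \code{traits} (tree-level TraitObservation table with
#'   column \code{value}) and \code{truth} (sidecar: drawn effects per
#'   layer, microsite values, parameters).
#' @examples
#' d <- simulateGardenDesign(3, 4, 2, localPopulations = 1, seed = 1)
#' s <- simulateTraits(d, truthParams(sigma2_P = 1, seed = 1))
#' head(s$traits)
#' @export
simulateTraits <- function(design, truth = truthParams(), pc1 = NULL,
                           gardenPC1 = NULL, micrositeAmplitude = 0.5,
                           seed = truth$seed) {
  stopifnot(inherits(truth, "truthParams"))
  pops <- sort(unique(design$population))
  if (is.null(pc1)) {
    pc1 <- as.numeric(scale(seq_along(pops)))
    if (length(pops) == 1L) pc1 <- 0
    names(pc1) <- pops
  } else if (is.data.frame(pc1)) {
    stopifnot(all(c("population", "pc1") %in% names(pc1)))
    pc1 <- stats::setNames(pc1$pc1, pc1$population)
  }
  if (!all(pops %in% names(pc1)))
    stop("missing climate PC1 for population(s): ",
         paste(setdiff(pops, names(pc1)), collapse = ", "))
  set.seed(as.integer(seed))
  genos <- sort(unique(design$genotype))
  gardens <- sort(unique(design$garden))
  popEff <- stats::setNames(stats::rnorm(length(pops),
                                         0, sqrt(truth$sigma2_P)), pops)
  genoEff <- stats::setNames(stats::rnorm(length(genos),
                                          0, sqrt(truth$sigma2_G)), genos)
  gardEff <- stats::setNames(stats::rnorm(length(gardens),
                                          0, sqrt(truth$sigma2_garden)),
                             gardens)
  pg <- as.vector(outer(pops, gardens, paste, sep = ":"))
  pgEff <- stats::setNames(stats::rnorm(length(pg),
                                        0, sqrt(truth$sigma2_GxE)), pg)
  ext <- c(max(design$x), max(design$y))
  micro <- numeric(nrow(design))
  surfs <- list()
  for (g in gardens) {
    surfs[[g]] <- micrositeSurface(ext, amplitude = micrositeAmplitude,
                                   seed = stageSeed(seed, paste0("ms", g)))
    i <- design$garden == g
    micro[i] <- surfs[[g]](design$x[i], design$y[i])
  }
  eps <- stats::rnorm(nrow(design), 0, sqrt(truth$sigma2_W))
  transfer <- 0
  if (!is.null(gardenPC1)) {
    if (!all(gardens %in% names(gardenPC1)))
      stop("missing garden PC1 for garden(s): ",
           paste(setdiff(gardens, names(gardenPC1)), collapse = ", "))
    pcTrd <- gardenPC1[design$garden] - pc1[design$population]
    transfer <- truth$quad_transfer * pcTrd^2
  }
  value <- truth$alpha0 +
    truth$climate_slope * pc1[design$population] +
    popEff[design$population] + genoEff[design$genotype] +
    gardEff[design$garden] +
    pgEff[paste(design$population, design$garden, sep = ":")] +
    micro + transfer + eps
  traits <- design
  traits$value <- as.numeric(value)
  list(
    traits = traits,
    truth = list(params = truth, pc1 = pc1,
                 populationEffects = popEff, genotypeEffects = genoEff,
                 gardenEffects = gardEff, interactionEffects = pgEff,
                 microsite = micro, residuals = eps)
  )
}

#' Simulate an arthropod community over a planting design
#'
#' Per-tree total counts are Poisson-lognormal: the log-mean carries
#' population, genotype and extra-Poisson (overdispersion) Gaussian layers;
#' totals are then allocated to taxa by a multinomial draw with a fixed
#' geometric abundance profile, so richness/abundance/diversity have known
#' expectations.
#'
#' @param design planting table (one garden's trees, typically).
#' @param truth \code{\link{truthParams}}; \code{sigma2_P} and
#'   \code{sigma2_G} act on the log scale here and
#'   \code{overdispersion_sd} is the residual log-scale sd.
#' @param nTaxa number of taxa (RTUs) in the pool.
#' @param abundanceDecay geometric decay of the taxon abundance profile
#'   (taxon k has relative abundance \code{abundanceDecay^k}).
#' @param seed integer seed.
#' @return list with \code{community} (tree x taxon integer matrix),
#'   \code{totals} (TraitObservation-shaped table of per-tree total
#'   counts) and \code{truth} sidecar.
#' @examples
#' d <- simulateGardenDesign(3, 4, 1, localPopulations = 1, seed = 1)
#' cc <- simulateCounts(d, truthParams(alpha0 = log(10), seed = 1))
#' dim(cc$community)
#' @export
simulateCounts <- function(design, truth = truthParams(alpha0 = log(10)),
                           nTaxa = 53, abundanceDecay = 0.85,
                           seed = truth$seed) {
  stopifnot(inherits(truth, "truthParams"))
  if (truth$overdispersion_sd < 0) stop("negative overdispersion")
  set.seed(as.integer(seed))
  pops <- sort(unique(design$population))
  genos <- sort(unique(design$genotype))
  popEff <- stats::setNames(stats::rnorm(length(pops),
                                         0, sqrt(truth$sigma2_P)), pops)
  genoEff <- stats::setNames(stats::rnorm(length(genos),
                                          0, sqrt(truth$sigma2_G)), genos)
  eps <- stats::rnorm(nrow(design), 0, truth$overdispersion_sd)
  eta <- truth$alpha0 + popEff[design$population] +
    genoEff[design$genotype] + eps
  totals <- stats::rpois(nrow(design), exp(eta))
  prof <- abundanceDecay^seq_len(nTaxa)
  prof <- prof / sum(prof)
  taxa <- sprintf("rtu%02d", seq_len(nTaxa))
  community <- t(vapply(totals, function(a)
    as.integer(stats::rmultinom(1, a, prof)), integer(nTaxa)))
  dimnames(community) <- list(design$tree, taxa)
  tt <- design
  tt$value <- totals
  list(
    community = community,
    totals = tt,
    truth = list(params = truth, populationEffects = popEff,
                 genotypeEffects = genoEff, logResiduals = eps,
                 abundanceProfile = stats::setNames(prof, taxa))
  )
}
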