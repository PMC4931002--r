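## Configuration, validation and end-to-end orchestration: simulate (or
## read) -> detrend -> per-trait fits -> Q_ST -> G x E -> transfer ->
## community, with a hashed output manifest.

#' Build a run configuration
#'
#' @param seed root seed; every stage derives its own substream via
#'   \code{\link{stageSeed}}.
#' @param outputDir directory for all outputs (created if needed).
#' @param mcmc list with \code{burnin}, \code{samples}, \code{thin}.
#' @param fst list with \code{point}, \code{lower}, \code{upper} of the
#'   externally supplied F_ST estimate.
#' @param stages named logical list switching the qst, gxe, transfer and
#'   community stages.
#' @param simulate list of synthetic-garden settings (design sizes and
#'   \code{truth} parameters); ignored when \code{inputs} is supplied.
#' @param inputs optional list of CSV paths (\code{traits},
#'   \code{community}, \code{climate}) for externally supplied data; the
#'   traits table needs tree/population/genotype/garden/x/y/value columns.
#' @return list of class \code{"runConfig"}.
#' @export
runConfig <- function(seed = 1L, outputDir = "gardenQst-out",
                      mcmc = list(burnin = 2000, samples = 4000, thin = 1),
                      fst = list(point = 0.21, lower = 0.16, upper = 0.26),
                      stages = list(qst = TRUE, gxe = TRUE,
                                    transfer = TRUE, community = TRUE),
                      simulate = list(), inputs = NULL) {
  simDefaults <- list(nPopulations = 9, genotypesPerPopulation = c(30, 60),
                      nGardens = 3, nLocalGenotypes = 20,
                      clonalReplicatesLocal = 5,
                      truth = list(alpha0 = 40, sigma2_P = 30,
                                   sigma2_G = 15, sigma2_W = 30,
                                   sigma2_garden = 5, sigma2_GxE = 5,
                                   climate_slope = 0, quad_transfer = 0,
                                   overdispersion_sd = 0.5))
  simulate <- utils::modifyList(simDefaults, simulate)
  structure(list(seed = as.integer(seed), outputDir = outputDir,
                 mcmc = mcmc, fst = fst, stages = stages,
                 simulate = simulate, inputs = inputs),
            class = "runConfig")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{runConfig}}; missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return list of class \code{"runConfig"}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(runConfig, y[intersect(names(y), names(formals(runConfig)))])
}

#' Validate analysis input tables
#'
#' Report-only schema and integrity check: required columns, key
#' resolution against the planting table, row counts, missingness, and
#' range checks (frost-damage percentages must lie in [0, 100]).
#'
#' @param traits TraitObservation table (or CSV path).
#' @param planting optional planting/design table for key checks.
#' @param community optional tree x taxon count matrix (or CSV path).
#' @param climate optional climate table (or CSV path).
#' @param percentTraits trait names (of a \code{trait} column, if present)
#'   constrained to [0, 100].
#' @return list with \code{issues} (data.frame: table, issue, detail) and
#'   \code{summary} (row counts and missingness per table).
#' @export
validateInputs <- function(traits, planting = NULL, community = NULL,
                           climate = NULL,
                           percentTraits = "frost_damage") {
  readMaybe <- function(x) if (is.character(x) && length(x) == 1L)
    utils::read.csv(x) else x
  traits <- readMaybe(traits); planting <- readMaybe(planting)
  climate <- readMaybe(climate)
  if (is.character(community) && length(community) == 1L)
    community <- as.matrix(utils::read.csv(community, row.names = 1))
  issues <- data.frame(table = character(), issue = character(),
                       detail = character())
  add <- function(tab, issue, detail)
    issues <<- rbind(issues, data.frame(table = tab, issue = issue,
                                        detail = detail))
  need <- c("tree", "population", "genotype", "garden", "value")
  miss <- setdiff(need, names(traits))
  if (length(miss))
    add("traits", "missing_column", paste(miss, collapse = ", "))
  if (!is.null(planting) && all(c("tree", "genotype") %in% names(traits))) {
    badg <- setdiff(traits$genotype, planting$genotype)
    if (length(badg))
      add("traits", "unknown_genotype", paste(badg, collapse = ", "))
    badt <- setdiff(traits$tree, planting$tree)
    if (length(badt))
      add("traits", "unknown_tree", paste(badt, collapse = ", "))
  }
  if (!is.null(traits$trait) && "value" %in% names(traits)) {
    pt <- traits$trait %in% percentTraits
    bad <- pt & (traits$value < 0 | traits$value > 100) & !is.na(traits$value)
    if (any(bad))
      add("traits", "range_violation",
          sprintf("%d percent value(s) outside [0, 100]", sum(bad)))
  }
  if (!is.null(community)) {
    if (any(community < 0, na.rm = TRUE))
      add("community", "negative_count", "counts must be nonnegative")
    if (any(community != round(community), na.rm = TRUE))
      add("community", "noninteger_count", "counts must be integers")
  }
  if (!is.null(climate) && !"population" %in% names(climate))
    add("climate", "missing_column", "population")
  summarize <- function(d) if (is.null(d)) NULL else
    list(rows = nrow(d), missing = sum(is.na(as.matrix(d))))
  list(issues = issues,
       summary = list(traits = summarize(traits),
                      planting = summarize(planting),
                      community = summarize(community),
                      climate = summarize(climate)))
}

## Round numerics to 10 significant digits before writing so manifest
## hashes are stable across platforms.
.writeTable <- function(d, path) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], signif, digits = 10)
  utils::write.csv(d, path, row.names = FALSE)
  path
}

#' Run the full common-garden analysis pipeline
#'
#' Executes the stages in order -- synthetic data generation (or input
#' loading), spatial detrending, replicated-genotype and nine-population
#' variance-component fits, Q_ST/H2 and Q_ST-F_ST calls, G x E
#' partitioning, the climate transfer function, and community diversity
#' analysis -- writing CSV outputs and a JSON manifest with content
#' hashes, seeds and sampler diagnostics.
#'
#' @param config a \code{\link{runConfig}} (or path to a YAML config).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = runConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  outPath <- function(f) file.path(config$outputDir, f)
  log <- list(seeds = list(root = config$seed), notes = character())
  note <- function(...) log$notes <<- c(log$notes, sprintf(...))
  mc <- function(stage) hbControl(burnin = config$mcmc$burnin,
                                  samples = config$mcmc$samples,
                                  thin = config$mcmc$thin,
                                  seed = stageSeed(config$seed, stage))
  files <- character()

  ## ---- stage: data ----
  if (is.null(config$inputs)) {
    sgSeed <- stageSeed(config$seed, "simulate")
    log$seeds$simulate <- sgSeed
    sim <- config$simulate
    design <- simulateGardenDesign(
      nPopulations = sim$nPopulations,
      genotypesPerPopulation = sim$genotypesPerPopulation,
      nGardens = sim$nGardens, nLocalGenotypes = sim$nLocalGenotypes,
      clonalReplicatesLocal = sim$clonalReplicatesLocal, seed = sgSeed)
    climate <- simulateClimateTable(sim$nPopulations, seed = sgSeed)
    truth <- do.call(truthParams, c(sim$truth, list(seed = sgSeed)))
    st <- simulateTraits(design, truth,
                         seed = stageSeed(config$seed, "traits"))
    traits <- st$traits
    cg <- design[design$garden == design$garden[1], ]
    cc <- simulateCounts(cg, truthParams(
      alpha0 = log(10), sigma2_P = 0.3, sigma2_G = 0.15,
      overdispersion_sd = truth$overdispersion_sd),
      seed = stageSeed(config$seed, "counts"))
    community <- cc$community
    files <- c(files, .writeTable(traits, outPath("traits_raw.csv")))
    truthTab <- data.frame(parameter = names(unclass(truth)),
                           value = unlist(unclass(truth)))
    files <- c(files, .writeTable(truthTab, outPath("truth_sidecar.csv")))
  } else {
    if (is.null(config$inputs$traits))
      stop("stage 'data' failed: config$inputs$traits path is required")
    traits <- utils::read.csv(config$inputs$traits)
    design <- traits[, intersect(c("tree", "population", "genotype",
                                   "garden", "x", "y"), names(traits))]
    community <- if (!is.null(config$inputs$community))
      as.matrix(utils::read.csv(config$inputs$community, row.names = 1))
    else NULL
    climate <- if (!is.null(config$inputs$climate))
      utils::read.csv(config$inputs$climate) else NULL
    if (isTRUE(config$stages$transfer) && is.null(climate))
      stop("stage 'transfer' enabled but no climate table supplied ",
           "in config$inputs$climate")
    if (isTRUE(config$stages$community) && is.null(community))
      stop("stage 'community' enabled but no community matrix supplied ",
           "in config$inputs$community")
  }
  val <- validateInputs(traits, planting = design, community = community,
                        climate = climate)
  if (nrow(val$issues)) {
    utils::write.csv(val$issues, outPath("input_issues.csv"),
                     row.names = FALSE)
    files <- c(files, outPath("input_issues.csv"))
    note("input validation flagged %d issue(s)", nrow(val$issues))
  }

  ## ---- stage: detrend ----
  traits <- detrendTraits(traits)
  files <- c(files, .writeTable(traits, outPath("traits_detrended.csv")))

  fst <- fstInterval(config$fst$point, config$fst$lower, config$fst$upper)
  pca <- if (!is.null(climate)) climatePCA(climate) else NULL
  if (!is.null(pca)) {
    files <- c(files, .writeTable(
      data.frame(variable = rownames(pca$loadings), pca$loadings),
      outPath("climate_pca_loadings.csv")))
    files <- c(files, .writeTable(
      data.frame(population = rownames(pca$scores), pca$scores),
      outPath("climate_pca_scores.csv")))
  }

  ## ---- stage: per-garden Q_ST ----
  if (isTRUE(config$stages$qst)) {
    reps <- table(traits$genotype, traits$garden)
    localGeno <- rownames(reps)[apply(reps, 1, min) >= 2]
    rows <- list()
    for (g in sort(unique(traits$garden))) {
      tg <- traits[traits$garden == g, ]
      t3 <- tg[tg$genotype %in% localGeno, ]
      fit3 <- fitGaussianHB(t3, mcmc = mc(paste0("fit3.", g)),
                            keepEffects = FALSE)
      fitCW <- fitGaussianHB(t3, population = NULL,
                             mcmc = mc(paste0("fitcw.", g)),
                             keepEffects = FALSE)
      fit9 <- fitGaussianHB(tg, genotype = NULL,
                            mcmc = mc(paste0("fit9.", g)),
                            keepEffects = FALSE)
      h2h <- h2FromDraws(fit3)
      h2cw <- h2FromDraws(fitCW)
      q3 <- qstFromDraws(fit3)
      q9 <- ninePopQst(fit9, h2h$mean)
      call9 <- qstFstTest(q9, fst)
      rows[[g]] <- data.frame(
        trait = "height", garden = g, year = 1,
        h2_collection = h2cw$mean, h2_hierarchical = h2h$mean,
        qst3_mean = q3@mean, qst3_lo = q3@ci[1], qst3_hi = q3@ci[2],
        qst9_mean = q9@mean, qst9_lo = q9@ci[1], qst9_hi = q9@ci[2],
        divergence = call9$call)
    }
    qstTab <- do.call(rbind, rows)
    rownames(qstTab) <- NULL
    files <- c(files, .writeTable(qstTab, outPath("table1_qst.csv")))
  }

  ## ---- stage: G x E ----
  if (isTRUE(config$stages$gxe)) {
    gxe <- fitGxE(traits, mcmc = mc("gxe"), keepEffects = FALSE)
    files <- c(files, .writeTable(gxe$proportions,
                                  outPath("table2_gxe.csv")))
  }

  ## ---- stage: transfer function ----
  if (isTRUE(config$stages$transfer) && !is.null(pca)) {
    srcPC1 <- stats::setNames(pca$scores[, "PC1"], rownames(pca$scores))
    gards <- sort(unique(traits$garden))
    ## gardens sit at the southern, central and northern extremes of the
    ## source gradient when simulating; externally supplied data should
    ## provide garden PC1 via the climate table (rows named like gardens)
    gpc <- if (all(gards %in% names(srcPC1))) srcPC1[gards]
           else stats::setNames(seq(min(srcPC1), max(srcPC1),
                                    length.out = length(gards)), gards)
    tf <- transferFunction(traits, srcPC1, gpc, mcmc = mc("transfer"))
    files <- c(files, .writeTable(tf@coef, outPath("transfer_coef.csv")))
    files <- c(files, .writeTable(tf@curve, outPath("transfer_curve.csv")))
    log$transfer <- list(apex = tf@apex,
                         localAdaptation = tf@localAdaptation)
  }

  ## ---- stage: community ----
  if (isTRUE(config$stages$community) && !is.null(community)) {
    div <- communityDiversity(community)
    files <- c(files, .writeTable(div, outPath("community_metrics.csv")))
    divd <- merge(div, design, by = "tree")
    rows <- list()
    for (metric in c("S", "A")) {
      fit <- fitPoissonHB(divd, response = metric,
                          mcmc = mc(paste0("comm.", metric)),
                          keepEffects = FALSE)
      q <- qstFromDraws(fit); h <- h2FromDraws(fit)
      rows[[metric]] <- data.frame(metric = metric, h2 = h$mean,
                                   qst_mean = q@mean, qst_lo = q@ci[1],
                                   qst_hi = q@ci[2],
                                   divergence = qstFstTest(q, fst)$call)
      log$acceptance[[metric]] <- fit@acceptance
    }
    fitH <- fitGaussianHB(divd, response = "H", mcmc = mc("comm.H"),
                          keepEffects = FALSE)
    qH <- qstFromDraws(fitH); hH <- h2FromDraws(fitH)
    rows$H <- data.frame(metric = "H", h2 = hH$mean, qst_mean = qH@mean,
                         qst_lo = qH@ci[1], qst_hi = qH@ci[2],
                         divergence = qstFstTest(qH, fst)$call)
    commTab <- do.call(rbind, rows)
    rownames(commTab) <- NULL
    files <- c(files, .writeTable(commTab, outPath("table3_community.csv")))
    acc <- accumulationCurve(community, seed = stageSeed(config$seed, "sac"))
    files <- c(files, .writeTable(acc, outPath("accumulation_curve.csv")))
  }

  ## ---- manifest ----
  manifest <- list(
    config = unclass(config),
    seeds = log$seeds,
    notes = log$notes,
    transfer = log$transfer,
    acceptance = log$acceptance,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, outPath("manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
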