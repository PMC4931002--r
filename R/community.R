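## Arthropod community diversity: per-tree richness/abundance/Shannon
## metrics, species accumulation curves, and multilevel community-trait
## correlations.

#' Per-tree community diversity metrics
#'
#' Richness S (taxa present), abundance A (total individuals) and Shannon
#' diversity H' (natural-log units) for each row of a tree x taxon count
#' matrix.  All-zero rows yield S = A = H' = 0.
#'
#' @param community nonnegative integer matrix, trees as rows, taxa as
#'   columns.
#' @return data.frame with columns \code{tree}, \code{S}, \code{A},
#'   \code{H}.
#' @examples
#' m <- rbind(a = c(5, 5, 5, 5), b = c(10, 0, 0, 0))
#' communityDiversity(m)   # H' = ln 4 for the even row, 0 for the other
#' @export
communityDiversity <- function(community) {
  community <- as.matrix(community)
  if (any(community < 0)) stop("negative counts are not allowed")
  if (anyDuplicated(colnames(community)))
    stop("taxon labels must be unique")
  data.frame(
    tree = if (!is.null(rownames(community))) rownames(community)
           else as.character(seq_len(nrow(community))),
    S = as.integer(vegan::specnumber(community)),
    A = as.integer(rowSums(community)),
    H = as.numeric(vegan::diversity(community, index = "shannon")),
    row.names = NULL
  )
}

#' Species accumulation curve
#'
#' Expected cumulative richness as trees are sampled.  The default
#' estimates the expectation over seeded random orderings of trees; the
#' exact mode computes the analytic expectation over all orderings
#' (identical to the exhaustive average) and is the default for 7 or
#' fewer trees.
#'
#' @param community tree x taxon count matrix.
#' @param permutations number of random orderings.
#' @param seed integer seed for the random orderings.
#' @param method \code{"auto"} (exact for <= 7 trees), \code{"random"} or
#'   \code{"exact"}.
#' @return data.frame with \code{trees} sampled, expected \code{richness}
#'   and its \code{sd} (0 in exact mode).
#' @export
accumulationCurve <- function(community, permutations = 100, seed = 1L,
                              method = c("auto", "random", "exact")) {
  method <- match.arg(method)
  community <- as.matrix(community)
  if (nrow(community) < 1L) stop("need at least one tree")
  if (permutations < 1L) stop("permutations must be >= 1")
  if (method == "auto")
    method <- if (nrow(community) <= 7L) "exact" else "random"
  ## muffle vegan/permute side notes: the exhaustive fallback for tiny
  ## permutation sets and the NaN sd of degenerate (zero-variance) curves
  quiet <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl("minperm|NaNs produced", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  if (method == "random") {
    set.seed(as.integer(seed))
    sa <- quiet(vegan::specaccum(community, method = "random",
                                 permutations = permutations))
  } else {
    sa <- quiet(vegan::specaccum(community, method = "exact"))
  }
  sdv <- if (is.null(sa$sd)) rep(0, length(sa$sites))
         else as.numeric(sa$sd)
  sdv[!is.finite(sdv)] <- 0
  data.frame(trees = sa$sites, richness = as.numeric(sa$richness),
             sd = sdv)
}

#' Multilevel community-trait correlations
#'
#' Correlates community diversity metrics with a plant trait at the
#' individual tree, genotype or population level.  Following the count
#' nature of S and A, those use Spearman rank correlation; H' uses
#' Pearson.  At the genotype and population levels the inputs are
#' expected to be posterior mean effects (one row per genotype or
#' population).
#'
#' @param metrics data.frame with an id column and metric columns
#'   (\code{S}, \code{A}, \code{H} by default).
#' @param traits data.frame with the same id column and the trait column.
#' @param by shared id column (\code{"tree"}, \code{"genotype"} or
#'   \code{"population"}).
#' @param level label recorded in the output (defaults to \code{by}).
#' @param traitCol trait column name.
#' @param metricCols metric column names.
#' @return data.frame: metric, level, method, n, estimate, p.value.
#' @export
multilevelCorrelation <- function(metrics, traits, by = "tree",
                                  level = NULL, traitCol = "value",
                                  metricCols = c("S", "A", "H")) {
  if (is.null(level))
    level <- switch(by, tree = "individual", by)
  m <- merge(metrics, traits[, c(by, traitCol)], by = by)
  out <- lapply(metricCols, function(mc) {
    ok <- stats::complete.cases(m[[mc]], m[[traitCol]])
    if (sum(ok) < 3L) stop("fewer than 3 complete pairs for ", mc)
    method <- if (mc == "H") "pearson" else "spearman"
    ct <- suppressWarnings(
      stats::cor.test(m[[mc]][ok], m[[traitCol]][ok], method = method,
                      exact = FALSE))
    data.frame(metric = mc, level = level, method = method,
               n = sum(ok), estimate = unname(ct$estimate),
               p.value = ct$p.value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
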