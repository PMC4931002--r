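#' Extract posterior draws
#'
#' @param object an \code{\linkS4class{HBPosterior}} or
#'   \code{\linkS4class{QstEstimate}}.
#' @param pars optional character vector of parameter names.
#' @return a numeric matrix (one column per parameter) or vector.
#' @export
setGeneric("posteriorDraws", function(object, pars = NULL)
  standardGeneric("posteriorDraws"))

#' Posterior summary table
#'
#' @param object a fitted posterior object.
#' @param level credible level for equal-tailed intervals.
#' @return data.frame with posterior mean, sd and credible bounds per
#'   parameter.
#' @export
setGeneric("posteriorSummary", function(object, level = 0.95)
  standardGeneric("posteriorSummary"))

#' Posterior mean random effects
#'
#' @param object an \code{\linkS4class{HBPosterior}}.
#' @param block name of the random-effect block (e.g. \code{"population"},
#'   \code{"genotype"}).
#' @return named numeric vector of posterior mean effects, one per level.
#' @export
setGeneric("effectMeans", function(object, block)
  standardGeneric("effectMeans"))

setMethod("posteriorDraws", "HBPosterior", function(object, pars = NULL) {
  if (is.null(pars)) return(object@draws)
  miss <- setdiff(pars, colnames(object@draws))
  if (length(miss))
    stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  object@draws[, pars, drop = FALSE]
})

setMethod("posteriorDraws", "QstEstimate", function(object, pars = NULL) {
  object@draws
})

setMethod("posteriorSummary", "HBPosterior", function(object, level = 0.95) {
  d <- object@draws
  ci <- apply(d, 2, credInterval, level = level)
  data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd),
    lower = ci[1, ],
    upper = ci[2, ],
    row.names = NULL
  )
})

setMethod("posteriorSummary", "QstEstimate", function(object, level = 0.95) {
  data.frame(
    parameter = "Q_ST",
    mean = object@mean,
    sd = stats::sd(object@draws),
    lower = object@ci[1],
    upper = object@ci[2],
    model = object@model,
    row.names = NULL
  )
})

setMethod("effectMeans", "HBPosterior", function(object, block) {
  if (!block %in% names(object@effects))
    stop("no random-effect block named '", block, "'; available: ",
         paste(names(object@effects), collapse = ", "))
  m <- colMeans(object@effects[[block]])
  names(m) <- object@effectLevels[[block]]
  m
})

setMethod("show", "HBPosterior", function(object) {
  cat("HBPosterior:", object@family, "hierarchical model\n")
  cat("  draws:", nrow(object@draws), "retained (burnin",
      object@mcmc$burnin, ", thin", object@mcmc$thin, ")\n")
  cat("  blocks:", if (length(object@effects))
    paste(names(object@effects), collapse = ", ") else "(none)", "\n")
  if (!is.na(object@acceptance))
    cat("  latent Metropolis acceptance:",
        sprintf("%.2f", object@acceptance), "\n")
  s <- posteriorSummary(object)
  s[, -1] <- signif(s[, -1], 3)
  print(s, row.names = FALSE)
  bad <- object@diagnostics$rhat > 1.05
  if (any(bad, na.rm = TRUE))
    cat("  warning: Rhat > 1.05 for",
        paste(object@diagnostics$parameter[which(bad)], collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "QstEstimate", function(object) {
  cat(sprintf("QstEstimate (%s): mean %.3f, 95%% CI (%.3f-%.3f)\n",
              object@model, object@mean, object@ci[1], object@ci[2]))
  if (object@excluded > 0L)
    cat("  draws excluded (both variances ~0):", object@excluded, "\n")
  invisible(object)
})

setMethod("show", "TransferResult", function(object) {
  cat("TransferResult: quadratic climate transfer function\n")
  co <- object@coef
  co[, -1] <- signif(co[, -1], 3)
  print(co, row.names = FALSE)
  cat(sprintf("  apex at pc_trd = %.3f; local adaptation: %s\n",
              object@apex, object@localAdaptation))
  invisible(object)
})
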