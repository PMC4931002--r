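## Trait preparation: bud-flush phenology interpolation and thin-plate
## spline spatial detrending of within-garden microsite heterogeneity.

#' Interpolate bud-flush stage dates from repeated surveys
#'
#' Spring bud flush is scored repeatedly on a 5-point stage scale (0-4).
#' For each tree, stage is regressed on day-of-year by ordinary least
#' squares (multiple buds per survey are averaged to one stage per date
#' first) and the fitted line is inverted to give the date at which each
#' requested stage was reached.  Trees with fewer than two distinct stage
#' values or a non-positive fitted slope cannot be interpolated and return
#' \code{NA} with a flag.
#'
#' @param surveys long-format data.frame with columns \code{tree},
#'   \code{date} (day-of-year) and \code{stage}.
#' @param stages stages at which to interpolate dates (default initiation
#'   stage 1 and completion stage 4).
#' @param scale valid stage range.
#' @return data.frame with one row per tree: interpolated date per stage
#'   (columns \code{stage1}, \code{stage4}, ...), the fitted slope, and a
#'   \code{flag} (\code{"ok"}, \code{"too_few_stages"},
#'   \code{"nonpositive_slope"}).
#' @examples
#' s <- data.frame(tree = "a", date = c(100, 120), stage = c(0, 4))
#' interpolateFlushDates(s)   # stage 1 at day 105, stage 4 at day 120
#' @export
interpolateFlushDates <- function(surveys, stages = c(1, 4),
                                  scale = c(0, 4)) {
  stopifnot(all(c("tree", "date", "stage") %in% names(surveys)))
  if (any(stages < scale[1] | stages > scale[2]))
    stop("requested stages outside the stage scale")
  out <- lapply(split(surveys, surveys$tree), function(d) {
    ## average the surveyed buds to one stage value per survey date
    ag <- stats::aggregate(stage ~ date, data = d, FUN = mean)
    ag <- ag[order(ag$date), ]
    if (any(diff(ag$date) <= 0)) stop("dates must be strictly increasing")
    res <- as.list(rep(NA_real_, length(stages)))
    names(res) <- paste0("stage", stages)
    if (length(unique(ag$stage)) < 2L)
      return(c(list(tree = d$tree[1]), res,
               list(slope = NA_real_, flag = "too_few_stages")))
    fit <- stats::lm.fit(cbind(1, ag$date), ag$stage)
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    if (b <= 0)
      return(c(list(tree = d$tree[1]), res,
               list(slope = b, flag = "nonpositive_slope")))
    for (i in seq_along(stages)) res[[i]] <- (stages[i] - a) / b
    c(list(tree = d$tree[1]), res, list(slope = b, flag = "ok"))
  })
  out <- do.call(rbind, lapply(out, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Bud-flush duration
#'
#' Days from flush initiation (stage 1) to completion (stage 4).
#'
#' @param stage1,stage4 interpolated dates (day-of-year), vectors or the
#'   columns of \code{\link{interpolateFlushDates}} output.
#' @return numeric vector of durations; \code{NA} where either date is
#'   missing.
#' @examples
#' flushDuration(105, 120)  # 15 days
#' @export
flushDuration <- function(stage1, stage4) {
  ifelse(is.na(stage1) | is.na(stage4), NA_real_, stage4 - stage1)
}

#' Remove within-garden microsite trends with a thin-plate spline
#'
#' Fits a smooth thin-plate spline surface of the trait over planting
#' coordinates (one trait, one garden, one year at a time) and returns the
#' residuals, which represent the trait after correction for spatial
#' microsite heterogeneity.  The smoothing parameter is chosen by
#' generalized cross-validation unless supplied.  Because the spline's
#' unpenalized null space contains all affine functions, exactly planar
#' (or constant) fields yield residuals of zero.
#'
#' @param observations data.frame with columns \code{x}, \code{y} and the
#'   trait column.
#' @param value name of the trait column.
#' @param k basis dimension of the thin-plate smooth (upper limit on
#'   surface wiggliness); reduced automatically for small gardens.
#' @param sp optional fixed smoothing parameter (overrides GCV).
#' @return the input data.frame with \code{value} replaced by the spatial
#'   residuals (original kept as \code{value_raw}).
#' @examples
#' d <- expand.grid(x = 1:6, y = 1:6)
#' d$value <- 2 + 0.5 * d$x - 0.2 * d$y     # planar field
#' r <- detrendSpatial(d)
#' max(abs(r$value))                        # ~0
#' @export
detrendSpatial <- function(observations, value = "value", k = 30,
                           sp = NULL) {
  stopifnot(all(c("x", "y", value) %in% names(observations)))
  v <- observations[[value]]
  ok <- !is.na(v)
  coords <- unique(observations[ok, c("x", "y")])
  out <- observations
  out[[paste0(value, "_raw")]] <- v
  if (nrow(coords) < 3L) {
    warning("coordinates nearly identical; surface unidentifiable, ",
            "returning centered values")
    out[[value]] <- v - mean(v, na.rm = TRUE)
    return(out)
  }
  k <- min(k, nrow(coords) - 1L)
  df <- data.frame(v = v[ok], x = observations$x[ok],
                   y = observations$y[ok])
  fit <- mgcv::gam(v ~ s(x, y, bs = "tp", k = k), data = df,
                   method = "GCV.Cp", sp = sp)
  res <- rep(NA_real_, length(v))
  res[ok] <- stats::residuals(fit)
  out[[value]] <- res
  out
}

#' Detrend a trait table per garden (and optionally year)
#'
#' Convenience wrapper applying \code{\link{detrendSpatial}} within each
#' garden x year stratum, the unit at which microsite surfaces are
#' estimated.
#'
#' @param observations TraitObservation table with \code{garden}, \code{x},
#'   \code{y} and the trait column; an optional \code{year} column defines
#'   additional strata.
#' @param value trait column name.
#' @param ... passed to \code{\link{detrendSpatial}}.
#' @return the table with the trait column replaced by spatial residuals.
#' @export
detrendTraits <- function(observations, value = "value", ...) {
  strata <- observations$garden
  if (!is.null(observations$year))
    strata <- paste(strata, observations$year, sep = ".")
  parts <- split(observations, strata)
  out <- do.call(rbind, lapply(parts, detrendSpatial, value = value, ...))
  rownames(out) <- NULL
  if (!is.null(out$tree))
    out <- out[order(match(out$tree, observations$tree)), , drop = FALSE]
  out
}
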