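#' Derive a reproducible stage-specific seed from a root seed
#'
#' All randomness in the package flows from a single root seed; each pipeline
#' stage draws from its own named substream so stages can be rerun
#' independently yet reproducibly.
#'
#' @param seed Integer root seed.
#' @param stage Character stage label (e.g. \code{"simulate"}, \code{"fit"}).
#' @return A single integer in \code{[1, 2^31 - 2]}.
#' @examples
#' stageSeed(1L, "simulate")
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483646L + 1)
}

## Inverse-gamma draws, shape/scale parameterization:
## density proportional to x^-(shape+1) * exp(-scale/x).
rinvgamma <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

qinvgamma <- function(p, shape, scale) {
  1 / stats::qgamma(1 - p, shape = shape, rate = scale)
}

## Equal-tailed credible interval of a draw vector.
credInterval <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE, na.rm = TRUE)
}

## Split-chain potential scale reduction factor (two halves of one chain).
splitRhat <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  ch <- cbind(x[seq_len(half)], x[(n - half + 1):n])
  m <- ncol(ch); nn <- nrow(ch)
  mu <- colMeans(ch)
  B <- nn * stats::var(mu)
  W <- mean(apply(ch, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

## Effective sample size from the initial positive sequence of autocorrelations.
essBasic <- function(x) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  k <- if (length(pos)) pos[1] - 1L else length(ac)
  if (k < 1L) return(n)
  max(1, n / (1 + 2 * sum(ac[seq_len(k)])))
}
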