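#' Wilson score confidence interval for a binomial proportion
#'
#' Default interval for screen QC proportions (e.g. functional fractions of
#' small clone panels before/after sorting), where the Wilson score interval
#' keeps good coverage at small n and extreme proportions. Vectorized over
#' `k` and `n`.
#'
#' @param k Successes, 0 <= k <= n.
#' @param n Trials, >= 1.
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"wald"`.
#' @return Data frame with `k`, `n`, `estimate`, `lower`, `upper`, `level`.
#' @export
binomial_proportion_ci <- function(k, n, level = 0.95, method = c("wilson", "wald")) {
  method <- match.arg(method)
  if (any(n < 1) || any(k < 0) || any(k > n))
    stop("need 0 <= k <= n and n >= 1")
  if (!(level > 0 && level < 1)) stop("level must be in (0,1)")
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wilson") {
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    # guard against floating-point excursions at k = 0 / k = n
    lower <- pmin(pmax(0, center - half), p)
    upper <- pmax(pmin(1, center + half), p)
  } else {
    half <- z * sqrt(p * (1 - p) / n)
    lower <- pmax(0, p - half)
    upper <- pmin(1, p + half)
  }
  data.frame(k = k, n = n, estimate = p, lower = lower, upper = upper,
             level = level)
}

#' Fold enrichment of a fraction across sorting
#'
#' @param fraction_before Active fraction before sorting, in (0, 1].
#' @param fraction_after Active fraction after sorting, in [0, 1].
#' @return `fraction_after / fraction_before`.
#' @examples
#' fold_enrichment(0.09, 0.95)  # ~10.6-fold
#' @export
fold_enrichment <- function(fraction_before, fraction_after) {
  if (any(fraction_before <= 0) || any(fraction_before > 1))
    stop("fraction_before must be in (0, 1]")
  if (any(fraction_after < 0) || any(fraction_after > 1))
    stop("fraction_after must be in [0, 1]")
  fraction_after / fraction_before
}

#' Classify a clone as functional relative to wild type
#'
#' A clone is functional iff its activity strictly exceeds
#' `threshold_fraction` of the wild-type activity (default: more than 50%
#' of wild type).
#'
#' @param activity Measured activity (vectorized).
#' @param wt_activity Wild-type activity, > 0.
#' @param threshold_fraction Fraction of wild type required (default 0.5).
#' @return Logical vector.
#' @export
classify_functional <- function(activity, wt_activity,
                                threshold_fraction = 0.5) {
  if (wt_activity <= 0) stop("wt_activity must be > 0")
  activity > threshold_fraction * wt_activity
}
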