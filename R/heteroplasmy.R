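#' Wilson score interval for a binomial proportion
#'
#' @param phat Observed proportion.
#' @param n Trial count.
#' @param conf Confidence level.
#' @return Numeric vector `c(low, high)`, clamped to `[0, 1]`.
#' @export
wilson_interval <- function(phat, n, conf = 0.95) {
  stopifnot(n >= 1, phat >= 0, phat <= 1)
  z <- qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Heteroplasmy estimate against the local-depth benchmark
#'
#' The deletion heteroplasmy of a sample is the number of junction-supporting
#' reads relative to the local mean depth at the windows flanking the repeat
#' pair: `h = min(1, n_support / (local_depth * junction_fraction))`.
#'
#' `junction_fraction` rescales the per-base depth to the depth of read
#' *placements* that can express a junction-supporting read. A read of length
#' r supports the junction only from `r - c + 1` of its r overlapping start
#' positions (c = required informative span around the breakpoint), whereas
#' every one of the r positions contributes flank depth; without the
#' correction the estimate is biased low by exactly that ratio. The pipeline
#' supplies the empirical fraction `mean((r - c + 1)+) / mean(r)` over the
#' sample's aligned reads; the default 1 reproduces the uncorrected ratio.
#'
#' The 95% interval is a Wilson score interval for `n_support` successes in
#' `round(local_depth * junction_fraction)` trials. When `poisson_numerator`
#' is `TRUE` (the pipeline's setting) the trial count is deflated so that
#' the implied binomial variance matches the delta-method variance of the
#' ratio with a Poisson-distributed numerator plus the relative variance
#' `depth_cv^2` of the estimated denominator — junction read counts are
#' Poisson rather than binomial (the "trials" are read placements, not a
#' fixed panel), and the denominator is itself estimated. Ignoring their
#' positive covariance makes the widening mildly conservative. The default
#' (`poisson_numerator = FALSE`, `depth_cv = 0`) is the plain Wilson
#' interval on `round(local_depth)` trials.
#'
#' @param n_support Junction-supporting read count (>= 1; samples without
#'   support report h = 0 at the report layer by convention).
#' @param local_depth Positive mean flank depth ([local_depth()]).
#' @param junction_fraction Fraction of read placements that can express a
#'   junction read, in (0, 1].
#' @param depth_cv Relative standard error of `local_depth` (0 = ignore).
#' @param poisson_numerator Treat `n_support` as Poisson when sizing the
#'   interval (see Details).
#' @param conf Confidence level of the interval.
#' @param high_het_threshold Reporting filter threshold (default 0.15).
#' @param mode Library mode label carried into the result.
#' @return One-row data frame: `n_support`, `local_depth`, `h`, `ci_low`,
#'   `ci_high`, `passes_high_het`, `mode`.
#' @examples
#' estimate_heteroplasmy(740, 1000) # h = 0.74
#' estimate_heteroplasmy(5, 10)     # Wilson 95% CI ~ (0.237, 0.763)
#' @export
estimate_heteroplasmy <- function(n_support, local_depth,
                                  junction_fraction = 1, depth_cv = 0,
                                  conf = 0.95, high_het_threshold = 0.15,
                                  mode = "present-day",
                                  poisson_numerator = FALSE) {
  if (local_depth <= 0) stop("no coverage at the flanking windows")
  if (n_support < 1) stop("n_support must be at least 1")
  stopifnot(junction_fraction > 0, junction_fraction <= 1)
  trials <- max(1L, as.integer(round(local_depth * junction_fraction)))
  h <- min(1, n_support / (local_depth * junction_fraction))
  eff_trials <- trials
  if ((poisson_numerator || depth_cv > 0) && h > 0) {
    # match binomial h(1-h)/T* to Var = h^2 (1/n + cv^2)
    base <- if (poisson_numerator) (1 - h) * trials else trials
    eff_trials <- max(1, base / (1 + trials * h * depth_cv^2))
  }
  ci <- wilson_interval(h, eff_trials, conf)
  data.frame(n_support = as.integer(n_support), local_depth = local_depth,
             h = h, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
             passes_high_het = h >= high_het_threshold, mode = mode)
}

#' Keep only high-heteroplasmy calls
#'
#' Applies the stringent reporting filter: calls with heteroplasmy of at
#' least `threshold` (boundary inclusive — a 15% call is kept) survive,
#' in their original order.
#'
#' @param calls Data frame with a column `h`.
#' @param threshold Heteroplasmy fraction (default 0.15).
#' @return The filtered data frame.
#' @export
filter_high_heteroplasmy <- function(calls, threshold = 0.15) {
  stopifnot(is.data.frame(calls), "h" %in% names(calls))
  calls[calls$h >= threshold, , drop = FALSE]
}
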