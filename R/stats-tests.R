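#' Two-sided Mann-Whitney rank-sum test with exact small-sample enumeration
#'
#' Computes the Mann-Whitney U statistic on midranks. For combined sample
#' sizes of at most `exact_max` the two-sided p-value is exact: every
#' C(n1+n2, n1) relabelling is enumerated and p is the probability of a U at
#' least as far from its null mean as observed — ties are handled naturally
#' by the midranks, where [stats::wilcox.test()] declines to be exact.
#' Larger samples use the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_max Largest combined size enumerated exactly.
#' @return An object of class `htest` with `statistic` (U for `x`),
#'   `p.value`, and `method` noting whether p is exact.
#' @examples
#' rank_sum_test(1:3, 4:6) # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(x, y, exact_max = 12L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  vals <- c(x, y)
  if (length(unique(vals)) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(rs_result(n1 * n2 / 2, 1, exact = FALSE))
  }
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_max) {
    combos <- combn(n, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    return(rs_result(u_obs, p, exact = TRUE))
  }
  ties <- table(vals)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) {
    warning("degenerate rank variance; p = 1")
    return(rs_result(u_obs, 1, exact = FALSE))
  }
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sig2)
  rs_result(u_obs, min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}

rs_result <- function(u, p, exact) {
  structure(list(
    statistic = c(U = u), p.value = p,
    alternative = "two.sided",
    method = paste0("Mann-Whitney rank-sum test (",
                    if (exact) "exact enumeration" else "normal approximation",
                    ", two-sided)"),
    data.name = "x and y", exact = exact
  ), class = "htest")
}

#' Two-sided Wilcoxon signed-rank test with exact small-sample enumeration
#'
#' Tests paired differences against a symmetric-around-zero null. Zero
#' differences are dropped (Wilcoxon convention). Up to `exact_max` non-zero
#' differences all 2^n sign assignments are enumerated for an exact
#' two-sided p-value (midranks make this valid under ties); beyond that the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact_max Largest n enumerated exactly.
#' @return An object of class `htest` with `statistic` (W, the positive-rank
#'   sum), `p.value`, `method`.
#' @examples
#' signed_rank_test(c(2, 3, 5, 8, 9, 11)) # W = 21, exact p = 2/64
#' @export
signed_rank_test <- function(diffs, exact_max = 12L) {
  d <- diffs[diffs != 0]
  if (!length(d)) {
    warning("all differences are zero; p = 1")
    return(sr_result(0, 1, exact = FALSE))
  }
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    return(sr_result(w_obs, p, exact = TRUE))
  }
  ties <- table(abs(d))
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) {
    warning("degenerate rank variance; p = 1")
    return(sr_result(w_obs, 1, exact = FALSE))
  }
  z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sig2)
  sr_result(w_obs, min(1, 2 * pnorm(-abs(z))), exact = FALSE)
}

sr_result <- function(w, p, exact) {
  structure(list(
    statistic = c(W = w), p.value = p,
    alternative = "two.sided",
    method = paste0("Wilcoxon signed-rank test (",
                    if (exact) "exact enumeration" else "normal approximation",
                    ", two-sided)"),
    data.name = "diffs", exact = exact
  ), class = "htest")
}
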