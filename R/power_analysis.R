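#' Power of a two-sided, two-sample pooled-variance t-test
#'
#' Exact power from the noncentral t distribution for equal group sizes:
#' with `n` per group, degrees of freedom `2n - 2` and noncentrality
#' `(effect/sd) * sqrt(n/2)`, the rejection probability at two-sided level
#' `alpha` is evaluated directly (no normal approximation).
#'
#' @param effect Mean difference between groups, measurement units.
#' @param sd Common per-group standard deviation (> 0).
#' @param n_per_group Group size (>= 2).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in (0, 1). At `effect = 0` the value is exactly `alpha`
#'   (the size of the test).
#' @examples
#' achieved_power(effect = 1, sd = 1, n_per_group = 17)  # ~0.81
#' @export
achieved_power <- function(effect, sd = 1, n_per_group, alpha = 0.05) {
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0,1)", call. = FALSE)
  if (any(n_per_group < 2)) stop("`n_per_group` must be >= 2", call. = FALSE)
  d <- effect / sd
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
}

#' Sample size per group for a target power
#'
#' Smallest integer group size at which a two-sided, two-sample
#' pooled-variance t-test reaches the requested power, found by integer
#' search over the exact noncentral-t power of [achieved_power()] (always
#' rounded up, never interpolated).
#'
#' @param effect Mean difference to detect (> 0).
#' @param sd Common per-group standard deviation (> 0).
#' @param alpha Two-sided significance level; default 0.05.
#' @param power Target power in (0, 1); default 0.8.
#' @param n_max Search cap; exceeding it raises an error.
#' @return Integer group size (>= 2). Scale-invariant in `(effect, sd)`:
#'   only the standardized effect `effect/sd` matters.
#' @examples
#' required_n_per_group(effect = 1, sd = 1)    # 17
#' required_n_per_group(effect = 0.5, sd = 1)  # 64
#' @export
required_n_per_group <- function(effect, sd = 1, alpha = 0.05, power = 0.8,
                                 n_max = 1e6) {
  if (!is.numeric(effect) || effect <= 0)
    stop("`effect` must be positive", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0,1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("`power` must be in (0,1)", call. = FALSE)
  if (power <= alpha)
    stop("requested power must exceed alpha (any n rejects at rate >= alpha)",
         call. = FALSE)
  ## bracket by doubling, then bisect on the monotone power curve
  lo <- 2L; hi <- 2L
  while (achieved_power(effect, sd, hi, alpha) < power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max)
      stop("required n exceeds n_max = ", n_max, call. = FALSE)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (achieved_power(effect, sd, mid, alpha) >= power) hi <- mid else lo <- mid
  }
  if (achieved_power(effect, sd, lo, alpha) >= power) lo else hi
}
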