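#' Extract mixture calibration points from a simulated or measured dataset
#'
#' Converts a mixture-series dataset (wells plus a layout of known mixing
#' ratios) into the long-form point table used by
#' [fit_sensitivity_curve()]: one row per replicate with its mixing ratio,
#' expected log2 ratio, delta-Ct, and control flag.
#'
#' @param dataset A `"sim_dataset"` from [simulate_mixture_series()], or a
#'   list with `wells` and a `samples` layout holding `sample_id`,
#'   `mix_ratio`, `is_control`.
#' @return Data frame with columns `sample_id`, `mix_ratio`,
#'   `expected_log2_ratio`, `delta_ct`, `is_control`.
#' @export
as_mixture_points <- function(dataset) {
  wells <- dataset$wells
  layout <- dataset$samples
  rec <- compute_delta_ct(wells)
  m <- merge(rec, layout[c("sample_id", "mix_ratio", "is_control")],
             by = "sample_id", sort = FALSE)
  data.frame(sample_id = m$sample_id, mix_ratio = m$mix_ratio,
             expected_log2_ratio = log2(m$mix_ratio),
             delta_ct = m$delta_ct, is_control = m$is_control,
             stringsAsFactors = FALSE)
}

#' Fit the mixture-series sensitivity curve
#'
#' Ordinary least-squares fit of replicate delta-Ct on log2(mixing ratio)
#' over the gDNA mixture points. At perfect amplification efficiency the
#' slope is 1 (one cycle per two-fold allelic excess) and the intercept
#' estimates the dye bias. Each mixture point is additionally tested
#' against the heterozygous 1:1 control replicates with a two-tailed
#' pooled-variance t-test, and the smallest ratio the assay can resolve
#' from 1:1 at the observed noise level is computed with
#' [minimal_detectable_ratio()].
#'
#' @param points Data frame as returned by [as_mixture_points()]; at least
#'   3 distinct ratios including 1:1 (as a mixture point or the
#'   heterozygous control).
#' @param alpha,power Level and power forwarded to the minimal-detectable-
#'   ratio computation.
#' @return An object of class `"sensitivity_curve"`: `slope`, `intercept`
#'   (each with standard error), `r_squared`, `residual_sd`, `per_point`
#'   (ratio, mean delta-Ct, t, p vs control), `minimal_detectable_ratio`,
#'   `n_replicates`.
#' @examples
#' mix <- simulate_mixture_series(simulation_config(noise_sd = 0,
#'                                                  dye_bias = 0.4))
#' fit_sensitivity_curve(as_mixture_points(mix))
#' @export
fit_sensitivity_curve <- function(points, alpha = 0.05, power = 0.8) {
  needed <- c("mix_ratio", "delta_ct")
  if (!all(needed %in% names(points)))
    stop("`points` must have columns mix_ratio and delta_ct", call. = FALSE)
  if (is.null(points$is_control)) points$is_control <- FALSE
  mix <- points[!points$is_control, , drop = FALSE]
  if (length(unique(mix$mix_ratio)) < 3)
    stop("insufficient design: need >= 3 distinct mixing ratios",
         call. = FALSE)
  if (!any(points$mix_ratio == 1))
    stop("insufficient design: a 1:1 point (mixture or heterozygous ",
         "control) is required", call. = FALSE)

  fit <- stats::lm(delta_ct ~ I(log2(mix_ratio)), data = mix)
  ## noise-free calibration data fits exactly; silence the perfect-fit notice
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  r2 <- sm$r.squared
  if (is.nan(r2)) r2 <- 1  # zero residual AND zero total variance cannot occur
                           # with >= 3 distinct ratios; guard anyway
  resid_sd <- sm$sigma

  ## per-point comparison against the 1:1 control replicates
  ctrl <- points$delta_ct[points$is_control]
  if (length(ctrl) < 2) ctrl <- points$delta_ct[points$mix_ratio == 1]
  per_point <- do.call(rbind, lapply(split(mix, mix$mix_ratio), function(g) {
    tt <- if (length(ctrl) >= 2 && nrow(g) >= 2)
      pooled_t_test(g$delta_ct, ctrl)
    else list(t = NA_real_, p = NA_real_)
    data.frame(mix_ratio = g$mix_ratio[1],
               expected_log2_ratio = log2(g$mix_ratio[1]),
               n = nrow(g), mean_delta_ct = mean(g$delta_ct),
               t_vs_control = tt$t, p_vs_control = tt$p,
               stringsAsFactors = FALSE)
  }))
  per_point <- per_point[order(per_point$mix_ratio, decreasing = TRUE), ]
  rownames(per_point) <- NULL

  n_rep <- as.integer(round(stats::median(table(mix$mix_ratio))))
  mdr <- minimal_detectable_ratio(noise_sd = resid_sd / sqrt(2),
                                  n_replicates = max(n_rep, 2L),
                                  alpha = alpha, power = power)

  structure(list(slope = unname(cf[2, 1]), slope_se = unname(cf[2, 2]),
                 intercept = unname(cf[1, 1]), intercept_se = unname(cf[1, 2]),
                 r_squared = r2, residual_sd = resid_sd,
                 per_point = per_point, minimal_detectable_ratio = mdr,
                 n_replicates = n_rep, fit = fit),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat("Mixture-series sensitivity curve (dCt ~ log2 ratio)\n")
  cat(sprintf("  slope     : %.4f (SE %.4f)   [1 = ideal efficiency]\n",
              x$slope, x$slope_se))
  cat(sprintf("  intercept : %.4f (SE %.4f)   [dye-bias estimate, cycles]\n",
              x$intercept, x$intercept_se))
  cat(sprintf("  R-squared : %.4f,  residual SD %.4f cycles\n",
              x$r_squared, x$residual_sd))
  cat(sprintf("  minimal detectable ratio (n = %d): %.3f : 1\n",
              x$n_replicates, x$minimal_detectable_ratio))
  invisible(x)
}

#' Smallest allelic ratio distinguishable from 1:1
#'
#' Operationalizes assay sensitivity: the smallest ratio `r >= 1` whose
#' delta-Ct shift `log2(r)` is detected with at least the requested power
#' by a two-sided, two-sample t-test of `n_replicates` measurements
#' against `n_replicates` 1:1 controls. Each delta-Ct carries noise SD
#' `sqrt(2) * noise_sd` (two independent channels). Power is evaluated
#' exactly from the noncentral t distribution on a log2-ratio grid of step
#' 0.01, not by a normal approximation.
#'
#' @param noise_sd Per-channel Ct noise SD, cycles (>= 0).
#' @param n_replicates Replicates per group (>= 2).
#' @param alpha Two-sided level in (0, 1).
#' @param power Target detection probability in (0, 1).
#' @param max_log2 Upper end of the search grid; exceeded means the assay
#'   cannot resolve any ratio up to `2^max_log2` and an error is raised.
#' @return The minimal detectable ratio (>= 1); exactly 1 when
#'   `noise_sd = 0`. Non-increasing in `n_replicates`.
#' @examples
#' minimal_detectable_ratio(noise_sd = 0.1, n_replicates = 3)
#' @export
minimal_detectable_ratio <- function(noise_sd, n_replicates, alpha = 0.05,
                                     power = 0.8, max_log2 = 10) {
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  if (n_replicates < 2) stop("`n_replicates` must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("`alpha` and `power` must lie in (0, 1)", call. = FALSE)
  if (noise_sd == 0) return(1)
  grid <- seq(0.01, max_log2, by = 0.01)
  pow <- achieved_power(effect = grid, sd = sqrt(2) * noise_sd,
                        n_per_group = n_replicates, alpha = alpha)
  hit <- which(pow >= power)
  if (length(hit) == 0)
    stop("no ratio up to 2^", max_log2, " reaches the requested power",
         call. = FALSE)
  2^grid[hit[1]]
}
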