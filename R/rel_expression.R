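#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct on log10(concentration) over a serial dilution.
#' The amplification efficiency follows from the slope as
#' `efficiency = 10^(-1/slope) - 1`; a perfect-doubling assay gives slope
#' `-1/log10(2) = -3.3219` and efficiency 1.
#'
#' @param points Data frame with columns `concentration` (ng/ul) and `ct`
#'   (cycles), e.g. from [simulate_dilution_series()]; an optional `gene`
#'   column labels the curve.
#' @return An object of class `"standard_curve"`: `gene`, `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `conc_range`, `ct_range`,
#'   `n_points`.
#' @examples
#' std <- simulate_dilution_series(simulation_config(noise_sd = 0))
#' fit_standard_curve(std)$efficiency  # 1
#' @export
fit_standard_curve <- function(points) {
  if (!all(c("concentration", "ct") %in% names(points)))
    stop("`points` must have columns concentration and ct", call. = FALSE)
  ok <- is.finite(points$ct) & is.finite(points$concentration) &
    points$concentration > 0
  points <- points[ok, , drop = FALSE]
  if (nrow(points) < 3)
    stop("a standard curve needs >= 3 valid points", call. = FALSE)
  if (length(unique(points$concentration)) < 3)
    stop("a standard curve needs >= 3 distinct concentrations", call. = FALSE)

  fit <- stats::lm(ct ~ log10(concentration), data = points)
  sm <- suppressWarnings(summary(fit))  # noise-free series fit exactly
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("fitted slope is nonnegative: Ct must fall with concentration; ",
         "the dilution series failed", call. = FALSE)
  structure(list(
    gene = if (!is.null(points$gene)) points$gene[1] else NA_character_,
    slope = slope, intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    efficiency = 10^(-1 / slope) - 1,
    conc_range = range(points$concentration),
    ct_range = range(points$ct),
    n_points = nrow(points)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve%s: Ct = %.4f %+.4f * log10(conc)\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              x$intercept, x$slope))
  cat(sprintf("  efficiency %.3f, R-squared %.4f, %d points (%.3g-%.3g ng/ul)\n",
              x$efficiency, x$r_squared, x$n_points,
              x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' Interpolate a quantity from a standard curve
#'
#' Inverts the curve: `quantity = 10^((ct - intercept) / slope)`, in the
#' concentration units of the dilution series. Monotone decreasing in Ct.
#' Cts outside the Ct range spanned by the curve are still converted but
#' flagged with a warning, since extrapolated quantities are unreliable.
#'
#' @param ct Numeric Ct value(s), cycles.
#' @param curve A [fit_standard_curve()] object.
#' @return Numeric quantity value(s).
#' @export
quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  outside <- is.finite(ct) & (ct < curve$ct_range[1] | ct > curve$ct_range[2])
  if (any(outside))
    warning(sum(outside), " Ct value(s) outside the standard-curve range; ",
            "quantities are extrapolated", call. = FALSE)
  10^((ct - curve$intercept) / curve$slope)
}

#' Pick the most stable reference gene
#'
#' A reference (housekeeping) gene should vary as little as possible across
#' samples; the candidate with the lowest Ct variance is selected.
#'
#' @param ct_table Data frame with columns `gene`, `sample_id`, `ct`.
#' @param candidates Character vector of candidate reference genes.
#' @return The selected gene symbol, with the per-candidate Ct SDs attached
#'   as attribute `"ct_sd"`.
#' @export
select_reference_gene <- function(ct_table, candidates) {
  sub <- ct_table[ct_table$gene %in% candidates, , drop = FALSE]
  if (nrow(sub) == 0) stop("no Ct data for any candidate reference gene",
                           call. = FALSE)
  sds <- tapply(sub$ct, factor(sub$gene, levels = candidates), stats::sd)
  sds <- sds[!is.na(sds)]
  if (length(sds) == 0) stop("reference candidates need >= 2 Cts each",
                             call. = FALSE)
  best <- names(sds)[which.min(sds)]
  attr(best, "ct_sd") <- sds
  best
}

#' Standard-curve relative expression, normalized to a reference gene
#'
#' For each sample, replicate Cts of the target and the reference gene are
#' averaged on the Ct scale (the usual treatment of duplicate wells; set
#' `average = "quantity"` to average interpolated quantities instead), both
#' are interpolated on their standard curves, and the target quantity is
#' divided by the reference quantity. The resulting normalized expression
#' is invariant to any common rescaling of the two quantities.
#'
#' @param ct_table Data frame with columns `sample_id`, `gene`, `ct` and
#'   (for the target rows) `genotype_group` (`risk_hom` /
#'   `protective_hom`).
#' @param target,reference Gene symbols.
#' @param target_curve,reference_curve [fit_standard_curve()] objects.
#' @param average `"ct"` (default) or `"quantity"`.
#' @return Data frame with one row per sample: `sample_id`,
#'   `genotype_group`, `target_quantity`, `reference_quantity`,
#'   `normalized_expression`.
#' @export
relative_expression <- function(ct_table, target, reference,
                                target_curve, reference_curve,
                                average = c("ct", "quantity")) {
  average <- match.arg(average)
  per_sample <- function(gene, curve) {
    sub <- ct_table[ct_table$gene == gene & is.finite(ct_table$ct), ,
                    drop = FALSE]
    if (nrow(sub) == 0) stop("no Ct data for gene ", gene, call. = FALSE)
    if (average == "ct") {
      cts <- tapply(sub$ct, sub$sample_id, mean)
      q <- quantify(as.numeric(cts), curve)
      stats::setNames(q, names(cts))
    } else {
      q <- tapply(quantify(sub$ct, curve), sub$sample_id, mean)
      stats::setNames(as.numeric(q), names(q))
    }
  }
  qt <- per_sample(target, target_curve)
  qr <- per_sample(reference, reference_curve)
  common <- intersect(names(qt), names(qr))
  if (length(common) == 0)
    stop("no samples measured for both target and reference", call. = FALSE)

  grp <- ct_table[ct_table$gene == target,
                  c("sample_id", "genotype_group"), drop = FALSE]
  grp <- grp[!duplicated(grp$sample_id), ]
  out <- data.frame(sample_id = common,
                    target_quantity = qt[common],
                    reference_quantity = qr[common],
                    normalized_expression = qt[common] / qr[common],
                    stringsAsFactors = FALSE)
  out <- merge(out, grp, by = "sample_id", all.x = TRUE, sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Compare expression between genotype groups
#'
#' Two-sided Mann-Whitney U test (Wilcoxon rank-sum) of normalized
#' expression in risk-allele homozygotes versus protective-allele
#' homozygotes. The exact null distribution is used for combined group
#' sizes up to 25 without ties; otherwise the normal approximation with
#' continuity and tie correction. Being rank-based, the p-value is
#' invariant under any strictly monotone transform of the measurements.
#'
#' @param records Data frame from [relative_expression()] (or any frame
#'   with `genotype_group` and a value column).
#' @param value Name of the value column; default
#'   `"normalized_expression"`.
#' @param groups Length-2 character vector naming the two genotype groups,
#'   first = risk homozygotes.
#' @param alpha Significance level.
#' @return One-row data frame: group sizes, medians, `U` (number of
#'   (risk, protective) pairs won by the risk group), `p_value`,
#'   `significant`, `direction` of the median difference.
#' @examples
#' rec <- data.frame(genotype_group = rep(c("risk_hom", "protective_hom"),
#'                                        each = 3),
#'                   normalized_expression = c(10, 11, 12, 1, 2, 3))
#' compare_genotype_groups(rec)
#' @export
compare_genotype_groups <- function(records, value = "normalized_expression",
                                    groups = c("risk_hom", "protective_hom"),
                                    alpha = 0.05) {
  x <- records[[value]][records$genotype_group == groups[1]]
  y <- records[[value]][records$genotype_group == groups[2]]
  if (length(x) == 0 || length(y) == 0)
    stop("both genotype groups must be nonempty", call. = FALSE)
  exact <- (length(x) + length(y)) <= 25 &&
    !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  med_x <- stats::median(x); med_y <- stats::median(y)
  data.frame(
    n_risk = length(x), n_protective = length(y),
    median_risk = med_x, median_protective = med_y,
    U = unname(wt$statistic), p_value = wt$p.value,
    significant = wt$p.value < alpha,
    direction = if (med_x > med_y) "risk_higher"
                else if (med_x < med_y) "risk_lower" else "none",
    stringsAsFactors = FALSE)
}

#' Delta-delta-Ct relative expression (alternative mode)
#'
#' The standard-curve route is the primary quantification; this companion
#' implements the classical ddCt shortcut (assumes equal, perfect
#' efficiencies): expression relative to a calibrator sample is
#' `2^-(dCt_sample - dCt_calibrator)` with `dCt = Ct_target - Ct_reference`.
#'
#' @param ct_target,ct_reference Per-sample mean Cts (equal-length numeric,
#'   same sample order).
#' @param calibrator Index of the calibrator sample; default 1.
#' @param base Amplification base; default 2.
#' @return Numeric fold-change vector (calibrator = 1).
#' @export
ddct_expression <- function(ct_target, ct_reference, calibrator = 1L,
                            base = 2) {
  if (length(ct_target) != length(ct_reference))
    stop("target and reference Ct vectors must align", call. = FALSE)
  dct <- ct_target - ct_reference
  base^-(dct - dct[calibrator])
}
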