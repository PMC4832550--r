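#' Compute per-well delta-Ct values
#'
#' The relative allelic signal of one well is
#' `delta-Ct = Ct(allele 2, FAM) - Ct(allele 1, VIC)`: positive values mean
#' less allele-2 template (later FAM threshold), i.e. relatively more
#' allele 1. Wells with an undetermined Ct in either channel are skipped
#' and counted, never imputed.
#'
#' @param wells Well-measurement data frame.
#' @return A data frame with columns `sample_id`, `snp_id`, `material`,
#'   `replicate`, `delta_ct`; the number of skipped wells is attached as
#'   attribute `"n_skipped"`.
#' @examples
#' w <- data.frame(sample_id = "S1", snp_id = "rs1", material = "cDNA",
#'                 replicate = 1, ct_vic = 24, ct_fam = 25)
#' compute_delta_ct(w)$delta_ct  # 1
#' @export
compute_delta_ct <- function(wells) {
  und <- is.na(wells$ct_vic) | is.na(wells$ct_fam)
  out <- wells[!und, c("sample_id", "snp_id", "material", "replicate"),
               drop = FALSE]
  out$delta_ct <- wells$ct_fam[!und] - wells$ct_vic[!und]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(und)
  out
}

#' Calibrate the gDNA reference for one SNP
#'
#' Heterozygous genomic DNA carries the two alleles exactly 1:1, so any
#' systematic delta-Ct in gDNA reflects fluorophore chemistry, not
#' expression. The mean delta-Ct over all retained gDNA replicates of all
#' heterozygous donors is the technical reference subtracted from every
#' cDNA measurement.
#'
#' @param records Delta-Ct records (from [compute_delta_ct()]); only rows
#'   with `material == "gDNA"` and matching `snp_id` contribute.
#' @param snp_id SNP to calibrate.
#' @return An object of class `"reference_calibration"`: `snp_id`,
#'   `gdna_mean_delta_ct`, `gdna_sd`, `n_gdna_values`, `samples`.
#' @export
calibrate_reference <- function(records, snp_id) {
  g <- records[records$material == "gDNA" & records$snp_id == snp_id, ,
               drop = FALSE]
  if (nrow(g) < 2)
    stop("insufficient gDNA reference: need >= 2 retained gDNA values for ",
         snp_id, call. = FALSE)
  structure(list(snp_id = snp_id,
                 gdna_mean_delta_ct = mean(g$delta_ct),
                 gdna_sd = stats::sd(g$delta_ct),
                 n_gdna_values = nrow(g),
                 samples = unique(g$sample_id)),
            class = "reference_calibration")
}

#' @export
print.reference_calibration <- function(x, ...) {
  cat(sprintf("gDNA reference for %s: mean dCt %.4f (SD %.4f, n = %d, %d donors)\n",
              x$snp_id, x$gdna_mean_delta_ct, x$gdna_sd, x$n_gdna_values,
              length(x$samples)))
  invisible(x)
}

#' Normalize delta-Ct values against the gDNA reference
#'
#' `nDCt = dCt_cDNA - mean(dCt_gDNA)`. Because the gDNA reference captures
#' the dye offset at equal allele presence, the normalized value is a pure
#' allelic-expression signal: at perfect efficiency, `nDCt` is the log2 of
#' the allele-1:allele-2 expression ratio. By construction the normalized
#' gDNA values of a SNP average exactly zero.
#'
#' @param delta_ct Numeric delta-Ct value(s), cycles.
#' @param reference A [calibrate_reference()] object.
#' @param snp_id Optional; when given, must match the reference (guards
#'   against mixing assays).
#' @return Numeric normalized delta-Ct value(s).
#' @export
normalize_delta_ct <- function(delta_ct, reference, snp_id = NULL) {
  stopifnot(inherits(reference, "reference_calibration"))
  if (!is.null(snp_id) && !all(snp_id == reference$snp_id))
    stop("SNP mismatch: reference is for ", reference$snp_id, call. = FALSE)
  delta_ct - reference$gdna_mean_delta_ct
}

## Classical pooled-variance two-sample t-test with an explicit contract for
## zero-variance inputs: equal means -> t = 0, p = 1, not significant;
## unequal means with zero pooled variance -> "degenerate, significant by
## contract" (p = 0, t = NA) instead of an infinite statistic.
pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    stop("pooled t-test needs >= 2 values per group", call. = FALSE)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (isTRUE(all.equal(delta, 0)) || delta == 0)
      return(list(t = 0, df = df, p = 1, mean_diff = delta, degenerate = TRUE))
    return(list(t = NA_real_, df = df, p = 0, mean_diff = delta,
                degenerate = TRUE))
  }
  tstat <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       mean_diff = delta, degenerate = FALSE)
}

#' Test one heterozygous sample for allelic imbalance
#'
#' Two-tailed, unpaired Student's t-test (pooled variance) of the sample's
#' normalized cDNA delta-Ct replicates against the grouped normalized gDNA
#' reference values. A significant shift away from the gDNA 1:1 baseline is
#' called allelic imbalance; its direction is reported in risk-allele
#' orientation (see Details).
#'
#' @details Sign convention: a positive nDCt means relatively higher
#' allele-1 (VIC) expression. With the risk allele on the allele-2/FAM
#' channel (the default orientation), nDCt above zero therefore means
#' *lower* expression of the risk allele; with `risk_allele = "allele1"`
#' the reading flips. `direction` is `"none"` whenever the test is not
#' significant at `alpha`.
#'
#' @param cdna_ndct Numeric; the sample's normalized cDNA replicates (>= 2).
#' @param gdna_ndct Numeric; all normalized gDNA reference values (>= 2).
#' @param alpha Two-sided significance level; default 0.05.
#' @param sample_id,snp_id Identifiers copied into the result.
#' @param risk_allele `"allele1"` or `"allele2"`; which allele is the
#'   disease-associated one.
#' @param base Ratio base; 2 at perfect amplification efficiency.
#' @return One-row data frame: `sample_id`, `snp_id`, `n_replicates_used`,
#'   `mean_ndct`, `sem`, `t_statistic`, `p_value`, `significant`,
#'   `degenerate`, `risk_ratio` (`base^|mean_ndct|`, >= 1), `direction`
#'   (`risk_higher` / `risk_lower` / `none`).
#' @export
per_sample_test <- function(cdna_ndct, gdna_ndct, alpha = 0.05,
                            sample_id = NA_character_, snp_id = NA_character_,
                            risk_allele = "allele2", base = 2) {
  if (length(cdna_ndct) < 2)
    stop("insufficient cDNA replicates after filtering (need >= 2)",
         call. = FALSE)
  tt <- pooled_t_test(cdna_ndct, gdna_ndct)
  m <- mean(cdna_ndct)
  signif_ <- tt$p < alpha
  data.frame(
    sample_id = sample_id, snp_id = snp_id,
    n_replicates_used = length(cdna_ndct),
    mean_ndct = m,
    sem = stats::sd(cdna_ndct) / sqrt(length(cdna_ndct)),
    t_statistic = tt$t, p_value = tt$p,
    significant = signif_, degenerate = tt$degenerate,
    risk_ratio = base^abs(m),
    direction = allelic_direction(m, significant = signif_,
                                  risk_allele = risk_allele),
    stringsAsFactors = FALSE)
}

#' Direction of allelic imbalance in risk-allele orientation
#'
#' @param ndct Normalized delta-Ct value(s).
#' @param significant Logical; non-significant calls get direction
#'   `"none"`. Default `TRUE` (pure sign reading).
#' @param risk_allele `"allele1"` or `"allele2"` (default); the channel
#'   carrying the disease-associated allele.
#' @return Character vector in `{"risk_higher", "risk_lower", "none"}`.
#' @export
allelic_direction <- function(ndct, significant = TRUE,
                              risk_allele = "allele2") {
  risk_allele <- match.arg(risk_allele, c("allele1", "allele2"))
  ## positive ndct = allele 1 higher
  dir_ <- ifelse(ndct > 0, "allele1_higher",
                 ifelse(ndct < 0, "allele2_higher", "none"))
  out <- ifelse(dir_ == "none", "none",
                ifelse((dir_ == "allele1_higher") == (risk_allele == "allele1"),
                       "risk_higher", "risk_lower"))
  out[!rep_len(significant, length(out))] <- "none"
  out
}

#' Pooled allelic-imbalance test across the cohort
#'
#' Global test of all cDNA measurements against all gDNA measurements for
#' one SNP, by two-tailed pooled-variance Student's t-test. The default
#' aggregation collapses replicates to per-sample means first, so each
#' donor contributes one value and replicate pseudoreplication does not
#' inflate the test; `level = "per_replicate"` pools the raw replicate
#' values instead.
#'
#' @param cdna_records,gdna_records Data frames with columns `sample_id`
#'   and `ndct` (normalized delta-Ct).
#' @param level `"per_sample_mean"` (default) or `"per_replicate"`.
#' @param alpha Significance level.
#' @return One-row data frame with `n_cdna`, `n_gdna` (at the chosen
#'   level), `n_cdna_replicates`, `n_gdna_replicates`, `mean_difference`,
#'   `t_statistic`, `p_value`, `significant`, `level`.
#' @export
pooled_test <- function(cdna_records, gdna_records,
                        level = c("per_sample_mean", "per_replicate"),
                        alpha = 0.05) {
  level <- match.arg(level)
  if (nrow(cdna_records) == 0 || nrow(gdna_records) == 0)
    stop("empty pool: both cDNA and gDNA values are required", call. = FALSE)
  pick <- function(df) {
    if (level == "per_sample_mean")
      as.numeric(tapply(df$ndct, df$sample_id, mean))
    else df$ndct
  }
  x <- pick(cdna_records); y <- pick(gdna_records)
  tt <- pooled_t_test(x, y)
  data.frame(n_cdna = length(x), n_gdna = length(y),
             n_cdna_replicates = nrow(cdna_records),
             n_gdna_replicates = nrow(gdna_records),
             mean_difference = tt$mean_diff,
             t_statistic = tt$t, p_value = tt$p,
             significant = tt$p < alpha, level = level,
             stringsAsFactors = FALSE)
}

#' Convert a normalized delta-Ct to an allelic expression ratio
#'
#' One normalized delta-Ct cycle corresponds to one `base`-fold difference
#' between the alleles, so the fold ratio of the higher-expressed over the
#' lower-expressed allele is `base^|ndct|`. The default base 2 assumes
#' perfect per-cycle doubling; pass `1 + efficiency` for an
#' efficiency-corrected conversion.
#'
#' @param ndct Normalized delta-Ct value(s), cycles.
#' @param base Ratio base, > 1. Default 2.
#' @return Numeric ratio(s), always >= 1. Antisymmetric in `ndct`:
#'   `ratio_from_ndct(-x) == ratio_from_ndct(x)` (the direction flips, see
#'   [allelic_direction()]).
#' @examples
#' ratio_from_ndct(1.17)   # ~2.25
#' ratio_from_ndct(0.202)  # ~1.15
#' @export
ratio_from_ndct <- function(ndct, base = 2) {
  if (!is.numeric(base) || length(base) != 1 || base <= 1)
    stop("`base` must be a single number > 1", call. = FALSE)
  base^abs(ndct)
}

#' Summarize allelic-imbalance directions across a cohort
#'
#' @param results Data frame of per-sample results (rows from
#'   [per_sample_test()]).
#' @return A data frame with one row per direction (`risk_higher`,
#'   `risk_lower`, `none`): counts and fractions (summing to 1).
#' @export
classify_cohort <- function(results) {
  if (nrow(results) == 0) stop("no per-sample results to classify",
                               call. = FALSE)
  lev <- c("risk_higher", "risk_lower", "none")
  counts <- table(factor(results$direction, levels = lev))
  data.frame(direction = lev, n = as.integer(counts),
             fraction = as.numeric(counts) / nrow(results),
             stringsAsFactors = FALSE)
}

#' Full allelic-imbalance analysis for one SNP
#'
#' End-to-end ASE workflow on a plate dataset: drop undetermined wells,
#' apply the two-pass box-plot replicate filter, compute delta-Ct, calibrate
#' the gDNA reference, normalize, run the per-sample t-tests and the pooled
#' cohort test, and classify directions. Samples left with fewer than two
#' usable cDNA replicates are skipped and listed in `skipped`.
#'
#' @param wells Well-measurement data frame (all materials, one or more
#'   SNPs).
#' @param snp_id SNP to analyse.
#' @param risk_allele `"allele1"` or `"allele2"` (default); ignored when
#'   `annotation` is given.
#' @param annotation Optional SNP annotation data frame (see
#'   [read_snp_annotation()]) used to resolve the risk allele.
#' @param alpha Two-sided significance level.
#' @param k_extreme,k_outlier Outlier-fence multipliers.
#' @param level Pooled-test aggregation, see [pooled_test()].
#' @param base Ratio base for nDCt-to-ratio conversion.
#' @return An object of class `"ase_analysis"`: `results` (per-sample
#'   table), `group` (pooled test), `reference`, `summary` (direction
#'   fractions), `mean_ndct_all`, `mean_ndct_significant`,
#'   `outlier_reports`, `skipped`, `counts`.
#' @examples
#' ds <- simulate_het_cohort(simulation_config(true_ratio = 2.25, seed = 3), 8)
#' fit <- ase_analysis(ds$wells, "rs0001")
#' fit$summary
#' @export
ase_analysis <- function(wells, snp_id, risk_allele = "allele2",
                         annotation = NULL, alpha = 0.05,
                         k_extreme = 3, k_outlier = 1.5,
                         level = c("per_sample_mean", "per_replicate"),
                         base = 2) {
  level <- match.arg(level)
  if (!is.null(annotation)) {
    row <- annotation[annotation$snp_id == snp_id, , drop = FALSE]
    if (nrow(row) != 1)
      stop("SNP ", snp_id, " not found (once) in the annotation",
           call. = FALSE)
    risk_allele <- row$risk_allele
  }
  wells <- wells[wells$snp_id == snp_id, , drop = FALSE]
  if (nrow(wells) == 0)
    stop("no wells for SNP ", snp_id, call. = FALSE)

  filt <- apply_outlier_filter(wells, k_extreme, k_outlier)
  records <- compute_delta_ct(filt$wells)
  ref <- calibrate_reference(records, snp_id)
  records$ndct <- normalize_delta_ct(records$delta_ct, ref)

  cdna <- records[records$material == "cDNA", , drop = FALSE]
  gdna <- records[records$material == "gDNA", , drop = FALSE]

  res_rows <- list(); skipped <- character(0)
  for (sid in unique(cdna$sample_id)) {
    x <- cdna$ndct[cdna$sample_id == sid]
    if (length(x) < 2) {
      skipped <- c(skipped, sid)
      next
    }
    res_rows[[sid]] <- per_sample_test(x, gdna$ndct, alpha = alpha,
                                       sample_id = sid, snp_id = snp_id,
                                       risk_allele = risk_allele, base = base)
  }
  if (length(res_rows) == 0)
    stop("no sample had >= 2 usable cDNA replicates", call. = FALSE)
  results <- do.call(rbind, res_rows)
  rownames(results) <- NULL

  sig <- results$mean_ndct[results$significant]
  structure(list(
    snp_id = snp_id, risk_allele = risk_allele,
    results = results,
    group = pooled_test(cdna, gdna, level = level, alpha = alpha),
    reference = ref,
    summary = classify_cohort(results),
    mean_ndct_all = mean(results$mean_ndct),
    mean_ndct_significant = if (length(sig)) mean(sig) else NA_real_,
    outlier_reports = filt$reports,
    skipped = skipped,
    counts = list(n_samples_tested = nrow(results),
                  n_skipped = length(skipped),
                  n_undetermined = filt$n_undetermined,
                  n_excluded = sum(filt$reports$status != "retained"))),
    class = "ase_analysis")
}

#' @export
print.ase_analysis <- function(x, ...) {
  cat(sprintf("Allelic-imbalance analysis for %s (risk allele: %s)\n",
              x$snp_id, x$risk_allele))
  cat(sprintf("  samples tested: %d (skipped %d); replicates excluded: %d\n",
              x$counts$n_samples_tested, x$counts$n_skipped,
              x$counts$n_excluded))
  cat(sprintf("  gDNA reference mean dCt: %.4f (n = %d)\n",
              x$reference$gdna_mean_delta_ct, x$reference$n_gdna_values))
  cat(sprintf("  cohort mean nDCt: %.4f (significant-only: %.4f)\n",
              x$mean_ndct_all, x$mean_ndct_significant))
  cat("  direction summary:\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("    %-12s %3d  (%.0f%%)\n", x$summary$direction[i],
                x$summary$n[i], 100 * x$summary$fraction[i]))
  cat(sprintf("  pooled test (%s): t = %.3f, p = %.3g\n",
              x$group$level, x$group$t_statistic, x$group$p_value))
  invisible(x)
}
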