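test_that("delta-Ct is FAM minus VIC, skipping undetermined wells", {
  w <- data.frame(sample_id = "S1", snp_id = "rs1", material = "cDNA",
                  replicate = 1:4,
                  ct_vic = c(24.0, 24.0, 25.7, NA),
                  ct_fam = c(25.0, 24.0, 23.5, 25.0))
  rec <- compute_delta_ct(w)
  expect_equal(rec$delta_ct, c(1.0, 0.0, -2.2))
  expect_equal(attr(rec, "n_skipped"), 1L)
})

test_that("gDNA reference calibration is the plain mean over retained values", {
  rec <- data.frame(sample_id = c("A", "B", "C"), snp_id = "rs1",
                    material = "gDNA", replicate = 1,
                    delta_ct = c(0.3, 0.5, 0.4))
  ref <- calibrate_reference(rec, "rs1")
  expect_equal(ref$gdna_mean_delta_ct, 0.4)
  expect_equal(ref$n_gdna_values, 3L)

  rec$delta_ct <- rep(0.7, 3)
  ref <- calibrate_reference(rec, "rs1")
  expect_equal(ref$gdna_mean_delta_ct, 0.7)
  expect_equal(ref$gdna_sd, 0)
  expect_error(calibrate_reference(rec[1, ], "rs1"), "insufficient")

  # recovers the dye bias on simulated gDNA (Monte-Carlo oracle)
  ds <- simulate_het_cohort(
    simulation_config(true_ratio = 2, dye_bias = 0.4, noise_sd = 0.1,
                      seed = 17), 30)
  rec <- compute_delta_ct(ds$wells)
  ref <- calibrate_reference(rec, "rs0001")
  se <- ref$gdna_sd / sqrt(ref$n_gdna_values)
  expect_lt(abs(ref$gdna_mean_delta_ct - 0.4), 3 * se)
})

test_that("normalization centers gDNA at exactly zero and is a plain shift", {
  rec <- data.frame(sample_id = "A", snp_id = "rs1", material = "gDNA",
                    replicate = 1:4, delta_ct = c(0.1, 0.5, 0.2, 0.4))
  ref <- calibrate_reference(rec, "rs1")
  expect_equal(normalize_delta_ct(1.5, ref), 1.5 - 0.3)
  expect_equal(normalize_delta_ct(ref$gdna_mean_delta_ct, ref), 0)
  expect_equal(mean(normalize_delta_ct(rec$delta_ct, ref)), 0)
  expect_error(normalize_delta_ct(1, ref, snp_id = "rs2"), "mismatch")
})

test_that("per-sample t-test agrees with the reference implementation", {
  set.seed(71)
  gdna <- rnorm(150, 0, 0.15)
  cdna <- c(1.15, 1.20, 1.18, 1.17, 1.16)
  res <- per_sample_test(cdna, gdna, sample_id = "S1", snp_id = "rs1")
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_value, oracle_t_p(cdna, gdna), tolerance = 1e-12)
  expect_equal(res$t_statistic,
               unname(t.test(cdna, gdna, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  expect_equal(res$direction, "risk_lower")  # positive nDCt, risk on FAM
  expect_equal(res$risk_ratio, 2^mean(cdna))
  expect_error(per_sample_test(1.1, gdna), "insufficient")
})

test_that("zero-variance degenerate inputs follow the stated contract", {
  # equal means, no variance anywhere: not significant, t = 0
  res <- per_sample_test(rep(0.5, 3), rep(0.5, 4))
  expect_false(res$significant)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  # unequal means on zero pooled variance: flagged, no infinite statistic
  res <- per_sample_test(rep(1, 3), rep(0, 4))
  expect_true(res$significant && res$degenerate)
  expect_true(is.na(res$t_statistic))
})

test_that("direction honours the risk-allele orientation", {
  # positive nDCt = allele 1 (VIC) higher
  expect_equal(allelic_direction(0.8, risk_allele = "allele2"), "risk_lower")
  expect_equal(allelic_direction(0.8, risk_allele = "allele1"), "risk_higher")
  expect_equal(allelic_direction(-0.8, risk_allele = "allele2"), "risk_higher")
  expect_equal(allelic_direction(0.8, significant = FALSE), "none")
  expect_equal(allelic_direction(0), "none")
})

test_that("ratio conversion is antisymmetric with identity at zero", {
  expect_equal(ratio_from_ndct(0), 1)
  x <- c(0.1, 0.5, 1.17, 3)
  expect_equal(ratio_from_ndct(-x), ratio_from_ndct(x))
  expect_equal(ratio_from_ndct(1, base = 1.9), 1.9)
  expect_error(ratio_from_ndct(1, base = 1), "base")
})

test_that("pooled cohort test reports both aggregation levels coherently", {
  cdna <- data.frame(sample_id = rep(c("A", "B"), each = 3),
                     ndct = c(1.1, 1.2, 1.0, 0.9, 1.0, 1.1))
  gdna <- data.frame(sample_id = rep(c("A", "B"), each = 3),
                     ndct = c(-0.1, 0.1, 0.0, 0.05, -0.05, 0.0))
  g1 <- pooled_test(cdna, gdna)  # default per-sample means
  expect_equal(g1$n_cdna, 2)
  expect_equal(g1$n_cdna_replicates, 6)
  g2 <- pooled_test(cdna, gdna, level = "per_replicate")
  expect_equal(g2$n_cdna, 6)
  expect_equal(g2$p_value,
               oracle_t_p(cdna$ndct, gdna$ndct), tolerance = 1e-12)
  # identical pools: t = 0, p = 1
  same <- pooled_test(cdna, cdna, level = "per_replicate")
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(pooled_test(cdna[0, ], gdna), "empty")
})

test_that("a strong-imbalance cohort is globally significant", {
  ds <- simulate_het_cohort(
    simulation_config(true_ratio = 2.25, seed = 23), 30)
  fit <- ase_analysis(ds$wells, "rs0001")
  expect_lt(fit$group$p_value, 1e-6)
  # risk allele on FAM and allele 1 over-expressed => risk allele lower
  expect_equal(fit$summary$fraction[fit$summary$direction == "risk_lower"], 1)
})

test_that("cohort classification fractions sum to one and match counts", {
  res <- data.frame(direction = c("risk_higher", "risk_higher", "none",
                                  "risk_lower"))
  cls <- classify_cohort(res)
  expect_equal(sum(cls$fraction), 1)
  expect_equal(cls$fraction[match(c("risk_higher", "risk_lower", "none"),
                                  cls$direction)], c(0.5, 0.25, 0.25))
  expect_error(classify_cohort(res[0, , drop = FALSE]), "no per-sample")
})

test_that("simulation recovery: strong effects are classified per the truth", {
  for (r in c(3, 1 / 3)) {
    ds <- simulate_het_cohort(
      simulation_config(true_ratio = r, noise_sd = 0.1, seed = 37), 10)
    fit <- ase_analysis(ds$wells, "rs0001")
    want <- if (r > 1) "risk_lower" else "risk_higher"
    expect_true(all(fit$results$direction == want))
  }
})

test_that("per-sample rejection rate is non-decreasing in the true ratio", {
  rates <- vapply(c(1, 1.3, 2), function(r) {
    ds <- simulate_het_cohort(
      simulation_config(true_ratio = r, noise_sd = 0.15, seed = 53), 40)
    rec <- compute_delta_ct(ds$wells)
    ref <- calibrate_reference(rec, "rs0001")
    rec$ndct <- normalize_delta_ct(rec$delta_ct, ref)
    cdna <- rec[rec$material == "cDNA", ]
    g <- rec$ndct[rec$material == "gDNA"]
    mean(vapply(split(cdna$ndct, cdna$sample_id),
                function(x) per_sample_test(x, g)$p_value, numeric(1)) < 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})
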