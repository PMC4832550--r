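test_that("standard-curve fit reproduces the closed-form slope and efficiency", {
  std <- simulate_dilution_series(simulation_config(noise_sd = 0))
  cv <- fit_standard_curve(std)
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(cv$efficiency, 1, tolerance = 1e-10)
  expect_equal(cv$r_squared, 1, tolerance = 1e-10)

  # efficiency is invariant to a constant Ct offset
  shifted <- std
  shifted$ct <- shifted$ct + 2.5
  cv2 <- fit_standard_curve(shifted)
  expect_equal(cv2$efficiency, cv$efficiency, tolerance = 1e-10)
  expect_equal(cv2$intercept, cv$intercept + 2.5, tolerance = 1e-10)
})

test_that("a sub-unity efficiency is recovered from a noisy series", {
  std <- simulate_dilution_series(
    simulation_config(noise_sd = 0.05, efficiency = 0.9, seed = 43),
    n_replicates = 4)
  cv <- fit_standard_curve(std)
  # delta-method SE on efficiency from the slope SE
  sm <- summary(lm(ct ~ log10(concentration), data = std))
  se_slope <- sm$coefficients[2, 2]
  slope <- sm$coefficients[2, 1]
  se_eff <- abs(log(10) * 10^(-1 / slope) / slope^2) * se_slope
  expect_lt(abs(cv$efficiency - 0.9), 3 * se_eff)
})

test_that("degenerate dilution designs are rejected", {
  expect_error(fit_standard_curve(data.frame(concentration = c(10, 5),
                                             ct = c(20, 21))), ">= 3")
  up <- data.frame(concentration = c(10, 5, 2.5, 1.25), ct = c(20, 19, 18, 17))
  expect_error(fit_standard_curve(up), "slope")
})

test_that("quantification inverts the curve and flags extrapolation", {
  std <- simulate_dilution_series(simulation_config(noise_sd = 0))
  cv <- fit_standard_curve(std)
  # Ct at the top point returns the top concentration
  top_ct <- min(std$ct)
  expect_equal(quantify(top_ct, cv), 33.33, tolerance = 1e-9)
  # one |slope| more in Ct is one log10 less quantity
  expect_equal(quantify(top_ct + abs(cv$slope), cv), 3.333, tolerance = 1e-9)
  # round trip across every simulated point
  expect_equal(quantify(std$ct, cv), std$concentration, tolerance = 1e-9)
  expect_warning(quantify(max(std$ct) + 5, cv), "extrapolated")
})

test_that("normalized expression is invariant to common rescaling", {
  set.seed(19)
  ct_tab <- expand.grid(sample_id = sprintf("S%02d", 1:8),
                        gene = c("TARGET", "REF18S"), replicate = 1:2,
                        stringsAsFactors = FALSE)
  ct_tab$ct <- rnorm(nrow(ct_tab), 28, 1)
  ct_tab$genotype_group <- ifelse(ct_tab$sample_id %in% sprintf("S%02d", 1:4),
                                  "risk_hom", "protective_hom")
  curve <- fit_standard_curve(
    simulate_dilution_series(simulation_config(noise_sd = 0)))
  rec <- suppressWarnings(
    relative_expression(ct_tab, "TARGET", "REF18S", curve, curve))
  expect_true(all(rec$normalized_expression > 0))
  # shifting both genes' Cts equally rescales both quantities by one factor
  ct_tab2 <- ct_tab
  ct_tab2$ct <- ct_tab2$ct + 1
  rec2 <- suppressWarnings(
    relative_expression(ct_tab2, "TARGET", "REF18S", curve, curve))
  expect_equal(rec2$normalized_expression, rec$normalized_expression,
               tolerance = 1e-9)
})

test_that("reference-gene selection picks the lowest-variance candidate", {
  set.seed(29)
  tab <- data.frame(
    gene = rep(c("G_STABLE", "G_WOBBLY"), each = 10),
    sample_id = rep(sprintf("S%02d", 1:10), 2),
    ct = c(rnorm(10, 15, 0.1), rnorm(10, 24, 1.5)))
  best <- select_reference_gene(tab, c("G_STABLE", "G_WOBBLY"))
  expect_equal(as.character(best), "G_STABLE")
})

test_that("genotype comparison matches exact Mann-Whitney enumeration", {
  rec <- data.frame(genotype_group = rep(c("risk_hom", "protective_hom"),
                                         each = 3),
                    normalized_expression = c(10, 11, 12, 1, 2, 3))
  res <- compare_genotype_groups(rec)
  expect_equal(unname(res$U), 9)  # risk group wins every pair
  expect_equal(res$p_value, exact_mw_p(c(10, 11, 12), c(1, 2, 3)),
               tolerance = 1e-12)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$direction, "risk_higher")

  # identical groups: p = 1
  same <- data.frame(genotype_group = rep(c("risk_hom", "protective_hom"),
                                          each = 3),
                     normalized_expression = rep(c(1, 2, 3), 2))
  expect_equal(compare_genotype_groups(same)$p_value, 1)

  # a random untied fixture agrees with enumeration too
  set.seed(47)
  x <- round(rnorm(5), 4); y <- round(rnorm(6, 0.5), 4)
  rec <- data.frame(genotype_group = rep(c("risk_hom", "protective_hom"),
                                         c(5, 6)),
                    normalized_expression = c(x, y))
  expect_equal(compare_genotype_groups(rec)$p_value, exact_mw_p(x, y),
               tolerance = 1e-12)
  expect_error(compare_genotype_groups(rec[rec$genotype_group == "risk_hom", ]),
               "nonempty")
})

test_that("rank-based comparison is invariant under monotone transforms", {
  set.seed(59)
  rec <- data.frame(genotype_group = rep(c("risk_hom", "protective_hom"),
                                         c(12, 15)),
                    normalized_expression = rlnorm(27))
  p0 <- compare_genotype_groups(rec)$p_value
  for (f in list(log, sqrt, function(v) v^3)) {
    rec2 <- rec
    rec2$normalized_expression <- f(rec$normalized_expression)
    expect_equal(compare_genotype_groups(rec2)$p_value, p0, tolerance = 1e-12)
  }
})

test_that("a shifted risk group is detected with the right direction", {
  set.seed(67)
  hits <- replicate(40, {
    rec <- data.frame(
      genotype_group = rep(c("risk_hom", "protective_hom"), c(23, 36)),
      normalized_expression = c(rlnorm(23, log(1.15), 0.2), rlnorm(36, 0, 0.2)))
    r <- compare_genotype_groups(rec)
    c(sig = r$significant, up = r$direction == "risk_higher")
  })
  # power is reported, direction of the median shift is recovered
  expect_gt(mean(hits["sig", ]), 0.3)
  expect_gt(mean(hits["up", ]), 0.9)
})

test_that("ddCt mode reproduces hand-computed fold changes", {
  fc <- ddct_expression(ct_target = c(24, 23, 25), ct_reference = c(15, 15, 15))
  expect_equal(fc, c(1, 2, 0.5))
})
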