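#' Simulation configuration for dual-dye qPCR data
#'
#' Bundles the generative parameters used by [simulate_het_cohort()],
#' [simulate_mixture_series()] and [simulate_dilution_series()]. The
#' generative model places the more abundant allele at `base_ct` cycles and
#' separates the channels by `log_b(true_ratio)` cycles with `b = 1 +
#' efficiency`, adds the systematic FAM-minus-VIC dye offset `dye_bias` to
#' the FAM channel, and perturbs every channel independently with Gaussian
#' noise of standard deviation `noise_sd` cycles. A delta-Ct value therefore
#' has expectation `log_b(true_ratio) + dye_bias` and standard deviation
#' `sqrt(2) * noise_sd`.
#'
#' @param true_ratio Positive real; allele-1 template quantity divided by
#'   allele-2 quantity (4 means 4:1, 0.25 means 1:4).
#' @param dye_bias Real, cycles; systematic FAM-minus-VIC Ct offset at equal
#'   template. Defaults to 0.4 cycles, a typical fluorophore offset.
#' @param noise_sd Nonnegative real, cycles; per-channel replicate Gaussian
#'   SD. Default 0.15 cycles.
#' @param efficiency Per-cycle amplification efficiency in (0, 1]; 1 means
#'   perfect doubling, so one cycle corresponds to one log2 unit.
#' @param n_replicates Positive integer; replicate wells per sample and
#'   material. Default 5, the usual replication depth for per-donor ASE
#'   calls.
#' @param base_ct Real, cycles; mean Ct of the more abundant allele.
#' @param seed Integer seed for the pseudo-random stream. Identical
#'   configuration and seed give bit-identical datasets.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @examples
#' cfg <- simulation_config(true_ratio = 2.25, seed = 42)
#' cfg$true_ratio
#' @export
simulation_config <- function(true_ratio = 1, dye_bias = 0.4, noise_sd = 0.15,
                              efficiency = 1, n_replicates = 5,
                              base_ct = 25, seed = 1L) {
  if (!is.numeric(true_ratio) || length(true_ratio) != 1 || !is.finite(true_ratio) ||
      true_ratio <= 0)
    stop("`true_ratio` must be a single positive number", call. = FALSE)
  if (!is.numeric(dye_bias) || length(dye_bias) != 1 || !is.finite(dye_bias))
    stop("`dye_bias` must be a single finite number", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || !is.finite(noise_sd) ||
      noise_sd < 0)
    stop("`noise_sd` must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(efficiency) || length(efficiency) != 1 ||
      efficiency <= 0 || efficiency > 1)
    stop("`efficiency` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      n_replicates < 1 || n_replicates != round(n_replicates))
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  if (!is.numeric(base_ct) || length(base_ct) != 1 || !is.finite(base_ct))
    stop("`base_ct` must be a single finite number", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  structure(list(true_ratio = true_ratio, dye_bias = dye_bias,
                 noise_sd = noise_sd, efficiency = efficiency,
                 n_replicates = as.integer(n_replicates),
                 base_ct = base_ct, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("qPCR simulation configuration\n")
  cat(sprintf("  true allelic ratio : %.4g (log2 = %.3f)\n",
              x$true_ratio, log2(x$true_ratio)))
  cat(sprintf("  dye bias (FAM-VIC) : %.3f cycles\n", x$dye_bias))
  cat(sprintf("  noise SD / channel : %.3f cycles\n", x$noise_sd))
  cat(sprintf("  efficiency         : %.3f\n", x$efficiency))
  cat(sprintf("  replicates         : %d,  base Ct: %.1f,  seed: %d\n",
              x$n_replicates, x$base_ct, x$seed))
  invisible(x)
}

## Mean channel Cts for one well. The more abundant allele sits at base_ct;
## the FAM channel additionally carries the dye offset. ratio = allele1/allele2.
channel_means <- function(ratio, config) {
  b <- 1 + config$efficiency
  L <- log(ratio, base = b)
  ct_vic <- config$base_ct + max(0, -L)
  ct_fam <- ct_vic + L + config$dye_bias
  c(vic = ct_vic, fam = ct_fam)
}

well_coords <- function(n) {
  rows <- rep(LETTERS[1:16], each = 24)
  cols <- rep(1:24, times = 16)
  idx <- ((seq_len(n) - 1L) %% 384L) + 1L
  sprintf("%s%02d", rows[idx], cols[idx])
}

new_sim_dataset <- function(wells, samples, truth, per_sample_true_ndct = NULL) {
  structure(list(wells = wells, samples = samples, truth = truth,
                 per_sample_true_ndct = per_sample_true_ndct),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated qPCR dataset: %d wells, %d samples\n",
              nrow(x$wells), length(unique(x$wells$sample_id))))
  invisible(x)
}

#' Simulate a heterozygous ASE cohort
#'
#' Generates replicate cDNA and gDNA wells for `n_samples` heterozygous
#' donors at one SNP. cDNA wells are drawn with the configured true allelic
#' ratio; gDNA wells always use a 1:1 ratio because genomic DNA of a
#' heterozygote carries one copy of each allele, so their expected delta-Ct
#' equals the dye bias alone. The per-sample true normalized delta-Ct
#' (`log_b(true_ratio)`, `b = 1 + efficiency`) is recorded for
#' parameter-recovery tests.
#'
#' @param config A [simulation_config()].
#' @param n_samples Positive integer; number of heterozygous donors.
#' @param snp_id,plate_id Identifiers stamped on the generated wells.
#' @return An object of class `"sim_dataset"`: a list with `wells` (a
#'   data frame in the plate-table layout of [read_plate_table()]),
#'   `samples` (a long-format sample sheet, every donor heterozygous at
#'   `snp_id`), `truth` (the configuration) and `per_sample_true_ndct`.
#' @examples
#' ds <- simulate_het_cohort(simulation_config(true_ratio = 2, seed = 7), 4)
#' head(ds$wells)
#' @export
simulate_het_cohort <- function(config, n_samples, snp_id = "rs0001",
                                plate_id = "P1") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1 ||
      n_samples != round(n_samples))
    stop("`n_samples` must be a positive integer", call. = FALSE)
  n_samples <- as.integer(n_samples)
  nrep <- config$n_replicates
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  withr::with_seed(config$seed, {
    rows <- vector("list", 2L * n_samples)
    k <- 0L
    for (sid in sample_ids) {
      for (material in c("cDNA", "gDNA")) {
        ratio <- if (material == "cDNA") config$true_ratio else 1
        mu <- channel_means(ratio, config)
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample_id = sid, snp_id = snp_id, material = material,
          replicate = seq_len(nrep),
          ct_vic = mu[["vic"]] + stats::rnorm(nrep, 0, config$noise_sd),
          ct_fam = mu[["fam"]] + stats::rnorm(nrep, 0, config$noise_sd),
          stringsAsFactors = FALSE)
      }
    }
  })
  wells <- do.call(rbind, rows)
  wells$plate_id <- plate_id
  wells$well <- well_coords(nrow(wells))

  samples <- data.frame(sample_id = sample_ids, cohort = "case",
                        snp_id = snp_id, genotype = "het",
                        stringsAsFactors = FALSE)
  b <- 1 + config$efficiency
  new_sim_dataset(wells, samples, config,
                  per_sample_true_ndct =
                    stats::setNames(rep(log(config$true_ratio, base = b),
                                        n_samples), sample_ids))
}

#' Default gDNA mixing ratios for sensitivity calibration
#'
#' The nine allele-1:allele-2 mixing proportions conventionally used to
#' titrate an allelic-discrimination assay, spanning 4:1 down to 1:4.
#'
#' @return Numeric vector of length 9 (each ratio expressed as a1/a2).
#' @export
default_mixture_ratios <- function() {
  c(4, 2, 1.5, 1.25, 1, 1 / 1.25, 1 / 1.5, 1 / 2, 1 / 4)
}

#' Simulate a gDNA mixture series
#'
#' Mixes of homozygous gDNA at known allelic ratios, run in replicate, plus
#' a heterozygous gDNA sample included as the 1:1 control. The expected
#' delta-Ct of a mix at ratio r is `log_b(r) + dye_bias`.
#'
#' @param config A [simulation_config()]; its `true_ratio` is ignored (each
#'   mixture point sets its own ratio).
#' @param ratios Positive reals, allele1:allele2 expressed as a single
#'   number. Defaults to [default_mixture_ratios()].
#' @param n_replicates Wells per mixture point; default 3 (triplicates).
#' @param snp_id,plate_id Identifiers stamped on the wells.
#' @return A `"sim_dataset"` whose `samples` element is the mixture layout
#'   (`sample_id`, `mix_ratio`, `is_control`). Pass the dataset to
#'   [as_mixture_points()] and then [fit_sensitivity_curve()].
#' @examples
#' mix <- simulate_mixture_series(simulation_config(noise_sd = 0, dye_bias = 0))
#' pts <- as_mixture_points(mix)
#' @export
simulate_mixture_series <- function(config, ratios = default_mixture_ratios(),
                                    n_replicates = 3, snp_id = "rs0001",
                                    plate_id = "MIX") {
  stopifnot(inherits(config, "sim_config"))
  if (length(ratios) == 0)
    stop("`ratios` must be nonempty", call. = FALSE)
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("all mixing ratios must be positive and finite", call. = FALSE)
  nrep <- as.integer(n_replicates)
  if (nrep < 1) stop("`n_replicates` must be >= 1", call. = FALSE)

  ratio_label <- function(r) {
    if (r >= 1) sprintf("mix_%g_1", r) else sprintf("mix_1_%g", 1 / r)
  }
  layout <- data.frame(
    sample_id = c(vapply(ratios, ratio_label, character(1)), "het_control"),
    mix_ratio = c(ratios, 1),
    is_control = c(rep(FALSE, length(ratios)), TRUE),
    stringsAsFactors = FALSE)

  withr::with_seed(config$seed, {
    rows <- lapply(seq_len(nrow(layout)), function(i) {
      mu <- channel_means(layout$mix_ratio[i], config)
      data.frame(
        sample_id = layout$sample_id[i], snp_id = snp_id, material = "gDNA",
        replicate = seq_len(nrep),
        ct_vic = mu[["vic"]] + stats::rnorm(nrep, 0, config$noise_sd),
        ct_fam = mu[["fam"]] + stats::rnorm(nrep, 0, config$noise_sd),
        stringsAsFactors = FALSE)
    })
  })
  wells <- do.call(rbind, rows)
  wells$plate_id <- plate_id
  wells$well <- well_coords(nrow(wells))
  new_sim_dataset(wells, layout, config)
}

#' Simulate a serial dilution series for a standard curve
#'
#' Generates single-channel Ct measurements for an n-point geometric
#' dilution starting at `top_conc` and dividing by `fold` at each step.
#' Expected Ct rises by `log_b(fold)` cycles per step, `b = 1 + efficiency`,
#' so at perfect doubling a 1:2 series climbs exactly one cycle per point
#' and the fitted slope of Ct on log10(concentration) is
#' `-1/log10(2) = -3.3219`.
#'
#' @param config A [simulation_config()]; `true_ratio` and `dye_bias` are
#'   not used (this is a total-expression assay, one dye).
#' @param top_conc Highest concentration, ng/ul. Default 33.33.
#' @param n_points Number of dilution points (>= 2). Default 8, reaching
#'   about 0.26 ng/ul at 1:2 steps.
#' @param fold Dilution factor between successive points (> 1). Default 2.
#' @param gene Gene symbol stamped on the rows.
#' @param n_replicates Replicate wells per point; default 2 (duplicates).
#' @return A data frame with columns `gene`, `concentration`, `replicate`,
#'   `ct`, carrying the generating `config` as attribute `"truth"`.
#' @examples
#' std <- simulate_dilution_series(simulation_config(noise_sd = 0))
#' fit_standard_curve(std)
#' @export
simulate_dilution_series <- function(config, top_conc = 33.33, n_points = 8,
                                     fold = 2, gene = "GENE1",
                                     n_replicates = 2) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(top_conc) || top_conc <= 0)
    stop("`top_conc` must be positive", call. = FALSE)
  if (n_points < 2)
    stop("`n_points` must be >= 2: a curve cannot be fitted to one point",
         call. = FALSE)
  if (fold <= 1) stop("`fold` must be > 1", call. = FALSE)
  nrep <- as.integer(n_replicates)

  conc <- top_conc / fold^(seq_len(n_points) - 1)
  b <- 1 + config$efficiency
  ct_mean <- config$base_ct + log(top_conc / conc, base = b)

  withr::with_seed(config$seed, {
    out <- data.frame(
      gene = gene,
      concentration = rep(conc, each = nrep),
      replicate = rep(seq_len(nrep), times = n_points),
      ct = rep(ct_mean, each = nrep) +
        stats::rnorm(n_points * nrep, 0, config$noise_sd),
      stringsAsFactors = FALSE)
  })
  attr(out, "truth") <- config
  out
}
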