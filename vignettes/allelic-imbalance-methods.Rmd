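---
title: "Measuring allelic imbalance with allelic-discrimination qPCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring allelic imbalance with allelic-discrimination qPCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asebalance)
```

## The measurement model

An allelic-discrimination qPCR well interrogates one transcribed SNP with
two allele-specific probes carrying different fluorophores: VIC for
allele 1, FAM for allele 2. Each channel crosses its fluorescence
threshold at a cycle number Ct that falls by one cycle per `b`-fold
increase in starting template, where `b = 1 + E` and `E` is the per-cycle
amplification efficiency (`E = 1` is perfect doubling). The per-well
allelic signal is

$$\Delta Ct = Ct_{\text{allele 2, FAM}} - Ct_{\text{allele 1, VIC}},$$

so $\Delta Ct = \log_b(q_1/q_2) + \beta$ where $q_1/q_2$ is the
allele-1:allele-2 template ratio and $\beta$ is a systematic
FAM-minus-VIC offset caused by fluorophore chemistry, not biology.

Heterozygous genomic DNA carries the two alleles exactly 1:1, so its
expected $\Delta Ct$ is $\beta$ alone. Averaging the gDNA $\Delta Ct$ of
all heterozygous donors estimates $\beta$, and

$$n\Delta Ct = \Delta Ct_{\text{cDNA}} - \overline{\Delta Ct}_{\text{gDNA}}$$

is a dye-corrected allelic expression signal: at `E = 1` it is the log2
allelic expression ratio, and the fold ratio of the higher- over the
lower-expressed allele is $2^{|n\Delta Ct|}$ (`ratio_from_ndct()`; the
base is a parameter for efficiency-corrected use, but both of the
reference conversions this package reproduces — 1.17 cycles ↔ 2.25:1 and
0.202 cycles ↔ 1.15:1 — are consistent with base 2 to two decimals, which
is why 2 is the default).

**Orientation.** A positive $n\Delta Ct$ means relatively more allele-1
transcript. Results are reported in risk-allele orientation via the SNP
annotation: with the risk allele on the FAM/allele-2 channel (the default,
and the layout of the assays this design follows), $n\Delta Ct > 0$ means
*lower* expression of the risk allele. `allelic_direction()` flips the
reading for assays with the opposite dye layout.

## The generative model (`simdata`)

`simulation_config()` fixes the study conditions the package is tested
under:

| parameter | default | units | meaning |
|---|---|---|---|
| `true_ratio` | 1 | — | allele-1:allele-2 template ratio |
| `dye_bias` | 0.4 | cycles | FAM−VIC offset at equal template |
| `noise_sd` | 0.15 | cycles | per-channel replicate Gaussian SD |
| `efficiency` | 1 | — | per-cycle amplification efficiency |
| `n_replicates` | 5 | — | wells per donor and material |
| `base_ct` | 25 | cycles | Ct of the more abundant allele |

Five replicates per donor is the replication depth this workflow is built
around. Replicate-level Ct variance is rarely published; the 0.15-cycle
default and the 0.4-cycle dye bias are *assumptions* chosen as typical
instrument values, not calibrated to any dataset — with 5 replicates they
put single-donor tests in a realistic regime where moderate ratios
(≈1.35:1, see `minimal_detectable_ratio()`) sit at the detection edge.
Noise is Gaussian on the Ct scale, independently per channel, the standard
instrument model; $\Delta Ct$ noise is then Gaussian with variance
$2\sigma^2$. One pseudo-random stream is seeded per dataset, so identical
configuration and seed reproduce datasets bit for bit.

The generator emulates: the two-channel mean structure above, gDNA
heterozygote controls (always generated at ratio 1 regardless of
`true_ratio`), gDNA mixture series at ratios 4:1…1:4 with a heterozygous
1:1 control, and 1:2 serial dilutions (33.33 down to ≈0.26 ng/µl) for
standard curves. It deliberately does **not** emulate plate spatial
effects, probe cross-hybridization, pipetting (mixture-ratio) error,
inter-donor variation in the true ratio, amplification failure
("Undetermined" wells), or raw fluorescence curves. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated noise model, not robustness to every artefact of real plates — the
"Undetermined" pathway is exercised separately through the I/O layer.

## Replicate QC (`two_pass_boxplot_filter`)

Per donor, replicate $\Delta Ct$ values are screened in two passes:
extreme values outside the Tukey fences at `k_extreme = 3` IQRs are
removed, the box plot is rebuilt from the survivors, and outliers outside
`k_outlier = 1.5` IQRs of the rebuilt plot are removed. The 3/1.5
multipliers are the box-plot conventions of mainstream statistics
software; both are exposed as parameters. Numerical choices that needed
fixing:

- **Quartile rule.** Quartile conventions differ across programs;
  Tukey hinges (`stats::fivenum`) are used and frozen.
- **Fence boundary.** Values exactly on a fence are retained (strict
  inequality), so a zero-IQR replicate set — all values identical — loses
  nothing.
- **Filtering level.** The filter acts on $\Delta Ct$, the quantity
  analysed downstream, not on raw per-dye Cts. Whether box-plot exclusion
  in this workflow is classically done per dye or per $\Delta Ct$ is
  ambiguous in practice; per-$\Delta Ct$ is the choice here and is worth
  knowing when comparing exclusion counts.
- Fewer than 3 replicates: fences are undefined; the set passes through
  with a warning. A group whose values would all be excluded raises an
  error rather than silently proceeding.

On clean Gaussian replicates at $n = 5$ the filter removes well under
10 % of values (checked by Monte Carlo in the test suite).

## Allelic-imbalance tests (`ase_core`)

Each donor's normalized cDNA replicates are compared to the grouped
normalized gDNA values by a two-tailed, unpaired, pooled-variance
Student's *t*-test; the cohort-level comparison pools all cDNA against
all gDNA. Design choices:

- **Pooled variance, not Welch.** The classical Student form is the
  default (Welch is a flag away via `stats::t.test` if wanted); the gDNA
  reference group is large, so the distinction is minor in practice.
- **gDNA at replicate level.** The per-sample test uses all retained gDNA
  replicate values as the reference group (not per-donor gDNA means);
  both granularities are computable from the returned records.
- **Degenerate inputs.** Zero pooled variance with equal means is
  declared not significant ($t = 0$, $p = 1$); zero pooled variance with
  unequal means is flagged `degenerate` and significant by contract
  rather than emitting an infinite statistic.
- **Pooled-test aggregation.** Default is per-sample means, so each donor
  contributes once and replicate pseudoreplication does not inflate the
  global test; `per_replicate` mode exists to pool raw replicates, and
  both sample sizes are always reported.
- **No multiple-testing correction by default** across donors — each
  donor's test is reported marginally, the convention in per-donor AI
  read-outs; `p.adjust` can be applied to the returned `p_value` column.
- The cohort summary reports both the all-sample mean $n\Delta Ct$ and
  the significant-only mean, since summaries of "the" cohort effect
  differ on which set they average.

## Sensitivity calibration (`calibration`)

Mixture points (gDNA of opposite homozygotes mixed at known ratios) are
fit by OLS of replicate $\Delta Ct$ on $\log_2(\text{ratio})$: the slope
is 1 at ideal efficiency and the intercept estimates the dye bias; every
point is additionally *t*-tested against the heterozygous 1:1 control
replicates. The minimal detectable ratio — the smallest $r \ge 1$ whose
shift $\log_2 r$ a two-sample *t*-test of $n$ replicates detects with the
requested power — is computed from exact noncentral-*t* power on a
$\log_2$-ratio grid of step 0.01 (not a normal approximation); the grid
step bounds the answer's resolution and matches the Monte-Carlo oracle in
the tests to within one step. Mixture ratios are encoded as a single
positive real (4:1 ↦ 4, 1:4 ↦ 0.25) to make the log2 linearity explicit.

## Total expression (`rel_expression`)

Relative quantification uses a standard curve (Ct on log10 concentration;
`efficiency = 10^(−1/slope) − 1`), matching how the assays this package
targets are normally quantified; the ΔΔCt shortcut is provided separately
and clearly labelled (`ddct_expression()`), since it silently assumes
equal, perfect efficiencies. Duplicate wells are averaged on the Ct scale
before interpolation (averaging interpolated quantities is available by
flag). The reference gene is a parameter, with
`select_reference_gene()` mirroring the usual lowest-Ct-variance
selection among candidate housekeeping genes. Genotype groups
(risk-allele vs protective-allele homozygotes) are compared by two-sided
Mann–Whitney U: exact null distribution for combined $n \le 25$ without
ties, normal approximation with continuity and tie correction otherwise
(the `stats::wilcox.test` conventions).

## Power planning (`power_analysis`)

`required_n_per_group()` returns the smallest integer group size at which
a two-sided, two-sample pooled-variance *t*-test reaches the target power,
computed from the exact noncentral-*t* distribution by bracketing and
bisection on the monotone power curve — never the normal-approximation
formula, which can be off by one or two at small $n$. Defaults are
$\alpha = 0.05$ two-sided and power 0.80. The answer depends only on the
standardized effect `effect/sd`.

## Problem sizes and verification

The test suite verifies the worked ratio conversions exactly; the
gDNA-centering identity to machine precision; parameter recovery on
30-donor cohorts at ratios 1, 1.15 and 2.25 within 3 Monte-Carlo standard
errors (the SE includes the shared gDNA-reference term, which does not
shrink with cohort size); type-I error on 1,000 simulated null donors
against exact binomial 99 % bounds; noise-free calibration closed forms
($slope = 1$, intercept = dye bias; dilution slope $-1/\log_{10} 2$);
100 % pass-1 capture of injected 10-cycle contaminants; *t* and
Mann–Whitney *p*-values against `stats::t.test`, exhaustive enumeration
and Monte Carlo to $10^{-10}$; and sample-size answers (17 at $d = 1$, 64
at $d = 0.5$) against `stats::power.t.test` and simulation. These sizes
were chosen as the smallest that make the Monte-Carlo bounds sharp; the
full suite runs in seconds.

## Known limitations

- The dye-bias correction assumes the offset is identical in gDNA and
  cDNA matrices; a matrix-dependent offset would bias $n\Delta Ct$ and is
  not modelled.
- Converting $n\Delta Ct$ to a ratio with base 2 assumes ideal, equal
  efficiency on both channels; allele-specific efficiency differences
  fold into the apparent ratio and are only partially absorbed by the
  gDNA reference.
- Per-donor tests share one gDNA reference group, so they are not
  strictly independent; with a large reference set the induced
  correlation is negligible (the type-I-error simulation bounds it), but
  it exists.
- The pipeline addresses assay-based ASE only; read-count (RNA-seq) ASE,
  haplotype phasing and formal eQTL mapping are out of scope.
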