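## Tukey box-plot fences. Quartiles are Tukey hinges (median-of-halves, as
## stats::fivenum computes them); conventions differ between programs, so the
## rule is fixed here and documented.
boxplot_fences <- function(x, k) {
  fn <- stats::fivenum(x)
  q1 <- fn[2]; q3 <- fn[4]
  iqr <- q3 - q1
  c(lower = q1 - k * iqr, upper = q3 + k * iqr)
}

#' Two-pass box-plot outlier exclusion
#'
#' Replicate delta-Ct values for one donor are screened in two passes, the
#' way box-plot based replicate QC is usually done: pass 1 removes extreme
#' values (beyond `k_extreme` interquartile ranges from the hinges), the
#' box plot is rebuilt from the survivors, and pass 2 removes ordinary
#' outliers (beyond `k_outlier` IQRs) from the rebuilt plot. Quartiles are
#' Tukey hinges; values exactly on a fence are retained (exclusion is
#' strict), so a degenerate replicate set with zero IQR loses nothing.
#'
#' @param values Numeric vector of replicate delta-Ct values (cycles).
#' @param k_extreme Fence multiplier for pass 1 (extreme values); default 3.
#' @param k_outlier Fence multiplier for pass 2 (outlier values); default 1.5.
#' @return An object of class `"outlier_report"`: a list with
#'   `pass1_excluded`, `pass2_excluded` and `retained` (indices into
#'   `values`, disjoint, jointly exhaustive) and `fences` (per-pass
#'   lower/upper bounds, cycles). Inputs of fewer than 3 values pass
#'   through untouched with a warning, since fences are undefined.
#' @examples
#' two_pass_boxplot_filter(c(1.0, 1.1, 0.9, 1.05, 9.0))
#' @export
two_pass_boxplot_filter <- function(values, k_extreme = 3, k_outlier = 1.5) {
  stopifnot(is.numeric(values))
  if (any(!is.finite(values)))
    stop("all values must be finite; drop undetermined wells first",
         call. = FALSE)
  if (k_extreme < 0 || k_outlier < 0)
    stop("fence multipliers must be nonnegative", call. = FALSE)
  idx <- seq_along(values)

  if (length(values) < 3) {
    warning("fewer than 3 replicates: fences undefined, all values retained",
            call. = FALSE)
    return(structure(list(pass1_excluded = integer(0),
                          pass2_excluded = integer(0), retained = idx,
                          fences = list(pass1 = c(lower = NA_real_,
                                                  upper = NA_real_),
                                        pass2 = c(lower = NA_real_,
                                                  upper = NA_real_))),
                     class = "outlier_report"))
  }

  f1 <- boxplot_fences(values, k_extreme)
  pass1 <- idx[values < f1["lower"] | values > f1["upper"]]
  surv1 <- setdiff(idx, pass1)

  f2 <- boxplot_fences(values[surv1], k_outlier)
  pass2 <- surv1[values[surv1] < f2["lower"] | values[surv1] > f2["upper"]]
  retained <- setdiff(surv1, pass2)
  if (length(retained) == 0)
    stop("all replicate values excluded: replicate set unusable",
         call. = FALSE)

  structure(list(pass1_excluded = pass1, pass2_excluded = pass2,
                 retained = retained,
                 fences = list(pass1 = f1, pass2 = f2)),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Two-pass box-plot filter: %d retained, %d extreme, %d outlier\n",
              length(x$retained), length(x$pass1_excluded),
              length(x$pass2_excluded)))
  invisible(x)
}

#' Apply the two-pass outlier filter to a plate dataset
#'
#' Wells with an undetermined Ct in either channel are dropped first (with
#' a count), delta-Ct values are computed, and [two_pass_boxplot_filter()]
#' is run per donor group — the replicate sets keyed by
#' `(sample_id, snp_id, material)`. Filtering acts on the delta-Ct, the
#' quantity the downstream analysis uses, not on raw per-dye Cts.
#'
#' @param wells Well-measurement data frame.
#' @param k_extreme,k_outlier Fence multipliers, see
#'   [two_pass_boxplot_filter()].
#' @return A list with `wells` (the retained wells), `reports` (a data
#'   frame, one row per excluded or retained replicate, with pass labels
#'   and the fences applied) and `n_undetermined`.
#' @export
apply_outlier_filter <- function(wells, k_extreme = 3, k_outlier = 1.5) {
  if (nrow(wells) == 0)
    return(list(wells = wells, reports = empty_outlier_table(),
                n_undetermined = 0L))

  und <- is.na(wells$ct_vic) | is.na(wells$ct_fam)
  n_und <- sum(und)
  if (n_und > 0)
    message(n_und, " well(s) with undetermined Ct dropped before filtering")
  wells <- wells[!und, , drop = FALSE]

  grp <- interaction(wells$sample_id, wells$snp_id, wells$material,
                     drop = TRUE)
  keep <- logical(nrow(wells))
  reports <- vector("list", nlevels(grp))
  for (gi in seq_len(nlevels(grp))) {
    rows <- which(grp == levels(grp)[gi])
    dct <- wells$ct_fam[rows] - wells$ct_vic[rows]
    rep_ <- suppressWarnings(
      two_pass_boxplot_filter(dct, k_extreme, k_outlier))
    keep[rows[rep_$retained]] <- TRUE
    status <- rep("retained", length(rows))
    status[rep_$pass1_excluded] <- "extreme"
    status[rep_$pass2_excluded] <- "outlier"
    reports[[gi]] <- data.frame(
      sample_id = wells$sample_id[rows], snp_id = wells$snp_id[rows],
      material = wells$material[rows], replicate = wells$replicate[rows],
      delta_ct = dct, status = status,
      fence1_lower = rep_$fences$pass1[["lower"]],
      fence1_upper = rep_$fences$pass1[["upper"]],
      fence2_lower = rep_$fences$pass2[["lower"]],
      fence2_upper = rep_$fences$pass2[["upper"]],
      stringsAsFactors = FALSE)
  }
  list(wells = wells[keep, , drop = FALSE],
       reports = do.call(rbind, reports),
       n_undetermined = n_und)
}

empty_outlier_table <- function() {
  data.frame(sample_id = character(0), snp_id = character(0),
             material = character(0), replicate = integer(0),
             delta_ct = numeric(0), status = character(0),
             fence1_lower = numeric(0), fence1_upper = numeric(0),
             fence2_lower = numeric(0), fence2_upper = numeric(0),
             stringsAsFactors = FALSE)
}
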