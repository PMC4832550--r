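#' Read a plate measurement table
#'
#' Reads the canonical long-form plate CSV: one row per well with columns
#' `sample_id`, `snp_id`, `material` (gDNA/cDNA), `replicate`, `ct_vic`,
#' `ct_fam`, `plate_id`, `well`. The instrument token `"Undetermined"` (any
#' capitalisation, or an empty field) in a Ct column is mapped to `NA` — an
#' explicit undetermined state, never silently coerced to a number. Wells
#' with undetermined channels are retained here and excluded (with a count)
#' at analysis time.
#'
#' @param path Path to a CSV file.
#' @return A data frame of well measurements.
#' @seealso [write_plate_table()] for the inverse; the pair is lossless.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stop("plate file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("sample_id", "snp_id", "material", "replicate",
                "ct_vic", "ct_fam")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("plate table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"plate_id" %in% names(df)) df$plate_id <- rep(NA_character_, nrow(df))
  if (!"well" %in% names(df)) df$well <- rep(NA_character_, nrow(df))

  parse_ct <- function(x) {
    x <- trimws(x)
    und <- tolower(x) %in% c("undetermined", "undet", "na", "") | is.na(x)
    out <- suppressWarnings(as.numeric(x))
    out[und] <- NA_real_
    bad <- !und & (is.na(out) | !is.finite(out) | out <= 0)
    if (any(bad))
      stop("unparseable or nonpositive Ct value(s): ",
           paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
    out
  }
  df$ct_vic <- parse_ct(df$ct_vic)
  df$ct_fam <- parse_ct(df$ct_fam)
  df$replicate <- as.integer(df$replicate)
  bad_mat <- !df$material %in% c("gDNA", "cDNA")
  if (any(bad_mat))
    stop("invalid material value(s): ",
         paste(unique(df$material[bad_mat]), collapse = ", "),
         " (must be gDNA or cDNA)", call. = FALSE)
  key <- paste(df$sample_id, df$snp_id, df$material, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate well key(s): ",
         paste(utils::head(unique(gsub("\r", "/", key[duplicated(key)])), 3),
               collapse = "; "), call. = FALSE)
  df[c("sample_id", "snp_id", "material", "replicate",
       "ct_vic", "ct_fam", "plate_id", "well")]
}

#' Write a plate measurement table
#'
#' Writes well measurements in the canonical CSV dialect read back by
#' [read_plate_table()]; `NA` Ct values are serialized as `"Undetermined"`.
#'
#' @param wells Data frame of well measurements (e.g. the `wells` element of
#'   a simulated dataset).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(wells, path) {
  out <- wells
  # 17 significant digits: lossless text round trip for doubles
  fmt_ct <- function(x) ifelse(is.na(x), "Undetermined",
                               formatC(x, digits = 17, format = "g"))
  out$ct_vic <- fmt_ct(out$ct_vic)
  out$ct_fam <- fmt_ct(out$ct_fam)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Long-format CSV with columns `sample_id`, `cohort` (case/control),
#' `snp_id`, `genotype` (one of `hom_allele1`, `het`, `hom_allele2`,
#' `missing`).
#'
#' @param path Path to a CSV file.
#' @return A data frame, one row per sample x SNP.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "snp_id", "genotype")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sample sheet is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ok <- c("hom_allele1", "het", "hom_allele2", "missing")
  bad <- !df$genotype %in% ok
  if (any(bad))
    stop("invalid genotype value(s): ",
         paste(unique(df$genotype[bad]), collapse = ", "), call. = FALSE)
  df
}

#' Read a SNP annotation table
#'
#' CSV with columns `snp_id`, `gene`, `allele1_base`, `allele2_base`,
#' `risk_allele` (`allele1` or `allele2`), and optionally `proxy_for` and
#' `ld_r2`. The `risk_allele` column resolves which dye channel carries the
#' disease-associated allele, so results can be reported in risk-versus-
#' protective orientation regardless of assay dye layout.
#'
#' @param path Path to a CSV file.
#' @return A data frame of SNP annotations.
#' @export
read_snp_annotation <- function(path) {
  if (!file.exists(path)) stop("SNP annotation not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("snp_id", "gene", "allele1_base", "allele2_base", "risk_allele")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("SNP annotation is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- !df$risk_allele %in% c("allele1", "allele2")
  if (any(bad))
    stop("`risk_allele` must be 'allele1' or 'allele2'", call. = FALSE)
  df
}

#' Select the heterozygous samples at a SNP
#'
#' ASE can only be read out within heterozygous donors, so every analysis
#' starts by subsetting the cohort to the samples with a `het` genotype at
#' the assayed SNP. Order of the input is preserved.
#'
#' @param samples Sample sheet data frame (see [read_sample_sheet()]).
#' @param snp_id SNP to subset on.
#' @return The heterozygous subset of `samples` (possibly empty).
#' @export
select_heterozygotes <- function(samples, snp_id) {
  if (!snp_id %in% samples$snp_id)
    stop("no genotypes recorded for SNP ", snp_id, call. = FALSE)
  sub <- samples[samples$snp_id == snp_id & samples$genotype == "het", ,
                 drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Cross-tabulate joint genotype state at two linked SNPs
#'
#' When the assayed SNP is a linkage-disequilibrium proxy for the
#' disease-associated SNP, incomplete LD means a donor heterozygous at the
#' proxy may be homozygous at the associated SNP. This tabulates the joint
#' state so that observed imbalance can (or cannot) be attributed to the
#' associated variant.
#'
#' @param samples Sample sheet data frame.
#' @param snp_a,snp_b The two SNP identifiers.
#' @return A list with `table` (per-sample joint states) and `counts`
#'   (named integer vector: `het_het`, `het_hom`, `hom_het`, `hom_hom`,
#'   `missing`).
#' @export
check_double_heterozygosity <- function(samples, snp_a, snp_b) {
  ga <- samples[samples$snp_id == snp_a, c("sample_id", "genotype")]
  gb <- samples[samples$snp_id == snp_b, c("sample_id", "genotype")]
  if (nrow(samples) > 0) {
    if (nrow(ga) == 0) stop("no genotypes for SNP ", snp_a, call. = FALSE)
    if (nrow(gb) == 0) stop("no genotypes for SNP ", snp_b, call. = FALSE)
  }
  names(ga)[2] <- "genotype_a"
  names(gb)[2] <- "genotype_b"
  joint <- merge(ga, gb, by = "sample_id", all = TRUE, sort = TRUE)
  cls <- function(g) {
    ifelse(is.na(g) | g == "missing", "missing",
           ifelse(g == "het", "het", "hom"))
  }
  joint$state <- paste(cls(joint$genotype_a), cls(joint$genotype_b), sep = "_")
  joint$state[grepl("missing", joint$state)] <- "missing"
  counts <- c(het_het = 0L, het_hom = 0L, hom_het = 0L, hom_hom = 0L,
              missing = 0L)
  tab <- table(joint$state)
  counts[names(tab)] <- as.integer(tab)
  list(table = joint, counts = counts)
}

#' Validate cross-references of a plate dataset
#'
#' Checks that every well refers to a sample present in the sample sheet
#' and (when an annotation is supplied) to an annotated SNP, and reports
#' undetermined-Ct counts.
#'
#' @param wells Well measurements.
#' @param samples Sample sheet (optional).
#' @param snps SNP annotation (optional).
#' @return Invisibly, a list of counts; errors on broken references.
#' @export
validate_dataset <- function(wells, samples = NULL, snps = NULL) {
  if (nrow(wells) == 0) stop("plate table is empty", call. = FALSE)
  if (!is.null(samples)) {
    unknown <- setdiff(unique(wells$sample_id), unique(samples$sample_id))
    if (length(unknown))
      stop("well(s) reference sample(s) absent from the sample sheet: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(snps)) {
    unknown <- setdiff(unique(wells$snp_id), unique(snps$snp_id))
    if (length(unknown))
      stop("well(s) reference unannotated SNP(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(list(n_wells = nrow(wells),
                 n_undetermined = sum(is.na(wells$ct_vic) | is.na(wells$ct_fam))))
}
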