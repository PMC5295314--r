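#' @keywords internal
"_PACKAGE"

# Closed vocabularies shared across the package.
.ethnicities <- c("Caucasian", "East Asian", "South Asian",
                  "Middle Eastern", "African", "Mixed")
.loci <- c("C677T", "A1298C")
.count_cols <- c("case_hom", "case_het", "case_wild",
                 "ctrl_hom", "ctrl_het", "ctrl_wild")

#' Accepted ethnicity labels
#'
#' The six race-ethnicity strata used throughout the package. Study tables must
#' use these labels verbatim.
#'
#' @return Character vector of the accepted labels.
#' @export
ethnicity_levels <- function() .ethnicities

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce a genotype-count arm
#'
#' An "arm" is one side (cases or controls) of one study group: counts of the
#' homozygous-variant, heterozygous and wild-type genotypes, in that order.
#'
#' @param x Numeric vector of length 3, optionally named `hom`, `het`, `wild`.
#' @return Named numeric vector `c(hom=, het=, wild=)`.
#' @noRd
as_genotype_counts <- function(x) {
  if (is.list(x)) x <- unlist(x)
  if (length(x) != 3L || !is.numeric(x))
    stop("genotype counts must be a numeric vector of length 3 (hom, het, wild)")
  if (!is.null(names(x)) && all(c("hom", "het", "wild") %in% names(x)))
    x <- x[c("hom", "het", "wild")]
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("genotype counts must be non-negative integers")
  stats::setNames(as.numeric(x), c("hom", "het", "wild"))
}

# Extract one arm of one study row as a genotype-count vector.
study_arm <- function(study, arm = c("case", "ctrl")) {
  arm <- match.arg(arm)
  as_genotype_counts(unlist(study[paste0(arm, c("_hom", "_het", "_wild"))]))
}

#' Validate a study-group table
#'
#' Checks the invariants every analysis assumes: non-negative integer counts,
#' arm totals of at least one, a known ethnicity label, air-pollution death
#' levels in \{2, 3, 4\} and quality scores in [0, 29] when present. All row
#' failures are collected and reported together, indexed by row.
#'
#' @param df A data frame with the study-table columns (see [load_studies()]).
#' @param locus `"C677T"` or `"A1298C"`.
#' @return The validated table with class `study_table`, columns normalised to
#'   the generic `case_hom`/`case_het`/`case_wild` (and `ctrl_*`) naming.
#' @export
validate_studies <- function(df, locus = c("C677T", "A1298C")) {
  locus <- match.arg(locus)
  required <- c("study_id", "country", "ethnicity", .count_cols)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  if (!"ap_death_level" %in% names(df)) df$ap_death_level <- NA_integer_
  if (!"quality_score" %in% names(df)) df$quality_score <- NA_real_
  if (!"vascular_ad" %in% names(df)) df$vascular_ad <- FALSE
  if (!"hwe_reported" %in% names(df)) df$hwe_reported <- NA
  df$vascular_ad[is.na(df$vascular_ad)] <- FALSE
  df$locus <- locus

  errs <- character(0)
  for (i in seq_len(nrow(df))) {
    row_err <- function(msg) errs[[length(errs) + 1L]] <<- sprintf("row %d: %s", i, msg)
    cnt <- suppressWarnings(as.numeric(df[i, .count_cols]))
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
      row_err("genotype counts must be non-negative integers")
    else {
      if (sum(cnt[1:3]) < 1) row_err("case arm total must be >= 1")
      if (sum(cnt[4:6]) < 1) row_err("control arm total must be >= 1")
    }
    if (!df$ethnicity[i] %in% .ethnicities)
      row_err(sprintf("unknown ethnicity '%s' (accepted: %s)",
                      df$ethnicity[i], paste(.ethnicities, collapse = ", ")))
    lev <- df$ap_death_level[i]
    if (!is.na(lev) && !lev %in% c(2, 3, 4))
      row_err("ap_death_level must be 2, 3 or 4 when present")
    qs <- df$quality_score[i]
    if (!is.na(qs) && (qs < 0 || qs > 29))
      row_err("quality_score must lie in [0, 29]")
  }
  if (length(errs))
    stop("study table validation failed:\n  ", paste(errs, collapse = "\n  "))

  keep <- c("study_id", "country", "ethnicity", "locus", .count_cols,
            "ap_death_level", "quality_score", "vascular_ad", "hwe_reported")
  df <- df[, keep]
  df$study_id <- as.character(df$study_id)
  for (col in .count_cols) df[[col]] <- as.numeric(df[[col]])
  rownames(df) <- NULL
  class(df) <- c("study_table", "data.frame")
  df
}

# Locus-specific column aliases: for C677T the variant homozygote is TT and the
# wild type CC; for A1298C the variant homozygote is CC and the wild type AA.
.locus_aliases <- function(locus) {
  if (locus == "C677T")
    c(case_tt = "case_hom", case_ct = "case_het", case_cc = "case_wild",
      ctrl_tt = "ctrl_hom", ctrl_ct = "ctrl_het", ctrl_cc = "ctrl_wild")
  else
    c(case_cc = "case_hom", case_ac = "case_het", case_aa = "case_wild",
      ctrl_cc = "ctrl_hom", ctrl_ac = "ctrl_het", ctrl_aa = "ctrl_wild")
}

#' Load a study-group table from delimited text
#'
#' Reads a UTF-8 delimited file (comma by default, tab auto-detected) with a
#' header row and one row per case-control study group. Count columns may be
#' named generically (`case_hom`, `case_het`, `case_wild`, `ctrl_*`) or with
#' locus-specific genotype names (`case_tt`, `case_ct`, `case_cc`, ... for
#' C677T; `case_cc`, `case_ac`, `case_aa`, ... for A1298C). Lines starting
#' with `#` are treated as comments. Optional columns: `ap_death_level`
#' (2, 3 or 4), `quality_score` (0-29), `vascular_ad`, `hwe_reported`.
#'
#' @param path Path to the file.
#' @param locus `"C677T"` (default) or `"A1298C"`; controls which genotype
#'   column names are recognised and how genotype-set labels are interpreted
#'   downstream.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab from
#'   the header line.
#' @return A validated `study_table` (see [validate_studies()]).
#' @examples
#' tab <- fixture_appendix_like()
#' f <- tempfile(fileext = ".csv")
#' write_study_table(tab, f)
#' identical(nrow(load_studies(f)), 44L)
#' @export
load_studies <- function(path, locus = c("C677T", "A1298C"), sep = NULL) {
  locus <- match.arg(locus)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[!startsWith(first, "#")][1]
    if (is.na(first)) stop("file has no header row: ", path)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", fileEncoding = "UTF-8")
  aliases <- .locus_aliases(locus)
  hit <- names(df) %in% names(aliases)
  names(df)[hit] <- aliases[names(df)[hit]]
  validate_studies(df, locus = locus)
}

#' Write a study-group table to delimited text
#'
#' Writes the generic-format CSV that [load_studies()] reads back. Optional
#' comment lines (prefixed `#`) can carry provenance such as a generator seed.
#'
#' @param studies A `study_table`.
#' @param path Output path.
#' @param header_comments Character vector of comment lines (written verbatim
#'   after a `# ` prefix), or `NULL`.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path, header_comments = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comments))
    writeLines(paste0("# ", header_comments), con)
  utils::write.table(as.data.frame(studies), con, sep = ",", row.names = FALSE,
                     quote = TRUE, qmethod = "double")
  invisible(path)
}

#' Genotype and allele frequencies for one arm
#'
#' Percentages for the three genotypes and for the two alleles of a
#' tri-genotype locus. Two allele conventions are exposed: the 2N chromosome
#' scale (`allele_variant_pct` uses `(2*hom + het) / (2*total)`) and the
#' per-person halved-count convention (`variant = hom + het/2`,
#' `wild = wild + het/2`), under which counts sum to the number of persons.
#' The two conventions give identical percentages.
#'
#' @param arm Genotype counts `c(hom, het, wild)`.
#' @return A list of class `frequency_summary`: `genotype_pct` (named hom/het/
#'   wild), `allele_variant_pct`, `allele_wild_pct`, `allele_counts_halved`.
#' @examples
#' f <- genotype_frequencies(c(822, 2246, 1664))
#' round(f$genotype_pct, 2)        # 17.37 47.46 35.16
#' round(f$allele_variant_pct, 2)  # 41.10
#' @export
genotype_frequencies <- function(arm) {
  x <- as_genotype_counts(arm)
  n <- sum(x)
  if (n < 1) stop("arm total must be >= 1")
  structure(list(
    genotype_pct = 100 * x / n,
    allele_variant_pct = 100 * (2 * x[["hom"]] + x[["het"]]) / (2 * n),
    allele_wild_pct = 100 * (2 * x[["wild"]] + x[["het"]]) / (2 * n),
    allele_counts_halved = c(variant = x[["hom"]] + x[["het"]] / 2,
                             wild = x[["wild"]] + x[["het"]] / 2),
    total = n
  ), class = "frequency_summary")
}

#' Per-study and pooled frequency report
#'
#' One row per study group and arm, plus `"(pooled)"` rows aggregating all
#' groups, with genotype and variant-allele percentages at full precision
#' (round only for display).
#'
#' @param studies A `study_table`.
#' @return Data frame with columns `study_id`, `arm`, `n`, `pct_hom`,
#'   `pct_het`, `pct_wild`, `allele_variant_pct`.
#' @export
frequency_table <- function(studies) {
  one <- function(id, counts, arm) {
    f <- genotype_frequencies(counts)
    data.frame(study_id = id, arm = arm, n = f$total,
               pct_hom = f$genotype_pct[["hom"]],
               pct_het = f$genotype_pct[["het"]],
               pct_wild = f$genotype_pct[["wild"]],
               allele_variant_pct = f$allele_variant_pct)
  }
  rows <- lapply(seq_len(nrow(studies)), function(i) {
    rbind(one(studies$study_id[i], study_arm(studies[i, ], "case"), "case"),
          one(studies$study_id[i], study_arm(studies[i, ], "ctrl"), "ctrl"))
  })
  pooled_case <- colSums(studies[, c("case_hom", "case_het", "case_wild")])
  pooled_ctrl <- colSums(studies[, c("ctrl_hom", "ctrl_het", "ctrl_wild")])
  out <- rbind(do.call(rbind, rows),
               one("(pooled)", pooled_case, "case"),
               one("(pooled)", pooled_ctrl, "ctrl"))
  rownames(out) <- NULL
  out
}

#' Hardy-Weinberg equilibrium test for a control arm
#'
#' Pearson chi-square goodness-of-fit test (1 df, no continuity correction)
#' of the observed genotype counts against the expectations `n*q^2`,
#' `n*2q(1-q)`, `n*(1-q)^2` at the sample variant-allele frequency `q`.
#' Monomorphic samples (q of 0 or 1) are returned with a chi-square of 0,
#' p-value 1 and a `monomorphic` flag; deviation from equilibrium is flagged
#' at alpha = 0.05 but studies are never dropped on that basis.
#'
#' @param controls Genotype counts `c(hom, het, wild)` for the control arm.
#' @return List of class `hwe_result`: `chi_square`, `df`, `p_value`,
#'   `in_equilibrium`, `monomorphic`.
#' @examples
#' hwe_test(c(25, 50, 25))$chi_square  # 0: exact HWE proportions
#' hwe_test(c(30, 40, 30))$chi_square  # 4
#' @export
hwe_test <- function(controls) {
  x <- as_genotype_counts(controls)
  n <- sum(x)
  if (n < 1) stop("control arm total must be >= 1")
  q <- (2 * x[["hom"]] + x[["het"]]) / (2 * n)
  if (q <= 0 || q >= 1) {
    return(structure(list(chi_square = 0, df = 1L, p_value = 1,
                          in_equilibrium = TRUE, monomorphic = TRUE),
                     class = "hwe_result"))
  }
  expected <- n * c(q^2, 2 * q * (1 - q), (1 - q)^2)
  chi <- sum((x - expected)^2 / expected)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  structure(list(chi_square = chi, df = 1L, p_value = p,
                 in_equilibrium = p >= 0.05, monomorphic = FALSE),
            class = "hwe_result")
}

#' Hardy-Weinberg report for every control arm in a table
#'
#' @param studies A `study_table`.
#' @return Data frame: `study_id`, `chi_square`, `p_value`, `in_equilibrium`,
#'   `monomorphic`, and `hwe_reported` (the study's own claim, if recorded)
#'   with a `discrepant` flag where claim and test disagree.
#' @export
hwe_table <- function(studies) {
  res <- lapply(seq_len(nrow(studies)),
                function(i) hwe_test(study_arm(studies[i, ], "ctrl")))
  out <- data.frame(
    study_id = studies$study_id,
    chi_square = vapply(res, `[[`, numeric(1), "chi_square"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    in_equilibrium = vapply(res, `[[`, logical(1), "in_equilibrium"),
    monomorphic = vapply(res, `[[`, logical(1), "monomorphic"),
    hwe_reported = studies$hwe_reported
  )
  out$discrepant <- !is.na(out$hwe_reported) & out$hwe_reported != out$in_equilibrium
  out
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.4f (df 1), p = %.4g; %s%s\n",
              x$chi_square, x$p_value,
              if (x$in_equilibrium) "in equilibrium" else "out of equilibrium",
              if (x$monomorphic) " (monomorphic)" else ""))
  invisible(x)
}

#' @export
print.frequency_summary <- function(x, ...) {
  cat(sprintf("n = %d persons\n", as.integer(x$total)))
  cat(sprintf("  genotypes: hom %.2f%%, het %.2f%%, wild %.2f%%\n",
              x$genotype_pct[["hom"]], x$genotype_pct[["het"]],
              x$genotype_pct[["wild"]]))
  cat(sprintf("  variant allele %.2f%% (halved count %.1f)\n",
              x$allele_variant_pct, x$allele_counts_halved[["variant"]]))
  invisible(x)
}
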