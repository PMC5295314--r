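# Meta-prediction: relating study-level genotype percentages and risk ratios
# to the ordinal air-pollution death-rate strata (levels 2 = 50-100,
# 3 = 100-250, 4 = 250-400+ annual deaths per million) via a single-split
# partition tree scored by AICc, Tukey-Kramer pairwise level comparisons,
# trend-curve fits, and heat-map matrices.

# Parse a series label such as "TT%ca", "CT%ct" or "RRTT" (C677T), their
# A1298C analogues ("CC%ca", "RRCC", ...), or generic forms ("hom%ca",
# "RRhom"). Returns list(kind, role, arm).
parse_series_variable <- function(variable, locus = "C677T") {
  v <- gsub("\\s", "", variable)
  if (grepl("^RR", v, ignore.case = TRUE)) {
    set <- sub("^RR", "", v, ignore.case = TRUE)
    return(list(kind = "rr", role = resolve_genotype_set(set, locus), arm = NA))
  }
  m <- regmatches(v, regexec("^([A-Za-z]+)%(ca|ct)$", v))[[1]]
  if (length(m) == 3) {
    return(list(kind = "pct", role = resolve_genotype_set(m[2], locus),
                arm = if (m[3] == "ca") "case" else "ctrl"))
  }
  stop("cannot parse series variable '", variable,
       "' (expected e.g. 'TT%ca', 'CT%ct' or 'RRTT')")
}

#' Build a study-level series over air-pollution levels
#'
#' Pairs each study's value of a variable -- a genotype percentage in one arm
#' (`"TT%ca"`, `"CT%ct"`, ...; `ca` = AD cases, `ct` = controls) or a
#' per-study risk ratio (`"RRTT"`, `"RRCT"`, `"RRCC"`) -- with that study's
#' air-pollution death-rate level. Studies lacking a level annotation are
#' excluded and counted.
#'
#' @param studies A `study_table`.
#' @param variable Series label as above (A1298C analogues and generic
#'   `hom`/`het`/`wild` forms accepted).
#' @return Data frame of class `level_series` with columns `study_id`,
#'   `level`, `value`; attributes `variable` and `n_excluded`.
#' @export
build_level_series <- function(studies, variable) {
  locus <- studies$locus[1] %||% "C677T"
  spec <- parse_series_variable(variable, locus)
  keep <- !is.na(studies$ap_death_level)
  n_excluded <- sum(!keep)
  studies <- studies[keep, , drop = FALSE]
  if (nrow(studies) == 0)
    stop("no studies carry an air-pollution death level")
  value <- if (spec$kind == "pct") {
    vapply(seq_len(nrow(studies)), function(i) {
      genotype_frequencies(study_arm(studies[i, ], spec$arm))$genotype_pct[[spec$role]]
    }, numeric(1))
  } else {
    study_effects(studies, spec$role)$rr
  }
  out <- data.frame(study_id = studies$study_id,
                    level = as.integer(studies$ap_death_level),
                    value = value)
  attr(out, "variable") <- variable
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("level_series", "data.frame")
  out
}

group_ss <- function(x) sum((x - mean(x))^2)

#' Single-split partition of an ordinal level series
#'
#' Evaluates every contiguous binary split of the ordered exposure levels
#' (with levels 2, 3, 4 present the candidates are `{2}|{3,4}` and
#' `{2,3}|{4}`), keeps the split minimising the residual sum of squares of
#' the two group means, and scores it by the small-sample-corrected Akaike
#' criterion `AICc = n*ln(SSE/n) + 2k + 2k(k+1)/(n-k-1)` with `k = 3`
#' parameters (two means and one variance). Ties in SSE are broken toward
#' the split isolating the lowest level; a zero SSE is floored at 1e-12
#' before the log.
#'
#' @param series A `level_series` (or data frame with `level` and `value`).
#' @return List of class `partition_result`: `left_levels`, `right_levels`,
#'   `left_n`, `right_n`, `left_mean`, `right_mean`, `left_sd`, `right_sd`,
#'   `sse`, `aicc` (`NA`, flagged, when `n - k - 1 <= 0`), `variable`.
#' @export
partition_one_split <- function(series) {
  lv <- sort(unique(series$level))
  n <- nrow(series)
  if (length(lv) < 2) stop("partition needs at least 2 distinct levels")
  if (n < 3) stop("partition needs at least 3 observations")
  best <- NULL
  for (i in seq_len(length(lv) - 1)) {
    left <- lv[seq_len(i)]
    in_left <- series$level %in% left
    sse <- group_ss(series$value[in_left]) + group_ss(series$value[!in_left])
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(left = left, right = setdiff(lv, left), sse = sse,
                   in_left = in_left)
    }
  }
  sse <- max(best$sse, 1e-12)
  k <- 3
  aicc <- if (n - k - 1 <= 0) NA_real_
          else n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  yl <- series$value[best$in_left]
  yr <- series$value[!best$in_left]
  structure(list(
    left_levels = best$left, right_levels = best$right,
    left_n = length(yl), right_n = length(yr),
    left_mean = mean(yl), right_mean = mean(yr),
    left_sd = stats::sd(yl), right_sd = stats::sd(yr),
    sse = best$sse, aicc = aicc,
    aicc_defined = n - k - 1 > 0,
    variable = attr(series, "variable") %||% NA_character_
  ), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("Partition%s: {%s} | {%s}\n",
              if (!is.na(x$variable)) paste0(" of ", x$variable) else "",
              paste(x$left_levels, collapse = ","),
              paste(x$right_levels, collapse = ",")))
  cat(sprintf("  left  n = %2d, mean = %.3f, sd = %.3f\n",
              x$left_n, x$left_mean, x$left_sd))
  cat(sprintf("  right n = %2d, mean = %.3f, sd = %.3f\n",
              x$right_n, x$right_mean, x$right_sd))
  cat(sprintf("  SSE = %.4f, AICc = %s\n", x$sse,
              if (is.na(x$aicc)) "undefined" else sprintf("%.3f", x$aicc)))
  invisible(x)
}

#' Tukey-Kramer pairwise comparisons across exposure levels
#'
#' One-way ANOVA of the series values on exposure level (error df `N - g`),
#' followed by all pairwise mean comparisons through the studentized-range
#' law with the Tukey-Kramer allowance for unequal group sizes: for groups i
#' and j the comparison statistic is `|diff| / sqrt(MSE*(1/n_i + 1/n_j)/2)`,
#' referred to the studentized range distribution with `g` groups and `N - g`
#' df. Confidence intervals are at the 95% family level, so an interval
#' excludes zero exactly when the adjusted p falls below 0.05. Levels with
#' fewer than 2 observations are excluded with a warning.
#'
#' @param series A `level_series`.
#' @return List of class `tukey_summary`: `comparisons` (data frame `pair`
#'   `"hi/lo"`, `difference` >= 0, `se_difference`, `ci_low`, `ci_high`,
#'   `p_adjusted`), `mse`, `df_error`, `group_stats` (`level`, `n`, `mean`,
#'   `sd`), `variable`.
#' @export
tukey_hsd <- function(series) {
  counts <- table(series$level)
  small <- as.integer(names(counts)[counts < 2])
  if (length(small)) {
    warning("excluding level(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    series <- series[!series$level %in% small, , drop = FALSE]
  }
  lv <- sort(unique(series$level))
  g <- length(lv)
  if (g < 2) stop("Tukey's test needs at least 2 levels with >= 2 observations")
  groups <- split(series$value, series$level)
  ni <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  n_tot <- sum(ni)
  df_err <- n_tot - g
  mse <- sum(vapply(groups, group_ss, numeric(1))) / df_err
  crit <- stats::qtukey(0.95, nmeans = g, df = df_err)
  pairs <- utils::combn(seq_len(g), 2, simplify = FALSE)
  comp <- do.call(rbind, lapply(pairs, function(p) {
    i <- p[1]; j <- p[2]
    hi <- if (means[j] >= means[i]) j else i
    lo <- if (hi == j) i else j
    diff <- means[hi] - means[lo]
    se_diff <- sqrt(mse * (1 / ni[i] + 1 / ni[j]))
    q_stat <- diff / (se_diff / sqrt(2))
    data.frame(pair = paste0(lv[hi], "/", lv[lo]), difference = diff,
               se_difference = se_diff,
               ci_low = diff - crit * se_diff / sqrt(2),
               ci_high = diff + crit * se_diff / sqrt(2),
               p_adjusted = stats::ptukey(q_stat, nmeans = g, df = df_err,
                                          lower.tail = FALSE))
  }))
  rownames(comp) <- NULL
  structure(list(comparisons = comp, mse = mse, df_error = df_err,
                 group_stats = data.frame(level = lv, n = unname(ni),
                                          mean = unname(means),
                                          sd = unname(sds)),
                 variable = attr(series, "variable") %||% NA_character_),
            class = "tukey_summary")
}

#' @export
print.tukey_summary <- function(x, ...) {
  cat(sprintf("Tukey-Kramer comparisons%s (MSE = %.3f, error df = %d)\n",
              if (!is.na(x$variable)) paste0(" for ", x$variable) else "",
              x$mse, x$df_error))
  print(cbind(x$comparisons[1], round(x$comparisons[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' Quadratic trend curve over exposure levels
#'
#' Least-squares fit of the series values on exposure level; by default a
#' quadratic in level, which with the three observed levels reproduces the
#' per-level means exactly. The "nonlinear" association shape between
#' air-pollution mortality strata and a genotype percentage or risk ratio is
#' summarised by the fitted values.
#'
#' @param series A `level_series`.
#' @param degree Polynomial degree (default 2).
#' @return List of class `trend_curve`: `coefficients` (intercept first),
#'   `fitted` (data frame `level`, `fitted`, `group_mean`, `n`),
#'   `residual_ss`, `variable`.
#' @export
trend_curve <- function(series, degree = 2L) {
  if (nrow(series) < degree + 1)
    stop("need more observations than polynomial coefficients")
  fit <- stats::lm(value ~ poly(level, degree, raw = TRUE), data = series)
  lv <- sort(unique(series$level))
  pred <- stats::predict(fit, newdata = data.frame(level = lv))
  groups <- split(series$value, series$level)
  structure(list(
    coefficients = stats::setNames(as.numeric(stats::coef(fit)),
                                   c("intercept", paste0("level^", seq_len(degree)))),
    fitted = data.frame(level = lv, fitted = as.numeric(pred),
                        group_mean = vapply(groups, mean, numeric(1)),
                        n = vapply(groups, length, integer(1))),
    residual_ss = sum(stats::resid(fit)^2),
    variable = attr(series, "variable") %||% NA_character_
  ), class = "trend_curve")
}

#' Case and control trend curves side by side
#'
#' Fits [trend_curve()] to the case and control percentage series of one
#' genotype, returning a long table suitable for overlaying the two curves
#' (the comparison in which a case curve rising above the control curve at
#' high pollution levels signals a gene-environment pattern).
#'
#' @param studies A `study_table`.
#' @param genotype Genotype label (e.g. `"TT"`) or generic role.
#' @param degree Polynomial degree passed through.
#' @return Data frame: `arm`, `level`, `fitted`, `group_mean`, `n`.
#' @export
genotype_trends <- function(studies, genotype, degree = 2L) {
  locus <- studies$locus[1] %||% "C677T"
  role <- resolve_genotype_set(genotype, locus)
  out <- do.call(rbind, lapply(c(case = "ca", ctrl = "ct"), function(a) {
    tc <- trend_curve(build_level_series(studies, paste0(role, "%", a)), degree)
    cbind(data.frame(arm = if (a == "ca") "case" else "ctrl"), tc$fitted)
  }))
  rownames(out) <- NULL
  out
}

#' Heat-map matrix of a series over levels and value bins
#'
#' Cross-tabulates a study-level series into an exposure-level by value-bin
#' matrix, each cell holding the study count (default) or the mean series
#' value of the studies falling in it. Cells with no studies are `NA`
#' (missing, never zero). Colouring is left to the caller.
#'
#' @param studies A `study_table`.
#' @param variable Series label as in [build_level_series()].
#' @param bins Number of equal-width value bins.
#' @param stat `"count"` or `"mean"`.
#' @return Numeric matrix, rows named by level, columns by bin interval.
#' @export
heatmap_matrix <- function(studies, variable, bins = 5L,
                           stat = c("count", "mean")) {
  stat <- match.arg(stat)
  series <- build_level_series(studies, variable)
  rng <- range(series$value)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  bin <- cut(series$value, breaks, include.lowest = TRUE, dig.lab = 4)
  lv <- sort(unique(series$level))
  mat <- matrix(NA_real_, nrow = length(lv), ncol = bins,
                dimnames = list(level = as.character(lv), bin = levels(bin)))
  for (i in seq_along(lv)) {
    for (j in seq_len(bins)) {
      vals <- series$value[series$level == lv[i] & as.integer(bin) == j]
      if (length(vals))
        mat[i, j] <- if (stat == "count") length(vals) else mean(vals)
    }
  }
  mat
}
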