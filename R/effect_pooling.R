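# Genotype-set roles: which function of (hom, het, wild) supplies the
# numerator count. Allele sets use the per-person halved-count convention
# (variant = hom + het/2) with the person-level arm total as denominator;
# the `allele_2n` option rescales to chromosomes (2N), which leaves the risk
# ratio unchanged and halves nothing else of substance.
.set_roles <- c("hom", "het", "wild", "variant_allele", "wild_allele",
                "hom_het", "wild_het")

.set_count <- function(counts, role) {
  switch(role,
    hom = counts[["hom"]],
    het = counts[["het"]],
    wild = counts[["wild"]],
    variant_allele = counts[["hom"]] + counts[["het"]] / 2,
    wild_allele = counts[["wild"]] + counts[["het"]] / 2,
    hom_het = counts[["hom"]] + counts[["het"]],
    wild_het = counts[["wild"]] + counts[["het"]],
    stop("unknown genotype-set role: ", role))
}

#' Genotype-set labels for a locus
#'
#' The seven analysis sets used throughout: the three genotypes, the two
#' alleles, and the two het-combined sets. For C677T these are
#' `TT, CT, CC, T, C, TT+CT, CC+CT`; for A1298C the analogues
#' `CC, AC, AA, C, A, CC+AC, AA+AC`.
#'
#' @param locus `"C677T"` or `"A1298C"`.
#' @return Character vector of the seven labels.
#' @export
genotype_sets <- function(locus = c("C677T", "A1298C")) {
  locus <- match.arg(locus)
  if (locus == "C677T") c("TT", "CT", "CC", "T", "C", "TT+CT", "CC+CT")
  else c("CC", "AC", "AA", "C", "A", "CC+AC", "AA+AC")
}

# Map a user-facing genotype-set label to its role. Generic role names are
# always accepted so A1298C tables can be analysed with locus-free code.
resolve_genotype_set <- function(label, locus = "C677T") {
  if (label %in% .set_roles) return(label)
  key <- toupper(gsub("\\s", "", label))
  map <- if (locus == "C677T") {
    c(TT = "hom", CT = "het", CC = "wild", T = "variant_allele",
      C = "wild_allele", `TT+CT` = "hom_het", `CT+TT` = "hom_het",
      `CC+CT` = "wild_het", `CT+CC` = "wild_het")
  } else {
    c(CC = "hom", AC = "het", AA = "wild", C = "variant_allele",
      A = "wild_allele", `CC+AC` = "hom_het", `AC+CC` = "hom_het",
      `AA+AC` = "wild_het", `AC+AA` = "wild_het")
  }
  if (!key %in% names(map))
    stop(sprintf("unknown genotype set '%s' for locus %s (accepted: %s or roles %s)",
                 label, locus, paste(genotype_sets(locus), collapse = ", "),
                 paste(.set_roles, collapse = ", ")))
  unname(map[key])
}

#' Per-study genotype-vs-total risk ratio
#'
#' The effect measure pooled everywhere in this package: with `a` the case
#' count in the genotype set, `N1` the case total over all three genotypes,
#' and `b`, `N0` the control analogues,
#' `RR = (a/N1) / (b/N0)`, with log-RR variance
#' `1/a - 1/N1 + 1/b - 1/N0`. Allele sets use halved counts
#' (`a = hom + het/2`) against the same person-level totals. When `a` or `b`
#' is zero the Haldane-Anscombe continuity correction adds 0.5 to each cell
#' of that study's 2x2 table (so `a`, `b` gain 0.5 and both totals gain 1)
#' before anything is computed.
#'
#' @param cases,controls Genotype counts `c(hom, het, wild)` for each arm.
#' @param genotype_set A label from [genotype_sets()] or a generic role
#'   (`"hom"`, `"het"`, `"wild"`, `"variant_allele"`, `"wild_allele"`,
#'   `"hom_het"`, `"wild_het"`).
#' @param locus Locus whose labels to interpret; default `"C677T"`.
#' @param correction Apply the zero-cell continuity rule (default `TRUE`).
#' @param study_id Identifier carried into the result.
#' @return One-row data frame: `study_id`, `genotype_set`, `a`, `n_case`,
#'   `b`, `n_ctrl`, `rr`, `log_rr`, `variance`, `ci_low`, `ci_high`,
#'   `corrected`.
#' @examples
#' e <- study_rr(c(10, 20, 70), c(5, 20, 75), "TT")
#' e$rr        # 2
#' e$variance  # 0.28
#' @export
study_rr <- function(cases, controls, genotype_set, locus = "C677T",
                     correction = TRUE, study_id = "study") {
  role <- resolve_genotype_set(genotype_set, locus)
  ca <- as_genotype_counts(cases)
  ct <- as_genotype_counts(controls)
  n1 <- sum(ca); n0 <- sum(ct)
  if (n1 < 1 || n0 < 1) stop("both arm totals must be >= 1")
  a <- .set_count(ca, role)
  b <- .set_count(ct, role)
  corrected <- FALSE
  if ((a == 0 || b == 0)) {
    if (!correction)
      stop("zero count in genotype set '", genotype_set,
           "' and continuity correction disabled")
    a <- a + 0.5; b <- b + 0.5; n1 <- n1 + 1; n0 <- n0 + 1
    corrected <- TRUE
  }
  log_rr <- log((a / n1) / (b / n0))
  v <- 1 / a - 1 / n1 + 1 / b - 1 / n0
  z <- stats::qnorm(0.975)
  data.frame(study_id = study_id, genotype_set = genotype_set,
             a = a, n_case = n1, b = b, n_ctrl = n0,
             rr = exp(log_rr), log_rr = log_rr, variance = v,
             ci_low = exp(log_rr - z * sqrt(v)),
             ci_high = exp(log_rr + z * sqrt(v)),
             corrected = corrected)
}

#' Risk-ratio estimates for every study in a table
#'
#' @param studies A `study_table`.
#' @inheritParams study_rr
#' @return Data frame with one [study_rr()] row per study group.
#' @export
study_effects <- function(studies, genotype_set, correction = TRUE) {
  locus <- studies$locus[1] %||% "C677T"
  out <- do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    study_rr(study_arm(studies[i, ], "case"), study_arm(studies[i, ], "ctrl"),
             genotype_set, locus = locus, correction = correction,
             study_id = studies$study_id[i])
  }))
  rownames(out) <- NULL
  out
}

new_pooled_result <- function(genotype_set, k, model, log_rr, se, q, q_p,
                              i2, tau2, weights, degenerate = FALSE) {
  z <- stats::qnorm(0.975)
  structure(list(
    genotype_set = genotype_set, k = k, model = model,
    log_rr = log_rr, se = se, pooled_rr = exp(log_rr),
    ci95 = c(low = exp(log_rr - z * se), high = exp(log_rr + z * se)),
    p_value = 2 * stats::pnorm(-abs(log_rr / se)),
    q = q, q_p = q_p, i_squared = i2, tau_squared = tau2,
    weights = weights, degenerate = degenerate
  ), class = "pooled_result")
}

.check_effects <- function(effects) {
  if (is.null(effects) || nrow(effects) == 0) stop("no effect estimates to pool")
  if (any(effects$variance <= 0)) stop("all effect variances must be > 0")
  effects
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Pools study log risk ratios with weights `w_i = 1/v_i`; the pooled log-RR
#' is the weighted mean, its standard error `1/sqrt(sum(w))`, and the
#' association p-value a two-sided Wald z test. A single study is returned
#' as-is, flagged degenerate, with no heterogeneity statistics.
#'
#' @param effects Data frame with columns `log_rr` and `variance`
#'   (as from [study_effects()]).
#' @param genotype_set Label recorded in the result.
#' @return A `pooled_result`: `pooled_rr`, `ci95`, `p_value`, `model`, `q`,
#'   `q_p`, `i_squared`, `tau_squared`, `k`, per-study `weights` (percent).
#' @export
pool_fixed <- function(effects, genotype_set = effects$genotype_set[1] %||% "") {
  .check_effects(effects)
  k <- nrow(effects)
  w <- 1 / effects$variance
  theta <- sum(w * effects$log_rr) / sum(w)
  se <- sqrt(1 / sum(w))
  if (k == 1L)
    return(new_pooled_result(genotype_set, 1L, "fixed", effects$log_rr[1],
                             sqrt(effects$variance[1]), NA_real_, NA_real_,
                             NA_real_, 0, c(100), degenerate = TRUE))
  q <- sum(w * (effects$log_rr - theta)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  new_pooled_result(genotype_set, k, "fixed", theta, se, q, q_p,
                    i_squared(q, k), 0,
                    stats::setNames(100 * w / sum(w), effects$study_id))
}

#' Cochran's Q and I-squared
#'
#' Q is the sum of fixed-effect-weighted squared deviations from the pooled
#' log-RR; its p-value comes from the chi-square upper tail with k-1 df.
#'
#' @inheritParams pool_fixed
#' @return List `q`, `q_p`, `i_squared`.
#' @export
cochran_q <- function(effects) {
  .check_effects(effects)
  if (nrow(effects) < 2) stop("Cochran's Q needs at least 2 studies")
  p <- pool_fixed(effects)
  list(q = p$q, q_p = p$q_p, i_squared = p$i_squared)
}

#' I-squared from Q and the study count
#'
#' `I2 = max(0, 100 * (Q - (k-1)) / Q)`, the percent of total variability
#' attributed to between-study heterogeneity.
#'
#' @param q Cochran's Q.
#' @param k Number of studies.
#' @return I-squared, in percent.
#' @examples
#' round(i_squared(67.85, 44), 1)  # 36.6
#' @export
i_squared <- function(q, k) {
  if (q <= 0) return(0)
  max(0, 100 * (q - (k - 1)) / q)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w`; studies are then re-weighted by
#' `1/(v_i + tau2)`. When Q is at or below its df, `tau2 = 0` and the result
#' coincides with the fixed-effect pooling.
#'
#' @inheritParams pool_fixed
#' @return A `pooled_result` with `model = "random"` and the DL `tau_squared`.
#' @export
pool_random <- function(effects, genotype_set = effects$genotype_set[1] %||% "") {
  .check_effects(effects)
  k <- nrow(effects)
  if (k == 1L) {
    out <- pool_fixed(effects, genotype_set)
    out$model <- "random"
    return(out)
  }
  fx <- pool_fixed(effects, genotype_set)
  w <- 1 / effects$variance
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (fx$q - (k - 1)) / c_dl)
  wr <- 1 / (effects$variance + tau2)
  theta <- sum(wr * effects$log_rr) / sum(wr)
  se <- sqrt(1 / sum(wr))
  new_pooled_result(genotype_set, k, "random", theta, se, fx$q, fx$q_p,
                    fx$i_squared, tau2,
                    stats::setNames(100 * wr / sum(wr), effects$study_id))
}

#' Q-driven model selection
#'
#' The default decision rule: heterogeneity is declared when the Q test
#' p-value falls below `threshold` (0.05 unless configured otherwise), in
#' which case the DerSimonian-Laird random-effects model is used; otherwise
#' the fixed-effect model.
#'
#' @inheritParams pool_fixed
#' @param threshold Q-test p-value threshold for switching to random effects.
#' @return A `pooled_result` whose `model` records the choice.
#' @export
pool_auto <- function(effects, genotype_set = effects$genotype_set[1] %||% "",
                      threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  .check_effects(effects)
  if (nrow(effects) < 2) return(pool_fixed(effects, genotype_set))
  fx <- pool_fixed(effects, genotype_set)
  if (!is.na(fx$q_p) && fx$q_p < threshold) pool_random(effects, genotype_set)
  else fx
}

# Flatten a pooled_result into a one-row data frame for report tables.
as_row <- function(x, ...) UseMethod("as_row")

#' @export
as_row.pooled_result <- function(x, ...) {
  data.frame(genotype_set = x$genotype_set, k = x$k, model = x$model,
             rr = x$pooled_rr, ci_low = x$ci95[["low"]],
             ci_high = x$ci95[["high"]], p_value = x$p_value,
             q = x$q, q_p = x$q_p, i_squared = x$i_squared,
             tau_squared = x$tau_squared)
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled RR [%s], k = %d (%s%s): %.3f (95%% CI %.3f, %.3f), p = %.4g\n",
              x$genotype_set, x$k, x$model,
              if (x$degenerate) ", single study" else "",
              x$pooled_rr, x$ci95[["low"]], x$ci95[["high"]], x$p_value))
  if (!is.na(x$q))
    cat(sprintf("  Q = %.2f (p = %.4g), I2 = %.1f%%, tau2 = %.4f\n",
                x$q, x$q_p, x$i_squared, x$tau_squared))
  invisible(x)
}

# Country-level pooled RRs and the {>1, <1, ~1} direction classes.
country_risk_classes <- function(studies, genotype_set, threshold = 0.05,
                                 rr_band = c(0.95, 1.05)) {
  countries <- unique(studies$country)
  rr <- vapply(countries, function(co) {
    pool_auto(study_effects(studies[studies$country == co, , drop = FALSE],
                            genotype_set),
              genotype_set, threshold)$pooled_rr
  }, numeric(1))
  cls <- ifelse(rr > rr_band[2], "RR>1", ifelse(rr < rr_band[1], "RR<1", "RR~1"))
  data.frame(country = countries, pooled_rr = rr, class = cls,
             row.names = NULL)
}

#' Subgroup pooling
#'
#' Pools one genotype set within each level of a grouping variable via
#' [pool_auto()]. The `risk_direction` grouping first pools within each
#' country, assigns countries to the classes RR>1, RR<1 or RR~1 (the last
#' defined as pooled RR inside `rr_band`), and then pools studies within each
#' class. Levels with no studies are omitted with a warning.
#'
#' @param studies A `study_table`.
#' @param grouping One of `"ethnicity"`, `"country"`, `"ap_death_level"`,
#'   `"quality_band"` (bands low `[0,10)`, medium `[10,20)`, high `[20,29]`),
#'   `"risk_direction"`.
#' @inheritParams study_rr
#' @inheritParams pool_auto
#' @param rr_band RR interval defining the "varied around 1" country class.
#' @return Data frame of pooled rows, one per subgroup level, with columns
#'   `grouping` and `level` prepended.
#' @export
subgroup_pool <- function(studies, grouping = c("ethnicity", "country",
                                                "ap_death_level",
                                                "quality_band",
                                                "risk_direction"),
                          genotype_set, threshold = 0.05,
                          rr_band = c(0.95, 1.05)) {
  grouping <- match.arg(grouping)
  fac <- switch(grouping,
    ethnicity = studies$ethnicity,
    country = studies$country,
    ap_death_level = as.character(studies$ap_death_level),
    quality_band = as.character(cut(studies$quality_score, c(0, 10, 20, 29),
                                    labels = c("low", "medium", "high"),
                                    include.lowest = TRUE, right = FALSE)),
    risk_direction = {
      cls <- country_risk_classes(studies, genotype_set, threshold, rr_band)
      cls$class[match(studies$country, cls$country)]
    })
  keep <- !is.na(fac)
  if (!all(keep))
    warning(sum(!keep), " studies lack '", grouping, "' and were omitted")
  studies <- studies[keep, , drop = FALSE]
  fac <- fac[keep]
  if (nrow(studies) == 0) stop("no studies carry '", grouping, "'")
  levels_present <- unique(fac)
  out <- do.call(rbind, lapply(levels_present, function(lv) {
    sub <- studies[fac == lv, , drop = FALSE]
    row <- as_row(pool_auto(study_effects(sub, genotype_set),
                            genotype_set, threshold))
    cbind(data.frame(grouping = grouping, level = lv), row)
  }))
  rownames(out) <- NULL
  out
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the genotype set k times, omitting one study each time, and once
#' more omitting all vascular-AD-flagged studies (when any are flagged) --
#' the study-level influence checks used to assess the stability of a pooled
#' result.
#'
#' @inheritParams subgroup_pool
#' @return List: `full` (the all-studies `pooled_result`), `loo` (data frame,
#'   one row per omitted study), `without_vascular` (a `pooled_result`, or
#'   `NULL` when no study is flagged).
#' @export
leave_one_out <- function(studies, genotype_set, threshold = 0.05) {
  if (nrow(studies) < 2) stop("leave-one-out needs at least 2 studies")
  effects <- study_effects(studies, genotype_set)
  full <- pool_auto(effects, genotype_set, threshold)
  loo <- do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    row <- as_row(pool_auto(effects[-i, , drop = FALSE], genotype_set, threshold))
    cbind(data.frame(omitted = studies$study_id[i]), row)
  }))
  rownames(loo) <- NULL
  without_vascular <- NULL
  if (any(studies$vascular_ad)) {
    keep <- !studies$vascular_ad
    if (sum(keep) >= 1)
      without_vascular <- pool_auto(effects[keep, , drop = FALSE],
                                    genotype_set, threshold)
  }
  list(full = full, loo = loo, without_vascular = without_vascular)
}

#' Forest-plot data export
#'
#' Per-study RR, 95% CI and model weight (percent), plus a final pooled row,
#' in plotting order. Rendering is left to the caller.
#'
#' @inheritParams subgroup_pool
#' @return Data frame: `study_id`, `rr`, `ci_low`, `ci_high`, `weight_pct`,
#'   `pooled` (logical marker for the summary row).
#' @export
forest_data <- function(studies, genotype_set, threshold = 0.05) {
  effects <- study_effects(studies, genotype_set)
  pooled <- pool_auto(effects, genotype_set, threshold)
  out <- data.frame(study_id = effects$study_id, rr = effects$rr,
                    ci_low = effects$ci_low, ci_high = effects$ci_high,
                    weight_pct = unname(pooled$weights[effects$study_id]),
                    pooled = FALSE)
  rbind(out, data.frame(study_id = sprintf("(pooled, %s)", pooled$model),
                        rr = pooled$pooled_rr, ci_low = pooled$ci95[["low"]],
                        ci_high = pooled$ci95[["high"]], weight_pct = 100,
                        pooled = TRUE))
}
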