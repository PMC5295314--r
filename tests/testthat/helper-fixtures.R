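# Builders for small in-code fixtures.

# Study table from row-wise count triples (hom, het, wild).
make_studies <- function(case, ctrl, country = "X", ethnicity = "Caucasian",
                         ap_death_level = NA, vascular_ad = FALSE,
                         quality = NA, locus = "C677T") {
  case <- matrix(case, ncol = 3, byrow = TRUE)
  ctrl <- matrix(ctrl, ncol = 3, byrow = TRUE)
  n <- nrow(case)
  df <- data.frame(
    study_id = sprintf("T%02d", seq_len(n)),
    country = rep_len(country, n),
    ethnicity = rep_len(ethnicity, n),
    case_hom = case[, 1], case_het = case[, 2], case_wild = case[, 3],
    ctrl_hom = ctrl[, 1], ctrl_het = ctrl[, 2], ctrl_wild = ctrl[, 3],
    ap_death_level = rep_len(ap_death_level, n),
    quality_score = rep_len(quality, n),
    vascular_ad = rep_len(vascular_ad, n),
    hwe_reported = NA)
  validate_studies(df, locus = locus)
}

make_effects <- function(log_rr, variance, genotype_set = "TT") {
  data.frame(study_id = sprintf("T%02d", seq_along(log_rr)),
             genotype_set = rep_len(genotype_set, length(log_rr)),
             rr = exp(log_rr),
             log_rr = log_rr, variance = variance)
}

make_series <- function(level, value) {
  out <- data.frame(study_id = sprintf("T%02d", seq_along(level)),
                    level = as.integer(level), value = value)
  class(out) <- c("level_series", "data.frame")
  out
}

# Independent enumeration oracle for the one-split partition: brute force
# over every contiguous split of the ordered levels.
brute_force_split <- function(level, value) {
  lv <- sort(unique(level))
  best <- NULL
  for (i in seq_len(length(lv) - 1)) {
    left <- lv[seq_len(i)]
    inl <- level %in% left
    sse <- sum((value[inl] - mean(value[inl]))^2) +
      sum((value[!inl] - mean(value[!inl]))^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(left = left, sse = sse)
  }
  best
}

# HWE multinomial draw at allele frequency q.
draw_hwe_controls <- function(n, q) {
  stats::rmultinom(1, n, c(q^2, 2 * q * (1 - q), (1 - q)^2))[, 1]
}
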