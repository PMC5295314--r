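#' Egger regression test for funnel asymmetry
#'
#' Classic form: ordinary least squares of the standardized effect
#' `log_rr / SE` on the precision `1 / SE`; the intercept estimates funnel
#' asymmetry and is tested against zero with a two-sided t test on k - 2 df.
#' A p-value below 0.05 is conventionally read as significant publication
#' bias. The `weighted` variant fits the algebraically equivalent
#' `log_rr ~ SE` regression with weights `1/variance`, reporting the
#' coefficient on SE as the asymmetry term.
#'
#' @param effects Data frame with `log_rr` and `variance` columns
#'   (as from [study_effects()]).
#' @param weighted Use the weighted-regression parameterisation.
#' @return List of class `egger_result`: `intercept`, `intercept_se`,
#'   `t_statistic`, `p_value`, `k`, `slope`, `degenerate` (`TRUE` when all
#'   standard errors coincide, leaving asymmetry unidentifiable).
#' @export
egger_test <- function(effects, weighted = FALSE) {
  .check_effects(effects)
  k <- nrow(effects)
  if (k < 3) stop("Egger's test needs at least 3 studies")
  se <- sqrt(effects$variance)
  degenerate <- stats::sd(se) < 1e-12
  if (degenerate) {
    return(structure(list(intercept = NA_real_, intercept_se = NA_real_,
                          t_statistic = NA_real_, p_value = NA_real_,
                          k = k, slope = NA_real_, degenerate = TRUE),
                     class = "egger_result"))
  }
  fit <- if (weighted) {
    f <- stats::lm(effects$log_rr ~ se, weights = 1 / effects$variance)
    # asymmetry term is the coefficient on SE in this parameterisation
    s <- summary(f)$coefficients
    list(est = s["se", "Estimate"], se = s["se", "Std. Error"],
         slope = s["(Intercept)", "Estimate"])
  } else {
    f <- stats::lm(I(effects$log_rr / se) ~ I(1 / se))
    s <- summary(f)$coefficients
    list(est = s["(Intercept)", "Estimate"], se = s["(Intercept)", "Std. Error"],
         slope = s[2, "Estimate"])
  }
  t_stat <- fit$est / fit$se
  p <- 2 * stats::pt(-abs(t_stat), df = k - 2)
  structure(list(intercept = fit$est, intercept_se = fit$se,
                 t_statistic = t_stat, p_value = p, k = k,
                 slope = fit$slope, degenerate = FALSE),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  if (x$degenerate)
    cat("Egger's test: degenerate (all study SEs identical)\n")
  else
    cat(sprintf("Egger intercept = %.4f (SE %.4f), t = %.3f, p = %.4g (k = %d)\n",
                x$intercept, x$intercept_se, x$t_statistic, x$p_value, x$k))
  invisible(x)
}

#' Funnel-plot data export
#'
#' Per-study points (log-RR against standard error) plus the fixed-effect
#' pooled vertical line and pseudo-95% confidence bounds
#' `pooled +/- 1.959964 * SE` over an SE grid. Rendering is left to the
#' caller; an asymmetric spread of points about the pooled line suggests
#' publication bias.
#'
#' @inheritParams egger_test
#' @param grid_n Number of SE grid points for the bounds.
#' @return List of class `funnel_data`: `points` (data frame `study_id`,
#'   `rr`, `log_rr`, `se`, `side`), `pooled_log_rr`, `pooled_rr`, `bounds`
#'   (data frame `se`, `lower`, `upper` on the log scale).
#' @export
funnel_data <- function(effects, grid_n = 50L) {
  .check_effects(effects)
  se <- sqrt(effects$variance)
  pooled <- pool_fixed(effects)$log_rr
  z <- stats::qnorm(0.975)
  grid <- seq(0, max(se) * 1.05, length.out = grid_n)
  structure(list(
    points = data.frame(study_id = effects$study_id, rr = effects$rr,
                        log_rr = effects$log_rr, se = se,
                        side = ifelse(effects$log_rr >= pooled, "right", "left")),
    pooled_log_rr = pooled, pooled_rr = exp(pooled),
    bounds = data.frame(se = grid, lower = pooled - z * grid,
                        upper = pooled + z * grid)
  ), class = "funnel_data")
}
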