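# Cohort-level statistics: age-adjusted group comparison of the fitted
# parameters (LS-means, Bonferroni over the 7-parameter family, Cohen's
# D) and cognition regressions.

#' Cohen's D (patient minus control, pooled SD)
#'
#' @param x values for the patient group.
#' @param y values for the control group.
#' @return standardized mean difference.
#' @export
cohen_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

check_cohort <- function(table, need = c("group", "age")) {
  stopifnot(is.data.frame(table), all(need %in% names(table)))
  g <- table$group
  if (!all(g %in% c("control", "patient")))
    stop("group must be 'control' or 'patient'")
  if (any(!is.finite(table$age)) || any(table$age <= 0))
    stop("ages must be finite and positive")
  counts <- table(factor(g, levels = c("control", "patient")))
  if (any(counts < 3)) stop("each group needs at least 3 subjects")
  invisible(table)
}

#' Age-adjusted group comparison of fitted SGM parameters
#'
#' For each of the 7 parameters fits `value ~ group + age` by OLS,
#' reports least-squares means per group (model predictions at the
#' pooled mean age) with 95% CIs, the t test on the group coefficient,
#' Bonferroni-corrected p (x7), and Cohen's D on the raw values
#' (patient minus control; set `d_on_residuals = TRUE` to compute it on
#' age-adjusted residuals instead).
#'
#' @param table cohort data.frame with columns `group`
#'   (`control`/`patient`), `age` and the 7 parameter columns.
#' @param params parameter column names (default the canonical 7).
#' @param d_on_residuals compute Cohen's D on age-residualized values.
#' @return data.frame of class `group_stats`, one row per parameter.
#' @export
group_compare <- function(table, params = SGM_PARAM_NAMES,
                          d_on_residuals = FALSE) {
  check_cohort(table, need = c("group", "age", params))
  table$group <- factor(table$group, levels = c("control", "patient"))
  mean_age <- mean(table$age)
  nfam <- length(params)
  rows <- lapply(params, function(pn) {
    d <- data.frame(y = table[[pn]], group = table$group, age = table$age)
    fit <- lm(y ~ group + age, data = d)
    sm <- summary(fit)$coefficients
    tstat <- sm["grouppatient", "t value"]
    p_raw <- sm["grouppatient", "Pr(>|t|)"]
    nd <- data.frame(group = factor(c("control", "patient"),
                                    levels = levels(d$group)),
                     age = mean_age)
    ci <- predict(fit, nd, interval = "confidence", level = 0.95)
    yv <- if (d_on_residuals) residuals(lm(y ~ age, data = d)) else d$y
    data.frame(param = pn,
               lsmean_control = ci[1, "fit"], ci_lo_control = ci[1, "lwr"],
               ci_hi_control = ci[1, "upr"],
               lsmean_patient = ci[2, "fit"], ci_lo_patient = ci[2, "lwr"],
               ci_hi_patient = ci[2, "upr"],
               t = tstat, p_raw = p_raw,
               p_bonferroni = min(1, nfam * p_raw),
               cohen_d = cohen_d(yv[d$group == "patient"],
                                 yv[d$group == "control"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_stats", class(out))
  out
}

#' Associations between SGM parameters and cognition
#'
#' Univariate mode regresses the cognition score on each parameter in
#' `params` separately (within the patient group by default, where the
#' scores are defined), Bonferroni-corrected over the family.
#' Multivariate mode fits a single model with all `params` plus age and
#' reports per-predictor p values, multiple r, adjusted r-squared and F.
#'
#' @param table cohort data.frame.
#' @param score cognition column name (`"mmse"` or `"cdr_sob"`).
#' @param mode `"univariate"` or `"multivariate"`.
#' @param params predictor parameter names (default `tau_G`, `tau_e`,
#'   `g_ii`, the group-discriminating parameters).
#' @param group restrict to one group (`"patient"` default; `NULL` for
#'   all subjects).
#' @return univariate: data.frame with slope, r, p_raw, p_bonferroni per
#'   parameter; multivariate: list with coefficient table, `model_r`,
#'   `adj_r2`, `F`, `p_model`.
#' @export
regress_cognition <- function(table, score = "mmse",
                              mode = c("univariate", "multivariate"),
                              params = c("tau_G", "tau_e", "g_ii"),
                              group = "patient") {
  mode <- match.arg(mode)
  stopifnot(score %in% names(table), all(params %in% names(table)))
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  table <- table[is.finite(table[[score]]), , drop = FALSE]
  if (nrow(table) < 10)
    stop("cognition scores present for fewer than 10 subjects")
  if (mode == "univariate") {
    nfam <- length(params)
    rows <- lapply(params, function(pn) {
      fit <- lm(table[[score]] ~ table[[pn]])
      sm <- summary(fit)
      p <- sm$coefficients[2, "Pr(>|t|)"]
      data.frame(param = pn, slope = coef(fit)[2],
                 r = sign(coef(fit)[2]) * sqrt(sm$r.squared),
                 p_raw = p, p_bonferroni = min(1, nfam * p),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else {
    fml <- stats::reformulate(c(params, "age"), response = score)
    fit <- lm(fml, data = table)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    list(coefficients = as.data.frame(sm$coefficients),
         model_r = sqrt(sm$r.squared),
         adj_r2 = sm$adj.r.squared,
         F = unname(fstat["value"]),
         p_model = unname(pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                             lower.tail = FALSE)))
  }
}
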