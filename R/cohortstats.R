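# Cohort-level statistics: soft/bone ratios, side comparisons, prediction
# models, normative comparison, reliability, normality.

#' Validate / construct a cohort table
#'
#' One record per (patient, side) with the measured quantities the
#' statistical analysis consumes.
#'
#' @param data a data.frame with columns `patient`, `side` ("L"/"R"),
#'   `soft_movement` (Y, mm), `bone_advancement` (X1, mm), `rotation`
#'   (X2, degrees), and optionally `cheek_position` (mm) and `stratum`.
#' @return the validated data.frame with class `cohort_table`; a missing
#'   `stratum` column is filled from [stratify_advancement()] of X1.
#' @export
cohort_table <- function(data) {
  need <- c("patient", "side", "soft_movement", "bone_advancement", "rotation")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    stop("cohort table missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(data$side %in% c("L", "R"))) stop("side must be 'L' or 'R'")
  if (is.null(data$stratum)) {
    data$stratum <- stratify_advancement(data$bone_advancement)
  }
  class(data) <- c("cohort_table", "data.frame")
  data
}

#' Soft-to-bone sagittal movement ratio
#'
#' Per-record ratio of the cheek soft-tissue movement to the maxillary bone
#' advancement, summarised per side and pooled.
#'
#' @param table a [cohort_table()].
#' @return data.frame with rows "R", "L", "Total" and columns `n`, `mean`,
#'   `sd` of the per-side ratios.
#' @export
soft_bone_ratio <- function(table) {
  table <- cohort_table(table)
  if (any(table$bone_advancement <= 0)) {
    bad <- which(table$bone_advancement <= 0)[1]
    stop(sprintf(
      "bone advancement must be positive (patient %s, side %s)",
      table$patient[bad], table$side[bad]
    ))
  }
  ratio <- table$soft_movement / table$bone_advancement
  summarise <- function(r) c(n = length(r), mean = mean(r), sd = sd(r))
  out <- rbind(
    R = summarise(ratio[table$side == "R"]),
    L = summarise(ratio[table$side == "L"]),
    Total = summarise(ratio)
  )
  data.frame(region = rownames(out), out, row.names = NULL)
}

#' Right-left side comparison
#'
#' Two-sided two-sample (Welch) t-test of the per-patient right-side values
#' against the left-side values of a measured variable.
#'
#' @param table a [cohort_table()].
#' @param variable column to compare (default `"soft_movement"`).
#' @return list with `t`, `df`, `p_value`, `mean_right`, `mean_left`.
#' @export
side_comparison <- function(table, variable = "soft_movement") {
  table <- cohort_table(table)
  x <- table[[variable]][table$side == "R"]
  y <- table[[variable]][table$side == "L"]
  if (length(x) < 2L || length(y) < 2L) {
    stop("side comparison needs at least 2 patients")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate but well-defined: identical constant sides
    t_stat <- if (mean(x) == mean(y)) 0 else Inf
    return(list(t = t_stat, df = NA_real_,
                p_value = if (t_stat == 0) 1 else 0,
                mean_right = mean(x), mean_left = mean(y)))
  }
  ht <- t.test(x, y)
  list(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_right = mean(x), mean_left = mean(y)
  )
}

#' Fit the soft-tissue prediction model
#'
#' Zero-intercept least-squares regression of the cheek soft-tissue
#' sagittal movement Y on the maxillary advancement X1 (mm) and rotation
#' X2 (degrees), matching the published two-term model form
#' Y = b1*X1 + b2*X2. The coefficient of determination is reported as the
#' squared Pearson correlation between observed and fitted Y (not the
#' uncentred sum-of-squares ratio, which is inflated for no-intercept
#' fits). Partial R-squared per predictor is the squared partial
#' correlation between the response and that predictor given the other.
#'
#' @param table a [cohort_table()].
#' @param region `"Total"`, `"R"` or `"L"`: which sides enter the fit.
#' @param intercept include an intercept (default `FALSE`; sensitivity
#'   analysis only).
#' @param interaction additionally report the p-value of an X1*X2 product
#'   term fitted alongside the main effects (the term is not part of the
#'   returned model).
#' @return object of class `prediction_model`: `coefficients` (b1, b2),
#'   `r_squared`, `partial_r2` (named, X1 and X2), `p_values`, `n`,
#'   `region`, `fitted`, `observed`, and optionally `interaction_p`.
#' @export
fit_prediction_model <- function(table, region = c("Total", "R", "L"),
                                 intercept = FALSE, interaction = FALSE) {
  region <- match.arg(region)
  table <- cohort_table(table)
  if (region != "Total") table <- table[table$side == region, , drop = FALSE]
  Y <- table$soft_movement
  X1 <- table$bone_advancement
  X2 <- table$rotation
  n <- length(Y)
  if (n < 10L) stop("prediction model needs at least 10 records")
  X <- cbind(X1, X2)
  if (kappa(crossprod(X)) > 1e8) stop("predictors are collinear")

  fml <- if (intercept) Y ~ X1 + X2 else Y ~ 0 + X1 + X2
  fit <- lm(fml)
  # summary.lm warns on numerically perfect fits (noiseless simulations)
  sm <- suppressWarnings(summary(fit))
  b <- coef(fit)
  fitted_y <- fitted(fit)

  r2 <- if (sd(fitted_y) == 0 || sd(Y) == 0) 0 else cor(Y, fitted_y)^2

  # squared partial correlation of Y with each predictor given the other
  partial_r2 <- c(
    X1 = cor(residuals(lm(Y ~ X2)), residuals(lm(X1 ~ X2)))^2,
    X2 = cor(residuals(lm(Y ~ X1)), residuals(lm(X2 ~ X1)))^2
  )
  pvals <- sm$coefficients[c("X1", "X2"), "Pr(>|t|)"]

  out <- list(
    coefficients = c(b1 = unname(b["X1"]), b2 = unname(b["X2"])),
    intercept = if (intercept) unname(b["(Intercept)"]) else 0,
    r_squared = r2,
    partial_r2 = partial_r2,
    p_values = c(X1 = unname(pvals[1]), X2 = unname(pvals[2])),
    n = n,
    region = region,
    observed = Y,
    fitted = as.numeric(fitted_y)
  )
  if (interaction) {
    fml_i <- if (intercept) Y ~ X1 * X2 else Y ~ 0 + X1 + X2 + X1:X2
    fit_i <- lm(fml_i)
    pi <- summary(fit_i)$coefficients
    out$interaction_p <- unname(pi["X1:X2", "Pr(>|t|)"])
  }
  structure(out, class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf(
    "<prediction_model> %s region (n = %d)\n  Y = %.3f X1 + %.3f X2%s\n  R^2 = %.3f, partial R^2 (X1, X2) = %.3f, %.3f\n",
    x$region, x$n, x$coefficients["b1"], x$coefficients["b2"],
    if (x$intercept != 0) sprintf(" %+.3f", x$intercept) else "",
    x$r_squared, x$partial_r2["X1"], x$partial_r2["X2"]
  ))
  invisible(x)
}

#' Multiple correlation coefficient of a fitted prediction model
#'
#' @param model a `prediction_model`.
#' @return r, the correlation between observed and fitted response
#'   (`sqrt` of the model's R-squared).
#' @export
multiple_correlation <- function(model) {
  sqrt(model$r_squared)
}

#' Welch t-test against a published normative summary
#'
#' @param group_mean,group_sd,group_n summary of the measured stratum.
#' @param norm_mean,norm_sd,norm_n summary of the normative cohort
#'   (defaults: the healthy-norm cheek-mass position 2.145 +/- 1.201 mm,
#'   n = 60).
#' @return list with `difference` (group - norm), `t`, `df`, `p_value` and
#'   the summaries.
#' @export
norm_comparison_summary <- function(group_mean, group_sd, group_n,
                                    norm_mean = 2.145, norm_sd = 1.201,
                                    norm_n = 60) {
  if (group_n < 2L) stop("stratum needs at least 2 sides")
  se2 <- group_sd^2 / group_n + norm_sd^2 / norm_n
  t_stat <- (group_mean - norm_mean) / sqrt(se2)
  df <- se2^2 / (
    (group_sd^2 / group_n)^2 / (group_n - 1) +
    (norm_sd^2 / norm_n)^2 / (norm_n - 1)
  )
  p <- 2 * pt(-abs(t_stat), df)
  list(
    difference = group_mean - norm_mean,
    t = t_stat, df = df, p_value = p,
    group = c(mean = group_mean, sd = group_sd, n = group_n),
    norm = c(mean = norm_mean, sd = norm_sd, n = norm_n)
  )
}

#' Compare a stratum's cheek-mass position with the healthy norm
#'
#' Welch two-sample t-test from summary statistics of the selected
#' advancement stratum against the published normative mean/SD.
#'
#' @param table a [cohort_table()] with a `cheek_position` column.
#' @param stratum one of [advancement_strata()].
#' @param norm_mean,norm_sd,norm_n normative summary (defaults
#'   2.145, 1.201, 60).
#' @return object of class `norm_comparison`: the stratum label plus the
#'   fields of [norm_comparison_summary()].
#' @export
norm_comparison <- function(table, stratum, norm_mean = 2.145,
                            norm_sd = 1.201, norm_n = 60) {
  table <- cohort_table(table)
  if (is.null(table$cheek_position)) {
    stop("cohort table has no cheek_position column")
  }
  vals <- table$cheek_position[table$stratum == stratum]
  if (length(vals) < 2L) stop("stratum '", stratum, "' has fewer than 2 sides")
  out <- norm_comparison_summary(mean(vals), sd(vals), length(vals),
                                 norm_mean, norm_sd, norm_n)
  out$stratum <- stratum
  structure(out, class = "norm_comparison")
}

#' @export
print.norm_comparison <- function(x, ...) {
  cat(sprintf(
    "<norm_comparison> %s: group %.3f +/- %.3f (n=%d) vs norm %.3f +/- %.3f (n=%d)\n  difference %+.3f mm, t = %.3f (df %.1f), p = %.4f\n",
    if (is.null(x$stratum)) "summary" else x$stratum,
    x$group["mean"], x$group["sd"], x$group["n"],
    x$norm["mean"], x$norm["sd"], x$norm["n"],
    x$difference, x$t, x$df, x$p_value
  ))
  invisible(x)
}

#' Intraclass correlation for absolute agreement (two-way random effects)
#'
#' Single-measure ICC(2,1): two-way random-effects ANOVA with absolute
#' agreement, computed from the standard mean-squares decomposition of a
#' raters x targets table.
#'
#' @param ratings numeric matrix, rows = targets (subjects), columns =
#'   raters (or repeated measurements).
#' @return list with `icc`, the mean squares (`ms_rows`, `ms_cols`,
#'   `ms_error`), `n` (targets) and `k` (raters).
#' @export
icc_absolute_agreement <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings must have no missing cells")
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 raters")
  if (n < 5L) stop("need at least 5 targets")
  if (var(as.numeric(m)) == 0) stop("ICC undefined for constant ratings")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_error / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, ms_rows = msr, ms_cols = msc, ms_error = mse,
       n = n, k = k)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the values against a normal distribution
#' with the sample mean and SD, with the asymptotic p-value.
#'
#' @param values numeric vector (n >= 5, non-constant).
#' @return list with `statistic` and `p_value`.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("normality check needs at least 5 values")
  if (sd(values) == 0) stop("normality check undefined for constant values")
  ht <- suppressWarnings(
    ks.test(values, "pnorm", mean(values), sd(values), exact = FALSE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Qualitative strength of a Pearson correlation
#'
#' Bins |r| as weak (< 0.3), moderate (0.3 to < 0.6), strong (0.6 to 0.8)
#' or extremely strong (> 0.8).
#'
#' @param r correlation coefficient(s), |r| <= 1.
#' @return character vector of labels.
#' @export
pearson_strength_label <- function(r) {
  a <- abs(r)
  if (any(a > 1 + 1e-12, na.rm = TRUE)) stop("|r| must not exceed 1")
  ifelse(a < 0.3, "weak",
    ifelse(a < 0.6, "moderate",
      ifelse(a <= 0.8, "strong", "extremely strong")
    )
  )
}
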