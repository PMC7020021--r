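make_table <- function(Y, X1, X2, side = NULL, position = NULL) {
  n <- length(Y)
  df <- data.frame(
    patient = rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)],
    side = if (is.null(side)) rep(c("L", "R"), length.out = n) else side,
    soft_movement = Y, bone_advancement = X1, rotation = X2
  )
  if (!is.null(position)) df$cheek_position <- position
  cohort_table(df)
}

test_that("soft/bone ratios reduce to exact values in constructed tables", {
  tab <- make_table(Y = c(2, 2, 3, 3), X1 = c(2, 2, 3, 3), X2 = 0)
  r <- soft_bone_ratio(tab)
  expect_equal(r$mean, c(1, 1, 1))
  expect_equal(r$sd, c(0, 0, 0))

  tab2 <- make_table(Y = c(1, 2), X1 = c(2, 4), X2 = 0)
  r2 <- soft_bone_ratio(tab2)
  expect_equal(r2$mean[r2$region == "Total"], 0.5)
  expect_equal(r2$sd[r2$region == "Total"], 0)

  tab_bad <- make_table(Y = c(1, 2), X1 = c(0, 4), X2 = 0)
  expect_error(soft_bone_ratio(tab_bad), "positive")
})

test_that("side comparison matches the textbook Welch formula", {
  set.seed(8)
  n <- 6
  right <- rnorm(n, 2, 0.5)
  left <- rnorm(n, 2.2, 0.4)
  tab <- make_table(
    Y = as.numeric(rbind(left, right)), X1 = 3, X2 = 0,
    side = rep(c("L", "R"), n)
  )
  sc <- side_comparison(tab, "soft_movement")
  o <- oracle_welch(mean(right), sd(right), n, mean(left), sd(left), n)
  expect_equal(sc$t, o$t, tolerance = 1e-9)
  expect_equal(sc$p_value, o$p, tolerance = 1e-9)

  # identical sides: no difference at all
  tab_id <- make_table(Y = rep(c(1, 2, 3), each = 2), X1 = 3, X2 = 0,
                       side = rep(c("L", "R"), 3))
  sc_id <- side_comparison(tab_id, "soft_movement")
  expect_equal(sc_id$t, 0)
  expect_equal(sc_id$p_value, 1)
})

test_that("symmetric cohorts rarely show a significant side difference", {
  hits <- 0L
  for (seed in 1:20) {
    tab <- generate_cohort(cohort_spec(seed = seed), mode = "fast")
    p <- side_comparison(tab, "soft_movement")$p_value
    if (p <= 0.05) hits <- hits + 1L
    expect_gt(side_comparison(tab, "bone_advancement")$p_value, 0.05)
  }
  expect_lte(hits, 1L)  # >= 95 % of replicates non-significant
})

test_that("the prediction model recovers exact coefficients on noiseless data", {
  set.seed(4)
  X1 <- runif(20, 1, 5)
  X2 <- runif(20, 0, 8)
  Y <- 0.6 * X1 + 0.1 * X2
  m <- fit_prediction_model(make_table(Y, X1, X2))
  expect_equal(unname(m$coefficients["b1"]), 0.6, tolerance = 1e-9)
  expect_equal(unname(m$coefficients["b2"]), 0.1, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_equal(multiple_correlation(m), 1, tolerance = 1e-9)
})

test_that("a single active predictor yields the identity fit", {
  X1 <- c(1, 2, 3, 1.5, 2.5, 3.5, 1.2, 2.2, 3.2, 2.8)
  m <- fit_prediction_model(make_table(Y = X1, X1 = X1, X2 = 0.001 * rev(X1)))
  expect_equal(unname(m$coefficients["b1"]), 1, tolerance = 1e-6)
  expect_equal(unname(m$coefficients["b2"]), 0, tolerance = 1e-3)
})

test_that("coefficients equal the closed-form normal-equations solution", {
  for (seed in 51:53) {
    set.seed(seed)
    X1 <- runif(30, 1, 5)
    X2 <- pmax(0, rnorm(30, 3.3, 2.3))
    Y <- 0.627 * X1 + 0.07 * X2 + rnorm(30, 0, 0.3)
    m <- fit_prediction_model(make_table(Y, X1, X2))
    X <- cbind(X1, X2)
    b <- solve(crossprod(X), crossprod(X, Y))  # explicit 2x2 solve
    expect_equal(unname(m$coefficients["b1"]), b[1], tolerance = 1e-10)
    expect_equal(unname(m$coefficients["b2"]), b[2], tolerance = 1e-10)
    expect_true(m$r_squared >= 0 && m$r_squared <= 1)
    expect_true(all(m$partial_r2 >= 0 & m$partial_r2 <= 1))
  }
})

test_that("collinear predictors and tiny tables are rejected", {
  X1 <- runif(12, 1, 5)
  expect_error(fit_prediction_model(make_table(Y = X1, X1 = X1, X2 = 2 * X1)),
               "collinear")
  expect_error(fit_prediction_model(make_table(Y = 1:4, X1 = 1:4, X2 = 4:1)),
               "at least 10")
})

test_that("multiple correlation is the square root of R-squared", {
  m <- list(r_squared = 0.788)
  class(m) <- "prediction_model"
  expect_equal(multiple_correlation(m), sqrt(0.788))
  expect_equal(round(multiple_correlation(m), 3), 0.888)
  m$r_squared <- 0
  expect_equal(multiple_correlation(m), 0)
})

test_that("normative comparison difference and Welch test match the oracle", {
  nc <- norm_comparison_summary(1.491, 0.607, 34)
  expect_equal(nc$difference, 1.491 - 2.145)
  o <- oracle_welch(1.491, 0.607, 34, 2.145, 1.201, 60)
  expect_equal(nc$t, o$t, tolerance = 1e-9)
  expect_equal(nc$df, o$df, tolerance = 1e-9)
  expect_equal(nc$p_value, o$p, tolerance = 1e-9)

  # group identical to the norm summary
  nc0 <- norm_comparison_summary(2.145, 1.201, 60)
  expect_equal(nc0$difference, 0)
  expect_equal(nc0$p_value, 1)
})

test_that("norm comparison runs per stratum on a cohort table", {
  tab <- generate_cohort(cohort_spec(seed = 3), mode = "fast")
  nc <- norm_comparison(tab, "2-3 mm")
  vals <- tab$cheek_position[tab$stratum == "2-3 mm"]
  expect_equal(unname(nc$group["n"]), 34)
  expect_equal(nc$difference, mean(vals) - 2.145, tolerance = 1e-12)
  expect_error(norm_comparison(tab, "nonexistent"), "fewer than 2")
})

test_that("ICC(2,1) behaves as the variance decomposition requires", {
  set.seed(14)
  target <- rnorm(40, 10, 3)
  dup <- cbind(target, target)
  expect_equal(icc_absolute_agreement(dup)$icc, 1, tolerance = 1e-12)

  # adding a common constant to all cells leaves the ICC unchanged
  noisy <- cbind(target + rnorm(40, 0, 1), target + rnorm(40, 0, 1))
  expect_equal(icc_absolute_agreement(noisy + 5)$icc,
               icc_absolute_agreement(noisy)$icc, tolerance = 1e-9)

  # target variance 9x the error variance gives ICC near 0.9
  set.seed(15)
  t2 <- rnorm(400, 0, 3)
  r2 <- cbind(t2 + rnorm(400), t2 + rnorm(400))
  expect_equal(icc_absolute_agreement(r2)$icc, 0.9, tolerance = 0.03)

  expect_error(icc_absolute_agreement(matrix(1, 10, 2)), "constant")
  expect_error(icc_absolute_agreement(matrix(rnorm(8), 4, 2)), "5 targets")
})

test_that("ICC mean squares equal the two-way ANOVA decomposition", {
  set.seed(16)
  ratings <- matrix(rnorm(12, 10, 2), 6, 2)
  ratings[, 2] <- ratings[, 2] + 0.5  # systematic rater offset
  ours <- icc_absolute_agreement(ratings)
  aovd <- oracle_icc_aov(ratings)
  expect_equal(ours$ms_rows, aovd$msr, tolerance = 1e-9)
  expect_equal(ours$ms_cols, aovd$msc, tolerance = 1e-9)
  expect_equal(ours$ms_error, aovd$mse, tolerance = 1e-9)
  expect_equal(ours$icc, aovd$icc, tolerance = 1e-9)
})

test_that("KS normality check distinguishes clean from skewed samples", {
  q <- qnorm(ppoints(60))  # values exactly at normal quantiles
  ksq <- ks_normality(q)
  expect_lt(ksq$statistic, 0.05)

  set.seed(17)
  skewed <- rexp(60)
  expect_gt(ks_normality(skewed)$statistic, ksq$statistic)

  expect_error(ks_normality(c(1, 2, 3, 4)), "at least 5")
  expect_error(ks_normality(rep(2, 10)), "constant")
})

test_that("correlation strength labels follow the stated boundaries", {
  expect_equal(pearson_strength_label(c(0.1, 0.3, 0.59, 0.6, 0.8, 0.81, 0.89)),
               c("weak", "moderate", "moderate", "strong", "strong",
                 "extremely strong", "extremely strong"))
  expect_equal(pearson_strength_label(-0.95), "extremely strong")
  expect_error(pearson_strength_label(1.2), "exceed")
})
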