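# One-way ANOVA and cross-validated classification from attractor features.

test_that("one-way ANOVA matches hand-computed sums of squares", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  # oracle: explicit between/within sums of squares and an F-CDF evaluation
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(f_oracle, 3.0)
  res <- anova_oneway(groups)
  expect_equal(res$statistic, 3.0, tolerance = 1e-12)
  expect_equal(res$p.value, 1 - pf(3.0, 2, 6), tolerance = 1e-12)

  twin <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(twin$statistic, 0)
  expect_equal(twin$p.value, 1)

  expect_error(anova_oneway(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(anova_oneway(list(1:3)), "2 groups")
})

test_that("ANOVA F is invariant to shifting and positive scaling", {
  set.seed(41)
  groups <- lapply(1:3, function(i) rnorm(8, mean = i))
  f0 <- anova_oneway(groups)$statistic
  expect_equal(anova_oneway(lapply(groups, function(g) g + 7))$statistic, f0,
               tolerance = 1e-10)
  expect_equal(anova_oneway(lapply(groups, function(g) 3.2 * g))$statistic, f0,
               tolerance = 1e-10)
})

test_that("axis ANOVA tables follow the within/between layouts", {
  feats <- acceptance_features()
  tabs <- axis_anova(feats)
  # long vs short axis differs strongly within every condition
  expect_equal(nrow(tabs$within_state), 4L)
  expect_true(all(tabs$within_state$p.value < 0.01))
  # every pairwise condition comparison of the long axis is significant
  la <- tabs$between_states[tabs$between_states$axis == "long_axis", ]
  expect_equal(nrow(la), 6L)
  expect_true(all(la$p.value < 0.01))

  one <- feats[feats$condition == "pre_acu", ]
  tabs1 <- axis_anova(one)
  expect_equal(nrow(tabs1$within_state), 1L)
  expect_equal(nrow(tabs1$between_states), 0L)
})

test_that("axis ANOVA p-values are uniform when axes are exchangeable", {
  set.seed(42)
  p <- replicate(200, {
    df <- data.frame(condition = "c",
                     long_axis = rnorm(12, 1), short_axis = rnorm(12, 1))
    axis_anova(df)$within_state$p.value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("cross-validation is perfect on separated classes, chance on shuffled labels", {
  set.seed(43)
  sep <- data.frame(
    condition = rep(c("a", "b", "c", "d"), each = 20L),
    long_axis = rep(c(1, 4, 8, 13), each = 20L) + rnorm(80, sd = 0.1),
    short_axis = rep(c(1, 2, 3, 4), each = 20L) + rnorm(80, sd = 0.05))
  for (mod in c("svm", "knn", "lda", "dt")) {
    cv <- cross_validate(sep, mod, seed = 5)
    expect_equal(cv$mean_accuracy, 1.0)
    expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 1))
  }
  shuffled <- sep
  shuffled$condition <- sample(shuffled$condition)
  shuffled$long_axis <- rnorm(80)
  shuffled$short_axis <- rnorm(80)
  cv0 <- cross_validate(shuffled, "lda", repeats = 20, seed = 6)
  expect_lt(abs(cv0$mean_accuracy - 0.25), 0.08)

  small <- sep[c(1:3, 21:40), ]
  expect_error(cross_validate(small, "lda", k = 5), "at least k")
})

test_that("fold standardization does not leak labels into training", {
  set.seed(44)
  n <- 80L
  lab <- rep(c("a", "b", "c", "d"), each = n / 4L)
  canary <- data.frame(condition = lab,
                       long_axis = as.numeric(factor(lab)) +   # label in disguise
                         rnorm(n, sd = 0.01),
                       short_axis = rnorm(n))
  expect_equal(cross_validate(canary, "lda", seed = 7)$mean_accuracy, 1.0)
  noise <- data.frame(condition = lab,
                      long_axis = rnorm(n), short_axis = rnorm(n))
  cv <- cross_validate(noise, "lda", repeats = 20, seed = 8)
  expect_lt(cv$mean_accuracy, 0.40)
})

test_that("model comparison is reproducible and ordered by separability", {
  set.seed(45)
  mk <- function(noise_sd) data.frame(
    condition = rep(c("a", "b", "c", "d"), each = 15L),
    long_axis = rep(c(1, 2, 3, 4), each = 15L) + rnorm(60, sd = noise_sd),
    short_axis = rep(c(1, 1.5, 2, 2.5), each = 15L) + rnorm(60, sd = noise_sd))
  tidy <- mk(0.05)
  t1 <- compare_models(tidy, seed = 9)
  t2 <- compare_models(tidy, seed = 9)
  expect_identical(t1, t2)
  expect_setequal(t1$model, c("svm", "knn", "lda", "dt"))
  messy <- mk(1.5)
  t3 <- compare_models(messy, seed = 9)
  expect_true(all(t3$mean_accuracy <= t1$mean_accuracy + 1e-12))
})

test_that("feature tables validate their contract", {
  expect_error(feature_table(data.frame(long_axis = 1)), "missing column")
  df <- data.frame(a = c(1, NA), b = 1, condition = "x")
  expect_error(feature_table(df), "missing values")
  ok <- feature_table(data.frame(a = c(1, 2), b = c(0.5, 0.6),
                                 condition = c("x", "y")))
  expect_true(all(c("long_axis", "short_axis", "subject", "trial") %in% names(ok)))
})
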