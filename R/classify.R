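# One-way ANOVA on attractor-axis lengths and cross-validated classification
# of brain state from (long, short) axis features.

#' One-way analysis of variance
#'
#' Classical one-way ANOVA (equal-variance F test) across two or more groups.
#'
#' @param groups List of numeric vectors, each with at least 2 values.
#' @return List with `statistic` (F), `p.value`, `df` (between, within).
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stopf("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stopf("every group needs at least 2 values")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::var(values) <= 0) stopf("degenerate ANOVA: total variance is zero")
  within_var <- vapply(groups, stats::var, numeric(1))
  if (all(within_var <= 0)) {
    stopf("degenerate ANOVA: zero within-group variance everywhere")
  }
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(ow$statistic), p.value = ow$p.value,
       df = unname(ow$parameter))
}

#' Attractor-feature table
#'
#' Validates and normalizes a table of per-trial attractor-axis features.
#'
#' @param df `data.frame` with columns `long_axis` (or `a`), `short_axis`
#'   (or `b`), `condition`, and optionally `subject` and `trial`.
#' @return The validated `data.frame` (class `feature_table` prepended) with
#'   canonical column names.
#' @export
feature_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"long_axis" %in% names(df) && "a" %in% names(df)) df$long_axis <- df$a
  if (!"short_axis" %in% names(df) && "b" %in% names(df)) df$short_axis <- df$b
  need <- c("long_axis", "short_axis", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("feature table is missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyNA(df[need])) stopf("feature table contains missing values")
  if (!"subject" %in% names(df)) df$subject <- NA_character_
  if (!"trial" %in% names(df)) df$trial <- seq_len(nrow(df))
  class(df) <- c("feature_table", "data.frame")
  df
}

#' ANOVA tables over attractor axes
#'
#' Two layouts: (i) within each condition, a one-way ANOVA comparing the long
#' against the short axis; (ii) for each axis, pairwise one-way ANOVAs between
#' conditions.
#'
#' @param features A feature table (see [feature_table()]).
#' @return List with `within_state` (`data.frame`: condition, F, p) and
#'   `between_states` (`data.frame`: axis, condition_a, condition_b, F, p;
#'   empty with a single condition).
#' @export
axis_anova <- function(features) {
  df <- feature_table(features)
  conds <- unique(df$condition)
  within_state <- do.call(rbind, lapply(conds, function(cc) {
    g <- df[df$condition == cc, ]
    res <- anova_oneway(list(g$long_axis, g$short_axis))
    data.frame(condition = cc, statistic = res$statistic, p.value = res$p.value)
  }))
  rownames(within_state) <- NULL
  between <- list()
  if (length(conds) >= 2L) {
    prs <- utils::combn(conds, 2L, simplify = FALSE)
    for (axis in c("long_axis", "short_axis")) {
      for (pr in prs) {
        res <- anova_oneway(list(df[df$condition == pr[1L], axis],
                                 df[df$condition == pr[2L], axis]))
        between[[length(between) + 1L]] <- data.frame(
          axis = axis, condition_a = pr[1L], condition_b = pr[2L],
          statistic = res$statistic, p.value = res$p.value)
      }
    }
  }
  between_states <- if (length(between)) do.call(rbind, between) else
    data.frame(axis = character(0), condition_a = character(0),
               condition_b = character(0), statistic = numeric(0),
               p.value = numeric(0))
  rownames(between_states) <- NULL
  list(within_state = within_state, between_states = between_states)
}

# Stratified fold assignment: within each class, shuffled members are dealt
# round-robin into k folds.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stopf("class '%s' has %d member(s); need at least k = %d", cl, length(idx), k)
    }
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_predict <- function(model, Xtr, ytr, Xte) {
  switch(model,
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial")
      stats::predict(fit, Xte)
    },
    knn = class::knn(Xtr, Xte, ytr, k = 5L),
    lda = {
      fit <- MASS::lda(Xtr, grouping = ytr)
      stats::predict(fit, Xte)$class
    },
    dt = {
      tr <- data.frame(Xtr, y = ytr)
      fit <- rpart::rpart(y ~ ., data = tr, method = "class")
      pred <- stats::predict(fit, data.frame(Xte), type = "class")
      pred
    },
    stopf("unknown model '%s'", model))
}

#' Repeated stratified k-fold cross-validation
#'
#' Features are standardized inside each training fold (the fold's mean and
#' standard deviation are applied to the held-out fold), so no information
#' leaks from test to train.
#'
#' @param features A feature table (see [feature_table()]); predictors are
#'   `long_axis` and `short_axis`, the class is `condition`.
#' @param model One of `"svm"` (RBF kernel), `"knn"` (k = 5), `"lda"`,
#'   `"dt"` (decision tree).
#' @param k Number of folds (default 5); every class needs >= k members.
#' @param repeats Number of repetitions (default 10).
#' @param seed Integer seed for fold assignment (and any stochastic learner).
#' @param predictors Character vector of predictor column names.
#' @return An object of class `cv_result`: `model`, `fold_accuracies`
#'   (repeats x k matrix), `mean_accuracy`, `confusion` (summed counts).
#' @export
cross_validate <- function(features, model = c("svm", "knn", "lda", "dt"),
                           k = 5L, repeats = 10L, seed = 1L,
                           predictors = c("long_axis", "short_axis")) {
  model <- match.arg(model)
  df <- feature_table(features)
  X <- as.matrix(df[predictors])
  y <- factor(df$condition)
  if (nlevels(y) < 2L) stopf("classification needs at least 2 conditions")
  acc <- matrix(NA_real_, repeats, k)
  conf <- table(y, y)
  conf[] <- 0L
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(y, k)
      for (f in seq_len(k)) {
        tr <- fold != f
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
        sdv[sdv < 1e-12] <- 1
        Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
        Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
        pred <- fit_predict(model, Xtr, y[tr], Xte)
        truth <- y[!tr]
        acc[r, f] <- mean(pred == truth)
        conf <- conf + table(factor(truth, levels(y)), factor(pred, levels(y)))
      }
    }
  })
  structure(list(model = model, fold_accuracies = acc,
                 mean_accuracy = mean(acc), confusion = conf),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean accuracy %.3f over %d x %d folds\n",
              x$model, x$mean_accuracy, nrow(x$fold_accuracies),
              ncol(x$fold_accuracies)))
  invisible(x)
}

#' Compare the four classifiers on one feature table
#'
#' Runs [cross_validate()] for SVM, KNN, LDA and decision tree with a shared
#' seed schedule and returns a one-row-per-model accuracy table.
#'
#' @inheritParams cross_validate
#' @return `data.frame` with columns `model`, `mean_accuracy`.
#' @export
compare_models <- function(features, k = 5L, repeats = 10L, seed = 1L) {
  models <- c("svm", "knn", "lda", "dt")
  data.frame(
    model = models,
    mean_accuracy = vapply(models, function(m) {
      cross_validate(features, m, k = k, repeats = repeats, seed = seed)$mean_accuracy
    }, numeric(1)),
    row.names = NULL)
}
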