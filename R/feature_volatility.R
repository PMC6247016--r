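# Supervised-regression "feature volatility" pipeline: features whose
# abundance predicts the sample state (time) are temporally informative.
# Samples are split 4:1 into training and test sets, cross-validated
# recursive feature elimination (RFE) selects the feature subset maximizing
# CV accuracy on the training set, a final model is trained on the selected
# features, and accuracy (MSE, R2) is measured on the untouched test set.
# Importance does not imply statistical significance; this is an exploratory
# screen.

#' Configure the feature-volatility regressor
#'
#' @param seed integer seed governing the train/test split, CV folds, and
#'   the stochastic regressors; required (no silent nondeterminism).
#' @param estimator regression estimator: `"random-forest"` (default),
#'   `"extra-trees"`, `"gradient-boosting"`, or `"elastic-net"`.
#' @param n_estimators trees (ensembles) or boosting rounds.
#' @param parameter_tuning cross-validated tuning of the main regularization
#'   knob (`mtry` for forests, tree depth for boosting) on the training set
#'   only.
#' @param cv_folds folds for RFE cross-validation (>= 2).
#' @param rfe_step fraction of remaining features eliminated per RFE round,
#'   in (0, 1].
#' @param test_fraction held-out proportion, in (0, 1); the default 0.2 is
#'   the 4:1 train:test split.
#' @return An object of class `regressor_config`.
#' @export
regressor_config <- function(seed,
                             estimator = c("random-forest", "extra-trees",
                                           "gradient-boosting", "elastic-net"),
                             n_estimators = 100L, parameter_tuning = FALSE,
                             cv_folds = 5L, rfe_step = 0.05,
                             test_fraction = 0.2) {
  estimator <- match.arg(estimator)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(test_fraction > 0, test_fraction < 1,
            cv_folds >= 2L, rfe_step > 0, rfe_step <= 1, n_estimators >= 1L)
  structure(list(estimator = estimator, n_estimators = as.integer(n_estimators),
                 parameter_tuning = isTRUE(parameter_tuning),
                 cv_folds = as.integer(cv_folds), rfe_step = rfe_step,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "regressor_config")
}

# Evaluate code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  code
}

next_seed <- function() sample.int(.Machine$integer.max, 1L)

fit_regressor <- function(X, y, config, tune = NULL) {
  switch(config$estimator,
    "random-forest" = ,
    "extra-trees" = {
      mtry <- if (!is.null(tune$mtry)) min(tune$mtry, ncol(X))
              else max(1L, floor(ncol(X) / 3))
      ranger::ranger(x = X, y = y, num.trees = config$n_estimators,
                     mtry = mtry, importance = "impurity",
                     splitrule = if (config$estimator == "extra-trees")
                                   "extratrees" else "variance",
                     oob.error = FALSE, num.threads = 1L,
                     seed = next_seed(), verbose = FALSE)
    },
    "gradient-boosting" = {
      depth <- if (!is.null(tune$max_depth)) tune$max_depth else 3L
      xgboost::xgboost(x = X, y = y, objective = "reg:squarederror",
                       nrounds = config$n_estimators, max_depth = depth,
                       learning_rate = 0.1, nthreads = 1L,
                       seed = next_seed() %% .Machine$integer.max,
                       verbosity = 0L)
    },
    "elastic-net" = {
      # glmnet requires >= 2 columns; pad single-feature fits with a zero
      # column that carries no signal and is never reported
      if (ncol(X) == 1L) X <- cbind(X, `..pad` = 0)
      glmnet::cv.glmnet(X, y, alpha = 0.5, nfolds = max(3L, config$cv_folds))
    })
}

predict_regressor <- function(model, X, config) {
  switch(config$estimator,
    "random-forest" = ,
    "extra-trees" = stats::predict(model, data = X, num.threads = 1L)$predictions,
    "gradient-boosting" = stats::predict(model, X),
    "elastic-net" = {
      if (ncol(X) == 1L) X <- cbind(X, `..pad` = 0)
      as.numeric(stats::predict(model, X, s = "lambda.min"))
    })
}

importance_regressor <- function(model, feature_ids, config) {
  imp <- stats::setNames(numeric(length(feature_ids)), feature_ids)
  raw <- switch(config$estimator,
    "random-forest" = ,
    "extra-trees" = ranger::importance(model),
    "gradient-boosting" = {
      tab <- xgboost::xgb.importance(model = model, feature_names = NULL)
      stats::setNames(tab$Gain, tab$Feature)
    },
    "elastic-net" = {
      co <- as.matrix(stats::coef(model, s = "lambda.min"))[-1L, 1L]
      abs(co)
    })
  raw <- raw[names(raw) %in% feature_ids]
  imp[names(raw)] <- pmax(raw, 0)
  imp
}

normalize_importance <- function(imp) {
  s <- sum(imp)
  if (s > 0) imp / s else imp
}

# Feature-subset sizes visited by RFE: from p down, removing
# max(1, floor(step * remaining)) per round, to a single feature.
rfe_sizes <- function(p, step) {
  sizes <- p
  while (sizes[length(sizes)] > 1L) {
    cur <- sizes[length(sizes)]
    sizes <- c(sizes, cur - max(1L, floor(step * cur)))
  }
  sizes
}

# One elimination pass on (X, y): fit at each subset size, rank by
# importance, drop the weakest block. Returns the retained feature IDs at
# each size and, optionally, held-out MSE at each size.
rfe_pass <- function(X, y, config, tune, X_valid = NULL, y_valid = NULL) {
  sizes <- rfe_sizes(ncol(X), config$rfe_step)
  keep <- colnames(X)
  retained <- vector("list", length(sizes))
  mse <- rep(NA_real_, length(sizes))
  for (k in seq_along(sizes)) {
    keep <- keep[seq_len(sizes[k])]
    model <- fit_regressor(X[, keep, drop = FALSE], y, config, tune)
    if (!is.null(X_valid)) {
      pred <- predict_regressor(model, X_valid[, keep, drop = FALSE], config)
      mse[k] <- mean((y_valid - pred)^2)
    }
    retained[[k]] <- keep
    imp <- importance_regressor(model, keep, config)
    keep <- names(sort(imp, decreasing = TRUE))  # next round drops the tail
  }
  list(sizes = sizes, retained = retained, mse = mse)
}

# Cross-validated RFE on the training set: per fold, run an elimination
# pass scored on the held-out fold; average MSE per subset size; pick the
# size with the lowest mean MSE (ties: fewer features); rerun the pass on
# the full training set down to that size.
rfe_cv <- function(X, y, config, tune) {
  n <- nrow(X)
  fold <- sample(rep_len(seq_len(config$cv_folds), n))
  sizes <- rfe_sizes(ncol(X), config$rfe_step)
  fold_mse <- sapply(seq_len(config$cv_folds), function(k) {
    tr <- fold != k
    rfe_pass(X[tr, , drop = FALSE], y[tr], config, tune,
             X_valid = X[!tr, , drop = FALSE], y_valid = y[!tr])$mse
  })
  mean_mse <- rowMeans(fold_mse)
  best <- which(mean_mse == min(mean_mse))
  best_size <- sizes[max(best)]  # ties broken toward fewer features
  full <- rfe_pass(X, y, config, tune)
  selected <- full$retained[[match(best_size, full$sizes)]]
  list(selected = selected, sizes = sizes, mean_cv_mse = mean_mse,
       best_size = best_size)
}

# Small CV grid over the estimator's main knob, on the training set only.
tune_regressor <- function(X, y, config) {
  p <- ncol(X)
  grid <- switch(config$estimator,
    "random-forest" = ,
    "extra-trees" = lapply(unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3),
                                             floor(p / 2)))),
                           function(m) list(mtry = m)),
    "gradient-boosting" = lapply(c(2L, 3L, 5L), function(d) list(max_depth = d)),
    "elastic-net" = return(NULL))  # cv.glmnet self-tunes lambda
  if (length(grid) < 2L) return(grid[[1L]])
  fold <- sample(rep_len(seq_len(config$cv_folds), nrow(X)))
  score <- vapply(grid, function(tune) {
    mean(vapply(seq_len(config$cv_folds), function(k) {
      tr <- fold != k
      model <- fit_regressor(X[tr, , drop = FALSE], y[tr], config, tune)
      pred <- predict_regressor(model, X[!tr, , drop = FALSE], config)
      mean((y[!tr] - pred)^2)
    }, numeric(1)))
  }, numeric(1))
  grid[[which.min(score)]]
}

#' Identify features whose abundance predicts time
#'
#' Runs the feature-volatility pipeline: (1) a seeded random 4:1 train/test
#' split (optionally subject-grouped to prevent within-subject leakage);
#' (2) optional cross-validated hyperparameter tuning on the training set;
#' (3) cross-validated recursive feature elimination on the training set,
#' selecting the feature subset that minimizes cross-validated MSE; (4) a
#' final model trained on the selected features; (5) importances extracted
#' and normalized to sum to 1; (6) MSE and R2 computed on the untouched
#' test set; (7) descriptive statistics for the retained ("important")
#' features; (8) a combined plot specification (per-feature volatility
#' charts plus importance/stat bar charts).
#'
#' @param table a [feature_table] (samples x features).
#' @param metadata a [sample_metadata]; its numeric state column is the
#'   regression target.
#' @param config a [regressor_config].
#' @param group_by_subject split subjects (not samples) between training
#'   and test sets, preventing within-subject leakage; recommended for
#'   longitudinal designs.
#' @param relative_frequency convert counts to per-sample proportions
#'   before modeling.
#' @param top_n number of top features given per-feature volatility charts
#'   in the plot spec.
#' @return An object of class `feature_volatility_result` with elements
#'   `importances` (feature, importance, descriptive stats; sorted by
#'   importance descending, feature ID ascending on ties), `accuracy`
#'   (`mse`, `r_squared`, `n_test`), `n_important_features`, `selection`
#'   (RFE diagnostics), and `plot_spec`.
#' @export
feature_volatility <- function(table, metadata, config,
                               group_by_subject = FALSE,
                               relative_frequency = FALSE, top_n = 10L) {
  stopifnot(inherits(table, "feature_table"),
            inherits(metadata, "sample_metadata"),
            inherits(config, "regressor_config"))
  lf <- longitudinal_frame(metadata)
  common <- intersect(rownames(table), lf$sample_id)
  if (length(common) < 20L) {
    stop("feature volatility requires at least 20 samples shared between ",
         "the table and usable metadata; got ", length(common))
  }
  lf <- lf[match(common, lf$sample_id), , drop = FALSE]
  X <- unclass(table)[common, , drop = FALSE]
  if (relative_frequency) {
    rs <- rowSums(X)
    X <- X / ifelse(rs == 0, 1, rs)
  }
  y <- lf$state
  if (stats::var(y) == 0) stop("state (regression target) is constant")

  with_seed(config$seed, {
    n <- nrow(X)
    if (group_by_subject) {
      subjects <- unique(lf$subject)
      test_subj <- sample(subjects, max(1L, round(config$test_fraction *
                                                    length(subjects))))
      test_idx <- which(lf$subject %in% test_subj)
    } else {
      test_idx <- sample(n, max(1L, round(config$test_fraction * n)))
    }
    X_train <- X[-test_idx, , drop = FALSE]
    y_train <- y[-test_idx]
    X_test <- X[test_idx, , drop = FALSE]
    y_test <- y[test_idx]
    if (stats::var(y_train) == 0) stop("training-set state is constant")

    tune <- if (config$parameter_tuning) tune_regressor(X_train, y_train, config)
    sel <- rfe_cv(X_train, y_train, config, tune)
    if (!length(sel$selected)) {
      stop("recursive feature elimination retained no features; ",
           "the data may carry no signal at any subset size")
    }
    final <- fit_regressor(X_train[, sel$selected, drop = FALSE], y_train,
                           config, tune)
    imp <- normalize_importance(
      importance_regressor(final, sel$selected, config))
    pred <- predict_regressor(final, X_test[, sel$selected, drop = FALSE],
                              config)
    mse <- mean((y_test - pred)^2)
    r2 <- 1 - sum((y_test - pred)^2) / sum((y_test - mean(y_test))^2)

    stats_tab <- feature_descriptive_stats(
      feature_table(X[, sel$selected, drop = FALSE]), metadata)
    ord <- order(-imp, names(imp))
    importances <- data.frame(feature = names(imp)[ord],
                              importance = unname(imp)[ord],
                              stringsAsFactors = FALSE)
    importances <- merge(importances, stats_tab, by = "feature", sort = FALSE)

    result <- structure(
      list(importances = importances,
           accuracy = c(mse = mse, r_squared = r2, n_test = length(y_test)),
           n_important_features = length(sel$selected),
           selection = sel[c("sizes", "mean_cv_mse", "best_size")],
           config = config,
           predictions = data.frame(sample_id = common[test_idx],
                                    true_state = y_test, predicted = pred)),
      class = "feature_volatility_result")
    result$plot_spec <- feature_volatility_spec(result, table, metadata,
                                                top_n = top_n)
    result
  })
}

#' @export
print.feature_volatility_result <- function(x, ...) {
  cat(sprintf("feature_volatility_result: %d important features (%s)\n",
              x$n_important_features, x$config$estimator))
  cat(sprintf("  test-set accuracy: MSE = %.4g, R2 = %.4g (n = %d)\n",
              x$accuracy[["mse"]], x$accuracy[["r_squared"]],
              as.integer(x$accuracy[["n_test"]])))
  cat("  top features by importance:\n")
  print.data.frame(utils::head(x$importances[, c("feature", "importance",
                                                 "mean", "net_avg_change")],
                               10L), row.names = FALSE)
  invisible(x)
}

#' Per-feature descriptive statistics for longitudinal tables
#'
#' For each feature: mean, median, variance, standard deviation, and
#' coefficient of variation over all samples (CV is missing when the mean
#' is 0); then, on the per-state mean abundance profile `m_f(t)` with states
#' ascending, the net average change `m_f(t_k) - m_f(t_1)`, the cumulative
#' average increase `sum max(0, m_f(t_{j+1}) - m_f(t_j))`, and the
#' cumulative average decrease `sum min(0, ...)`. Increase + decrease = net,
#' always.
#'
#' @param table a [feature_table].
#' @param metadata a [sample_metadata] providing the state column.
#' @return A data.frame with one row per feature: `feature`, `mean`,
#'   `median`, `variance`, `sd`, `cv`, `net_avg_change`,
#'   `cumulative_avg_increase`, `cumulative_avg_decrease`.
#' @export
feature_descriptive_stats <- function(table, metadata) {
  stopifnot(inherits(table, "feature_table"),
            inherits(metadata, "sample_metadata"))
  state_column <- attr(metadata, "state_column")
  states_all <- metadata[rownames(table), state_column]
  keep <- !is.na(states_all)
  X <- unclass(table)[keep, , drop = FALSE]
  st <- states_all[keep]
  states <- sort(unique(st))
  if (length(states) < 2L) {
    warning("a single state is observed; change statistics reported as 0")
  }
  profile <- vapply(states, function(t) colMeans(X[st == t, , drop = FALSE]),
                    numeric(ncol(X)))
  if (!is.matrix(profile)) profile <- matrix(profile, nrow = ncol(X))
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  steps <- if (length(states) >= 2L) {
    profile[, -1L, drop = FALSE] - profile[, -length(states), drop = FALSE]
  } else matrix(0, nrow = ncol(X), ncol = 0L)
  inc <- rowSums(pmax(steps, 0))
  dec <- rowSums(pmin(steps, 0))
  data.frame(feature = colnames(X),
             mean = unname(mu),
             median = unname(apply(X, 2L, stats::median)),
             variance = unname(sdv^2),
             sd = unname(sdv),
             cv = unname(ifelse(mu == 0, NA_real_, sdv / mu)),
             net_avg_change = if (length(states) >= 2L)
               unname(profile[, length(states)] - profile[, 1L]) else
               rep(0, ncol(X)),
             cumulative_avg_increase = unname(inc),
             cumulative_avg_decrease = unname(dec),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Combined plot spec: per-feature volatility charts for the top features
# plus importance/stat bar charts for every retained feature.
feature_volatility_spec <- function(result, table, metadata, top_n = 10L) {
  top <- utils::head(result$importances$feature, top_n)
  charts <- lapply(top, function(f) {
    md <- as.data.frame(metadata)
    md$.abundance <- unclass(table)[rownames(metadata), f]
    md2 <- sample_metadata(md, state_column = attr(metadata, "state_column"),
                           subject_column = attr(metadata, "subject_column"))
    vs <- volatility_stats(md2, ".abundance")
    spec <- volatility_plot_spec(vs, options = list(title = f))
    spec$metric <- f
    unclass(spec)
  })
  stat_cols <- c("importance", "mean", "median", "variance", "sd", "cv",
                 "net_avg_change", "cumulative_avg_increase",
                 "cumulative_avg_decrease")
  bars <- lapply(stat_cols, function(sc) {
    list(type = "bar_chart", statistic = sc,
         bars = lapply(seq_len(nrow(result$importances)), function(i) {
           list(feature = result$importances$feature[i],
                value = result$importances[[sc]][i])
         }))
  })
  list(chart = "feature_volatility",
       accuracy = as.list(result$accuracy),
       feature_charts = charts,
       bar_charts = bars)
}

#' Bar chart of feature importances
#'
#' @param result a `feature_volatility_result`.
#' @param top_n number of features displayed.
#' @return A ggplot object.
#' @export
feature_volatility_plot <- function(result, top_n = 20L) {
  stopifnot(inherits(result, "feature_volatility_result"))
  df <- utils::head(result$importances, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "importance", y = NULL) +
    ggplot2::theme_minimal()
}
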