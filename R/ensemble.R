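#' Repeated-subsampling penalized regression ensembles
#'
#' The prediction workflow: within the discovery sample, 100 random
#' train/test partitions are drawn; on each, preprocessing is fitted to the
#' train block and carried to the test block, the LASSO penalty is tuned by
#' 10-fold cross-validated RMSE over a geometric grid on [1e-10, 1], and
#' the tuned model's standardized coefficients are recorded. Features whose
#' percentile 95% confidence interval across the repeats excludes zero are
#' significant; the averaged significant coefficients predict the holdout
#' (and, cross-wise, the other outcome). An Elastic Net penalty is
#' available as a sensitivity variant and reproduces the LASSO at mixing 1.
#'
#' @name penalized_ensemble
NULL

#' Ensemble configuration
#'
#' @param n_repeats random train/test subsampling repeats.
#' @param cv_folds folds for penalty tuning.
#' @param lambda_grid penalty grid; default 100 geometric points spanning
#'   exactly \[1e-10, 1\].
#' @param penalty `"lasso"` or `"elastic_net"`.
#' @param alpha_grid L1/L2 mixing values tried when `penalty` is
#'   `"elastic_net"` (1 = pure LASSO).
#' @param ci_level coverage of the per-feature percentile interval.
#' @param seed RNG seed; repeat `r` derives its own sub-seed for both the
#'   inner split handling and the CV fold assignment.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(n_repeats = 100, cv_folds = 10,
                            lambda_grid = exp(seq(log(1e-10), log(1),
                                                  length.out = 100)),
                            penalty = c("lasso", "elastic_net"),
                            alpha_grid = seq(0.1, 1, by = 0.1),
                            ci_level = 0.95, seed = 1) {
  penalty <- match.arg(penalty)
  stopifnot(n_repeats >= 1, cv_folds >= 2, all(lambda_grid > 0),
            ci_level > 0, ci_level < 1,
            all(alpha_grid > 0), all(alpha_grid <= 1))
  structure(list(n_repeats = as.integer(n_repeats),
                 cv_folds = as.integer(cv_folds),
                 lambda_grid = sort(as.numeric(lambda_grid),
                                    decreasing = TRUE),
                 penalty = penalty,
                 alpha_grid = if (penalty == "lasso") 1 else
                   sort(alpha_grid),
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Tune the penalty by cross-validated RMSE
#'
#' For every point of the penalty grid (and each mixing value for Elastic
#' Net), computes the mean out-of-fold RMSE across `cv_folds` folds and
#' returns the minimizing penalty; ties go to the stronger penalty.
#'
#' @param X standardized design matrix.
#' @param y standardized outcome (nonzero variance).
#' @param config an [ensemble_config()].
#' @param seed RNG seed for the fold assignment.
#' @return List with `lambda`, `alpha`, and `cv_rmse` (mean out-of-fold
#'   RMSE per grid point for the chosen `alpha`).
#' @export
tune_lambda_cv <- function(X, y, config = ensemble_config(), seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < config$cv_folds) stop("fewer rows than CV folds")
  if (sd(y) == 0) stop("outcome has zero variance")
  grid <- config$lambda_grid
  folds <- with_seed(seed, sample(rep(seq_len(config$cv_folds),
                                      length.out = n)))
  best <- NULL
  for (alpha in config$alpha_grid) {
    rmse <- matrix(NA_real_, config$cv_folds, length(grid))
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = alpha,
                            lambda = grid, standardize = FALSE)
      pred <- predict(fit, X[!tr, , drop = FALSE]) # columns follow the grid
      if (ncol(pred) < length(grid)) { # glmnet stopped early on the path
        pred <- cbind(pred, matrix(pred[, ncol(pred)], nrow(pred),
                                   length(grid) - ncol(pred)))
      }
      rmse[f, ] <- sqrt(colMeans((pred - y[!tr])^2))
    }
    mean_rmse <- colMeans(rmse)
    k <- which.min(mean_rmse) # grid is decreasing: first min = largest lambda
    if (is.null(best) || mean_rmse[k] < best$cv_rmse[best$k]) {
      best <- list(lambda = grid[k], alpha = alpha, cv_rmse = mean_rmse,
                   k = k)
    }
  }
  best$k <- NULL
  best
}

# one repeat: standardize (or fully preprocess) on the train block, tune,
# fit, evaluate on the test block
fit_one_repeat <- function(data, y, train_idx, test_idx, config, plan,
                           repeat_seed) {
  if (inherits(data, "feature_table")) {
    train_tab <- feature_table(data$values[train_idx, , drop = FALSE],
                               data$dictionary)
    fitres <- fit_transform(train_tab, plan)
    X_tr <- fitres$X
    test_tab <- feature_table(data$values[test_idx, , drop = FALSE],
                              data$dictionary)
    X_te <- apply_transform(fitres$transform, test_tab)
  } else {
    X <- as.matrix(data)
    mu <- colMeans(X[train_idx, , drop = FALSE])
    sds <- apply(X[train_idx, , drop = FALSE], 2, sd)
    keep <- sds > 0
    X_tr <- sweep(sweep(X[train_idx, keep, drop = FALSE], 2, mu[keep]),
                  2, sds[keep], "/")
    X_te <- sweep(sweep(X[test_idx, keep, drop = FALSE], 2, mu[keep]),
                  2, sds[keep], "/")
  }
  ysc <- fit_outcome_scaler(y[train_idx])
  y_tr <- apply_outcome_scaler(ysc, y[train_idx])
  y_te <- apply_outcome_scaler(ysc, y[test_idx])

  tuned <- tune_lambda_cv(X_tr, y_tr, config, seed = repeat_seed)
  fit <- glmnet::glmnet(X_tr, y_tr, alpha = tuned$alpha,
                        lambda = config$lambda_grid, standardize = FALSE)
  beta <- drop(as.matrix(predict(fit, type = "coefficients",
                                 s = tuned$lambda)))
  intercept <- beta[1]
  beta <- beta[-1]
  pred <- drop(X_te %*% beta) + intercept
  r <- suppressWarnings(cor(pred, y_te))
  list(beta = beta, intercept = intercept, lambda = tuned$lambda,
       alpha = tuned$alpha,
       metrics = data.frame(
         r = r, r_squared = r^2,
         rmse = sqrt(mean((pred - y_te)^2)),
         mae = mean(abs(pred - y_te))))
}

#' Run the repeated-subsampling penalized ensemble
#'
#' Executes one repeat per inner partition of the split plan (preprocess on
#' the train block, tune the penalty, fit, record standardized
#' coefficients and test metrics), then forms the percentile confidence
#' interval of each feature's coefficient across repeats, zeroes features
#' whose interval spans zero, and averages the survivors. Repeats that fail
#' are logged and skipped; fewer than 90% successes aborts. Coefficients
#' are indexed by design-column name; columns absent from a repeat's fitted
#' design (unseen category, zero variance) count as zero.
#'
#' @param data a [feature_table()] (full per-repeat preprocessing) or a
#'   numeric matrix (per-repeat z-scoring only), rows matching the split
#'   plan's universe.
#' @param y raw outcome vector (standardized per repeat on the train
#'   block).
#' @param splits a [make_splits()] plan carrying the inner partitions.
#' @param config an [ensemble_config()].
#' @param plan a [preprocess_plan()], used when `data` is a feature table.
#' @return An `ensemble_model`: `betas` (repeats x features), `intercepts`,
#'   `best_lambdas`, `alphas`, `ci_low`, `ci_high`, `significance_mask`,
#'   `mean_significant_beta`, `mean_intercept`, `metrics`, `n_failed`.
#' @export
run_ensemble <- function(data, y, splits, config = ensemble_config(),
                         plan = preprocess_plan()) {
  stopifnot(inherits(splits, "split_plan"))
  reps <- splits$repeat_splits
  n_rep <- min(length(reps), config$n_repeats)
  results <- vector("list", n_rep)
  failures <- character()
  for (r in seq_len(n_rep)) {
    seed_r <- derive_seed(config$seed, paste0("cv-", r))
    results[[r]] <- tryCatch(
      fit_one_repeat(data, y, reps[[r]]$train_idx, reps[[r]]$test_idx,
                     config, plan, seed_r),
      error = function(e) {
        failures <<- c(failures, sprintf("repeat %d: %s", r,
                                         conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(results, is.null, logical(1))
  if (sum(ok) < 0.9 * n_rep) {
    stop(sprintf("only %d of %d ensemble repeats succeeded:\n%s",
                 sum(ok), n_rep, paste(head(failures, 5), collapse = "\n")))
  }
  results <- results[ok]
  feature_names <- sort(unique(unlist(lapply(results, function(x)
    names(x$beta)))))
  B <- matrix(0, length(results), length(feature_names),
              dimnames = list(NULL, feature_names))
  for (i in seq_along(results)) {
    b <- results[[i]]$beta
    B[i, names(b)] <- b
  }
  a <- (1 - config$ci_level) / 2
  ci_low <- apply(B, 2, quantile, probs = a)
  ci_high <- apply(B, 2, quantile, probs = 1 - a)
  mask <- ci_low > 0 | ci_high < 0
  mean_beta <- colMeans(B)
  msb <- mean_beta
  msb[!mask] <- 0
  structure(
    list(betas = B,
         intercepts = vapply(results, `[[`, numeric(1), "intercept"),
         best_lambdas = vapply(results, `[[`, numeric(1), "lambda"),
         alphas = vapply(results, `[[`, numeric(1), "alpha"),
         ci_low = ci_low, ci_high = ci_high,
         significance_mask = mask,
         mean_beta = mean_beta,
         mean_significant_beta = msb,
         mean_intercept = mean(vapply(results, `[[`, numeric(1),
                                      "intercept")),
         metrics = do.call(rbind, lapply(results, `[[`, "metrics")),
         feature_names = feature_names,
         n_failed = sum(!ok), failures = failures,
         config = config),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "<ensemble_model> %d repeats, %d features, %d significant (mean test r %.3f)\n",
    nrow(x$betas), ncol(x$betas), sum(x$significance_mask),
    mean(x$metrics$r, na.rm = TRUE)))
  invisible(x)
}

#' Predict with the averaged significant coefficients
#'
#' `yhat = X_new %*% mean_significant_beta + mean intercept`, scored
#' against `y_new` (standardized with the discovery statistics). When every
#' averaged coefficient is zero the prediction is constant and the
#' correlation-based metrics are flagged degenerate (`NA`).
#'
#' @param model an `ensemble_model`.
#' @param X_new design matrix transformed by the discovery-fitted
#'   transform; must contain every model feature column.
#' @param y_new standardized outcome to score against.
#' @return A `prediction_metrics` list: `r`, `r_squared`, `rmse`, `mae`,
#'   `degenerate`.
#' @export
predict_with_mean_betas <- function(model, X_new, y_new) {
  stopifnot(inherits(model, "ensemble_model"))
  X_new <- as.matrix(X_new)
  missing_cols <- setdiff(model$feature_names, colnames(X_new))
  if (length(missing_cols)) {
    stop("design mismatch; missing columns: ",
         paste(head(missing_cols, 5), collapse = ", "))
  }
  X <- X_new[, model$feature_names, drop = FALSE]
  pred <- drop(X %*% model$mean_significant_beta) + model$mean_intercept
  degenerate <- sd(pred) == 0
  r <- if (degenerate) NA_real_ else cor(pred, y_new)
  structure(
    list(r = r, r_squared = if (degenerate) NA_real_ else r^2,
         rmse = sqrt(mean((pred - y_new)^2)),
         mae = mean(abs(pred - y_new)),
         degenerate = degenerate, predictions = pred),
    class = "prediction_metrics"
  )
}

#' @export
print.prediction_metrics <- function(x, ...) {
  if (x$degenerate) {
    cat("<prediction_metrics> degenerate (constant prediction);",
        sprintf("rmse %.3f, mae %.3f\n", x$rmse, x$mae))
  } else {
    cat(sprintf(
      "<prediction_metrics> r %.3f, R^2 %.3f, rmse %.3f, mae %.3f\n",
      x$r, x$r_squared, x$rmse, x$mae))
  }
  invisible(x)
}

#' Cross-outcome prediction
#'
#' Applies one outcome's averaged model to the holdout features and scores
#' it against the other outcome, quantifying shared predictive information.
#'
#' @param model_a the `ensemble_model` trained on outcome A.
#' @param X_holdout holdout design matrix (discovery-fitted transform).
#' @param y_other the other outcome, standardized comparably.
#' @return A `prediction_metrics` list.
#' @export
cross_predict <- function(model_a, X_holdout, y_other) {
  predict_with_mean_betas(model_a, X_holdout, y_other)
}

#' Overlap features and restricted models
#'
#' The overlap set is the intersection of the two significance masks; each
#' restricted model keeps its averaged coefficients on the overlap and
#' zeroes the rest (no refit).
#'
#' @param model_a,model_b `ensemble_model`s fitted on the same design.
#' @return List with `overlap_features`, `model_a`, `model_b` (restricted).
#' @export
overlap_and_restrict <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "ensemble_model"),
            inherits(model_b, "ensemble_model"))
  sig_a <- model_a$feature_names[model_a$significance_mask]
  sig_b <- model_b$feature_names[model_b$significance_mask]
  overlap <- intersect(sig_a, sig_b)
  if (length(overlap) == 0L) {
    warning("empty overlap between the two significance masks")
  }
  restrict <- function(m) {
    keep <- m$feature_names %in% overlap
    m$significance_mask <- m$significance_mask & keep
    m$mean_significant_beta[!keep] <- 0
    m
  }
  list(overlap_features = overlap,
       model_a = restrict(model_a), model_b = restrict(model_b))
}
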