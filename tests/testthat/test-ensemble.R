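test_that("penalty tuning tracks the signal-to-noise regime", {
  grid <- ensemble_config()$lambda_grid
  expect_equal(max(grid), 1)
  expect_equal(min(grid), 1e-10)
  expect_length(grid, 100)

  # pure noise: heavy shrinkage wins (checked over seeds)
  top <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(200 * 20), 200)
    colnames(X) <- paste0("f", 1:20)
    y <- rnorm(200)
    tune_lambda_cv(scale(X), drop(scale(y)), seed = s)$lambda
  }, numeric(1))
  expect_gt(median(top), 0.05)

  # strong noiseless signal, n >> p: minimal shrinkage wins
  bottom <- vapply(1:10, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(400 * 5), 400)
    colnames(X) <- paste0("f", 1:5)
    y <- drop(X %*% c(1, -1, 0.5, 0.7, -0.3))
    tune_lambda_cv(scale(X), drop(scale(y)), seed = s)$lambda
  }, numeric(1))
  expect_lt(median(bottom), 1e-4)

  expect_error(tune_lambda_cv(matrix(rnorm(40), 20), rep(1, 20)),
               "zero variance")
})

test_that("lambda = 1 on standardized data shrinks to the mean prediction", {
  set.seed(6)
  X <- scale(matrix(rnorm(300 * 10), 300))
  y <- drop(scale(0.5 * X[, 1] + rnorm(300)))
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = 1, standardize = FALSE)
  beta <- as.matrix(fit$beta)
  expect_lt(max(abs(beta)), 1e-8)
  expect_lt(max(abs(predict(fit, X) - mean(y))), 1e-6)
})

test_that("tuned LASSO solutions satisfy the KKT conditions", {
  set.seed(7)
  n <- 300; p <- 25
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- paste0("f", 1:p)
  y <- drop(scale(0.6 * X[, 1] - 0.4 * X[, 2] + rnorm(n)))
  cfg <- ensemble_config()
  lam <- tune_lambda_cv(X, y, cfg, seed = 1)$lambda
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = cfg$lambda_grid,
                        standardize = FALSE, thresh = 1e-12)
  beta <- drop(as.matrix(predict(fit, type = "coefficients", s = lam)))[-1]
  resid <- y - drop(X %*% beta) - mean(y)
  g <- drop(crossprod(X, resid)) / n
  active <- beta != 0
  expect_lt(max(abs(g[!active])) - lam, 1e-6)
  if (any(active)) {
    expect_lt(max(abs(g[active] - lam * sign(beta[active]))), 1e-6)
  }
})

test_that("the CI rule recovers a planted effect and zeroes null betas", {
  pd <- planted_design(n = 600, p_noise = 20, beta = 0.5, seed = 8)
  sp <- make_splits(600, n_repeats = 25, seed = 8)
  m <- run_ensemble(pd$X, pd$y, sp, ensemble_config(n_repeats = 25, seed = 8))
  expect_true(m$significance_mask["planted"])
  expect_true(all(m$mean_significant_beta[!m$significance_mask] == 0))
  expect_true(all(m$ci_low <= colMeans(m$betas) + 1e-12))
  expect_true(all(m$ci_high >= colMeans(m$betas) - 1e-12))
  # a feature with betas identically zero is never significant
  all_zero <- colSums(m$betas != 0) == 0
  if (any(all_zero)) expect_false(any(m$significance_mask[all_zero]))
})

test_that("prediction metrics behave on exact, degenerate and generic input", {
  pd <- planted_design(n = 400, p_noise = 10, beta = 0.6, seed = 9)
  sp <- make_splits(400, n_repeats = 15, seed = 9)
  m <- run_ensemble(pd$X, pd$y, sp, ensemble_config(n_repeats = 15, seed = 9))
  Xs <- scale(pd$X); ys <- drop(scale(pd$y))

  pm <- predict_with_mean_betas(m, Xs, ys)
  expect_false(pm$degenerate)
  expect_equal(pm$r_squared, pm$r^2, tolerance = 1e-12)
  expect_gte(pm$rmse, pm$mae)

  # perfect prediction limit
  m2 <- m
  m2$feature_names <- "planted"
  m2$mean_significant_beta <- c(planted = 1)
  m2$mean_intercept <- 0
  pm2 <- predict_with_mean_betas(m2, Xs[, "planted", drop = FALSE],
                                 drop(Xs[, "planted"]))
  expect_equal(pm2$r, 1)
  expect_equal(pm2$rmse, 0)
  expect_equal(pm2$mae, 0)

  # all-zero coefficients: flagged degenerate
  m3 <- m
  m3$mean_significant_beta[] <- 0
  pm3 <- predict_with_mean_betas(m3, Xs, ys)
  expect_true(pm3$degenerate)
  expect_true(is.na(pm3$r))

  expect_error(predict_with_mean_betas(m, Xs[, 1:3], ys), "mismatch")
})

test_that("cross-prediction with the own outcome equals own prediction", {
  pd <- planted_design(n = 400, p_noise = 10, beta = 0.6, seed = 10)
  sp <- make_splits(400, n_repeats = 12, seed = 10)
  m <- run_ensemble(pd$X, pd$y, sp, ensemble_config(n_repeats = 12, seed = 10))
  Xs <- scale(pd$X); ys <- drop(scale(pd$y))
  own <- predict_with_mean_betas(m, Xs, ys)
  crossed <- cross_predict(m, Xs, ys)
  expect_equal(crossed$r, own$r)
  expect_equal(crossed$rmse, own$rmse)
})

test_that("overlap extraction intersects masks and restriction is faithful", {
  pd <- planted_design(n = 500, p_noise = 15, beta = 0.5, seed = 11)
  y2 <- 0.5 * pd$X[, "planted"] + 0.4 * pd$X[, "noise1"] +
    sqrt(1 - 0.41) * rnorm(500)
  sp <- make_splits(500, n_repeats = 20, seed = 11)
  cfg <- ensemble_config(n_repeats = 20, seed = 11)
  ma <- run_ensemble(pd$X, pd$y, sp, cfg)
  mb <- run_ensemble(pd$X, y2, sp, cfg)
  ov <- overlap_and_restrict(ma, mb)
  expect_setequal(
    ov$overlap_features,
    intersect(names(which(ma$significance_mask)),
              names(which(mb$significance_mask))))
  expect_true("planted" %in% ov$overlap_features)
  # restricting a model to its own full mask changes nothing
  same <- overlap_and_restrict(ma, ma)
  expect_equal(same$model_a$mean_significant_beta, ma$mean_significant_beta)
})

test_that("elastic net at mixing 1 reproduces the LASSO ensemble", {
  pd <- planted_design(n = 300, p_noise = 10, beta = 0.5, seed = 12)
  sp <- make_splits(300, n_repeats = 8, seed = 12)
  m_lasso <- run_ensemble(pd$X, pd$y, sp,
                          ensemble_config(n_repeats = 8, seed = 12))
  m_en <- run_ensemble(pd$X, pd$y, sp,
                       ensemble_config(n_repeats = 8, seed = 12,
                                       penalty = "elastic_net",
                                       alpha_grid = 1))
  expect_lt(max(abs(m_lasso$betas - m_en$betas)), 1e-6)
  # a mixing grid is searched when requested
  set.seed(12)
  X <- scale(matrix(rnorm(300 * 15), 300))
  colnames(X) <- paste0("f", 1:15)
  y <- drop(scale(0.5 * X[, 1] + 0.3 * X[, 2] + rnorm(300)))
  tuned <- tune_lambda_cv(X, y,
                          ensemble_config(penalty = "elastic_net",
                                          alpha_grid = c(0.5, 1)), seed = 2)
  expect_true(tuned$alpha %in% c(0.5, 1))
})
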