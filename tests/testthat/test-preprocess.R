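test_that("item filter applies the strict 25% rule and drops string items", {
  tab <- tiny_table(n = 100)
  # 26% missing -> removed; exactly 25% -> retained
  tab$values$num1[1:26] <- NA
  tab$values$num2[1:25] <- NA
  tab$dictionary$type[tab$dictionary$item == "num3"] <- "string"
  out <- filter_items(tab)
  kept <- out$dictionary$item[out$dictionary$role == "feature"]
  expect_false("num1" %in% kept)
  expect_true("num2" %in% kept)
  expect_false("num3" %in% kept)
  log <- attr(out, "removal_log")
  expect_setequal(log$item, c("num1", "num3"))
  expect_equal(log$reason[log$item == "num3"], "string_response")

  # no missingness anywhere: identity
  clean <- tiny_table(n = 30)
  expect_identical(filter_items(clean)$values, clean$values)
})

test_that("participant filter excludes on outcomes and excess missingness", {
  tab <- tiny_table(n = 60)
  plan <- preprocess_plan(min_participants = 5)
  # one missing outcome item -> excluded
  tab$values$bp1[1] <- NA
  # 50% feature missingness (2 of 4) -> excluded
  tab$values$num1[2] <- NA
  tab$values$num2[2] <- NA
  out <- filter_participants(tab, plan = plan)
  expect_setequal(attr(out, "excluded"), c("p01", "p02"))
  expect_equal(nrow(out$values), 58)

  # complete table: no exclusions
  clean <- tiny_table(n = 30)
  expect_equal(nrow(filter_participants(clean, plan = plan)$values), 30)

  # survival floor
  strict <- preprocess_plan(min_participants = 1000)
  expect_error(filter_participants(tab, plan = strict), "survive")
})

test_that("splits reproduce the cohort partition sizes deterministically", {
  sp <- make_splits(2184, seed = 3)
  expect_equal(length(sp$discovery_idx), 1638)
  expect_equal(length(sp$holdout_idx), 546)
  expect_equal(length(sp$repeat_splits), 100)
  expect_length(intersect(sp$discovery_idx, sp$holdout_idx), 0)
  r1 <- sp$repeat_splits[[1]]
  expect_length(intersect(r1$train_idx, r1$test_idx), 0)
  expect_true(all(c(r1$train_idx, r1$test_idx) %in% sp$discovery_idx))

  small <- make_splits(8, seed = 1, n_repeats = 3)
  expect_equal(length(small$discovery_idx), 6)
  expect_equal(length(small$holdout_idx), 2)

  expect_identical(make_splits(500, seed = 9), make_splits(500, seed = 9))
  expect_error(make_splits(100, discovery_frac = 1.2), "fractions")
  expect_error(make_splits(4), "n >= 8")
})

test_that("fitted transform dummy-codes, drops constants, and standardizes", {
  tab <- tiny_table(n = 50)
  tab$values$num3 <- 5 # constant -> dropped
  res <- fit_transform(tab)
  expect_true(all(c("nom1=A", "nom1=B") %in% colnames(res$X)))
  expect_false("num3" %in% colnames(res$X))
  expect_true(all(res$X[, "nom1=A"] %in%
                    ((c(0, 1) - res$transform$center["nom1=A"]) /
                       res$transform$scale["nom1=A"])))
  expect_lt(max(abs(colMeans(res$X))), 1e-10)
  expect_lt(max(abs(apply(res$X, 2, sd) - 1)), 1e-10)
})

test_that("kNN imputation averages the nearest observed neighbours", {
  # row 1 misses num2; its 25 nearest rows (identical num1) all hold 7
  set.seed(4)
  n <- 46
  values <- data.frame(
    num1 = c(rep(0, 26), rep(50, 20)),
    num2 = c(NA, rep(7, 25), rnorm(20, 100, 10)),
    stringsAsFactors = FALSE
  )
  rownames(values) <- sprintf("p%02d", seq_len(n))
  dict <- data.frame(item = c("num1", "num2"), scale = "s1",
                     type = "numeric", role = "feature",
                     stringsAsFactors = FALSE)
  tab <- feature_table(values, dict)
  res <- fit_transform(tab, preprocess_plan(knn_k = 20))
  z7 <- (7 - res$transform$center["num2"]) / res$transform$scale["num2"]
  expect_equal(unname(res$X[1, "num2"]), unname(z7))
})

test_that("apply_transform reproduces the training design exactly", {
  co <- generate_cohort(light_config(120, 0.5, seed = 6, missing = TRUE,
                                     n_items = 24))
  tab <- co$table
  tab$values$nomx <- sample(c("u", "v", "w"), 120, replace = TRUE)
  tab <- feature_table(tab$values,
                       rbind(tab$dictionary,
                             data.frame(item = "nomx", scale = "scale01",
                                        type = "nominal", role = "feature")))
  res <- fit_transform(tab)
  expect_equal(apply_transform(res$transform, tab), res$X)
})

test_that("categories unseen in training map to all-zero dummies", {
  tab <- tiny_table(n = 50)
  res <- fit_transform(tab)
  new_tab <- tiny_table(n = 50, seed = 2)
  new_tab$values$nom1 <- "Z" # never seen in training
  X <- apply_transform(res$transform, new_tab)
  zero_a <- (0 - res$transform$center["nom1=A"]) / res$transform$scale["nom1=A"]
  expect_true(all(X[, "nom1=A"] == zero_a))
})

test_that("holdout rows never influence fitted statistics", {
  co <- generate_cohort(light_config(150, 0.5, seed = 8, missing = TRUE,
                                     n_items = 24))
  sp <- make_splits(nrow(co$table$values), n_repeats = 2, seed = 1)
  disc_tab <- feature_table(co$table$values[sp$discovery_idx, , drop = FALSE],
                            co$table$dictionary)
  ft1 <- fit_transform(disc_tab)
  perturbed <- co$table$values
  feats <- co$table$dictionary$item[co$table$dictionary$role == "feature"]
  perturbed[sp$holdout_idx, feats] <- perturbed[rev(sp$holdout_idx), feats]
  disc_tab2 <- feature_table(perturbed[sp$discovery_idx, , drop = FALSE],
                             co$table$dictionary)
  ft2 <- fit_transform(disc_tab2)
  expect_identical(ft1$transform$center, ft2$transform$center)
  expect_identical(ft1$transform$scale, ft2$transform$scale)
  expect_identical(ft1$X, ft2$X)
})
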