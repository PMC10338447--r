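test_that("default configuration emulates the target cohort shape", {
  co <- generate_cohort(synthetic_config())
  dict <- co$table$dictionary
  feats <- dict[dict$role == "feature", ]
  expect_equal(nrow(feats), 300)
  expect_equal(length(unique(feats$scale)), 29)
  expect_equal(nrow(co$table$values), 2184)
  expect_equal(sum(dict$role == "outcome"), 20)
  # enough high-missingness items for the 25% filter to bite
  miss_frac <- colMeans(is.na(co$table$values[feats$item]))
  expect_gt(sum(miss_frac > 0.25), 50)
})

test_that("generation is deterministic given the seed", {
  cfg <- light_config(100, 0.5, seed = 11, missing = TRUE)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$truth$missing_mask, b$truth$missing_mask)
  c <- generate_cohort(light_config(100, 0.5, seed = 12, missing = TRUE))
  expect_false(identical(a$table$values, c$table$values))
})

test_that("shared determinants drive the outcome-signal correlation", {
  # identical determinants: signals coincide exactly
  co <- generate_cohort(light_config(500, f = 1, noise = 0, seed = 3))
  expect_equal(cor(co$truth$y1_signal, co$truth$y2_signal), 1)
  # disjoint determinants: outcomes analytically independent
  rs <- vapply(1:5, function(s) {
    co <- generate_cohort(light_config(5000, f = 0, noise = 1, seed = s))
    gp <- compute_general_psychopathology(co$outcome_items[, 1:8])
    cor(gp$score, compute_bpaq(co$outcome_items[, 9:20])$total)
  }, numeric(1))
  expect_lt(max(abs(rs)), 0.1)
})

test_that("shared-factor bookkeeping matches the configured fraction", {
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    cfg <- light_config(50, f, seed = 1)
    co <- generate_cohort(cfg)
    expect_equal(length(co$truth$true_shared_factors),
                 round(f * cfg$n_outcome_factors))
  }
  cfg <- light_config(50, 0.5, seed = 1)
  lam <- generate_cohort(cfg)$truth$factor_loadings
  lam <- lam[lam != 0]
  expect_true(all(lam >= cfg$loading_range[1] & lam <= cfg$loading_range[2]))
})

test_that("item correlations converge to the factor-model structure", {
  cfg <- light_config(20000, 0.5, seed = 4)
  co <- generate_cohort(cfg)
  dict <- co$table$dictionary
  feats <- dict$item[dict$role == "feature" & dict$type == "numeric"]
  X <- as.matrix(co$table$values[feats])
  L <- co$truth$factor_loadings[feats, , drop = FALSE]
  target <- tcrossprod(L)
  diag(target) <- 1
  expect_lt(max(abs(cor(X) - target)), 0.05)
})

test_that("missingness rate matches the configuration", {
  cfg <- synthetic_config(n_high_missing_items = 0,
                          participant_missing_boost = 0,
                          item_missing_rate = 0.02, seed = 5)
  co <- generate_cohort(cfg)
  feats <- co$table$dictionary$item[co$table$dictionary$role == "feature"]
  rate <- mean(is.na(co$table$values[feats]))
  expect_lt(abs(rate - 0.02), 0.01)
})

test_that("too many latent factors is rejected", {
  cfg <- light_config(50, 0.5)
  cfg$n_latent_factors <- 100L
  expect_error(generate_cohort(cfg), "exceeds")
})

test_that("calibration hits a target outcome correlation", {
  base <- light_config(2184, 0, noise = 0.5, n_items = 30)
  # zero target returns a fully disjoint configuration
  cfg0 <- tune_overlap_for_target_r(base, 0)
  expect_equal(cfg0$shared_factor_fraction, 0)
  # the observed regime: calibrate then verify on fresh seeds
  cfg <- tune_overlap_for_target_r(base, 0.56, n_probe = 5000)
  rs <- vapply(1:10, function(s) {
    cc <- cfg
    cc$n_participants <- 5000L
    cc$seed <- 100L + s
    co <- generate_cohort(cc)
    gp <- compute_general_psychopathology(co$outcome_items[, 1:8])
    cor(gp$score, compute_bpaq(co$outcome_items[, 9:20])$total)
  }, numeric(1))
  expect_true(all(rs >= 0.51 & rs <= 0.61))
  # noise bounds the attainable correlation
  noisy <- light_config(2000, 0, noise = 3, n_items = 30)
  expect_error(tune_overlap_for_target_r(noisy, 0.99, n_probe = 2000),
               "bracketing")
})

test_that("cohorts round-trip through CSV/YAML", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(light_config(60, 0.5, seed = 2, missing = TRUE,
                                     n_items = 20))
  write_cohort(co, dir)
  back <- read_cohort(file.path(dir, "cohort.csv"),
                      file.path(dir, "dictionary.yaml"))
  expect_equal(back$table$dictionary, co$table$dictionary,
               ignore_attr = TRUE)
  num <- co$table$dictionary$item[co$table$dictionary$type == "numeric"]
  expect_equal(as.matrix(back$table$values[num]),
               as.matrix(co$table$values[num]), tolerance = 1e-8)
})
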