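#' Synthetic youth-cohort generator
#'
#' Generates participant-by-item survey tables with the statistical
#' structure the downstream analysis assumes: items organized in scales and
#' driven by latent factors, two outcomes (eight symptom-scale totals
#' feeding a p-factor, and a 12-item aggression questionnaire) whose
#' determinants overlap through a controllable set of shared factors, MCAR
#' missingness with a high-missingness item subset and a boosted
#' participant subset, and a minority of nominal items obtained by
#' thresholding latent normals. Ground truth (loadings, outcome weights,
#' shared factors, missing mask) is returned for recovery tests.
#'
#' @name synthetic_cohort
NULL

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions: 2184 participants and 300 items
#' across 29 scales, of which roughly 70 carry enough missingness to fall
#' to the 25% item filter (leaving about 230 features), with around 5% of
#' participants receiving boosted missingness. Each outcome draws on
#' `n_outcome_factors` latent factors; a fraction
#' `shared_factor_fraction` of them is shared between the outcomes, which
#' with the default outcome noise places the outcome correlation near the
#' 0.56 observed regime.
#'
#' @param n_participants,n_scales,items_per_scale,n_items cohort shape;
#'   `n_items` (total item count, spread as evenly as possible over the
#'   scales) wins over `n_scales * items_per_scale` when both are given.
#' @param n_latent_factors latent factors behind the items.
#' @param n_outcome_factors factors determining each outcome.
#' @param loading_range uniform range for primary loadings, within [0, 1].
#' @param shared_factor_fraction fraction of outcome-relevant factors
#'   shared by both outcomes, in [0, 1].
#' @param outcome_noise_sd noise standard deviation on outcome items
#'   (unit-variance factor signals).
#' @param item_missing_rate baseline MCAR cell-missingness of feature items.
#' @param participant_missing_boost extra missingness probability for a
#'   random 5% of participants.
#' @param n_nominal_items thresholded-categorical items (in addition to
#'   `sex`), 3-5 equiprobable categories each.
#' @param n_high_missing_items,high_missing_rate items given elevated
#'   missingness so the item filter has work to do.
#' @param seed RNG seed; generation is byte-identical given the seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 2184, n_scales = 29,
                             items_per_scale = 10, n_items = 300,
                             n_latent_factors = 12, n_outcome_factors = 4,
                             loading_range = c(0.4, 0.8),
                             shared_factor_fraction = 0.75,
                             outcome_noise_sd = 1.8,
                             item_missing_rate = 0.0015,
                             participant_missing_boost = 0.15,
                             n_nominal_items = 30,
                             n_high_missing_items = 70,
                             high_missing_rate = 0.35,
                             seed = 1) {
  if (is.null(n_items)) n_items <- n_scales * items_per_scale
  stopifnot(
    n_participants > 0, n_scales > 0, n_items >= n_scales,
    n_latent_factors > 0, n_outcome_factors > 0,
    length(loading_range) == 2, all(loading_range >= 0),
    all(loading_range <= 1), loading_range[1] <= loading_range[2],
    shared_factor_fraction >= 0, shared_factor_fraction <= 1,
    outcome_noise_sd >= 0,
    item_missing_rate >= 0, item_missing_rate <= 1,
    participant_missing_boost >= 0, participant_missing_boost <= 1,
    high_missing_rate >= 0, high_missing_rate <= 1,
    n_nominal_items >= 0, n_high_missing_items >= 0
  )
  shared <- round(shared_factor_fraction * n_outcome_factors)
  if (n_latent_factors < 2 * n_outcome_factors - shared) {
    stop("not enough latent factors for two outcome factor sets")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_scales = as.integer(n_scales),
         items_per_scale = as.integer(items_per_scale),
         n_items = as.integer(n_items),
         n_latent_factors = as.integer(n_latent_factors),
         n_outcome_factors = as.integer(n_outcome_factors),
         loading_range = loading_range,
         shared_factor_fraction = shared_factor_fraction,
         outcome_noise_sd = outcome_noise_sd,
         item_missing_rate = item_missing_rate,
         participant_missing_boost = participant_missing_boost,
         n_nominal_items = as.integer(n_nominal_items),
         n_high_missing_items = as.integer(min(n_high_missing_items, n_items)),
         high_missing_rate = high_missing_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# outcome-relevant factor index sets: y1 takes the first m factors, y2 the
# shared prefix plus the next disjoint block
outcome_factor_sets <- function(config) {
  m <- config$n_outcome_factors
  shared <- round(config$shared_factor_fraction * m)
  s1 <- seq_len(m)
  s2 <- c(seq_len(shared), if (shared < m) (m + 1):(2 * m - shared))
  list(y1 = s1, y2 = s2, shared = seq_len(shared))
}

#' Generate a synthetic cohort
#'
#' Items follow `x = lambda * z + sqrt(1 - lambda^2) * e` with standard
#' multivariate-normal factors `z`, so the item correlation matrix
#' converges to `Lambda Lambda' + diag(uniquenesses)`. The two outcome
#' signals are normalized sums over their factor sets; symptom-scale totals
#' and aggression items add independent noise with `outcome_noise_sd`.
#' MCAR missingness is applied per the configuration.
#'
#' @param config a [synthetic_config()].
#' @return List with `table` (a [feature_table()] holding features and
#'   outcome items), `outcome_items` (data frame of the 8 symptom totals
#'   and 12 aggression items), and `truth` (a `ground_truth` list:
#'   `factor_loadings`, `outcome_weights_y1`, `outcome_weights_y2`,
#'   `true_shared_factors`, `shared_feature_items`, `missing_mask`,
#'   `y1_signal`, `y2_signal`, `item_factor`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_participants
  p <- config$n_items
  kf <- config$n_latent_factors
  if (kf > p) stop("n_latent_factors exceeds the number of items")

  with_seed(config$seed, {
    # scale sizes as even as possible; scale s loads factor ((s-1) mod kf)+1
    sizes <- rep(p %/% config$n_scales, config$n_scales)
    extra <- p - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    scale_of_item <- rep(seq_len(config$n_scales), sizes)
    factor_of_item <- ((scale_of_item - 1L) %% kf) + 1L

    Z <- matrix(rnorm(n * kf), n, kf)
    lambda <- runif(p, config$loading_range[1], config$loading_range[2])
    E <- matrix(rnorm(n * p), n, p)
    X <- Z[, factor_of_item, drop = FALSE] *
      rep(lambda, each = n) + E * rep(sqrt(1 - lambda^2), each = n)

    item_names <- sprintf("s%02d_i%02d", scale_of_item,
                          sequence(sizes))
    scale_names <- sprintf("scale%02d", scale_of_item)
    colnames(X) <- item_names

    # items 1-2 of the first scale play age and sex
    item_names[1] <- "age"; item_names[2] <- "sex"
    colnames(X) <- item_names
    types <- rep("numeric", p)

    # nominal items: sex plus a random subset, 3-5 equiprobable categories
    nominal_idx <- 2L
    pool <- setdiff(seq_len(p), 1:2)
    if (config$n_nominal_items > 0) {
      nominal_idx <- c(nominal_idx,
                       sort(sample(pool, min(config$n_nominal_items,
                                             length(pool)))))
    }
    values <- as.data.frame(X)
    values[["age"]] <- round(20 + 2.8 * X[, 1], 1)
    for (j in nominal_idx) {
      if (j == 2L) {
        cuts <- qnorm(0.41)
        labs <- c("male", "female")
      } else {
        ncat <- sample(3:5, 1)
        cuts <- qnorm(seq_len(ncat - 1) / ncat)
        labs <- paste0("cat", seq_len(ncat))
      }
      values[[j]] <- labs[findInterval(X[, j], cuts) + 1L]
      types[j] <- "nominal"
    }

    # outcome signals: normalized sums over the factor sets
    sets <- outcome_factor_sets(config)
    m <- config$n_outcome_factors
    w1 <- w2 <- numeric(kf)
    w1[sets$y1] <- 1 / sqrt(m)
    w2[sets$y2] <- 1 / sqrt(m)
    g1 <- drop(Z %*% w1)
    g2 <- drop(Z %*% w2)
    sig <- config$outcome_noise_sd
    sym <- vapply(1:8, function(t) g1 + sig * rnorm(n), numeric(n))
    colnames(sym) <- sprintf("sym_%d", 1:8)
    bpaq <- vapply(1:12, function(t) g2 + sig * rnorm(n), numeric(n))
    colnames(bpaq) <- sprintf("bpaq_%d", 1:12)
    outcome_items <- as.data.frame(cbind(sym, bpaq))

    # MCAR missingness on features (baseline + high-missing items +
    # boosted participants) and a light rate on outcome items
    miss <- matrix(runif(n * p) < config$item_missing_rate, n, p)
    if (config$n_high_missing_items > 0) {
      hi_items <- sort(sample(pool, min(config$n_high_missing_items,
                                        length(pool))))
      miss[, hi_items] <- miss[, hi_items] |
        (matrix(runif(n * length(hi_items)), n) < config$high_missing_rate)
    } else {
      hi_items <- integer()
    }
    boosted <- sample.int(n, round(0.05 * n))
    if (length(boosted) && config$participant_missing_boost > 0) {
      miss[boosted, ] <- miss[boosted, ] |
        (matrix(runif(length(boosted) * p), length(boosted)) <
           config$participant_missing_boost)
    }
    for (j in seq_len(p)) values[miss[, j], j] <- NA
    miss_out <- matrix(runif(n * 20) < config$item_missing_rate / 10, n, 20)
    outcome_values <- outcome_items
    for (j in seq_len(20)) outcome_values[miss_out[, j], j] <- NA

    all_values <- cbind(values, outcome_values)
    rownames(all_values) <- sprintf("p%04d", seq_len(n))
    dictionary <- data.frame(
      item = c(item_names, colnames(outcome_items)),
      scale = c(scale_names, rep("symptoms", 8), rep("bpaq", 12)),
      type = c(types, rep("numeric", 20)),
      role = c(rep("feature", p), rep("outcome", 20)),
      stringsAsFactors = FALSE
    )

    loadings <- matrix(0, p, kf,
                       dimnames = list(item_names, paste0("Z", seq_len(kf))))
    loadings[cbind(seq_len(p), factor_of_item)] <- lambda
    truth <- structure(
      list(factor_loadings = loadings,
           outcome_weights_y1 = w1, outcome_weights_y2 = w2,
           true_shared_factors = sets$shared,
           shared_feature_items = item_names[factor_of_item %in% sets$shared],
           high_missing_items = item_names[hi_items],
           boosted_participants = rownames(all_values)[sort(boosted)],
           missing_mask = cbind(miss, miss_out),
           y1_signal = g1, y2_signal = g2,
           item_factor = setNames(factor_of_item, item_names)),
      class = "ground_truth"
    )

    list(table = feature_table(all_values, dictionary),
         outcome_items = outcome_items, truth = truth)
  })
}

# simulated outcome correlation (p-factor vs aggression total) for a config
# at a probe size, on complete data
probe_outcome_r <- function(config, n_probe, probe_seed) {
  cfg <- config
  cfg$n_participants <- as.integer(n_probe)
  cfg$item_missing_rate <- 0
  cfg$participant_missing_boost <- 0
  cfg$high_missing_rate <- 0
  cfg$seed <- as.integer(probe_seed)
  co <- generate_cohort(cfg)
  gp <- compute_general_psychopathology(co$outcome_items[, 1:8])
  ag <- compute_bpaq(co$outcome_items[, 9:20])
  cor(gp$score, ag$total)
}

#' Calibrate the generator to a target outcome correlation
#'
#' Finds a configuration whose simulated correlation between the p-factor
#' and the aggression total is within `tol` of `target_r` at `n_probe`
#' participants: the shared-factor count is raised until the correlation
#' brackets the target at the configured noise level, then the outcome
#' noise is bisected upward to meet it. An unattainable target (the
#' configured noise bounds the reachable correlation) raises a
#' bracketing-failure error.
#'
#' @param config a [synthetic_config()]; its `outcome_noise_sd` acts as the
#'   noise floor.
#' @param target_r target correlation in [0, 1).
#' @param n_probe probe cohort size.
#' @param tol acceptance half-width on the simulated correlation.
#' @return A calibrated `synthetic_config`.
#' @export
tune_overlap_for_target_r <- function(config = synthetic_config(), target_r,
                                      n_probe = 5000, tol = 0.05) {
  stopifnot(inherits(config, "synthetic_config"),
            target_r >= 0, target_r < 1)
  if (target_r == 0) {
    config$shared_factor_fraction <- 0
    return(config)
  }
  m <- config$n_outcome_factors
  probe_seed <- derive_seed(config$seed, "tune-probe")
  r_at <- function(f, noise) {
    cfg <- config
    cfg$shared_factor_fraction <- f
    cfg$outcome_noise_sd <- noise
    probe_outcome_r(cfg, n_probe, probe_seed)
  }
  base_noise <- config$outcome_noise_sd
  f_star <- NA
  for (c_shared in seq_len(m)) {
    f <- c_shared / m
    r <- r_at(f, base_noise)
    if (r >= target_r - tol) {
      f_star <- f
      break
    }
  }
  if (is.na(f_star)) {
    stop("bracketing failure: target correlation ", target_r,
         " is unattainable at the configured noise level (max simulated r ",
         sprintf("%.3f", r), ")")
  }
  if (abs(r - target_r) <= tol) {
    config$shared_factor_fraction <- f_star
    return(config)
  }
  # r exceeds target: raise noise; bisect on [base_noise, hi]
  hi <- max(base_noise, 0.25)
  r_hi <- r
  while (r_hi > target_r && hi < 64) {
    hi <- hi * 2
    r_hi <- r_at(f_star, hi)
  }
  if (r_hi > target_r) stop("bracketing failure: could not bound noise")
  lo <- base_noise
  for (it in seq_len(40)) {
    mid <- (lo + hi) / 2
    r_mid <- r_at(f_star, mid)
    if (abs(r_mid - target_r) <= tol / 2) {
      lo <- hi <- mid
      break
    }
    if (r_mid > target_r) lo <- mid else hi <- mid
  }
  config$shared_factor_fraction <- f_star
  config$outcome_noise_sd <- (lo + hi) / 2
  r_final <- r_at(f_star, config$outcome_noise_sd)
  if (abs(r_final - target_r) > tol) {
    stop(sprintf(
      "bracketing failure: calibrated r = %.3f misses target %.3f", r_final,
      target_r))
  }
  config
}

#' Write / read a cohort on disk
#'
#' The cohort is persisted as plain text: values as CSV (one row per
#' participant, `NA` for missing), the data dictionary as YAML, and the
#' ground truth (when present) as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  values <- data.frame(participant = rownames(cohort$table$values),
                       cohort$table$values, check.names = FALSE)
  write.csv(values, file.path(dir, "cohort.csv"), row.names = FALSE)
  dict <- cohort$table$dictionary
  yaml::write_yaml(
    setNames(lapply(seq_len(nrow(dict)), function(i) {
      list(scale = dict$scale[i], type = dict$type[i], role = dict$role[i])
    }), dict$item),
    file.path(dir, "dictionary.yaml")
  )
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(factor_loadings = tr$factor_loadings,
           outcome_weights_y1 = tr$outcome_weights_y1,
           outcome_weights_y2 = tr$outcome_weights_y2,
           true_shared_factors = tr$true_shared_factors,
           shared_feature_items = tr$shared_feature_items,
           item_factor = as.list(tr$item_factor)),
      file.path(dir, "ground_truth.json"), digits = NA
    )
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param csv_path,dictionary_path file paths written by [write_cohort()].
#' @export
read_cohort <- function(csv_path, dictionary_path) {
  values <- read.csv(csv_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
  rownames(values) <- values$participant
  values$participant <- NULL
  dict_raw <- yaml::read_yaml(dictionary_path)
  dictionary <- data.frame(
    item = names(dict_raw),
    scale = vapply(dict_raw, `[[`, "", "scale"),
    type = vapply(dict_raw, `[[`, "", "type"),
    role = vapply(dict_raw, `[[`, "", "role"),
    stringsAsFactors = FALSE
  )
  for (it in dictionary$item[dictionary$type %in% c("numeric")]) {
    values[[it]] <- as.numeric(values[[it]])
  }
  list(table = feature_table(values, dictionary))
}
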