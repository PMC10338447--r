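#' End-to-end pipeline
#'
#' Orchestrates the full analysis: cohort generation (or ingestion),
#' item/participant filtering, outcome scoring, discovery/holdout and
#' repeated inner splits, per-outcome penalized ensembles, overlap
#' extraction, holdout and cross-outcome prediction, factor reduction of
#' the overlap features on the complete-case subset, automatic
#' normalization, GGM estimation, and stability analysis. Every stage seed
#' is derived deterministically from the master seed, so a run is
#' reproducible end to end. The p-factor, every preprocessing statistic,
#' the penalty choices and the coefficients are fitted on discovery rows
#' only; holdout rows are touched solely by the final prediction step.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()] used when no cohort is given.
#' @param cohort optional pre-built cohort (result of [generate_cohort()]
#'   or [read_cohort()]); when supplied, generation is skipped.
#' @param plan a [preprocess_plan()].
#' @param ensemble an [ensemble_config()].
#' @param ggm a [ggm_config()].
#' @param stability list with `n_boot`, `n_boot_per_level`, `drop_grid`.
#' @param master_seed master seed; each stage derives its own sub-seed.
#' @param out_dir optional directory where artifacts (CSV/JSON) are
#'   persisted.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(), cohort = NULL,
                       plan = preprocess_plan(),
                       ensemble = ensemble_config(),
                       ggm = ggm_config(),
                       stability = list(n_boot = 250, n_boot_per_level = 20,
                                        drop_grid = seq(0.05, 0.75, 0.05)),
                       master_seed = 1, out_dir = NULL) {
  structure(list(synthetic = synthetic, cohort = cohort, plan = plan,
                 ensemble = ensemble, ggm = ggm, stability = stability,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "run_config")
}

outcome_item_names <- function(dict) {
  list(symptoms = dict$item[dict$role == "outcome" & dict$scale == "symptoms"],
       bpaq = dict$item[dict$role == "outcome" & dict$scale == "bpaq"])
}

#' Run the full pipeline
#'
#' @param config a [run_config()].
#' @return A `run_report` list aggregating, per stage: the filtered cohort
#'   dimensions, outcome correlations (discovery and holdout, plus the
#'   subfactor-by-scale FDR grid), per-outcome holdout metrics (all
#'   features and overlap-restricted), cross-prediction metrics, the
#'   overlap feature set, the factor count and model, the normalization
#'   choices, the network edge list, and the stability reports.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  ms <- config$master_seed
  stage <- function(name) derive_seed(ms, name)

  # --- cohort ---------------------------------------------------------
  cohort <- config$cohort
  if (is.null(cohort)) {
    scfg <- config$synthetic
    scfg$seed <- stage("cohort")
    cohort <- generate_cohort(scfg)
  }
  tab <- filter_items(cohort$table, config$plan)
  removal_log <- attr(tab, "removal_log")
  tab <- filter_participants(tab, plan = config$plan)
  n <- nrow(tab$values)
  dict <- tab$dictionary
  onames <- outcome_item_names(dict)
  if (length(onames$symptoms) < 2 || length(onames$bpaq) != 12) {
    stop("cohort must carry symptom-scale totals and 12 aggression items ",
         "(dictionary scales 'symptoms' and 'bpaq')")
  }

  # --- splits ---------------------------------------------------------
  splits <- make_splits(n, n_repeats = config$ensemble$n_repeats,
                        seed = stage("splits"))
  disc <- splits$discovery_idx
  hold <- splits$holdout_idx

  # --- outcomes (fitted on discovery, projected on holdout) -----------
  sym <- as.matrix(tab$values[onames$symptoms])
  bp <- as.matrix(tab$values[onames$bpaq])
  gp_fit <- compute_general_psychopathology(sym[disc, , drop = FALSE])
  y_gpsy <- numeric(n)
  y_gpsy[disc] <- gp_fit$score
  y_gpsy[hold] <- project_general_psychopathology(gp_fit,
                                                  sym[hold, , drop = FALSE])
  aggr <- compute_bpaq(bp)
  y_aggr <- aggr$total

  r_discovery <- cor(y_gpsy[disc], y_aggr[disc])
  r_holdout <- cor(y_gpsy[hold], y_aggr[hold])
  scale_grid <- correlate_with_fdr(
    cbind(total = y_aggr, aggr$subfactors)[disc, , drop = FALSE],
    sym[disc, , drop = FALSE])

  # --- canonical discovery transform + ensembles ----------------------
  disc_tab <- feature_table(tab$values[disc, , drop = FALSE], dict)
  canon <- fit_transform(disc_tab, config$plan)
  hold_tab <- feature_table(tab$values[hold, , drop = FALSE], dict)
  X_hold <- apply_transform(canon$transform, hold_tab)

  ecfg <- config$ensemble
  ecfg$seed <- stage("ensemble-gpsy")
  model_gpsy <- run_ensemble(tab, y_gpsy, splits, ecfg, config$plan)
  ecfg$seed <- stage("ensemble-aggr")
  model_aggr <- run_ensemble(tab, y_aggr, splits, ecfg, config$plan)

  sc_gpsy <- fit_outcome_scaler(y_gpsy[disc])
  sc_aggr <- fit_outcome_scaler(y_aggr[disc])
  yh_gpsy <- apply_outcome_scaler(sc_gpsy, y_gpsy[hold])
  yh_aggr <- apply_outcome_scaler(sc_aggr, y_aggr[hold])

  holdout_gpsy <- predict_with_mean_betas(model_gpsy, X_hold, yh_gpsy)
  holdout_aggr <- predict_with_mean_betas(model_aggr, X_hold, yh_aggr)

  ov <- overlap_and_restrict(model_gpsy, model_aggr)
  holdout_gpsy_overlap <- predict_with_mean_betas(ov$model_a, X_hold, yh_gpsy)
  holdout_aggr_overlap <- predict_with_mean_betas(ov$model_b, X_hold, yh_aggr)
  cross_aggr_to_gpsy <- cross_predict(ov$model_b, X_hold, yh_gpsy)
  cross_gpsy_to_aggr <- cross_predict(ov$model_a, X_hold, yh_aggr)

  if (length(ov$overlap_features) < 3) {
    stop("network stage needs at least 3 overlap features, got ",
         length(ov$overlap_features))
  }

  # --- complete-case network stage ------------------------------------
  feats <- dict$item[dict$role == "feature"]
  complete_rows <- which(rowSums(is.na(tab$values[feats])) == 0)
  cc_tab <- feature_table(tab$values[complete_rows, , drop = FALSE], dict)
  X_cc <- apply_transform(canon$transform, cc_tab)
  X_cc <- X_cc[, ov$overlap_features, drop = FALSE]

  n_factors <- parallel_analysis(X_cc, seed = stage("parallel"))
  if (n_factors < 1) {
    warning("parallel analysis retained no factor; using 1")
    n_factors <- 1L
  }
  fmodel <- fit_minres_oblimin(X_cc, n_factors)
  scores <- factor_scores(fmodel, X_cc)

  node_data <- cbind(scores,
                     GPsy = y_gpsy[complete_rows],
                     Aggr = y_aggr[complete_rows])
  normalized <- auto_normalize_columns(node_data)

  net <- ggm_mod_select(normalized$X, config$ggm)
  ei <- expected_influence(net)

  st <- config$stability
  edge_report <- bootstrap_edges(normalized$X, config$ggm,
                                 n_boot = st$n_boot, seed = stage("boot"))
  cs <- casedrop_cs(normalized$X, config$ggm, drop_grid = st$drop_grid,
                    n_boot_per_level = st$n_boot_per_level,
                    seed = stage("casedrop"))

  report <- structure(
    list(
      n_participants = n,
      n_features = sum(dict$role == "feature"),
      removal_log = removal_log,
      n_discovery = length(disc), n_holdout = length(hold),
      pfactor_variance_explained = gp_fit$variance_explained,
      pfactor_loadings = gp_fit$loadings,
      outcome_r = c(discovery = r_discovery, holdout = r_holdout),
      scale_grid = scale_grid,
      n_significant = c(gpsy = sum(model_gpsy$significance_mask),
                        aggr = sum(model_aggr$significance_mask)),
      overlap_features = ov$overlap_features,
      holdout_metrics = list(gpsy = holdout_gpsy, aggr = holdout_aggr),
      holdout_metrics_overlap = list(gpsy = holdout_gpsy_overlap,
                                     aggr = holdout_aggr_overlap),
      cross_prediction = list(aggr_model_to_gpsy = cross_aggr_to_gpsy,
                              gpsy_model_to_aggr = cross_gpsy_to_aggr),
      model_gpsy = model_gpsy, model_aggr = model_aggr,
      n_complete = length(complete_rows),
      n_factors = as.integer(n_factors),
      factor_model = fmodel,
      transform_choices = lapply(normalized$choices, function(ch)
        list(method = ch$method, normality_stat = ch$normality_stat)),
      network = net,
      expected_influence = ei,
      edge_report = edge_report,
      edge_table = edge_stability_table(edge_report,
                                        nodes = c("GPsy", "Aggr")),
      cs = cs,
      master_seed = ms
    ),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) persist_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  participants: %d (%d discovery / %d holdout), %d features\n",
              x$n_participants, x$n_discovery, x$n_holdout, x$n_features))
  cat(sprintf("  p-factor PC1 variance explained: %.1f%%\n",
              100 * x$pfactor_variance_explained))
  cat(sprintf("  outcome correlation: discovery %.3f, holdout %.3f\n",
              x$outcome_r["discovery"], x$outcome_r["holdout"]))
  cat(sprintf("  significant features: %d (GPsy), %d (Aggr); overlap %d\n",
              x$n_significant["gpsy"], x$n_significant["aggr"],
              length(x$overlap_features)))
  cat(sprintf("  holdout r: GPsy %.3f, Aggr %.3f; cross r: Aggr->GPsy %.3f, GPsy->Aggr %.3f\n",
              x$holdout_metrics$gpsy$r, x$holdout_metrics$aggr$r,
              x$cross_prediction$aggr_model_to_gpsy$r,
              x$cross_prediction$gpsy_model_to_aggr$r))
  cat(sprintf("  network: %d factors + 2 outcomes, %d edges, CS = %.2f\n",
              x$n_factors, sum(x$network$structure) / 2,
              x$cs$cs_coefficient))
  invisible(x)
}

# persist the main artifacts as plain text
persist_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(report$network, file.path(dir, "network_edges.csv"))
  write.csv(report$edge_table, file.path(dir, "edge_stability.csv"),
            row.names = FALSE)
  write.csv(report$expected_influence,
            file.path(dir, "expected_influence.csv"), row.names = FALSE)
  write.csv(data.frame(feature = rownames(report$factor_model$loadings),
                       report$factor_model$loadings, check.names = FALSE),
            file.path(dir, "factor_loadings.csv"), row.names = FALSE)
  write_correlation_report(report$scale_grid,
                           file.path(dir, "correlation_grid.csv"))
  metr <- function(m) m[c("r", "r_squared", "rmse", "mae")]
  jsonlite::write_json(
    list(
      n_participants = report$n_participants,
      n_discovery = report$n_discovery, n_holdout = report$n_holdout,
      pfactor_variance_explained = report$pfactor_variance_explained,
      outcome_r = as.list(report$outcome_r),
      n_significant = as.list(report$n_significant),
      n_overlap = length(report$overlap_features),
      overlap_features = report$overlap_features,
      holdout = lapply(report$holdout_metrics, metr),
      holdout_overlap = lapply(report$holdout_metrics_overlap, metr),
      cross_prediction = lapply(report$cross_prediction, metr),
      n_factors = report$n_factors,
      transform_choices = report$transform_choices,
      cs_coefficient = report$cs$cs_coefficient,
      master_seed = report$master_seed
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
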