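#' Network stability analysis
#'
#' Robustness of an estimated GGM is quantified three ways: percentile
#' bootstrap intervals for edge weights (rows resampled with replacement,
#' full model-selection refit per resample), expected-influence centrality,
#' and the case-drop correlation-stability (CS) coefficient: the largest
#' proportion of cases that can be dropped while, with 95% certainty, the
#' subset-based centrality still correlates at least 0.7 with the
#' full-sample centrality.
#'
#' @name network_stability
NULL

#' Expected-influence centrality
#'
#' One-step expected influence: the signed sum of each node's edge weights.
#' For all-positive networks it coincides with strength centrality; a node
#' with no edges scores 0.
#'
#' @param net a `ggm_network`.
#' @return Data frame with columns `node` and `expected_influence`.
#' @export
expected_influence <- function(net) {
  stopifnot(inherits(net, "ggm_network"))
  data.frame(node = net$nodes,
             expected_influence = unname(rowSums(net$weights)),
             stringsAsFactors = FALSE)
}

#' Nonparametric bootstrap of edge weights
#'
#' Resamples rows with replacement `n_boot` times, refits the full stepwise
#' GGM selection on each resample, and reports percentile 95% intervals per
#' edge. Edges absent from a resampled network contribute weight 0. Edges
#' whose interval excludes 0 are flagged stable. Resamples whose refit fails
#' are skipped; more than 10% failures aborts.
#'
#' @param X complete numeric matrix (participants x nodes).
#' @param config a [ggm_config()].
#' @param n_boot number of bootstrap resamples (reference default 1000).
#' @param seed RNG seed.
#' @param ci_level interval coverage.
#' @return An `edge_ci_report` data frame: `node1`, `node2`, `sample`
#'   (full-data weight), `boot_mean`, `ci_low`, `ci_high`, `stable`,
#'   with attributes `n_boot` and `n_failed`.
#' @export
bootstrap_edges <- function(X, config = ggm_config(), n_boot = 1000,
                            seed = NULL, ci_level = 0.95) {
  X <- as.matrix(X)
  full <- ggm_mod_select(X, config)
  p <- length(full$nodes)
  idx <- which(upper.tri(full$weights), arr.ind = TRUE)
  boot_w <- matrix(NA_real_, n_boot, nrow(idx))
  n_failed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nrow(X), nrow(X), replace = TRUE)
      net_b <- tryCatch(ggm_mod_select(X[rows, , drop = FALSE], config),
                        error = function(e) NULL)
      if (is.null(net_b)) {
        n_failed <- n_failed + 1L
        next
      }
      boot_w[b, ] <- net_b$weights[idx]
    }
  })
  if (n_failed > 0.1 * n_boot) {
    stop(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot))
  }
  ok <- !is.na(boot_w[, 1])
  a <- (1 - ci_level) / 2
  rep_ <- data.frame(
    node1 = full$nodes[idx[, 1]],
    node2 = full$nodes[idx[, 2]],
    sample = full$weights[idx],
    boot_mean = colMeans(boot_w[ok, , drop = FALSE]),
    ci_low = apply(boot_w[ok, , drop = FALSE], 2, quantile, probs = a),
    ci_high = apply(boot_w[ok, , drop = FALSE], 2, quantile, probs = 1 - a),
    stringsAsFactors = FALSE
  )
  rep_$stable <- rep_$ci_low > 0 | rep_$ci_high < 0
  attr(rep_, "n_boot") <- sum(ok)
  attr(rep_, "n_failed") <- n_failed
  class(rep_) <- c("edge_ci_report", "data.frame")
  rep_
}

#' Case-drop bootstrap and the CS coefficient for expected influence
#'
#' At each drop proportion `d`, subsamples `(1 - d) * n` rows without
#' replacement `n_boot_per_level` times, refits the network, and correlates
#' the subsample expected influence with the full-sample expected influence
#' across nodes. The CS coefficient is the largest `d` at which at least
#' `certainty` of the correlations reach `correlation_threshold` (0 when no
#' level qualifies). Degenerate refits (no edges, so constant centrality)
#' count as correlation 0.
#'
#' @param X complete numeric matrix.
#' @param config a [ggm_config()].
#' @param drop_grid drop proportions (convention caps at 0.75).
#' @param n_boot_per_level subsamples per level.
#' @param seed RNG seed.
#' @param correlation_threshold,certainty CS definition constants.
#' @return A `cs_report` list: `cs_coefficient`, `levels` (per-level
#'   data frame with correlation quantiles and the pass fraction),
#'   `correlation_threshold`, `certainty`.
#' @export
casedrop_cs <- function(X, config = ggm_config(),
                        drop_grid = seq(0.05, 0.75, by = 0.05),
                        n_boot_per_level = 50, seed = NULL,
                        correlation_threshold = 0.7, certainty = 0.95) {
  X <- as.matrix(X)
  n <- nrow(X)
  full <- ggm_mod_select(X, config)
  ei_full <- expected_influence(full)$expected_influence
  if (min(1 - drop_grid) * n <= ncol(X)) {
    stop("maximum drop proportion leaves too few rows")
  }
  levels_ <- vector("list", length(drop_grid))
  with_seed(seed, {
    for (li in seq_along(drop_grid)) {
      d <- drop_grid[li]
      m <- floor((1 - d) * n)
      cors <- numeric(n_boot_per_level)
      failed <- 0L
      for (b in seq_len(n_boot_per_level)) {
        rows <- sample.int(n, m)
        net_b <- tryCatch(ggm_mod_select(X[rows, , drop = FALSE], config),
                          error = function(e) NULL)
        if (is.null(net_b)) {
          failed <- failed + 1L
          cors[b] <- NA_real_
          next
        }
        ei_b <- expected_influence(net_b)$expected_influence
        r <- suppressWarnings(cor(ei_b, ei_full))
        cors[b] <- if (is.na(r)) 0 else r
      }
      if (failed > 0.1 * n_boot_per_level) {
        stop(sprintf("too many refit failures at drop %.2f", d))
      }
      cors <- cors[!is.na(cors)]
      levels_[[li]] <- data.frame(
        drop = d,
        q05 = quantile(cors, 0.05, names = FALSE),
        q25 = quantile(cors, 0.25, names = FALSE),
        median = median(cors),
        pass_fraction = mean(cors >= correlation_threshold)
      )
    }
  })
  levels_ <- do.call(rbind, levels_)
  ok <- levels_$pass_fraction >= certainty
  cs <- if (any(ok)) max(levels_$drop[ok]) else 0
  structure(
    list(cs_coefficient = cs, levels = levels_,
         correlation_threshold = correlation_threshold,
         certainty = certainty,
         full_expected_influence = ei_full),
    class = "cs_report"
  )
}

#' @export
print.cs_report <- function(x, ...) {
  cat(sprintf(
    "<cs_report> CS = %.2f (correlation >= %.2f with %.0f%% certainty)\n",
    x$cs_coefficient, x$correlation_threshold, 100 * x$certainty))
  invisible(x)
}

#' Edge-stability summary table
#'
#' Restricts an [bootstrap_edges()] report to edges incident to the given
#' nodes (typically the two outcomes) and formats it with one row per edge:
#' sample weight, bootstrapped mean, and the bootstrapped 95% CI.
#'
#' @param edge_report an `edge_ci_report`.
#' @param nodes optional node labels to filter on (`NULL` keeps all edges).
#' @return Data frame with columns `Node1`, `Node2`, `Sample`,
#'   `Bootstrapped mean`, `Bootstrapped 95% CI`.
#' @export
edge_stability_table <- function(edge_report, nodes = NULL) {
  stopifnot(inherits(edge_report, "edge_ci_report"))
  keep <- if (is.null(nodes)) rep(TRUE, nrow(edge_report)) else
    edge_report$node1 %in% nodes | edge_report$node2 %in% nodes
  r <- edge_report[keep, , drop = FALSE]
  data.frame(
    Node1 = r$node1, Node2 = r$node2,
    Sample = r$sample,
    `Bootstrapped mean` = r$boot_mean,
    `Bootstrapped 95% CI` = sprintf("%.3f, %.3f", r$ci_low, r$ci_high),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
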