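#' Survey preprocessing with strict train/test separation
#'
#' Implements the study's preprocessing rules: item-level missingness
#' filtering (> 25% removed, strictly), exclusion of string-response items,
#' participant exclusion (missing outcome/age/sex items, or > 5% feature
#' missingness), full-indicator dummy coding of nominal items,
#' zero-variance removal, z-scoring, and k-nearest-neighbour imputation
#' (k = 20) on the standardized features. Every statistic is fitted on
#' training rows only and carried forward to test/holdout rows.
#'
#' @name preprocess
NULL

#' Construct a participant-by-item feature table
#'
#' @param values data frame, participants x items; `NA` marks missing;
#'   nominal items hold category labels.
#' @param dictionary data frame with columns `item`, `scale`, `type`
#'   (`numeric`, `nominal`, or `string`) and `role` (`feature` or
#'   `outcome`); every column of `values` must appear exactly once.
#' @return A `feature_table`.
#' @export
feature_table <- function(values, dictionary) {
  values <- as.data.frame(values)
  dictionary <- as.data.frame(dictionary)
  stopifnot(all(c("item", "scale", "type", "role") %in% names(dictionary)))
  if (anyDuplicated(dictionary$item)) stop("duplicate items in dictionary")
  if (!setequal(names(values), dictionary$item)) {
    stop("dictionary must cover exactly the columns of `values`")
  }
  dictionary <- dictionary[match(names(values), dictionary$item), ]
  structure(list(values = values, dictionary = dictionary),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d participants x %d items (%d features, %d outcome items)\n",
              nrow(x$values), ncol(x$values),
              sum(x$dictionary$role == "feature"),
              sum(x$dictionary$role == "outcome")))
  invisible(x)
}

#' Missingness mask of a feature table
#' @param table a `feature_table`.
#' @return Logical matrix, `TRUE` where missing.
#' @export
missing_mask <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  as.matrix(is.na(table$values))
}

ft_items <- function(table, role) {
  table$dictionary$item[table$dictionary$role == role]
}

#' Preprocessing plan
#'
#' @param item_missing_threshold items with a missing fraction strictly
#'   above this are removed (default 0.25).
#' @param participant_missing_threshold participants with a feature-missing
#'   fraction strictly above this are removed (default 0.05).
#' @param knn_k neighbours for imputation (default 20).
#' @param drop_string_items remove free-text items (default TRUE).
#' @param min_participants abort when fewer survive filtering.
#' @return A `preprocess_plan` list.
#' @export
preprocess_plan <- function(item_missing_threshold = 0.25,
                            participant_missing_threshold = 0.05,
                            knn_k = 20, drop_string_items = TRUE,
                            min_participants = 50) {
  stopifnot(item_missing_threshold > 0, item_missing_threshold < 1,
            participant_missing_threshold > 0,
            participant_missing_threshold < 1, knn_k >= 1)
  structure(list(item_missing_threshold = item_missing_threshold,
                 participant_missing_threshold = participant_missing_threshold,
                 knn_k = as.integer(knn_k),
                 drop_string_items = isTRUE(drop_string_items),
                 min_participants = min_participants),
            class = "preprocess_plan")
}

#' Remove high-missingness and string feature items
#'
#' Feature items whose missing fraction strictly exceeds the threshold
#' ("more than 25% missing") and string-response items are dropped; outcome
#' items are never touched. The removal log is attached as attribute
#' `removal_log` (columns `item`, `reason`, `missing_fraction`).
#'
#' @param table a `feature_table`. @param plan a [preprocess_plan()].
#' @return Filtered `feature_table` with a `removal_log` attribute.
#' @export
filter_items <- function(table, plan = preprocess_plan()) {
  stopifnot(inherits(table, "feature_table"))
  feats <- ft_items(table, "feature")
  miss_frac <- colMeans(is.na(table$values[feats]))
  types <- table$dictionary$type[match(feats, table$dictionary$item)]
  too_missing <- miss_frac > plan$item_missing_threshold
  is_string <- plan$drop_string_items & types == "string"
  drop <- too_missing | is_string
  log <- data.frame(
    item = feats[drop],
    reason = ifelse(is_string[drop], "string_response", "missingness"),
    missing_fraction = miss_frac[drop],
    row.names = NULL, stringsAsFactors = FALSE
  )
  keep_cols <- setdiff(names(table$values), feats[drop])
  if (!any(table$dictionary$role == "feature" &
           table$dictionary$item %in% keep_cols)) {
    stop("all feature items removed by the missingness/string filter")
  }
  out <- feature_table(table$values[keep_cols],
                       table$dictionary[table$dictionary$item %in% keep_cols, ])
  attr(out, "removal_log") <- log
  out
}

#' Exclude participants with missing key items or excess missingness
#'
#' Drops participants with any missing value among the outcome items (plus
#' `age` and `sex` when present), or with a feature-missing fraction
#' strictly above the participant threshold.
#'
#' @param table a `feature_table` (already item-filtered).
#' @param outcomes character vector of key item names; defaults to all
#'   items with role `outcome` plus `age`/`sex` if present.
#' @param plan a [preprocess_plan()].
#' @return Filtered `feature_table` with attribute `excluded` (row names of
#'   removed participants).
#' @export
filter_participants <- function(table, outcomes = NULL,
                                plan = preprocess_plan()) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(outcomes)) {
    outcomes <- c(ft_items(table, "outcome"),
                  intersect(c("age", "sex"), names(table$values)))
  }
  outcomes <- intersect(outcomes, names(table$values))
  feats <- setdiff(ft_items(table, "feature"), outcomes)
  key_missing <- if (length(outcomes)) {
    rowSums(is.na(table$values[outcomes])) > 0
  } else rep(FALSE, nrow(table$values))
  feat_frac <- rowMeans(is.na(table$values[feats]))
  drop <- key_missing | feat_frac > plan$participant_missing_threshold
  if (sum(!drop) < plan$min_participants) {
    stop(sprintf("only %d participants survive filtering (minimum %d)",
                 sum(!drop), plan$min_participants))
  }
  out <- feature_table(table$values[!drop, , drop = FALSE], table$dictionary)
  attr(out, "excluded") <- rownames(table$values)[drop]
  out
}

#' Discovery/holdout and repeated train/test splits
#'
#' One fixed discovery (3/4) / holdout (1/4) partition and `n_repeats`
#' independent train (3/4) / test (1/4) partitions of the discovery set.
#' The smaller block of each split takes the floor of its fraction, so
#' n = 2184 gives 1638 discovery and 546 holdout rows. Fully reproducible
#' from `seed`; repeat `r` derives its own sub-seed.
#'
#' @param n number of participants (>= 8).
#' @param discovery_frac,inner_train_frac split fractions in (0, 1).
#' @param n_repeats number of inner partitions.
#' @param seed RNG seed.
#' @return A `split_plan`: `discovery_idx`, `holdout_idx`, `repeat_splits`
#'   (list of `train_idx`/`test_idx`), `seed`.
#' @export
make_splits <- function(n, discovery_frac = 0.75, inner_train_frac = 0.75,
                        n_repeats = 100, seed = 1) {
  if (n < 8) stop("need n >= 8")
  if (discovery_frac <= 0 || discovery_frac >= 1 ||
      inner_train_frac <= 0 || inner_train_frac >= 1) {
    stop("split fractions must lie in (0, 1)")
  }
  n_holdout <- floor(n * (1 - discovery_frac))
  holdout <- with_seed(seed, sort(sample.int(n, n_holdout)))
  discovery <- setdiff(seq_len(n), holdout)
  n_test <- floor(length(discovery) * (1 - inner_train_frac))
  repeat_splits <- lapply(seq_len(n_repeats), function(r) {
    test <- with_seed(derive_seed(seed, paste0("repeat-", r)),
                      sort(sample(discovery, n_test)))
    list(train_idx = setdiff(discovery, test), test_idx = test)
  })
  structure(list(discovery_idx = discovery, holdout_idx = holdout,
                 repeat_splits = repeat_splits, seed = seed),
            class = "split_plan")
}

# ---- design-matrix construction ------------------------------------------

# raw (unscaled) design: numeric items as-is, nominal items expanded to one
# indicator column per training category; unseen categories map to all-zero
# dummies, NA stays NA
build_raw_design <- function(values, numeric_items, dummy_map) {
  n <- nrow(values)
  cols <- list()
  for (it in numeric_items) {
    cols[[it]] <- as.numeric(values[[it]])
  }
  for (it in names(dummy_map)) {
    v <- as.character(values[[it]])
    for (cat in dummy_map[[it]]) {
      col <- as.numeric(v == cat)
      col[is.na(v)] <- NA
      cols[[paste0(it, "=", cat)]] <- col
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(values)
  X
}

# squared Euclidean distances over mutually observed coordinates, rescaled
# by the fraction observed: d2 = p / |obs| * sum_obs (x - y)^2
masked_distances <- function(Zt, Zr) {
  p <- ncol(Zt)
  Mt <- !is.na(Zt); Mr <- !is.na(Zr)
  X0t <- Zt; X0t[!Mt] <- 0
  X0r <- Zr; X0r[!Mr] <- 0
  A <- (X0t^2) %*% t(Mr) + Mt %*% t(X0r^2) - 2 * X0t %*% t(X0r)
  C <- Mt %*% t(Mr)
  D2 <- p * A / C
  D2[C == 0] <- Inf
  D2
}

# impute missing cells of Zt as the unweighted mean of the k nearest
# reference rows (by masked distance) that observe the column; distance
# ties broken by reference row index
knn_impute <- function(Zt, Zr, k) {
  if (!anyNA(Zt)) return(Zt)
  D2 <- masked_distances(Zt, Zr)
  out <- Zt
  for (j in seq_len(ncol(Zt))) {
    rows <- which(is.na(Zt[, j]))
    if (length(rows) == 0L) next
    cand <- which(!is.na(Zr[, j]))
    if (length(cand) == 0L) {
      out[rows, j] <- 0 # standardized column mean
      next
    }
    vals <- Zr[cand, j]
    for (i in rows) {
      d <- D2[i, cand]
      sel <- order(d, cand)[seq_len(min(k, length(cand)))]
      out[i, j] <- mean(vals[sel])
    }
  }
  out
}

#' Fit the feature transform on training data
#'
#' Dummy-codes nominal items (full indicator set per category), drops
#' zero-variance and never-observed columns, z-scores with training
#' mean/sd, and imputes missing entries by the unweighted mean of the
#' `knn_k` nearest training rows (Euclidean distance over mutually observed
#' standardized features, rescaled by the fraction observed; ties by row
#' index). All statistics are retained so [apply_transform()] can reproduce
#' them on unseen rows.
#'
#' @param train a `feature_table` (already item/participant filtered).
#' @param plan a [preprocess_plan()].
#' @return List with `transform` (a `fitted_transform`) and `X`, the
#'   imputed standardized training design matrix.
#' @export
fit_transform <- function(train, plan = preprocess_plan()) {
  stopifnot(inherits(train, "feature_table"))
  dict <- train$dictionary
  feats <- dict$item[dict$role == "feature"]
  types <- dict$type[match(feats, dict$item)]
  numeric_items <- feats[types == "numeric"]
  nominal_items <- feats[types == "nominal"]
  dummy_map <- lapply(setNames(nominal_items, nominal_items), function(it) {
    sort(unique(as.character(train$values[[it]][!is.na(train$values[[it]])])))
  })
  dummy_map <- dummy_map[lengths(dummy_map) > 0]

  raw <- build_raw_design(train$values, numeric_items, dummy_map)
  n_obs <- colSums(!is.na(raw))
  if (any(n_obs == 0)) {
    warning("dropping never-observed columns: ",
            paste(colnames(raw)[n_obs == 0], collapse = ", "))
  }
  sds <- apply(raw, 2, sd, na.rm = TRUE)
  keep <- n_obs > 0 & !is.na(sds) & sds > 0
  raw <- raw[, keep, drop = FALSE]
  center <- colMeans(raw, na.rm = TRUE)
  scale_ <- apply(raw, 2, sd, na.rm = TRUE)
  Z <- sweep(sweep(raw, 2, center), 2, scale_, "/")

  ft <- structure(
    list(dummy_map = dummy_map, numeric_items = numeric_items,
         kept_items = colnames(raw), center = center, scale = scale_,
         imputer_reference = Z, knn_k = plan$knn_k),
    class = "fitted_transform"
  )
  list(transform = ft, X = knn_impute(Z, Z, plan$knn_k))
}

#' Apply a fitted transform to another feature table
#'
#' Reuses the training dummy map, kept columns, centering/scaling
#' statistics, and the training rows as the neighbour reference for
#' imputation. Categories unseen in training map to all-zero dummies.
#'
#' @param ft a `fitted_transform` from [fit_transform()].
#' @param other a `feature_table` over the same items.
#' @return Imputed standardized design matrix for `other`.
#' @export
apply_transform <- function(ft, other) {
  stopifnot(inherits(ft, "fitted_transform"), inherits(other, "feature_table"))
  raw <- build_raw_design(other$values, ft$numeric_items, ft$dummy_map)
  missing_cols <- setdiff(ft$kept_items, colnames(raw))
  if (length(missing_cols)) {
    stop("columns missing from new data: ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, ft$kept_items, drop = FALSE]
  Z <- sweep(sweep(raw, 2, ft$center), 2, ft$scale, "/")
  knn_impute(Z, ft$imputer_reference, ft$knn_k)
}

#' Fit / apply an outcome standardizer
#'
#' Outcomes are scaled and centered with training statistics; all reported
#' prediction errors are on this standardized scale.
#'
#' @param y numeric training outcome.
#' @return An `outcome_scaler` (center, scale).
#' @export
fit_outcome_scaler <- function(y) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) stop("outcome has zero variance")
  structure(list(center = mean(y), scale = s), class = "outcome_scaler")
}

#' @rdname fit_outcome_scaler
#' @param scaler an `outcome_scaler`. @param y_new outcome values to scale.
#' @export
apply_outcome_scaler <- function(scaler, y_new) {
  (y_new - scaler$center) / scaler$scale
}
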