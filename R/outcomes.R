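#' Outcome scoring: general psychopathology and proneness to aggression
#'
#' General psychopathology (the p-factor) is the first principal component
#' across the symptom-scale totals, oriented so higher scores mean more
#' symptoms. Proneness to aggression is the 12-item Buss-Perry Aggression
#' Questionnaire (short form) total with four intercorrelated subfactors:
#' physical aggression, verbal aggression, anger, hostility (3 items each).
#'
#' @name outcomes
NULL

#' First-principal-component general psychopathology score
#'
#' PCA on the correlation matrix (z-scored scale totals). The score is the
#' projection on the leading eigenvector, with the orientation flipped when
#' the loading sum is negative so that every symptom scale loads positively
#' for a common-factor structure.
#'
#' @param scale_scores complete numeric matrix, participants x symptom
#'   scales (>= 2 scales, >= 3 participants).
#' @return A `general_psychopathology` object: `score` (per participant,
#'   mean zero), `loadings` (per scale), `variance_explained`
#'   (leading eigenvalue / trace).
#' @export
compute_general_psychopathology <- function(scale_scores) {
  X <- as.matrix(scale_scores)
  if (anyNA(X)) stop("missing values must be handled upstream")
  if (ncol(X) < 2 || nrow(X) < 3) stop("need >= 2 scales and >= 3 participants")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop("zero-variance scale: ", paste(
    colnames(X)[sds == 0], collapse = ", "))
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  v <- pc$rotation[, 1]
  if (sum(v) < 0) v <- -v
  Z <- scale(X)
  score <- drop(Z %*% v)
  eig <- pc$sdev^2
  structure(
    list(score = score, loadings = v,
         variance_explained = eig[1] / sum(eig),
         center = colMeans(X), scale = apply(X, 2, sd)),
    class = "general_psychopathology"
  )
}

#' Project new participants onto a fitted p-factor
#'
#' Standardizes new scale totals with the fitting sample's statistics and
#' projects them on the stored leading eigenvector, so holdout scores never
#' feed back into the component definition.
#'
#' @param gp a `general_psychopathology` fit.
#' @param scale_scores new participants x symptom scales matrix.
#' @return Numeric score vector.
#' @export
project_general_psychopathology <- function(gp, scale_scores) {
  stopifnot(inherits(gp, "general_psychopathology"))
  X <- as.matrix(scale_scores)
  Z <- sweep(sweep(X, 2, gp$center), 2, gp$scale, "/")
  drop(Z %*% gp$loadings)
}

#' @export
print.general_psychopathology <- function(x, ...) {
  cat(sprintf("<general_psychopathology> PC1 explains %.1f%% of variance\n",
              100 * x$variance_explained))
  invisible(x)
}

#' Default mapping of the 12 BPAQ items to subfactors
#' @return Named list of three item indices per subfactor.
#' @export
bpaq_subfactor_map <- function() {
  list(physical = 1:3, verbal = 4:6, anger = 7:9, hostility = 10:12)
}

#' BPAQ aggression scores
#'
#' Total = sum of the 12 items; subfactor scores are the sums of their three
#' items and always add up to the total.
#'
#' @param items complete numeric matrix, participants x 12.
#' @param subfactor_map list mapping the four subfactors to item indices.
#' @return An `aggression_score` object: `total` plus `subfactors`
#'   (participants x 4 matrix).
#' @export
compute_bpaq <- function(items, subfactor_map = bpaq_subfactor_map()) {
  X <- as.matrix(items)
  if (ncol(X) != 12) stop("expected 12 BPAQ items")
  if (anyNA(X)) stop("missing BPAQ items must be handled upstream")
  idx <- sort(as.integer(unname(unlist(subfactor_map))))
  if (!identical(idx, 1:12)) stop("subfactor map must partition the 12 items")
  sub <- vapply(subfactor_map, function(ii) rowSums(X[, ii, drop = FALSE]),
                numeric(nrow(X)))
  structure(list(total = rowSums(X), subfactors = sub),
            class = "aggression_score")
}

#' Pairwise Pearson correlations with Benjamini-Hochberg FDR control
#'
#' Correlates every column of `left` with every column of `right`; p-values
#' come from the t transform of r, and q-values from the Benjamini-Hochberg
#' step-up over the full grid of tests as one family. Constant columns give
#' flagged (NA) cells that are excluded from the FDR family.
#'
#' @param left,right numeric matrices with equal row counts (n >= 4).
#' @param alpha significance threshold on q.
#' @return A `correlation_report`: matrices `r`, `p`, `q`, and logical
#'   `significant` (`q < alpha`).
#' @export
correlate_with_fdr <- function(left, right, alpha = 0.05) {
  L <- as.matrix(left); R <- as.matrix(right)
  if (nrow(L) != nrow(R)) stop("row counts differ")
  n <- nrow(L)
  if (n < 4) stop("need n >= 4")
  const_l <- apply(L, 2, sd) == 0
  const_r <- apply(R, 2, sd) == 0
  r <- suppressWarnings(cor(L, R))
  r[const_l, ] <- NA
  r[, const_r] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  q <- p
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  structure(
    list(r = r, p = p, q = q, significant = !is.na(q) & q < alpha,
         alpha = alpha, n = n),
    class = "correlation_report"
  )
}

#' Write a correlation report to CSV (long format)
#'
#' @param report a `correlation_report`.
#' @param path CSV destination (or `NULL` to just return the data frame).
#' @return Long data frame (`left`, `right`, `r`, `p`, `q`,
#'   `significant`), invisibly.
#' @export
write_correlation_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "correlation_report"))
  grid <- expand.grid(left = rownames(report$r), right = colnames(report$r),
                      stringsAsFactors = FALSE)
  out <- data.frame(grid, r = as.vector(report$r), p = as.vector(report$p),
                    q = as.vector(report$q),
                    significant = as.vector(report$significant))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  invisible(out)
}
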