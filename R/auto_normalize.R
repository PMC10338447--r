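#' Automatic normalizing-transformation selection
#'
#' Variables entering the Gaussian graphical model are first transformed
#' towards normality. For each variable a family of candidate transforms is
#' fitted and the one with the lowest Pearson chi-square normality statistic
#' (per class) on the training values is kept. Candidates, in tie-break
#' order (the simpler transform wins a tie): no transformation, Yeo-Johnson,
#' Box-Cox (positive data only), log10(x + a), square-root(x + a), arcsinh,
#' and ordered quantile normalization.
#'
#' @name auto_normalize
NULL

.AN_EPS <- 1e-3

#' Pearson chi-square normality statistic (per class)
#'
#' Standardizes `x`, partitions the standard normal into `ceiling(2 * n^0.4)`
#' equiprobable classes, and returns the Pearson chi-square statistic
#' `sum((O - E)^2 / E)` divided by the number of classes. Lower values
#' indicate better agreement with normality; a large standard-normal sample
#' scores close to 1. The statistic is invariant under affine maps of `x`.
#'
#' @param x numeric vector, length >= 20, finite values.
#' @return Non-negative scalar; `Inf` for zero-variance input.
#' @export
pearson_normality_stat <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("`x` must be finite")
  n <- length(x)
  if (n < 20L) stop("need at least 20 observations")
  if (sd(x) == 0) return(Inf)
  n_classes <- ceiling(2 * n^0.4)
  pt <- nortest::pearson.test(x, n.classes = n_classes)
  unname(pt$statistic) / n_classes
}

# ---- individual transforms ------------------------------------------------

yeo_johnson <- function(x, lambda) {
  pos <- x >= 0
  out <- numeric(length(x))
  if (abs(lambda) > 1e-8) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  l2 <- 2 - lambda
  if (abs(l2) > 1e-8) {
    out[!pos] <- -(((-x[!pos] + 1)^l2 - 1) / l2)
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out
}

yj_loglik <- function(lambda, x) {
  z <- yeo_johnson(x, lambda)
  s2 <- mean((z - mean(z))^2)
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -length(x) / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

box_cox <- function(x, lambda) {
  if (abs(lambda) > 1e-8) (x^lambda - 1) / lambda else log(x)
}

bc_loglik <- function(lambda, x) {
  z <- box_cox(x, lambda)
  s2 <- mean((z - mean(z))^2)
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -length(x) / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

# ordered quantile map: training value -> normal quantile of plotting
# position (r - 0.5)/n, mid-ranks for ties; new values interpolate linearly
# and extrapolate along the end segments
fit_orderquant <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  z <- qnorm((r - 0.5) / n)
  ux <- sort(unique(x))
  uz <- vapply(ux, function(v) z[match(v, x)], numeric(1))
  list(x = ux, z = uz)
}

apply_orderquant <- function(map, xnew) {
  ux <- map$x
  uz <- map$z
  if (length(ux) == 1L) return(rep(uz, length(xnew)))
  out <- approx(ux, uz, xout = xnew, rule = 2)$y
  # linear tail extrapolation keeps the map strictly monotone outside range
  lo <- xnew < ux[1]
  hi <- xnew > ux[length(ux)]
  if (any(lo)) {
    s <- (uz[2] - uz[1]) / (ux[2] - ux[1])
    out[lo] <- uz[1] + s * (xnew[lo] - ux[1])
  }
  if (any(hi)) {
    m <- length(ux)
    s <- (uz[m] - uz[m - 1]) / (ux[m] - ux[m - 1])
    out[hi] <- uz[m] + s * (xnew[hi] - ux[m])
  }
  out
}

.an_methods <- c("identity", "yeo_johnson", "box_cox", "log10_shift",
                 "sqrt_shift", "arcsinh", "ordered_quantile")

an_fit_one <- function(method, x) {
  eps <- .AN_EPS
  switch(method,
    identity = list(),
    yeo_johnson = {
      opt <- optimize(yj_loglik, interval = c(-5, 5), x = x, maximum = TRUE)
      list(lambda = opt$maximum)
    },
    box_cox = {
      if (any(x <= 0)) return(NULL)
      opt <- optimize(bc_loglik, interval = c(-5, 5), x = x, maximum = TRUE)
      list(lambda = opt$maximum)
    },
    log10_shift = list(a = max(eps, eps - min(x))),
    sqrt_shift = list(a = max(eps, eps - min(x))),
    arcsinh = list(),
    ordered_quantile = list(map = fit_orderquant(x))
  )
}

an_apply_one <- function(method, params, x) {
  switch(method,
    identity = x,
    yeo_johnson = yeo_johnson(x, params$lambda),
    box_cox = box_cox(pmax(x, .AN_EPS^2), params$lambda),
    log10_shift = log10(pmax(x + params$a, .AN_EPS^2)),
    sqrt_shift = sqrt(pmax(x + params$a, 0)),
    arcsinh = asinh(x),
    ordered_quantile = apply_orderquant(params$map, x)
  )
}

#' Fit the best normalizing transform for one variable
#'
#' Fits every admissible candidate (Yeo-Johnson and Box-Cox lambdas by
#' maximum likelihood; shifts `a = max(eps, eps - min(x))`; ordered quantile
#' via normal scores of plotting positions) and returns the one whose
#' transformed training values have the lowest [pearson_normality_stat()].
#' Ties go to the earlier (simpler) candidate in the listed order.
#'
#' @param x numeric training vector (length >= 20, finite).
#' @return A `transform_choice` object with elements `method`, `params`,
#'   and `normality_stat`.
#' @seealso [apply_transform_choice()]
#' @export
fit_best_transform <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("`x` must be finite")
  if (length(x) < 20L) stop("need at least 20 observations")
  stats_ <- rep(Inf, length(.an_methods))
  fits <- vector("list", length(.an_methods))
  for (i in seq_along(.an_methods)) {
    m <- .an_methods[i]
    p <- an_fit_one(m, x)
    if (is.null(p)) next
    z <- an_apply_one(m, p, x)
    if (any(!is.finite(z))) next
    fits[[i]] <- p
    stats_[i] <- pearson_normality_stat(z)
  }
  if (all(!is.finite(stats_))) {
    warning("all candidate transforms failed; falling back to identity")
    best <- 1L
    fits[[1L]] <- list()
    stats_[1L] <- pearson_normality_stat(x)
  } else {
    best <- which.min(stats_) # which.min returns the first minimum: tie-break
  }
  structure(
    list(method = .an_methods[best], params = fits[[best]],
         normality_stat = stats_[best]),
    class = "transform_choice"
  )
}

#' Apply a fitted normalizing transform to new values
#'
#' Monotone on the training range; ordered-quantile maps extrapolate new
#' values along the fitted tail segments.
#'
#' @param choice a `transform_choice` from [fit_best_transform()].
#' @param x numeric vector.
#' @return Transformed numeric vector.
#' @export
apply_transform_choice <- function(choice, x) {
  stopifnot(inherits(choice, "transform_choice"))
  an_apply_one(choice$method, choice$params, as.numeric(x))
}

#' @export
print.transform_choice <- function(x, ...) {
  cat("<transform_choice>", x$method,
      sprintf("(normality stat %.3f)\n", x$normality_stat))
  invisible(x)
}

#' Auto-normalize every column of a matrix or data frame
#'
#' @param X numeric matrix / data frame.
#' @return List with `X` (transformed matrix) and `choices` (named list of
#'   `transform_choice`, serializable to JSON for audit).
#' @export
auto_normalize_columns <- function(X) {
  X <- as.matrix(X)
  choices <- setNames(vector("list", ncol(X)), colnames(X))
  out <- X
  for (j in seq_len(ncol(X))) {
    ch <- fit_best_transform(X[, j])
    choices[[j]] <- ch
    out[, j] <- apply_transform_choice(ch, X[, j])
  }
  list(X = out, choices = choices)
}
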