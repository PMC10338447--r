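#' Factor reduction of overlapping features
#'
#' Overlapping predictive features are reduced to a smaller set of oblique
#' factors before network estimation: parallel analysis fixes the factor
#' count, minimum-residual (minres) factor analysis extracts loadings,
#' oblimin rotation allows the factors to correlate, and regression
#' (Thurstone) scores carry participants into the network stage.
#'
#' @name factor_reduction
NULL

# squared multiple correlations for the reduced-correlation diagonal;
# ridge fallback when R is near-singular
smc <- function(R) {
  Ri <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-6, ncol(R))))
  pmin(pmax(1 - 1 / diag(Ri), 0), 1)
}

reduced_eigenvalues <- function(R) {
  Rr <- R
  diag(Rr) <- smc(R)
  eigen(Rr, symmetric = TRUE, only.values = TRUE)$values
}

#' Parallel analysis for the number of factors
#'
#' Compares the eigenvalues of the reduced correlation matrix (squared
#' multiple correlations on the diagonal, i.e. factor-model eigenvalues)
#' against the mean -- or, optionally, the 95th percentile -- of the same
#' eigenvalues computed on `n_resamples` standard-normal datasets of the
#' same shape. The retained factor count is the number of leading observed
#' eigenvalues consecutively exceeding the reference (the tail of a reduced
#' correlation matrix is negative on both sides and carries no factor
#' signal). Invariant to column order and to sign flips of the inputs.
#'
#' @param X complete numeric matrix, participants x features,
#'   `nrow(X) > ncol(X)`.
#' @param n_resamples random comparison datasets.
#' @param seed RNG seed.
#' @param criterion `"mean"` (default) or `"q95"` reference.
#' @return Integer factor count, with the observed and reference eigenvalue
#'   vectors attached as attributes.
#' @export
parallel_analysis <- function(X, n_resamples = 100, seed = NULL,
                              criterion = c("mean", "q95")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  if (anyNA(X)) stop("`X` must be complete")
  n <- nrow(X); p <- ncol(X)
  if (p >= n) stop("need more participants than features")
  obs <- reduced_eigenvalues(cor(X))
  rand <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      reduced_eigenvalues(cor(matrix(rnorm(n * p), n, p)))
    }, numeric(p))
  })
  ref <- if (criterion == "mean") rowMeans(rand) else
    apply(rand, 1, quantile, probs = 0.95)
  # consecutive exceedances from the top; reduced-matrix tail eigenvalues
  # are negative on both sides and carry no factor signal
  below <- which(obs <= ref)
  nf <- if (length(below)) below[1] - 1L else p
  structure(as.integer(nf), observed = obs, reference = ref)
}

# minres objective: squared off-diagonal residuals of the reduced
# correlation matrix at the eigen-based loading solution for uniquenesses u
minres_objective <- function(u, R, nf) {
  Rs <- R
  diag(Rs) <- 1 - u
  e <- eigen(Rs, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(nf)], 0)
  L <- e$vectors[, seq_len(nf), drop = FALSE] %*% diag(sqrt(ev), nf)
  resid <- Rs - tcrossprod(L)
  diag(resid) <- 0
  sum(resid^2)
}

minres_loadings <- function(u, R, nf) {
  Rs <- R
  diag(Rs) <- 1 - u
  e <- eigen(Rs, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(nf)], 0)
  e$vectors[, seq_len(nf), drop = FALSE] %*% diag(sqrt(ev), nf)
}

# direct quartimin criterion and gradient (oblimin with gamma = 0)
quartimin_vgQ <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  M <- matrix(1, k, k) - diag(k)
  list(f = sum(L2 * (L2 %*% M)) / 4, Gq = L * (L2 %*% M))
}

# gradient-projection algorithm for oblique rotation (quartimin)
gpf_oblq <- function(A, max_iter = 1000, tol = 1e-6) {
  k <- ncol(A)
  Tmat <- diag(k)
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- quartimin_vgQ(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  al <- 1
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (inner in seq_len(20)) {
      Xm <- Tmat - al * Gp
      v <- 1 / sqrt(colSums(Xm^2))
      Tt <- Xm %*% diag(v, k)
      Ti_t <- solve(Tt)
      Lt <- A %*% t(Ti_t)
      vg_t <- quartimin_vgQ(Lt)
      if (vg_t$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt; Ti <- Ti_t; L <- Lt; f <- vg_t$f
    G <- -t(t(L) %*% vg_t$Gq %*% Ti)
  }
  list(loadings = L, Tmat = Tmat, Phi = t(Tmat) %*% Tmat, f = f)
}

#' Minimum-residual factor analysis with oblimin rotation
#'
#' Extracts `n_factors` by minimizing the sum of squared off-diagonal
#' residuals of the correlation matrix over the uniquenesses (L-BFGS-B over
#' communality-iteration starting values), then applies direct-quartimin
#' (oblimin, gamma = 0) rotation by gradient projection. Factors are
#' ordered by explained variance and signed so the largest-magnitude
#' loading of each factor is positive.
#'
#' @param X complete numeric matrix, participants x features.
#' @param n_factors number of factors, `1 <= n_factors < ncol(X)`.
#' @param rotate `"oblimin"` (default) or `"none"`.
#' @return A `factor_model`: `n_factors`, `loadings` (pattern matrix),
#'   `phi` (factor correlations), `communalities`, `uniquenesses`, `rmsr`
#'   (root-mean-square off-diagonal residual of the reproduced correlation
#'   matrix), plus the training `center`/`scale` used by [factor_scores()].
#' @export
fit_minres_oblimin <- function(X, n_factors, rotate = c("oblimin", "none")) {
  rotate <- match.arg(rotate)
  X <- as.matrix(X)
  if (anyNA(X)) stop("`X` must be complete")
  p <- ncol(X)
  if (n_factors < 1 || n_factors >= p) {
    stop("`n_factors` must be in [1, ncol(X) - 1]")
  }
  R <- cor(X)
  start <- pmin(pmax(1 - smc(R), 0.05), 0.95)
  opt <- optim(start, minres_objective, R = R, nf = n_factors,
               method = "L-BFGS-B", lower = 0.005, upper = 1,
               control = list(maxit = 200, factr = 1e9))
  if (opt$convergence != 0 && opt$convergence != 1) {
    stop("minres optimization failed: ", opt$message)
  }
  u <- opt$par
  L <- minres_loadings(u, R, n_factors)

  if (rotate == "oblimin" && n_factors > 1) {
    rot <- gpf_oblq(L)
    L <- rot$loadings
    Phi <- rot$Phi
  } else {
    Phi <- diag(n_factors)
  }

  # order by explained variance (diag of Phi t(L) L), sign-fix each factor
  expl <- diag(Phi %*% crossprod(L))
  ord <- order(expl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  for (j in seq_len(n_factors)) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]
      Phi[, j] <- -Phi[, j]
    }
  }
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("F", seq_len(n_factors))
  dimnames(Phi) <- list(colnames(L), colnames(L))

  reproduced <- L %*% Phi %*% t(L)
  communalities <- pmin(pmax(diag(reproduced), 0), 1)
  resid <- R - reproduced
  diag(resid) <- 0
  rmsr <- sqrt(sum(resid^2) / (p * (p - 1)))

  structure(
    list(n_factors = as.integer(n_factors), loadings = L, phi = Phi,
         communalities = communalities, uniquenesses = u, rmsr = rmsr,
         R = R, center = colMeans(X), scale = apply(X, 2, sd),
         objective = opt$value),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d factors over %d features, RMSR %.4f\n",
              x$n_factors, nrow(x$loadings), x$rmsr))
  invisible(x)
}

#' Regression (Thurstone) factor scores
#'
#' Scores are `Z %*% solve(R) %*% loadings %*% phi` with `Z` the input
#' standardized by the model's training statistics. A singular correlation
#' matrix is ridge-stabilized with a warning.
#'
#' @param model a `factor_model`.
#' @param X numeric matrix over the same features the model was fitted on.
#' @return Participants x factors score matrix.
#' @export
factor_scores <- function(model, X) {
  stopifnot(inherits(model, "factor_model"))
  X <- as.matrix(X)
  if (!identical(colnames(X), rownames(model$loadings)) &&
      ncol(X) != nrow(model$loadings)) {
    stop("`X` must carry the features the model was fitted on")
  }
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Ri <- tryCatch(solve(model$R), error = function(e) {
    warning("singular correlation matrix; using ridge-stabilized inverse")
    solve(model$R + diag(1e-6, ncol(model$R)))
  })
  S <- Z %*% Ri %*% model$loadings %*% model$phi
  colnames(S) <- colnames(model$loadings)
  S
}
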