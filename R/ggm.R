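#' Gaussian graphical models by unregularized stepwise EBIC selection
#'
#' The network over factor scores and outcomes is a Gaussian graphical model
#' (GGM): nodes are variables, edges are partial correlations after
#' conditioning on every other node. For samples well above the node count,
#' the model is estimated without regularization: a graphical-lasso path
#' supplies candidate structures, the best EBIC structure is refitted by
#' constrained maximum likelihood, and a stepwise search over single-edge
#' additions/removals descends to a local EBIC optimum.
#'
#' @name ggm_network
NULL

#' GGM estimation settings
#'
#' @param ebic_gamma EBIC hyperparameter; 0 recovers the BIC.
#' @param glasso_path_length number of penalty values on the seed path.
#' @param convergence_tol convergence tolerance for the iterative ML fit.
#' @param max_sweeps iteration cap for the ML fit.
#' @param max_steps cap on accepted stepwise moves.
#' @return A `ggm_config` list.
#' @export
ggm_config <- function(ebic_gamma = 0, glasso_path_length = 100,
                       convergence_tol = 1e-8, max_sweeps = 200,
                       max_steps = 500) {
  stopifnot(ebic_gamma >= 0, convergence_tol > 0, glasso_path_length >= 1,
            max_sweeps >= 1, max_steps >= 1)
  structure(list(ebic_gamma = ebic_gamma,
                 glasso_path_length = glasso_path_length,
                 convergence_tol = convergence_tol,
                 max_sweeps = max_sweeps,
                 max_steps = max_steps),
            class = "ggm_config")
}

#' Partial correlations from a precision matrix
#'
#' `w_ij = -k_ij / sqrt(k_ii * k_jj)` with a zeroed diagonal.
#'
#' @param precision symmetric positive-definite matrix.
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
partial_correlations <- function(precision) {
  K <- as.matrix(precision)
  if (max(abs(K - t(K))) > 1e-8) stop("precision matrix must be symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix must be positive definite")
  d <- 1 / sqrt(diag(K))
  W <- -K * tcrossprod(d)
  diag(W) <- 0
  dimnames(W) <- dimnames(K)
  W
}

#' Constrained maximum-likelihood fit of a GGM structure
#'
#' Fits the Gaussian precision matrix that maximizes the likelihood subject
#' to zeros off the given structure, by iteratively matching the covariance
#' on structural entries (regression/IPF-style column updates). The
#' saturated structure returns `solve(S)` exactly; the empty structure the
#' diagonal `1/S_ii`.
#'
#' @param S sample covariance/correlation matrix (positive definite).
#' @param structure symmetric logical matrix of allowed off-diagonal edges.
#' @param n sample size (enters the log-likelihood scale).
#' @param config a [ggm_config()].
#' @param W_init optional warm-start covariance estimate.
#' @return List with `precision`, `loglik`, `W` (fitted covariance), and
#'   `iterations`.
#' @export
fit_constrained_ml <- function(S, structure, n, config = ggm_config(),
                               W_init = NULL) {
  S <- as.matrix(S)
  p <- ncol(S)
  adj <- structure | t(structure)
  diag(adj) <- FALSE
  W <- if (is.null(W_init)) S else as.matrix(W_init)
  nb_list <- lapply(seq_len(p), function(j) which(adj[, j]))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta <- 0
    for (j in seq_len(p)) {
      nb <- nb_list[[j]]
      w_old <- W[-j, j]
      if (length(nb) == 0L) {
        w_new <- numeric(p - 1L)
      } else {
        b <- solve(W[nb, nb, drop = FALSE], S[nb, j])
        w_new <- drop(W[-j, nb, drop = FALSE] %*% b)
      }
      delta <- max(delta, max(abs(w_new - w_old)))
      W[-j, j] <- w_new
      W[j, -j] <- w_new
    }
    if (delta < config$convergence_tol) break
    if (iter >= config$max_sweeps) {
      stop(sprintf(
        "constrained ML fit did not converge in %d sweeps (last delta %.3g)",
        config$max_sweeps, delta))
    }
  }
  K <- matrix(0, p, p, dimnames = dimnames(S))
  for (j in seq_len(p)) {
    nb <- nb_list[[j]]
    if (length(nb) == 0L) {
      K[j, j] <- 1 / W[j, j]
    } else {
      b <- solve(W[nb, nb, drop = FALSE], S[nb, j])
      kjj <- 1 / (W[j, j] - sum(W[nb, j] * b))
      K[j, j] <- kjj
      K[nb, j] <- K[nb, j] - b * kjj / 2
      K[j, nb] <- K[j, nb] - b * kjj / 2
    }
  }
  K <- (K + t(K)) / 2
  K[!adj & !diag(p)] <- 0
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) stop("fitted precision matrix is not positive definite")
  loglik <- n / 2 * (as.numeric(ld$modulus) - sum(S * K))
  list(precision = K, loglik = loglik, W = W, iterations = iter)
}

#' Extended Bayesian information criterion for a GGM
#'
#' `-2 loglik + E log(n) + 4 gamma E log(p)` with `E` the edge count;
#' `gamma = 0` reduces to the BIC.
#'
#' @param loglik Gaussian log-likelihood of the fitted model.
#' @param n sample size. @param n_edges number of edges.
#' @param p number of nodes. @param gamma EBIC hyperparameter.
#' @return EBIC value (lower is better).
#' @export
ebic <- function(loglik, n, n_edges, p, gamma = 0) {
  stopifnot(n >= 1, p >= 1, n_edges >= 0, gamma >= 0)
  -2 * loglik + n_edges * log(n) + 4 * gamma * n_edges * log(p)
}

# quadratic lasso by coordinate descent with an active-set strategy:
# minimize 0.5 b' V b - s' b + rho * ||b||_1
quad_lasso_cd <- function(V, s, rho, b0 = NULL, tol = 1e-8, max_iter = 500L) {
  m <- length(s)
  b <- if (is.null(b0)) numeric(m) else b0
  if (m == 0L) return(b)
  dV <- diag(V)
  Vb <- drop(V %*% b)
  sweep_over <- function(idx) {
    delta <- 0
    for (k in idx) {
      r <- s[k] - Vb[k] + dV[k] * b[k]
      bk <- sign(r) * max(abs(r) - rho, 0) / dV[k]
      d <- bk - b[k]
      if (d != 0) {
        Vb <<- Vb + V[, k] * d
        b[k] <<- bk
        delta <- max(delta, abs(d))
      }
    }
    delta
  }
  for (it in seq_len(max_iter)) {
    delta <- sweep_over(seq_len(m)) # full sweep refreshes the active set
    if (delta < tol) break
    active <- which(b != 0)
    for (inner in seq_len(max_iter)) {
      if (length(active) == 0L || sweep_over(active) < tol) break
    }
  }
  b
}

# one graphical-lasso solve (Friedman blockwise CD); returns covariance
# estimate W and the per-column coefficient matrix whose nonzero pattern is
# the selected structure
glasso_fit <- function(S, rho, W_init = NULL, B_init = NULL,
                       tol = 1e-6, max_sweeps = 100L) {
  p <- ncol(S)
  W <- if (is.null(W_init)) S + diag(rho, p) else W_init
  B <- if (is.null(B_init)) matrix(0, p, p) else B_init
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      V <- W[-j, -j, drop = FALSE]
      b <- quad_lasso_cd(V, S[-j, j], rho, b0 = B[-j, j])
      w_new <- drop(V %*% b)
      delta <- max(delta, max(abs(w_new - W[-j, j])))
      W[-j, j] <- w_new
      W[j, -j] <- w_new
      B[-j, j] <- b
    }
    if (delta < tol * (1 + max(abs(S)))) break
  }
  list(W = W, B = B)
}

# candidate structures along a descending glasso penalty path
glasso_path_structures <- function(S, path_length) {
  p <- ncol(S)
  off <- abs(S); diag(off) <- 0
  rho_max <- max(off)
  if (rho_max < 1e-12) return(list(matrix(FALSE, p, p)))
  rhos <- exp(seq(log(rho_max), log(rho_max * 0.01),
                  length.out = path_length))
  structures <- list(matrix(FALSE, p, p)) # empty model is always a candidate
  W <- NULL; B <- NULL
  for (rho in rhos) {
    fit <- glasso_fit(S, rho, W_init = W, B_init = B)
    W <- fit$W; B <- fit$B
    st <- (abs(fit$B) > 1e-10) | t(abs(fit$B) > 1e-10)
    diag(st) <- FALSE
    structures[[length(structures) + 1L]] <- st
  }
  keys <- vapply(structures, function(s) paste(which(s), collapse = ","), "")
  structures[!duplicated(keys)]
}

edge_count <- function(structure) sum(structure[upper.tri(structure)])

#' Estimate a GGM by unregularized stepwise EBIC model selection
#'
#' Seeds the search with the best-EBIC structure along a graphical-lasso
#' path (each candidate refitted by constrained ML), then repeatedly
#' evaluates every single-edge addition and removal, accepting the best
#' strictly EBIC-improving change until a local optimum. Ties are broken by
#' lexicographic edge order; the final refit's partial correlations are the
#' edge weights.
#'
#' @param X complete numeric matrix, participants x nodes, `nrow > ncol`.
#' @param config a [ggm_config()].
#' @return A `ggm_network`: `nodes`, `weights` (partial correlations),
#'   `structure`, `ebic`, `n`, `precision`.
#' @export
ggm_mod_select <- function(X, config = ggm_config()) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("`X` must be complete")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than nodes")
  nodes <- colnames(X)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  S <- cor(X)
  dimnames(S) <- list(nodes, nodes)

  score <- function(structure, W_init = NULL) {
    fit <- fit_constrained_ml(S, structure, n, config, W_init = W_init)
    fit$ebic <- ebic(fit$loglik, n, edge_count(structure), p,
                     config$ebic_gamma)
    fit
  }

  cands <- glasso_path_structures(S, config$glasso_path_length)
  best <- NULL
  cur_structure <- NULL
  for (st in cands) {
    fit <- tryCatch(score(st), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$ebic < best$ebic) {
      best <- fit
      cur_structure <- st
    }
  }
  if (is.null(best)) stop("no candidate structure could be fitted")

  pairs <- which(upper.tri(S), arr.ind = TRUE) # lexicographic by column-major
  steps <- 0L
  capped <- FALSE
  repeat {
    cand_ebic <- rep(Inf, nrow(pairs))
    cand_fits <- vector("list", nrow(pairs))
    for (e in seq_len(nrow(pairs))) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      st <- cur_structure
      st[i, j] <- st[j, i] <- !st[i, j]
      fit <- tryCatch(score(st, W_init = best$W), error = function(x) NULL)
      if (is.null(fit)) next
      cand_ebic[e] <- fit$ebic
      cand_fits[[e]] <- fit
    }
    k <- which.min(cand_ebic)
    if (!is.finite(cand_ebic[k]) || cand_ebic[k] >= best$ebic - 1e-9) break
    i <- pairs[k, 1]; j <- pairs[k, 2]
    cur_structure[i, j] <- cur_structure[j, i] <- !cur_structure[i, j]
    best <- cand_fits[[k]]
    steps <- steps + 1L
    if (steps >= config$max_steps) {
      warning("stepwise search hit the step cap; returning best-so-far")
      capped <- TRUE
      break
    }
  }

  weights <- partial_correlations(best$precision)
  weights[!cur_structure] <- 0
  dimnames(weights) <- list(nodes, nodes)
  dimnames(cur_structure) <- list(nodes, nodes)
  structure(
    list(nodes = nodes, weights = weights, structure = cur_structure,
         ebic = best$ebic, n = n, precision = best$precision,
         loglik = best$loglik, steps = steps, capped = capped),
    class = "ggm_network"
  )
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf("<ggm_network> %d nodes, %d edges, EBIC %.2f (n = %d)\n",
              length(x$nodes), edge_count(x$structure), x$ebic, x$n))
  invisible(x)
}

#' Flow decomposition of a network from a source node
#'
#' Layer 1 lists the source's neighbours with their edge weights; layer 2
#' lists the remaining nodes with their edges into layer 1; remaining nodes
#' without any edge into layer 1 are reported as isolated from the source.
#'
#' @param net a `ggm_network`. @param source node label.
#' @return List with `source`, `layer1` (node, weight), `layer2`
#'   (node, via, weight), `isolated` (character).
#' @export
flow_from <- function(net, source) {
  stopifnot(inherits(net, "ggm_network"))
  if (!source %in% net$nodes) stop("unknown node: ", source)
  W <- net$weights
  nb <- net$nodes[W[source, ] != 0]
  layer1 <- data.frame(node = nb, weight = W[source, nb],
                       row.names = NULL, stringsAsFactors = FALSE)
  rest <- setdiff(net$nodes, c(source, nb))
  l2 <- list()
  isolated <- character()
  for (v in rest) {
    via <- nb[W[v, nb] != 0]
    if (length(via) == 0L) {
      isolated <- c(isolated, v)
    } else {
      l2[[length(l2) + 1L]] <- data.frame(
        node = v, via = via, weight = W[v, via],
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  layer2 <- if (length(l2)) do.call(rbind, l2) else
    data.frame(node = character(), via = character(), weight = numeric())
  list(source = source, layer1 = layer1, layer2 = layer2,
       isolated = isolated)
}

#' Write a network as an edge list
#'
#' @param net a `ggm_network`. @param path CSV destination.
#' @return The edge-list data frame, invisibly.
#' @export
write_edge_list <- function(net, path = NULL) {
  idx <- which(upper.tri(net$weights) & net$structure, arr.ind = TRUE)
  el <- data.frame(node1 = net$nodes[idx[, 1]], node2 = net$nodes[idx[, 2]],
                   weight = net$weights[idx], stringsAsFactors = FALSE)
  el <- el[order(el$node1, el$node2), , drop = FALSE]
  if (!is.null(path)) write.csv(el, path, row.names = FALSE)
  invisible(el)
}
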