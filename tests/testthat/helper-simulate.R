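# shared simulation helpers for the test suite

# sparse p-node precision matrix whose nonzero partial correlations are
# about `w` in magnitude; diagonal inflated if needed to stay well
# conditioned
benchmark_precision <- function(p = 15, n_edges = 15, w = 0.25, seed = 1) {
  set.seed(seed)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  sel <- pairs[sample(nrow(pairs), n_edges), , drop = FALSE]
  K <- diag(p)
  K[cbind(sel[, 1], sel[, 2])] <- -w
  K[cbind(sel[, 2], sel[, 1])] <- -w
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 0.1) K <- K + diag(0.1 - ev, p)
  K
}

gaussian_sample <- function(n, K, seed = 1) {
  set.seed(seed)
  MASS::mvrnorm(n, rep(0, nrow(K)), solve(K))
}

# design with one planted standardized effect among noise features
planted_design <- function(n, p_noise = 50, beta = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * (p_noise + 1)), n,
              dimnames = list(NULL, c("planted", paste0("noise", 1:p_noise))))
  y <- beta * X[, 1] + sqrt(1 - beta^2) * rnorm(n)
  list(X = X, y = y)
}

# hand-built network object for centrality / flow checks
manual_network <- function(weights, nodes = colnames(weights)) {
  if (is.null(nodes)) nodes <- paste0("V", seq_len(ncol(weights)))
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights,
                 structure = weights != 0, ebic = NA_real_,
                 n = NA_integer_),
            class = "ggm_network")
}

# brute-force Benjamini-Hochberg step-up with monotonicity enforcement
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# multi-factor item data with simple structure (for factor-analysis tests)
simple_structure_data <- function(n = 1000, n_factors = 4,
                                  items_per_factor = 5, loading = 0.7,
                                  seed = 1, phi = NULL) {
  set.seed(seed)
  p <- n_factors * items_per_factor
  if (is.null(phi)) phi <- diag(n_factors)
  Z <- MASS::mvrnorm(n, rep(0, n_factors), phi)
  L <- matrix(0, p, n_factors)
  for (j in seq_len(n_factors)) {
    L[((j - 1) * items_per_factor + 1):(j * items_per_factor), j] <- loading
  }
  X <- Z %*% t(L) +
    matrix(rnorm(n * p), n) %*% diag(sqrt(1 - rowSums(L^2)))
  colnames(X) <- paste0("x", seq_len(p))
  list(X = X, Z = Z, L = L)
}

# small mixed-type feature table with controllable missingness
tiny_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  values <- data.frame(
    num1 = rnorm(n), num2 = rnorm(n), num3 = rnorm(n),
    nom1 = sample(c("A", "B"), n, replace = TRUE),
    sym_1 = rnorm(n), sym_2 = rnorm(n),
    bp1 = rnorm(n),
    stringsAsFactors = FALSE
  )
  rownames(values) <- sprintf("p%02d", seq_len(n))
  dictionary <- data.frame(
    item = names(values),
    scale = c("s1", "s1", "s2", "s2", "symptoms", "symptoms", "bpaq"),
    type = c("numeric", "numeric", "numeric", "nominal", "numeric",
             "numeric", "numeric"),
    role = c(rep("feature", 4), rep("outcome", 3)),
    stringsAsFactors = FALSE
  )
  feature_table(values, dictionary)
}

# light generator configuration: outcome structure only, no missingness
light_config <- function(n, f, noise = 1, seed = 1, n_items = 40,
                         missing = FALSE) {
  synthetic_config(
    n_participants = n, n_scales = 8, n_items = n_items,
    n_latent_factors = 12, n_outcome_factors = 4,
    shared_factor_fraction = f, outcome_noise_sd = noise,
    item_missing_rate = if (missing) 0.0015 else 0,
    participant_missing_boost = if (missing) 0.15 else 0,
    n_nominal_items = 0, n_high_missing_items = 0,
    high_missing_rate = 0, seed = seed
  )
}
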