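test_that("partial correlations follow the precision-matrix formula", {
  K <- matrix(c(2, -1, -1, 2), 2, 2)
  expect_equal(partial_correlations(K)[1, 2], 0.5)
  expect_equal(diag(partial_correlations(K)), c(0, 0))
  D <- diag(c(1, 2, 3))
  expect_true(all(partial_correlations(D) == 0))
  expect_error(partial_correlations(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(partial_correlations(diag(c(1, -1))), "positive definite")
})

test_that("three-variable partial correlations match the recursive formula", {
  set.seed(1)
  for (i in 1:10) {
    X <- matrix(rnorm(300 * 3), 300)
    S <- cor(X)
    W <- partial_correlations(solve(S))
    r12 <- (S[1, 2] - S[1, 3] * S[2, 3]) /
      sqrt((1 - S[1, 3]^2) * (1 - S[2, 3]^2))
    expect_equal(W[1, 2], r12, tolerance = 1e-10)
  }
})

test_that("constrained ML reproduces saturated and empty closed forms", {
  set.seed(2)
  S <- cor(matrix(rnorm(500 * 5), 500))
  sat <- fit_constrained_ml(S, matrix(TRUE, 5, 5), n = 500)
  expect_lt(max(abs(sat$precision - solve(S))), 1e-8)
  oracle <- -stats::cov2cor(solve(S))
  diag(oracle) <- 0
  expect_lt(max(abs(partial_correlations(sat$precision) - oracle)), 1e-8)
  emp <- fit_constrained_ml(S, matrix(FALSE, 5, 5), n = 500)
  expect_equal(emp$precision, diag(1 / diag(S)), ignore_attr = TRUE)
})

test_that("constrained ML satisfies the stationarity conditions on edges", {
  set.seed(3)
  K <- benchmark_precision(p = 8, n_edges = 8, seed = 3)
  X <- gaussian_sample(1000, K, seed = 3)
  S <- cor(X)
  st <- abs(K) > 1e-8; diag(st) <- FALSE
  fit <- fit_constrained_ml(S, st, n = 1000)
  Sigma <- solve(fit$precision)
  # implied covariance matches S on structural edges and the diagonal
  expect_lt(max(abs(Sigma[st] - S[st])), 1e-6)
  expect_lt(max(abs(diag(Sigma) - diag(S))), 1e-6)
  # exact zeros off structure
  off <- !st & !diag(8)
  expect_true(all(fit$precision[off] == 0))
})

test_that("EBIC reduces to BIC at gamma zero and penalizes edges", {
  expect_equal(ebic(-100, n = 500, n_edges = 4, p = 10, gamma = 0),
               200 + 4 * log(500))
  expect_gt(ebic(-100, 500, 5, 10, 0), ebic(-100, 500, 4, 10, 0))
  expect_gt(ebic(-100, 500, 4, 10, 0.5), ebic(-100, 500, 4, 10, 0))
})

test_that("stepwise selection stays at or below the seed EBIC", {
  K <- benchmark_precision(p = 8, n_edges = 8, seed = 4)
  X <- gaussian_sample(2000, K, seed = 4)
  net <- ggm_mod_select(X)
  S <- cor(X)
  for (st in list(matrix(FALSE, 8, 8), matrix(TRUE, 8, 8))) {
    fit <- fit_constrained_ml(S, st, n = 2000)
    alt <- ebic(fit$loglik, 2000, sum(st[upper.tri(st)]), 8, 0)
    expect_lte(net$ebic, alt + 1e-9)
  }
  # weights are zero exactly off the selected structure
  expect_true(all(net$weights[!net$structure] == 0))
  expect_equal(net$weights, t(net$weights))
})

test_that("independent variables yield a near-empty network", {
  spurious <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(5000 * 8), 5000)
    net <- ggm_mod_select(X, ggm_config(glasso_path_length = 40))
    sum(net$structure) / 2
  }, numeric(1))
  expect_gte(mean(spurious <= 1), 0.9)
})

test_that("selection rejects degenerate inputs", {
  expect_error(ggm_mod_select(matrix(rnorm(12), 3, 4)), "more observations")
  X <- matrix(rnorm(100 * 3), 100)
  X[1, 1] <- NA
  expect_error(ggm_mod_select(X), "complete")
})

test_that("flow diagrams layer the network around a source", {
  W <- matrix(0, 4, 4, dimnames = rep(list(c("a", "b", "c", "d")), 2))
  W["a", "b"] <- W["b", "a"] <- 0.3
  W["b", "c"] <- W["c", "b"] <- -0.2
  net <- manual_network(W)
  fl <- flow_from(net, "a")
  expect_equal(fl$layer1$node, "b")
  expect_equal(fl$layer1$weight, 0.3)
  expect_equal(fl$layer2$node, "c")
  expect_equal(fl$layer2$via, "b")
  expect_equal(fl$isolated, "d")
  # star graph: everything in layer 1
  Ws <- matrix(0, 4, 4, dimnames = rep(list(c("s", "x", "y", "z")), 2))
  Ws["s", 2:4] <- Ws[2:4, "s"] <- 0.2
  expect_setequal(flow_from(manual_network(Ws), "s")$layer1$node,
                  c("x", "y", "z"))
  # no edges at the source: empty first layer
  expect_equal(nrow(flow_from(net, "d")$layer1), 0)
  expect_error(flow_from(net, "nope"), "unknown")
})

test_that("edge lists round-trip the selected structure", {
  K <- benchmark_precision(p = 6, n_edges = 5, seed = 5)
  X <- gaussian_sample(3000, K, seed = 5)
  net <- ggm_mod_select(X)
  el <- write_edge_list(net)
  expect_equal(nrow(el), sum(net$structure) / 2)
  for (i in seq_len(nrow(el))) {
    expect_equal(el$weight[i], net$weights[el$node1[i], el$node2[i]])
  }
})
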