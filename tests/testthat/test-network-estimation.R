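fixture_slice <- function(n0 = 2000, seed = 1, identity = FALSE) {
  tr <- default_truth(1)
  wave_slice(simulate_panel(tr, n0 = n0, retention = 1,
                            identity_marginals = identity, seed = seed), "T0")
}

test_that("correlation_matrix validates input and repairs borderline PSD", {
  set.seed(1)
  x <- as.data.frame(matrix(rnorm(300), 100, 3))
  names(x) <- c("a", "b", "c")
  S <- correlation_matrix(x)
  expect_equal(diag(S), c(a = 1, b = 1, c = 1))
  expect_equal(S, t(S))

  x$dup <- x$a
  S2 <- correlation_matrix(x)
  expect_equal(S2["a", "dup"], 1)
  expect_gte(min(eigen(S2, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  x$flat <- 2
  expect_error(correlation_matrix(x), "flat")
  expect_error(correlation_matrix(x[1:2, 1:3]), "3 complete rows")
})

test_that("independent columns have near-zero correlations at large n", {
  set.seed(2)
  x <- matrix(rnorm(100000 * 4), ncol = 4)
  S <- correlation_matrix(as.data.frame(x))
  expect_lt(max(abs(S[upper.tri(S)])), 0.02)
})

test_that("pearson and spearman both give PSD but different entries on skewed scores", {
  sl <- fixture_slice(n0 = 400, seed = 3)
  Sp <- correlation_matrix(sl, "pearson")
  Ss <- correlation_matrix(sl, "spearman")
  expect_gte(min(eigen(Sp, only.values = TRUE)$values), -1e-10)
  expect_gte(min(eigen(Ss, only.values = TRUE)$values), -1e-10)
  expect_gt(max(abs(Sp - Ss)), 1e-4)
})

test_that("glasso at lambda = 0 equals the matrix inverse", {
  set.seed(3)
  for (i in 1:5) {
    S <- random_spd_cor(4, 60)
    expect_lt(max(abs(glasso_fit(S, 0) - solve(S))), 1e-6)
  }
})

test_that("full shrinkage empties the network and solutions match the oracle", {
  set.seed(4)
  S <- random_spd_cor(5, 100)
  lam <- max(abs(S[upper.tri(S)]))
  W <- precision_to_partial(glasso_fit(S, lam * 1.0001))
  expect_equal(max(abs(W)), 0)

  # spot check against the independent proximal-gradient oracle
  Th <- glasso_fit(S, 0.1)
  Th_o <- glasso_oracle(S, 0.1)
  expect_lt(max(abs(Th - Th_o)), 1e-4)
})

test_that("precision_to_partial implements the scaled negative inverse", {
  expect_equal(precision_to_partial(diag(4)), matrix(0, 4, 4))
  Th2 <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(precision_to_partial(Th2)[1, 2], 0.5)

  set.seed(5)
  S3 <- random_spd_cor(3, 50)
  Th3 <- solve(S3)
  expect_equal(precision_to_partial(Th3), partial_cor_oracle(S3),
               tolerance = 1e-12)
  expect_error(precision_to_partial(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("EBIC formula and monotonicity in gamma", {
  expect_equal(ebic_score(-500, n = 100, E = 5, p = 10, gamma = 0.5),
               1000 + 5 * log(100) + 10 * log(10))
  expect_equal(ebic_score(-500, 100, 5, 10, 0.5), 1046.0517, tolerance = 1e-4)
  expect_equal(ebic_score(-123.4, n = 50, E = 0, p = 10, gamma = 0.5), 246.8)
  expect_lt(ebic_score(-500, 100, 5, 10, 0.25), ebic_score(-500, 100, 5, 10, 0.5))
})

test_that("estimate_network is deterministic, empty under independence, and records its path", {
  set.seed(6)
  x <- as.data.frame(matrix(rnorm(2000 * 10), ncol = 10))
  net <- estimate_network(x)
  expect_equal(sum(abs(net$weights)), 0)

  sl <- fixture_slice(n0 = 500, seed = 2)
  n1 <- estimate_network(sl)
  n2 <- estimate_network(sl)
  expect_identical(n1$weights, n2$weights)

  expect_equal(n1$ebic_selected, min(n1$path$ebic))
  expect_equal(diag(n1$weights), setNames(rep(0, 10), n1$node_labels))
  expect_equal(n1$weights, t(n1$weights))
  expect_true(all(abs(n1$weights) < 1))
  # edge count non-increasing as lambda increases: strict over the
  # model-selection range; deep in the path a single borderline edge may
  # jitter in and out of the exact-zero support, so allow one-edge blips
  best <- which(n1$path$lambda == n1$lambda_selected)
  expect_true(all(diff(n1$path$edge_count[1:best]) >= 0)) # descending lambda
  expect_lte(max(diff(rev(n1$path$edge_count))), 1)
})

test_that("seed-1 fixture recovery: strong edges found with matching sign", {
  tr <- default_truth(1)
  P <- true_partial_cor(tr)
  net <- estimate_network(fixture_slice(n0 = 2000, seed = 1))
  strong <- which(upper.tri(P) & abs(P) >= 0.3, arr.ind = TRUE)
  for (k in seq_len(nrow(strong))) {
    w <- net$weights[strong[k, 1], strong[k, 2]]
    expect_gt(abs(w), 0)
    expect_equal(sign(w), sign(P[strong[k, 1], strong[k, 2]]))
  }
})

test_that("network tidiers and disk round-trip", {
  net <- estimate_network(fixture_slice(n0 = 500, seed = 4))
  td <- tidy(net)
  expect_true(all(abs(td$weight) > 0))
  expect_equal(nrow(tidy(net, all = TRUE)), 45)
  g <- glance(net)
  expect_equal(g$edge_count, nrow(td))

  tmp <- withr::local_tempdir()
  files <- write_network(net, file.path(tmp, "net"))
  expect_true(all(file.exists(files)))
  back <- read_network(file.path(tmp, "net.json"))
  expect_equal(back$weights, net$weights)
  expect_equal(back$path, net$path)
})

test_that("redundancy screen flags near-duplicates and passes the fixture", {
  set.seed(7)
  x <- as.data.frame(matrix(rnorm(200 * 5), ncol = 5))
  names(x) <- paste0("V", 1:5)
  x$V5 <- x$V1 + rnorm(200, sd = 0.05)
  rep1 <- redundancy_screen(x)
  expect_true(any(rep1$flagged[rep1$node_a == "V1" & rep1$node_b == "V5"]))

  y <- as.data.frame(matrix(rnorm(200 * 5), ncol = 5))
  rep2 <- redundancy_screen(y)
  expect_equal(nrow(rep2), 0)

  # the default truth was built non-redundant: no pair drops out
  sl <- fixture_slice(n0 = 361, seed = 1)
  rep3 <- redundancy_screen(sl)
  expect_false(any(rep3$flagged))

  expect_error(redundancy_screen(x[, 1:2]), "3 nodes")
  expect_error(redundancy_screen(x[1:10, ]), "20 complete rows")
})
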