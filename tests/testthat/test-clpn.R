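test_that("CLPN recovers a noiselessly generated sparse lagged map per entry", {
  tr <- default_truth(1)
  tr$noise_sd[] <- 1e-8 # wave 2 is (almost) a deterministic map of wave 1
  pan <- simulate_panel(tr, n0 = 2000, retention = 1,
                        identity_marginals = TRUE, seed = 21)
  m <- fit_clpn(pan, seed = 21)
  Bstd <- true_lagged_std(tr)
  expect_lt(max(abs(m$W - Bstd)), 0.05)
  expect_equal(m$autoregressive, diag(m$W), ignore_attr = TRUE)
  # autoregressive dominance: fixture diagonal exceeds all cross effects
  expect_gte(max(abs(diag(m$W))), max(abs(m$W[row(m$W) != col(m$W)])))
})

test_that("standardization makes the fit scale invariant", {
  tr <- default_truth(1)
  pan <- simulate_panel(tr, n0 = 300, retention = 1, seed = 22)
  m1 <- fit_clpn(pan, seed = 5)
  pan2 <- pan
  pan2$D1 <- pan2$D1 * 1000
  m2 <- fit_clpn(pan2, seed = 5)
  expect_equal(m1$W, m2$W, tolerance = 1e-8)
})

test_that("input validation: completers, folds, zero variance", {
  tr <- default_truth(1)
  pan <- simulate_panel(tr, n0 = 60, retention = 0.5, seed = 23)
  expect_error(fit_clpn(pan), "at least 50")
  pan2 <- simulate_panel(tr, n0 = 80, retention = 1, seed = 23)
  expect_error(fit_clpn(pan2, n_folds = 200), "exceeds")
  pan3 <- pan2
  pan3$O3 <- 5
  expect_error(fit_clpn(pan3), "O3")
})

test_that("reported_edges filters cross-lagged entries only and matches a brute scan", {
  labs <- paste0("n", 1:4)
  W <- matrix(0, 4, 4, dimnames = list(labs, labs))
  diag(W) <- c(0.3, 0.05, 0.4, 0.2)
  model <- structure(list(node_labels = labs, W = W, report_threshold = 0.1),
                     class = "clpn_network")
  W[1, 2] <- 0.09
  model$W <- W
  re <- reported_edges(model)
  expect_equal(sum(re$type == "cross_lagged"), 0) # 0.09 below threshold
  expect_equal(sum(re$type == "autoregressive"), 4) # diagonal unthresholded

  W[3, 1] <- -0.15
  W[2, 1] <- 0.2
  model$W <- W
  re2 <- reported_edges(model)
  cl <- re2[re2$type == "cross_lagged", ]
  expect_setequal(paste(cl$from, cl$to), c("n3 n1", "n2 n1"))
  expect_equal(cl$weight[cl$from == "n3"], -0.15)

  # brute-force scan agrees
  brute <- which(row(W) != col(W) & abs(W) > 0.1, arr.ind = TRUE)
  expect_equal(nrow(cl), nrow(brute))
})

test_that("temporal EI sums incoming and outgoing cross-lagged weights", {
  labs <- c("A", "B", "C")
  W <- matrix(0, 3, 3, dimnames = list(labs, labs))
  model <- structure(list(node_labels = labs, W = W, report_threshold = 0.1,
                          in_ei = setNames(colSums(W) - diag(W), labs),
                          out_ei = setNames(rowSums(W) - diag(W), labs)),
                     class = "clpn_network")
  expect_true(all(temporal_ei(model)$in_ei == 0))

  W["A", "B"] <- 0.3
  diag(W) <- 0.5 # diagonal must not leak into EI
  model$W <- W
  model$in_ei <- setNames(colSums(W) - diag(W), labs)
  model$out_ei <- setNames(rowSums(W) - diag(W), labs)
  te <- temporal_ei(model)
  expect_equal(te$out_ei, c(0.3, 0, 0))
  expect_equal(te$in_ei, c(0, 0.3, 0))
})

test_that("the node with the largest true signed out-degree tops estimated out-EI", {
  tr <- default_truth(1)
  pan <- simulate_panel(tr, n0 = 5000, retention = 1,
                        identity_marginals = TRUE, seed = 24)
  m <- fit_clpn(pan, seed = 24)
  Bstd <- true_lagged_std(tr)
  true_out <- rowSums(Bstd) - diag(Bstd)
  expect_equal(which.max(m$out_ei), which.max(true_out))
})

test_that("reported-edge decisions are stable across fold seeds on a strong fixture", {
  tr <- default_truth(1)
  pan <- simulate_panel(tr, n0 = 2000, retention = 1,
                        identity_marginals = TRUE, seed = 25)
  Bstd <- true_lagged_std(tr)
  strong <- which(row(Bstd) != col(Bstd) & abs(Bstd) >= 0.15)
  for (fs in 1:5) {
    m <- fit_clpn(pan, seed = fs)
    expect_true(all(abs(m$W[strong]) > 0.1),
                info = paste("fold seed", fs))
  }
})
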