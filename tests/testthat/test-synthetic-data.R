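test_that("default truth satisfies its structural guarantees", {
  tr <- default_truth(seed = 1)
  expect_s3_class(tr, "sim_truth")
  ev <- eigen(tr$Omega, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))

  # implied partial correlations via independent matrix inversion
  P <- partial_cor_oracle(solve(tr$Omega)) # Sigma -> invert -> partials
  ut <- P[upper.tri(P)]
  expect_gte(sum(abs(ut) >= 0.3), 5)
  expect_gte(mean(abs(ut) < 1e-12), 0.6)
  expect_gte(abs(P[1, 2]), 0.3) # D1-D2

  expect_true(all(diag(tr$Bmat) >= 0.2 & diag(tr$Bmat) <= 0.6))
  off <- tr$Bmat[row(tr$Bmat) != col(tr$Bmat)]
  expect_gte(sum(abs(off) >= 0.15), 3)
  expect_true(any(off <= -0.15))

  expect_identical(default_truth(seed = 1), default_truth(seed = 1))
})

test_that("true_partial_cor matches the inversion oracle and rejects non-PD input", {
  tr <- default_truth(1)
  expect_equal(true_partial_cor(tr), partial_cor_oracle(solve(tr$Omega)),
               tolerance = 1e-12, ignore_attr = TRUE)
  bad <- diag(3); bad[1, 1] <- -1
  expect_error(true_partial_cor(bad), "positive definite")
})

test_that("simulated panels are deterministic and honour the design counts", {
  tr <- default_truth(seed = 42)
  p1 <- simulate_panel(tr)
  p2 <- simulate_panel(tr)
  expect_identical(p1, p2)

  expect_equal(sum(p1$wave == "T0"), 361)
  expect_equal(sum(p1$wave == "T1"), 209)
  expect_true(all(completers(p1) %in% p1$subject_id[p1$wave == "T0"]))
  expect_false(any(duplicated(p1[c("subject_id", "wave")])))

  # scores respect the declared marginal ranges
  for (k in seq_along(tr$node_labels)) {
    v <- p1[[tr$node_labels[k]]]
    expect_true(all(v >= tr$marginals$low[k] & v <= tr$marginals$high[k]))
  }

  expect_error(simulate_panel(tr, retention = 0), "retention")
  bad <- tr
  bad$Omega[1, 1] <- -5
  expect_error(simulate_panel(bad), "eigenvalue")
})

test_that("large-sample recovery closure: partials and lagged coefficients", {
  tr <- default_truth(1)
  pan <- simulate_panel(tr, n0 = 50000, retention = 1,
                        identity_marginals = TRUE, seed = 99)
  x <- as.matrix(wave_slice(pan, "T0"))
  P_emp <- partial_cor_oracle(cor(x))
  expect_lt(max(abs(P_emp - true_partial_cor(tr))), 0.02)

  # standardized lagged regression recovers Bmat
  m <- panelnet:::completer_matrices(pan)
  z0 <- scale(m$x0)
  z1 <- scale(m$x1)
  Bhat <- qr.solve(z0, z1)
  expect_lt(max(abs(Bhat - true_lagged_std(tr))), 0.02)
})

test_that("zero lagged structure yields cross-wave independence", {
  tr <- default_truth(1)
  tr$Bmat[, ] <- 0
  tr$noise_sd[] <- 1
  pan <- simulate_panel(tr, n0 = 100000, retention = 1,
                        identity_marginals = TRUE, seed = 5)
  m <- panelnet:::completer_matrices(pan)
  cc <- cor(m$x0, m$x1)
  expect_lt(max(abs(cc)), 0.02)
})

test_that("attrition is missing completely at random", {
  tr <- default_truth(1)
  pan <- simulate_panel(tr, n0 = 10000, retention = 0.6,
                        identity_marginals = TRUE, seed = 7)
  t0 <- pan[pan$wave == "T0", ]
  kept <- t0$subject_id %in% completers(pan)
  for (nd in panel_nodes(pan)[c(1, 5, 10)]) {
    a <- t0[[nd]][kept]
    b <- t0[[nd]][!kept]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), 3 * se)
  }
})

test_that("score-dependent dropout shifts retained-sample means when enabled", {
  tr <- default_truth(1)
  pan <- simulate_panel(tr, n0 = 10000, retention = 0.5,
                        identity_marginals = TRUE, dropout_by = "D1",
                        seed = 7)
  t0 <- pan[pan$wave == "T0", ]
  kept <- t0$subject_id %in% completers(pan)
  # higher D1 preferentially dropped, so completers sit below the dropped
  expect_lt(mean(t0$D1[kept]), mean(t0$D1[!kept]))
})

test_that("ordinalize is monotone, range-respecting and rank-preserving", {
  spec <- marginal_spec("X", low = 13, high = 91, integer = TRUE, skew = 0.8)
  z <- sort(rnorm(500))
  y <- ordinalize(z, spec)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 13 & y <= 91))
  expect_true(all(y == round(y)))

  expect_equal(ordinalize(rep(1.3, 10), spec), rep(ordinalize(1.3, spec), 10))
  expect_error(marginal_spec("X", low = 5, high = 5), "low")
  expect_error(ordinalize(z, list(low = 5, high = 4, integer = FALSE, skew = 0)),
               "low")

  # location-scale branch clamps to range
  ssrt <- marginal_spec("SSRT", 50, 600, integer = FALSE, mean = 260, sd = 40)
  y2 <- ordinalize(c(-20, 0, 20), ssrt)
  expect_equal(y2[2], 260)
  expect_true(all(y2 >= 50 & y2 <= 600))
})

test_that("panels and truth objects round-trip through disk", {
  tr <- default_truth(3)
  pan <- simulate_panel(tr, n0 = 40, retention = 0.5)
  tmp <- withr::local_tempdir()
  write_panel(pan, file.path(tmp, "panel.csv"))
  back <- read_panel(file.path(tmp, "panel.csv"))
  expect_equal(as.data.frame(back), as.data.frame(pan), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(nrow(attr(back, "rejects")), 0)

  write_truth(tr, file.path(tmp, "truth.json"))
  tr2 <- read_truth(file.path(tmp, "truth.json"))
  expect_equal(tr2$Omega, tr$Omega)
  expect_equal(tr2$Bmat, tr$Bmat)
  expect_equal(tr2$marginals, tr$marginals)
  expect_identical(simulate_panel(tr2, n0 = 40, retention = 0.5), pan)
})
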