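test_that("edge bootstrap is seeded-deterministic with coherent intervals", {
  tr <- default_truth(1)
  sl <- wave_slice(simulate_panel(tr, n0 = 200, retention = 1, seed = 12), "T0")
  b1 <- bootstrap_edges(sl, B = 50, seed = 3)
  b2 <- bootstrap_edges(sl, B = 50, seed = 3)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$ci_lower <= b1$ci_upper))
  expect_true(all(b1$B == 50))
  expect_equal(nrow(b1), 45)
  expect_error(bootstrap_edges(sl, B = 1), "at least 2")
  expect_error(bootstrap_edges(sl[1:10, ], B = 10), "at least 30")
})

test_that("strong fixture edge excludes zero; bootstrap mean tracks the estimate", {
  tr <- default_truth(1)
  sl <- wave_slice(simulate_panel(tr, n0 = 2000, retention = 1, seed = 13), "T0")
  b <- bootstrap_edges(sl, B = 1000, seed = 4)
  e <- b[b$node_a == "D1" & b$node_b == "D2", ]
  expect_gt(e$ci_lower, 0) # true rho = 0.4
  nz <- b[abs(b$estimate) > 0.05, ]
  expect_lt(max(abs(nz$boot_mean - nz$estimate)), 0.02)
})

test_that("independent data yield intervals that mostly contain zero", {
  set.seed(14)
  x <- as.data.frame(matrix(rnorm(500 * 10), ncol = 10))
  b <- bootstrap_edges(x, B = 200, seed = 5)
  contains0 <- mean(b$ci_lower <= 0 & b$ci_upper >= 0)
  expect_gte(contains0, 0.9)
})

test_that("CS decision rule follows the all-points-up-to-q definition", {
  # injected correlations: 97% pass at q <= 0.2, only 60% pass at q = 0.3
  make <- function(q, pass_rate) {
    tibble::tibble(drop = q, rep = 1:100,
                   correlation = c(rep(0.9, pass_rate), rep(0.5, 100 - pass_rate)))
  }
  cors <- dplyr::bind_rows(make(0.1, 97), make(0.2, 97), make(0.3, 60),
                           make(0.4, 97))
  expect_equal(cs_from_correlations(cors), 0.2)
  # a later qualifying point does not rescue a broken prefix
  expect_equal(cs_from_correlations(dplyr::bind_rows(make(0.1, 50), make(0.2, 99))), 0)
  # all points qualify -> grid ceiling
  expect_equal(cs_from_correlations(dplyr::bind_rows(make(0.1, 96), make(0.75, 95))), 0.75)
  # missing correlations count as failures
  na_tbl <- tibble::tibble(drop = 0.1, rep = 1:100,
                           correlation = c(rep(0.9, 94), rep(NA, 6)))
  expect_equal(cs_from_correlations(na_tbl), 0)
})

test_that("case-dropping bootstrap is reproducible and drops infeasible grid points", {
  tr <- default_truth(1)
  sl <- wave_slice(simulate_panel(tr, n0 = 120, retention = 1, seed = 15), "T0")
  s1 <- cs_coefficient(sl, "strength", drop_grid = c(0.1, 0.3),
                       B_per_drop = 25, seed = 6)
  s2 <- cs_coefficient(sl, "strength", drop_grid = c(0.1, 0.3),
                       B_per_drop = 25, seed = 6)
  expect_identical(s1$correlations, s2$correlations)
  expect_true(s1$cs %in% c(0, s1$drop_grid))

  # with many nodes, deep drops leave fewer rows than nodes + 1
  set.seed(99)
  wide <- as.data.frame(matrix(rnorm(50 * 15), 50, 15))
  expect_warning(
    s3 <- cs_coefficient(wide, "strength", drop_grid = c(0.1, 0.75),
                         B_per_drop = 10, seed = 6),
    "subsample"
  )
  expect_equal(s3$drop_grid, 0.1)
  expect_error(cs_coefficient(sl[1:40, ], "strength"), "at least 50")
})

test_that("CS is non-decreasing in sample size on the fixture family", {
  tr <- default_truth(1)
  cs_at <- function(n) {
    sl <- wave_slice(simulate_panel(tr, n0 = n, retention = 1, seed = 16), "T0")
    cs_coefficient(sl, "strength", B_per_drop = 100, seed = 8)$cs
  }
  vals <- c(cs_at(100), cs_at(500), cs_at(3000))
  expect_true(all(diff(vals) >= 0))
})
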