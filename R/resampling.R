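#' Nonparametric bootstrap accuracy of edge weights
#'
#' Resamples subjects with replacement `B` times and re-runs the full
#' estimation chain (correlation, graphical lasso path, EBIC selection) on
#' every replicate, yielding empirical quantile confidence intervals per
#' edge. Replicates that produce a degenerate sample (a zero-variance
#' column) are redrawn; the redraw count is recorded.
#'
#' @param data Subjects-by-nodes data frame (n >= 30 complete rows).
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Seed for the resampling stream.
#' @param level Confidence level of the quantile intervals.
#' @inheritParams estimate_network
#' @return An `edge_bootstrap` tibble: per edge the sample `estimate`,
#'   `boot_mean`, `ci_lower`, `ci_upper` and replicate count `B`, with the
#'   redraw count in `attr(, "redraws")`.
#' @export
bootstrap_edges <- function(data, B = 1000L, seed = 1L, level = 0.95,
                            gamma = 0.5, n_lambda = 100L,
                            lambda_min_ratio = 0.01,
                            cor_method = c("pearson", "spearman"),
                            edge_threshold = TRUE) {
  cor_method <- match.arg(cor_method)
  if (B < 2) stop("`B` must be at least 2", call. = FALSE)
  x <- as.matrix(data)
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 30) stop("bootstrap needs at least 30 complete rows", call. = FALSE)
  est <- function(m) {
    core <- estimate_core(m, gamma = gamma, n_lambda = n_lambda,
                          lambda_min_ratio = lambda_min_ratio,
                          cor_method = cor_method)
    W <- precision_to_partial(core$Theta)
    if (edge_threshold) W <- apply_edge_threshold(W, core$n)
    W
  }
  W0 <- est(x)
  labs <- colnames(W0)
  ut <- upper.tri(W0)
  redraws <- 0L
  boot <- with_seed(seed, {
    out <- matrix(NA_real_, B, sum(ut))
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        m <- x[idx, , drop = FALSE]
        if (all(apply(m, 2, sd) > 0)) break
        redraws <- redraws + 1L
      }
      out[b, ] <- est(m)[ut]
    }
    out
  })
  alpha <- (1 - level) / 2
  idx <- which(ut, arr.ind = TRUE)
  out <- tibble::tibble(
    node_a = labs[idx[, 1]],
    node_b = labs[idx[, 2]],
    estimate = W0[ut],
    boot_mean = colMeans(boot),
    ci_lower = apply(boot, 2, quantile, probs = alpha),
    ci_upper = apply(boot, 2, quantile, probs = 1 - alpha),
    B = as.integer(B)
  )
  structure(out, redraws = redraws, level = level, n = n,
            class = c("edge_bootstrap", class(out)))
}

#' Correlation-stability decision rule
#'
#' Given case-dropping bootstrap correlations between subsample and
#' full-sample centralities, the CS coefficient is the largest drop
#' proportion q such that, at every grid point up to and including q, at
#' least `confidence` of the correlations reach `corr_threshold`. Returns 0
#' when no grid point qualifies. Missing correlations (degenerate
#' subsamples) count as failures.
#'
#' @param correlations Data frame with columns `drop` (proportion dropped)
#'   and `correlation`.
#' @param corr_threshold Correlation level that must be maintained
#'   (default 0.7).
#' @param confidence Required fraction of replicates reaching the threshold
#'   (default 0.95).
#' @return CS coefficient (a value of the drop grid, or 0).
#' @export
cs_from_correlations <- function(correlations, corr_threshold = 0.7,
                                 confidence = 0.95) {
  stopifnot(all(c("drop", "correlation") %in% names(correlations)))
  ok <- correlations |>
    dplyr::group_by(.data$drop) |>
    dplyr::summarise(
      pass = mean(!is.na(.data$correlation) &
                    .data$correlation >= corr_threshold) >= confidence,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$drop)
  qualifying <- ok$drop[cumsum(!ok$pass) == 0 & ok$pass]
  if (length(qualifying)) max(qualifying) else 0
}

#' Case-dropping bootstrap stability of centrality (CS coefficient)
#'
#' For each drop proportion q in `drop_grid`, draws `B_per_drop` subsamples
#' without replacement of size `round(n * (1 - q))`, re-estimates the
#' network and the chosen centrality index, and records the Pearson
#' correlation with the full-sample centralities across nodes. The CS
#' coefficient is then computed with [cs_from_correlations()]; benchmarks
#' in the field are 0.25 (minimum acceptable) and 0.5 (good).
#'
#' @param data Subjects-by-nodes data frame (n >= 50 complete rows).
#' @param index `"strength"` or `"expected_influence"`.
#' @param drop_grid Ordered drop proportions in (0, 0.75].
#' @param B_per_drop Subsamples per grid point (a desk-scale default; the
#'   field convention of 1000 total case-dropping samples can be matched by
#'   raising it).
#' @param corr_threshold,confidence See [cs_from_correlations()].
#' @param seed Seed for the subsampling stream.
#' @inheritParams estimate_network
#' @return A `stability_result`: the per-replicate `correlations` tibble
#'   (`drop`, `rep`, `correlation`), the `cs` coefficient, and the settings.
#' @export
cs_coefficient <- function(data, index = c("strength", "expected_influence"),
                           drop_grid = seq(0.05, 0.75, by = 0.05),
                           B_per_drop = 200L, corr_threshold = 0.7,
                           confidence = 0.95, seed = 1L,
                           gamma = 0.5, n_lambda = 100L,
                           lambda_min_ratio = 0.01,
                           cor_method = c("pearson", "spearman"),
                           edge_threshold = TRUE) {
  index <- match.arg(index)
  cor_method <- match.arg(cor_method)
  stopifnot(all(drop_grid > 0), all(drop_grid <= 0.75))
  drop_grid <- sort(drop_grid)
  x <- as.matrix(data)
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  if (n < 50) stop("case-dropping bootstrap needs at least 50 complete rows",
                   call. = FALSE)
  cent <- function(m) {
    core <- estimate_core(m, gamma = gamma, n_lambda = n_lambda,
                          lambda_min_ratio = lambda_min_ratio,
                          cor_method = cor_method)
    W <- precision_to_partial(core$Theta)
    if (edge_threshold) W <- apply_edge_threshold(W, core$n)
    if (index == "strength") colSums(abs(W)) else colSums(W)
  }
  full <- cent(x)
  sizes <- round(n * (1 - drop_grid))
  usable <- sizes >= p + 1
  if (any(!usable)) {
    warning("dropping grid point(s) ",
            paste(drop_grid[!usable], collapse = ", "),
            ": subsample smaller than nodes + 1", call. = FALSE)
  }
  grid <- drop_grid[usable]
  cors <- with_seed(seed, {
    purrr::map_dfr(grid, function(q) {
      m_size <- round(n * (1 - q))
      cc <- vapply(seq_len(B_per_drop), function(b) {
        idx <- sample.int(n, m_size)
        sub <- x[idx, , drop = FALSE]
        if (any(apply(sub, 2, sd) == 0)) return(NA_real_)
        cs <- cent(sub)
        if (sd(cs) == 0 || sd(full) == 0) return(NA_real_)
        cor(cs, full)
      }, numeric(1))
      tibble::tibble(drop = q, rep = seq_len(B_per_drop), correlation = cc)
    })
  })
  structure(
    list(
      correlations = cors,
      cs = cs_from_correlations(cors, corr_threshold, confidence),
      index = index,
      drop_grid = grid,
      B_per_drop = as.integer(B_per_drop),
      corr_threshold = corr_threshold,
      confidence = confidence,
      n = n
    ),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result> index = ", x$index, ", CS(cor = ",
      x$corr_threshold, ") = ", format(x$cs), " (n = ", x$n, ", ",
      x$B_per_drop, " subsamples per drop)\n", sep = "")
  invisible(x)
}

#' @export
tidy.stability_result <- function(x, ...) x$correlations

#' @export
glance.stability_result <- function(x, ...) {
  tibble::tibble(
    index = x$index,
    cs = x$cs,
    corr_threshold = x$corr_threshold,
    confidence = x$confidence,
    B_per_drop = x$B_per_drop,
    n = x$n
  )
}
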