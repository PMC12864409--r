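#' Marginal transform specification for one node
#'
#' Describes how a standardized latent score is mapped onto the observed
#' scale of one instrument subscale. Two monotone maps are supported:
#'
#' * Likert-sum emulation (default): the standard-normal CDF value of the
#'   latent score is pushed through a beta quantile with shapes
#'   `4 * exp(-skew)` and `4 * exp(skew)` and rescaled to `[low, high]`;
#'   positive `skew` gives the right-skewed, floor-heavy distributions
#'   typical of craving subscale sums. `integer = TRUE` rounds to whole
#'   scores afterwards.
#' * Location-scale (`mean`/`sd` given): `mean + sd * z`, clamped to
#'   `[low, high]` — used for quasi-continuous reaction-time nodes.
#'
#' @param node Node label.
#' @param low,high Bounds of the observed score range (`low < high`).
#' @param integer Round to integers (Likert sums)?
#' @param skew Skewness parameter; 0 is symmetric, positive skews right.
#' @param mean,sd Optional location-scale parameters; when given they take
#'   precedence over the beta map.
#' @return One-row tibble usable as a row of `sim_truth$marginals`.
#' @export
marginal_spec <- function(node, low, high, integer = TRUE, skew = 0,
                          mean = NA_real_, sd = NA_real_) {
  if (low >= high) stop("`low` must be < `high`", call. = FALSE)
  tibble::tibble(node = node, low = low, high = high, integer = integer,
                 skew = skew, mean = mean, sd = sd)
}

#' Map standardized latent scores onto an observed subscale range
#'
#' Applies the monotone marginal transform described by [marginal_spec()].
#' Rank order is preserved before any integer rounding, and every output
#' lies within `[low, high]`.
#'
#' @param values Numeric vector of (approximately standardized) latent
#'   scores.
#' @param spec A one-row data frame (or list) with the [marginal_spec()]
#'   fields.
#' @return Numeric vector of observed-scale scores.
#' @export
ordinalize <- function(values, spec) {
  spec <- as.list(spec)
  if (spec$low >= spec$high) stop("`low` must be < `high`", call. = FALSE)
  if (!is.null(spec$mean) && !is.na(spec$mean)) {
    out <- spec$mean + spec$sd * values
    out <- pmin(pmax(out, spec$low), spec$high)
  } else {
    a <- 4 * exp(-spec$skew)
    b <- 4 * exp(spec$skew)
    u <- pnorm(values)
    out <- spec$low + (spec$high - spec$low) * qbeta(u, a, b)
  }
  if (isTRUE(spec$integer)) out <- round(out)
  out
}

#' Simulate a two-wave symptom panel from known ground truth
#'
#' Wave-1 latent scores are drawn from the zero-mean Gaussian with precision
#' `truth$Omega`. Wave-2 latent scores are generated as
#' `t(Bmat) %*% z1_standardized + noise`, i.e. a linear autoregressive and
#' cross-lagged map on the standardized wave-1 latents plus independent
#' Gaussian innovations with the per-node `noise_sd`. Marginal transforms
#' ([ordinalize()]) are applied last, and attrition removes a random
#' (score-independent) subset of subjects from wave 2, retaining exactly
#' `round(n0 * retention)` completers.
#'
#' @param truth A [sim_truth()] object.
#' @param n0 Baseline sample size (defaults to `truth$n0`).
#' @param retention Wave-2 retention fraction (defaults to
#'   `truth$retention`). An optional score-dependent dropout mechanism is
#'   available via `dropout_by`: subjects with higher wave-1 scores on that
#'   node are preferentially dropped (logistic weighting), for sensitivity
#'   analyses; the default is missing completely at random.
#' @param identity_marginals If `TRUE`, skip the marginal transforms and
#'   return latent (standardized-scale) scores — used for parameter-recovery
#'   checks.
#' @param dropout_by Optional node label for score-dependent attrition.
#' @param seed Seed for the panel's single pseudo-random stream (defaults to
#'   `truth$seed`).
#' @return A `symptom_panel`: a tibble with columns `subject_id`, `wave`
#'   (`"T0"`/`"T1"`) and one column per node; one row per observed
#'   subject-wave. Node labels are kept in `attr(panel, "node_labels")`.
#' @export
simulate_panel <- function(truth, n0 = NULL, retention = NULL,
                           identity_marginals = FALSE, dropout_by = NULL,
                           seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  n0 <- as.integer(n0 %||% truth$n0)
  retention <- retention %||% truth$retention
  seed <- seed %||% truth$seed
  if (retention <= 0) stop("`retention` must be > 0", call. = FALSE)
  if (retention > 1) stop("`retention` must be <= 1", call. = FALSE)
  p <- length(truth$node_labels)
  ev <- eigen(truth$Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("`Omega` is not positive definite: smallest eigenvalue ",
         format(min(ev)), call. = FALSE)
  }
  Sigma <- solve(truth$Omega)
  sd1 <- sqrt(diag(Sigma))
  CH <- chol(Sigma)

  with_seed(seed, {
    z1 <- matrix(rnorm(n0 * p), n0, p) %*% CH
    z1s <- sweep(z1, 2, sd1, "/")
    eps <- matrix(rnorm(n0 * p), n0, p)
    z2 <- z1s %*% truth$Bmat + sweep(eps, 2, truth$noise_sd, "*")
    n1 <- as.integer(round(n0 * retention))
    if (is.null(dropout_by)) {
      keep <- sample.int(n0, n1)
    } else {
      j <- match(dropout_by, truth$node_labels)
      if (is.na(j)) stop("unknown `dropout_by` node: ", dropout_by, call. = FALSE)
      w <- stats::plogis(-z1s[, j])  # higher score -> more likely to drop
      keep <- sample.int(n0, n1, prob = w)
    }
    keep <- sort(keep)

    score_cols <- function(z) {
      if (identity_marginals) {
        out <- as.data.frame(z)
      } else {
        out <- as.data.frame(
          lapply(seq_len(p), function(k) {
            ordinalize(z[, k], truth$marginals[k, ])
          })
        )
      }
      names(out) <- truth$node_labels
      out
    }
    ids <- sprintf("S%04d", seq_len(n0))
    t0 <- tibble::as_tibble(cbind(
      data.frame(subject_id = ids, wave = "T0", stringsAsFactors = FALSE),
      score_cols(z1)
    ))
    t1 <- tibble::as_tibble(cbind(
      data.frame(subject_id = ids[keep], wave = "T1", stringsAsFactors = FALSE),
      score_cols(z2[keep, , drop = FALSE])
    ))
    new_symptom_panel(dplyr::bind_rows(t0, t1), truth$node_labels)
  })
}

new_symptom_panel <- function(df, node_labels) {
  df <- tibble::as_tibble(df)
  structure(df,
            node_labels = node_labels,
            class = c("symptom_panel", class(tibble::tibble())))
}

#' @export
print.symptom_panel <- function(x, ...) {
  nl <- panel_nodes(x)
  cat("<symptom_panel> ", length(unique(x$subject_id)), " subjects, ",
      sum(x$wave == "T0"), " at T0, ", sum(x$wave == "T1"), " at T1; nodes: ",
      paste(nl, collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Panel accessors
#'
#' `panel_nodes()` returns the node labels of a panel; `wave_slice()`
#' extracts the complete-case subjects-by-nodes score table of one wave;
#' `completers()` returns the IDs of subjects observed at both waves.
#'
#' @param panel A `symptom_panel` (or any data frame with `subject_id`,
#'   `wave` and node columns).
#' @param wave Wave label, e.g. `"T0"`.
#' @return `wave_slice()`: a tibble of node columns (complete cases only)
#'   with the number of dropped incomplete rows in `attr(,"n_incomplete")`.
#' @export
panel_nodes <- function(panel) {
  attr(panel, "node_labels") %||%
    setdiff(names(panel), c("subject_id", "wave"))
}

#' @rdname panel_nodes
#' @export
wave_slice <- function(panel, wave) {
  stopifnot(wave %in% panel$wave)
  nodes <- panel_nodes(panel)
  sl <- panel[panel$wave == wave, nodes, drop = FALSE]
  cc <- complete.cases(sl)
  out <- tibble::as_tibble(sl[cc, , drop = FALSE])
  attr(out, "n_incomplete") <- sum(!cc)
  out
}

#' @rdname panel_nodes
#' @export
completers <- function(panel) {
  t0 <- unique(panel$subject_id[panel$wave == "T0"])
  t1 <- unique(panel$subject_id[panel$wave == "T1"])
  intersect(t0, t1)
}

# subjects x nodes matrices of completers at each wave, aligned by subject
completer_matrices <- function(panel) {
  nodes <- panel_nodes(panel)
  ids <- completers(panel)
  t0 <- panel[panel$wave == "T0", , drop = FALSE]
  t1 <- panel[panel$wave == "T1", , drop = FALSE]
  x0 <- as.matrix(t0[match(ids, t0$subject_id), nodes, drop = FALSE])
  x1 <- as.matrix(t1[match(ids, t1$subject_id), nodes, drop = FALSE])
  cc <- complete.cases(x0) & complete.cases(x1)
  list(x0 = x0[cc, , drop = FALSE], x1 = x1[cc, , drop = FALSE],
       subject_ids = ids[cc])
}
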