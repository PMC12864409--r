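#' Fit a cross-lagged panel network (CLPN)
#'
#' Estimates the directed wave-1 -> wave-2 coefficient matrix by node-wise
#' LASSO regression on completers: for each outcome node j, the
#' z-standardized wave-2 score is regressed on all z-standardized wave-1
#' scores, with the L1 penalty chosen by 10-fold cross-validation (fold
#' assignment seeded and shared across the ten outcome regressions).
#' `W[i, j]` is the standardized coefficient of wave-1 node i predicting
#' wave-2 node j; the diagonal holds the autoregressive effects.
#'
#' @param panel A `symptom_panel` (long tibble with `subject_id`, `wave`
#'   and node columns). Complete-case analysis on subjects observed at both
#'   waves.
#' @param n_folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @param report_threshold Absolute-value cutoff used by
#'   [reported_edges()] for cross-lagged edges; it never alters `W`.
#' @param penalty_rule `"min"` (penalty minimizing mean CV error, the
#'   default) or `"1se"` (one-standard-error rule).
#' @return A `clpn_network`: node labels, the directed coefficient matrix
#'   `W`, per-outcome selected penalties, the autoregressive diagonal and
#'   per-node in-/out- expected influence (signed sums over incoming /
#'   outgoing cross-lagged entries, diagonal excluded).
#' @export
fit_clpn <- function(panel, n_folds = 10L, seed = 1L, report_threshold = 0.1,
                     penalty_rule = c("min", "1se")) {
  penalty_rule <- match.arg(penalty_rule)
  mats <- completer_matrices(panel)
  x0 <- mats$x0
  x1 <- mats$x1
  n <- nrow(x0)
  nodes <- colnames(x0)
  p <- length(nodes)
  if (n < 50) stop("CLPN estimation needs at least 50 completers", call. = FALSE)
  if (n_folds > n) stop("`n_folds` exceeds the number of completers", call. = FALSE)
  sd0 <- apply(x0, 2, sd)
  sd1 <- apply(x1, 2, sd)
  if (any(sd0 == 0)) {
    stop("zero-variance wave-1 predictor(s): ",
         paste(nodes[sd0 == 0], collapse = ", "), call. = FALSE)
  }
  if (any(sd1 == 0)) {
    stop("zero-variance wave-2 outcome(s): ",
         paste(nodes[sd1 == 0], collapse = ", "), call. = FALSE)
  }
  z0 <- scale(x0)
  z1 <- scale(x1)
  foldid <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))
  lambda_sel <- setNames(numeric(p), nodes)
  for (j in seq_len(p)) {
    cv <- glmnet::cv.glmnet(z0, z1[, j], family = "gaussian",
                            foldid = foldid, standardize = FALSE)
    s <- if (penalty_rule == "min") cv$lambda.min else cv$lambda.1se
    lambda_sel[j] <- s
    W[, j] <- as.numeric(stats::coef(cv, s = s))[-1]
  }
  structure(
    list(
      node_labels = nodes,
      W = W,
      lambda_per_outcome = lambda_sel,
      report_threshold = report_threshold,
      autoregressive = setNames(diag(W), nodes),
      in_ei = setNames(colSums(W) - diag(W), nodes),
      out_ei = setNames(rowSums(W) - diag(W), nodes),
      n = n,
      n_folds = as.integer(n_folds),
      penalty_rule = penalty_rule,
      fold_seed = as.integer(seed)
    ),
    class = "clpn_network"
  )
}

#' Reported edges of a cross-lagged panel network
#'
#' Cross-lagged (off-diagonal) entries of `W` with absolute value above the
#' report threshold, plus all autoregressive (diagonal) entries,
#' unthresholded. The filter affects only this report, never the fitted
#' matrix.
#'
#' @param model A `clpn_network`.
#' @param threshold Override of the model's report threshold.
#' @return Tibble with columns `from`, `to`, `weight`,
#'   `type` (`"cross_lagged"` or `"autoregressive"`).
#' @export
reported_edges <- function(model, threshold = NULL) {
  stopifnot(inherits(model, "clpn_network"))
  thr <- threshold %||% model$report_threshold
  W <- model$W
  labs <- model$node_labels
  idx <- which(row(W) != col(W) & abs(W) > thr, arr.ind = TRUE)
  cross <- tibble::tibble(
    from = labs[idx[, 1]],
    to = labs[idx[, 2]],
    weight = W[idx],
    type = "cross_lagged"
  )
  auto <- tibble::tibble(
    from = labs, to = labs, weight = unname(diag(W)),
    type = "autoregressive"
  )
  dplyr::bind_rows(dplyr::arrange(cross, dplyr::desc(abs(.data$weight))), auto)
}

#' Temporal expected influence of a cross-lagged panel network
#'
#' Signed sums of incoming (`in_ei`) and outgoing (`out_ei`) cross-lagged
#' coefficients per node; autoregressive (diagonal) entries are excluded.
#'
#' @param model A `clpn_network`.
#' @return Tibble with columns `node`, `in_ei`, `out_ei`.
#' @export
temporal_ei <- function(model) {
  stopifnot(inherits(model, "clpn_network"))
  tibble::tibble(
    node = model$node_labels,
    in_ei = unname(model$in_ei),
    out_ei = unname(model$out_ei)
  )
}

#' @export
print.clpn_network <- function(x, ...) {
  ncl <- sum(row(x$W) != col(x$W) & abs(x$W) > x$report_threshold)
  cat("<clpn_network> ", length(x$node_labels), " nodes, n = ", x$n,
      " completers, ", x$n_folds, "-fold CV (", x$penalty_rule, ")\n",
      sep = "")
  cat("  ", ncl, " cross-lagged edge(s) above |", x$report_threshold,
      "|; strongest autoregressive: ",
      x$node_labels[which.max(x$autoregressive)], " = ",
      format(max(x$autoregressive), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.clpn_network <- function(x, ...) {
  W <- x$W
  labs <- x$node_labels
  idx <- which(abs(W) > 1e-10, arr.ind = TRUE)
  tibble::tibble(
    from = labs[idx[, 1]],
    to = labs[idx[, 2]],
    weight = W[idx],
    type = ifelse(idx[, 1] == idx[, 2], "autoregressive", "cross_lagged")
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)))
}

#' @export
glance.clpn_network <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    nodes = length(x$node_labels),
    n_folds = x$n_folds,
    penalty_rule = x$penalty_rule,
    report_threshold = x$report_threshold,
    reported_cross_lagged = sum(row(x$W) != col(x$W) &
                                  abs(x$W) > x$report_threshold),
    max_out_ei_node = x$node_labels[which.max(x$out_ei)],
    max_in_ei_node = x$node_labels[which.max(x$in_ei)]
  )
}

#' Export a cross-lagged panel network
#'
#' Writes the directed edge list CSV (`<stem>_edges.csv`, all nonzero
#' entries with type) and a JSON model dump (`<stem>.json`).
#'
#' @param model A `clpn_network`.
#' @param stem Output path stem.
#' @return Invisible character vector of files written.
#' @export
write_clpn <- function(model, stem) {
  stopifnot(inherits(model, "clpn_network"))
  files <- paste0(stem, c("_edges.csv", ".json"))
  readr::write_csv(tidy(model), files[1])
  payload <- list(
    node_labels = model$node_labels,
    W = unname(model$W),
    lambda_per_outcome = unname(model$lambda_per_outcome),
    report_threshold = model$report_threshold,
    n = model$n,
    n_folds = model$n_folds,
    penalty_rule = model$penalty_rule,
    fold_seed = model$fold_seed
  )
  jsonlite::write_json(payload, files[2], auto_unbox = TRUE, digits = I(17))
  invisible(files)
}
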