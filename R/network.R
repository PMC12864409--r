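#' Correlation matrix of a wave slice
#'
#' Pearson (default) or Spearman correlations after listwise deletion.
#' The result must be positive semidefinite up to numerical tolerance;
#' eigenvalues in `[-1e-10, 0)` are clipped to zero and the matrix rescaled
#' to unit diagonal, while harder violations raise an error.
#'
#' @param data Subjects-by-nodes data frame (e.g. from [wave_slice()]).
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("`data` must be numeric", call. = FALSE)
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete rows", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  S <- cor(x, method = method)
  ee <- eigen(S, symmetric = TRUE)
  if (min(ee$values) < -1e-10) {
    stop("correlation matrix is not positive semidefinite (smallest ",
         "eigenvalue ", format(min(ee$values)), ")", call. = FALSE)
  }
  if (min(ee$values) < 0) {
    vals <- pmax(ee$values, 0)
    S <- ee$vectors %*% diag(vals) %*% t(ee$vectors)
    S <- stats::cov2cor(S)
    dimnames(S) <- dimnames(cor(x))
  }
  S
}

#' Graphical lasso estimate of a sparse precision matrix
#'
#' Maximizes `log det(Theta) - trace(S Theta) - lambda * sum(|Theta_ij|, i != j)`
#' (off-diagonal L1 penalty only) by block coordinate descent. At
#' `lambda = 0` the maximizer is the matrix inverse of `S`, computed
#' directly.
#'
#' @param S Symmetric positive-semidefinite correlation/covariance matrix.
#' @param lambda Non-negative penalty.
#' @param maxit Maximum number of outer sweeps.
#' @param tol Relative convergence tolerance on the working covariance.
#' @return Symmetric positive-definite precision matrix estimate.
#' @export
glasso_fit <- function(S, lambda, maxit = 10000L, tol = 1e-5) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S), lambda >= 0)
  if (max(abs(S - t(S))) > 1e-8) stop("`S` must be symmetric", call. = FALSE)
  if (lambda == 0) {
    Theta <- tryCatch(chol2inv(chol(S)),
                      error = function(e) stop("`S` is singular; lambda = 0 ",
                                               "requires an invertible input",
                                               call. = FALSE))
    dimnames(Theta) <- dimnames(S)
    return(Theta)
  }
  fit <- glasso_fit_cpp(S, lambda, maxit = maxit, tol = tol)
  if (!fit$converged) {
    stop("graphical lasso did not converge in ", maxit,
         " sweeps (duality gap ", format(fit$dual_gap), ")", call. = FALSE)
  }
  Theta <- fit$theta
  dimnames(Theta) <- dimnames(S)
  Theta
}

#' Partial correlations from a precision matrix
#'
#' `weights_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)` for `i != j`, zero
#' diagonal: the edge weights of the Gaussian graphical model.
#'
#' @param Theta Symmetric positive-definite precision matrix.
#' @return Symmetric weight matrix with zero diagonal.
#' @export
precision_to_partial <- function(Theta) {
  Theta <- as.matrix(Theta)
  if (max(abs(Theta - t(Theta))) > 1e-8) {
    stop("`Theta` must be symmetric", call. = FALSE)
  }
  ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("`Theta` must be positive definite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  W <- -Theta / sqrt(tcrossprod(diag(Theta)))
  diag(W) <- 0
  W
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 loglik + E log(n) + 4 gamma E log(p)`, where `E` is the number
#' of nonzero off-diagonal precision entries (edges), `n` the sample size,
#' `p` the node count and `gamma >= 0` the sparsity-preference
#' hyperparameter (0 reduces to BIC).
#'
#' @param loglik Gaussian log-likelihood at the estimate.
#' @param n Sample size.
#' @param E Edge count.
#' @param p Node count.
#' @param gamma EBIC hyperparameter.
#' @return EBIC value (smaller is better).
#' @export
ebic_score <- function(loglik, n, E, p, gamma = 0.5) {
  stopifnot(n > 0, E >= 0, gamma >= 0)
  -2 * loglik + E * log(n) + 4 * gamma * E * log(p)
}

# High-dimensional-consistency edge threshold (Jankova & van de Geer style):
# partial correlations smaller than this cannot be distinguished from zero
# at sample size n, and dropping them controls the false-positive inclusion
# of tiny edges that a single global penalty otherwise admits at large n.
edge_cutoff <- function(p, n) sqrt(log(p * (p - 1) / 2) / n)

apply_edge_threshold <- function(W, n) {
  cut <- edge_cutoff(ncol(W), n)
  W[abs(W) < cut] <- 0
  W
}

# Fast internal estimator: correlation -> warm-started glasso path -> EBIC
# minimum (ties toward the sparser / larger-lambda model). Returns raw
# pieces; estimate_network() wraps them into the user-facing object.
estimate_core <- function(x, gamma = 0.5, n_lambda = 100L,
                          lambda_min_ratio = 0.01,
                          cor_method = "pearson", tol = 1e-5) {
  S <- correlation_matrix(x, method = cor_method)
  n <- sum(complete.cases(as.matrix(x)))
  p <- ncol(S)
  lambda_max <- max(abs(S[upper.tri(S)]))
  if (lambda_max <= 0) lambda_max <- 1e-4
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  path <- glasso_path_cpp(S, lambdas, maxit = 10000L, tol = tol)
  if (!all(as.logical(path$converged))) {
    stop("graphical lasso failed to converge along the penalty path",
         call. = FALSE)
  }
  loglik <- (n / 2) * (path$logdet - path$trace_s_theta)
  ebic <- ebic_score(loglik, n = n, E = path$edges, p = p, gamma = gamma)
  best <- which.min(ebic) # first index = largest lambda among exact ties
  Theta <- path$thetas[, , best]
  dimnames(Theta) <- dimnames(S)
  list(S = S, n = n, lambdas = lambdas, edges = as.integer(path$edges),
       loglik = loglik, ebic = ebic, best = best, Theta = Theta)
}

#' Estimate a regularized partial-correlation network (GGM)
#'
#' Runs the full estimation chain on one wave of panel data: correlation
#' matrix, graphical lasso along a log-spaced penalty path from
#' `lambda_max` (the smallest penalty yielding an empty graph) down to
#' `lambda_max * lambda_min_ratio`, and EBIC model selection with ties
#' broken toward the sparser model.
#'
#' A single global penalty cannot separate weak true edges from spurious
#' ones at large n: the penalty small enough to retain the former admits a
#' scatter of tiny false positives. The `edge_threshold` step (on by
#' default) therefore zeroes selected partial correlations below
#' `sqrt(log(p(p-1)/2)/n)`, the magnitude below which an edge is not
#' distinguishable from zero at sample size n; this is the standard
#' thresholded-glasso false-positive control and matches the aim of a
#' concise, conservative network.
#'
#' @param data Subjects-by-nodes data frame (listwise deletion applied).
#' @param gamma EBIC hyperparameter; 0.5 is the conservative field default.
#' @param n_lambda Number of penalty values on the path.
#' @param lambda_min_ratio Smallest penalty as a fraction of `lambda_max`.
#' @param cor_method Input correlation: `"pearson"` or `"spearman"`.
#' @param edge_threshold Apply the consistency threshold to the selected
#'   weight matrix?
#' @return A `ggm_network` object: node labels, the selected
#'   partial-correlation weight matrix, the selected penalty and EBIC, and
#'   the full `path` tibble (`lambda`, `edge_count`, `loglik`, `ebic`).
#' @export
estimate_network <- function(data, gamma = 0.5, n_lambda = 100L,
                             lambda_min_ratio = 0.01,
                             cor_method = c("pearson", "spearman"),
                             edge_threshold = TRUE) {
  cor_method <- match.arg(cor_method)
  core <- estimate_core(data, gamma = gamma, n_lambda = n_lambda,
                        lambda_min_ratio = lambda_min_ratio,
                        cor_method = cor_method)
  weights <- precision_to_partial(core$Theta)
  if (edge_threshold) weights <- apply_edge_threshold(weights, core$n)
  structure(
    list(
      node_labels = colnames(core$S),
      weights = weights,
      theta = core$Theta,
      lambda_selected = core$lambdas[core$best],
      ebic_selected = core$ebic[core$best],
      gamma = gamma,
      n = core$n,
      cor_method = cor_method,
      edge_threshold = edge_threshold,
      path = tibble::tibble(lambda = core$lambdas,
                            edge_count = core$edges,
                            loglik = core$loglik,
                            ebic = core$ebic)
    ),
    class = "ggm_network"
  )
}

edge_count <- function(W) sum(abs(W[upper.tri(W)]) > 1e-10)

#' @export
print.ggm_network <- function(x, ...) {
  cat("<ggm_network> ", length(x$node_labels), " nodes, ",
      edge_count(x$weights), " edges (n = ", x$n, ", ", x$cor_method,
      ")\n", sep = "")
  cat("  lambda = ", format(x$lambda_selected, digits = 4),
      ", EBIC = ", format(x$ebic_selected, digits = 6),
      " (gamma = ", x$gamma, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.ggm_network <- function(x, all = FALSE, ...) {
  W <- x$weights
  idx <- which(upper.tri(W), arr.ind = TRUE)
  out <- tibble::tibble(
    node_a = x$node_labels[idx[, 1]],
    node_b = x$node_labels[idx[, 2]],
    weight = W[idx]
  )
  if (!all) out <- dplyr::filter(out, abs(.data$weight) > 1e-10)
  dplyr::arrange(out, dplyr::desc(abs(.data$weight)))
}

#' @export
glance.ggm_network <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    nodes = length(x$node_labels),
    edge_count = edge_count(x$weights),
    lambda_selected = x$lambda_selected,
    ebic_selected = x$ebic_selected,
    gamma = x$gamma,
    cor_method = x$cor_method
  )
}

#' Export / import an estimated network
#'
#' `write_network()` writes the weighted edge list (`<stem>_edges.csv`), the
#' full weight matrix (`<stem>_matrix.csv`) and the model metadata including
#' the penalty path (`<stem>.json`). `read_network()` reconstructs the
#' `ggm_network` from the JSON file.
#'
#' @param network A `ggm_network`.
#' @param stem Output path stem (no extension).
#' @return `write_network()`: invisible character vector of files written.
#' @export
write_network <- function(network, stem) {
  stopifnot(inherits(network, "ggm_network"))
  files <- paste0(stem, c("_edges.csv", "_matrix.csv", ".json"))
  readr::write_csv(tidy(network), files[1])
  mat <- tibble::as_tibble(network$weights, rownames = "node")
  readr::write_csv(mat, files[2])
  payload <- list(
    node_labels = network$node_labels,
    weights = unname(network$weights),
    theta = unname(network$theta),
    lambda_selected = network$lambda_selected,
    ebic_selected = network$ebic_selected,
    gamma = network$gamma,
    n = network$n,
    cor_method = network$cor_method,
    path = network$path
  )
  jsonlite::write_json(payload, files[3], auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(files)
}

#' @rdname write_network
#' @param path Path to a `<stem>.json` file written by `write_network()`.
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(x$node_labels)
  to_mat <- function(m) {
    m <- matrix(unlist(m), p, p, byrow = FALSE)
    dimnames(m) <- list(x$node_labels, x$node_labels)
    m
  }
  structure(
    list(
      node_labels = x$node_labels,
      weights = to_mat(x$weights),
      theta = to_mat(x$theta),
      lambda_selected = x$lambda_selected,
      ebic_selected = x$ebic_selected,
      gamma = x$gamma,
      n = x$n,
      cor_method = x$cor_method,
      path = tibble::as_tibble(x$path)
    ),
    class = "ggm_network"
  )
}
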