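#' Ground-truth parameters for the two-wave panel generator
#'
#' A `sim_truth` object fully determines a simulated two-wave symptom panel:
#' the baseline Gaussian graphical model (a precision matrix `Omega` whose
#' scaled negative off-diagonal is the partial-correlation network), the
#' standardized lagged coefficient matrix `Bmat` (rows = wave-1 predictor,
#' columns = wave-2 outcome; diagonal = autoregressive effects), per-node
#' innovation standard deviations, per-node marginal transforms emulating
#' Likert-sum subscale scores, the baseline sample size and the retention
#' fraction at wave 2.
#'
#' @param node_labels Character vector of node names.
#' @param Omega Symmetric positive-definite precision matrix (nodes x nodes).
#' @param Bmat Matrix of standardized lagged coefficients, same dimension.
#' @param noise_sd Per-node innovation standard deviations for the wave-2
#'   latent scores. Default `NULL` solves for the values that give the wave-2
#'   latents unit variance, so that `Bmat` is itself the standardized lagged
#'   coefficient matrix a cross-lagged panel regression estimates.
#' @param marginals Tibble with one row per node and columns `node`, `low`,
#'   `high`, `integer`, `skew`, `mean`, `sd` (see [marginal_spec()]).
#' @param n0 Baseline sample size.
#' @param retention Fraction of subjects retained at wave 2, in (0, 1].
#' @param seed Integer seed consumed by [simulate_panel()].
#'
#' @return An object of class `sim_truth`.
#' @seealso [default_truth()], [simulate_panel()], [true_partial_cor()]
#' @export
sim_truth <- function(node_labels, Omega, Bmat, noise_sd = NULL, marginals,
                      n0 = 361L, retention = 209 / 361, seed = 1L) {
  p <- length(node_labels)
  stopifnot(is.matrix(Omega), is.matrix(Bmat))
  if (!all(dim(Omega) == p) || !all(dim(Bmat) == p)) {
    stop("`Omega` and `Bmat` must be ", p, "x", p, " to match `node_labels`",
         call. = FALSE)
  }
  if (max(abs(Omega - t(Omega))) > 1e-8) {
    stop("`Omega` must be symmetric", call. = FALSE)
  }
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("`Omega` must be positive definite; smallest eigenvalue is ",
         format(min(ev)), call. = FALSE)
  }
  if (!(retention > 0 && retention <= 1)) {
    stop("`retention` must lie in (0, 1]", call. = FALSE)
  }
  marginals <- tibble::as_tibble(marginals)
  need <- c("node", "low", "high", "integer", "skew", "mean", "sd")
  if (!all(need %in% names(marginals)) ||
      !identical(marginals$node, node_labels)) {
    stop("`marginals` must have one row per node (in node order) with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(marginals$low >= marginals$high)) {
    stop("marginal ranges must satisfy low < high", call. = FALSE)
  }
  R <- stats::cov2cor(solve(Omega))
  lagged_var <- diag(t(Bmat) %*% R %*% Bmat)
  if (is.null(noise_sd)) {
    if (any(lagged_var >= 1)) {
      stop("cannot solve for unit-variance innovations: lagged signal ",
           "variance >= 1 for node(s) ",
           paste(node_labels[lagged_var >= 1], collapse = ", "), call. = FALSE)
    }
    noise_sd <- sqrt(1 - lagged_var)
  }
  stopifnot(length(noise_sd) == p, all(noise_sd > 0))
  structure(
    list(
      node_labels = node_labels,
      Omega = `dimnames<-`(Omega, list(node_labels, node_labels)),
      Bmat = `dimnames<-`(Bmat, list(node_labels, node_labels)),
      noise_sd = setNames(as.numeric(noise_sd), node_labels),
      marginals = marginals,
      n0 = as.integer(n0),
      retention = retention,
      seed = as.integer(seed)
    ),
    class = "sim_truth"
  )
}

#' Default ground truth: a sparse 10-node, two-wave symptom system
#'
#' Fixed fixture emulating a substance-use-disorder symptom battery measured
#' at admission (T0) and one month later (T1): three craving subscales
#' (D1-D3), three compulsive-drug-seeking subscales (O1-O3), three
#' impulsivity subscales (B1-B3) and a stop-signal reaction time (SSRT).
#' The baseline partial-correlation network is sparse (11 of 45 possible
#' edges) with six strong edges (|rho| >= 0.3), including D1-D2, O1-O2 and
#' B1-B3; the lagged matrix carries autoregressive effects of 0.25-0.50 and
#' seven cross-lagged effects of |b| >= 0.15, among them the protective
#' (negative) paths O3 -> B1 and O3 -> B3.
#'
#' The precision matrix has unit diagonal and is strictly diagonally
#' dominant, so it is positive definite and its implied partial correlation
#' between nodes i and j is exactly the tabulated edge value.
#'
#' @param seed Integer seed stored in the object and used by
#'   [simulate_panel()]. The parameters themselves do not depend on it.
#' @return A [sim_truth()] object.
#' @export
default_truth <- function(seed = 1L) {
  labs <- c("D1", "D2", "D3", "O1", "O2", "O3", "B1", "B2", "B3", "SSRT")
  p <- length(labs)
  rho <- matrix(0, p, p, dimnames = list(labs, labs))
  edge <- function(a, b, w) {
    rho[a, b] <<- w
    rho[b, a] <<- w
  }
  edge("D1", "D2", 0.40)
  edge("D1", "O2", 0.30)
  edge("D1", "O1", 0.12)
  edge("D2", "D3", 0.15)
  edge("D3", "O3", 0.30)
  edge("O1", "O2", 0.40)
  edge("O1", "O3", 0.30)
  edge("O1", "B2", 0.12)
  edge("B1", "B2", 0.20)
  edge("B1", "B3", 0.35)
  edge("B3", "SSRT", 0.15)
  Omega <- diag(p) - rho
  dimnames(Omega) <- list(labs, labs)

  B <- matrix(0, p, p, dimnames = list(labs, labs))
  diag(B) <- c(0.30, 0.30, 0.25, 0.40, 0.50, 0.25, 0.40, 0.30, 0.40, 0.35)
  B["D2", "D1"] <- 0.20
  B["O1", "D1"] <- 0.18
  B["D1", "O2"] <- 0.20
  B["O1", "B1"] <- 0.18
  B["O2", "B1"] <- -0.15
  B["O3", "B1"] <- -0.22
  B["O3", "B3"] <- -0.18

  marg <- tibble::tibble(
    node = labs,
    low = c(4, 4, 4, 5, 5, 3, 10, 10, 10, 50),
    high = c(28, 28, 28, 25, 25, 15, 40, 40, 40, 600),
    integer = c(rep(TRUE, 9), FALSE),
    skew = c(1.0, 1.0, 0.8, 0.5, 0.5, 0.5, 0, 0, 0, 0),
    mean = c(rep(NA_real_, 9), 260),
    sd = c(rep(NA_real_, 9), 40)
  )
  sim_truth(labs, Omega, B, noise_sd = NULL, marginals = marg,
            n0 = 361L, retention = 209 / 361, seed = seed)
}

#' True partial-correlation network implied by a precision matrix
#'
#' Computes `rho_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)` with a zero
#' diagonal: the population edge weights of the Gaussian graphical model.
#'
#' @param x A `sim_truth` object or a symmetric positive-definite precision
#'   matrix.
#' @return Symmetric weight matrix with zero diagonal.
#' @export
true_partial_cor <- function(x) {
  Omega <- if (inherits(x, "sim_truth")) x$Omega else x
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("precision matrix must be positive definite", call. = FALSE)
  }
  P <- -stats::cov2cor(Omega)
  diag(P) <- 0
  P
}

#' Population standardized lagged coefficients of a simulation truth
#'
#' The cross-lagged panel regression standardizes both the wave-1 predictors
#' and the wave-2 outcomes, so its population coefficient matrix is `Bmat`
#' with each column rescaled by the implied wave-2 latent standard deviation.
#' Under the default unit-variance innovations this equals `Bmat` exactly.
#'
#' @param truth A [sim_truth()] object.
#' @return Matrix of population standardized lagged coefficients.
#' @export
true_lagged_std <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  R <- stats::cov2cor(solve(truth$Omega))
  v2 <- diag(t(truth$Bmat) %*% R %*% truth$Bmat) + truth$noise_sd^2
  sweep(truth$Bmat, 2, sqrt(v2), "/")
}

#' @export
print.sim_truth <- function(x, ...) {
  P <- true_partial_cor(x)
  ut <- P[upper.tri(P)]
  cat("<sim_truth> ", length(x$node_labels), " nodes (",
      paste(x$node_labels, collapse = ", "), ")\n", sep = "")
  cat("  baseline edges: ", sum(abs(ut) > 1e-12), " nonzero, ",
      sum(abs(ut) >= 0.3), " with |rho| >= 0.3\n", sep = "")
  cat("  lagged effects: ", sum(abs(x$Bmat) > 1e-12) - sum(abs(diag(x$Bmat)) > 1e-12),
      " cross-lagged, autoregressive range [",
      format(min(diag(x$Bmat)), digits = 3), ", ",
      format(max(diag(x$Bmat)), digits = 3), "]\n", sep = "")
  cat("  n0 = ", x$n0, ", retention = ", format(x$retention, digits = 4),
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read simulation truth as JSON
#'
#' Round-trips all fields of a [sim_truth()] object through a plain JSON
#' file.
#'
#' @param truth A `sim_truth` object.
#' @param path File path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   the reconstructed `sim_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  payload <- list(
    node_labels = truth$node_labels,
    Omega = unname(truth$Omega),
    Bmat = unname(truth$Bmat),
    noise_sd = unname(truth$noise_sd),
    marginals = truth$marginals,
    n0 = truth$n0,
    retention = truth$retention,
    seed = truth$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  marg <- tibble::as_tibble(x$marginals)
  marg$integer <- as.logical(marg$integer)
  sim_truth(
    node_labels = x$node_labels,
    Omega = matrix(unlist(x$Omega), length(x$node_labels), byrow = FALSE),
    Bmat = matrix(unlist(x$Bmat), length(x$node_labels), byrow = FALSE),
    noise_sd = as.numeric(x$noise_sd),
    marginals = marg,
    n0 = x$n0,
    retention = x$retention,
    seed = x$seed
  )
}
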