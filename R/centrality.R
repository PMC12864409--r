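get_weights <- function(network) {
  if (inherits(network, "ggm_network")) network$weights
  else if (is.matrix(network)) network
  else stop("`network` must be a ggm_network or a weight matrix", call. = FALSE)
}

resolve_node <- function(W, node) {
  labs <- colnames(W) %||% as.character(seq_len(ncol(W)))
  if (is.character(node)) {
    j <- match(node, labs)
    if (is.na(j)) stop("unknown node: ", node, call. = FALSE)
  } else {
    j <- as.integer(node)
    if (j < 1 || j > ncol(W)) stop("unknown node index: ", node, call. = FALSE)
  }
  j
}

#' Node strength
#'
#' Sum of absolute weights of the edges incident to a node.
#'
#' @param network A `ggm_network` or symmetric weight matrix.
#' @param node Node label or index.
#' @return Non-negative scalar.
#' @export
strength <- function(network, node) {
  W <- get_weights(network)
  j <- resolve_node(W, node)
  sum(abs(W[-j, j]))
}

#' Expected influence (one-step)
#'
#' Sum of the signed weights of the edges incident to a node. On an
#' all-positive network it equals [strength()].
#'
#' @inheritParams strength
#' @return Real scalar.
#' @export
expected_influence <- function(network, node) {
  W <- get_weights(network)
  j <- resolve_node(W, node)
  sum(W[-j, j])
}

#' Centrality table for an undirected network
#'
#' Raw and z-standardized strength and expected influence for every node.
#' Standardization is across the nodes of the one network (the convention
#' used for standardized centrality plots); if an index is constant across
#' nodes its z column is set to 0 and a warning is recorded.
#'
#' @param network A `ggm_network` or symmetric weight matrix (>= 2 nodes).
#' @return Tibble with columns `node`, `strength`, `expected_influence`,
#'   `z_strength`, `z_expected_influence`. Any degeneracy warnings are kept
#'   in `attr(, "warnings")`.
#' @export
centrality_table <- function(network) {
  W <- get_weights(network)
  p <- ncol(W)
  if (p < 2) stop("centrality needs at least 2 nodes", call. = FALSE)
  labs <- colnames(W) %||% as.character(seq_len(p))
  s <- colSums(abs(W)) - abs(diag(W))
  ei <- colSums(W) - diag(W)
  warnings <- character()
  zscore <- function(v, name) {
    if (sd(v) > 0) return((v - mean(v)) / sd(v))
    warnings <<- c(warnings,
                   paste0(name, " constant across nodes; z set to 0"))
    rep(0, length(v))
  }
  zs <- zscore(s, "strength")
  zei <- zscore(ei, "expected_influence")
  if (length(warnings)) warning(paste(warnings, collapse = "; "), call. = FALSE)
  out <- tibble::tibble(
    node = labs,
    strength = unname(s),
    expected_influence = unname(ei),
    z_strength = unname(zs),
    z_expected_influence = unname(zei)
  )
  attr(out, "warnings") <- warnings
  out
}
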