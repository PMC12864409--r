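# Steiger-style z test for two dependent overlapping correlations
# r(A,k) vs r(B,k) sharing node k, with r(A,B) = r_ab. Fisher transforms are
# compared using the covariance term evaluated at the back-transformed
# average correlation.
steiger_overlap_test <- function(r_ak, r_bk, r_ab, n) {
  rbar <- tanh(mean(atanh(c(r_ak, r_bk))))
  s <- (r_ab * (1 - 2 * rbar^2) -
          0.5 * rbar^2 * (1 - 2 * rbar^2 - r_ab^2)) / (1 - rbar^2)^2
  z <- (atanh(r_ak) - atanh(r_bk)) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Screen node pairs for redundancy (goldbricker-style)
#'
#' Two nodes are candidate duplicates when their zero-order correlation is
#' at least `r_min`. For each candidate pair the screen compares, for every
#' third node k, the correlation of A with k against the correlation of B
#' with k using a dependent-overlapping-correlations z test; if fewer than
#' `prop_threshold` of those comparisons differ significantly at `alpha`,
#' the two nodes relate to the rest of the network near-identically and the
#' pair is flagged redundant.
#'
#' @param data Subjects-by-nodes data frame (>= 20 complete rows).
#' @param r_min Zero-order correlation cutoff for candidacy.
#' @param alpha Significance level of the z tests.
#' @param prop_threshold Pairs with a significant-difference proportion
#'   below this are flagged.
#' @param cor_method Correlation estimator passed to
#'   [correlation_matrix()].
#' @return A `redundancy_report`: tibble of candidate pairs with columns
#'   `node_a`, `node_b`, `zero_order_r`, `prop_significant`, `flagged`, plus
#'   the parameters as attributes.
#' @export
redundancy_screen <- function(data, r_min = 0.50, alpha = 0.05,
                              prop_threshold = 0.25,
                              cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  x <- as.matrix(data)
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  if (p < 3) stop("redundancy screening needs at least 3 nodes", call. = FALSE)
  if (n < 20) stop("redundancy screening needs at least 20 complete rows",
                   call. = FALSE)
  R <- correlation_matrix(x, method = cor_method)
  labs <- colnames(R)
  rows <- list()
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      if (abs(R[a, b]) < r_min) next
      others <- setdiff(seq_len(p), c(a, b))
      sig <- vapply(others, function(k) {
        steiger_overlap_test(R[a, k], R[b, k], R[a, b], n)$p < alpha
      }, logical(1))
      prop <- mean(sig)
      rows[[length(rows) + 1]] <- tibble::tibble(
        node_a = labs[a], node_b = labs[b],
        zero_order_r = R[a, b],
        prop_significant = prop,
        flagged = prop < prop_threshold
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(node_a = character(), node_b = character(),
                   zero_order_r = numeric(), prop_significant = numeric(),
                   flagged = logical())
  }
  structure(out,
            r_min = r_min, alpha = alpha, prop_threshold = prop_threshold,
            cor_method = cor_method, n = n,
            class = c("redundancy_report", class(out)))
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat("<redundancy_report> ", nrow(x), " candidate pair(s), ",
      sum(x$flagged), " flagged redundant (|r| >= ", attr(x, "r_min"),
      ", n = ", attr(x, "n"), ")\n", sep = "")
  NextMethod()
}
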