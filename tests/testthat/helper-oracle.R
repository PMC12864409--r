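# Independent slow oracle for the graphical lasso objective
#   f(Theta) = -log det(Theta) + tr(S Theta) + lambda * ||offdiag(Theta)||_1
# solved by proximal gradient (ISTA) with backtracking line search. Shares
# no code with the package's block coordinate descent.
glasso_oracle <- function(S, lambda, maxit = 50000, tol = 1e-10) {
  soft <- function(M, t) {
    out <- sign(M) * pmax(abs(M) - t, 0)
    diag(out) <- diag(M) # diagonal unpenalized
    out
  }
  smooth_part <- function(Th) {
    ch <- tryCatch(chol(Th), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    -2 * sum(log(diag(ch))) + sum(S * Th)
  }
  Theta <- diag(1 / diag(S))
  for (it in seq_len(maxit)) {
    G <- -solve(Theta) + S
    t_step <- 1
    f_cur <- smooth_part(Theta)
    repeat {
      cand <- soft(Theta - t_step * G, t_step * lambda)
      f_new <- smooth_part(cand)
      if (is.finite(f_new) &&
          f_new <= f_cur + sum(G * (cand - Theta)) +
            sum((cand - Theta)^2) / (2 * t_step)) break
      t_step <- t_step / 2
      if (t_step < 1e-14) break
    }
    delta <- max(abs(cand - Theta))
    Theta <- cand
    if (delta < tol && it > 5) break
  }
  Theta
}

# Brute-force partial correlations by inverting a covariance/correlation
# matrix directly.
partial_cor_oracle <- function(S) {
  K <- solve(S)
  P <- -K / sqrt(tcrossprod(diag(K)))
  diag(P) <- 0
  P
}

random_spd_cor <- function(p, n = 4 * p) {
  stats::cor(matrix(stats::rnorm(n * p), n, p))
}
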