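# shared helpers for the fluxep test suite

# relative comparison with a sensible floor for near-zero targets
expect_rel_equal <- function(actual, expected, rel_tol, floor = 0) {
  scale <- pmax(abs(expected), floor)
  expect_true(all(abs(actual - expected) <= rel_tol * scale),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) / scale), rel_tol))
}

# direct tilted-marginal oracle: invert the precision matrix with D_nn = 0
# (flux n's Gaussian factor deleted) and truncate the resulting marginal
tilted_direct <- function(polytope, beta, a, d, n) {
  S <- polytope$S
  N <- ncol(S)
  dn <- 1 / d
  dn[n] <- 0
  P <- beta * crossprod(S) + diag(dn, N)
  Sigma_n <- solve(P)
  h <- beta * as.vector(crossprod(S, polytope$b)) + a * dn
  mu_n <- as.vector(Sigma_n %*% h)
  tm <- trunc_moments(mu_n[n], Sigma_n[n, n],
                      polytope$lower[n], polytope$upper[n])
  list(mu_c = mu_n[n], s_c = Sigma_n[n, n],
       mean = tm$mean, var = tm$var)
}

# uniform Dirichlet(1,...,1) draws: rows on the standard simplex
rdirichlet_unif <- function(n, N) {
  e <- matrix(stats::rexp(n * N), n, N)
  e / rowSums(e)
}
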