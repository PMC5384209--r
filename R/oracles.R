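# Independent reference computations: uniform polytope sampling by
# hit-and-run, adaptive-quadrature truncated-Gaussian moments, exact simplex
# marginals, closed-form Gaussian conditioning, and LP-based flux balance
# analysis. These back the validation protocol (EP vs sampler moments,
# Pearson correlation) and the test suite's oracles.

# ---- linear programming via boot::simplex -------------------------------
# boot::simplex wants x >= 0 and nonnegative right-hand sides; rows are
# flipped between the <= and >= blocks as needed.
.lp_solve <- function(obj, A_le = NULL, b_le = NULL, A_eq = NULL, b_eq = NULL,
                      maximize = FALSE) {
  nv <- length(obj)
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
  if (!is.null(A_le) && nrow(A_le)) {
    neg <- b_le < 0
    if (any(!neg)) { A1 <- A_le[!neg, , drop = FALSE]; b1 <- b_le[!neg] }
    if (any(neg)) { A2 <- -A_le[neg, , drop = FALSE]; b2 <- -b_le[neg] }
  }
  A3 <- NULL; b3 <- NULL
  if (!is.null(A_eq) && nrow(A_eq)) {
    sgn <- ifelse(b_eq < 0, -1, 1)
    A3 <- A_eq * sgn; b3 <- b_eq * sgn
  }
  res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = A3, b3 = b3, maxi = maximize,
                       n.iter = max(200L, 20L * nv))
  if (res$solved < 0)
    stop("linear program infeasible", call. = FALSE)
  if (res$solved == 0)
    stop("linear program did not converge", call. = FALSE)
  list(x = res$soln, value = res$value)
}

# ---- null-space machinery ----------------------------------------------
# orthonormal null-space basis B and minimum-norm particular solution of
# S v = b; tolerance-based rank decision
.nullspace <- function(S, b) {
  N <- ncol(S)
  if (nrow(S) == 0L)
    return(list(B = diag(N), vp = rep(0, N), rank = 0L))
  sv <- svd(S, nu = nrow(S), nv = N)
  tol <- max(dim(S)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  B <- sv$v[, seq(r + 1, N), drop = FALSE]
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  vp <- as.vector(sv$v[, seq_len(length(sv$d)), drop = FALSE] %*%
                    (dinv * as.vector(crossprod(sv$u[, seq_len(length(sv$d)), drop = FALSE], b))))
  # consistency: S vp must reproduce b
  if (max(abs(S %*% vp - b)) > 1e-8 * max(1, max(abs(b))))
    stop("equality constraints are inconsistent (S v = b has no solution)",
         call. = FALSE)
  list(B = B, vp = vp, rank = r)
}

#' Chebyshev-centre interior point of a flux polytope
#'
#' Finds the centre of the largest ball inscribed in the polytope's
#' null-space section by linear programming; a robust interior point for
#' starting the hit-and-run walk even on thin polytopes.
#'
#' @param polytope a [flux_polytope()].
#' @return numeric flux vector (internal units) strictly inside the box.
#' @export
chebyshev_center <- function(polytope) {
  ns <- .nullspace(polytope$S, polytope$b)
  B <- ns$B; vp <- ns$vp
  K <- ncol(B); N <- nrow(B)
  rn <- sqrt(rowSums(B^2))
  # variables: y+ (K), y- (K), r (1); maximize r
  rows_le <- list(); rhs <- c()
  for (i in seq_len(N)) {
    if (is.finite(polytope$upper[i])) {
      rows_le <- c(rows_le, list(c(B[i, ], -B[i, ], rn[i])))
      rhs <- c(rhs, polytope$upper[i] - vp[i])
    }
    if (is.finite(polytope$lower[i])) {
      rows_le <- c(rows_le, list(c(-B[i, ], B[i, ], rn[i])))
      rhs <- c(rhs, vp[i] - polytope$lower[i])
    }
  }
  A_le <- do.call(rbind, rows_le)
  obj <- c(rep(0, 2 * K), 1)
  sol <- tryCatch(.lp_solve(obj, A_le, rhs, maximize = TRUE),
                  error = function(e)
                    stop("no feasible interior point found: ",
                         conditionMessage(e), call. = FALSE))
  if (sol$value <= 0)
    stop("no feasible interior point found (inscribed radius <= 0)",
         call. = FALSE)
  y <- sol$x[seq_len(K)] - sol$x[K + seq_len(K)]
  as.vector(vp + B %*% y)
}

#' Uniform sampling of a flux polytope by hit-and-run
#'
#' Random-walk sampler in the affine null-space parametrisation of
#' `S v = b`: from the current point, draw an isotropic direction in the
#' null space, intersect the line with the box to get the feasible chord,
#' and jump to a uniform point on it. Every `T / n_samples`-th state is
#' recorded. Asymptotically (large `T`) the records are uniform draws from
#' the polytope.
#'
#' @param polytope a [flux_polytope()].
#' @param T total number of explored configurations (walk steps).
#' @param n_samples number of recorded samples (the protocol default 1e4).
#' @param seed integer seed; identical inputs and seed give identical
#'   samples.
#' @param x0 optional starting interior point (internal units); defaults to
#'   the polytope's certificate or, failing that, the Chebyshev centre.
#' @return an object of class `sample_set`: list with `points`
#'   (`n_samples` x N matrix, native units, columns named by reaction),
#'   `T`, `seed`.
#' @export
#' @examples
#' s <- hit_and_run(make_simplex(3), T = 1e4, n_samples = 100, seed = 1)
#' colMeans(s$points)
hit_and_run <- function(polytope, T = 1e6, n_samples = 1e4, seed = 1,
                        x0 = NULL) {
  stopifnot(inherits(polytope, "flux_polytope"))
  ns <- .nullspace(polytope$S, polytope$b)
  if (ncol(ns$B) == 0L)
    stop("polytope has no interior: null space of S is trivial", call. = FALSE)
  if (is.null(x0)) x0 <- polytope$x0
  if (is.null(x0)) x0 <- chebyshev_center(polytope)
  if (!is_feasible(polytope, x0, tol_eq = 1e-6, tol_box = 1e-8))
    stop("starting point is not feasible", call. = FALSE)
  y0 <- as.vector(crossprod(ns$B, x0 - ns$vp))
  pts <- .with_seed(seed,
    hr_walk_cpp(ns$B, ns$vp, polytope$lower, polytope$upper, y0,
                as.double(T), as.integer(n_samples)))
  pts <- pts * polytope$scale
  colnames(pts) <- polytope$reaction_ids
  structure(list(points = pts, T = T, n_samples = as.integer(n_samples),
                 seed = seed, scale = polytope$scale),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples of %d fluxes (T = %g explored states)\n",
              nrow(x$points), ncol(x$points), x$T))
  invisible(x)
}

#' Per-flux moments of a sample set
#'
#' @param x a `sample_set`.
#' @param ... unused.
#' @return a tibble with columns `reaction`, `mean`, `var` (native units).
#' @method tidy sample_set
#' @export
tidy.sample_set <- function(x, ...) {
  tibble::tibble(reaction = colnames(x$points),
                 mean = colMeans(x$points),
                 var = apply(x$points, 2, stats::var))
}

#' Exact marginal of the uniform distribution on the standard simplex
#'
#' One coordinate of a uniform draw from `{v >= 0, sum(v) = 1}` in `N`
#' dimensions is Beta(1, N-1): mean `1/N`, variance `(N-1)/(N^2 (N+1))`.
#'
#' @param N simplex dimension, at least 2.
#' @return list with `mean` and `var`.
#' @export
simplex_exact_marginal <- function(N) {
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  list(mean = 1 / N, var = (N - 1) / (N^2 * (N + 1)))
}

#' Truncated-Gaussian moments by adaptive quadrature
#'
#' Reference implementation used to validate [trunc_moments()]: integrates
#' the truncated density's moments with [stats::integrate()] on a shifted
#' integrand (relative to the density's maximum over the interval), which
#' stays accurate in the deep-tail regime.
#'
#' @param mu,sigma2,lo,hi as in [trunc_moments()]; scalars.
#' @return list with `mean` and `var`.
#' @export
quadrature_moments <- function(mu, sigma2, lo, hi) {
  stopifnot(sigma2 > 0, lo < hi)
  s <- sqrt(sigma2)
  a <- (lo - mu) / s; b <- (hi - mu) / s
  if (is.infinite(a) && is.infinite(b)) return(list(mean = mu, var = sigma2))
  xref <- min(max(0, a), b)
  ta <- max(a - xref, -xref - sqrt(xref^2 + 160))
  tb <- min(b - xref, -xref + sqrt(xref^2 + 160))
  w <- tb - ta
  f <- function(u, k) { t <- ta + w * u; t^k * exp(-(xref * t + t^2 / 2)) }
  ig <- function(k, at) {
    for (rt in c(1e-13, 1e-12, 1e-11)) {
      r <- tryCatch(stats::integrate(f, 0, 1, k = k, rel.tol = rt,
                                     abs.tol = at, subdivisions = 500L),
                    error = function(e) NULL)
      if (!is.null(r)) return(w * r$value)
    }
    stop("quadrature oracle failed on [", lo, ", ", hi, "]", call. = FALSE)
  }
  N0 <- ig(0, 0)
  sc <- max(abs(ta), abs(tb))
  N1 <- ig(1, 1e-13 * N0 / w * sc)
  N2 <- ig(2, 1e-13 * N0 / w * sc^2)
  g1 <- N1 / N0
  list(mean = mu + s * (xref + g1), var = sigma2 * (N2 / N0 - g1^2))
}

#' Exact Gaussian conditioning on linear equality constraints
#'
#' Closed-form mean and covariance of `N(a, diag(d))` conditioned on
#' `S v = b` via the standard projection formula; the beta -> infinity
#' limit of the non-adaptive baseline.
#'
#' @param a,d prior means and variances (length N, `d > 0`).
#' @param S full-row-rank constraint matrix.
#' @param b right-hand side.
#' @return list with `mean` (length N) and `cov` (N x N).
#' @export
gaussian_conditioning <- function(a, d, S, b) {
  S <- as.matrix(S)
  stopifnot(length(a) == ncol(S), length(d) == ncol(S), all(d > 0))
  G <- S %*% (d * t(S))      # S diag(d) S'
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R) || min(diag(R))^2 < 1e-12 * max(diag(G)))
    stop("S is rank-deficient; conditioning oracle undefined", call. = FALSE)
  K <- d * t(S)              # diag(d) S'
  W <- K %*% chol2inv(R)     # diag(d) S' (S diag(d) S')^-1
  mean <- as.vector(a + W %*% (b - S %*% a))
  cov <- diag(d, length(d)) - W %*% t(K)
  list(mean = mean, cov = (cov + t(cov)) / 2)
}

#' Minimise a flux over the polytope by linear programming
#'
#' Flux balance analysis in minimisation form: the smallest feasible value
#' of one reaction's flux, optionally with other reactions pinned to fixed
#' values (e.g. fix the biomass flux and minimise the glucose exchange to
#' obtain its lower bound).
#'
#' @param model a [metabolic_model()].
#' @param objective reaction identifier to minimise.
#' @param fixed named numeric vector: reactions pinned to equality values.
#' @param maximize minimise (default) or maximise the objective.
#' @param big finite stand-in for infinite bounds in the LP.
#' @return the optimal flux value (native units).
#' @export
#' @examples
#' m <- make_diamond()
#' fba_min_flux(m, "R_in", fixed = c(R_out = 4))
fba_min_flux <- function(model, objective, fixed = NULL, maximize = FALSE,
                         big = 1e9) {
  stopifnot(inherits(model, "metabolic_model"))
  j <- match(objective, model$reaction_ids)
  if (is.na(j)) stop("unknown objective reaction: ", objective, call. = FALSE)
  lower <- model$lower; upper <- model$upper
  if (!is.null(fixed)) {
    idx <- match(names(fixed), model$reaction_ids)
    if (anyNA(idx))
      stop("unknown fixed reaction(s): ",
           paste(names(fixed)[is.na(idx)], collapse = ", "), call. = FALSE)
    out_of_box <- fixed < lower[idx] | fixed > upper[idx]
    if (any(out_of_box))
      stop("infeasible: fixed value outside bounds for ",
           paste(names(fixed)[out_of_box], collapse = ", "), call. = FALSE)
    lower[idx] <- upper[idx] <- fixed
  }
  L <- pmax(lower, -big); U <- pmin(upper, big)
  N <- length(L)
  # x = v - L >= 0; S x = b - S L; x <= U - L
  A_eq <- model$S
  b_eq <- model$b - as.vector(model$S %*% L)
  A_le <- diag(N)
  b_le <- U - L
  obj <- as.double(seq_len(N) == j)
  sol <- .lp_solve(obj, A_le, b_le, A_eq, b_eq, maximize = maximize)
  unname(sol$value + L[j])
}

#' Compare EP marginals with sampler moments
#'
#' The validation protocol: per-flux means and variances from an
#' [ep_result] are matched by reaction identifier against the empirical
#' moments of a `sample_set` (or any tibble with `reaction`, `mean`, `var`),
#' and the Pearson product-moment correlations of the two sets are
#' reported. Pinned fluxes are excluded (they carry no variability).
#'
#' @param ep an [ep_result].
#' @param samples a `sample_set` or a data frame with columns `reaction`,
#'   `mean`, `var`.
#' @return an object of class `ep_comparison`: list with `table` (tibble:
#'   reaction, mean_ep, mean_ref, var_ep, var_ref), `r_means`, `r_vars`.
#' @export
compare_moments <- function(ep, samples) {
  stopifnot(inherits(ep, "ep_result"))
  ref <- if (inherits(samples, "sample_set")) tidy(samples)
         else tibble::as_tibble(samples)
  if (!all(c("reaction", "mean", "var") %in% names(ref)))
    stop("samples must provide columns reaction, mean, var", call. = FALSE)
  epm <- dplyr::filter(ep$marginals, !.data$pinned)
  if (!setequal(epm$reaction, ref$reaction))
    stop("reaction identifiers do not match between EP result and samples",
         call. = FALSE)
  tab <- dplyr::inner_join(
    dplyr::select(epm, "reaction", mean_ep = "mean", var_ep = "var"),
    dplyr::select(ref, "reaction", mean_ref = "mean", var_ref = "var"),
    by = "reaction")
  structure(list(
    table = tab,
    r_means = stats::cor(tab$mean_ep, tab$mean_ref),
    r_vars = stats::cor(tab$var_ep, tab$var_ref)),
    class = "ep_comparison")
}

#' @export
print.ep_comparison <- function(x, ...) {
  cat(sprintf("<ep_comparison> %d fluxes: Pearson r(means) = %.4f, r(vars) = %.4f\n",
              nrow(x$table), x$r_means, x$r_vars))
  invisible(x)
}

#' @method tidy ep_comparison
#' @export
tidy.ep_comparison <- function(x, ...) x$table

#' @method glance ep_comparison
#' @export
glance.ep_comparison <- function(x, ...) {
  tibble::tibble(n_fluxes = nrow(x$table), r_means = x$r_means,
                 r_vars = x$r_vars)
}
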