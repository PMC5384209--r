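# Expectation propagation over the steady-state flux polytope.
#
# The posterior is P(v) ~ exp(-beta/2 ||S v - b||^2) * prod_n psi_n(v_n),
# with psi_n the indicator of [lower_n, upper_n]. EP replaces each indicator
# by a Gaussian factor phi_n(v_n; a_n, d_n) and refines (a_n, d_n) by moment
# matching against the tilted distribution Q^(n), in which only flux n keeps
# its exact box prior. The full approximation Q is the multivariate Gaussian
# with precision beta * S'S + D, D = diag(1/d). The tilted marginal of flux n
# is the cavity Gaussian (obtained by deleting factor n, i.e. setting
# D_nn = 0) truncated to the flux's box, so the fixed-point marginals are
# truncated Gaussians.

#' EP algorithm parameters
#'
#' @param beta inverse temperature: precision of the Gaussian likelihood
#'   penalising violations of `S v = b`. The mass-balance residual of the
#'   reported means shrinks as `beta` grows; beyond ~1e11 the updates become
#'   numerically unstable, so 1e10 is the default (drop to 1e9 if a large
#'   model fails to converge).
#' @param tol convergence target on the error `eps`, the largest change of
#'   tilted mean + second moment between iterations (internal units).
#' @param max_iter iteration cap; non-convergence is reported, not raised.
#' @param damp fraction of the old natural parameters retained at each
#'   update, in `[0, 1)`. Parallel EP without damping oscillates on
#'   correlated stoichiometric rows.
#' @param d_min,d_max clamping range for the approximate-prior variances
#'   `d`; a wide range admits both nearly-flat and nearly-pinned factors
#'   without breaking conditioning.
#' @param schedule `"parallel"` (one matrix factorisation per sweep,
#'   Theta(N^3) per iteration, deterministic) or `"sequential"` (one
#'   factorisation per flux, the Theta(N^4) textbook formulation, kept for
#'   cross-checking).
#' @param seed optional integer; when set with the sequential schedule, the
#'   flux update order is freshly permuted each sweep.
#' @return an object of class `ep_params`.
#' @export
ep_params <- function(beta = 1e10, tol = 1e-5, max_iter = 2000L, damp = 0.5,
                      d_min = 1e-50, d_max = 1e50,
                      schedule = c("parallel", "sequential"), seed = NULL) {
  schedule <- match.arg(schedule)
  stopifnot(beta > 0, tol > 0, max_iter >= 1, damp >= 0, damp < 1,
            d_min > 0, d_max > d_min)
  structure(list(beta = beta, tol = tol, max_iter = as.integer(max_iter),
                 damp = damp, d_min = d_min, d_max = d_max,
                 schedule = schedule, seed = seed),
            class = "ep_params")
}

#' Empirical constraint on a flux posterior
#'
#' Pins the posterior of one flux to an empirically measured Gaussian, e.g.
#' a single-cell growth-rate profile fitted by `N(0.92, 0.0324)` in doubling
#' per hour. Used by [run_constrained_ep()].
#'
#' @param flux reaction identifier.
#' @param mean empirical mean, native units.
#' @param variance empirical variance, native units squared; positive.
#' @return an object of class `flux_constraint`.
#' @export
flux_constraint <- function(flux, mean, variance) {
  stopifnot(is.character(flux), length(flux) == 1L, variance > 0)
  structure(list(flux = flux, mean = as.double(mean),
                 variance = as.double(variance)),
            class = "flux_constraint")
}

#' Gaussian approximation of the posterior for given factor parameters
#'
#' Computes the covariance `Sigma = (beta S'S + D)^-1`, `D = diag(1/d)`,
#' and mean `mu = Sigma (beta S'b + D a)` of the full Gaussian
#' approximation. The precision matrix is factorised by Cholesky with
#' escalating diagonal jitter (`1e-12 * trace/N`, x10, three attempts)
#' before singularity is declared: `beta S'S` is rank-deficient by
#' construction and extreme `d` values can break conditioning.
#'
#' @param polytope a [flux_polytope()].
#' @param beta inverse temperature.
#' @param a,d approximate-prior means and (positive) variances, length N.
#' @return list with `Sigma` (N x N, symmetric) and `mu` (length N).
#' @export
gaussian_update <- function(polytope, beta, a, d) {
  S <- polytope$S
  N <- ncol(S)
  stopifnot(length(a) == N, length(d) == N, all(d > 0))
  P <- beta * crossprod(S)
  diag(P) <- diag(P) + 1 / d
  jitter <- 0
  base <- 1e-12 * sum(diag(P)) / N
  for (try in 0:3) {
    R <- tryCatch(chol(P + diag(jitter, N)), error = function(e) NULL)
    if (!is.null(R)) break
    jitter <- if (jitter == 0) base else jitter * 10
  }
  if (is.null(R))
    stop(sprintf(
      "precision matrix numerically singular (rcond ~ %.3g) after jitter escalation",
      1 / kappa(P, exact = FALSE)), call. = FALSE)
  Sigma <- chol2inv(R)
  Sigma <- (Sigma + t(Sigma)) / 2
  h <- beta * as.vector(crossprod(S, polytope$b)) + a / d
  mu <- as.vector(Sigma %*% h)
  # the precision matrix has condition ~ beta * max(d): two steps of
  # iterative refinement recover the mean to near working precision
  for (k in 1:2) {
    resid <- h - beta * as.vector(crossprod(S, S %*% mu)) - mu / d
    mu <- mu + as.vector(Sigma %*% resid)
  }
  list(Sigma = Sigma, mu = mu)
}

#' Cavity marginal of one flux
#'
#' Removes flux `n`'s Gaussian factor from the full approximation: the
#' cavity precision is `1/s_c = 1/Sigma[n,n] - 1/d[n]` and the cavity mean
#' `mu_c = s_c (mu[n]/Sigma[n,n] - a[n]/d[n])`. Multiplying the cavity
#' Gaussian back by factor `(a[n], d[n])` recovers `(mu[n], Sigma[n,n])`
#' exactly. A nonpositive cavity precision (possible when `d[n] <
#' Sigma[n,n]`) is returned as-is; callers apply the skip-and-clamp rule.
#'
#' @param Sigma,mu moments of the full Gaussian approximation.
#' @param a,d approximate-prior parameters.
#' @param n flux index (1-based).
#' @return list with `mu_c` and `s_c` (`s_c <= 0` flags an invalid cavity).
#' @export
cavity <- function(Sigma, mu, a, d, n) {
  s <- Sigma[n, n]
  inv_sc <- 1 / s - 1 / d[n]
  if (inv_sc <= 0) return(list(mu_c = NA_real_, s_c = -Inf))
  s_c <- 1 / inv_sc
  list(mu_c = s_c * (mu[n] / s - a[n] / d[n]), s_c = s_c)
}

# vectorised cavity over all fluxes. A cavity precision that is zero or
# negligible relative to the marginal precision (rel < 1e-10) means the flux
# is informed only by its own factor -- e.g. a flux disconnected from every
# constraint row -- and the cavity is flat: the tilted marginal is then the
# uniform density on the box. Negative values beyond round-off cannot occur
# for a consistent Gaussian factorisation and are lumped into `flat`.
.cavity_all <- function(svec, mu, a, d) {
  inv_sc <- 1 / svec - 1 / d
  rel <- inv_sc * svec          # fraction of marginal precision from the cavity
  flat <- rel < 1e-10
  ok <- !flat
  s_c <- ifelse(ok, 1 / inv_sc, NA_real_)
  mu_c <- ifelse(ok, s_c * (mu / svec - a / d), NA_real_)
  list(mu_c = mu_c, s_c = s_c, ok = ok, flat = flat)
}

#' Convergence error between consecutive tilted moments
#'
#' The maximum over fluxes of `|delta mean| + |delta second moment|` of the
#' tilted marginals, the statistic the EP loop drives below `tol`.
#'
#' @param prev_mean,prev_second,new_mean,new_second numeric vectors of equal
#'   length; `NA` entries (fluxes not yet visited) yield `Inf`.
#' @return a single number.
#' @export
convergence_error <- function(prev_mean, prev_second, new_mean, new_second) {
  stopifnot(length(prev_mean) == length(new_mean),
            length(prev_second) == length(new_second))
  if (length(new_mean) == 0L) return(0)
  if (anyNA(prev_mean) || anyNA(new_mean) ||
      anyNA(prev_second) || anyNA(new_second)) return(Inf)
  max(abs(new_mean - prev_mean) + abs(new_second - prev_second))
}

# fresh EP state at the non-adaptive baseline: uniform-prior moments for
# finite boxes, (0, d_max) for unbounded fluxes
.ep_init <- function(polytope, params) {
  lo <- polytope$lower; hi <- polytope$upper
  finite <- is.finite(lo) & is.finite(hi)
  a <- ifelse(finite, (lo + hi) / 2, 0)
  d <- ifelse(finite, (hi - lo)^2 / 12, params$d_max)
  d <- pmin(pmax(d, params$d_min), params$d_max)
  g <- gaussian_update(polytope, params$beta, a, d)
  list(a = a, d = d, Sigma = g$Sigma, mu = g$mu,
       tilted_mean = rep(NA_real_, length(a)),
       tilted_second = rep(NA_real_, length(a)),
       tilted_var = rep(NA_real_, length(a)),
       iteration = 0L, eps_trace = numeric(0), n_skipped = 0L)
}

# tilted moments for given cavities; constrained fluxes use the empirical
# moments instead of the truncated-Gaussian ones
.tilted_moments <- function(mu_c, s_c, ok, lower, upper, cons_idx, cons_m, cons_v) {
  m <- v <- rep(NA_real_, length(mu_c))
  if (any(ok)) {
    tm <- trunc_moments(mu_c[ok], s_c[ok], lower[ok], upper[ok])
    m[ok] <- tm$mean; v[ok] <- tm$var
  }
  unif <- !ok & is.finite(lower) & is.finite(upper)
  if (any(unif)) {
    m[unif] <- (lower[unif] + upper[unif]) / 2
    v[unif] <- (upper[unif] - lower[unif])^2 / 12
  }
  if (length(cons_idx)) {
    m[cons_idx] <- cons_m
    v[cons_idx] <- cons_v
  }
  list(m = m, v = v)
}

#' One EP sweep over all fluxes
#'
#' For each flux: form the cavity, compute the tilted (truncated-Gaussian)
#' moments, convert the moment-matching condition to new natural parameters
#' `1/d' = 1/v - 1/s_c`, `a'/d' = m/v - mu_c/s_c`, damp them against the old
#' values, clamp `d'` to `[d_min, d_max]`, and refresh `(Sigma, mu)`.
#' With the parallel schedule all cavities are computed from one shared
#' `Sigma`; the sequential schedule refreshes `Sigma` after every single
#' flux. Fluxes whose cavity or proposed precision is nonpositive are
#' skipped this sweep and their `d` pushed toward `d_max` (counted in
#' `n_skipped`).
#'
#' @param polytope a [flux_polytope()].
#' @param params an [ep_params()].
#' @param state EP state as produced by a previous call or internally by
#'   [run_ep()].
#' @param constraints internal: resolved constraint list.
#' @return the updated state.
#' @export
ep_step <- function(polytope, params, state, constraints = NULL) {
  lo <- polytope$lower; hi <- polytope$upper
  N <- length(lo)
  cons_idx <- if (is.null(constraints)) integer(0) else constraints$idx
  cons_m <- if (is.null(constraints)) numeric(0) else constraints$mean
  cons_v <- if (is.null(constraints)) numeric(0) else constraints$var

  apply_update <- function(state, n_set) {
    sv <- diag(state$Sigma)
    cav <- .cavity_all(sv, state$mu, state$a, state$d)
    tm <- .tilted_moments(cav$mu_c, cav$s_c, cav$ok, lo, hi,
                          cons_idx, cons_m, cons_v)
    inv_sc <- ifelse(cav$ok, 1 / cav$s_c, 0)
    mc_over_sc <- ifelse(cav$ok, cav$mu_c / cav$s_c, 0)
    q_prop <- 1 / tm$v - inv_sc
    r_prop <- tm$m / tm$v - mc_over_sc
    valid <- !is.na(q_prop) & q_prop > 0
    upd <- intersect(n_set, which(valid))
    skip <- intersect(n_set, which(!valid))
    if (length(upd)) {
      q_old <- 1 / state$d[upd]
      r_old <- state$a[upd] / state$d[upd]
      q_new <- (1 - params$damp) * q_prop[upd] + params$damp * q_old
      r_new <- (1 - params$damp) * r_prop[upd] + params$damp * r_old
      pos <- q_new > 0
      d_new <- ifelse(pos, pmin(pmax(1 / q_new, params$d_min), params$d_max),
                      pmin(state$d[upd] * 10, params$d_max))
      a_new <- ifelse(pos, r_new / q_new, state$a[upd])
      state$a[upd] <- a_new
      state$d[upd] <- d_new
      state$n_skipped <- state$n_skipped + sum(!pos)
    }
    if (length(skip)) {
      state$d[skip] <- pmin(state$d[skip] * 10, params$d_max)
      state$n_skipped <- state$n_skipped + length(skip)
    }
    keep <- intersect(n_set, which(!is.na(tm$m)))
    state$tilted_mean[keep] <- tm$m[keep]
    state$tilted_second[keep] <- tm$m[keep]^2 + tm$v[keep]
    state$tilted_var[keep] <- tm$v[keep]
    state
  }

  if (params$schedule == "parallel") {
    state <- apply_update(state, seq_len(N))
    g <- gaussian_update(polytope, params$beta, state$a, state$d)
    state$Sigma <- g$Sigma; state$mu <- g$mu
  } else {
    order <- seq_len(N)
    if (!is.null(params$seed)) order <- sample.int(N)
    for (n in order) {
      state <- apply_update(state, n)
      g <- gaussian_update(polytope, params$beta, state$a, state$d)
      state$Sigma <- g$Sigma; state$mu <- g$mu
    }
  }
  state$iteration <- state$iteration + 1L
  state
}

# resolve user constraints (data frame, flux_constraint, or list thereof)
# against the polytope; returns idx/mean/var in *internal* units
.resolve_constraints <- function(polytope, constraints) {
  if (is.null(constraints)) return(NULL)
  if (inherits(constraints, "flux_constraint")) constraints <- list(constraints)
  if (is.data.frame(constraints)) {
    nm <- names(constraints)
    fcol <- intersect(c("flux", "reaction", "reaction_id"), nm)[1]
    if (is.na(fcol) || !all(c("mean", "variance") %in% nm))
      stop("constraints data frame needs columns flux (or reaction), mean, variance",
           call. = FALSE)
    constraints <- purrr::pmap(
      list(constraints[[fcol]], constraints$mean, constraints$variance),
      flux_constraint)
  }
  flux <- vapply(constraints, `[[`, character(1), "flux")
  if (anyDuplicated(flux))
    stop("duplicate constraints on flux: ",
         paste(unique(flux[duplicated(flux)]), collapse = ", "), call. = FALSE)
  idx <- match(flux, polytope$reaction_ids)
  if (anyNA(idx))
    stop("constraint on unknown or pinned flux: ",
         paste(flux[is.na(idx)], collapse = ", "), call. = FALSE)
  m <- vapply(constraints, `[[`, double(1), "mean") / polytope$scale
  v <- vapply(constraints, `[[`, double(1), "variance") / polytope$scale^2
  bad <- m < polytope$lower[idx] | m > polytope$upper[idx]
  if (any(bad))
    stop("constraint mean outside flux bounds for: ",
         paste(flux[bad], collapse = ", "), call. = FALSE)
  if (any(v <= 0)) stop("constraint variance must be positive", call. = FALSE)
  list(idx = idx, mean = m, var = v, flux = flux)
}

# assemble the ep_result object from a final state
.ep_result <- function(polytope, params, state, converged, constraints,
                       method = "ep") {
  scale <- polytope$scale
  lo <- polytope$lower; hi <- polytope$upper
  N <- length(lo)
  sv <- diag(state$Sigma)
  cav <- .cavity_all(sv, state$mu, state$a, state$d)
  # flat cavities (box-only information): report the uniform density on the
  # box via a very wide cavity Gaussian; infinite boxes fall back to the
  # full-Gaussian marginal
  finite_box <- is.finite(lo) & is.finite(hi)
  wide <- 1e8 * (hi - lo)^2
  mu_c <- ifelse(cav$ok, cav$mu_c, ifelse(finite_box, (lo + hi) / 2, state$mu))
  s_c <- ifelse(cav$ok, cav$s_c, ifelse(finite_box, wide, sv))
  tm <- trunc_moments(mu_c, s_c, lo, hi)
  mean_i <- tm$mean; var_i <- tm$var
  cons_flag <- rep(FALSE, N)
  if (!is.null(constraints)) {
    mean_i[constraints$idx] <- constraints$mean
    var_i[constraints$idx] <- constraints$var
    cons_flag[constraints$idx] <- TRUE
  }
  marg <- tibble::tibble(
    reaction = polytope$reaction_ids,
    mean = mean_i * scale,
    var = var_i * scale^2,
    lo = lo * scale,
    hi = hi * scale,
    mu_c = mu_c * scale,
    s_c = s_c * scale^2,
    pinned = FALSE,
    constrained = cons_flag)
  if (length(polytope$fixed)) {
    marg <- dplyr::bind_rows(marg, tibble::tibble(
      reaction = names(polytope$fixed),
      mean = unname(polytope$fixed),
      var = 0, lo = unname(polytope$fixed), hi = unname(polytope$fixed),
      mu_c = unname(polytope$fixed), s_c = 0,
      pinned = TRUE, constrained = FALSE))
  }
  structure(
    list(marginals = marg,
         converged = converged,
         iterations = state$iteration,
         eps_final = if (length(state$eps_trace)) utils::tail(state$eps_trace, 1) else NA_real_,
         eps_trace = state$eps_trace,
         params = params,
         method = method,
         n_skipped = state$n_skipped,
         polytope = polytope,
         diagnostics = list(
           gauss_mean = state$mu, gauss_var = sv,
           tilted_mean = state$tilted_mean, tilted_var = state$tilted_var,
           a = state$a, d = state$d)),
    class = "ep_result")
}

#' Run expectation propagation on a flux polytope
#'
#' Iterates [ep_step()] until the convergence error drops below
#' `params$tol` or `params$max_iter` sweeps have run. At the fixed point the
#' marginal of each free flux is the cavity Gaussian truncated to the
#' flux's box, reported in native units; fluxes pinned by their bounds are
#' reported as point masses.
#'
#' @param x a [flux_polytope()], or a [metabolic_model()] (converted with
#'   [to_polytope()] first).
#' @param params an [ep_params()].
#' @param constraints optional empirical flux constraints; see
#'   [run_constrained_ep()].
#' @param rescale passed to [to_polytope()] when `x` is a model.
#' @return an [ep_result] object; `tidy()` extracts the per-flux marginal
#'   table, `glance()` the run summary. Non-convergence yields a warning and
#'   `converged = FALSE`, never an error.
#' @export
#' @examples
#' fit <- run_ep(make_simplex(3), ep_params(beta = 1e8, damp = 0.5))
#' tidy(fit)
run_ep <- function(x, params = ep_params(), constraints = NULL,
                   rescale = TRUE) {
  polytope <- if (inherits(x, "metabolic_model")) to_polytope(x, rescale) else x
  stopifnot(inherits(polytope, "flux_polytope"))
  if (ncol(polytope$S) == 0L)
    stop("polytope has no free fluxes", call. = FALSE)
  cons <- .resolve_constraints(polytope, constraints)
  state <- .ep_init(polytope, params)
  converged <- FALSE
  run_par <- params
  for (it in seq_len(params$max_iter)) {
    prev_m <- state$tilted_mean; prev_s <- state$tilted_second
    state <- ep_step(polytope, run_par, state, constraints = cons)
    eps <- convergence_error(prev_m, prev_s,
                             state$tilted_mean, state$tilted_second)
    state$eps_trace <- c(state$eps_trace, eps)
    if (eps <= params$tol) { converged <- TRUE; break }
    # oscillation guard: if eps has not halved over the last 20 sweeps,
    # retain more of the old natural parameters (heavier damping)
    if (it %% 20L == 0L && it >= 40L && run_par$damp < 0.95) {
      if (eps > 0.5 * state$eps_trace[it - 20L])
        run_par$damp <- min(0.95, (1 + run_par$damp) / 2)
    }
  }
  if (!converged)
    warning(sprintf("EP did not converge in %d iterations (eps = %.3g > tol = %.3g)",
                    params$max_iter, utils::tail(state$eps_trace, 1), params$tol),
            call. = FALSE)
  .ep_result(polytope, params, state, converged, cons,
             method = if (is.null(cons)) "ep" else "constrained_ep")
}

#' Non-adaptive Gaussian baseline
#'
#' Replaces each box prior once and for all by the Gaussian with the same
#' mean and variance as the uniform density on the box
#' (`a = (lower+upper)/2`, `d = (upper-lower)^2/12`) and performs a single
#' Gaussian update. In this approximation fluxes are unbounded: marginals
#' are reported as untruncated Gaussians and their means may fall outside
#' the box. This is the warm-up approximation EP improves upon.
#'
#' @param x a [flux_polytope()] or [metabolic_model()].
#' @param beta inverse temperature.
#' @param rescale passed to [to_polytope()] when `x` is a model.
#' @return an [ep_result] with `method = "non_adaptive"`.
#' @export
non_adaptive <- function(x, beta = 1e10, rescale = TRUE) {
  polytope <- if (inherits(x, "metabolic_model")) to_polytope(x, rescale) else x
  stopifnot(inherits(polytope, "flux_polytope"))
  lo <- polytope$lower; hi <- polytope$upper
  if (!all(is.finite(lo) & is.finite(hi)))
    stop("non_adaptive requires finite bounds (uniform moments undefined)",
         call. = FALSE)
  a <- (lo + hi) / 2
  d <- (hi - lo)^2 / 12
  g <- gaussian_update(polytope, beta, a, d)
  scale <- polytope$scale
  marg <- tibble::tibble(
    reaction = polytope$reaction_ids,
    mean = g$mu * scale,
    var = diag(g$Sigma) * scale^2,
    lo = lo * scale, hi = hi * scale,
    mu_c = g$mu * scale, s_c = diag(g$Sigma) * scale^2,
    pinned = FALSE, constrained = FALSE)
  if (length(polytope$fixed)) {
    marg <- dplyr::bind_rows(marg, tibble::tibble(
      reaction = names(polytope$fixed), mean = unname(polytope$fixed),
      var = 0, lo = unname(polytope$fixed), hi = unname(polytope$fixed),
      mu_c = unname(polytope$fixed), s_c = 0, pinned = TRUE,
      constrained = FALSE))
  }
  structure(
    list(marginals = marg, converged = TRUE, iterations = 1L,
         eps_final = NA_real_, eps_trace = numeric(0),
         params = ep_params(beta = beta), method = "non_adaptive",
         n_skipped = 0L, polytope = polytope,
         diagnostics = list(gauss_mean = g$mu, gauss_var = diag(g$Sigma),
                            a = a, d = d, Sigma = g$Sigma)),
    class = "ep_result")
}

#' EP with empirically constrained flux posteriors
#'
#' Identical to [run_ep()] except that for each constrained flux the
#' moment-matching step uses the empirical mean and variance in place of
#' the truncated-Gaussian tilted moments, so at convergence the reported
#' posterior of that flux equals the measurement and every other flux
#' adjusts to stay consistent with mass balance.
#'
#' @param x a [flux_polytope()] or [metabolic_model()].
#' @param params an [ep_params()].
#' @param constraints one [flux_constraint()], a list of them, or a data
#'   frame with columns `flux` (or `reaction`), `mean`, `variance` in native
#'   units.
#' @param rescale passed to [to_polytope()] when `x` is a model.
#' @return an [ep_result].
#' @export
#' @examples
#' p <- make_simplex(2)
#' fit <- run_constrained_ep(p, ep_params(beta = 1e8, damp = 0.5),
#'                           flux_constraint("v1", 0.7, 1e-4))
#' tidy(fit)
run_constrained_ep <- function(x, params = ep_params(), constraints,
                               rescale = TRUE) {
  if (is.null(constraints)) stop("constraints must be supplied", call. = FALSE)
  run_ep(x, params, constraints = constraints, rescale = rescale)
}

#' @export
print.ep_result <- function(x, ...) {
  cat(sprintf("<ep_result: %s> %d fluxes; %s after %d iteration(s)",
              x$method, nrow(x$marginals),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  if (!is.na(x$eps_final)) cat(sprintf(" (eps = %.3g)", x$eps_final))
  cat("\n")
  print(utils::head(x$marginals, 10))
  if (nrow(x$marginals) > 10) cat("...\n")
  invisible(x)
}
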