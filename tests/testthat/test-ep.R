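# The EP machinery: Gaussian update algebra, cavity identities, tilted
# moments against a direct leave-one-out inversion, the convergence
# statistic, full runs on polytopes with known marginals, the non-adaptive
# baseline, and the constrained variant.

test_that("gaussian_update reproduces hand-computed algebra and limits", {
  p <- flux_polytope(S = matrix(c(1, 1), 1, 2), b = 1,
                     lower = c(-10, -10), upper = c(10, 10))
  g <- gaussian_update(p, beta = 1, a = c(0, 0), d = c(1, 1))
  expect_equal(g$Sigma, matrix(c(2, -1, -1, 2) / 3, 2, 2), tolerance = 1e-12)
  expect_equal(g$mu, c(1, 1) / 3, tolerance = 1e-12)
  expect_equal(g$Sigma, t(g$Sigma), tolerance = 1e-12)

  # b = 0, a = 0 has odd symmetry: mu = 0
  p0 <- make_random(3, 6, density = 0.5, seed = 11)
  p0 <- flux_polytope(p0$S, rep(0, 3), p0$lower, p0$upper)
  g0 <- gaussian_update(p0, beta = 7, a = rep(0, 6), d = runif(6, 0.5, 2))
  expect_equal(g0$mu, rep(0, 6), tolerance = 1e-12)

  # beta -> 0: prior only
  a <- c(0.3, -0.2); d <- c(0.5, 2)
  g1 <- gaussian_update(p, beta = 1e-14, a = a, d = d)
  expect_equal(diag(g1$Sigma), d, tolerance = 1e-10)
  expect_equal(g1$mu, a, tolerance = 1e-10)
})

test_that("cavity removes a factor exactly (recombination identity)", {
  set.seed(42)
  for (rep in 1:5) {
    p <- make_random(3, 7, density = 0.5, seed = rep)
    a <- runif(7, -0.5, 0.5); d <- runif(7, 0.1, 5)
    g <- gaussian_update(p, beta = 1e4, a = a, d = d)
    connected <- which(colSums(p$S != 0) > 0)
    for (n in connected[c(1, length(connected))]) {
      cv <- cavity(g$Sigma, g$mu, a, d, n)
      # recombine: precision and precision-weighted means add
      prec <- 1 / cv$s_c + 1 / d[n]
      mean_rec <- (cv$mu_c / cv$s_c + a[n] / d[n]) / prec
      expect_lt(abs(1 / prec - g$Sigma[n, n]) / g$Sigma[n, n], 1e-10)
      expect_lt(abs(mean_rec - g$mu[n]) / max(abs(g$mu[n]), sqrt(g$Sigma[n, n])),
                1e-10)
    }
    # an effectively flat factor leaves the marginal untouched
    d_flat <- d; d_flat[2] <- 1e50
    gf <- gaussian_update(p, beta = 1e4, a = a, d = d_flat)
    cvf <- cavity(gf$Sigma, gf$mu, a, d_flat, 2)
    expect_equal(cvf$s_c, gf$Sigma[2, 2], tolerance = 1e-8)
    expect_equal(cvf$mu_c, gf$mu[2], tolerance = 1e-8)
  }
})

test_that("cavity equals the direct D_nn = 0 inversion", {
  # two-flux constraint v1 + v2 = 1 at moderate beta
  p <- flux_polytope(S = matrix(c(1, 1), 1, 2), b = 1,
                     lower = c(0, 0), upper = c(1, 1))
  a <- c(0.4, 0.6); d <- c(0.7, 1.3)
  g <- gaussian_update(p, beta = 50, a = a, d = d)
  for (n in 1:2) {
    cv <- cavity(g$Sigma, g$mu, a, d, n)
    oracle <- tilted_direct(p, 50, a, d, n)
    expect_equal(cv$mu_c, oracle$mu_c, tolerance = 1e-9)
    expect_equal(cv$s_c, oracle$s_c, tolerance = 1e-9)
  }
  # and on a larger random instance
  pr <- make_random(4, 9, density = 0.4, seed = 5)
  ar <- runif(9, -0.3, 0.3); dr <- runif(9, 0.2, 3)
  gr <- gaussian_update(pr, beta = 100, a = ar, d = dr)
  for (n in c(2, 9)) {
    cv <- cavity(gr$Sigma, gr$mu, ar, dr, n)
    oracle <- tilted_direct(pr, 100, ar, dr, n)
    expect_equal(cv$mu_c, oracle$mu_c, tolerance = 1e-8)
    expect_equal(cv$s_c, oracle$s_c, tolerance = 1e-8)
  }
})

test_that("convergence_error implements max over fluxes of summed changes", {
  expect_equal(convergence_error(c(1, 2), c(3, 4), c(1, 2), c(3, 4)), 0)
  expect_equal(convergence_error(0, 0, 0.001, 0.002), 0.003)
  expect_equal(convergence_error(c(0, 0), c(0, 0), c(0.001, 0.003),
                                 c(0.003, 0.004)), 0.007)
  expect_equal(convergence_error(NA, 1, 1, 1), Inf)
  expect_error(convergence_error(c(1, 2), 1, 1, 1), "length")
})

test_that("a moment-matched state is a fixed point of ep_step", {
  p <- make_simplex(3)
  params <- ep_params()
  fit <- run_ep(p, params)
  # rebuild the final state and apply one more sweep: tilted moments move
  # by less than the convergence tolerance
  st <- list(a = fit$diagnostics$a, d = fit$diagnostics$d,
             Sigma = NULL, mu = NULL,
             tilted_mean = fit$diagnostics$tilted_mean,
             tilted_second = fit$diagnostics$tilted_mean^2 +
               fit$diagnostics$tilted_var,
             tilted_var = fit$diagnostics$tilted_var,
             iteration = 0L, eps_trace = numeric(0), n_skipped = 0L)
  g <- gaussian_update(p, params$beta, st$a, st$d)
  st$Sigma <- g$Sigma; st$mu <- g$mu
  st2 <- ep_step(p, params, st)
  expect_lt(convergence_error(st$tilted_mean, st$tilted_second,
                              st2$tilted_mean, st2$tilted_second),
            2 * params$tol)
})

test_that("one-flux problem is symmetric after a single step", {
  p <- flux_polytope(S = matrix(1, 1, 1), b = 0, lower = -1, upper = 1)
  params <- ep_params(beta = 1e10)
  st <- fluxep:::.ep_init(p, params)
  st <- ep_step(p, params, st)
  expect_equal(st$tilted_mean, 0, tolerance = 1e-8)
})

test_that("EP recovers the exact simplex marginals", {
  for (N in c(2, 3, 5, 10)) {
    fit <- run_ep(make_simplex(N), ep_params())
    ex <- simplex_exact_marginal(N)
    expect_true(fit$converged)
    expect_true(all(abs(tidy(fit)$mean - ex$mean) < 1e-3),
                label = sprintf("simplex N=%d means", N))
    if (N > 2)
      expect_true(all(abs(tidy(fit)$var / ex$var - 1) < 0.15),
                  label = sprintf("simplex N=%d variances", N))
  }
})

test_that("the two-flux segment shows the known EP variance bias", {
  # v2 = 1 - v1 makes the exact marginal uniform; the EP fixed point
  # self-consistently approximates the partner's box by a Gaussian with
  # d such that the tilted variance equals d/2, giving ~0.064 instead of
  # 1/12 -- a genuine, reproducible limitation of the Gaussian factor family
  fit <- run_ep(make_simplex(2), ep_params(tol = 1e-10, max_iter = 5000))
  ratio <- tidy(fit)$var / simplex_exact_marginal(2)$var
  expect_true(all(ratio > 0.70 & ratio < 0.85))
})

test_that("reported means respect bounds; tilted marginals match HR on the diamond", {
  p <- to_polytope(make_diamond())
  fit <- run_ep(p, ep_params())
  tt <- tidy(fit)
  expect_true(all(tt$mean > tt$lo & tt$mean < tt$hi))
  s <- hit_and_run(p, T = 1e6, n_samples = 1e4, seed = 77)
  cmp <- compare_moments(fit, s)
  expect_gt(cmp$r_means, 0.99)
  # the diamond's flux variances are nearly uniform across reactions, so a
  # Pearson coefficient on them is noise-dominated; check relative agreement
  expect_true(all(cmp$table$var_ep / cmp$table$var_ref > 0.5 &
                  cmp$table$var_ep / cmp$table$var_ref < 1.5))
})

test_that("mass-balance residual decreases as beta grows", {
  # run each ladder step well below its convergence floor so the residual
  # reflects beta, not the stopping rule
  p <- to_polytope(make_diamond())
  res <- vapply(c(1e4, 1e6, 1e8, 1e10), function(beta) {
    fit <- run_ep(p, ep_params(beta = beta, tol = 1e-9, max_iter = 10000))
    means <- tidy(fit)$mean[match(p$reaction_ids, tidy(fit)$reaction)]
    max(abs(p$S %*% (means / p$scale) - p$b))
  }, double(1))
  expect_true(all(diff(res) <= 0))
  expect_lt(res[4], 1e-8)
})

test_that("at convergence the Gaussian moments match the tilted moments", {
  for (p in list(make_simplex(5), to_polytope(make_diamond()),
                 make_random(10, 20, 0.3, seed = 2))) {
    fit <- run_ep(p, ep_params())
    expect_true(fit$converged)
    d <- fit$diagnostics
    gap <- abs(d$gauss_mean - d$tilted_mean) +
      abs((d$gauss_var + d$gauss_mean^2) -
            (d$tilted_var + d$tilted_mean^2))
    expect_lt(max(gap), 10 * fit$params$tol)
  }
})

test_that("parallel and sequential schedules agree; parallel is deterministic", {
  p <- make_simplex(3)
  fp <- run_ep(p, ep_params(schedule = "parallel"))
  fs <- run_ep(p, ep_params(schedule = "sequential"))
  expect_equal(tidy(fp)$mean, tidy(fs)$mean, tolerance = 100 * 1e-5)
  expect_equal(tidy(fp)$var, tidy(fs)$var, tolerance = 100 * 1e-5)

  pd <- to_polytope(make_diamond())
  f1 <- run_ep(pd, ep_params())
  f2 <- run_ep(pd, ep_params())
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$eps_trace, f2$eps_trace)
})

test_that("non-adaptive baseline equals uniform-moment Gaussian conditioning", {
  # [0, 1] bounds produce the uniform moments exactly
  p01 <- flux_polytope(S = matrix(c(1, 1), 1, 2), b = 1,
                       lower = c(0, 0), upper = c(1, 1))
  na <- non_adaptive(p01, beta = 1e10)
  expect_equal(na$diagnostics$a, c(0.5, 0.5))
  expect_equal(na$diagnostics$d, c(1 / 12, 1 / 12))
  expect_equal(tidy(na)$mean, c(0.5, 0.5), tolerance = 1e-6)

  # random fixtures against the closed-form conditioning oracle
  for (sd in 1:3) {
    p <- make_random(3, 6, density = 0.5, seed = sd)
    na <- non_adaptive(p, beta = 1e10)
    or <- gaussian_conditioning((p$lower + p$upper) / 2,
                                (p$upper - p$lower)^2 / 12, p$S, p$b)
    expect_lt(max(abs(tidy(na)$mean - or$mean)), 1e-6)
    expect_lt(max(abs(tidy(na)$var - diag(or$cov))), 1e-6)
  }

  # infinite bounds are rejected
  pinf <- flux_polytope(matrix(1, 1, 2), 1, c(0, -Inf), c(1, Inf))
  expect_error(non_adaptive(pinf), "finite")
})

test_that("constrained EP pins the flux and propagates through conservation", {
  p <- make_simplex(2)
  fit <- run_constrained_ep(p, ep_params(),
                            flux_constraint("v1", 0.7, 1e-4))
  tt <- tidy(fit)
  expect_equal(tt$mean[tt$reaction == "v1"], 0.7, tolerance = 1e-6)
  expect_equal(tt$var[tt$reaction == "v1"], 1e-4, tolerance = 1e-8)
  # v2 = 1 - v1 exactly
  expect_equal(tt$mean[tt$reaction == "v2"], 0.3, tolerance = 1e-4)
  expect_equal(tt$var[tt$reaction == "v2"], 1e-4, tolerance = 0.1)
})

test_that("constraining a flux to its own EP posterior changes nothing", {
  p <- to_polytope(make_diamond())
  pars <- ep_params(tol = 1e-9, max_iter = 10000)
  free_fit <- run_ep(p, pars)
  tt <- tidy(free_fit)
  i <- which(tt$reaction == "R_out")
  fit2 <- run_constrained_ep(p, pars,
                             flux_constraint("R_out", tt$mean[i], tt$var[i]))
  tt2 <- tidy(fit2)
  expect_equal(tt2$mean, tt$mean, tolerance = 1e-6)
  expect_equal(tt2$var, tt$var, tolerance = 1e-5)
})

test_that("constrained EP shifts the diamond consistently with conditioned HR", {
  p <- to_polytope(make_diamond())
  # constrain the export to a low band; upstream fluxes must follow
  fit <- run_constrained_ep(p, ep_params(), flux_constraint("R_out", 3, 0.04))
  tt <- tidy(fit)
  s <- hit_and_run(p, T = 1e6, n_samples = 2e4, seed = 5)
  keep <- abs(s$points[, "R_out"] - 3) < 2 * sqrt(0.04)
  expect_gt(sum(keep), 200)
  hr_mean <- colMeans(s$points[keep, , drop = FALSE])
  for (rx in c("R_in", "R_ad")) {
    expect_equal(tt$mean[tt$reaction == rx], unname(hr_mean[rx]),
                 tolerance = 0.15)
  }
})

test_that("constraint validation catches bad input", {
  p <- make_simplex(2)
  expect_error(run_constrained_ep(p, ep_params(),
                                  flux_constraint("nope", 0.5, 1e-4)),
               "unknown")
  expect_error(run_constrained_ep(p, ep_params(),
                                  flux_constraint("v1", 7, 1e-4)),
               "outside")
  expect_error(flux_constraint("v1", 0.5, -1), "variance")
  df <- data.frame(flux = c("v1", "v1"), mean = c(0.4, 0.5),
                   variance = c(1e-4, 1e-4))
  expect_error(run_constrained_ep(p, ep_params(), df), "duplicate")
})

test_that("non-convergence warns and returns partial results", {
  p <- make_random(10, 20, 0.3, seed = 14)
  expect_warning(fit <- run_ep(p, ep_params(max_iter = 2)), "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$iterations, 2L)
  expect_s3_class(tidy(fit), "tbl_df")
})
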