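# Deterministic toy networks and random polytopes. Every test and the whole
# pipeline can run on these with no external model downloads. All generators
# are reproducible: randomness is confined to make_random() and driven by an
# explicit seed that does not disturb the caller's RNG stream.

#' Standard simplex polytope
#'
#' The single constraint `sum(v) = 1` with bounds `[0, 1]^N`. The uniform
#' distribution on this polytope has exactly Beta(1, N-1) marginals, making
#' it the canonical closed-form check for marginal estimators.
#'
#' @param N number of fluxes, at least 2.
#' @return a [flux_polytope()] carrying the barycentre as interior point.
#' @export
#' @examples
#' make_simplex(3)
make_simplex <- function(N) {
  stopifnot(N >= 2)
  flux_polytope(S = matrix(1, 1, N), b = 1,
                lower = rep(0, N), upper = rep(1, N),
                x0 = rep(1 / N, N))
}

#' Diamond toy network
#'
#' Four metabolites and seven reactions: one intake into A, two parallel
#' internal branches A->B->D and A->C->D, a direct shortcut A->D, and one
#' export of D. All bounds are `[0, 10]`. Every metabolite has at least one
#' producer and one consumer, so dead-end pruning leaves the network
#' unchanged; closing the export to `[0, 0]` cascades the whole network away.
#'
#' @return a [metabolic_model()].
#' @export
#' @examples
#' make_diamond()
make_diamond <- function() {
  mets <- c("A", "B", "C", "D")
  rxns <- c("R_in", "R_ab", "R_ac", "R_bd", "R_cd", "R_ad", "R_out")
  S <- matrix(0, 4, 7, dimnames = list(mets, rxns))
  S["A", "R_in"] <- 1
  S["A", "R_ab"] <- -1; S["B", "R_ab"] <- 1
  S["A", "R_ac"] <- -1; S["C", "R_ac"] <- 1
  S["B", "R_bd"] <- -1; S["D", "R_bd"] <- 1
  S["C", "R_cd"] <- -1; S["D", "R_cd"] <- 1
  S["A", "R_ad"] <- -1; S["D", "R_ad"] <- 1
  S["D", "R_out"] <- -1
  metabolic_model(mets, rxns, S, b = rep(0, 4),
                  lower = rep(0, 7), upper = rep(10, 7))
}

#' Linear chain network with a terminal dead end
#'
#' An intake into the first metabolite followed by a chain of conversions;
#' the last metabolite has no consumer, so [prune_dead_ends()] removes the
#' final reaction and then, by cascade, the entire chain.
#'
#' @param n_mets chain length (number of metabolites), at least 2.
#' @return a [metabolic_model()].
#' @export
make_chain <- function(n_mets = 3) {
  stopifnot(n_mets >= 2)
  mets <- paste0("M", seq_len(n_mets))
  rxns <- c("R_in", paste0("R", seq_len(n_mets - 1)))
  S <- matrix(0, n_mets, n_mets, dimnames = list(mets, rxns))
  S[1, 1] <- 1
  for (k in seq_len(n_mets - 1)) {
    S[k, k + 1] <- -1
    S[k + 1, k + 1] <- 1
  }
  metabolic_model(mets, rxns, S, b = rep(0, n_mets),
                  lower = rep(0, n_mets), upper = rep(10, n_mets))
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random sparse feasible polytope
#'
#' Generates a sparse integer stoichiometry with entries in
#' `{-2, -1, 1, 2}`, bounds `[-bound_width, bound_width]^N`, and a
#' right-hand side `b = S v0` for a random interior point `v0`, so the
#' polytope is nonempty by construction and carries its own feasibility
#' certificate. With `correlated_rows = TRUE`, extra rows duplicating the
#' support of existing ones are appended (coefficients re-drawn), emulating
#' the strongly row-correlated stoichiometries of genome-scale
#' reconstructions that defeat tree-based message passing.
#'
#' @param M,N numbers of constraints and fluxes, `M < N`.
#' @param density fraction of nonzero entries per row, in (0, 1].
#' @param seed integer seed; identical seeds give identical polytopes.
#' @param bound_width half-width of the flux box.
#' @param correlated_rows append duplicated-support rows (the last
#'   `floor(M/3)` rows re-use the supports of the first rows).
#' @return a [flux_polytope()] with the certificate in `$x0`.
#' @export
#' @examples
#' p <- make_random(4, 8, density = 0.5, seed = 1)
#' is_feasible(p, p$x0)
make_random <- function(M, N, density = 0.3, seed = 1, bound_width = 1,
                        correlated_rows = FALSE) {
  stopifnot(M < N, density > 0, density <= 1, bound_width > 0)
  .with_seed(seed, {
    n_base <- if (correlated_rows) M - max(1L, M %/% 3L) else M
    n_base <- max(1L, n_base)
    k <- max(2L, round(density * N))
    draw_row <- function(support) {
      row <- numeric(N)
      row[support] <- sample(c(-2, -1, 1, 2), length(support), replace = TRUE)
      row
    }
    # redraw until S has full row rank so every constraint is informative
    # (and the Gaussian-conditioning oracle is well defined on the fixture)
    for (attempt in 1:100) {
      supports <- replicate(n_base, sort(sample.int(N, k)), simplify = FALSE)
      rows <- lapply(supports, draw_row)
      if (correlated_rows) {
        extra <- M - n_base
        for (e in seq_len(extra)) rows <- c(rows, list(draw_row(supports[[((e - 1L) %% n_base) + 1L]])))
      }
      S <- do.call(rbind, rows)[seq_len(M), , drop = FALSE]
      if (qr(S)$rank == M) break
    }
    x0 <- stats::runif(N, -0.5, 0.5) * bound_width
    b <- as.vector(S %*% x0)
    flux_polytope(S, b, lower = rep(-bound_width, N),
                  upper = rep(bound_width, N), x0 = x0)
  })
}
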