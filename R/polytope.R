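# The steady-state flux polytope {v : S v = b, lower <= v <= upper}, after
# preprocessing. This is the mathematical object the EP machinery consumes.
# Internally the problem may be rescaled so that bounds and intakes lie in
# [-1, 1]; `scale` maps internal units back to the model's native units
# (native = scale * internal).

#' Construct a flux polytope
#'
#' Low-level constructor for the constraint set `S v = b`,
#' `lower <= v <= upper`. Most users will call [to_polytope()] on a
#' [metabolic_model()] instead.
#'
#' @param S numeric M x N constraint matrix.
#' @param b numeric length-M right-hand side.
#' @param lower,upper numeric length-N box bounds, `lower <= upper`.
#' @param scale positive scalar mapping internal to native units
#'   (native = scale * internal); 1 for an unscaled polytope.
#' @param fixed named numeric vector of reactions removed as variables
#'   because their flux is pinned, in native units.
#' @param reaction_ids,metabolite_ids identifiers for the free variables and
#'   constraint rows; generated when missing.
#' @param x0 optional interior point certificate (internal units), used as
#'   the starting state by [hit_and_run()].
#' @return an object of class `flux_polytope`.
#' @export
flux_polytope <- function(S, b, lower, upper, scale = 1,
                          fixed = stats::setNames(numeric(0), character(0)),
                          reaction_ids = NULL, metabolite_ids = NULL,
                          x0 = NULL) {
  S <- as.matrix(S); storage.mode(S) <- "double"
  M <- nrow(S); N <- ncol(S)
  b <- as.double(b); lower <- as.double(lower); upper <- as.double(upper)
  stopifnot(length(b) == M, length(lower) == N, length(upper) == N)
  if (any(lower > upper)) stop("lower > upper", call. = FALSE)
  if (!(is.numeric(scale) && length(scale) == 1L && scale > 0))
    stop("scale must be a positive scalar", call. = FALSE)
  if (is.null(reaction_ids)) reaction_ids <- sprintf("v%d", seq_len(N))
  if (is.null(metabolite_ids)) metabolite_ids <- sprintf("m%d", seq_len(M))
  structure(
    list(S = S, b = b, lower = lower, upper = upper, scale = scale,
         fixed = fixed, reaction_ids = as.character(reaction_ids),
         metabolite_ids = as.character(metabolite_ids), x0 = x0),
    class = "flux_polytope")
}

#' @export
print.flux_polytope <- function(x, ...) {
  cat(sprintf("<flux_polytope> %d constraints x %d free fluxes (scale = %g, %d pinned)\n",
              nrow(x$S), ncol(x$S), x$scale, length(x$fixed)))
  invisible(x)
}

#' Convert a metabolic model to its flux polytope
#'
#' Reactions whose bounds pin them to a single value (`lower == upper`) are
#' removed as variables: their contribution `S[, n] * value` is folded into
#' `b` and recorded in `fixed`. Optionally the right-hand side and bounds
#' are rescaled by `scale = max(|lower|, |upper|, |b|)` over finite entries,
#' so all internal quantities lie in `[-1, 1]`; this keeps the EP
#' convergence tolerance scale-free.
#'
#' @param model a `metabolic_model`, already pruned if desired.
#' @param rescale logical; apply the scaling described above.
#' @return a [flux_polytope()].
#' @export
to_polytope <- function(model, rescale = TRUE) {
  stopifnot(inherits(model, "metabolic_model"))
  pinned <- model$lower == model$upper
  b <- model$b
  if (any(pinned)) {
    vals <- model$lower[pinned]
    b <- b - as.vector(model$S[, pinned, drop = FALSE] %*% vals)
    fixed <- stats::setNames(vals, model$reaction_ids[pinned])
  } else {
    fixed <- stats::setNames(numeric(0), character(0))
  }
  S <- model$S[, !pinned, drop = FALSE]
  lower <- model$lower[!pinned]; upper <- model$upper[!pinned]
  scale <- 1
  if (rescale) {
    cand <- abs(c(lower, upper, b))
    cand <- cand[is.finite(cand)]
    scale <- if (length(cand)) max(cand) else 0
    if (scale == 0)
      stop("cannot rescale: all bounds and intakes are zero or infinite",
           call. = FALSE)
    b <- b / scale; lower <- lower / scale; upper <- upper / scale
  }
  flux_polytope(S, b, lower, upper, scale = scale, fixed = fixed,
                reaction_ids = model$reaction_ids[!pinned],
                metabolite_ids = model$metabolite_ids)
}

#' Check feasibility of flux vectors against a polytope
#'
#' @param polytope a `flux_polytope`.
#' @param v numeric vector (length N) or matrix (rows are points), in
#'   internal units.
#' @param tol_eq,tol_box tolerances on `S v = b` and the box bounds.
#' @return logical vector, one entry per point.
#' @export
is_feasible <- function(polytope, v, tol_eq = 1e-8, tol_box = 1e-10) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  res <- abs(v %*% t(polytope$S) - rep(polytope$b, each = nrow(v)))
  eq_ok <- if (ncol(polytope$S) == 0L || nrow(polytope$S) == 0L)
    rep(TRUE, nrow(v)) else apply(res, 1, max) <= tol_eq
  box_ok <- apply(v, 1, function(row)
    all(row >= polytope$lower - tol_box & row <= polytope$upper + tol_box))
  eq_ok & box_ok
}
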