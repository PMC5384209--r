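# Broom-style accessors and plots for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-flux marginal table of an EP fit
#'
#' @param x an [ep_result].
#' @param ... unused.
#' @return a tibble with one row per flux: `reaction`, posterior `mean` and
#'   `var`, bounds `lo`/`hi`, the untruncated cavity parameters `mu_c` and
#'   `s_c`, and the `pinned`/`constrained` flags. All in native units.
#' @method tidy ep_result
#' @export
tidy.ep_result <- function(x, ...) x$marginals

#' One-row summary of an EP fit
#'
#' @param x an [ep_result].
#' @param ... unused.
#' @return a tibble with the run outcome and resolved parameters.
#' @method glance ep_result
#' @export
glance.ep_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    converged = x$converged,
    iterations = x$iterations,
    eps_final = x$eps_final,
    n_fluxes = nrow(x$marginals),
    n_skipped = x$n_skipped,
    beta = x$params$beta,
    tol = x$params$tol,
    damp = x$params$damp,
    schedule = x$params$schedule)
}

# density of one reported marginal on a grid (native units)
.marginal_density <- function(row, n_grid = 200) {
  if (row$pinned) return(NULL)
  sd_c <- sqrt(row$s_c)
  lo <- max(row$lo, row$mu_c - 5 * sd_c)
  hi <- min(row$hi, row$mu_c + 5 * sd_c)
  if (!is.finite(lo)) lo <- row$mean - 5 * sqrt(row$var)
  if (!is.finite(hi)) hi <- row$mean + 5 * sqrt(row$var)
  v <- seq(lo, hi, length.out = n_grid)
  if (row$constrained) {
    dens <- stats::dnorm(v, row$mean, sqrt(row$var))
  } else {
    logZ <- trunc_moments(row$mu_c, row$s_c, row$lo, row$hi)$logZ
    dens <- exp(stats::dnorm(v, row$mu_c, sd_c, log = TRUE) - logZ)
  }
  tibble::tibble(reaction = row$reaction, flux = v, density = dens)
}

#' Plot the fitted flux marginals
#'
#' Draws each free flux's posterior density (a truncated Gaussian, or the
#' pinned empirical Gaussian for constrained fluxes), one facet per
#' reaction.
#'
#' @param object an [ep_result].
#' @param reactions optional character vector restricting the plot.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ep_result
#' @export
autoplot.ep_result <- function(object, reactions = NULL, ...) {
  marg <- dplyr::filter(object$marginals, !.data$pinned)
  if (!is.null(reactions))
    marg <- dplyr::filter(marg, .data$reaction %in% reactions)
  dens <- purrr::map_dfr(seq_len(nrow(marg)),
                         function(i) .marginal_density(marg[i, ]))
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$flux, y = .data$density)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_wrap(~reaction, scales = "free") +
    ggplot2::labs(x = "flux (native units)", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Scatter plot of EP versus sampler moments
#'
#' The fixture-scale analogue of the standard EP-versus-hit-and-run
#' validation figure: means and variances of the two estimates against
#' each other, with the identity line.
#'
#' @param object an `ep_comparison` from [compare_moments()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ep_comparison
#' @export
autoplot.ep_comparison <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object$table, .data$reaction, what = "mean",
                     ep = .data$mean_ep, ref = .data$mean_ref),
    dplyr::transmute(object$table, .data$reaction, what = "variance",
                     ep = .data$var_ep, ref = .data$var_ref))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ref, y = .data$ep)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~what, scales = "free") +
    ggplot2::labs(x = "sampler estimate", y = "EP estimate") +
    ggplot2::theme_minimal()
}

#' Write EP marginals and the run report to disk
#'
#' The marginal table goes to `<stem>_marginals.tsv` (columns reaction,
#' mean, variance, lo, hi, mu_c, s_c, pinned flag) and a machine-readable
#' run report with the fully resolved configuration to `<stem>_report.json`.
#'
#' @param ep an [ep_result].
#' @param stem output path stem.
#' @return invisibly, the two file paths.
#' @export
write_ep_result <- function(ep, stem) {
  stopifnot(inherits(ep, "ep_result"))
  tsv <- paste0(stem, "_marginals.tsv")
  rep_path <- paste0(stem, "_report.json")
  tab <- dplyr::rename(ep$marginals, reaction_id = "reaction",
                       variance = "var")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    method = ep$method,
    params = ep$params[c("beta", "tol", "max_iter", "damp", "d_min", "d_max",
                         "schedule")],
    converged = ep$converged,
    iterations = ep$iterations,
    eps_final = ep$eps_final,
    eps_trace = ep$eps_trace,
    n_skipped = ep$n_skipped,
    scale = ep$polytope$scale)
  jsonlite::write_json(report, rep_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tsv, rep_path))
}

#' @importFrom rlang .data
NULL
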