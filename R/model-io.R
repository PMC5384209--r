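# Metabolic model containers and input/output.
#
# A `metabolic_model` holds the stoichiometric matrix S (M metabolites x N
# reactions), the intake vector b, and per-reaction flux bounds in the model's
# native units (typically mmol/gDW/h). Three on-disk formats are supported:
# a bespoke sparse JSON dialect, a 3-column TSV with sidecar files for bounds
# and intakes, and SBML Level 3 (read-only, core + fbc bounds).

#' Construct and validate a metabolic model
#'
#' @param metabolite_ids character vector of unique metabolite identifiers
#'   (length M).
#' @param reaction_ids character vector of unique reaction identifiers
#'   (length N).
#' @param S numeric M x N matrix of stoichiometric coefficients; positive
#'   entries produce the metabolite, negative entries consume it.
#' @param b numeric length-M vector of fixed intakes/uptakes; defaults to the
#'   zero vector (pure mass balance).
#' @param lower,upper numeric length-N flux bounds; infinities allowed,
#'   `lower <= upper` elementwise.
#' @return an object of class `metabolic_model`.
#' @export
#' @examples
#' m <- metabolic_model(c("A"), c("in", "out"),
#'                      matrix(c(1, -1), 1, 2), b = 0,
#'                      lower = c(0, 0), upper = c(10, 10))
metabolic_model <- function(metabolite_ids, reaction_ids, S,
                            b = rep(0, length(metabolite_ids)),
                            lower, upper) {
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  S <- as.matrix(S)
  if (length(metabolite_ids) == 0L) S <- matrix(0, 0, length(reaction_ids))
  storage.mode(S) <- "double"
  M <- length(metabolite_ids); N <- length(reaction_ids)
  if (!identical(dim(S), c(M, N)))
    stop(sprintf("S has dimensions %d x %d; expected %d x %d",
                 nrow(S), ncol(S), M, N), call. = FALSE)
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite identifiers: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction identifiers: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "),
         call. = FALSE)
  b <- as.double(b); lower <- as.double(lower); upper <- as.double(upper)
  if (length(b) != M) stop("b must have length M = ", M, call. = FALSE)
  if (length(lower) != N || length(upper) != N)
    stop("lower and upper must have length N = ", N, call. = FALSE)
  if (any(is.na(S)) || any(is.na(b)) || any(is.na(lower)) || any(is.na(upper)))
    stop("NA values are not allowed", call. = FALSE)
  bad <- which(lower > upper)
  if (length(bad))
    stop("lower > upper for reaction(s): ",
         paste(reaction_ids[bad], collapse = ", "), call. = FALSE)
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  structure(
    list(metabolite_ids = metabolite_ids, reaction_ids = reaction_ids,
         S = S, b = b, lower = lower, upper = upper),
    class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites x %d reactions, %d nonzeros\n",
              length(x$metabolite_ids), length(x$reaction_ids), sum(x$S != 0)))
  nrev <- sum(x$lower < 0 & x$upper > 0)
  cat(sprintf("  reversible: %d; nonzero intakes b: %d\n", nrev, sum(x$b != 0)))
  invisible(x)
}

#' Summarise a metabolic model as a tibble of reactions
#'
#' One row per reaction with its bounds, reversibility and connectivity.
#'
#' @param x a `metabolic_model`.
#' @param ... unused.
#' @return a tibble with columns `reaction`, `lower`, `upper`, `reversible`,
#'   `n_metabolites`.
#' @method tidy metabolic_model
#' @export
tidy.metabolic_model <- function(x, ...) {
  tibble::tibble(
    reaction = x$reaction_ids,
    lower = x$lower,
    upper = x$upper,
    reversible = x$lower < 0 & x$upper > 0,
    n_metabolites = colSums(x$S != 0)
  )
}

.num_out <- function(x) {
  # infinities serialised as the literal strings "-inf"/"inf"
  ifelse(is.finite(x), as.list(x),
         ifelse(x > 0, list("inf"), list("-inf")))
}

.num_in <- function(x) {
  vapply(x, function(v) {
    if (is.character(v)) {
      switch(tolower(v), "inf" = Inf, "+inf" = Inf, "-inf" = -Inf,
             suppressWarnings(as.double(v)))
    } else as.double(v)
  }, double(1))
}

#' Write a metabolic model to disk
#'
#' Supported formats: `json` (a sparse triple-list dialect: top-level keys
#' `metabolites`, `reactions`, `S` as 0-based `[metabolite, reaction, coeff]`
#' triples, `b`, `lower`, `upper`) and `tsv` (a 3-column
#' `metabolite<TAB>reaction<TAB>coefficient` table plus a `<path>.bounds`
#' sidecar with per-reaction bounds and, when any intake is nonzero, a
#' `<path>.b` sidecar). Infinite bounds are serialised as the strings
#' `"-inf"`/`"inf"`. `read_model(write_model(m))` reproduces `m` exactly.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`; guessed from the file extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "tsv")) {
  stopifnot(inherits(model, "metabolic_model"))
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("json", "tsv")) ext else "json"
  }
  format <- match.arg(format)
  nz <- which(model$S != 0, arr.ind = TRUE)
  if (format == "json") {
    triples <- lapply(seq_len(nrow(nz)), function(k) {
      list(nz[k, 1] - 1L, nz[k, 2] - 1L, model$S[nz[k, 1], nz[k, 2]])
    })
    obj <- list(metabolites = model$metabolite_ids,
                reactions = model$reaction_ids,
                S = triples,
                b = .num_out(model$b),
                lower = .num_out(model$lower),
                upper = .num_out(model$upper))
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), null = "list")
    writeLines(json, path)
  } else {
    df <- data.frame(metabolite = model$metabolite_ids[nz[, 1]],
                     reaction = model$reaction_ids[nz[, 2]],
                     coefficient = sprintf("%.17g", model$S[nz]))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    fmtb <- function(x) ifelse(is.finite(x), sprintf("%.17g", x),
                               ifelse(x > 0, "inf", "-inf"))
    bdf <- data.frame(reaction = model$reaction_ids,
                      lower = fmtb(model$lower), upper = fmtb(model$upper))
    utils::write.table(bdf, paste0(path, ".bounds"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bfile <- paste0(path, ".b")
    if (any(model$b != 0) || file.exists(bfile)) {
      mdf <- data.frame(metabolite = model$metabolite_ids,
                        b = sprintf("%.17g", model$b))
      utils::write.table(mdf, bfile, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}

.read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("metabolites", "reactions"))
    if (is.null(obj[[key]])) stop("JSON model missing key '", key, "'", call. = FALSE)
  mets <- as.character(unlist(obj$metabolites))
  rxns <- as.character(unlist(obj$reactions))
  S <- matrix(0, length(mets), length(rxns))
  for (tr in obj$S) {
    if (length(tr) != 3L)
      stop("JSON model: S entries must be [metabolite, reaction, coeff] triples",
           call. = FALSE)
    i <- as.integer(tr[[1]]) + 1L; j <- as.integer(tr[[2]]) + 1L
    if (i < 1L || i > length(mets) || j < 1L || j > length(rxns))
      stop("JSON model: S triple index out of range: [", tr[[1]], ", ", tr[[2]], "]",
           call. = FALSE)
    S[i, j] <- as.double(tr[[3]])
  }
  b <- if (is.null(obj$b)) rep(0, length(mets)) else .num_in(obj$b)
  metabolic_model(mets, rxns, S, b,
                  lower = .num_in(obj$lower), upper = .num_in(obj$upper))
}

.read_model_tsv <- function(path, default_bound) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  if (!identical(names(df), c("metabolite", "reaction", "coefficient")))
    stop("TSV model must have header metabolite<TAB>reaction<TAB>coefficient",
         call. = FALSE)
  bounds_path <- paste0(path, ".bounds")
  bdf <- if (file.exists(bounds_path)) {
    utils::read.table(bounds_path, sep = "\t", header = TRUE,
                      colClasses = "character")
  } else data.frame(reaction = character(), lower = character(),
                    upper = character())
  mets <- unique(df$metabolite)
  rxns <- unique(c(df$reaction, bdf$reaction))
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  S[cbind(match(df$metabolite, mets), match(df$reaction, rxns))] <- df$coefficient
  lower <- rep(-default_bound, length(rxns))
  upper <- rep(default_bound, length(rxns))
  if (nrow(bdf)) {
    idx <- match(bdf$reaction, rxns)
    lower[idx] <- .num_in(as.list(bdf$lower))
    upper[idx] <- .num_in(as.list(bdf$upper))
  }
  b <- rep(0, length(mets))
  b_path <- paste0(path, ".b")
  if (file.exists(b_path)) {
    mdf <- utils::read.table(b_path, sep = "\t", header = TRUE,
                             colClasses = "character")
    b[match(mdf$metabolite, mets)] <- as.double(mdf$b)
  }
  metabolic_model(mets, rxns, S, b, lower, upper)
}

.read_model_sbml <- function(path, default_bound) {
  doc <- xml2::read_xml(path)
  sp <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp, "id")
  boundary <- tolower(xml2::xml_attr(sp, "boundaryCondition")) %in% "true"
  mets <- sp_id[!boundary]
  # fbc parameters for flux bounds
  pars <- xml2::xml_find_all(doc, "//*[local-name()='parameter']")
  par_val <- stats::setNames(as.double(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  if (length(rx) == 0L && length(mets) == 0L)
    stop("no reactions or species found; not an SBML model? ", path, call. = FALSE)
  rxn_id <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, rxn_id))
  lower <- upper <- rep(NA_real_, length(rx))
  attr_any <- function(node, name) {
    at <- xml2::xml_attrs(node)
    hit <- grep(paste0("(^|:)", name, "$"), names(at))
    if (length(hit)) at[[hit[1]]] else NA_character_
  }
  for (j in seq_along(rx)) {
    node <- rx[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(
        node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      for (ref in refs) {
        species <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.double(st)
        i <- match(species, mets)
        if (!is.na(i)) S[i, j] <- S[i, j] + sgn * st
      }
    }
    lb_ref <- attr_any(node, "lowerFluxBound")
    ub_ref <- attr_any(node, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_val)) lower[j] <- par_val[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_val)) upper[j] <- par_val[[ub_ref]]
    if (is.na(lower[j]) || is.na(upper[j])) {
      rev <- !(tolower(xml2::xml_attr(node, "reversible")) %in% "false")
      if (is.na(lower[j])) lower[j] <- if (rev) -default_bound else 0
      if (is.na(upper[j])) upper[j] <- default_bound
    }
  }
  metabolic_model(mets, rxn_id, S, rep(0, length(mets)), lower, upper)
}

#' Read a metabolic model
#'
#' @param path file path.
#' @param format one of `"json"`, `"tsv"`, `"sbml"`; guessed from the file
#'   extension (`.xml`/`.sbml` map to SBML) when missing.
#' @param default_bound bound magnitude assigned to reactions with no
#'   declared bounds (TSV bounds sidecar absent, or SBML without fbc
#'   annotations); the common COBRA convention of 1000 native units.
#' @return a validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("json", "tsv", "sbml"),
                       default_bound = 1000) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", tsv = "tsv",
                     xml = "sbml", sbml = "sbml",
                     stop("cannot guess model format from extension '.", ext,
                          "'; pass format=", call. = FALSE))
  }
  format <- match.arg(format)
  switch(format,
         json = .read_model_json(path),
         tsv = .read_model_tsv(path, default_bound),
         sbml = .read_model_sbml(path, default_bound))
}

#' Remove dead-end metabolites and their reactions
#'
#' Iterates to a fixed point the preprocessing rule that removes every
#' reaction touching a metabolite which, at steady state, can only be
#' produced or only be consumed. Reaction direction is read off the bounds:
#' a reversible reaction (`lower < 0 < upper`) counts as both a producer and
#' a consumer of its metabolites, an irreversible one contributes with the
#' sign of its stoichiometric entry (orientation-corrected for reactions
#' that can only run backwards). Metabolites with a nonzero intake `b` are
#' exempt: the external exchange balances them. Reactions pinned to exactly
#' zero flux are dropped first, since they can never carry mass.
#'
#' @param model a `metabolic_model`.
#' @return the pruned `metabolic_model`; attributes `removed_reactions` and
#'   `removed_metabolites` list what was cut. May be empty.
#' @export
prune_dead_ends <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  keep_r <- !(model$lower == 0 & model$upper == 0)
  keep_m <- rep(TRUE, length(model$metabolite_ids))
  S <- model$S
  repeat {
    changed <- FALSE
    # orientation: can the reaction run forward / backward?
    fwd <- model$upper > 0 & keep_r
    bwd <- model$lower < 0 & keep_r
    dead <- logical(length(keep_m))
    for (i in which(keep_m)) {
      if (model$b[i] != 0) next
      row <- S[i, ]
      produced <- any((row > 0 & fwd) | (row < 0 & bwd))
      consumed <- any((row < 0 & fwd) | (row > 0 & bwd))
      touched <- any(row != 0 & keep_r)
      if (!touched) {
        keep_m[i] <- FALSE   # vacuous zero row
        changed <- TRUE
      } else if (xor(produced, consumed)) {
        dead[i] <- TRUE
      }
    }
    if (any(dead)) {
      hit <- keep_r & colSums(abs(S[dead, , drop = FALSE])) > 0
      keep_r[hit] <- FALSE
      keep_m[dead] <- FALSE
      changed <- TRUE
    }
    if (!changed) break
  }
  out <- metabolic_model(model$metabolite_ids[keep_m],
                         model$reaction_ids[keep_r],
                         S[keep_m, keep_r, drop = FALSE],
                         model$b[keep_m],
                         model$lower[keep_r], model$upper[keep_r])
  attr(out, "removed_reactions") <- model$reaction_ids[!keep_r]
  attr(out, "removed_metabolites") <- model$metabolite_ids[!keep_m]
  out
}
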