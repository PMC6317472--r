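#' Deconvolve an observed response vector into glycan abundances
#'
#' The central fitting function: given a candidate glycan library, an
#' experiment panel, and an observed lectin-binding response vector, it
#' (1) builds and per-lectin-normalizes the model response matrix,
#' (2) optionally restricts candidates to MS-supported compositions/masses,
#' (3) clusters candidates by response similarity, (4) removes perfectly
#' colinear columns, (5) solves the nonnegative least-squares problem
#' `min ||C a - d||^2, a >= 0`, (6) samples alternative fits by recursive
#' exclusion, and (7) aggregates the accepted fits into a report whose
#' weights read as relative glycan abundances.
#'
#' @param glycans A `glycan_library` (or coercible input).
#' @param panel A [gmap_panel()].
#' @param observed An `observed_vector` or plain numeric vector on the
#'   panel's channels. Raw observed data are normalized per lectin unless
#'   already flagged normalized (pass [observed_vector()] with
#'   `normalized = TRUE` for data on the model scale).
#' @param config A [solver_config()].
#' @param compositions,masses Optional MS restriction of the candidate set,
#'   see [restrict_candidates()].
#' @param mass_table A `mass_table` for mass matching and summaries.
#' @param cluster_cutoff Distance cutoff for [cluster_model_glycans()];
#'   `NULL` uses 10% of the maximum pairwise distance.
#' @param binding_mode Aggregation over multiple matching lectin motifs, see
#'   [predict_binding()].
#' @return A `glycan_solution` with components `report` (the
#'   [make_report()] output), `fit` (initial `nnls_fit`), `accepted_n`,
#'   `n_refits`, `quality` (solution/observed correlation and R-squared),
#'   `matrix` (filtered model matrix), `observed` (normalized), `glycans`
#'   (post-restriction library), `clusters`, `colinear_groups`, `config`.
#' @examples
#' lib <- as_glycan_library(c(A = "Neu5Aca2-6Galb1-4GlcNAc",
#'                            B = "Neu5Aca2-3Galb1-4GlcNAc"))
#' enz <- list(s23 = enzyme("s23", "Neu5Aca2-3Gal", "Gal"))
#' lec <- list(SNA = lectin("SNA", list(list(motif = "Neu5Aca2-6Gal", score = 0.9))),
#'             MAL = lectin("MAL", list(list(motif = "Neu5Aca2-3Gal", score = 0.8))))
#' pan <- gmap_panel(list(untreated = character(0), s23 = "s23"), lec, enz)
#' rm <- build_model_matrix(lib, pan)
#' d <- observed_vector(as.numeric(rm$C %*% c(0.7, 0.3)), pan, normalized = TRUE)
#' fit <- glycan_solve(lib, pan, d)
#' coef(fit)
#' @seealso [summary.glycan_solution()], [core_fractions()],
#'   [terminal_feature_fractions()], [mass_fractions()]
#' @export
glycan_solve <- function(glycans, panel, observed, config = solver_config(),
                         compositions = NULL, masses = NULL,
                         mass_table = default_mass_table(),
                         cluster_cutoff = NULL,
                         binding_mode = c("max", "sum", "site_count")) {
  binding_mode <- match.arg(binding_mode)
  glycans <- if (inherits(glycans, "glycan_library")) glycans else
    as_glycan_library(glycans)
  stopifnot(inherits(panel, "gmap_panel"))
  if (!is.null(compositions) || !is.null(masses)) {
    glycans <- restrict_candidates(glycans, compositions, masses, mass_table)
    if (length(glycans) == 0L) {
      stop("no candidates remain after mass restriction", call. = FALSE)
    }
  }
  rm <- build_model_matrix(glycans, panel, normalize = TRUE,
                           mode = binding_mode)
  if (!inherits(observed, "observed_vector")) {
    observed <- observed_vector(observed, panel)
  }
  if (!isTRUE(attr(observed, "normalized"))) {
    observed <- normalize_per_lectin(observed)
  }
  clusters <- cluster_model_glycans(rm, cluster_cutoff)
  flt <- filter_colinear(rm, glycans, panel)
  # canonical column order (by id) so the fit never depends on input order
  ord <- order(colnames(flt$matrix$C))
  flt$matrix$C <- flt$matrix$C[, ord, drop = FALSE]
  flt$glycans <- as_glycan_library(unclass(flt$glycans)[ord])
  initial <- nnls_fit(flt$matrix, observed,
                      epsilon = config$positive_weight_epsilon)
  accepted <- sample_alternatives(flt$matrix, observed, initial, config)
  report <- make_report(accepted, flt$matrix, flt$glycans, config,
                        clusters[names(flt$glycans)])
  quality <- withCallingHandlers(
    solution_fit_quality(report, observed),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(report = report, fit = initial,
                 accepted_n = length(accepted),
                 n_refits = attr(accepted, "n_refits"),
                 quality = quality,
                 matrix = flt$matrix, observed = observed,
                 glycans = flt$glycans, clusters = clusters,
                 colinear_groups = flt$groups,
                 mass_table = mass_table, config = config,
                 call = match.call()),
            class = "glycan_solution")
}

#' @export
print.glycan_solution <- function(x, ...) {
  cat("Glycan deconvolution by nonnegative least squares\n")
  cat("  candidates: ", length(x$clusters), " (",
      ncol(x$matrix$C), " after colinearity filter)\n", sep = "")
  cat("  initial R2: ", format(x$fit$r2, digits = 4),
      "; accepted fits: ", x$accepted_n,
      " (", x$n_refits, " refits)\n", sep = "")
  cat("  solution vs observed: r = ",
      format(x$quality$correlation, digits = 3),
      ", R2 = ", format(x$quality$r2, digits = 3), "\n", sep = "")
  cat("  reported glycans (inclusion frequency >= ",
      format(x$config$inclusion_threshold), "): ", nrow(x$report), "\n",
      sep = "")
  invisible(x)
}

#' Summarize a glycan deconvolution
#'
#' @param object A `glycan_solution`.
#' @param ... Unused.
#' @return A `summary.glycan_solution`: the report plus core-type, terminal-
#'   feature and per-mass fraction tables.
#' @export
summary.glycan_solution <- function(object, ...) {
  w <- stats::setNames(object$report$mean_weight, object$report$glycan_id)
  structure(list(
    report = object$report,
    quality = object$quality,
    core = core_fractions(w, object$glycans),
    terminal = tryCatch(terminal_feature_fractions(w, object$glycans),
                        error = function(e) NULL),
    mass = mass_fractions(w, object$glycans)
  ), class = "summary.glycan_solution")
}

#' @export
print.summary.glycan_solution <- function(x, ...) {
  print(x$report)
  cat("\nCore-type fractions:\n")
  print(round(x$core, 4))
  if (!is.null(x$terminal)) {
    cat("\nTerminal-feature fractions (per antenna site):\n")
    print(round(x$terminal, 4))
  }
  cat("\nMass (composition) fractions:\n")
  print(round(x$mass, 4))
  invisible(x)
}

#' @export
coef.glycan_solution <- function(object, all = FALSE, ...) {
  if (all) attr(object$report, "mean_weights")
  else stats::setNames(object$report$mean_weight, object$report$glycan_id)
}

#' @export
fitted.glycan_solution <- function(object, ...) {
  attr(object$report, "solution_vector")
}

#' @export
residuals.glycan_solution <- function(object, ...) {
  as.numeric(object$observed) - fitted(object)
}

#' Predict the response vector of a glycan mixture
#'
#' Multiplies the fitted (filtered, normalized) model matrix by a weight
#' vector. With no new weights this is the solution response vector.
#'
#' @param object A `glycan_solution`.
#' @param weights Optional named weight vector over (a subset of) the model
#'   glycans.
#' @param ... Unused.
#' @return A numeric vector on the panel channels.
#' @export
predict.glycan_solution <- function(object, weights = NULL, ...) {
  if (is.null(weights)) return(fitted(object))
  w <- stats::setNames(numeric(ncol(object$matrix$C)),
                       colnames(object$matrix$C))
  unknown <- setdiff(names(weights), names(w))
  if (length(unknown)) {
    stop(sprintf("unknown glycan id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  w[names(weights)] <- weights
  stats::setNames(as.numeric(object$matrix$C %*% w), rownames(object$matrix$C))
}

#' Plot observed versus solution response vectors
#'
#' Paired bars per channel: the observed response vector next to the solution
#' response vector, grouped by lectin.
#'
#' @param x A `glycan_solution`.
#' @param ... Passed on to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.glycan_solution <- function(x, ...) {
  obs <- as.numeric(x$observed)
  sol <- fitted(x)
  m <- rbind(observed = obs, solution = sol)
  colnames(m) <- names(x$observed)
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(m, beside = TRUE, las = 2, cex.names = 0.7,
                    col = c("grey25", "steelblue"),
                    ylab = "normalized binding",
                    legend.text = rownames(m),
                    args.legend = list(x = "topright", bty = "n"), ...)
  invisible(x)
}
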