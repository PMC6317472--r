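# Deconvolution core: the glycan weights a are the nonnegative least-squares
# solution of min ||C a - d||^2, a >= 0, where C is the per-lectin-normalized
# model response matrix and d the normalized observed response vector. A
# colinearity filter first removes perfectly proportional columns; remaining
# ambiguity is explored by recursively excluding initially predicted glycans
# and refitting, and the report aggregates over all accepted fits.

#' Solver configuration
#'
#' @param r2_window An alternative refit is accepted when its R-squared is
#'   within this window below the initial fit's.
#' @param max_additional_glycans Maximum number of glycans an accepted
#'   alternative may use beyond the initial predicted set.
#' @param samples_per_glycan Refit budget per initially predicted glycan; the
#'   total number of refits collected never exceeds
#'   `samples_per_glycan * |initial predicted set|`.
#' @param inclusion_threshold Minimum inclusion frequency over accepted fits
#'   for a glycan to appear in the report.
#' @param positive_weight_epsilon Weight cutoff above which a glycan counts as
#'   predicted by a fit (data are normalized so the observed maximum per
#'   lectin is 1; weights below this are numerically zero).
#' @param zero_fill_mean Average reported weights over all accepted fits,
#'   filling zero where a fit lacks the glycan (default); `FALSE` averages
#'   only over the fits containing it.
#' @return A `solver_config` list.
#' @export
solver_config <- function(r2_window = 0.05, max_additional_glycans = 2,
                          samples_per_glycan = 100, inclusion_threshold = 0.10,
                          positive_weight_epsilon = 1e-8,
                          zero_fill_mean = TRUE) {
  stopifnot(r2_window >= 0, max_additional_glycans >= 0,
            samples_per_glycan >= 1,
            inclusion_threshold >= 0, inclusion_threshold <= 1,
            positive_weight_epsilon >= 0)
  structure(list(r2_window = r2_window,
                 max_additional_glycans = as.integer(max_additional_glycans),
                 samples_per_glycan = as.integer(samples_per_glycan),
                 inclusion_threshold = inclusion_threshold,
                 positive_weight_epsilon = positive_weight_epsilon,
                 zero_fill_mean = isTRUE(zero_fill_mean)),
            class = "solver_config")
}

#' Remove perfectly colinear model columns
#'
#' Groups columns that are pairwise proportional (cosine similarity within
#' `tol` of 1, or both all-zero) and keeps one representative per group: the
#' glycan with the most residues covered by at least one matching lectin
#' motif, ties broken by total residue count, then by id. Proportional
#' columns are indistinguishable to the fit, so keeping the most thoroughly
#' probed structure loses nothing; remaining (non-proportional) near-
#' dependence is handled by alternative-fit sampling.
#'
#' @param rm A `response_matrix`.
#' @param glycans The matching `glycan_library`.
#' @param panel The `gmap_panel` (supplies the lectins used for the coverage
#'   score); optional — without it ties fall through to residue count.
#' @param tol Cosine-similarity tolerance for "proportional".
#' @return List with the reduced `matrix` (`response_matrix`), reduced
#'   `glycans`, and `groups` (named list: representative id -> member ids).
#' @export
filter_colinear <- function(rm, glycans, panel = NULL, tol = 1e-9) {
  stopifnot(inherits(rm, "response_matrix"))
  C <- rm$C
  M <- ncol(C)
  nrm <- sqrt(colSums(C^2))
  U <- C
  nz <- nrm > 0
  U[, nz] <- sweep(C[, nz, drop = FALSE], 2, nrm[nz], "/")
  # union-find over proportional pairs
  parent <- seq_len(M)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (M > 1L) {
    for (i in 1:(M - 1L)) {
      for (j in (i + 1L):M) {
        prop <- if (!nz[i] && !nz[j]) TRUE
                else if (nz[i] && nz[j]) sum(U[, i] * U[, j]) >= 1 - tol
                else FALSE
        if (prop) parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(M), find, integer(1))
  ids <- colnames(C)
  coverage <- if (!is.null(panel)) {
    vapply(glycans[ids], motif_coverage, numeric(1), lectins = panel$lectins)
  } else rep(0, M)
  nres <- vapply(glycans[ids], residue_count, numeric(1))
  keep <- logical(M)
  groups <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    ord <- members[order(-coverage[members], -nres[members], ids[members])]
    keep[ord[1L]] <- TRUE
    groups[[ids[ord[1L]]]] <- ids[members]
  }
  rm$C <- C[, keep, drop = FALSE]
  list(matrix = rm, glycans = as_glycan_library(glycans[ids[keep]]),
       groups = groups)
}

r_squared <- function(d, resid_ss, tol = 1e-12) {
  ss_tot <- sum((d - mean(d))^2)
  if (ss_tot <= tol) {
    return(if (resid_ss <= tol) 1 else 0)
  }
  1 - resid_ss / ss_tot
}

#' Nonnegative least-squares fit of model vectors to an observed vector
#'
#' Solves `min ||C a - d||^2` subject to `a >= 0` (Lawson-Hanson active set,
#' via [pracma::lsqnonneg()]). The nonnegativity constraint is what lets the
#' weights be read as relative glycan abundances.
#'
#' @param C Numeric matrix (channels x glycans) or `response_matrix`.
#' @param d Numeric vector (or `observed_vector`) of length `nrow(C)`.
#' @param epsilon Weight cutoff defining the predicted set.
#' @return An `nnls_fit`: `weights` (named, >= 0), `residual_ss`, `r2`
#'   (conventional coefficient of determination; 1 for an exact fit to a
#'   constant `d`, 0 otherwise when `d` is constant), and `predicted`
#'   (ids with weight above `epsilon`).
#' @export
nnls_fit <- function(C, d, epsilon = 1e-8) {
  if (inherits(C, "response_matrix")) C <- C$C
  C <- as.matrix(C)
  d <- as.numeric(d)
  if (nrow(C) != length(d)) {
    stop(sprintf("dimension mismatch: C has %d rows, d has length %d",
                 nrow(C), length(d)), call. = FALSE)
  }
  if (all(C == 0) || all(d == 0)) {
    a <- stats::setNames(numeric(ncol(C)), colnames(C))
    rss <- sum(d^2)
  } else {
    sol <- pracma::lsqnonneg(C, d)
    a <- stats::setNames(pmax(sol$x, 0), colnames(C))
    rss <- sum((C %*% a - d)^2)
  }
  structure(list(weights = a, residual_ss = rss, r2 = r_squared(d, rss),
                 predicted = names(a)[a > epsilon]),
            class = "nnls_fit")
}

#' @export
print.nnls_fit <- function(x, ...) {
  cat("<nnls_fit> R2 = ", format(x$r2, digits = 4),
      ", ", length(x$predicted), " glycans with positive weight\n", sep = "")
  w <- sort(x$weights[x$predicted], decreasing = TRUE)
  if (length(w)) print(round(w, 4))
  invisible(x)
}

# zero-filled refit on the columns not excluded
refit_excluding <- function(C, d, excluded, epsilon) {
  keep <- setdiff(colnames(C), excluded)
  fit <- nnls_fit(C[, keep, drop = FALSE], d, epsilon)
  w <- stats::setNames(numeric(ncol(C)), colnames(C))
  w[keep] <- fit$weights
  fit$weights <- w
  fit
}

#' Sample alternative fits by recursive exclusion
#'
#' Explores alternative deconvolutions deterministically: starting from the
#' initial fit, each initially predicted glycan (in descending order of
#' initial weight) is excluded in turn and the model refit on all remaining
#' candidates. A refit is accepted as an alternative when its R-squared is
#' within `r2_window` of the initial fit and it uses at most
#' `max_additional_glycans` glycans outside the initial predicted set.
#' Accepted fits are recursed into, excluding further initially predicted
#' glycans along the path; the recursion depth is capped at the size of the
#' initial predicted set, each exclusion set is evaluated once, and
#' exploration stops after `samples_per_glycan` refits per initially
#' predicted glycan. The initial fit is always part of the result.
#'
#' @param C Model matrix (colinearity-filtered) or `response_matrix`.
#' @param d Observed vector.
#' @param initial The initial `nnls_fit` on the same matrix.
#' @param config A [solver_config()].
#' @return List of accepted `nnls_fit`s (initial first), with attributes
#'   `n_refits` (refits attempted) and `budget`.
#' @export
sample_alternatives <- function(C, d, initial, config = solver_config()) {
  if (inherits(C, "response_matrix")) C <- C$C
  d <- as.numeric(d)
  init_pred <- initial$predicted[order(-initial$weights[initial$predicted],
                                       initial$predicted)]
  accepted <- list(initial)
  if (length(init_pred) == 0L) {
    return(structure(accepted, n_refits = 0L, budget = 0L))
  }
  budget <- config$samples_per_glycan * length(init_pred)
  depth_cap <- length(init_pred)
  floor_r2 <- initial$r2 - config$r2_window
  st <- new.env(parent = emptyenv())
  st$count <- 0L
  st$seen <- character(0)
  st$accepted <- accepted
  recurse <- function(excluded) {
    if (length(excluded) >= depth_cap) return(invisible(NULL))
    for (gid in init_pred) {
      if (gid %in% excluded) next
      if (st$count >= budget) return(invisible(NULL))
      key <- paste(sort(c(excluded, gid)), collapse = "\r")
      if (key %in% st$seen) next
      st$seen <- c(st$seen, key)
      st$count <- st$count + 1L
      fit <- refit_excluding(C, d, c(excluded, gid),
                             config$positive_weight_epsilon)
      extra <- setdiff(fit$predicted, init_pred)
      if (fit$r2 >= floor_r2 &&
          length(extra) <= config$max_additional_glycans) {
        st$accepted[[length(st$accepted) + 1L]] <- fit
        recurse(c(excluded, gid))
      }
    }
    invisible(NULL)
  }
  recurse(character(0))
  structure(st$accepted, n_refits = st$count, budget = budget)
}

#' Aggregate accepted fits into a solver report
#'
#' Inclusion frequency is the fraction of accepted fits giving the glycan a
#' positive weight; glycans below `inclusion_threshold` are dropped from the
#' report. Reported weights are means over all accepted fits (zero where
#' absent, by default). The contribution of a reported glycan is the share of
#' the solution response vector attributable to its weighted model column
#' (using the column L1 norm); contributions sum to 1 over the report and
#' serve as a per-glycan confidence. The solution vector is the weighted sum
#' of all model columns.
#'
#' @param accepted List of accepted fits from [sample_alternatives()].
#' @param rm The (filtered) `response_matrix` or plain matrix.
#' @param glycans Optional `glycan_library` supplying structures/compositions.
#' @param config A [solver_config()].
#' @param clusters Optional named cluster labels from
#'   [cluster_model_glycans()].
#' @return A `solver_report`: data frame (one row per reported glycan:
#'   `glycan_id`, `structure`, `composition`, `cluster`,
#'   `inclusion_frequency`, `mean_weight`, `contribution`) with attributes
#'   `mean_weights` (all glycans), `solution_vector`, `n_accepted`,
#'   `initial_r2`.
#' @export
make_report <- function(accepted, rm, glycans = NULL,
                        config = solver_config(), clusters = NULL) {
  if (length(accepted) == 0L) stop("no accepted fits", call. = FALSE)
  C <- if (inherits(rm, "response_matrix")) rm$C else as.matrix(rm)
  eps <- config$positive_weight_epsilon
  W <- do.call(rbind, lapply(accepted, `[[`, "weights"))
  freq <- colMeans(W > eps)
  mean_w <- if (config$zero_fill_mean) colMeans(W) else {
    apply(W, 2, function(col) if (any(col > eps)) mean(col[col > eps]) else 0)
  }
  solution <- as.numeric(C %*% mean_w)
  names(solution) <- rownames(C)
  keep <- names(freq)[freq >= config$inclusion_threshold & mean_w > 0]
  contrib_raw <- mean_w[keep] * colSums(abs(C[, keep, drop = FALSE]))
  contrib <- if (length(keep) && sum(contrib_raw) > 0) {
    contrib_raw / sum(contrib_raw)
  } else stats::setNames(numeric(length(keep)), keep)
  ord <- keep[order(-mean_w[keep], keep)]
  df <- data.frame(
    glycan_id = ord,
    structure = if (!is.null(glycans)) {
      vapply(glycans[ord], write_glycan, character(1))
    } else NA_character_,
    composition = if (!is.null(glycans)) {
      vapply(glycans[ord], function(g) format_composition(composition_of(g)),
             character(1))
    } else NA_character_,
    cluster = if (!is.null(clusters)) as.integer(clusters[ord]) else NA_integer_,
    inclusion_frequency = as.numeric(freq[ord]),
    mean_weight = as.numeric(mean_w[ord]),
    contribution = as.numeric(contrib[ord]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(df, class = c("solver_report", "data.frame"),
            mean_weights = mean_w, solution_vector = solution,
            n_accepted = length(accepted), initial_r2 = accepted[[1L]]$r2)
}

#' @export
print.solver_report <- function(x, ...) {
  if (!is.null(attr(x, "n_accepted"))) {
    cat("<solver_report> ", nrow(x), " glycans over ", attr(x, "n_accepted"),
        " accepted fits (initial R2 = ",
        format(attr(x, "initial_r2"), digits = 4), ")\n", sep = "")
  }
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Closeness of the solution response vector to the observed vector
#'
#' @param report A `solver_report` (or a numeric solution vector).
#' @param d The observed vector it was fit to.
#' @return List with `correlation` (Pearson r; `NA` with a warning if either
#'   vector is constant) and `r2` (coefficient of determination of the
#'   solution vector for `d`).
#' @export
solution_fit_quality <- function(report, d) {
  sv <- if (inherits(report, "solver_report")) attr(report, "solution_vector")
        else as.numeric(report)
  d <- as.numeric(d)
  if (length(sv) != length(d)) stop("length mismatch", call. = FALSE)
  r <- if (stats::sd(sv) == 0 || stats::sd(d) == 0) {
    warning("correlation undefined for a constant vector")
    NA_real_
  } else stats::cor(sv, d)
  list(correlation = r, r2 = r_squared(d, sum((sv - d)^2)))
}

#' Write a solver report to TSV
#' @param report A `solver_report`.
#' @param path Output TSV path.
#' @return Invisibly, the report data frame.
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}
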