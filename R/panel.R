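# The experiment panel and model response matrix. A channel is one
# (treatment condition, lectin) pair; the model response matrix C holds the
# predicted, per-lectin-normalized binding of every lectin x condition channel
# (rows) to every candidate glycan (columns). The observed response vector d
# lives on the same channels.

#' Define an experiment panel
#'
#' @param conditions Named list of treatment conditions; each element is a
#'   character vector of enzyme names applied in order (the empty vector is
#'   the untreated condition).
#' @param lectins Named list of `lectin` objects.
#' @param enzymes Named list of `enzyme` objects; every name used in
#'   `conditions` must resolve here.
#' @return A `gmap_panel` with a fixed channel order: lectin-major, so each
#'   lectin's conditions form a contiguous row block.
#' @export
gmap_panel <- function(conditions, lectins, enzymes = list()) {
  stopifnot(length(conditions) >= 1L, length(lectins) >= 1L)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("conditions must be named", call. = FALSE)
  }
  if (anyDuplicated(names(conditions))) {
    stop("condition names must be unique", call. = FALSE)
  }
  used <- unique(unlist(conditions, use.names = FALSE))
  missing_e <- setdiff(used, names(enzymes))
  if (length(missing_e)) {
    stop(sprintf("unknown enzyme(s) in panel conditions: %s",
                 paste(missing_e, collapse = ", ")), call. = FALSE)
  }
  channels <- expand.grid(condition = names(conditions),
                          lectin = names(lectins),
                          stringsAsFactors = FALSE)[, c("lectin", "condition")]
  channels <- channels[order(match(channels$lectin, names(lectins)),
                             match(channels$condition, names(conditions))), ]
  rownames(channels) <- NULL
  channels$label <- paste(channels$lectin, channels$condition, sep = "|")
  structure(list(conditions = conditions, lectins = lectins,
                 enzymes = enzymes, channels = channels),
            class = "gmap_panel")
}

#' @export
print.gmap_panel <- function(x, ...) {
  cat("<gmap_panel> ", length(x$lectins), " lectins x ",
      length(x$conditions), " conditions = ", nrow(x$channels),
      " channels\n", sep = "")
  cat("  lectins:   ", paste(names(x$lectins), collapse = ", "), "\n")
  cat("  conditions:", paste(vapply(names(x$conditions), function(nm) {
    enz <- x$conditions[[nm]]
    if (length(enz)) paste0(nm, " [", paste(enz, collapse = " > "), "]") else nm
  }, character(1)), collapse = "; "), "\n")
  invisible(x)
}

#' Build the model response matrix for a candidate library
#'
#' For every condition, each candidate is digested in silico by the
#' condition's enzyme sequence; binding of every lectin to the digested
#' structure is then predicted from the motif binding scores. Entry
#' `(channel (t, l), glycan g)` is `predict_binding(apply_treatment(g, t), l)`.
#'
#' @param glycans A `glycan_library` (or coercible input).
#' @param panel A `gmap_panel`.
#' @param normalize Normalize per lectin (the default); see
#'   [normalize_per_lectin()].
#' @param mode Binding aggregation mode, see [predict_binding()].
#' @return A `response_matrix`: list with `C` (channels x glycans), the
#'   panel's `channels` table, and a `normalized` flag.
#' @export
build_model_matrix <- function(glycans, panel, normalize = TRUE,
                               mode = c("max", "sum", "site_count")) {
  mode <- match.arg(mode)
  glycans <- if (inherits(glycans, "glycan_library")) glycans else
    as_glycan_library(glycans)
  stopifnot(inherits(panel, "gmap_panel"))
  digested <- lapply(names(panel$conditions), function(cond) {
    enz <- panel$enzymes[panel$conditions[[cond]]]
    lapply(glycans, apply_treatment, enzymes = enz)
  })
  names(digested) <- names(panel$conditions)
  C <- matrix(0, nrow = nrow(panel$channels), ncol = length(glycans),
              dimnames = list(panel$channels$label, names(glycans)))
  for (i in seq_len(nrow(panel$channels))) {
    l <- panel$lectins[[panel$channels$lectin[i]]]
    gs <- digested[[panel$channels$condition[i]]]
    C[i, ] <- vapply(gs, predict_binding, numeric(1), l = l, mode = mode)
  }
  rm <- structure(list(C = C, channels = panel$channels, normalized = FALSE),
                  class = "response_matrix")
  if (normalize) rm <- normalize_per_lectin(rm) else rm
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$C), " channels x ", ncol(x$C), " glycans",
      if (x$normalized) "  (normalized per lectin)", "\n", sep = "")
  invisible(x)
}

#' Normalize binding data per lectin
#'
#' Each lectin's row block is divided by the block maximum — over all
#' conditions and, for a model matrix, over all glycans — so the strongest
#' binding per lectin is 1 and data from lectins with different signal scales
#' become comparable. All-zero blocks are left unchanged. Idempotent.
#'
#' @param x A `response_matrix`, or an `observed_vector` (see
#'   [observed_vector()]).
#' @return Same shape as the input, with entries in `[0, 1]` per block (up to
#'   sign: negative background-subtracted values are kept, not clamped).
#' @export
normalize_per_lectin <- function(x) UseMethod("normalize_per_lectin")

#' @export
normalize_per_lectin.response_matrix <- function(x) {
  for (l in unique(x$channels$lectin)) {
    rows <- x$channels$lectin == l
    mx <- max(x$C[rows, , drop = FALSE])
    if (mx > 0) x$C[rows, ] <- x$C[rows, , drop = FALSE] / mx
  }
  x$normalized <- TRUE
  x
}

#' @export
normalize_per_lectin.observed_vector <- function(x) {
  ch <- attr(x, "channels")
  v <- as.numeric(x)
  for (l in unique(ch$lectin)) {
    rows <- ch$lectin == l
    mx <- max(v[rows])
    if (mx > 0) v[rows] <- v[rows] / mx
  }
  observed_vector(v, ch, normalized = TRUE)
}

#' Construct an observed response vector
#'
#' @param values Numeric vector of observed binding, one value per channel.
#' @param channels A channel table (`lectin`, `condition`, `label`), usually
#'   `panel$channels`.
#' @param normalized Whether values are already per-lectin normalized.
#' @return An `observed_vector`.
#' @export
observed_vector <- function(values, channels, normalized = FALSE) {
  if (inherits(channels, "gmap_panel")) channels <- channels$channels
  stopifnot(length(values) == nrow(channels))
  structure(stats::setNames(as.numeric(values), channels$label),
            channels = channels, normalized = normalized,
            class = "observed_vector")
}

#' @export
print.observed_vector <- function(x, ...) {
  cat("<observed_vector> ", length(x), " channels",
      if (isTRUE(attr(x, "normalized"))) "  (normalized per lectin)", "\n",
      sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Cluster candidate glycans by response-vector similarity
#'
#' Agglomerative complete-linkage clustering of the model matrix columns by
#' Euclidean distance, cut at a uniform height. Glycans in one cluster have
#' similar response vectors and therefore potentially represent alternate
#' solutions.
#'
#' @param rm A `response_matrix`.
#' @param cutoff Distance cutoff; default 10% of the maximum pairwise
#'   distance.
#' @return An integer vector of dense cluster labels, named by glycan id and
#'   numbered in column order of first appearance.
#' @export
cluster_model_glycans <- function(rm, cutoff = NULL) {
  stopifnot(inherits(rm, "response_matrix"))
  M <- ncol(rm$C)
  if (M == 1L) return(stats::setNames(1L, colnames(rm$C)))
  d <- stats::dist(t(rm$C))
  if (is.null(cutoff)) cutoff <- 0.1 * max(d)
  if (max(d) == 0) {
    labels <- rep(1L, M)
  } else {
    hc <- stats::hclust(d, method = "complete")
    labels <- stats::cutree(hc, h = cutoff)
  }
  # renumber densely and order-independently: clusters sorted by their
  # lexicographically smallest member id
  labels <- stats::setNames(labels, colnames(rm$C))
  min_id <- tapply(names(labels), labels, min)
  rank_of <- stats::setNames(rank(min_id), names(min_id))
  stats::setNames(as.integer(rank_of[as.character(labels)]), names(labels))
}

#' Restrict candidates by MS-derived compositions or masses
#'
#' Implements mass-informed candidate filtering: keeps candidates whose
#' monosaccharide composition is in the allowed set, or whose computed mass
#' lies within tolerance of an allowed mass. Published mass labels frequently
#' follow an unstated derivatization convention, so composition matching is
#' the safer route when compositions are known.
#'
#' @param glycans A `glycan_library`.
#' @param compositions Character vector of allowed compositions
#'   (e.g. `"Hex5HexNAc4Neu5Ac2"`), or a list of `glycan_composition`s.
#' @param masses Numeric vector of allowed masses in Da.
#' @param mass_table A `mass_table` supplying residue masses and the matching
#'   `tolerance`.
#' @return The restricted `glycan_library`, input order preserved. Empty
#'   results are returned with a warning.
#' @export
restrict_candidates <- function(glycans, compositions = NULL, masses = NULL,
                                mass_table = default_mass_table()) {
  glycans <- if (inherits(glycans, "glycan_library")) glycans else
    as_glycan_library(glycans)
  if ((is.null(compositions) || length(compositions) == 0L) &&
      (is.null(masses) || length(masses) == 0L)) {
    stop("restrict_candidates: the allowed set is empty", call. = FALSE)
  }
  allowed_comp <- character(0)
  if (!is.null(compositions)) {
    allowed_comp <- vapply(compositions, function(cc) {
      if (inherits(cc, "glycan_composition")) format_composition(cc)
      else format_composition(parse_composition(cc))
    }, character(1))
  }
  keep <- vapply(glycans, function(g) {
    comp <- composition_of(g)
    if (format_composition(comp) %in% allowed_comp) return(TRUE)
    if (!is.null(masses) && length(masses)) {
      m <- mass_of(comp, mass_table)
      if (any(abs(masses - m) <= mass_table$tolerance)) return(TRUE)
    }
    FALSE
  }, logical(1))
  if (!any(keep)) {
    warning("restrict_candidates: no candidate matches the allowed set")
  }
  as_glycan_library(glycans[keep])
}

#' Pearson correlation between two response vectors
#'
#' Used to score how well a panel discriminates two candidate isomers: near-1
#' correlation between their model vectors means the panel cannot tell them
#' apart.
#'
#' @param v1,v2 Numeric vectors of equal length >= 2.
#' @return Pearson r; `NA` (with a warning) when either vector is constant.
#' @export
vector_correlation <- function(v1, v2) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  if (length(v1) != length(v2) || length(v1) < 2L) {
    stop("vectors must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("correlation undefined for a constant response vector")
    return(NA_real_)
  }
  stats::cor(v1, v2)
}

#' Read a panel definition from YAML
#'
#' Expected layout:
#' ```yaml
#' conditions:
#'   untreated: []
#'   sialidase: [sialidase_a23]
#' lectins: [SNA, MAL]
#' ```
#' Names are resolved against the supplied lectin and enzyme lists.
#'
#' @param path YAML file path.
#' @param lectins Named list of `lectin` objects.
#' @param enzymes Named list of `enzyme` objects.
#' @return A `gmap_panel`.
#' @export
read_panel <- function(path, lectins, enzymes) {
  y <- yaml::read_yaml(path)
  if (is.null(y$conditions) || is.null(y$lectins)) {
    stop("panel YAML needs 'conditions' and 'lectins'", call. = FALSE)
  }
  conds <- lapply(y$conditions, function(x) as.character(unlist(x)))
  use <- as.character(unlist(y$lectins))
  missing_l <- setdiff(use, names(lectins))
  if (length(missing_l)) {
    stop(sprintf("unknown lectin(s) in panel: %s",
                 paste(missing_l, collapse = ", ")), call. = FALSE)
  }
  gmap_panel(conds, lectins[use], enzymes)
}

#' Export a model matrix to TSV (channels as rows, glycans as columns)
#' @param rm A `response_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_model_matrix <- function(rm, path) {
  df <- data.frame(channel = rownames(rm$C), rm$C, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
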