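# Weighted structural summaries of a deconvolution result: which glycan cores
# are present, which terminal features decorate them, and how weight
# distributes across masses (compositions) and across isomers within a mass.

find_child <- function(node, cls, ppos = NULL, ano = NULL) {
  for (ch in node$children) {
    if (ch$cls != cls) next
    if (!is.null(ppos) && (is.na(ch$ppos) || ch$ppos != ppos)) next
    if (!is.null(ano) && (is.na(ch$ano) || ch$ano != ano)) next
    return(ch)
  }
  NULL
}

#' Classify the core type of a glycan
#'
#' N-glycans are detected by the trimannosyl-chitobiose core (GlcNAc-GlcNAc-
#' Man with alpha-3/6 mannoses); antennarity is the number of GlcNAc branches
#' on the two core alpha-mannoses. A bisecting GlcNAc (beta1-4 on the core
#' beta-mannose) counts as a flag, not an antenna, and core fucose (alpha1-6
#' on the reducing GlcNAc) is likewise a flag. O-glycan cores 1 and 2 are
#' detected from the reducing GalNAc. Everything else is `"other"`.
#'
#' @param g A `glycan`.
#' @return A label (`"N-biantennary"`, `"N-triantennary"`,
#'   `"N-tetraantennary"`, `"N-monoantennary"`, `"N-core"`, `"O-core1"`,
#'   `"O-core2"`, or `"other"`) with attributes `bisecting` and
#'   `core_fucose` for N-glycans.
#' @export
core_type_of <- function(g) {
  stopifnot(inherits(g, "glycan"))
  root <- g$root
  if (root$cls == "GlcNAc") {
    gn2 <- find_child(root, "GlcNAc", ppos = "4", ano = "b")
    bman <- if (!is.null(gn2)) find_child(gn2, "Man", ppos = "4", ano = "b")
    if (!is.null(bman)) {
      man3 <- find_child(bman, "Man", ppos = "3", ano = "a")
      man6 <- find_child(bman, "Man", ppos = "6", ano = "a")
      if (!is.null(man3) && !is.null(man6)) {
        antennae <- 0L
        for (am in list(man3, man6)) {
          antennae <- antennae +
            sum(vapply(am$children, function(ch) ch$cls == "GlcNAc", logical(1)))
        }
        bisect <- !is.null(find_child(bman, "GlcNAc", ppos = "4", ano = "b"))
        fuc <- !is.null(find_child(root, "Fuc", ppos = "6", ano = "a"))
        label <- if (antennae == 0L) "N-core"
                 else if (antennae == 1L) "N-monoantennary"
                 else if (antennae == 2L) "N-biantennary"
                 else if (antennae == 3L) "N-triantennary"
                 else "N-tetraantennary"
        return(structure(label, bisecting = bisect, core_fucose = fuc))
      }
    }
  }
  if (root$cls == "GalNAc") {
    gal13 <- find_child(root, "Gal", ppos = "3", ano = "b")
    gn6 <- find_child(root, "GlcNAc", ppos = "6", ano = "b")
    if (!is.null(gal13) && !is.null(gn6)) return("O-core2")
    if (!is.null(gal13)) return("O-core1")
  }
  "other"
}

as_weights <- function(weights) {
  if (inherits(weights, "glycan_solution")) {
    stats::setNames(weights$report$mean_weight, weights$report$glycan_id)
  } else if (inherits(weights, "solver_report")) {
    stats::setNames(weights$mean_weight, weights$glycan_id)
  } else weights
}

#' Weighted core-type fractions of a solution
#'
#' @param weights A named weight vector, a `solver_report`, or a
#'   `glycan_solution`.
#' @param glycans The `glycan_library` resolving the ids.
#' @return A named numeric vector of fractions summing to 1 (descending).
#' @export
core_fractions <- function(weights, glycans) {
  w <- as_weights(weights)
  if (length(w) == 0L || sum(w) <= 0) {
    stop("core_fractions needs at least one positive weight", call. = FALSE)
  }
  labels <- vapply(glycans[names(w)], function(g) as.character(core_type_of(g)),
                   character(1))
  tab <- tapply(w, labels, sum) / sum(w)
  sort(stats::setNames(as.numeric(tab), names(tab)), decreasing = TRUE)
}

#' Default terminal-feature detectors
#'
#' Terminal-anchored motifs for the features the lectin/enzyme repertoire
#' discriminates: sialic-acid linkage (alpha2-3 vs alpha2-6), galactose
#' linkage (beta1-3 vs beta1-4), and exposed (terminal) GlcNAc.
#'
#' @return A named list of terminal-required `motif`s.
#' @export
default_terminal_features <- function() {
  list(
    "Neu5Ac a2-3" = motif("Neu5Aca2-3Gal", terminal_required = TRUE),
    "Neu5Ac a2-6" = motif("Neu5Aca2-6Gal", terminal_required = TRUE),
    "Gal b1-3"    = motif("Galb1-3GlcNAc", terminal_required = TRUE),
    "Gal b1-4"    = motif("Galb1-4GlcNAc", terminal_required = TRUE),
    "terminal GlcNAc" = motif("GlcNAc", terminal_required = TRUE)
  )
}

#' Weighted terminal-feature fractions
#'
#' Each glycan contributes its weight split across its terminal features in
#' proportion to site counts (per-arm accounting: a glycan with one alpha2-3
#' and one alpha2-6 arm contributes half its weight to each); set
#' `per_site = FALSE` for presence/absence accounting. Glycans displaying
#' none of the features contribute nothing.
#'
#' @param weights Named weights, `solver_report`, or `glycan_solution`.
#' @param glycans The `glycan_library`.
#' @param features Named list of terminal-required `motif`s.
#' @param core Optional core filter: keep only glycans whose
#'   [core_type_of()] label is in this character vector.
#' @param per_site Per-site (default) or per-glycan accounting.
#' @return Named fractions over features, summing to 1.
#' @export
terminal_feature_fractions <- function(weights, glycans,
                                       features = default_terminal_features(),
                                       core = NULL, per_site = TRUE) {
  w <- as_weights(weights)
  stopifnot(length(features) >= 1L)
  if (!all(vapply(features, function(m) m$terminal, logical(1)))) {
    stop("terminal-feature detectors must be terminal-required motifs",
         call. = FALSE)
  }
  if (!is.null(core)) {
    keep <- vapply(glycans[names(w)],
                   function(g) as.character(core_type_of(g)) %in% core,
                   logical(1))
    w <- w[keep]
    if (length(w) == 0L) {
      stop("no glycans match the core filter", call. = FALSE)
    }
  }
  acc <- stats::setNames(numeric(length(features)), names(features))
  for (id in names(w)) {
    g <- glycans[[id]]
    counts <- vapply(features, function(m) length(match_motif(g, m)), numeric(1))
    if (!per_site) counts <- as.numeric(counts > 0)
    total <- sum(counts)
    if (total > 0) acc <- acc + w[[id]] * counts / total
  }
  if (sum(acc) <= 0) {
    stop("no glycan displays any of the terminal features", call. = FALSE)
  }
  acc / sum(acc)
}

#' Weighted per-mass (composition) fractions
#'
#' Sums the weights of all isomers sharing a monosaccharide composition and
#' converts the sums to fractions of the total — the solution-side analogue of
#' a relative-abundance-by-mass profile from MS.
#'
#' @param weights Named weights, `solver_report`, or `glycan_solution`.
#' @param glycans The `glycan_library`.
#' @param by Group by `"composition"` text or computed `"mass"` (Da, printed
#'   to 2 decimals).
#' @param mass_table `mass_table` used when `by = "mass"`.
#' @return Named fractions per group, summing to 1 (descending); empty input
#'   gives an empty table.
#' @export
mass_fractions <- function(weights, glycans, by = c("composition", "mass"),
                           mass_table = default_mass_table()) {
  by <- match.arg(by)
  w <- as_weights(weights)
  if (length(w) == 0L || sum(w) <= 0) return(stats::setNames(numeric(0), character(0)))
  key <- vapply(glycans[names(w)], function(g) {
    comp <- composition_of(g)
    if (by == "composition") format_composition(comp)
    else sprintf("%.2f", mass_of(comp, mass_table))
  }, character(1))
  tab <- tapply(w, key, sum) / sum(w)
  sort(stats::setNames(as.numeric(tab), names(tab)), decreasing = TRUE)
}

#' Isomer breakdown within one mass group
#'
#' @param weights Named weights, `solver_report`, or `glycan_solution`.
#' @param glycans The `glycan_library`.
#' @param group A composition string (e.g. `"Hex5HexNAc4Neu5Ac2"`).
#' @return Named fractions over the group members, summing to 1.
#' @export
isomer_breakdown <- function(weights, glycans, group) {
  w <- as_weights(weights)
  key <- vapply(glycans[names(w)],
                function(g) format_composition(composition_of(g)), character(1))
  target <- format_composition(parse_composition(group))
  w <- w[key == target]
  if (length(w) == 0L || sum(w) <= 0) {
    stop(sprintf("no reported weight in composition group '%s'", group),
         call. = FALSE)
  }
  sort(w / sum(w), decreasing = TRUE)
}

#' Write a fraction table to TSV
#' @param fractions A named numeric vector from one of the summary functions.
#' @param path Output TSV path.
#' @param label Column name for the grouping variable.
#' @return Invisibly, the data frame written.
#' @export
write_fractions <- function(fractions, path, label = "group") {
  df <- data.frame(names(fractions), as.numeric(fractions),
                   stringsAsFactors = FALSE)
  names(df) <- c(label, "fraction")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
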