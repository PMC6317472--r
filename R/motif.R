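# Motif matching on glycan trees.
#
# A motif is a glycan-shaped template whose anomericity/position fields may be
# "?" wildcards. It matches at a residue of a target glycan when the template
# maps, root-first, onto a connected subtree oriented toward the reducing end:
# residue classes equal exactly, non-wildcard linkage fields equal exactly,
# and wildcard template fields match anything. A "?" stored in the *glycan*
# only satisfies a wildcard template field — unknowns never silently satisfy a
# specific pattern.

#' Construct a motif
#'
#' @param pattern Condensed IUPAC text for the template (wildcards allowed in
#'   anomericity/position fields, e.g. `"Neu5Aca2-?Gal"`), or a `glycan`.
#' @param terminal_required If `TRUE`, every leaf residue of the template must
#'   map to a residue with no further non-reducing extension (no children).
#'   Used for epitopes that must sit at an antenna terminus and for
#'   exoglycosidase recognition sites.
#' @return A `motif` object.
#' @export
motif <- function(pattern, terminal_required = FALSE) {
  g <- if (inherits(pattern, "glycan")) pattern else parse_glycan(pattern)
  structure(list(root = g$root, text = write_glycan(g),
                 terminal = isTRUE(terminal_required)),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif> ", x$text, if (x$terminal) "  [terminal]", "\n", sep = "")
  invisible(x)
}

field_matches <- function(pattern_val, glycan_val) {
  if (is.na(pattern_val) || pattern_val == "?") return(TRUE)
  !is.na(glycan_val) && glycan_val == pattern_val
}

# Try to map pattern node `p` onto glycan node `n` (linkage of p's root is not
# constrained; the site may occur anywhere). Returns NULL on failure, else the
# list of glycan paths covered by the mapping. `path` locates `n` in the tree.
match_at <- function(n, p, terminal, path) {
  if (n$cls != p$cls) return(NULL)
  if (length(p$children) == 0L) {
    if (terminal && length(n$children) > 0L) return(NULL)
    return(list(path))
  }
  assign_children(n, p$children, seq_along(n$children), terminal, path,
                  covered = list(path))
}

# Injectively assign each pattern child to a distinct glycan child
# (backtracking; arities are tiny).
assign_children <- function(n, pkids, avail, terminal, path, covered) {
  if (length(pkids) == 0L) return(covered)
  p <- pkids[[1L]]
  for (i in avail) {
    cnode <- n$children[[i]]
    if (!field_matches(p$ano, cnode$ano)) next
    if (!field_matches(p$cpos, cnode$cpos)) next
    if (!field_matches(p$ppos, cnode$ppos)) next
    sub <- match_at(cnode, p, terminal, c(path, i))
    if (is.null(sub)) next
    res <- assign_children(n, pkids[-1L], setdiff(avail, i), terminal, path,
                           c(covered, sub))
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Find all sites at which a motif matches a glycan
#'
#' @param g A `glycan`.
#' @param m A `motif` (or pattern text, coerced with default options).
#' @return A list of match sites; each site has `site` (path of the residue
#'   matched by the template root: integer child indices from the reducing
#'   end) and `covered` (paths of all residues the template mapped onto).
#'   Zero-length list when the motif is absent.
#' @examples
#' g <- parse_glycan("Neu5Aca2-6Galb1-4GlcNAc")
#' length(match_motif(g, motif("Neu5Aca2-?Gal")))  # 1
#' length(match_motif(g, motif("Neu5Aca2-3Gal")))  # 0
#' @export
match_motif <- function(g, m) {
  stopifnot(inherits(g, "glycan"))
  if (!inherits(m, "motif")) m <- motif(m)
  sites <- list()
  walk_residues(g$root, function(node, path) {
    hit <- match_at(node, m$root, m$terminal, path)
    if (!is.null(hit)) {
      sites[[length(sites) + 1L]] <<- list(site = path, covered = hit)
    }
  })
  sites
}

#' Construct a lectin specificity
#'
#' A lectin is modelled as a set of (motif, binding score) entries; the
#' binding score is a dimensionless level derived from glycan-array data that
#' approximates how strongly the lectin binds glycans containing the motif.
#'
#' @param name Lectin name.
#' @param entries A list of `list(motif =, score =)` pairs; motifs may be
#'   given as text (then `terminal_required` applies) or `motif` objects.
#' @param terminal_required Default terminal anchoring for text motifs.
#' @return A `lectin` object.
#' @export
lectin <- function(name, entries, terminal_required = FALSE) {
  stopifnot(length(entries) >= 1L)
  entries <- lapply(entries, function(e) {
    m <- if (inherits(e$motif, "motif")) e$motif else
      motif(e$motif, terminal_required = isTRUE(e$terminal_required) ||
              (is.null(e$terminal_required) && terminal_required))
    score <- as.numeric(e$score)
    if (!is.finite(score) || score < 0) {
      stop("binding scores must be finite and >= 0", call. = FALSE)
    }
    list(motif = m, score = score)
  })
  structure(list(name = name, entries = entries), class = "lectin")
}

#' @export
print.lectin <- function(x, ...) {
  cat("<lectin> ", x$name, "\n", sep = "")
  for (e in x$entries) {
    cat(sprintf("  %-40s score %.3g%s\n", e$motif$text, e$score,
                if (e$motif$terminal) "  [terminal]" else ""))
  }
  invisible(x)
}

#' Predict the binding level of a lectin to a glycan
#'
#' Searches the glycan for each of the lectin's motifs and, where a motif is
#' present, uses its binding score to approximate the binding level. When
#' several motifs match, the default aggregation takes the maximum score
#' (binding is presence-driven); `"sum"` and `"site_count"` (score times
#' number of sites) modes are available for sensitivity analysis.
#'
#' @param g A `glycan`.
#' @param l A `lectin`.
#' @param mode Aggregation over matching motifs.
#' @return A non-negative score; 0 when no motif matches.
#' @export
predict_binding <- function(g, l, mode = c("max", "sum", "site_count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(l, "lectin"))
  total <- 0
  for (e in l$entries) {
    ns <- length(match_motif(g, e$motif))
    if (ns == 0L) next
    contrib <- switch(mode,
      max = e$score,
      sum = e$score,
      site_count = e$score * ns)
    total <- switch(mode,
      max = max(total, contrib),
      sum = total + contrib,
      site_count = total + contrib)
  }
  total
}

# Residue paths of `g` covered by at least one motif of any lectin; used to
# pick colinear-set representatives ("most monosaccharides evaluated by the
# lectins").
motif_coverage <- function(g, lectins) {
  covered <- character(0)
  for (l in lectins) {
    for (e in l$entries) {
      for (site in match_motif(g, e$motif)) {
        covered <- c(covered,
                     vapply(site$covered, paste, character(1), collapse = "."))
      }
    }
  }
  length(unique(covered))
}

#' Read a lectin specificity table from TSV
#'
#' Expected columns: `lectin`, `motif`, `binding_score`, optional
#' `terminal_required` (logical; default `FALSE`). One row per motif entry;
#' rows sharing a lectin name are pooled into one specificity.
#'
#' @param path TSV file path.
#' @return A named list of `lectin` objects, in first-appearance order.
#' @export
read_lectins <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("lectin", "motif", "binding_score")
  if (!all(need %in% names(df))) {
    stop("lectin table needs columns lectin, motif, binding_score", call. = FALSE)
  }
  if (is.null(df$terminal_required)) df$terminal_required <- FALSE
  out <- list()
  for (nm in unique(df$lectin)) {
    rows <- df[df$lectin == nm, , drop = FALSE]
    entries <- lapply(seq_len(nrow(rows)), function(i) {
      list(motif = motif(rows$motif[i],
                         terminal_required = isTRUE(as.logical(rows$terminal_required[i]))),
           score = rows$binding_score[i])
    })
    out[[nm]] <- lectin(nm, entries)
  }
  out
}

#' Write lectin specificities to TSV
#' @param lectins Named list of `lectin` objects.
#' @param path Output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_lectins <- function(lectins, path) {
  rows <- do.call(rbind, lapply(lectins, function(l) {
    data.frame(lectin = l$name,
               motif = vapply(l$entries, function(e) e$motif$text, character(1)),
               binding_score = vapply(l$entries, `[[`, numeric(1), "score"),
               terminal_required = vapply(l$entries, function(e) e$motif$terminal,
                                          logical(1)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
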