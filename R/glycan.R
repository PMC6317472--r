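#' @keywords internal
"_PACKAGE"

# Controlled vocabulary, ordered longest-first so tokenization is unambiguous
# (Neu5Ac before Glc etc.).
GLYCAN_RESIDUES <- c("Neu5Ac", "Neu5Gc", "GlcNAc", "GalNAc",
                     "Glc", "Gal", "Man", "Fuc", "Xyl")

# Residue class -> composition class used for mass grouping.
COMPOSITION_CLASS <- c(
  Glc = "Hex", Gal = "Hex", Man = "Hex",
  GlcNAc = "HexNAc", GalNAc = "HexNAc",
  Fuc = "dHex", Neu5Ac = "Neu5Ac", Neu5Gc = "Neu5Gc", Xyl = "Pent"
)
COMPOSITION_ORDER <- c("Hex", "HexNAc", "dHex", "Neu5Ac", "Neu5Gc", "Pent")

new_residue <- function(cls, ano = NA_character_, cpos = NA_character_,
                        ppos = NA_character_, children = list()) {
  list(cls = cls, ano = ano, cpos = cpos, ppos = ppos, children = children)
}

#' Parse a glycan structure from condensed IUPAC text
#'
#' Reads a glycan written in the condensed IUPAC dialect used throughout the
#' package: the reducing-end residue is rightmost, linkages are written as
#' e.g. `"b1-4"` or `"a2-6"` (anomericity, child anomeric carbon, parent
#' hydroxyl position), and branches are parenthesized immediately before
#' their parent residue, as in
#' `"Galb1-4GlcNAcb1-2Mana1-3(Galb1-4GlcNAcb1-2Mana1-6)Manb1-4GlcNAc"`.
#' Any of the anomericity or position fields may be `"?"` (unknown).
#'
#' @param text A single structure string.
#' @param id Optional identifier attached to the returned object.
#' @return A `glycan` object (a rooted, ordered tree of monosaccharides).
#' @examples
#' g <- parse_glycan("Neu5Aca2-6Galb1-4GlcNAc")
#' residue_count(g)
#' composition_of(g)
#' @seealso [write_glycan()], [canonical_form()], [composition_of()]
#' @export
parse_glycan <- function(text, id = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("glycan text must be a non-empty string", call. = FALSE)
  }
  s <- gsub("[[:space:]]", "", text)
  depth <- 0L
  for (i in seq_len(nchar(s))) {
    ch <- substr(s, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("unbalanced ')' at position %d in '%s'", i, text),
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("unbalanced '(' in '%s'", text), call. = FALSE)
  }
  root <- parse_subtree(s, expect_link = FALSE, start = 1L, full = text)
  structure(list(id = if (is.null(id)) s else id, root = root),
            class = "glycan")
}

# Parse `s` as a subtree whose root is the rightmost residue. When
# expect_link, `s` must end with that root's linkage to its parent.
# `start` is the 1-based offset of `s` within the full input, for errors.
parse_subtree <- function(s, expect_link, start, full) {
  ano <- cpos <- ppos <- NA_character_
  if (expect_link) {
    m <- regmatches(s, regexec("([ab?])([1-9?])-([1-9?])$", s))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("expected a linkage (e.g. 'b1-4') ending at position %d in '%s'",
                   start + nchar(s) - 1L, full), call. = FALSE)
    }
    ano <- m[2]; cpos <- m[3]; ppos <- m[4]
    s <- substr(s, 1L, nchar(s) - nchar(m[1]))
  }
  cls <- NA_character_
  for (res in GLYCAN_RESIDUES) {
    if (endsWith(s, res)) { cls <- res; break }
  }
  if (is.na(cls)) {
    stop(sprintf("unknown or malformed token ending at position %d in '%s'",
                 start + nchar(s) - 1L, full), call. = FALSE)
  }
  rest <- substr(s, 1L, nchar(s) - nchar(cls))
  children <- list()
  while (nzchar(rest)) {
    if (endsWith(rest, ")")) {
      # scan right-to-left for the matching '('
      depth <- 0L
      open <- NA_integer_
      for (i in rev(seq_len(nchar(rest)))) {
        ch <- substr(rest, i, i)
        if (ch == ")") depth <- depth + 1L
        if (ch == "(") {
          depth <- depth - 1L
          if (depth == 0L) { open <- i; break }
        }
      }
      inner <- substr(rest, open + 1L, nchar(rest) - 1L)
      if (!nzchar(inner)) {
        stop(sprintf("empty branch '()' at position %d in '%s'",
                     start + open - 1L, full), call. = FALSE)
      }
      children[[length(children) + 1L]] <-
        parse_subtree(inner, expect_link = TRUE, start = start + open, full = full)
      rest <- substr(rest, 1L, open - 1L)
    } else {
      # everything remaining is the unparenthesized chain child
      children[[length(children) + 1L]] <-
        parse_subtree(rest, expect_link = TRUE, start = start, full = full)
      rest <- ""
    }
  }
  # children were collected right-to-left; restore left-to-right written order
  new_residue(cls, ano, cpos, ppos, children = rev(children))
}

link_suffix <- function(node) {
  if (is.na(node$ano)) "" else paste0(node$ano, node$cpos, "-", node$ppos)
}

serialize_residue <- function(node) {
  out <- ""
  ch <- node$children
  if (length(ch) >= 1L) {
    out <- serialize_residue(ch[[1L]])
    if (length(ch) > 1L) {
      for (k in 2:length(ch)) {
        out <- paste0(out, "(", serialize_residue(ch[[k]]), ")")
      }
    }
  }
  paste0(out, node$cls, link_suffix(node))
}

#' Write a glycan back to condensed IUPAC text
#'
#' @param g A `glycan` object.
#' @return The structure string; `parse_glycan(write_glycan(g))` reproduces
#'   `g` up to branch order.
#' @export
write_glycan <- function(g) {
  stopifnot(inherits(g, "glycan"))
  serialize_residue(g$root)
}

canonicalize_residue <- function(node) {
  if (length(node$children)) {
    kids <- lapply(node$children, canonicalize_residue)
    keys <- vapply(kids, function(k) {
      # "?" positions sort after specific ones; then by subtree text
      pos <- if (is.na(k$ppos) || k$ppos == "?") "~" else k$ppos
      paste0(pos, "|", serialize_residue(k))
    }, character(1))
    node$children <- kids[order(keys, method = "radix")]
  }
  node
}

#' Canonical serialization of a glycan
#'
#' Deterministic structure string that is invariant under permutation of
#' sibling branches: siblings are sorted by parent-attachment position (with
#' `"?"` last), then by subtree text. Two glycans are structurally equal iff
#' their canonical forms are equal strings.
#'
#' @param g A `glycan` object.
#' @return A character scalar.
#' @export
canonical_form <- function(g) {
  stopifnot(inherits(g, "glycan"))
  serialize_residue(canonicalize_residue(g$root))
}

#' @export
print.glycan <- function(x, ...) {
  cat("<glycan> ", x$id, "\n  ", write_glycan(x),
      "\n  residues: ", residue_count(x),
      ", composition: ", format_composition(composition_of(x)), "\n", sep = "")
  invisible(x)
}

walk_residues <- function(node, fn, path = integer(0)) {
  fn(node, path)
  for (i in seq_along(node$children)) {
    walk_residues(node$children[[i]], fn, c(path, i))
  }
  invisible(NULL)
}

#' Number of monosaccharide residues in a glycan
#' @param g A `glycan` object.
#' @return Integer count.
#' @export
residue_count <- function(g) {
  stopifnot(inherits(g, "glycan"))
  n <- 0L
  walk_residues(g$root, function(node, path) n <<- n + 1L)
  n
}

#' Monosaccharide composition of a glycan
#'
#' Collapses residue identities to composition classes: Glc/Gal/Man count as
#' Hex, GlcNAc/GalNAc as HexNAc, Fuc as dHex, Xyl as Pent; the sialic acids
#' keep their own classes.
#'
#' @param g A `glycan` object.
#' @return A `glycan_composition`: a named integer vector over
#'   Hex, HexNAc, dHex, Neu5Ac, Neu5Gc, Pent.
#' @export
composition_of <- function(g) {
  stopifnot(inherits(g, "glycan"))
  counts <- stats::setNames(integer(length(COMPOSITION_ORDER)), COMPOSITION_ORDER)
  walk_residues(g$root, function(node, path) {
    cc <- COMPOSITION_CLASS[[node$cls]]
    counts[cc] <<- counts[cc] + 1L
  })
  structure(counts, class = "glycan_composition")
}

#' Format a composition as compact text
#'
#' @param x A `glycan_composition` (or named count vector).
#' @return A string such as `"Hex5HexNAc4Neu5Ac2"`; zero counts are omitted,
#'   class order is fixed so equal compositions format identically.
#' @export
format_composition <- function(x) {
  x <- x[COMPOSITION_ORDER]
  x[is.na(x)] <- 0L
  nz <- x > 0
  if (!any(nz)) return("empty")
  paste0(COMPOSITION_ORDER[nz], x[nz], collapse = "")
}

#' Parse compact composition text
#'
#' @param text A string such as `"Hex5HexNAc4Neu5Ac2"`.
#' @return A `glycan_composition`.
#' @export
parse_composition <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  counts <- stats::setNames(integer(length(COMPOSITION_ORDER)), COMPOSITION_ORDER)
  # match longest class names first (HexNAc before Hex, Neu5Ac/Gc intact)
  ord <- COMPOSITION_ORDER[order(-nchar(COMPOSITION_ORDER))]
  while (nzchar(s)) {
    hit <- FALSE
    for (cl in ord) {
      if (startsWith(s, cl)) {
        s <- substr(s, nchar(cl) + 1L, nchar(s))
        m <- regmatches(s, regexpr("^[0-9]+", s))
        n <- if (length(m)) as.integer(m) else 1L
        s <- sub("^[0-9]+", "", s)
        counts[cl] <- counts[cl] + n
        hit <- TRUE
        break
      }
    }
    if (!hit) stop(sprintf("cannot parse composition '%s'", text), call. = FALSE)
  }
  structure(counts, class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<composition>", format_composition(x), "\n")
  invisible(x)
}

#' Default monoisotopic residue-mass table
#'
#' Monoisotopic residue masses (Da) of underivatized glycans, plus the mass
#' of one water added for the free reducing end. Fully overridable: published
#' mass labels often follow a derivatization or adduct convention, in which
#' case candidates are better matched by composition or by a user-supplied
#' mass list with a tolerance.
#'
#' @param tolerance Matching tolerance in Da used by [restrict_candidates()].
#' @return A `mass_table` list with `masses`, `water` and `tolerance`.
#' @export
default_mass_table <- function(tolerance = 0.5) {
  structure(list(
    masses = c(Hex = 162.0528, HexNAc = 203.0794, dHex = 146.0579,
               Neu5Ac = 291.0954, Neu5Gc = 307.0903, Pent = 132.0423),
    water = 18.0106,
    tolerance = tolerance
  ), class = "mass_table")
}

#' Read a mass table from a YAML file
#'
#' Expected keys: `masses` (residue class -> Da), optional `water` and
#' `tolerance`; missing entries fall back to [default_mass_table()].
#'
#' @param path YAML file path.
#' @return A `mass_table`.
#' @export
read_mass_table <- function(path) {
  y <- yaml::read_yaml(path)
  mt <- default_mass_table()
  if (!is.null(y$masses)) {
    m <- unlist(y$masses)
    mt$masses[names(m)] <- m
  }
  if (!is.null(y$water)) mt$water <- as.numeric(y$water)
  if (!is.null(y$tolerance)) mt$tolerance <- as.numeric(y$tolerance)
  if (any(mt$masses <= 0) || mt$tolerance < 0) {
    stop("mass table requires positive masses and non-negative tolerance",
         call. = FALSE)
  }
  mt
}

#' Monoisotopic mass of a composition
#'
#' @param comp A `glycan_composition` (or a `glycan`, whose composition is
#'   taken first).
#' @param mass_table A `mass_table`; defaults to [default_mass_table()].
#' @return Mass in Da of the free reducing glycan: sum of residue masses plus
#'   one water.
#' @export
mass_of <- function(comp, mass_table = default_mass_table()) {
  if (inherits(comp, "glycan")) comp <- composition_of(comp)
  cls <- COMPOSITION_ORDER[comp[COMPOSITION_ORDER] > 0 &
                           !is.na(comp[COMPOSITION_ORDER])]
  missing_cls <- setdiff(cls, names(mass_table$masses))
  if (length(missing_cls)) {
    stop(sprintf("mass table lacks class(es): %s",
                 paste(missing_cls, collapse = ", ")), call. = FALSE)
  }
  sum(comp[cls] * mass_table$masses[cls]) + mass_table$water
}

#' Read a candidate glycan library from TSV
#'
#' Expects columns `glycan_id` and `structure` (condensed IUPAC text);
#' optional columns `composition` and `mass_label` are carried through as
#' attributes on each glycan.
#'
#' @param path TSV file path.
#' @return A `glycan_library`: a named list of `glycan` objects.
#' @export
read_glycan_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("glycan_id", "structure")
  if (!all(need %in% names(df))) {
    stop("glycan library needs columns glycan_id and structure", call. = FALSE)
  }
  if (anyDuplicated(df$glycan_id)) {
    stop("duplicate glycan_id in library", call. = FALSE)
  }
  gl <- lapply(seq_len(nrow(df)), function(i) {
    g <- parse_glycan(df$structure[i], id = df$glycan_id[i])
    if (!is.null(df$mass_label)) attr(g, "mass_label") <- df$mass_label[i]
    g
  })
  names(gl) <- df$glycan_id
  as_glycan_library(gl)
}

#' Assemble a glycan library from structures or glycan objects
#'
#' @param x A named character vector of structure strings, or a list of
#'   `glycan` objects (named, or carrying ids).
#' @return A `glycan_library`.
#' @export
as_glycan_library <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("g", seq_along(x))
    x <- Map(parse_glycan, x, ids)
    names(x) <- ids
  }
  stopifnot(all(vapply(x, inherits, logical(1), "glycan")))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- vapply(x, `[[`, character(1), "id")
  }
  if (anyDuplicated(names(x))) stop("duplicate glycan ids", call. = FALSE)
  structure(x, class = "glycan_library")
}

#' @export
print.glycan_library <- function(x, ...) {
  cat("<glycan_library> ", length(x), " candidate structures\n", sep = "")
  show <- utils::head(names(x), 5)
  for (id in show) cat("  ", id, ": ", write_glycan(x[[id]]), "\n", sep = "")
  if (length(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Write a glycan library to TSV
#'
#' @param lib A `glycan_library`.
#' @param path Output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_glycan_library <- function(lib, path) {
  df <- data.frame(
    glycan_id = names(lib),
    structure = vapply(lib, write_glycan, character(1)),
    composition = vapply(lib, function(g) format_composition(composition_of(g)),
                         character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
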