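# Exoglycosidase simulation by recognition/replace motif substitution. Where
# the recognition motif matches, the residues present in the recognition
# template but absent from the replace template are deleted — a substitution
# can only prune at the non-reducing side, which models the terminal,
# context-sensitive action of exoglycosidases.

# Pre-order deletion flags for the recognition template relative to the
# replace template. Stops with an error if replace is not a pruning of
# recognition.
prune_flags <- function(rec, kept) {
  if (is.null(kept)) {
    return(rep(TRUE, subtree_size(rec)))
  }
  if (rec$cls != kept$cls ||
      !identical(link_suffix(rec), link_suffix(kept))) {
    stop("replace motif must be a pruning of the recognition motif",
         call. = FALSE)
  }
  flags <- FALSE
  used <- rep(FALSE, length(rec$children))
  assigned <- vector("list", length(rec$children))
  for (rk in kept$children) {
    found <- FALSE
    for (i in seq_along(rec$children)) {
      ck <- rec$children[[i]]
      if (!used[i] && ck$cls == rk$cls &&
          identical(link_suffix(ck), link_suffix(rk))) {
        used[i] <- TRUE
        assigned[[i]] <- rk
        found <- TRUE
        break
      }
    }
    if (!found) {
      stop("replace motif must be a pruning of the recognition motif",
           call. = FALSE)
    }
  }
  for (i in seq_along(rec$children)) {
    flags <- c(flags, prune_flags(rec$children[[i]],
                                  if (used[i]) assigned[[i]] else NULL))
  }
  flags
}

subtree_size <- function(node) {
  1L + sum(vapply(node$children, subtree_size, integer(1)))
}

#' Construct an exoglycosidase specificity
#'
#' @param name Enzyme name.
#' @param recognition Condensed IUPAC text (or `motif`) for the site the
#'   enzyme recognizes, e.g. `"Neu5Aca2-3Gal"`.
#' @param replace Text (or `motif`) for what remains after cleavage, e.g.
#'   `"Gal"`. Must be a pruning of the recognition template at the
#'   non-reducing side; the substitution never adds residues.
#' @param terminal_required Whether the recognition site must be terminal
#'   (default `TRUE`: exoglycosidases act at non-reducing termini).
#' @return An `enzyme` object.
#' @export
enzyme <- function(name, recognition, replace, terminal_required = TRUE) {
  rec <- if (inherits(recognition, "motif")) recognition else
    motif(recognition, terminal_required = terminal_required)
  rep_ <- if (inherits(replace, "motif")) replace else motif(replace)
  flags <- prune_flags(rec$root, rep_$root)
  if (!any(flags)) {
    stop("recognition and replace motifs are identical; the enzyme would never act",
         call. = FALSE)
  }
  structure(list(name = name, recognition = rec, replace = rep_,
                 delete_flags = flags),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  cat("<enzyme> ", x$name, ": ", x$recognition$text, " -> ", x$replace$text,
      if (x$recognition$terminal) "  [terminal]", "\n", sep = "")
  invisible(x)
}

delete_at <- function(node, path) {
  if (length(path) == 1L) {
    node$children[[path]] <- NULL
    return(node)
  }
  node$children[[path[1L]]] <- delete_at(node$children[[path[1L]]], path[-1L])
  node
}

#' Digest a glycan with one exoglycosidase, to exhaustion
#'
#' Repeatedly finds recognition sites and deletes the residues present in the
#' recognition template but absent from the replace template, until no site
#' remains. Sites are processed outermost-first (deepest from the reducing
#' end, ties broken by branch order) so the fixed point is deterministic.
#' Digestion is all-or-none; no partial/kinetic modelling.
#'
#' @param g A `glycan`.
#' @param e An `enzyme`.
#' @return The digested `glycan` (same id). Applying the enzyme again is a
#'   no-op.
#' @examples
#' sial <- enzyme("broad sialidase", "Neu5Aca2-?Gal", "Gal")
#' g <- parse_glycan("Neu5Aca2-6Galb1-4GlcNAc")
#' write_glycan(apply_enzyme(g, sial))  # "Galb1-4GlcNAc"
#' @export
apply_enzyme <- function(g, e) {
  stopifnot(inherits(g, "glycan"), inherits(e, "enzyme"))
  max_iter <- residue_count(g) + 1L
  for (iter in seq_len(max_iter)) {
    sites <- match_motif(g, e$recognition)
    if (length(sites) == 0L) return(g)
    depth <- vapply(sites, function(s) length(s$site), integer(1))
    key <- vapply(sites, function(s) paste(s$site, collapse = "."), character(1))
    pick <- sites[[order(-depth, key)[1L]]]
    todel <- pick$covered[e$delete_flags]
    if (length(todel) == 0L) {
      stop(sprintf("enzyme '%s': substitution failed to reduce residue count",
                   e$name), call. = FALSE)
    }
    # delete deepest paths first so earlier deletions don't shift later ones
    ord <- order(-vapply(todel, length, integer(1)),
                 vapply(todel, paste, character(1), collapse = "."))
    before <- residue_count(g)
    for (p in todel[ord]) {
      if (length(p) == 0L) {
        stop(sprintf("enzyme '%s' would delete the reducing-end residue",
                     e$name), call. = FALSE)
      }
      g$root <- delete_at(g$root, p)
    }
    if (residue_count(g) >= before) {
      stop(sprintf("enzyme '%s': substitution failed to reduce residue count",
                   e$name), call. = FALSE)
    }
  }
  stop(sprintf("enzyme '%s' did not reach a fixed point", e$name), call. = FALSE)
}

#' Apply an ordered sequence of enzymes
#'
#' Each enzyme is applied to exhaustion before the next one starts, matching
#' sequential on-chip incubations. The empty sequence is the identity, and
#' order matters: a galactosidase before a sialidase leaves sialic-acid-capped
#' galactoses untouched.
#'
#' @param g A `glycan`.
#' @param enzymes A list of `enzyme` objects (possibly empty).
#' @return The digested `glycan`.
#' @export
apply_treatment <- function(g, enzymes) {
  for (e in enzymes) g <- apply_enzyme(g, e)
  g
}

#' Read an enzyme table from TSV
#'
#' Expected columns: `enzyme`, `recognition_motif`, `replace_motif`, optional
#' `terminal_required` (default `TRUE`).
#'
#' @param path TSV file path.
#' @return A named list of `enzyme` objects.
#' @export
read_enzymes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("enzyme", "recognition_motif", "replace_motif")
  if (!all(need %in% names(df))) {
    stop("enzyme table needs columns enzyme, recognition_motif, replace_motif",
         call. = FALSE)
  }
  if (is.null(df$terminal_required)) df$terminal_required <- TRUE
  if (anyDuplicated(df$enzyme)) stop("duplicate enzyme names", call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    enzyme(df$enzyme[i], df$recognition_motif[i], df$replace_motif[i],
           terminal_required = isTRUE(as.logical(df$terminal_required[i])))
  })
  names(out) <- df$enzyme
  out
}

#' Write enzyme specificities to TSV
#' @param enzymes Named list of `enzyme` objects.
#' @param path Output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_enzymes <- function(enzymes, path) {
  df <- data.frame(
    enzyme = vapply(enzymes, `[[`, character(1), "name"),
    recognition_motif = vapply(enzymes, function(e) e$recognition$text, character(1)),
    replace_motif = vapply(enzymes, function(e) e$replace$text, character(1)),
    terminal_required = vapply(enzymes, function(e) e$recognition$terminal, logical(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
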