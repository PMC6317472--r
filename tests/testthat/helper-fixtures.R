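# Shared fixtures and independent oracles.

# Disialylated (all alpha2-6) biantennary N-glycan, 11 residues.
BIANTENNARY_A26 <- paste0(
  "Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3",
  "(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6)",
  "Manb1-4GlcNAcb1-4GlcNAc"
)

# Same structure with one arm alpha2-3 sialylated.
BIANTENNARY_MIXED <- paste0(
  "Neu5Aca2-3Galb1-4GlcNAcb1-2Mana1-3",
  "(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6)",
  "Manb1-4GlcNAcb1-4GlcNAc"
)

# Independent NNLS oracle: exhaustive enumeration over column subsets. The
# optimum of min ||Ca - d||, a >= 0 restricts, on its support, to the
# unconstrained least-squares solution (KKT stationarity), and that solution
# is feasible; so the best feasible subset solution is the NNLS optimum.
nnls_enum_oracle <- function(C, d) {
  M <- ncol(C)
  best <- rep(0, M)
  best_rss <- sum(d^2)  # empty support
  for (k in seq_len(M)) {
    for (S in utils::combn(M, k, simplify = FALSE)) {
      cs <- C[, S, drop = FALSE]
      coefs <- tryCatch(qr.coef(qr(cs), d), error = function(e) NULL)
      if (is.null(coefs) || anyNA(coefs)) next
      if (any(coefs < -1e-9)) next
      rss <- sum((cs %*% coefs - d)^2)
      if (rss < best_rss - 1e-12) {
        best_rss <- rss
        best <- rep(0, M)
        best[S] <- pmax(coefs, 0)
      }
    }
  }
  best
}

# Randomly permute sibling order everywhere in a glycan (canonical_form must
# be invariant under this).
shuffle_siblings <- function(g) {
  shuf <- function(node) {
    if (length(node$children) > 1L) {
      node$children <- sample(node$children)
    }
    node$children <- lapply(node$children, shuf)
    node
  }
  g$root <- shuf(g$root)
  g
}

# Count residues of a class by brute-force walk (oracle for 1-residue motifs).
count_residues_of_class <- function(g, cls) {
  n <- 0L
  walker <- function(node) {
    if (node$cls == cls) n <<- n + 1L
    for (ch in node$children) walker(ch)
  }
  walker(g$root)
  n
}

# Small fixed library exercising the main structure space.
fixture_library <- function() {
  as_glycan_library(c(
    bi_a26 = BIANTENNARY_A26,
    bi_mixed = BIANTENNARY_MIXED,
    bi_asialo = nglycan_structure(list(list(gal = "b4", sia = "none"),
                                       list(gal = "b4", sia = "none"))),
    tri = nglycan_structure(list(list(gal = "b4", sia = "a3"),
                                 list(gal = "b4", sia = "a6"),
                                 list(gal = "b3", sia = "none"))),
    tetra = nglycan_structure(list(list(gal = "b4", sia = "a3"),
                                   list(gal = "b4", sia = "a6"),
                                   list(gal = "b4", sia = "a3"),
                                   list(gal = "b4", sia = "a6"))),
    ocore1 = "Neu5Aca2-3Galb1-3GalNAc",
    man = "Man"
  ))
}

# Minimal hand-built response_matrix for normalization tests.
toy_response_matrix <- function(C, lectins_per_row) {
  channels <- data.frame(lectin = lectins_per_row,
                         condition = paste0("c", seq_along(lectins_per_row)),
                         stringsAsFactors = FALSE)
  channels$label <- paste(channels$lectin, channels$condition, sep = "|")
  rownames(C) <- channels$label
  structure(list(C = C, channels = channels, normalized = FALSE),
            class = "response_matrix")
}
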