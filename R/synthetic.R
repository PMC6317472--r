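# Seeded synthetic-data generation. The generator draws N-glycans from the
# biosynthetic grammar the lectin/enzyme repertoire is designed to
# discriminate — bi/tri/tetra-antennary structures with alpha2-3/alpha2-6
# sialic acids, beta1-3/beta1-4 galactoses, core fucose and bisecting GlcNAc —
# plus sialylated O-core1 structures, and simulates replicate spot-level
# fluorescence so the whole pipeline is testable without any experimental
# input.

#' Simulation settings
#'
#' @param library_size Number of unique candidate structures to generate.
#' @param antenna_range Min/max antennae of generated N-glycans.
#' @param p_oglycan Probability a generated structure is an O-core1 glycan.
#' @param p_galactose Per-arm probability an antenna carries a galactose.
#' @param p_gal_b13 Probability a galactose is beta1-3 linked (else beta1-4).
#' @param p_sialylated Per-arm probability a galactose is sialylated.
#' @param p_sia_a23 Probability a sialic acid is alpha2-3 linked (else
#'   alpha2-6).
#' @param p_core_fucose Probability of core fucose.
#' @param p_bisecting Probability of bisecting GlcNAc.
#' @param support_size Number of glycans in the simulated true mixture.
#' @param noise_sd Spot-level noise as a fraction of the fluorescence scale.
#' @param n_spots,n_arrays Replicate structure per channel.
#' @param signal_scale Fluorescence units corresponding to normalized
#'   binding 1.
#' @param background Mean local background (fluorescence units).
#' @param seed Integer seed; fixes every random draw.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(library_size = 50, antenna_range = c(2, 4),
                            p_oglycan = 0.1, p_galactose = 0.9,
                            p_gal_b13 = 0.15, p_sialylated = 0.75,
                            p_sia_a23 = 0.5, p_core_fucose = 0.3,
                            p_bisecting = 0.15, support_size = 4,
                            noise_sd = 0.05, n_spots = 6, n_arrays = 3,
                            signal_scale = 10000, background = 500,
                            seed = 1) {
  probs <- c(p_oglycan, p_galactose, p_gal_b13, p_sialylated, p_sia_a23,
             p_core_fucose, p_bisecting)
  stopifnot(all(probs >= 0 & probs <= 1), noise_sd >= 0,
            antenna_range[1] >= 1, antenna_range[2] <= 4,
            n_spots >= 1, n_arrays >= 1, library_size >= 1, support_size >= 1)
  structure(list(library_size = as.integer(library_size),
                 antenna_range = as.integer(antenna_range),
                 p_oglycan = p_oglycan, p_galactose = p_galactose,
                 p_gal_b13 = p_gal_b13, p_sialylated = p_sialylated,
                 p_sia_a23 = p_sia_a23, p_core_fucose = p_core_fucose,
                 p_bisecting = p_bisecting,
                 support_size = as.integer(support_size),
                 noise_sd = noise_sd, n_spots = as.integer(n_spots),
                 n_arrays = as.integer(n_arrays),
                 signal_scale = signal_scale, background = background,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

arm_structure <- function(gal, sia) {
  s <- "GlcNAc"
  if (gal != "none") s <- paste0("Galb1-", if (gal == "b3") "3" else "4", s)
  if (sia != "none" && gal != "none") {
    s <- paste0("Neu5Aca2-", if (sia == "a3") "3" else "6", s)
  }
  s
}

#' Assemble an N-glycan structure string from arm descriptions
#'
#' Antennae attach in biosynthetic order: beta1-2 on the alpha1-3 mannose,
#' beta1-2 on the alpha1-6 mannose, then beta1-4 (alpha1-3 arm) and beta1-6
#' (alpha1-6 arm).
#'
#' @param arms List of up to 4 `list(gal =, sia =)` entries with
#'   `gal` in `"none"/"b3"/"b4"` and `sia` in `"none"/"a3"/"a6"`.
#' @param core_fucose,bisecting Core modification flags.
#' @return A condensed IUPAC structure string.
#' @export
nglycan_structure <- function(arms, core_fucose = FALSE, bisecting = FALSE) {
  n <- length(arms)
  stopifnot(n >= 1L, n <= 4L)
  a <- lapply(arms, function(x) arm_structure(x$gal, x$sia))
  man3 <- paste0(a[[1]], "b1-2",
                 if (n >= 3) paste0("(", a[[3]], "b1-4)") else "",
                 "Mana1-3")
  man6 <- if (n >= 2) {
    paste0(a[[2]], "b1-2",
           if (n >= 4) paste0("(", a[[4]], "b1-6)") else "",
           "Mana1-6")
  } else "Mana1-6"
  paste0(man3, "(", man6, ")",
         if (bisecting) "(GlcNAcb1-4)" else "",
         "Manb1-4GlcNAcb1-4",
         if (core_fucose) "(Fuca1-6)" else "",
         "GlcNAc")
}

#' Assemble an O-core1 structure string
#'
#' @param sia3 Sialylate the core galactose alpha2-3.
#' @param sia6 Sialylate the core GalNAc alpha2-6.
#' @return A condensed IUPAC structure string.
#' @export
ocore1_structure <- function(sia3 = FALSE, sia6 = FALSE) {
  gal <- if (sia3) "Neu5Aca2-3Galb1-3" else "Galb1-3"
  paste0(gal, if (sia6) "(Neu5Aca2-6)" else "", "GalNAc")
}

random_arm <- function(spec) {
  gal <- if (stats::runif(1) < spec$p_galactose) {
    if (stats::runif(1) < spec$p_gal_b13) "b3" else "b4"
  } else "none"
  sia <- if (gal != "none" && stats::runif(1) < spec$p_sialylated) {
    if (stats::runif(1) < spec$p_sia_a23) "a3" else "a6"
  } else "none"
  list(gal = gal, sia = sia)
}

#' Generate a synthetic candidate glycan library
#'
#' Draws unique (by canonical form) structures from the biosynthetic grammar
#' until the requested size — or the grammar's maximum under the settings — is
#' reached. Fully determined by `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return A `glycan_library` with ids `g001`, `g002`, ...
#' @export
generate_library <- function(spec = simulation_spec()) {
  set.seed(spec$seed)
  seen <- character(0)
  structures <- character(0)
  max_tries <- spec$library_size * 400L
  tries <- 0L
  while (length(structures) < spec$library_size && tries < max_tries) {
    tries <- tries + 1L
    s <- if (stats::runif(1) < spec$p_oglycan) {
      ocore1_structure(sia3 = stats::runif(1) < spec$p_sia_a23,
                       sia6 = stats::runif(1) < 0.5)
    } else {
      rng <- seq(spec$antenna_range[1], spec$antenna_range[2])
      n <- rng[sample.int(length(rng), 1L)]
      arms <- replicate(n, random_arm(spec), simplify = FALSE)
      nglycan_structure(arms,
                        core_fucose = stats::runif(1) < spec$p_core_fucose,
                        bisecting = stats::runif(1) < spec$p_bisecting)
    }
    key <- canonical_form(parse_glycan(s))
    if (key %in% seen) next
    seen <- c(seen, key)
    structures <- c(structures, s)
  }
  ids <- sprintf("g%03d", seq_along(structures))
  as_glycan_library(stats::setNames(structures, ids))
}

#' Built-in demonstration lectin set
#'
#' Seven lectins whose motifs mirror the specificities of a standard
#' profiling panel: sialic-acid linkage (SNA alpha2-6, MAL alpha2-3),
#' exposed galactose linkage (ECL beta1-4, BPL beta1-3 and the O-core1
#' disaccharide), exposed GlcNAc (GSL-II), the trimannosyl core (ConA), and
#' internal LacNAc (DSL). Binding scores are illustrative levels on a 0-1
#' scale, in the spirit of scores derived from glycan-array data.
#'
#' @return A named list of `lectin` objects.
#' @export
demo_lectins <- function() {
  list(
    SNA = lectin("SNA", list(list(motif = "Neu5Aca2-6Gal", score = 0.90))),
    MAL = lectin("MAL", list(list(motif = "Neu5Aca2-3Gal", score = 0.80))),
    ECL = lectin("ECL", list(list(motif = "Galb1-4GlcNAc", score = 0.85,
                                  terminal_required = TRUE))),
    BPL = lectin("BPL", list(list(motif = "Galb1-3GlcNAc", score = 0.70,
                                  terminal_required = TRUE),
                             list(motif = "Galb1-3GalNAc", score = 0.75,
                                  terminal_required = TRUE))),
    GSL = lectin("GSL", list(list(motif = "GlcNAc", score = 0.75,
                                  terminal_required = TRUE))),
    ConA = lectin("ConA", list(list(motif = "Mana1-?Man", score = 0.60))),
    DSL = lectin("DSL", list(list(motif = "Galb1-4GlcNAc", score = 0.50)))
  )
}

#' Built-in demonstration enzyme set
#'
#' Linkage-specific alpha2-3 sialidase, broad sialidase, and beta1-3 /
#' beta1-4 galactosidases (all terminal-acting), plus a core-1
#' beta1-3 galactosidase acting on O-glycans.
#'
#' @return A named list of `enzyme` objects.
#' @export
demo_enzymes <- function() {
  list(
    sialidase_a23 = enzyme("sialidase_a23", "Neu5Aca2-3Gal", "Gal"),
    sialidase_broad = enzyme("sialidase_broad", "Neu5Aca2-?Gal", "Gal"),
    gal_b13 = enzyme("gal_b13", "Galb1-3GlcNAc", "GlcNAc"),
    gal_b14 = enzyme("gal_b14", "Galb1-4GlcNAc", "GlcNAc"),
    gal_b13_core1 = enzyme("gal_b13_core1", "Galb1-3GalNAc", "GalNAc")
  )
}

#' Built-in demonstration panels
#'
#' `"sialidase"`: untreated plus two sialidase rounds across all seven demo
#' lectins (3 x 7 = 21 channels), probing sialic-acid linkage and little
#' else. `"extended"` adds galactosidase rounds after broad desialylation
#' (6 x 7 = 42 channels) to expose galactose linkage and branch structure.
#'
#' @param design Panel design name.
#' @return A `gmap_panel`.
#' @export
demo_panel <- function(design = c("sialidase", "extended")) {
  design <- match.arg(design)
  enz <- demo_enzymes()
  conds <- list(
    untreated = character(0),
    sialidase_a23 = "sialidase_a23",
    sialidase_broad = "sialidase_broad"
  )
  if (design == "extended") {
    conds$desial_gal_b13 <- c("sialidase_broad", "gal_b13")
    conds$desial_gal_b14 <- c("sialidase_broad", "gal_b14")
    conds$desial_gal_both <- c("sialidase_broad", "gal_b13", "gal_b14")
  }
  gmap_panel(conds, demo_lectins(), enz)
}

#' Draw a true mixture over a candidate library
#'
#' Samples `spec$support_size` glycans and positive weights (uniform on
#' `[0.25, 1]`, normalized to sum 1) such that the mixture is unambiguously
#' resolvable by the panel, in the solver's own sense of ambiguity: the
#' colinearity-filtered support columns are linearly independent, the
#' nonnegative least-squares fit of the clean mixture response returns
#' exactly the true weights, and excluding any support member admits no
#' acceptable alternative fit (one within the R-squared window using at most
#' the allowed additional glycans). This emulates an experiment designed so
#' that each mixture component is distinguishable — the regime in which
#' deconvolution is meaningful; a component reproducible by a small
#' combination of other candidates is unresolvable for any method on these
#' data, and such mixtures are reported with spread inclusion frequencies
#' rather than recovered exactly.
#'
#' @param rm A normalized `response_matrix` for the library.
#' @param glycans The `glycan_library`.
#' @param spec A [simulation_spec()]; uses `support_size` and `seed`.
#' @param panel Optional `gmap_panel` for colinearity-representative scoring.
#' @param config The [solver_config()] defining the ambiguity rule
#'   (R-squared window and additional-glycan allowance).
#' @return A named weight vector over the support.
#' @export
simulate_truth <- function(rm, glycans, spec = simulation_spec(),
                           panel = NULL, config = solver_config()) {
  set.seed(spec$seed + 1L)
  flt <- filter_colinear(rm, glycans, panel)
  C <- flt$matrix$C
  pool <- colnames(C)
  k <- min(spec$support_size, length(pool))
  for (try in 1:500) {
    ids <- sort(sample(pool, k))
    sub <- C[, ids, drop = FALSE]
    if (qr(sub)$rank < k) next
    w <- stats::runif(k, 0.25, 1)
    w <- w / sum(w)
    d <- as.numeric(sub %*% w)
    full <- nnls_fit(C, d, config$positive_weight_epsilon)
    a_true <- stats::setNames(numeric(ncol(C)), pool)
    a_true[ids] <- w
    if (max(abs(full$weights - a_true)) > 1e-8) next
    ambiguous <- any(vapply(seq_len(k), function(j) {
      alt <- refit_excluding(C, d, ids[j], config$positive_weight_epsilon)
      extra <- setdiff(alt$predicted, ids)
      alt$r2 >= full$r2 - config$r2_window &&
        length(extra) <= config$max_additional_glycans
    }, logical(1)))
    if (!ambiguous) return(stats::setNames(w, ids))
  }
  stop("could not draw a mixture resolvable by this panel; library too colinear",
       call. = FALSE)
}

#' Simulate spot-level observations for a known mixture
#'
#' The clean response is `d_clean = C %*% a_true` on the normalized model
#' scale; each channel is rendered as `n_spots x n_arrays` replicate spots at
#' `background + signal_scale * d_clean` with additive Gaussian noise of sd
#' `noise_sd * signal_scale`.
#'
#' @param rm A normalized `response_matrix`.
#' @param a_true Named non-negative weights with support in the library.
#' @param spec A [simulation_spec()].
#' @param protein Protein label stamped on the records.
#' @return A spot-record data frame with attribute `d_clean`.
#' @export
simulate_observation <- function(rm, a_true, spec = simulation_spec(),
                                 protein = "synthetic") {
  stopifnot(inherits(rm, "response_matrix"), all(a_true >= 0))
  unknown <- setdiff(names(a_true), colnames(rm$C))
  if (length(unknown)) {
    stop(sprintf("a_true contains unknown id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  set.seed(spec$seed + 2L)
  a <- stats::setNames(numeric(ncol(rm$C)), colnames(rm$C))
  a[names(a_true)] <- a_true
  d_clean <- as.numeric(rm$C %*% a)
  ch <- rm$channels
  n_per_channel <- spec$n_spots * spec$n_arrays
  rows <- vector("list", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    noise <- if (spec$noise_sd > 0) {
      stats::rnorm(n_per_channel, 0, spec$noise_sd * spec$signal_scale)
    } else numeric(n_per_channel)
    rows[[i]] <- data.frame(
      slide_id = "s1",
      array_id = rep(seq_len(spec$n_arrays), each = spec$n_spots),
      spot_id = rep(seq_len(spec$n_spots), times = spec$n_arrays),
      protein = protein,
      lectin = ch$lectin[i],
      condition = ch$condition[i],
      median_signal = spec$background + spec$signal_scale * d_clean[i] + noise,
      mean_background = spec$background,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "d_clean") <- stats::setNames(d_clean, ch$label)
  out
}

#' Reduce simulated spots back to the model scale
#'
#' Runs [reduce_spot_table()] and divides by the simulation's fluorescence
#' scale, returning an observed vector directly comparable to the normalized
#' model matrix (ground truth is defined on that scale).
#'
#' @param records Spot records from [simulate_observation()].
#' @param panel The `gmap_panel`.
#' @param spec The [simulation_spec()] that produced the records.
#' @return An `observed_vector` flagged as normalized.
#' @export
spots_to_model_scale <- function(records, panel, spec) {
  red <- reduce_spot_table(records, panel)
  stopifnot(length(red) == 1L)
  observed_vector(as.numeric(red[[1L]]) / spec$signal_scale, panel,
                  normalized = TRUE)
}

#' Recovery metrics against a known truth
#'
#' @param a_true Named true weights (the support is the truth set).
#' @param report A `solver_report` or `glycan_solution` (the reported set).
#' @return List with `precision`, `recall`, and `weight_correlation`
#'   (Pearson, over the union of supports, zeros filled; defined as 1 when
#'   both weight vectors are identical and otherwise NA if degenerate).
#' @export
recovery_metrics <- function(a_true, report) {
  w <- as_weights(report)
  truth <- names(a_true)[a_true > 0]
  found <- names(w)[w > 0]
  precision <- if (length(found) == 0L) 0 else
    length(intersect(found, truth)) / length(found)
  recall <- if (length(truth) == 0L) 1 else
    length(intersect(found, truth)) / length(truth)
  ids <- union(truth, found)
  vt <- stats::setNames(numeric(length(ids)), ids)
  vt[truth] <- a_true[truth]
  vf <- stats::setNames(numeric(length(ids)), ids)
  vf[intersect(found, ids)] <- w[intersect(found, ids)]
  wc <- if (max(abs(vt - vf)) < 1e-12) 1
        else if (length(ids) < 2L || stats::sd(vt) == 0 || stats::sd(vf) == 0)
          NA_real_
        else stats::cor(vt, vf)
  list(precision = precision, recall = recall, weight_correlation = wc)
}

#' End-to-end synthetic recovery benchmark
#'
#' Generates a library, draws a true mixture, simulates replicate spot-level
#' observations, reduces and deconvolves them, and scores recovery — the full
#' pipeline under known ground truth.
#'
#' @param spec A [simulation_spec()].
#' @param panel A `gmap_panel`; default the extended demo panel, whose
#'   galactosidase rounds give the discrimination the truth-drawing step
#'   requires.
#' @param config A [solver_config()].
#' @return List with `metrics`, `solution` (the `glycan_solution`), `a_true`,
#'   `library`, and `spec`.
#' @export
recovery_benchmark <- function(spec = simulation_spec(),
                               panel = demo_panel("extended"),
                               config = solver_config()) {
  lib <- generate_library(spec)
  rm <- build_model_matrix(lib, panel)
  a_true <- simulate_truth(rm, lib, spec, panel, config)
  spots <- simulate_observation(rm, a_true, spec)
  d <- spots_to_model_scale(spots, panel, spec)
  sol <- glycan_solve(lib, panel, d, config = config)
  list(metrics = recovery_metrics(a_true, sol), solution = sol,
       a_true = a_true, library = lib, spec = spec)
}
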