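test_that("motif matching respects linkage specificity, wildcards, and termini", {
  g <- parse_glycan(BIANTENNARY_A26)
  expect_length(match_motif(g, motif("Neu5Aca2-3Gal")), 0L)
  expect_length(match_motif(g, motif("Neu5Aca2-?Gal")), 2L)
  expect_length(match_motif(g, motif("Neu5Aca2-6Gal")), 2L)

  desial <- apply_enzyme(g, enzyme("sial", "Neu5Aca2-?Gal", "Gal"))
  expect_length(match_motif(desial, motif("Galb1-4GlcNAc",
                                          terminal_required = TRUE)), 2L)
  # capped galactose is not terminal
  expect_length(match_motif(g, motif("Galb1-4GlcNAc",
                                     terminal_required = TRUE)), 0L)
  # but is still present as an internal epitope
  expect_length(match_motif(g, motif("Galb1-4GlcNAc")), 2L)
})

test_that("unknown linkage in a glycan never satisfies a specific pattern", {
  g <- parse_glycan("Neu5Ac?2-?Galb1-4GlcNAc")
  expect_length(match_motif(g, motif("Neu5Aca2-6Gal")), 0L)
  expect_length(match_motif(g, motif("Neu5Aca2-3Gal")), 0L)
  expect_length(match_motif(g, motif("Neu5Ac?2-?Gal")), 1L)
})

test_that("single-residue wildcard-free motifs count residues of that class", {
  lib <- fixture_library()
  for (g in lib) {
    for (cls in c("Gal", "GlcNAc", "Man", "Neu5Ac", "Fuc")) {
      expect_equal(length(match_motif(g, motif(cls))),
                   count_residues_of_class(g, cls),
                   info = paste(g$id, cls))
    }
  }
})

test_that("binding prediction aggregates motif scores as configured", {
  g <- parse_glycan(BIANTENNARY_A26)
  one <- lectin("L1", list(list(motif = "Neu5Aca2-6Gal", score = 0.8)))
  expect_equal(predict_binding(g, one), 0.8)

  none <- lectin("L0", list(list(motif = "Neu5Aca2-3Gal", score = 0.8)))
  expect_equal(predict_binding(g, none), 0)

  two <- lectin("L2", list(list(motif = "Neu5Aca2-6Gal", score = 0.8),
                           list(motif = "Galb1-4GlcNAc", score = 0.3)))
  expect_equal(predict_binding(g, two), 0.8)
  expect_equal(predict_binding(g, two, mode = "sum"), 1.1)
  expect_equal(predict_binding(g, two, mode = "site_count"), 2 * 0.8 + 2 * 0.3)
})

test_that("adding a matching entry never decreases the max-mode score", {
  lib <- fixture_library()
  base_entries <- list(list(motif = "Galb1-4GlcNAc", score = 0.5))
  extra_entries <- c(base_entries,
                     list(list(motif = "Neu5Aca2-?Gal", score = 0.9)))
  l1 <- lectin("base", base_entries)
  l2 <- lectin("ext", extra_entries)
  for (g in lib) {
    expect_gte(predict_binding(g, l2), predict_binding(g, l1))
  }
})

test_that("enzymes respect linkage specificity and order of application", {
  g <- parse_glycan(BIANTENNARY_A26)
  s23 <- enzyme("s23", "Neu5Aca2-3Gal", "Gal")
  broad <- enzyme("broad", "Neu5Aca2-?Gal", "Gal")
  g14 <- enzyme("g14", "Galb1-4GlcNAc", "GlcNAc")

  # alpha2-3 sialidase leaves the all-alpha2-6 glycan untouched
  expect_equal(canonical_form(apply_enzyme(g, s23)), canonical_form(g))
  # broad sialidase removes both sialic acids
  expect_equal(format_composition(composition_of(apply_enzyme(g, broad))),
               "Hex5HexNAc4")
  # galactosidase alone is blocked by the sialic-acid caps
  expect_equal(canonical_form(apply_enzyme(g, g14)), canonical_form(g))
  # sialidase then galactosidase strips both layers
  expect_equal(format_composition(composition_of(
    apply_treatment(g, list(broad, g14)))), "Hex3HexNAc4")
  # empty treatment is the identity
  expect_equal(canonical_form(apply_treatment(g, list())), canonical_form(g))
})

test_that("digestion is idempotent and never adds residues", {
  lib <- fixture_library()
  enzymes <- demo_enzymes()
  for (g in lib) {
    for (e in enzymes) {
      once <- apply_enzyme(g, e)
      expect_lte(residue_count(once), residue_count(g))
      if (length(match_motif(g, e$recognition)) > 0L) {
        expect_lt(residue_count(once), residue_count(g))
      }
      expect_equal(canonical_form(apply_enzyme(once, e)), canonical_form(once),
                   info = paste(g$id, e$name))
    }
  }
})

test_that("invalid recognition/replace pairs are rejected", {
  expect_error(enzyme("bad", "Gal", "Galb1-4GlcNAc"), "pruning")
  expect_error(enzyme("noop", "Galb1-4GlcNAc", "Galb1-4GlcNAc"), "never act")
  expect_error(enzyme("swap", "Neu5Aca2-3Gal", "Man"), "pruning")
})

test_that("lectin and enzyme tables round-trip through TSV", {
  lpath <- withr::local_tempfile(fileext = ".tsv")
  write_lectins(demo_lectins(), lpath)
  lecs <- read_lectins(lpath)
  expect_equal(names(lecs), names(demo_lectins()))
  expect_equal(lecs$BPL$entries[[2]]$score, 0.75)
  expect_true(lecs$ECL$entries[[1]]$motif$terminal)

  epath <- withr::local_tempfile(fileext = ".tsv")
  write_enzymes(demo_enzymes(), epath)
  enz <- read_enzymes(epath)
  expect_equal(names(enz), names(demo_enzymes()))
  expect_equal(enz$sialidase_broad$recognition$text, "Neu5Aca2-?Gal")
})
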