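test_that("core typing recognizes N-glycan antennarity, flags, and O-cores", {
  expect_equal(as.character(core_type_of(parse_glycan(BIANTENNARY_A26))),
               "N-biantennary")
  tri <- parse_glycan(nglycan_structure(list(
    list(gal = "b4", sia = "a3"), list(gal = "b4", sia = "a6"),
    list(gal = "b3", sia = "none"))))
  expect_equal(as.character(core_type_of(tri)), "N-triantennary")
  tetra <- parse_glycan(nglycan_structure(rep(list(list(gal = "b4", sia = "none")), 4)))
  expect_equal(as.character(core_type_of(tetra)), "N-tetraantennary")

  # bisecting GlcNAc is a flag, not an antenna; core fucose likewise
  bis <- parse_glycan(nglycan_structure(list(
    list(gal = "b4", sia = "none"), list(gal = "b4", sia = "none")),
    core_fucose = TRUE, bisecting = TRUE))
  ct <- core_type_of(bis)
  expect_equal(as.character(ct), "N-biantennary")
  expect_true(attr(ct, "bisecting"))
  expect_true(attr(ct, "core_fucose"))

  expect_equal(as.character(core_type_of(parse_glycan("Neu5Aca2-3Galb1-3GalNAc"))),
               "O-core1")
  expect_equal(as.character(core_type_of(
    parse_glycan("Galb1-3(GlcNAcb1-6)GalNAc"))), "O-core2")
  expect_equal(as.character(core_type_of(parse_glycan("Man"))), "other")
})

test_that("every generated glycan receives exactly one known core label", {
  lib <- generate_library(simulation_spec(library_size = 40, seed = 9))
  known <- c("N-monoantennary", "N-biantennary", "N-triantennary",
             "N-tetraantennary", "N-core", "O-core1", "O-core2", "other")
  labels <- vapply(lib, function(g) as.character(core_type_of(g)), character(1))
  expect_true(all(labels %in% known))
})

test_that("core fractions are weight-proportional and sum to one", {
  lib <- fixture_library()
  w <- c(bi_a26 = 0.5, bi_mixed = 0.3, tri = 0.2)
  fr <- core_fractions(w, lib)
  expect_equal(unname(fr["N-biantennary"]), 0.8)
  expect_equal(unname(fr["N-triantennary"]), 0.2)
  expect_equal(sum(fr), 1)
  expect_equal(core_fractions(c(bi_a26 = 1), lib),
               c("N-biantennary" = 1))
  expect_error(core_fractions(c(bi_a26 = 0), lib), "positive weight")
})

test_that("terminal features are counted per antenna site", {
  lib <- fixture_library()
  # both arms alpha2-6
  fr <- terminal_feature_fractions(c(bi_a26 = 1), lib)
  expect_equal(unname(fr["Neu5Ac a2-6"]), 1)
  # one alpha2-3 arm, one alpha2-6 arm
  fr2 <- terminal_feature_fractions(c(bi_mixed = 1), lib)
  expect_equal(unname(fr2[c("Neu5Ac a2-3", "Neu5Ac a2-6")]), c(0.5, 0.5))
  # equal-weight mix of the two
  fr3 <- terminal_feature_fractions(c(bi_a26 = 0.5, bi_mixed = 0.5), lib)
  expect_equal(unname(fr3[c("Neu5Ac a2-6", "Neu5Ac a2-3")]), c(0.75, 0.25))
  expect_equal(sum(fr3), 1)
  # presence/absence accounting differs for the mixed glycan
  fr4 <- terminal_feature_fractions(c(bi_mixed = 1), lib, per_site = FALSE)
  expect_equal(unname(fr4[c("Neu5Ac a2-3", "Neu5Ac a2-6")]), c(0.5, 0.5))
})

test_that("terminal features honor the core filter and reject non-terminal detectors", {
  lib <- fixture_library()
  w <- c(bi_a26 = 0.6, ocore1 = 0.4)
  fr <- terminal_feature_fractions(w, lib, core = "N-biantennary")
  expect_equal(unname(fr["Neu5Ac a2-6"]), 1)
  expect_error(terminal_feature_fractions(w, lib, core = "N-tetraantennary"),
               "core filter")
  expect_error(
    terminal_feature_fractions(w, lib,
                               features = list(x = motif("Gal"))),
    "terminal-required")
})

test_that("mass fractions group isomers by composition", {
  lib <- fixture_library()
  w <- c(bi_a26 = 0.3, bi_mixed = 0.3, tri = 0.4)
  fr <- mass_fractions(w, lib)
  expect_equal(unname(fr["Hex5HexNAc4Neu5Ac2"]), 0.6)
  expect_equal(sum(fr), 1)
  expect_length(mass_fractions(stats::setNames(numeric(0), character(0)), lib), 0L)

  br <- isomer_breakdown(w, lib, "Hex5HexNAc4Neu5Ac2")
  expect_equal(unname(br), c(0.5, 0.5))
  br2 <- isomer_breakdown(c(bi_a26 = 0.45, bi_mixed = 0.15), lib,
                          "Hex5HexNAc4Neu5Ac2")
  expect_equal(unname(br2), c(0.75, 0.25))
  expect_equal(isomer_breakdown(c(tri = 0.2), lib, "Hex6HexNAc5Neu5Ac2"),
               c(tri = 1))
  expect_error(isomer_breakdown(w, lib, "Pent7"), "no reported weight")
})

test_that("all fraction tables sum to one and are scale-invariant", {
  lib <- generate_library(simulation_spec(library_size = 25, seed = 13))
  set.seed(99)
  for (i in 1:5) {
    w <- stats::setNames(runif(8), sample(names(lib), 8))
    for (fr in list(core_fractions(w, lib), mass_fractions(w, lib),
                    terminal_feature_fractions(w, lib))) {
      expect_equal(sum(fr), 1, tolerance = 1e-12)
    }
    expect_equal(core_fractions(w * 7, lib), core_fractions(w, lib))
    expect_equal(mass_fractions(w * 7, lib), mass_fractions(w, lib))
    expect_equal(terminal_feature_fractions(w * 7, lib),
                 terminal_feature_fractions(w, lib))
  }
})
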