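test_that("parser handles single residues, branched structures, and errors", {
  g <- parse_glycan("Man")
  expect_equal(residue_count(g), 1L)
  expect_equal(unname(composition_of(g)["Hex"]), 1L)

  big <- parse_glycan(BIANTENNARY_A26)
  expect_equal(residue_count(big), 11L)

  expect_error(parse_glycan("Galb1-"), "malformed token")
  expect_error(parse_glycan(""), "non-empty")
  expect_error(parse_glycan("Galb1-4Qux"), "malformed token")
  expect_error(parse_glycan("Galb1-4(GlcNAc"), "unbalanced")
  expect_error(parse_glycan("Galb1-4)GlcNAc("), "unbalanced")
})

test_that("canonical form is branch-order invariant, idempotent, and stable", {
  lin <- "Neu5Aca2-6Galb1-4GlcNAc"
  expect_equal(canonical_form(parse_glycan(lin)), lin)

  swapped <- paste0(
    "Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6",
    "(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3)",
    "Manb1-4GlcNAcb1-4GlcNAc"
  )
  expect_equal(canonical_form(parse_glycan(swapped)),
               canonical_form(parse_glycan(BIANTENNARY_A26)))

  g <- parse_glycan(BIANTENNARY_MIXED)
  cf <- canonical_form(g)
  expect_equal(canonical_form(parse_glycan(cf)), cf)
})

test_that("round trip and canonicalization hold over a generated library", {
  lib <- generate_library(simulation_spec(library_size = 30, seed = 42))
  expect_length(lib, 30L)
  set.seed(7)
  for (g in lib) {
    cf <- canonical_form(g)
    expect_equal(canonical_form(parse_glycan(write_glycan(g))), cf)
    expect_equal(canonical_form(shuffle_siblings(g)), cf)
    expect_equal(sum(composition_of(g)), residue_count(g))
  }
})

test_that("composition classes map correctly", {
  comp <- composition_of(parse_glycan("Fuca1-6GlcNAc"))
  expect_equal(unname(comp[c("dHex", "HexNAc")]), c(1L, 1L))
  comp2 <- composition_of(parse_glycan(BIANTENNARY_A26))
  expect_equal(format_composition(comp2), "Hex5HexNAc4Neu5Ac2")
  expect_equal(format_composition(parse_composition("Hex5HexNAc4Neu5Ac2")),
               "Hex5HexNAc4Neu5Ac2")
})

test_that("mass computation matches monoisotopic residue arithmetic", {
  empty <- structure(stats::setNames(integer(6),
                                     c("Hex", "HexNAc", "dHex", "Neu5Ac",
                                       "Neu5Gc", "Pent")),
                     class = "glycan_composition")
  expect_equal(mass_of(empty), 18.0106, tolerance = 1e-6)
  expect_equal(mass_of(parse_composition("Hex1")), 180.0634, tolerance = 1e-6)
  expect_equal(mass_of(parse_glycan(BIANTENNARY_A26)), 2222.783,
               tolerance = 1e-3)

  mt <- default_mass_table()
  mt$masses <- mt$masses[c("Hex", "HexNAc")]
  expect_error(mass_of(parse_composition("Neu5Ac1"), mt), "lacks class")
})

test_that("mass is additive over composition union minus one water", {
  set.seed(11)
  for (i in 1:10) {
    c1 <- parse_composition(sprintf("Hex%dHexNAc%d", sample(0:5, 1), sample(0:4, 1)))
    c2 <- parse_composition(sprintf("dHex%dNeu5Ac%d", sample(0:2, 1), sample(0:3, 1)))
    joint <- structure(c1 + c2, class = "glycan_composition")
    expect_equal(mass_of(joint), mass_of(c1) + mass_of(c2) - 18.0106,
                 tolerance = 1e-9)
  }
})

test_that("glycan library TSV round-trips", {
  lib <- fixture_library()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_glycan_library(lib, path)
  lib2 <- read_glycan_library(path)
  expect_equal(names(lib2), names(lib))
  for (id in names(lib)) {
    expect_equal(canonical_form(lib2[[id]]), canonical_form(lib[[id]]))
  }
})
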