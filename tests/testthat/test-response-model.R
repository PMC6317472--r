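test_that("model matrix entries are digest-then-predict and dimensions check out", {
  enz <- list(broad = enzyme("broad", "Neu5Aca2-?Gal", "Gal"))
  lec <- list(SNA = lectin("SNA", list(list(motif = "Neu5Aca2-6Gal", score = 0.9))))
  pan <- gmap_panel(list(untreated = character(0), desial = "broad"), lec, enz)
  lib <- as_glycan_library(c(bi = BIANTENNARY_A26, man = "Man"))
  raw <- build_model_matrix(lib, pan, normalize = FALSE)
  expect_equal(unname(raw$C[, "bi"]), c(0.9, 0))
  expect_equal(unname(raw$C[, "man"]), c(0, 0))

  pan7 <- demo_panel("sialidase")
  m <- build_model_matrix(fixture_library(), pan7)
  expect_equal(nrow(m$C), 7L * 3L)
  expect_equal(nrow(m$C), length(pan7$lectins) * length(pan7$conditions))
})

test_that("per-lectin normalization divides by the block maximum and is idempotent", {
  C <- matrix(c(0.9, 0, 0.45, 0.9), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("g1", "g2")))
  C <- rbind(C, matrix(0, 2, 2))  # second, all-zero lectin block
  rm <- toy_response_matrix(C, c("L1", "L1", "L2", "L2"))
  nm <- normalize_per_lectin(rm)
  expect_equal(unname(nm$C[1:2, ]), matrix(c(1, 0.5, 0, 1), 2),
               tolerance = 1e-12)
  expect_equal(unname(nm$C[3:4, ]), matrix(0, 2, 2))
  expect_equal(normalize_per_lectin(nm)$C, nm$C)

  # scale invariance: scaling one lectin's raw block changes nothing
  rm2 <- rm
  rm2$C[1:2, ] <- rm2$C[1:2, ] * 7
  expect_equal(normalize_per_lectin(rm2)$C, nm$C)
})

test_that("complete-linkage clustering groups identical vectors and respects the cutoff", {
  C <- cbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  rm <- toy_response_matrix(C, c("L", "L"))
  lab <- cluster_model_glycans(rm, cutoff = 1)
  expect_equal(lab[["a"]], lab[["b"]])
  expect_false(lab[["a"]] == lab[["c"]])  # distance sqrt(2) > 1
  expect_equal(unname(cluster_model_glycans(rm, cutoff = 2)), rep(1L, 3))
  expect_equal(sort(unique(lab)), seq_len(max(lab)))
})

test_that("mass restriction keeps composition and mass matches, in order", {
  lib <- fixture_library()
  kept <- restrict_candidates(lib, compositions = "Hex5HexNAc4Neu5Ac2")
  expect_equal(names(kept), c("bi_a26", "bi_mixed"))

  kept2 <- restrict_candidates(lib, masses = 2222.8,
                               mass_table = default_mass_table(tolerance = 0.5))
  expect_true(all(c("bi_a26", "bi_mixed") %in% names(kept2)))
  expect_false("tetra" %in% names(kept2))

  expect_error(restrict_candidates(lib), "empty")
  expect_warning(restrict_candidates(lib, compositions = "Pent9"),
                 "no candidate")
})

test_that("vector correlation matches hand computations and flags constants", {
  v <- c(0.2, 0.5, 0.9)
  expect_equal(vector_correlation(v, v), 1)
  expect_equal(vector_correlation(c(1, 0), c(0, 1)), -1)
  expect_equal(vector_correlation(c(1, 0, 1, 0), c(1, 0, 0, 1)), 0)
  expect_warning(r <- vector_correlation(c(1, 1), c(0, 1)), "constant")
  expect_true(is.na(r))
})

test_that("panel YAML resolves names and rejects unknowns", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(conditions = list(untreated = list(),
                                          desial = list("sialidase_broad")),
                        lectins = list("SNA", "MAL")), path)
  pan <- read_panel(path, demo_lectins(), demo_enzymes())
  expect_s3_class(pan, "gmap_panel")
  expect_equal(nrow(pan$channels), 4L)

  yaml::write_yaml(list(conditions = list(u = list()), lectins = list("XXX")),
                   path)
  expect_error(read_panel(path, demo_lectins(), demo_enzymes()), "unknown lectin")
  expect_error(gmap_panel(list(u = "nope"), demo_lectins(), demo_enzymes()),
               "unknown enzyme")
})
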