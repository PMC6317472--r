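test_that("nnls_fit reproduces known solutions and handles degenerate inputs", {
  fit <- nnls_fit(diag(2), c(0.5, 0.25))
  expect_equal(unname(fit$weights), c(0.5, 0.25), tolerance = 1e-10)
  expect_equal(fit$r2, 1)

  # the unconstrained optimum has a negative weight; the constraint binds
  C <- cbind(c(1, 0), c(1, 1))
  fit2 <- nnls_fit(C, c(0, 1))
  expect_equal(unname(fit2$weights), c(0, 0.5), tolerance = 1e-10)
  expect_equal(fit2$residual_ss, 0.5, tolerance = 1e-10)
  expect_equal(fit2$r2, 0, tolerance = 1e-10)

  fit3 <- nnls_fit(C, c(0, 0))
  expect_equal(unname(fit3$weights), c(0, 0))

  expect_error(nnls_fit(C, c(1, 2, 3)), "dimension mismatch")
})

test_that("nnls_fit agrees with exhaustive support enumeration on random instances", {
  set.seed(314)
  for (i in 1:30) {
    # N >= M keeps the minimizer generically unique, so weights are comparable
    M <- sample(2:4, 1)
    N <- sample(M:6, 1)
    C <- matrix(runif(N * M), N, M)
    d <- runif(N)
    fit <- nnls_fit(C, d)
    expect_lt(max(abs(unname(fit$weights) - nnls_enum_oracle(C, d))), 1e-6)
  }
})

test_that("colinearity filter keeps the most-probed representative", {
  # identical response vectors: sialylated pair, one carrying an extra,
  # unprobed core fucose
  plain <- BIANTENNARY_A26
  fuc <- paste0(
    "Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3",
    "(Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6)",
    "Manb1-4GlcNAcb1-4(Fuca1-6)GlcNAc"
  )
  lib <- as_glycan_library(c(plain = plain, fuc = fuc))
  pan <- demo_panel("sialidase")
  rm <- build_model_matrix(lib, pan)
  expect_equal(unname(rm$C[, "plain"]), unname(rm$C[, "fuc"]))
  flt <- filter_colinear(rm, lib, pan)
  expect_equal(colnames(flt$matrix$C), "fuc")  # tie on coverage -> more residues
  expect_equal(sort(flt$groups$fuc), c("fuc", "plain"))

  # proportional (not identical) columns collapse too
  C <- cbind(a = c(1, 2, 0), b = c(2, 4, 0), c = c(0, 1, 1))
  rm2 <- toy_response_matrix(C, c("L", "L", "L"))
  lib3 <- fixture_library()[1:3]
  names(lib3) <- c("a", "b", "c")
  for (nm in names(lib3)) lib3[[nm]]$id <- nm
  flt2 <- filter_colinear(rm2, as_glycan_library(lib3))
  expect_equal(ncol(flt2$matrix$C), 2L)
  expect_true("c" %in% colnames(flt2$matrix$C))

  # independent columns pass through untouched
  C3 <- cbind(a = c(1, 0), b = c(1, 1))
  flt3 <- filter_colinear(toy_response_matrix(C3, c("L", "L")),
                          as_glycan_library(lib3[1:2]))
  expect_equal(ncol(flt3$matrix$C), 2L)
})

test_that("no proportional pair survives the filter on random matrices", {
  set.seed(21)
  for (i in 1:10) {
    M <- 8
    base <- matrix(runif(5 * 4), 5, 4)
    C <- cbind(base, base[, sample(4, 4, replace = TRUE)] *
                 matrix(rep(runif(4, 0.5, 2), each = 5), 5))
    colnames(C) <- paste0("g", 1:M)
    lib <- generate_library(simulation_spec(library_size = M, seed = i))
    names(lib) <- colnames(C)
    for (nm in names(lib)) lib[[nm]]$id <- nm
    flt <- filter_colinear(toy_response_matrix(C, rep("L", 5)),
                           as_glycan_library(lib))
    K <- flt$matrix$C
    if (ncol(K) > 1L) {
      U <- sweep(K, 2, sqrt(colSums(K^2)), "/")
      G <- crossprod(U)
      diag(G) <- 0
      expect_lt(max(G), 1 - 1e-9)
    }
  }
})

test_that("a dominant unambiguous fit yields only the initial model", {
  C <- cbind(a = c(1, 0.5), b = c(0.6, 0))
  fit <- nnls_fit(C, c(1, 0.5))
  acc <- sample_alternatives(C, c(1, 0.5), fit)
  expect_length(acc, 1L)
  rep_ <- make_report(acc, C)
  expect_equal(rep_$glycan_id, "a")
  expect_equal(rep_$inclusion_frequency, 1)
})

test_that("near-duplicate columns split the inclusion frequency", {
  C <- cbind(a = c(1, 0.5), b = c(1, 0.49))
  d <- c(1, 0.5)
  fit <- nnls_fit(C, d)
  acc <- sample_alternatives(C, d, fit)
  expect_length(acc, 2L)
  rep_ <- make_report(acc, C)
  expect_equal(sort(rep_$glycan_id), c("a", "b"))
  expect_equal(rep_$inclusion_frequency, c(0.5, 0.5))
})

test_that("alternative acceptance enforces the additional-glycan allowance", {
  # the mixture column equals e1+e2+e3: replacing it needs three new glycans
  C <- cbind(mix = c(1, 1, 1), e1 = c(1, 0, 0), e2 = c(0, 1, 0),
             e3 = c(0, 0, 1))
  d <- c(1, 1, 1)
  fit <- nnls_fit(C, d)
  expect_equal(fit$predicted, "mix")
  acc <- sample_alternatives(C, d, fit)
  expect_length(acc, 1L)  # the exact 3-glycan alternative is rejected
  acc2 <- sample_alternatives(C, d, fit,
                              solver_config(max_additional_glycans = 3))
  expect_length(acc2, 2L)  # allowed when the budget admits three
})

test_that("refit count respects the per-glycan sampling budget", {
  set.seed(5)
  C <- matrix(runif(60), 6, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  d <- as.numeric(C[, 1:4] %*% runif(4, 0.5, 1))
  fit <- nnls_fit(C, d)
  cfg <- solver_config(samples_per_glycan = 3)
  acc <- sample_alternatives(C, d, fit, cfg)
  expect_lte(attr(acc, "n_refits"), 3 * length(fit$predicted))
  cfg100 <- solver_config()
  acc100 <- sample_alternatives(C, d, fit, cfg100)
  expect_lte(attr(acc100, "n_refits"), 100 * length(fit$predicted))
})

test_that("report applies the inclusion threshold and zero-filled averaging", {
  C <- cbind(a = c(1, 0), b = c(0, 1))
  mkfit <- function(w) {
    structure(list(weights = stats::setNames(w, colnames(C)),
                   residual_ss = 0, r2 = 1,
                   predicted = colnames(C)[w > 1e-8]),
              class = "nnls_fit")
  }
  # glycan b present in 1 of 20 fits: frequency 0.05 < 0.10 -> dropped
  fits <- c(replicate(19, mkfit(c(0.4, 0)), simplify = FALSE),
            list(mkfit(c(0.4, 0.2))))
  rep_ <- make_report(fits, C)
  expect_equal(rep_$glycan_id, "a")
  expect_equal(rep_$inclusion_frequency, 1)
  expect_equal(rep_$mean_weight, 0.4)

  # zero-filled averaging: weight 0.4 in 1 of 2 fits reports as 0.2
  fits2 <- list(mkfit(c(0.3, 0.4)), mkfit(c(0.3, 0)))
  rep2 <- make_report(fits2, C)
  expect_equal(rep2$mean_weight[rep2$glycan_id == "b"], 0.2)
  expect_equal(sum(rep2$contribution), 1)
  expect_true(all(rep2$mean_weight >= 0))

  # containing-fit averaging is available as a config switch
  rep3 <- make_report(fits2, C, config = solver_config(zero_fill_mean = FALSE))
  expect_equal(rep3$mean_weight[rep3$glycan_id == "b"], 0.4)
})

test_that("the report is invariant to candidate input order", {
  spec <- simulation_spec(library_size = 20, noise_sd = 0, seed = 3)
  lib <- generate_library(spec)
  pan <- demo_panel("extended")
  rm <- build_model_matrix(lib, pan)
  a_true <- simulate_truth(rm, lib, spec, pan)
  d <- observed_vector(as.numeric(rm$C[, names(a_true)] %*% a_true), pan,
                       normalized = TRUE)
  sol1 <- glycan_solve(lib, pan, d)
  perm <- rev(seq_along(lib))
  lib2 <- as_glycan_library(unclass(lib)[perm])
  sol2 <- glycan_solve(lib2, pan, d)
  r1 <- sol1$report[order(sol1$report$glycan_id), ]
  r2 <- sol2$report[order(sol2$report$glycan_id), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-10)
})

test_that("solution fit quality reports correlation and R-squared", {
  C <- cbind(a = c(1, 0, 0.5), b = c(0, 1, 0.5))
  d <- as.numeric(C %*% c(0.6, 0.4))
  fit <- nnls_fit(C, d)
  acc <- sample_alternatives(C, d, fit)
  rep_ <- make_report(acc, C)
  q <- solution_fit_quality(rep_, d)
  expect_equal(q$correlation, 1, tolerance = 1e-9)
  expect_equal(q$r2, 1, tolerance = 1e-9)

  q0 <- suppressWarnings(solution_fit_quality(rep(0, 3), d))
  expect_lte(q0$r2, 0)
  expect_warning(solution_fit_quality(rep(0, 3), d), "constant")
})
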