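# End-to-end pipeline driven by a YAML config. All stages are the exported
# functions; this wrapper adds validation-before-computation, file IO, and a
# run log, so identical inputs and config give byte-identical outputs.

#' Run the full deconvolution pipeline from a config file
#'
#' Stages: read inputs, build the panel, reduce spot-level data (or read a
#' ready response-vector table), optionally restrict candidates by
#' composition/mass, deconvolve with [glycan_solve()], and write the report
#' plus summary tables. Input names (lectins, enzymes) are validated before
#' any computation; any stage failure aborts with the stage name.
#'
#' Config layout (YAML):
#' ```yaml
#' inputs:
#'   glycans: library.tsv        # glycan_id, structure
#'   lectins: lectins.tsv        # lectin, motif, binding_score[, terminal_required]
#'   enzymes: enzymes.tsv        # enzyme, recognition_motif, replace_motif[, ...]
#'   spots: spots.tsv            # spot-level table; or
#'   observed: observed.tsv      # channel-level table: label, value[, normalized]
#'   compositions: [Hex5HexNAc4Neu5Ac2]   # optional restriction
#'   masses: [2222.78]                    # optional restriction
#'   mass_table: masses.yaml              # optional
#' panel:
#'   conditions: {untreated: [], sialidase: [sialidase_a23]}
#'   lectins: [SNA, MAL]
#' solver: {r2_window: 0.05, max_additional_glycans: 2, ...}
#' output: results/
#' ```
#'
#' @param config Path to a YAML config file, or an equivalent list.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of `glycan_solution`s (one per protein in
#'   the spot table, or a single `"sample"` entry for a response-vector
#'   input). Writes `<protein>_report.tsv`, `<protein>_solution_vector.tsv`,
#'   summary TSVs, and `run_log.txt` under the output directory.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  say <- function(...) if (!quiet) message(...)
  inp <- config$inputs
  if (is.null(inp$glycans) || is.null(inp$lectins)) {
    stop("config needs inputs$glycans and inputs$lectins", call. = FALSE)
  }
  base <- if (!is.null(cfg_path)) dirname(cfg_path) else "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)

  lib <- stage("read glycans", read_glycan_library(resolve(inp$glycans)))
  lectins <- stage("read lectins", read_lectins(resolve(inp$lectins)))
  enzymes <- if (!is.null(inp$enzymes)) {
    stage("read enzymes", read_enzymes(resolve(inp$enzymes)))
  } else list()
  mass_table <- if (!is.null(inp$mass_table)) {
    stage("read mass table", read_mass_table(resolve(inp$mass_table)))
  } else default_mass_table()

  panel <- stage("build panel", {
    if (is.null(config$panel)) stop("config needs a 'panel' section")
    conds <- lapply(config$panel$conditions, function(x) as.character(unlist(x)))
    use <- as.character(unlist(config$panel$lectins))
    missing_l <- setdiff(use, names(lectins))
    if (length(missing_l)) {
      stop(sprintf("unknown lectin(s): %s", paste(missing_l, collapse = ", ")))
    }
    gmap_panel(conds, lectins[use], enzymes)
  })

  solver_cfg <- stage("solver config",
                      do.call(solver_config, as.list(config$solver)))

  observed <- stage("observed data", {
    if (!is.null(inp$spots)) {
      reduce_spot_table(read_spot_table(resolve(inp$spots)), panel)
    } else if (!is.null(inp$observed)) {
      df <- utils::read.delim(resolve(inp$observed), stringsAsFactors = FALSE)
      if (!all(c("label", "value") %in% names(df))) {
        stop("observed table needs columns label, value")
      }
      miss <- setdiff(panel$channels$label, df$label)
      if (length(miss)) {
        stop(sprintf("observed table lacks channel(s): %s",
                     paste(miss, collapse = "; ")))
      }
      v <- df$value[match(panel$channels$label, df$label)]
      list(sample = observed_vector(v, panel,
                                    normalized = isTRUE(inp$normalized)))
    } else {
      stop("config needs inputs$spots or inputs$observed")
    }
  })

  outdir <- if (!is.null(config$output)) config$output else "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  solutions <- list()
  for (prot in names(observed)) {
    say("solving: ", prot)
    sol <- stage(paste0("solve ", prot), glycan_solve(
      lib, panel, observed[[prot]], config = solver_cfg,
      compositions = inp$compositions, masses = inp$masses,
      mass_table = mass_table,
      cluster_cutoff = config$cluster_cutoff))
    solutions[[prot]] <- sol
    stage(paste0("write ", prot), {
      write_report(sol$report, file.path(outdir, paste0(prot, "_report.tsv")))
      sv <- data.frame(label = names(fitted(sol)), value = fitted(sol),
                       observed = as.numeric(sol$observed))
      utils::write.table(sv, file.path(outdir, paste0(prot, "_solution_vector.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      s <- summary(sol)
      write_fractions(s$core, file.path(outdir, paste0(prot, "_core_fractions.tsv")),
                      label = "core")
      if (!is.null(s$terminal)) {
        write_fractions(s$terminal,
                        file.path(outdir, paste0(prot, "_terminal_fractions.tsv")),
                        label = "feature")
      }
      write_fractions(s$mass, file.path(outdir, paste0(prot, "_mass_fractions.tsv")),
                      label = "composition")
    })
  }

  stage("run log", {
    log <- c(
      paste0("gmapsolve ", as.character(utils::packageVersion("gmapsolve"))),
      paste0("R ", R.version.string),
      paste0("config: ", if (!is.null(cfg_path)) cfg_path else "<in-memory>"),
      paste0("config sha: ", config_digest(config)),
      paste0("glycans: ", length(lib), "; channels: ", nrow(panel$channels)),
      paste0("proteins: ", paste(names(observed), collapse = ", "))
    )
    writeLines(log, file.path(outdir, "run_log.txt"))
  })
  invisible(solutions)
}

# Small deterministic digest of the config (no external dependency): sums a
# polynomial hash of the deparsed config.
config_digest <- function(config) {
  s <- paste(deparse(config), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%010d", h)
}

#' Write a complete synthetic data set to disk
#'
#' Materializes the synthetic generator's outputs — candidate library, lectin
#' and enzyme tables, panel YAML, spot-level table, and ground-truth
#' weights — as the plain-text inputs the pipeline consumes.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [simulation_spec()].
#' @param panel A `gmap_panel`; default the extended demo panel.
#' @return Invisibly, the file paths written.
#' @export
write_synthetic_dataset <- function(dir, spec = simulation_spec(),
                                    panel = demo_panel("extended")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- generate_library(spec)
  rm <- build_model_matrix(lib, panel)
  a_true <- simulate_truth(rm, lib, spec, panel)
  spots <- simulate_observation(rm, a_true, spec)
  paths <- c(
    glycans = file.path(dir, "glycans.tsv"),
    lectins = file.path(dir, "lectins.tsv"),
    enzymes = file.path(dir, "enzymes.tsv"),
    panel = file.path(dir, "panel.yaml"),
    spots = file.path(dir, "spots.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_glycan_library(lib, paths["glycans"])
  write_lectins(panel$lectins, paths["lectins"])
  write_enzymes(panel$enzymes, paths["enzymes"])
  yaml::write_yaml(list(conditions = panel$conditions,
                        lectins = names(panel$lectins)), paths["panel"])
  utils::write.table(spots, paths["spots"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(glycan_id = names(a_true), weight = a_true),
                     paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
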