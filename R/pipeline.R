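#' Run the end-to-end pipeline
#'
#' Wires the stages together on a simulated (or supplied) sample:
#' `simulate` -> `unmix` -> `qc` -> `gate` -> `profile` -> `integrate`.
#' Stages must form a prefix-closed chain: a stage may only run when the
#' stage producing its input has run (or the input file is supplied in the
#' config). Every run writes a JSON manifest (files produced, parameters,
#' package version, seed) sufficient to re-run it exactly.
#'
#' Config fields (list or YAML path): `panel` (id or path), `stages`
#' (subset of the chain above, default all), `n_events` (default 20000),
#' `n_batches` (default 3, integrate stage), `seed`, `out_dir`,
#' `input_fcs` (optional detector-space FCS to use instead of simulating).
#'
#' @param config configuration list or path to a YAML file.
#' @return the manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages_all <- c("simulate", "unmix", "qc", "gate", "profile", "integrate")
  stages <- config$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad)) {
    sf_stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
            "sf_bad_input")
  }
  stages <- stages_all[stages_all %in% stages]
  need <- function(stage, prereq, have_input) {
    if (stage %in% stages && !(prereq %in% stages) && !have_input) {
      sf_stop(sprintf("stage '%s' requires stage '%s' (or a supplied input)",
                      stage, prereq), "sf_stage_dependency")
    }
  }
  need("unmix", "simulate", !is.null(config$input_fcs))
  need("qc", "unmix", FALSE)
  need("gate", "unmix", FALSE)
  need("profile", "gate", FALSE)

  panel <- load_panel(config$panel %||% "tb")
  seed <- as.integer(config$seed %||% 1)
  n_events <- config$n_events %||% 20000
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(out_dir, name)
  files <- character(0)
  log_msg <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  raw <- NULL; unmixed <- NULL; gated <- NULL; trans <- NULL
  if ("simulate" %in% stages) {
    log_msg("simulating %d events (panel %s)", n_events, panel$panel)
    raw <- simulate_panel_sample(panel, n_events, seed = seed)
    write_fcs(raw, out("sample.fcs"))
    utils::write.csv(data.frame(event = seq_len(n_events),
                                truth = raw$truth_labels),
                     out("truth.csv"), row.names = FALSE)
    files <- c(files, "sample.fcs", "truth.csv")
  } else if (!is.null(config$input_fcs)) {
    raw <- read_fcs(config$input_fcs)
  }

  if ("unmix" %in% stages) {
    log_msg("unmixing")
    unmixed <- unmix(raw, panel$signatures, viability = panel$viability)
    write_fcs(unmixed, out("unmixed.fcs"))
    files <- c(files, "unmixed.fcs")
    trans <- transform_events(drop_af(unmixed), panel$cofactor)
  }

  if ("qc" %in% stages) {
    log_msg("panel QC")
    screen_markers <- setdiff(panel$markers, panel$viability)
    screen <- nxn_screen(trans, screen_markers)
    write_qc_report(screen, validate_panel(panel$signatures),
                    out("qc.json"), out("qc_pairs.csv"))
    files <- c(files, "qc.json", "qc_pairs.csv")
  }

  if ("gate" %in% stages) {
    log_msg("gating")
    pregated <- apply_pregates(trans, viability = panel$viability,
                               cutoffs = panel$cutoffs)
    gated <- run_gating_tree(panel$tree, pregated, panel$cutoffs)
    utils::write.csv(gated$table, out("populations.csv"), row.names = FALSE)
    files <- c(files, "populations.csv")
    gated$events <- pregated
  }

  if ("profile" %in% stages) {
    log_msg("profiling")
    pmm <- population_marker_matrix(gated$events, gated$membership,
                                    populations = canonical_populations(panel$tree))
    write_marker_matrix(pmm, out("marker_matrix.csv"), out("marker_matrix.json"))
    files <- c(files, "marker_matrix.csv", "marker_matrix.json")
  }

  if ("integrate" %in% stages) {
    n_batches <- config$n_batches %||% 3
    log_msg("integrating %d batches", n_batches)
    batches <- simulate_batches(panel_templates(panel),
                                n_events = config$batch_events %||% 2000,
                                n_batches = n_batches, space = "marker",
                                seed = seed)
    res <- integrate_batches(batches,
                             integration_config(seed = seed),
                             cofactor = panel$cofactor)
    write_integration_report(res, out("integration.json"))
    write_fcs(res$events, out("integrated.fcs"))
    files <- c(files, "integration.json", "integrated.fcs")
  }

  manifest <- list(
    package = "specflow",
    version = as.character(utils::packageVersion("specflow")),
    panel = panel$panel, stages = stages, seed = seed,
    n_events = n_events, out_dir = out_dir, files = files
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
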