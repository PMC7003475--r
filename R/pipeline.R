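# package-level cache for the two canonical waveform pairs
.coroflow_cache <- new.env(parent = emptyenv())

#' Cached tier-1 boundary data
#'
#' The closed loop produces exactly two inflow waveform pairs (resting,
#' hyperaemic) per configuration; this memoizes [tier1_boundary_data] keyed
#' by its arguments so every case in a cohort reuses the same pair.
#'
#' @param dt,tol,n_samples passed to [tier1_boundary_data]
#' @return see [tier1_boundary_data]
#' @export
cached_boundary_data <- function(dt = 1e-3, tol = 0.02, n_samples = 201) {
  key <- paste0("bd_", dt, "_", tol, "_", n_samples)
  if (is.null(.coroflow_cache[[key]]))
    .coroflow_cache[[key]] <- tier1_boundary_data(dt = dt, tol = tol,
                                                  n_samples = n_samples)
  .coroflow_cache[[key]]
}

#' Load and validate a run configuration
#'
#' Configurations are JSON; unknown keys are rejected, missing required keys
#' are named. All defaults in force are resolved into the returned object so
#' emitted metadata records the full configuration.
#'
#' @param path JSON file path, or a named list
#' @return a validated named list with class `run_config`
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else path
  known <- c("seed", "network_file", "synthesis", "stenoses", "solver",
             "output_dir", "cohort_n", "severity_range", "tier1", "case_id")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("missing config key: seed")
  defaults <- list(
    synthesis = list(n_generations = 3, root_diameter = 0.35, gamma = 2.27),
    stenoses = list(),
    solver = list(dx_target = 0.1, dt = 1e-3, max_cycles = 8,
                  periodic_tol = 2e-3),
    tier1 = list(dt = 1e-3, tol = 0.02),
    output_dir = ".", cohort_n = 8, severity_range = c(0.2, 0.9),
    case_id = "case")
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      for (kk in setdiff(names(defaults[[k]]), names(cfg[[k]])))
        cfg[[k]][[kk]] <- defaults[[k]][[kk]]
  structure(cfg, class = "run_config")
}

cfg_solver <- function(cfg) do.call(solver_config, cfg$solver)

cfg_network <- function(cfg, seed_offset = 0) {
  if (!is.null(cfg$network_file)) read_network(cfg$network_file)
  else do.call(generate_synthetic_tree,
               c(list(seed = cfg$seed + seed_offset), cfg$synthesis))
}

#' Emit tier-1 waveforms and ventricular traces
#'
#' Writes the two canonical inflow waveform CSVs per side, the ventricular
#' pressure trace CSV, and a JSON of the calibrated summary for both states.
#'
#' @param config a `run_config` (or path)
#' @return invisibly, the list of written files
#' @export
cmd_tier1 <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  bd <- cached_boundary_data(dt = cfg$tier1$dt, tol = cfg$tier1$tol)
  files <- character(0)
  for (stname in c("resting", "hyperaemic")) {
    b <- bd[[stname]]
    for (side in c("left", "right")) {
      f <- file.path(cfg$output_dir, sprintf("inflow_%s_%s.csv", stname, side))
      write_waveform(b[[paste0("inflow_", side)]], f)
      files <- c(files, f)
    }
    f <- file.path(cfg$output_dir, sprintf("ventricular_%s.csv", stname))
    utils::write.csv(data.frame(t_s = b$ventricular$t,
                                P_LV_mmHg = cgs_to_mmhg(b$ventricular$P_LV),
                                P_RV_mmHg = cgs_to_mmhg(b$ventricular$P_RV)),
                     f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(cfg$output_dir, "tier1_summary.json")
  jsonlite::write_json(list(
    resting = bd$resting$summary, hyperaemic = bd$hyperaemic$summary,
    flow_ratio = bd$flow_ratio, config = unclass(cfg)),
    f, auto_unbox = TRUE, digits = NA)
  invisible(c(files, f))
}

#' Run one case end to end
#'
#' Chains tier-1 (cached), tier-2 resistance assignment, the two 1D
#' simulations and both indices; writes the diagnostic record JSON.
#'
#' @param config a `run_config` (or path)
#' @return the `diagnostic_record` (invisibly writes JSON into output_dir)
#' @export
cmd_run_case <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  net <- cfg_network(cfg)
  bd <- cached_boundary_data(dt = cfg$tier1$dt, tol = cfg$tier1$tol)
  stenoses <- cfg$stenoses
  if (length(stenoses) && !is.null(names(stenoses[[1]])) == FALSE)
    stop("stenoses must be a list of named lists")
  rec <- run_case(net, stenoses, boundary_data = bd,
                  config = cfg_solver(cfg), case_id = cfg$case_id)
  write_record(rec, file.path(cfg$output_dir,
                              paste0(cfg$case_id, "_record.json")))
  invisible(rec)
}

#' Run a synthetic cohort and its statistics report
#'
#' Generates `cohort_n` synthetic trees (seeded from the config seed), puts
#' one focal stenosis on each root segment with severities spanning
#' `severity_range`, runs every case in both states, assembles the cohort
#' table, fits the degree-1..3 polynomial relations, extracts the ciFR
#' threshold at FFR = 0.8 and runs ROC of ciFR against cFFR < 0.8 labels.
#'
#' @param config a `run_config` (or path)
#' @return list with `cohort` (data.frame) and `report` (see
#'   [cohort_report]); writes cohort.csv and stats_report.json
#' @export
cmd_cohort <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  bd <- cached_boundary_data(dt = cfg$tier1$dt, tol = cfg$tier1$tol)
  n <- cfg$cohort_n
  sev <- seq(cfg$severity_range[1], cfg$severity_range[2], length.out = n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    net <- cfg_network(cfg, seed_offset = i)
    root <- net$segments[[net$root]]
    sten <- list(segment_id = net$root, center_fraction = 0.5,
                 stenosed_length = min(1.5, 0.6 * root$length),
                 area_reduction = sev[i])
    rec <- run_case(net, list(sten), boundary_data = bd,
                    config = cfg_solver(cfg),
                    case_id = sprintf("case%03d", i))
    rows[[i]] <- data.frame(case_id = rec$case_id, severity = sev[i],
                            cffr = rec$cffr, cifr = rec$cifr,
                            stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  cohort$ref_class <- ifelse(cohort$cffr < 0.8, "positive", "negative")
  report <- if (length(unique(cohort$ref_class)) == 2)
    cohort_report(cohort) else NULL
  utils::write.csv(cohort, file.path(cfg$output_dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(report = report, config = unclass(cfg)),
                       file.path(cfg$output_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(cohort = cohort, report = report)
}

#' Statistics report on an existing cohort CSV
#'
#' @param path cohort CSV with columns case_id, cffr, cifr, ref_class
#' @param out optional JSON output path
#' @return the report list (see [cohort_report])
#' @export
cmd_stats <- function(path, out = NULL) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cffr", "cifr")
  if (!all(need %in% names(cohort)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  report <- cohort_report(cohort)
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  report
}

#' Command-line entry point
#'
#' Dispatches `coroflow tier1|run|cohort|stats <config.json>` as used by the
#' shipped executable script (`inst/cli/coroflow`).
#'
#' @param argv character vector of arguments (default from the command line)
#' @return exit status, invisibly
#' @export
coroflow_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: coroflow {tier1|run|cohort} <config.json> | coroflow stats <cohort.csv> [out.json]"
  if (length(argv) < 2) { message(usage); return(invisible(1L)) }
  cmd <- argv[1]
  switch(cmd,
    tier1 = cmd_tier1(argv[2]),
    run = cmd_run_case(argv[2]),
    cohort = cmd_cohort(argv[2]),
    stats = cmd_stats(argv[2], if (length(argv) > 2) argv[3] else NULL),
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}
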