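.config_keys <- c("cohort", "model", "analysis")
.cohort_keys <- c("source", "path", "sim_params")
.analysis_keys <- c("comparator", "wtp", "wtp_grid", "psa_n", "seed",
                    "threshold", "alpha", "sample_validity")

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration with up to three sections:
#'
#' * `cohort`: `source: simulate` with optional `sim_params` overrides for
#'   [cohort_sim_params()], or `source: file` with a `path` to a cohort CSV;
#' * `model`: overrides for [model_parameters()] fields;
#' * `analysis`: `comparator`, `wtp`, `wtp_grid` (`low`/`high`/`step`),
#'   `psa_n`, `seed`, `threshold`, `alpha`, `sample_validity`.
#'
#' Unknown keys are rejected; omitted values fall back to the documented
#' defaults. Structural parameters whose defaults are not literature-sourced
#' are listed in the returned object's `non_paper_defaults` attribute and
#' echoed with a warning-level log message when left at their defaults.
#'
#' @param path configuration file path (`.yaml`/`.yml`/`.json`).
#' @param quiet suppress provenance messages.
#' @return An object of class `run_config`: a list with `cohort_source`,
#'   `cohort_path`, `sim_params`, `model_params` and `analysis` elements.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(.config_keys, collapse = ", "), ")",
         call. = FALSE)

  cohort <- raw[["cohort"]]
  if (is.null(cohort)) cohort <- list(source = "simulate")
  if (is.character(cohort) && length(cohort) == 1L)
    cohort <- list(source = cohort)
  unknown <- setdiff(names(cohort), .cohort_keys)
  if (length(unknown))
    stop("unknown cohort key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  source <- match.arg(cohort[["source"]], c("simulate", "file"))
  if (source == "file" && is.null(cohort[["path"]]))
    stop("cohort source 'file' requires 'path'", call. = FALSE)
  sim_params <- NULL
  if (source == "simulate") {
    sp <- cohort[["sim_params"]]
    if (!is.null(sp)) {
      unknown <- setdiff(names(sp), names(formals(cohort_sim_params)))
      if (length(unknown))
        stop("unknown sim_params key(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
    }
    sim_params <- do.call(cohort_sim_params, as.list(sp))
  }

  mp <- raw[["model"]]
  if (!is.null(mp)) {
    unknown <- setdiff(names(mp), names(formals(model_parameters)))
    if (length(unknown))
      stop("unknown model key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (!is.null(mp[["screening_costs"]]))
      mp[["screening_costs"]] <- unlist(mp[["screening_costs"]])
  }
  model_params <- do.call(model_parameters, as.list(mp))

  an <- raw[["analysis"]]
  if (!is.null(an)) {
    unknown <- setdiff(names(an), .analysis_keys)
    if (length(unknown))
      stop("unknown analysis key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  grid <- an[["wtp_grid"]]
  wtp_grid <- if (is.null(grid)) seq(0, 200000, by = 5000)
              else seq(grid[["low"]], grid[["high"]], by = grid[["step"]])
  analysis <- list(
    comparator = if (is.null(an[["comparator"]])) "DAY1" else an[["comparator"]],
    wtp = if (is.null(an[["wtp"]])) model_params$wtp_threshold else an[["wtp"]],
    wtp_grid = wtp_grid,
    psa_n = if (is.null(an[["psa_n"]])) 1000L else as.integer(an[["psa_n"]]),
    seed = if (is.null(an[["seed"]])) 1L else as.integer(an[["seed"]]),
    threshold = if (is.null(an[["threshold"]])) 30 else an[["threshold"]],
    alpha = if (is.null(an[["alpha"]])) 0.05 else an[["alpha"]],
    sample_validity = if (is.null(an[["sample_validity"]])) TRUE
                      else isTRUE(an[["sample_validity"]]))

  non_paper_used <- setdiff(.non_paper_params, names(mp))
  if (!quiet && length(non_paper_used))
    message("using package defaults for non-paper parameter(s): ",
            paste(non_paper_used, collapse = ", "))
  structure(list(cohort_source = source,
                 cohort_path = cohort[["path"]],
                 sim_params = sim_params,
                 model_params = model_params,
                 analysis = analysis),
            class = "run_config",
            non_paper_defaults = non_paper_used)
}

# normalized plain-list view of a config (stable key order, no classes);
# the WTP grid is folded back to its low/high/step description so that a
# dumped config reloads to the same object
#' @export
as.list.run_config <- function(x, ...) {
  an <- x$analysis
  g <- an$wtp_grid
  an$wtp_grid <- list(low = min(g), high = max(g),
                      step = if (length(g) > 1) g[2] - g[1] else 1)
  list(cohort = list(source = x$cohort_source,
                     path = x$cohort_path,
                     sim_params = if (!is.null(x$sim_params))
                       unclass(x$sim_params)),
       model = {m <- unclass(x$model_params)
                m$screening_costs <- as.list(m$screening_costs)
                m},
       analysis = an)
}

#' Run the full screening evaluation pipeline
#'
#' Executes every stage in order: cohort acquisition (simulation or file),
#' screening-validity assessment, base-case cost-effectiveness analysis,
#' one-way tornado analysis, probabilistic sensitivity analysis and the
#' acceptability curves, writing one CSV per stage plus a JSON run manifest
#' (seed, package version, parameters with paper/non-paper provenance) to
#' `out_dir`. All randomness derives from the master seed in
#' `config$analysis$seed`: the cohort stage uses the seed itself and the PSA
#' stage uses `seed + 1`, so each stage is independently reproducible.
#'
#' @param config a [load_config()] result (or a path to a config file).
#' @param out_dir output directory, created if missing.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with elements `cohort`, `validity`, `cea`,
#'   `tornado`, `psa`, `ceac` and `manifest`.
#' @export
run_all <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config, quiet = quiet)
  if (!inherits(config, "run_config"))
    stop("'config' must be a 'run_config' or a file path", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  an <- config$analysis

  say("stage cohort (", config$cohort_source, ")")
  cohort <- stage("cohort", {
    if (config$cohort_source == "simulate") {
      sp <- config$sim_params
      if (is.null(sp$seed)) sp$seed <- an$seed
      generate_cohort(sp)
    } else read_cohort(config$cohort_path)
  })
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  say("stage validity")
  vt <- stage("validity",
              validity_table(cohort, threshold = an$threshold,
                             alpha = an$alpha))
  utils::write.csv(vt, file.path(out_dir, "validity.csv"),
                   row.names = FALSE)

  say("stage cea")
  cea_res <- stage("cea", run_cea(config$model_params, vt,
                                  comparator = an$comparator,
                                  wtp = an$wtp))
  utils::write.csv(cea_res$table, file.path(out_dir, "cea.csv"),
                   row.names = FALSE)
  traces <- do.call(rbind, lapply(names(cea_res$traces), function(s)
    cbind(strategy = s, cea_res$traces[[s]]$trace)))
  utils::write.csv(traces, file.path(out_dir, "trace.csv"),
                   row.names = FALSE)

  say("stage tornado")
  tornado <- stage("tornado",
                   one_way_tornado(config$model_params, vt,
                                   pair = c(an$comparator,
                                            "DAY1_RANDOM_DAY2"),
                                   wtp = an$wtp))
  utils::write.csv(tornado, file.path(out_dir, "tornado.csv"),
                   row.names = FALSE)

  say("stage psa (n = ", an$psa_n, ")")
  psa <- stage("psa", run_psa(config$model_params, vt, an$psa_n,
                              seed = an$seed + 1L,
                              sample_validity = an$sample_validity))
  utils::write.csv(psa, file.path(out_dir, "psa.csv"), row.names = FALSE)
  ceac_tab <- stage("ceac", ceac(psa, an$wtp_grid))
  utils::write.csv(ceac_tab, file.path(out_dir, "ceac.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "albuscreen",
    version = as.character(utils::packageVersion("albuscreen")),
    seed = an$seed,
    stage_seeds = list(cohort = an$seed, psa = an$seed + 1L),
    cohort_source = config$cohort_source,
    parameters = unclass(config$model_params),
    parameter_provenance = stats::setNames(
      ifelse(names(unclass(config$model_params)) %in% .non_paper_params,
             "non-paper default", "literature-sourced"),
      names(unclass(config$model_params))),
    analysis = an)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(cohort = cohort, validity = vt, cea = cea_res,
                 tornado = tornado, psa = psa, ceac = ceac_tab,
                 manifest = manifest))
}
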