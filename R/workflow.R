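# Pipeline orchestration: constrain -> repair -> sample -> summarize ->
# differential, driven by a YAML configuration.

#' Read and validate a pipeline configuration
#'
#' YAML file with keys: `model` (path to model JSON); `seed` (mandatory
#' integer used for every stochastic stage); `sampler` (`n_points`,
#' `n_steps`); `differential` (`p_thresh`, `fc_thresh`, `n_perm`,
#' `excluded_subsystems`); `output_dir`; `reference` (name of the reference
#' condition); `conditions` — a map of condition name to a block with
#' optional `knockouts` (reaction ids), `rates` (measured-rates TSV) and
#' `cis` (MFA confidence-interval TSV).
#'
#' @param path YAML file.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_fluxpath("io", paste0("config not found: ", path))
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed))
    stop_fluxpath("validation", "config must set a seed (stochastic stages)")
  if (is.null(cfg$model)) stop_fluxpath("validation", "config must set model")
  if (is.null(cfg$conditions) || !length(cfg$conditions))
    stop_fluxpath("validation", "config must define at least one condition")
  if (is.null(cfg$reference)) cfg$reference <- names(cfg$conditions)[1]
  if (!cfg$reference %in% names(cfg$conditions))
    stop_fluxpath("validation", "reference must name a condition")
  defaults <- list(n_points = 5000L, n_steps = 5000L)
  cfg$sampler <- utils::modifyList(defaults, cfg$sampler %||% list())
  dflt_diff <- list(p_thresh = 0.05, fc_thresh = 0.001, n_perm = 1000L,
                    levels = c("reaction", "metabolite", "subsystem"),
                    excluded_subsystems = default_excluded_subsystems())
  cfg$differential <- utils::modifyList(dflt_diff, cfg$differential %||% list())
  with(cfg$differential, {
    if (p_thresh <= 0 || p_thresh > 1)
      stop_fluxpath("validation", "p_thresh must be in (0, 1]")
    if (fc_thresh < 0) stop_fluxpath("validation", "fc_thresh must be >= 0")
  })
  cfg$output_dir <- cfg$output_dir %||% "fluxpath_out"
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the sampling and differential-flux workflow
#'
#' For every condition: applies knockouts, measured-rate constraints and MFA
#' CI constraints (with [repair_constraints()] discarding conflicting CIs),
#' samples the flux polytope, computes the mixed-fraction diagnostic and the
#' per-reaction summary; then runs [differential_levels()] for each
#' non-reference condition against the reference at the configured levels.
#' All tables are written under `output_dir` along with a JSON run report
#' echoing the configuration, seeds, discarded constraints and diagnostics.
#'
#' @param config a `pipeline_config` (or path to one).
#' @return The run report (list), invisibly; side effect: files under
#'   `output_dir`.
#' @export
run_workflow <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
  else validate_pipeline_config(unclass(config))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  base_model <- read_model(cfg$model)
  report <- list(package_version = as.character(utils::packageVersion("fluxpath")),
                 config = unclass(cfg), conditions = list())
  samples <- list()
  models <- list()
  for (cond in names(cfg$conditions)) {
    spec <- cfg$conditions[[cond]] %||% list()
    model <- base_model
    if (length(spec$knockouts))
      model <- apply_knockout(model, unlist(spec$knockouts))
    # measured rates and MFA CIs share the elastic repair: constraints that
    # make the model infeasible are discarded greedily, then resampled
    all_cis <- NULL
    if (!is.null(spec$rates))
      all_cis <- rates_to_ci(read_rate_measurements(spec$rates))
    if (!is.null(spec$cis)) {
      ci <- read_flux_ci(spec$cis)
      all_cis <- if (is.null(all_cis)) ci else rbind(all_cis, ci)
    }
    discarded <- character()
    if (!is.null(all_cis)) {
      rep_out <- repair_constraints(model, all_cis)
      model <- rep_out$model
      discarded <- rep_out$discarded
      write_repair_report(rep_out,
                          file.path(cfg$output_dir,
                                    paste0(cond, "_repair.json")))
    }
    smp <- sample_fluxes(model, n_points = cfg$sampler$n_points,
                         n_steps = cfg$sampler$n_steps, seed = cfg$seed)
    mf <- mixed_fraction(smp)
    write_sample(smp, file.path(cfg$output_dir, paste0(cond, "_sample.tsv")))
    utils::write.table(summarize_sample(smp),
                       file.path(cfg$output_dir, paste0(cond, "_summary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$conditions[[cond]] <- list(discarded_cis = discarded,
                                      mixed_fraction = mf)
    samples[[cond]] <- smp
    models[[cond]] <- model
  }
  for (cond in setdiff(names(cfg$conditions), cfg$reference)) {
    for (lev in cfg$differential$levels) {
      recs <- differential_levels(
        samples[[cond]], samples[[cfg$reference]], base_model, level = lev,
        p_thresh = cfg$differential$p_thresh,
        fc_thresh = cfg$differential$fc_thresh,
        n_perm = cfg$differential$n_perm, seed = cfg$seed,
        excluded_subsystems = cfg$differential$excluded_subsystems)
      write_differential_report(
        recs, file.path(cfg$output_dir,
                        paste0(cond, "_vs_", cfg$reference, "_", lev, ".tsv")))
    }
  }
  jsonlite::write_json(report, file.path(cfg$output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
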