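#' Build a full-analysis run configuration
#'
#' Assembles the configuration consumed by [run_full_analysis()]: the
#' synthetic-data generator settings plus per-stage options. Per-stage seeds
#' are derived from the master seed by fixed offsets (generator: seed;
#' jackknife: seed + 1; simulation: seed + 2).
#'
#' @param seed Master seed for the run.
#' @param synthetic Named list of [synthetic_config()] arguments (the master
#'   seed is injected).
#' @param gap_threshold,window Movement-extraction settings (seconds).
#' @param curve_reps,frac_removed Jackknife settings.
#' @param fit_species Species fitted independently (default the two most
#'   common).
#' @param variant,convention Fit settings (see [fit_decision_model()]).
#' @param compute_ci Compute profile CIs for the fits (default `TRUE`).
#' @param n_flocks,n_decisions Agent-based simulation scale.
#' @param figures Write PNG figures (default `TRUE`).
#' @return A `flock_run_config` list.
#' @export
flock_run_config <- function(seed = 1L, synthetic = list(),
                             gap_threshold = 240, window = 30,
                             curve_reps = 1000L, frac_removed = 0.4,
                             fit_species = c("blue_tit", "great_tit"),
                             variant = "two_species",
                             convention = "conditional",
                             compute_ci = TRUE,
                             n_flocks = 1000L, n_decisions = 50L,
                             figures = TRUE) {
  synthetic$seed <- as.integer(seed)
  structure(
    list(seed = as.integer(seed), synthetic = synthetic,
         gap_threshold = gap_threshold, window = window,
         curve_reps = curve_reps, frac_removed = frac_removed,
         fit_species = fit_species, variant = variant,
         convention = convention, compute_ci = compute_ci,
         n_flocks = n_flocks, n_decisions = n_decisions, figures = figures),
    class = "flock_run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the arguments of [flock_run_config()]; a
#' `synthetic$generator_params` block with `s` (or `s_c`/`s_h`), `k`, `a` is
#' converted to [decision_params()].
#'
#' @param path Path to a YAML file.
#' @return A `flock_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- y$synthetic %||% list()
  if (!is.null(syn$generator_params)) {
    syn$generator_params <- as_flock_params(syn$generator_params)
  }
  if (!is.null(syn$species_weights)) {
    syn$species_weights <- as.numeric(syn$species_weights)
  }
  args <- y[setdiff(names(y), "synthetic")]
  args$synthetic <- syn
  do.call(flock_run_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes generate -> extract -> curves (+ jackknife envelope + TASP) ->
#' fit (per species) -> agent-based replay -> comparison as one reproducible
#' run, writing all tables as CSV, fits as JSON, optional figures as PNG, and
#' a manifest (seeds, per-stage event counts, md5 digests of every output)
#' as JSON. A re-run with the same configuration reproduces all numeric
#' outputs.
#'
#' @param config A `flock_run_config` (or YAML path).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list; also written to
#'   `manifest.json`).
#' @export
run_full_analysis <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "flock_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # 1. generate
  syn_cfg <- stage("generate", do.call(synthetic_config, config$synthetic))
  stream <- stage("generate", generate_dataset(syn_cfg))
  f <- file.path(out_dir, "detections.csv")
  write_detections(stream, f, seed = syn_cfg$seed)
  outputs <- c(outputs, f, paste0(f, ".meta.json"))
  counts$detections <- nrow(stream)

  # 2. extract
  events <- stage("extract", extract_movements(
    stream, gap_threshold = config$gap_threshold, window = config$window))
  if (nrow(events) == 0L) stop("pipeline stage 'extract' failed: no movement events", call. = FALSE)
  f <- file.path(out_dir, "events.csv")
  write_events(events, f)
  outputs <- c(outputs, f, paste0(f, ".meta.json"))
  counts$events <- nrow(events)

  # 3. curves + envelope + TASP
  curve <- stage("curves", empirical_density_curves(events))
  env <- stage("curves", jackknife_envelope(
    events, reps = config$curve_reps, frac_removed = config$frac_removed,
    seed = config$seed + 1L))
  tasp <- tasp_curves(curve$bin_mid,
                      n_feeders = attr(events, "n_feeders"))
  f <- file.path(out_dir, "curves.csv")
  write_curves(curve, f, envelope = env, tasp = tasp)
  outputs <- c(outputs, f)

  # 4. fits per species
  fits <- list()
  for (sp in config$fit_species) {
    fit <- stage(paste0("fit_", sp), fit_decision_model(
      events, variant = config$variant, species = sp,
      convention = config$convention, compute_ci = config$compute_ci))
    fits[[sp]] <- fit
    f <- file.path(out_dir, sprintf("fit_%s.json", sp))
    write_fit_json(fit, f)
    outputs <- c(outputs, f)
    counts[[sprintf("fit_%s_events", sp)]] <- fit$n_events
  }

  # 5. agent-based replay with the fitted (or configured) rules
  sim_params <- resolve_params_by_species(syn_cfg$generator_params,
                                          syn_cfg$species_labels)
  sim_params[names(fits)] <- lapply(fits, `[[`, "params")
  pool <- stage("simulate", snapshot_pool(stream))
  sim_events <- stage("simulate", simulate_flocks(
    sim_params, pool, n_flocks = config$n_flocks,
    n_decisions = config$n_decisions, seed = config$seed + 2L))
  f <- file.path(out_dir, "sim_events.csv")
  write_events(sim_events, f)
  outputs <- c(outputs, f, paste0(f, ".meta.json"))
  counts$sim_events <- nrow(sim_events)

  cmp <- stage("compare", compare_simulation_to_curves(sim_events, curve))
  f <- file.path(out_dir, "sim_comparison.csv")
  write.csv(cmp$table, f, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, f)

  # figures
  if (isTRUE(config$figures)) {
    f <- file.path(out_dir, "curves.png")
    ggplot2::ggsave(f, plot_density_curves(curve, envelope = env, tasp = tasp),
                    width = 8, height = 4, dpi = 150)
    outputs <- c(outputs, f)
    for (sp in names(fits)) {
      dat <- fits[[sp]]$data
      surf <- choice_surface(fits[[sp]]$params,
                             n_c_total = max(1L, round(mean(rowSums(dat$nc)))),
                             n_h_total = max(1L, round(mean(rowSums(dat$nh)))))
      fs <- file.path(out_dir, sprintf("surface_%s.csv", sp))
      write_surface(surf, fs)
      fp <- file.path(out_dir, sprintf("surface_%s.png", sp))
      ggplot2::ggsave(fp, plot_choice_surface(surf), width = 5, height = 4,
                      dpi = 150)
      outputs <- c(outputs,
                   fs, fp,
                   Filter(file.exists,
                          sub("\\.csv$", "_contour.csv", fs)))
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("flockdecide")),
    master_seed = config$seed,
    stage_seeds = list(generate = config$seed, jackknife = config$seed + 1L,
                       simulate = config$seed + 2L),
    counts = counts,
    comparison = list(max_abs_discrepancy = cmp$max_abs_discrepancy,
                      pass = cmp$pass),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
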