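#' The calibrated reference profile
#'
#' The package's reference configuration (profile name `"paper"`, i.e. the
#' parameter set whose benchmarks come from the primary experimental
#' literature rather than from any one simulation run): calcium gating,
#' synapse kinetics, spike-train metrics, neuron electrical parameters and
#' morphology scale, jointly calibrated so that the simulator reproduces
#' the classical quantitative benchmarks of hippocampal synaptic
#' transmission (17
#' vesicles/s leaving rate and release probability ~0.85 under sustained
#' 4 Hz drive, saturation at the 20 vesicles/s synapse cap at 100 Hz,
#' ~20 s recovery of an exhausted recycling pool with a ~6.5 s exponential
#' time constant). See the methods vignette for the calibration rationale.
#'
#' @return A named list of parameter objects (`calcium`, `synapse`,
#'   `metrics`, `electrical`), plus `total_length` (um) and `seed`.
#' @export
paper_profile <- function() {
  list(calcium = calcium_params(),
       synapse = synapse_params(),
       metrics = metrics_params(),
       electrical = electrical_params(),
       total_length = 11500,
       seed = 1L)
}

.block_ctors <- function() {
  list(calcium = calcium_params,
       synapse = synapse_params,
       regulation = regulation_params,
       metrics = metrics_params,
       electrical = electrical_params)
}

#' Load a run configuration
#'
#' Builds a validated configuration from the calibrated profile plus
#' optional overrides in a YAML file. The file may contain blocks
#' `calcium`, `synapse`, `regulation`, `metrics`, `electrical`,
#' `morphology` (key `total_length`), and top-level `seed` / `out_dir`.
#' Every key must name a documented parameter of the corresponding block
#' (units as in the parameter documentation); unknown keys are rejected by
#' name.
#'
#' @param path YAML file path, or `NULL` for pure profile defaults.
#' @param profile base profile name; only `"paper"` is defined.
#' @return A `run_config` object: list of parameter objects plus `seed`,
#'   `total_length` and `out_dir`.
#' @export
load_config <- function(path = NULL, profile = "paper") {
  if (!identical(profile, "paper"))
    stop("unknown profile: ", profile, call. = FALSE)
  cfg <- paper_profile()
  cfg$out_dir <- "."
  overrides <- if (is.null(path)) list()
               else yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  ctors <- .block_ctors()
  known_top <- c(names(ctors), "morphology", "seed", "out_dir")
  bad <- setdiff(names(overrides), known_top)
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (block in names(ctors)) {
    ov <- overrides[[block]]
    if (block == "regulation" && is.null(ov) && is.null(cfg$regulation))
      next
    ctor <- ctors[[block]]
    ok <- names(formals(ctor))
    bad <- setdiff(names(ov), ok)
    if (length(bad))
      stop("unknown config key: ", block, ".", bad[1], call. = FALSE)
    if (block == "regulation") {
      if (is.null(ov$e_desired))
        stop("regulation block requires e_desired (ATP/s)", call. = FALSE)
      cfg$regulation <- do.call(ctor, ov)
    } else if (length(ov)) {
      cfg[[block]] <- do.call(ctor, ov)
    }
  }
  if (!is.null(overrides$morphology)) {
    bad <- setdiff(names(overrides$morphology), "total_length")
    if (length(bad))
      stop("unknown config key: morphology.", bad[1], call. = FALSE)
    cfg$total_length <- overrides$morphology$total_length
  }
  if (!is.null(overrides$seed)) cfg$seed <- as.integer(overrides$seed)
  if (!is.null(overrides$out_dir)) cfg$out_dir <- overrides$out_dir
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' Writes the configuration back to YAML (full precision), so that
#' `load_config(save_config(cfg, f))` round-trips.
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  out <- list(calcium = strip(config$calcium),
              synapse = strip(config$synapse),
              metrics = strip(config$metrics),
              electrical = strip(config$electrical),
              morphology = list(total_length = config$total_length),
              seed = config$seed,
              out_dir = config$out_dir)
  out$synapse$h_m <- NULL   # derived field
  if (!is.null(config$regulation)) out$regulation <- strip(config$regulation)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Run a packaged experiment
#'
#' Reproducible end-to-end runs of the package's four standard experiments:
#' \describe{
#'   \item{`fig2-unconstrained`}{vesicle cycle without energy regulation
#'     under sustained 4 Hz and 100 Hz periodic drive (100 s each);
#'     reports steady leaving rates and release probabilities.}
#'   \item{`fig3-regulated`}{energy-regulated run at 4 Hz (desired level
#'     8.2e5 ATP/s unless a regulation block overrides it); reports the
#'     first-window and steady leaving counts, steady `tau_s` and the
#'     relative energy mismatch.}
#'   \item{`fig3d-recovery`}{recovery of an exhausted recycling pool;
#'     reports the time to 95% of capacity and the fitted exponential time
#'     constant.}
#'   \item{`fig45-sweep`}{firing-frequency / ATP-per-bit sweep over active
#'     proximal-basal synapse counts on the compartmental neuron.}
#' }
#' Each run writes its trajectory/trace CSVs, a `summary.json` and a
#' provenance record (config file, seed, package version) under
#' `config$out_dir`.
#'
#' @param name experiment name (see above).
#' @param config a [load_config()] configuration.
#' @return The summary list, invisibly.
#' @export
run_experiment <- function(name, config = load_config()) {
  valid <- c("fig2-unconstrained", "fig3-regulated", "fig3d-recovery",
             "fig45-sweep")
  if (!name %in% valid)
    stop("unknown experiment '", name, "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  summary <- switch(
    name,
    "fig2-unconstrained" = {
      res <- list()
      for (f in c(4, 100)) {
        train <- periodic_train(f, 100)
        traj <- simulate_synapse(train, config$synapse, config$calcium)
        export_trajectory(traj, out(sprintf("unconstrained_%dHz.csv", f)))
        res[[sprintf("rate_%dHz", f)]] <- leaving_rate(traj)
        res[[sprintf("rp_%dHz", f)]] <- release_probability(traj)
      }
      res
    },
    "fig3-regulated" = {
      reg <- if (!is.null(config$regulation)) config$regulation
             else regulation_params(e_desired = 8.2e5)
      train <- periodic_train(4, 100 * reg$window)
      run <- simulate_regulated(train, config$synapse, config$calcium, reg)
      write.csv(run$trace, out("regulated_trace.csv"), row.names = FALSE)
      ss <- steady_state(run)
      list(first_window_leaving = run$trace$leaving[1],
           steady_leaving_per_window = ss$leaving_per_window,
           steady_rp = ss$rp, steady_tau_s = ss$tau_s,
           energy_mismatch_rel = ss$objective_rel,
           pool_ratio = ss$pool_ratio)
    },
    "fig3d-recovery" = {
      curve <- recovery_curve(config$synapse, 40)
      write.csv(curve, out("recovery_curve.csv"), row.names = FALSE)
      h_m <- config$synapse$h_m
      t95 <- curve$time[which(curve$pool >= 0.95 * h_m)[1]]
      list(time_to_95pct = t95,
           fitted_tau = fit_recovery_tau(curve, h_m))
    },
    "fig45-sweep" = {
      morph <- morphology_spec(total_length = config$total_length)
      neuron <- build_neuron(morph, config$electrical)
      cap <- synapse_capacity(morph)[["proximal_basal"]]
      surf <- sweep_firing(neuron,
                           list(proximal_basal =
                                  unique(round(seq(0, cap, length.out = 6)))),
                           duration = 2, seed = config$seed,
                           metrics = config$metrics)
      write.csv(surf, out("sweep_proximal_basal.csv"), row.names = FALSE)
      list(max_frequency = max(surf$frequency),
           max_atp_per_bit = max(surf$atp_per_bit, na.rm = TRUE))
    })
  jsonlite::write_json(summary, out("summary.json"), digits = NA,
                       auto_unbox = TRUE)
  cfg_path <- out("config_used.yaml")
  save_config(config, cfg_path)
  prov <- list(experiment = name, seed = config$seed,
               config_file = basename(cfg_path),
               config_md5 = unname(tools::md5sum(cfg_path)),
               package_version =
                 as.character(utils::packageVersion("synvesim")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, out("provenance.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(summary)
}
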