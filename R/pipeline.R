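# Configuration-driven orchestration: validate a YAML analysis config and
# run the full hydration-dynamics sequence (structure -> transport ->
# hydration -> hydrogen bonds) on a trajectory, collecting a
# machine-readable report.

default_config <- function() {
  list(
    trajectory = list(coordinate_path = NULL, trajectory_path = NULL, dt = 1),
    selections = list(protein = "protein", shell_reference = "protein_heavy",
                      water = "water", msd = "all", rmsd = "ca"),
    cutoffs = list(shell = 0.6, local_shell = 0.5,
                   hbond_da = 0.35, hbond_angle = 30),
    windows = list(msd_window = 200, residence_window = 200),
    lags = list(reorientation_max_lag = 20, hbond_max_lag = 500,
                msd_max_lag = NULL),
    strides = list(origin_stride = 1),
    fit = list(bounds = NULL, fix_gamma = NULL),
    msd_fit = list(fit_min = 10, fit_max = 100),
    rdf = list(r_max = 3.0, bin_width = 0.002),
    sasa = list(probe = 0.14, n_sphere_points = 960),
    stages = list("structure", "transport", "hydration", "hbond"),
    seed = 1,
    output_dir = NULL
  )
}

# positive-parameter checks: config key path -> error naming the path
check_config_values <- function(cfg) {
  pos <- c("trajectory.dt", "cutoffs.shell", "cutoffs.local_shell",
           "cutoffs.hbond_da", "cutoffs.hbond_angle", "windows.msd_window",
           "windows.residence_window", "lags.reorientation_max_lag",
           "lags.hbond_max_lag", "rdf.r_max", "rdf.bin_width",
           "sasa.probe", "strides.origin_stride")
  for (key in pos) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)) {
      hs_stop("config key '%s' must be a positive number (got %s)",
              "hs_config_error", key, paste(format(v), collapse = ","))
    }
  }
  known_stages <- c("structure", "transport", "hydration", "hbond")
  bad <- setdiff(unlist(cfg$stages), known_stages)
  if (length(bad)) {
    hs_stop("config key 'stages' contains unknown stage(s): %s",
            "hs_config_error", paste(bad, collapse = ", "))
  }
  cfg
}

merge_config <- function(defaults, user, path = character(0)) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    hs_stop("unknown config key(s): %s", "hs_config_error",
            paste(paste(c(path, ""), collapse = "."), unknown,
                  sep = "", collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[k] <- list(user[[k]])  # keeps explicit NULLs as values
    }
  }
  defaults
}

#' Validate an analysis configuration
#'
#' Reads a YAML file (or takes a list), checks every key against the
#' schema, fills defaults (shell 0.6 nm, local shell 0.5 nm, H-bond
#' criterion 0.35 nm / 30 degrees, 200 ps windows), and verifies that all
#' physical parameters are positive. An empty file yields the all-defaults
#' configuration. Violations are reported with their key path.
#'
#' @param x path to a YAML file, or a configuration list.
#' @return Validated config list of class `analysis_config`, carrying a
#'   `config_hash` attribute.
#' @export
validate_config <- function(x = list()) {
  if (is.character(x)) {
    if (!file.exists(x)) hs_stop("config file '%s' not found", "hs_io_error", x)
    x <- tryCatch(yaml::read_yaml(x), error = function(e)
      hs_stop("config file does not parse as YAML: %s", "hs_config_error",
              conditionMessage(e)))
    if (is.null(x)) x <- list()
  }
  if (inherits(x, "analysis_config")) x <- unclass(x)
  if (!is.list(x)) hs_stop("config must be a YAML mapping", "hs_config_error")
  cfg <- check_config_values(merge_config(default_config(), x))
  attr(cfg, "config_hash") <- fnv1a_hash(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

#' Serialize a validated configuration to YAML text
#'
#' @param cfg an `analysis_config`.
#' @return A YAML string (round-trips through [validate_config()]).
#' @export
dump_config <- function(cfg) {
  yaml::as.yaml(unclass(cfg))
}

run_stage <- function(report, name, expr, log = TRUE) {
  t0 <- proc.time()["elapsed"]
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  wall <- proc.time()["elapsed"] - t0
  if (log) {
    message(sprintf("[hydrashell] stage=%s status=%s wall=%.2fs", name,
                    if (res$ok) "ok" else "failed", wall))
  }
  report$stages[[name]] <- if (res$ok) {
    c(list(status = "ok"), res$value)
  } else {
    list(status = "failed", error = res$value)
  }
  report
}

#' Run the full hydration-dynamics analysis pipeline
#'
#' Executes, per the configuration: structure metrics (RMSF, RMSD, SASA),
#' transport metrics (windowed MSD, MSD + diffusion coefficient, RDF with
#' peak statistics), hydration dynamics (shell membership, residence
#' correlation + stretched-exponential fit, dipole autocorrelation +
#' exponential fit), and hydrogen-bond dynamics (counts, existence matrix,
#' continuous lifetime, intermittent correlation, relaxation time). Each
#' stage is independently trapped: a failure is recorded in the report and
#' later stages still run. When `output_dir` is set, per-stage CSV/JSON
#' tables (stamped with the config hash) and a consolidated
#' `report.json` are written. Outputs are a pure function of (inputs,
#' config, seed).
#'
#' @param config an `analysis_config` (or anything [validate_config()]
#'   accepts).
#' @param traj optional `md_trajectory`; when `NULL` it is read from the
#'   paths in the config.
#' @param log emit one log line per stage.
#' @return Report list: `config_hash`, `parameters`, `stages` (named list
#'   with per-stage results or failure diagnostics).
#' @export
run_pipeline <- function(config = list(), traj = NULL, log = TRUE) {
  cfg <- validate_config(config)
  if (is.null(traj)) {
    if (is.null(cfg$trajectory$coordinate_path)) {
      hs_stop("no trajectory supplied and no coordinate_path in config", "hs_config_error")
    }
    traj <- read_trajectory(cfg$trajectory$coordinate_path,
                            cfg$trajectory$trajectory_path,
                            dt = cfg$trajectory$dt)
  }
  stages <- unlist(cfg$stages)
  crit <- hbond_criterion(cfg$cutoffs$hbond_da, cfg$cutoffs$hbond_angle)
  outdir <- cfg$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  hash <- attr(cfg, "config_hash")
  meta <- c(config_hash = hash, seed = cfg$seed)
  save_tab <- function(tab, file) {
    if (!is.null(outdir)) write_series(tab, file.path(outdir, file), "csv", meta = meta)
  }
  report <- list(config_hash = hash, parameters = unclass(cfg), stages = list())
  span <- traj$time[n_frames(traj)] - traj$time[1]

  if ("structure" %in% stages) {
    report <- run_stage(report, "structure", {
      prof <- rmsf(traj, "heavy", align_first = TRUE, by_residue = TRUE)
      rser <- rmsd_series(traj, 1, cfg$selections$rmsd, superpose_flag = TRUE)
      area <- sasa(traj, frame = n_frames(traj), selection = "heavy",
                   probe = cfg$sasa$probe,
                   n_sphere_points = cfg$sasa$n_sphere_points)
      save_tab(prof, "rmsf.csv"); save_tab(rser, "rmsd.csv")
      list(rmsf_mean = mean(prof$rmsf), rmsd_final = rser$rmsd[nrow(rser)],
           sasa_total = area$total)
    }, log)
  }
  if ("transport" %in% stages) {
    report <- run_stage(report, "transport", {
      tu <- unwrap_coordinates(traj)
      win <- min(cfg$windows$msd_window, span / 2)
      mw <- msd_windowed(tu, cfg$selections$msd, window = win)
      max_lag <- cfg$lags$msd_max_lag %||% (span / 2)
      ms <- msd(tu, cfg$selections$msd, max_lag = max_lag,
                origin_stride = cfg$strides$origin_stride)
      fit_min <- min(cfg$msd_fit$fit_min, max_lag / 2)
      fit_max <- min(cfg$msd_fit$fit_max, max_lag)
      dc <- diffusion_coefficient(ms, fit_min, fit_max)
      save_tab(ms, "msd.csv")
      rmax <- min(cfg$rdf$r_max, if (is.null(traj$box)) Inf else min(traj$box) / 2)
      curve <- rdf(traj, cfg$selections$shell_reference, "water_oxygen",
                   r_max = rmax, bin_width = cfg$rdf$bin_width)
      save_tab(curve, "rdf.csv")
      peaks <- tryCatch(rdf_peak_stats(curve), error = function(e) NULL)
      list(msd_window_mean = mw$mean, msd_window_sd = mw$sd,
           D = dc$D, D_se = dc$se, D_r_squared = dc$r_squared,
           rdf_peaks = peaks)
    }, log)
  }
  mem <- NULL
  if ("hydration" %in% stages) {
    report <- run_stage(report, "hydration", {
      mem <- shell_membership(traj, cfg$selections$shell_reference,
                              cfg$cutoffs$shell)
      win <- min(cfg$windows$residence_window, span)
      cr <- residence_correlation(mem, window = win,
                                  origin_stride = cfg$strides$origin_stride)
      rfit <- fit_residence(cr, bounds = cfg$fit$bounds,
                            fix_gamma = cfg$fit$fix_gamma, seed = cfg$seed)
      save_tab(cr, "residence_correlation.csv")
      cmu <- dipole_autocorrelation(traj, water_subset = mem,
                                    max_lag = min(cfg$lags$reorientation_max_lag, span),
                                    origin_stride = cfg$strides$origin_stride)
      mfit <- fit_reorientation(cmu)
      save_tab(cmu, "dipole_autocorrelation.csv")
      list(shell_mean_count = mean(colSums(mem$occupancy)),
           occupancy = mem$occupancy,
           residence_fit = rfit[c("params", "param_uncertainty",
                                  "rms_residual", "converged")],
           reorientation_fit = mfit[c("params", "param_uncertainty",
                                      "rms_residual", "converged")])
    }, log)
  }
  if ("hbond" %in% stages) {
    report <- run_stage(report, "hbond", {
      prot <- cfg$selections$protein
      wat <- cfg$selections$water
      cnt_pw <- hbond_count_series(traj, prot, wat, crit)
      cnt_ww <- hbond_count_series(traj, wat, wat, crit)
      hb <- hbond_existence(traj, prot, wat, crit)
      if (isTRUE(attr(hb, "empty"))) {
        hs_stop("no protein-water hydrogen bonds found in any frame", "hs_analysis_error")
      }
      tl <- continuous_lifetime(hb)
      ct <- intermittent_correlation(hb, max_lag = min(cfg$lags$hbond_max_lag, span),
                                     origin_stride = cfg$strides$origin_stride)
      save_tab(ct, "hbond_ct.csv")
      tr <- tryCatch(relaxation_time(ct), error = function(e) NULL)
      swc <- shell_water_count(traj, cfg$selections$shell_reference,
                               cfg$cutoffs$local_shell)
      list(protein_water_mean = cnt_pw$mean, protein_water_sd = cnt_pw$sd,
           water_water_mean = cnt_ww$mean,
           tau_hb = tl$tau_hb,
           tau_r = if (is.null(tr)) NA_real_ else tr$tau_r,
           shell_count_mean = swc$mean)
    }, log)
  }
  if (!is.null(outdir)) {
    rep_out <- report
    rep_out$stages <- lapply(rep_out$stages, function(s) {
      s$occupancy <- NULL  # matrices stay in the R object, not the JSON
      s
    })
    jsonlite::write_json(rep_out, file.path(outdir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE,
                         force = TRUE)
  }
  report
}
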