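#' Build a validated study configuration
#'
#' The configuration fixes every tunable of the pipeline so a run is fully
#' reproducible from (config, manifest).  Unknown keys are rejected.
#'
#' @param config nested list (e.g. from [read_config()]); see
#'   [default_config()] for the schema.
#' @return the validated config (class `study_config`).
#' @export
study_config <- function(config) {
  schema <- list(
    grid = c("dims", "voxel_mm", "origin_mm"),
    band = c("f_lo", "f_hi"),
    smoothing = c("fwhm_mm"),
    glm = c("hrf_time_to_peak", "hrf_shape", "hrf_duration"),
    seeds = NULL,
    group = c("per_voxel_z", "alpha", "n_iter", "connectivity", "seed",
              "report_floor_mm3", "rule", "var_equal"),
    scenario = c("phantom", "n_time", "TR", "noise_sd", "drift_amp",
                 "task_amp", "signal_amp", "n_adults", "n_children",
                 "seed_adults", "seed_children")
  )
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop(sprintf("unknown config section(s): %s", paste(unknown, collapse = ", ")))
  for (sec in names(schema)) {
    if (is.null(schema[[sec]]) || is.null(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in config$%s: %s", sec,
                   paste(bad, collapse = ", ")))
  }
  required <- c("grid", "band", "smoothing", "glm", "seeds", "group", "scenario")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop(sprintf("missing config section(s): %s", paste(missing, collapse = ", ")))
  with(config$band, {
    if (f_lo >= f_hi) stop("config band: f_lo must be < f_hi")
  })
  if (config$band$f_hi > 1 / (2 * config$scenario$TR))
    stop("config band: f_hi exceeds the Nyquist frequency for this TR")
  if (config$smoothing$fwhm_mm < 0) stop("config smoothing: fwhm_mm must be >= 0")
  if (config$group$alpha <= 0 || config$group$alpha >= 1)
    stop("config group: alpha must be in (0, 1)")
  if (!config$group$connectivity %in% c(6, 26))
    stop("config group: connectivity must be 6 or 26")
  stopifnot(is.data.frame(config$seeds),
            all(c("name", "x", "y", "z") %in% names(config$seeds)))
  structure(config, class = "study_config")
}

#' Demo configuration: desk-scale phantom, 8 + 8 subjects
#'
#' A complete configuration for the end-to-end pipeline on the
#' [mini_phantom()]: three seeds (left frontal, left temporal, left
#' precentral region centers), reduced run length, and a small Monte Carlo
#' iteration count.
#'
#' @param n_time run length (default 128 time steps).
#' @param n_per_group subjects per group (default 8).
#' @param n_iter Monte Carlo iterations (default 200).
#' @return a `study_config`.
#' @export
demo_config <- function(n_time = 128, n_per_group = 8, n_iter = 200) {
  ph <- mini_phantom()
  study_config(list(
    grid = list(dims = ph$grid$dims, voxel_mm = ph$grid$voxel_mm,
                origin_mm = ph$grid$origin_mm),
    band = list(f_lo = 0.0166, f_hi = 0.1),
    smoothing = list(fwhm_mm = 4),
    glm = list(hrf_time_to_peak = 6, hrf_shape = 6, hrf_duration = 32),
    seeds = data.frame(name = c("LF", "LT", "LP"),
                       x = c(-21, -21, -15), y = c(15, -18, 0),
                       z = c(6, 3, 18), stringsAsFactors = FALSE),
    group = list(per_voxel_z = 2.576, alpha = 0.05, n_iter = n_iter,
                 connectivity = 26, seed = 7, report_floor_mm3 = 300,
                 rule = "size", var_equal = TRUE),
    scenario = list(phantom = "mini", n_time = n_time, TR = 2,
                    noise_sd = 0.5, drift_amp = 1, task_amp = c(1, 1, 1, 1),
                    signal_amp = 1, n_adults = n_per_group,
                    n_children = n_per_group, seed_adults = 1001,
                    seed_children = 2002)))
}

#' Default full-scale configuration
#'
#' The [default_phantom()] grid, the three canonical seeds, the 0.0166-0.1 Hz
#' band, 4 mm smoothing and the 16/15 group design.
#'
#' @return a `study_config`.
#' @export
default_config <- function() {
  ph_grid <- volume_grid(c(44, 50, 40), c(3, 3, 3), origin_mm = c(-66, -75, -45))
  study_config(list(
    grid = list(dims = ph_grid$dims, voxel_mm = ph_grid$voxel_mm,
                origin_mm = ph_grid$origin_mm),
    band = list(f_lo = 0.0166, f_hi = 0.1),
    smoothing = list(fwhm_mm = 4),
    glm = list(hrf_time_to_peak = 6, hrf_shape = 6, hrf_duration = 32),
    seeds = default_seeds(),
    group = list(per_voxel_z = 2.576, alpha = 0.05, n_iter = 1000,
                 connectivity = 26, seed = 7, report_floor_mm3 = 300,
                 rule = "size", var_equal = TRUE),
    scenario = list(phantom = "default", n_time = 540, TR = 2,
                    noise_sd = 0.5, drift_amp = 1, task_amp = c(1, 1, 1, 1),
                    signal_amp = 1, n_adults = 16, n_children = 15,
                    seed_adults = 1001, seed_children = 2002)))
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML file.
#' @param config a `study_config`.
#' @name config_io
NULL

#' @rdname config_io
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$seeds)) raw$seeds <- as.data.frame(raw$seeds)
  study_config(raw)
}

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$seeds <- as.list(cfg$seeds)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_phantom <- function(config) {
  switch(config$scenario$phantom,
         mini = mini_phantom(),
         default = default_phantom(),
         null = null_phantom(),
         stop(sprintf("unknown phantom '%s'", config$scenario$phantom)))
}

config_scenarios <- function(config) {
  sc <- config$scenario
  common <- list(noise_sd = sc$noise_sd, drift_amp = sc$drift_amp,
                 task_amp = sc$task_amp, signal_amp = sc$signal_amp,
                 n_time = sc$n_time, TR = sc$TR)
  if (identical(sc$phantom, "mini")) {
    a <- do.call(mini_adult_scenario, c(list(n_subjects = sc$n_adults), common))
    b <- do.call(mini_child_scenario, c(list(n_subjects = sc$n_children), common))
  } else {
    a <- do.call(adult_scenario, c(list(n_subjects = sc$n_adults), common))
    b <- do.call(child_scenario, c(list(n_subjects = sc$n_children), common))
  }
  a$seed <- sc$seed_adults
  b$seed <- sc$seed_children
  list(a = a, b = b)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> smooth+GLM -> band-pass -> seed connectivity ->
#' group inference -> report.  Each subject is simulated (or read back from
#' a previously written study directory), spatially smoothed, residualized
#' against the task design, band-pass filtered, and correlated with each
#' seed; per seed, the two groups are contrasted with Monte Carlo
#' small-volume correction and a cluster table is written.  All outputs land
#' in `out_dir` together with a provenance sidecar (config, seeds, package
#' version, config file hash).
#'
#' @param config a `study_config` (see [demo_config()], [default_config()]).
#' @param out_dir output directory.
#' @param simulate if TRUE (default) subjects are simulated in memory from
#'   the config scenarios; if FALSE, `in_dir` must hold a study written by
#'   [simulate_study()].
#' @param in_dir input study directory when `simulate = FALSE`.
#' @param write_maps write per-subject z maps and group maps as NIfTI
#'   (default FALSE: only group-level outputs are written).
#' @param verbose log per-stage timing to stderr.
#' @return list with per-seed contrast results (`stat`, `mc`, `clusters`),
#'   the combined cluster table, and output paths.
#' @export
run_pipeline <- function(config, out_dir, simulate = TRUE, in_dir = NULL,
                         write_maps = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  log_stage <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[lffconn] ", fmt), ...))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    log_stage("%s: %.1f s", name, proc.time()[3] - t0)
    res
  }

  phantom <- config_phantom(config)
  grid <- phantom$grid
  band <- c(config$band$f_lo, config$band$f_hi)
  hrf <- gamma_hrf(config$scenario$TR, duration = config$glm$hrf_duration,
                   time_to_peak = config$glm$hrf_time_to_peak,
                   shape = config$glm$hrf_shape)
  seeds <- lapply(seq_len(nrow(config$seeds)), function(i)
    seed_spec(config$seeds$name[i],
              as.numeric(config$seeds[i, c("x", "y", "z")])))

  # analysis mask: VOI (plus the resolved seed spheres, which must be in it)
  mask <- phantom$mask
  for (sd_ in seeds) mask[flat_index(resolve_seed(sd_, grid), grid$dims)] <- TRUE

  subj_plan <- stage("plan", {
    if (simulate) {
      scen <- config_scenarios(config)
      rbind(
        data.frame(group = scen$a$label, k = seq_len(scen$a$n_subjects),
                   stringsAsFactors = FALSE),
        data.frame(group = scen$b$label, k = seq_len(scen$b$n_subjects),
                   stringsAsFactors = FALSE))
    } else {
      man <- read_manifest(file.path(in_dir, "manifest.json"))
      man$subjects
    }
  })

  events <- default_events(config$scenario$n_time, config$scenario$TR,
                           n_conditions = length(config$scenario$task_amp))
  design <- build_design(events, config$scenario$n_time, config$scenario$TR,
                         hrf = hrf)

  zmaps <- stage("subjects", {
    out <- list()
    if (simulate) scen <- config_scenarios(config)
    for (i in seq_len(nrow(subj_plan))) {
      if (simulate) {
        s <- if (subj_plan$group[i] == scen$a$label) scen$a else scen$b
        sid <- sprintf("%s_%02d", s$label, subj_plan$k[i])
        run <- simulate_subject(s, phantom, events = events, subject_id = sid,
                                seed = s$seed + subj_plan$k[i])$run
      } else {
        sid <- subj_plan$subject_id[i]
        run <- read_bold_nifti(file.path(in_dir, subj_plan$file[i]), grid,
                               subject_id = sid, group = subj_plan$group[i])
      }
      run <- smooth_spatial(run, config$smoothing$fwhm_mm)
      run <- glm_residuals(run, design, mask = mask)
      run <- bandpass(run, band, mask = mask)
      for (sd_ in seeds) {
        tc <- seed_timecourse(run, resolve_seed(sd_, grid))
        zm <- z_map(correlation_map(tc, run, mask, seed_name = sd_$name,
                                    subject_id = sid))
        out[[sd_$name]] <- c(out[[sd_$name]], list(zm))
        if (write_maps)
          write_map_nifti(zm, grid,
                          file.path(out_dir, sprintf("zmap_%s_%s.nii", sid, sd_$name)))
      }
      out[["group"]] <- c(out[["group"]], run$group)
    }
    out
  })
  groups <- unlist(zmaps$group)
  group_names <- unique(groups)

  results <- list()
  all_clusters <- list()
  for (sd_ in seeds) {
    res <- stage(paste0("group:", sd_$name), {
      maps <- zmaps[[sd_$name]]
      ga <- maps[groups == group_names[1]]
      gb <- maps[groups == group_names[2]]
      group_contrast(ga, gb, mask, grid,
                     per_voxel_z = config$group$per_voxel_z,
                     alpha = config$group$alpha,
                     n_iter = config$group$n_iter,
                     connectivity = config$group$connectivity,
                     seed = config$group$seed,
                     report_floor_mm3 = config$group$report_floor_mm3,
                     labels = list(map = phantom$labels,
                                   names = phantom$region_names),
                     labels_ab = group_names,
                     var_equal = config$group$var_equal,
                     rule = config$group$rule)
    })
    tab_path <- file.path(out_dir, sprintf("clusters_%s.csv", sd_$name))
    cluster_table(res$clusters, tab_path)
    if (write_maps) {
      gm <- group_mean_rmap(zmaps[[sd_$name]][groups == group_names[1]])
      write_map_nifti(gm, grid,
                      file.path(out_dir, sprintf("groupmean_%s_%s.nii",
                                                 group_names[1], sd_$name)))
      write_map_nifti(res$stat, grid,
                      file.path(out_dir, sprintf("statmap_%s.nii", sd_$name)))
    }
    results[[sd_$name]] <- res
    all_clusters[[sd_$name]] <- res$clusters
  }

  combined <- do.call(rbind, all_clusters)
  stage("report", {
    cluster_table(combined, file.path(out_dir, "clusters_all.csv"))
    cfg_path <- file.path(out_dir, "config.json")
    cfg <- unclass(config)
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "columns")
    sidecar <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                    package_version = as.character(utils::packageVersion("lffconn")),
                    n_subjects = nrow(subj_plan),
                    groups = group_names)
    jsonlite::write_json(sidecar, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(list(results = results, clusters = combined,
                 out_dir = out_dir,
                 tables = file.path(out_dir, c(sprintf("clusters_%s.csv",
                                                       config$seeds$name),
                                               "clusters_all.csv"))))
}
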