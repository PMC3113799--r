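#' Define a group simulation scenario
#'
#' A scenario fixes everything needed to simulate one group's runs: the
#' number of subjects, the coupling topology (edges between named phantom
#' regions with target correlations), noise and drift levels, task
#' amplitudes, run length and TR, and the base RNG seed.
#'
#' Coupling is implemented through shared latent band-limited signals: for an
#' edge (A, B, r) both regions receive the latent with weight sqrt(r) and a
#' private band-limited signal carrying the remaining variance, so the model
#' correlation of the two regions' noiseless band-limited components is
#' exactly r.  Consequently the target correlations incident to any one
#' region must sum to at most 1.
#'
#' @param label group label (e.g. "adults").
#' @param n_subjects number of subjects.
#' @param edges data.frame with columns region_a, region_b, r (each r in
#'   [0, 1)); NULL or empty for an uncoupled (null) group.
#' @param noise_sd white-noise standard deviation per voxel and time step
#'   (relative to the unit-variance band signal; default 0.5).
#' @param drift_amp amplitude of the sub-0.0166 Hz baseline drift (default 1).
#' @param task_amp per-condition amplitudes of the evoked response
#'   (default c(1, 1, 1, 1): the four-condition auditory design).
#' @param signal_amp amplitude of the regional band-limited signal (default 1).
#' @param n_time run length in time steps (default 540).
#' @param TR repetition time in seconds (default 2).
#' @param seed base RNG seed; subject k uses seed + k.
#' @return object of class `group_scenario`.
#' @export
group_scenario <- function(label, n_subjects, edges = NULL, noise_sd = 0.5,
                           drift_amp = 1, task_amp = c(1, 1, 1, 1),
                           signal_amp = 1, n_time = 540, TR = 2, seed = 1) {
  if (is.null(edges))
    edges <- data.frame(region_a = character(), region_b = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(edges),
            all(c("region_a", "region_b", "r") %in% names(edges)))
  if (any(edges$r >= 1)) stop("coupling r_target must be < 1")
  if (any(edges$r < 0)) stop("coupling r_target must be nonnegative")
  if (n_time < 64) stop("n_time must be >= 64 (enough LFF cycles in band)")
  if (TR <= 0) stop("TR must be positive")
  if (noise_sd < 0 || !is.finite(noise_sd)) stop("noise_sd must be a nonnegative finite number")
  if (drift_amp < 0 || any(task_amp < 0) || signal_amp < 0 ||
      any(!is.finite(c(drift_amp, task_amp, signal_amp))))
    stop("amplitudes must be nonnegative and finite")
  # per-region coupling budget
  regs <- unique(c(edges$region_a, edges$region_b))
  for (rg in regs) {
    tot <- sum(edges$r[edges$region_a == rg | edges$region_b == rg])
    if (tot > 1)
      stop(sprintf("region '%s': incident coupling targets sum to %.3g > 1", rg, tot))
  }
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 edges = edges, noise_sd = noise_sd, drift_amp = drift_amp,
                 task_amp = task_amp, signal_amp = signal_amp,
                 n_time = as.integer(n_time), TR = TR, seed = as.integer(seed)),
            class = "group_scenario")
}

#' Default adult-group scenario
#'
#' Couples the left frontal seed regions to the left posterior temporal
#' region: the ipsilateral frontotemporal topology of the mature language
#' network.
#'
#' @param n_subjects default 16.
#' @param ... further arguments to [group_scenario()].
#' @export
adult_scenario <- function(n_subjects = 16, ...) {
  edges <- data.frame(
    region_a = c("L_BA44", "L_IFS"),
    region_b = c("L_pSTS", "L_pSTS"),
    r = c(0.5, 0.4), stringsAsFactors = FALSE)
  group_scenario("adults", n_subjects, edges, seed = 1001, ...)
}

#' Default child-group scenario
#'
#' Couples left to right temporal regions, homotopic inferior frontal
#' regions, and the bilateral precentral regions: the interhemispheric
#' topology reported for children.
#'
#' @param n_subjects default 15.
#' @param ... further arguments to [group_scenario()].
#' @export
child_scenario <- function(n_subjects = 15, ...) {
  edges <- data.frame(
    region_a = c("L_pSTS", "L_BA44", "L_PCG"),
    region_b = c("R_pSTS", "R_BA44", "R_PCG"),
    r = c(0.5, 0.4, 0.5), stringsAsFactors = FALSE)
  group_scenario("children", n_subjects, edges, seed = 2002, ...)
}

#' Uncoupled (null) scenario
#'
#' All regions carry independent band-limited signals; useful for
#' false-positive-rate experiments.
#'
#' @param label,n_subjects,... passed to [group_scenario()].
#' @export
null_scenario <- function(label = "null", n_subjects = 8, ...) {
  group_scenario(label, n_subjects, edges = NULL, ...)
}

#' Simulate one subject's 4D BOLD run
#'
#' Voxel time courses are the sum of: a task component (the four-condition
#' event design convolved with the Gamma hemodynamic kernel, with random
#' per-voxel gains); a baseline drift below 0.0166 Hz (random per-voxel
#' mixture of Legendre/sinusoid trends); the region's band-limited signal
#' (0.0166-0.1 Hz) whose cross-region correlation structure is set by the
#' scenario's coupling edges; white Gaussian noise; and a constant baseline
#' of 100.
#'
#' @param scenario a [group_scenario()].
#' @param phantom a phantom from [make_phantom_voi()] (supplies grid, VOI and
#'   region membership).
#' @param events optional event table; defaults to
#'   [default_events()] for the scenario's run length.
#' @param subject_id subject identifier.
#' @param seed RNG seed for this subject (defaults to the scenario seed).
#' @return list with `run` (a [bold_run()]) and `truth` (group, seed, planted
#'   edges).
#' @export
simulate_subject <- function(scenario, phantom, events = NULL,
                             subject_id = "subj", seed = scenario$seed) {
  grid <- phantom$grid
  nt <- scenario$n_time
  TR <- scenario$TR
  edges <- scenario$edges
  unknown <- setdiff(unique(c(edges$region_a, edges$region_b)),
                     phantom$region_names)
  if (length(unknown))
    stop(sprintf("coupling edge references unknown region(s): %s",
                 paste(unknown, collapse = ", ")))
  set.seed(seed)
  if (is.null(events))
    events <- default_events(nt, TR, n_conditions = length(scenario$task_amp))
  design <- build_design(events, nt, TR)

  # regional band-limited signals with the planted correlation structure
  band <- lff_band()
  latents <- lapply(seq_len(nrow(edges)), function(e)
    band_limited_signal(nt, TR, band))
  region_sig <- matrix(0, nt, length(phantom$region_names))
  colnames(region_sig) <- phantom$region_names
  for (rg in phantom$region_names) {
    s <- numeric(nt)
    budget <- 0
    for (e in seq_len(nrow(edges))) {
      if (edges$region_a[e] == rg || edges$region_b[e] == rg) {
        s <- s + sqrt(edges$r[e]) * latents[[e]]
        budget <- budget + edges$r[e]
      }
    }
    s <- s + sqrt(1 - budget) * band_limited_signal(nt, TR, band)
    region_sig[, rg] <- s
  }

  dims <- grid$dims
  V <- prod(dims)
  M <- matrix(stats::rnorm(V * nt, sd = scenario$noise_sd), V, nt)

  # evoked response: per-voxel random gains on the condition regressors
  task_cols <- design$values[, -1, drop = FALSE]
  nc <- ncol(task_cols)
  gains <- matrix(stats::runif(V * nc, 0.5, 1.5), V, nc)
  gains <- sweep(gains, 2, scenario$task_amp[seq_len(nc)], "*")
  M <- M + gains %*% t(task_cols)

  # baseline drift below the analysis band
  B <- drift_basis(nt, TR)
  K <- ncol(B)
  coef <- matrix(stats::rnorm(V * K), V, K) * scenario$drift_amp / sqrt(K)
  M <- M + coef %*% t(B)

  # regional band-limited signal
  for (i in seq_along(phantom$region_names)) {
    vox <- which(phantom$labels == i)
    if (length(vox))
      M[vox, ] <- M[vox, ] +
        scenario$signal_amp * matrix(region_sig[, i], length(vox), nt,
                                     byrow = TRUE)
  }

  M <- M + 100
  run <- bold_run(array(M, c(dims, nt)), TR, grid,
                  subject_id = subject_id, group = scenario$label)
  truth <- list(subject_id = subject_id, group = scenario$label, seed = seed,
                edges = edges)
  list(run = run, truth = truth)
}

#' Simulate and write a full two-group study
#'
#' Writes one 4D NIfTI per subject, the VOI mask and region label map, the
#' event table (TSV), and a JSON manifest recording every subject's file,
#' group, planted edges and RNG seed, so any run can be regenerated
#' bit-identically from the manifest alone.
#'
#' @param scenario_a,scenario_b the two [group_scenario()]s.
#' @param phantom a phantom from [make_phantom_voi()].
#' @param out_dir output directory (created if missing).
#' @param events optional shared event table; defaults to [default_events()].
#' @return the manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
simulate_study <- function(scenario_a, scenario_b, phantom, out_dir,
                           events = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  nt <- scenario_a$n_time
  if (is.null(events))
    events <- default_events(nt, scenario_a$TR,
                             n_conditions = length(scenario_a$task_amp))
  write_events(events, file.path(out_dir, "events.tsv"))
  write_mask_nifti(phantom$mask, phantom$grid, file.path(out_dir, "voi_mask.nii"))
  write_mask_nifti(phantom$labels, phantom$grid, file.path(out_dir, "voi_labels.nii"))

  subjects <- list()
  for (scen in list(scenario_a, scenario_b)) {
    for (k in seq_len(scen$n_subjects)) {
      sid <- sprintf("%s_%02d", scen$label, k)
      sseed <- scen$seed + k
      sim <- simulate_subject(scen, phantom, events = events,
                              subject_id = sid, seed = sseed)
      path <- file.path(out_dir, paste0(sid, ".nii"))
      write_bold_nifti(sim$run, path)
      subjects[[length(subjects) + 1]] <-
        list(subject_id = sid, group = scen$label, file = basename(path),
             seed = sseed, edges = sim$truth$edges)
    }
  }
  manifest <- list(
    subjects = subjects,
    groups = list(a = scenario_meta(scenario_a), b = scenario_meta(scenario_b)),
    grid = list(dims = phantom$grid$dims, voxel_mm = phantom$grid$voxel_mm,
                origin_mm = phantom$grid$origin_mm),
    regions = phantom$regions,
    files = list(events = "events.tsv", voi_mask = "voi_mask.nii",
                 voi_labels = "voi_labels.nii"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

scenario_meta <- function(s) {
  list(label = s$label, n_subjects = s$n_subjects, edges = s$edges,
       noise_sd = s$noise_sd, drift_amp = s$drift_amp, task_amp = s$task_amp,
       signal_amp = s$signal_amp, n_time = s$n_time, TR = s$TR, seed = s$seed)
}

#' Desk-scale analogues of the default group scenarios
#'
#' Same coupling strengths and group sizes as [adult_scenario()] /
#' [child_scenario()], but on the region names of the [mini_phantom()]
#' (LF/RF frontal, LT/RT posterior temporal, LP/RP precentral).
#'
#' @param n_subjects group size (defaults 16 / 15).
#' @param ... further arguments to [group_scenario()] (e.g. `n_time`).
#' @name mini_scenarios
NULL

#' @rdname mini_scenarios
#' @export
mini_adult_scenario <- function(n_subjects = 16, ...) {
  edges <- data.frame(region_a = "LF", region_b = "LT", r = 0.5,
                      stringsAsFactors = FALSE)
  group_scenario("adults", n_subjects, edges, seed = 1001, ...)
}

#' @rdname mini_scenarios
#' @export
mini_child_scenario <- function(n_subjects = 15, ...) {
  edges <- data.frame(region_a = c("LT", "LP"), region_b = c("RT", "RP"),
                      r = c(0.5, 0.5), stringsAsFactors = FALSE)
  group_scenario("children", n_subjects, edges, seed = 2002, ...)
}
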