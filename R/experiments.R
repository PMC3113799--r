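#' Per-subject processing chain used by the validation experiments
#'
#' Simulate, smooth, residualize and band-pass one subject, returning the
#' filtered run.
#'
#' @param scenario a [group_scenario()].
#' @param phantom a phantom list.
#' @param design a `design_matrix` matching the scenario.
#' @param events the event table the design was built from.
#' @param mask analysis mask (default the phantom VOI).
#' @param fwhm_mm smoothing FWHM (default 4).
#' @param band analysis band (default [lff_band()]).
#' @param seed subject RNG seed.
#' @param subject_id subject identifier.
#' @return the processed [bold_run()].
#' @export
process_subject <- function(scenario, phantom, design, events,
                            mask = phantom$mask, fwhm_mm = 4,
                            band = lff_band(), seed = scenario$seed,
                            subject_id = "subj") {
  run <- simulate_subject(scenario, phantom, events = events,
                          subject_id = subject_id, seed = seed)$run
  run <- smooth_spatial(run, fwhm_mm)
  run <- glm_residuals(run, design, mask = mask)
  bandpass(run, band, mask = mask)
}

#' Planted-coupling recovery experiment
#'
#' Simulates subjects with a single coupled region pair, processes each
#' through smoothing, GLM residualization and band filtering, seeds a
#' 7-voxel sphere at the first region's center, and measures the mean
#' correlation-map value over the coupled region's voxels.  Recovery holds
#' when the subject-mean r is within tolerance of the planted target.
#'
#' @param r_target planted coupling.
#' @param n_subjects number of simulated subjects (default 100).
#' @param n_time run length (default 540).
#' @param phantom phantom (default [mini_phantom()]); the edge couples the
#'   first two region names.
#' @param seed base RNG seed.
#' @return list with `mean_r`, `r_target`, per-subject values `r`.
#' @export
coupling_recovery_experiment <- function(r_target, n_subjects = 100,
                                         n_time = 540,
                                         phantom = mini_phantom(),
                                         seed = 11) {
  ra <- phantom$region_names[1]
  rb <- phantom$region_names[3]
  edges <- if (r_target > 0)
    data.frame(region_a = ra, region_b = rb, r = r_target,
               stringsAsFactors = FALSE) else NULL
  scen <- group_scenario("sim", n_subjects, edges, n_time = n_time, seed = seed)
  events <- default_events(n_time, scen$TR)
  design <- build_design(events, n_time, scen$TR)
  seed_def <- seed_spec(ra, as.numeric(
    phantom$regions[phantom$regions$name == ra, c("x", "y", "z")]))
  seed_vox <- resolve_seed(seed_def, phantom$grid)
  target_flat <- flat_index(region_voxels(phantom, rb), phantom$grid$dims)
  rs <- numeric(n_subjects)
  for (k in seq_len(n_subjects)) {
    run <- process_subject(scen, phantom, design, events, seed = seed + k,
                           subject_id = sprintf("s%03d", k))
    tc <- seed_timecourse(run, seed_vox)
    cm <- correlation_map(tc, run, phantom$mask, seed_name = ra)
    rs[k] <- mean(cm$values[target_flat], na.rm = TRUE)
  }
  list(mean_r = mean(rs), r_target = r_target, r = rs)
}

#' Family-wise error calibration experiment
#'
#' Repeats the full null pipeline (no planted group difference): two groups
#' are simulated from the same uncoupled scenario, processed, seeded, and
#' contrasted with Monte Carlo cluster-size correction.  The returned rate
#' is the fraction of repetitions with at least one surviving cluster, which
#' should match the corrected alpha.
#'
#' @param n_reps study repetitions (default 300).
#' @param n_per_group subjects per group (default 8).
#' @param n_time run length (default 128).
#' @param n_iter Monte Carlo iterations per repetition (default 500).
#' @param alpha corrected level (default 0.05).
#' @param per_voxel_z cluster-forming threshold (default 2.576).
#' @param phantom phantom (default [null_phantom()]).
#' @param seed base RNG seed.
#' @return list with `fwe_rate`, `alpha`, and the per-repetition indicator.
#' @export
fwe_null_experiment <- function(n_reps = 300, n_per_group = 8, n_time = 128,
                                n_iter = 500, alpha = 0.05,
                                per_voxel_z = 2.576,
                                phantom = null_phantom(), seed = 42) {
  scen <- null_scenario(n_subjects = n_per_group, n_time = n_time)
  events <- default_events(n_time, scen$TR)
  design <- build_design(events, n_time, scen$TR)
  ra <- phantom$region_names[1]
  seed_def <- seed_spec(ra, as.numeric(
    phantom$regions[phantom$regions$name == ra, c("x", "y", "z")]))
  seed_vox <- resolve_seed(seed_def, phantom$grid)
  hits <- logical(n_reps)
  for (rep in seq_len(n_reps)) {
    base <- seed + rep * 1000L
    zm <- vector("list", 2 * n_per_group)
    for (k in seq_len(2 * n_per_group)) {
      run <- process_subject(scen, phantom, design, events, seed = base + k,
                             subject_id = sprintf("s%02d", k))
      tc <- seed_timecourse(run, seed_vox)
      zm[[k]] <- z_map(correlation_map(tc, run, phantom$mask, seed_name = ra))
    }
    ga <- zm[seq_len(n_per_group)]
    gb <- zm[n_per_group + seq_len(n_per_group)]
    res <- group_contrast(ga, gb, phantom$mask, phantom$grid,
                          per_voxel_z = per_voxel_z, alpha = alpha,
                          n_iter = n_iter, seed = base,
                          report_floor_mm3 = 0)
    hits[rep] <- nrow(res$clusters) > 0
  }
  list(fwe_rate = mean(hits), alpha = alpha, hits = hits)
}

#' Group-topology recovery experiment
#'
#' Simulates the two default group scenarios (adult: left frontal to left
#' posterior temporal coupling; child: interhemispheric temporal and
#' bilateral precentral coupling) on the desk-scale phantom, seeds the left
#' posterior temporal region, and checks per replicate that the corrected
#' group contrast contains an adults > children cluster overlapping the
#' planted left frontal region and a children > adults cluster overlapping
#' the planted right temporal region.
#'
#' @param n_reps replicates (default 20).
#' @param n_adults,n_children group sizes (defaults 16 / 15).
#' @param n_time run length (default 128).
#' @param n_iter Monte Carlo iterations (default 300).
#' @param phantom phantom (default [mini_phantom()]).
#' @param seed base RNG seed.
#' @return list with `success_rate` and the per-replicate indicators.
#' @export
topology_recovery_experiment <- function(n_reps = 20, n_adults = 16,
                                         n_children = 15, n_time = 128,
                                         n_iter = 300,
                                         phantom = mini_phantom(),
                                         seed = 73) {
  sa <- mini_adult_scenario(n_adults, n_time = n_time)
  sb <- mini_child_scenario(n_children, n_time = n_time)
  events <- default_events(n_time, sa$TR)
  design <- build_design(events, n_time, sa$TR)
  seed_def <- seed_spec("LT", as.numeric(
    phantom$regions[phantom$regions$name == "LT", c("x", "y", "z")]))
  seed_vox <- resolve_seed(seed_def, phantom$grid)
  lf_flat <- flat_index(region_voxels(phantom, "LF"), phantom$grid$dims)
  rt_flat <- flat_index(region_voxels(phantom, "RT"), phantom$grid$dims)
  ok <- logical(n_reps)
  for (rep in seq_len(n_reps)) {
    base <- seed + rep * 10000L
    zma <- lapply(seq_len(n_adults), function(k) {
      run <- process_subject(sa, phantom, design, events, seed = base + k,
                             subject_id = sprintf("a%02d", k))
      z_map(correlation_map(seed_timecourse(run, seed_vox), run,
                            phantom$mask, seed_name = "LT"))
    })
    zmb <- lapply(seq_len(n_children), function(k) {
      run <- process_subject(sb, phantom, design, events,
                             seed = base + 500L + k,
                             subject_id = sprintf("c%02d", k))
      z_map(correlation_map(seed_timecourse(run, seed_vox), run,
                            phantom$mask, seed_name = "LT"))
    })
    res <- group_contrast(zma, zmb, phantom$mask, phantom$grid,
                          n_iter = n_iter, seed = base,
                          report_floor_mm3 = 0,
                          labels_ab = c("adults", "children"))
    cl <- res$clusters
    pos_ok <- FALSE
    neg_ok <- FALSE
    if (nrow(cl)) {
      for (i in seq_len(nrow(cl))) {
        cvox <- cluster_voxels(res$stat, phantom$grid,
                               sign(cl$max_z[i]), cl[i, ],
                               res$mc$per_voxel_z)
        if (cl$max_z[i] > 0 && length(intersect(cvox, lf_flat))) pos_ok <- TRUE
        if (cl$max_z[i] < 0 && length(intersect(cvox, rt_flat))) neg_ok <- TRUE
      }
    }
    ok[rep] <- pos_ok && neg_ok
  }
  list(success_rate = mean(ok), ok = ok)
}

# flat voxel indices of the supra-threshold component containing the
# record's peak
cluster_voxels <- function(stat, grid, sgn, record, per_voxel_z) {
  vals <- stat$values * sgn
  supra <- !is.na(vals) & vals >= per_voxel_z
  lab <- label_components_cpp(supra, as.integer(grid$dims), 26L)
  pk <- flat_index(mm_to_index(c(record$x, record$y, record$z), grid),
                   grid$dims)
  which(lab == lab[pk])
}
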