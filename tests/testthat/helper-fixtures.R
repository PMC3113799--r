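# small reusable fixtures for the unit tests

tiny_grid <- function(n = 9) volume_grid(rep(n, 3))

# a small processed-subject chain on the mini phantom with reduced run length
quick_processed_subject <- function(scenario, phantom, seed = 1,
                                    fwhm_mm = 4) {
  ev <- default_events(scenario$n_time, scenario$TR)
  des <- build_design(ev, scenario$n_time, scenario$TR)
  process_subject(scenario, phantom, des, ev, fwhm_mm = fwhm_mm, seed = seed)
}

# deterministic synthetic run: supplied voxelwise series generator
run_from_fun <- function(grid, nt, TR = 2, fun) {
  V <- prod(grid$dims)
  M <- matrix(0, V, nt)
  for (v in seq_len(V)) M[v, ] <- fun(v)
  bold_run(array(M, c(grid$dims, nt)), TR, grid)
}

expect_no_na <- function(x) expect_false(anyNA(x))
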