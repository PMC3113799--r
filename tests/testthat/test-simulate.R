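test_that("scenario validation enforces the coupling contract", {
  e <- function(...) data.frame(..., stringsAsFactors = FALSE)
  expect_error(group_scenario("g", 4, e(region_a = "A", region_b = "B", r = 1)),
               "< 1")
  expect_error(group_scenario("g", 4, e(region_a = "A", region_b = "B", r = -0.1)),
               "nonnegative")
  expect_error(group_scenario("g", 4,
                              e(region_a = c("A", "A"), region_b = c("B", "C"),
                                r = c(0.7, 0.6))),
               "sum to")
  expect_error(group_scenario("g", 4, NULL, n_time = 32), ">= 64")
  ph <- mini_phantom()
  sc <- group_scenario("g", 1, e(region_a = "LF", region_b = "nowhere", r = 0.3),
                       n_time = 64)
  expect_error(simulate_subject(sc, ph), "unknown region")
})

test_that("the noiseless strongly-coupled limit yields r > 0.99", {
  ph <- mini_phantom()
  sc <- group_scenario("g", 1,
                       data.frame(region_a = "LF", region_b = "LT",
                                  r = 1 - 1e-6, stringsAsFactors = FALSE),
                       noise_sd = 0, drift_amp = 0, task_amp = c(0, 0, 0, 0),
                       n_time = 128, seed = 31)
  sim <- simulate_subject(sc, ph, seed = 31)
  a <- seed_timecourse(sim$run, region_voxels(ph, "LF"))
  b <- seed_timecourse(sim$run, region_voxels(ph, "LT"))
  expect_gt(cor(a, b), 0.99)
})

test_that("uncoupled regions have region-mean correlations centered at zero", {
  ph <- mini_phantom()
  sc <- null_scenario(n_subjects = 40, n_time = 128)
  rs <- sapply(1:40, function(k) {
    sim <- simulate_subject(sc, ph, seed = 100 + k)
    cor(seed_timecourse(sim$run, region_voxels(ph, "LF")),
        seed_timecourse(sim$run, region_voxels(ph, "LT")))
  })
  # null r at ~43 band dof: mean of 40 draws has se ~ 0.025
  expect_lt(abs(mean(rs)), 0.08)
})

test_that("simulation is bit-identical under a fixed seed", {
  ph <- mini_phantom()
  sc <- mini_adult_scenario(1, n_time = 64)
  s1 <- simulate_subject(sc, ph, seed = 77)
  s2 <- simulate_subject(sc, ph, seed = 77)
  expect_identical(s1$run$data, s2$run$data)
})

test_that("simulate_study writes a complete, exactly regenerable study", {
  ph <- mini_phantom()
  sa <- mini_adult_scenario(3, n_time = 64)
  sb <- mini_child_scenario(2, n_time = 64)
  dir_ <- file.path(tempdir(), "study_test")
  man <- simulate_study(sa, sb, ph, dir_)
  files <- list.files(dir_)
  expect_equal(sum(grepl("^(adults|children)_.*\\.nii$", files)), 5)
  expect_length(man$subjects, 5)
  expect_true(all(c("events.tsv", "voi_mask.nii", "voi_labels.nii",
                    "manifest.json") %in% files))
  # the mask round-trips
  mask_back <- read_volume_nifti(file.path(dir_, "voi_mask.nii"))
  expect_equal(sum(mask_back > 0), sum(ph$mask))
  # regenerate a subject from its manifest seed: bit-identical voxel data
  m <- read_manifest(file.path(dir_, "manifest.json"))
  rec <- m$subjects[2, ]
  ev <- read_events(file.path(dir_, "events.tsv"))
  again <- simulate_subject(sa, ph, events = ev, subject_id = rec$subject_id,
                            seed = rec$seed)
  on_disk <- read_bold_nifti(file.path(dir_, rec$file), ph$grid)
  expect_equal(max(abs(on_disk$data - again$run$data)), 0)
  expect_equal(on_disk$TR, 2)
  unlink(dir_, recursive = TRUE)
})

test_that("an empty group simulates but refuses downstream group testing", {
  ph <- mini_phantom()
  sa <- mini_adult_scenario(2, n_time = 64)
  sb <- mini_child_scenario(0, n_time = 64)
  dir_ <- file.path(tempdir(), "study_empty")
  man <- simulate_study(sa, sb, ph, dir_)
  expect_length(man$subjects, 2)
  expect_error(voxelwise_group_test(list(), list()), "at least 2")
  unlink(dir_, recursive = TRUE)
})
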