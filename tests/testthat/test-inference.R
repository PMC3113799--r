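mk_zmap <- function(vals, dims, seed_name = "s", group = "g") {
  structure(list(values = array(vals, dims), type = "z", seed = seed_name,
                 subject_id = "x", group = group), class = "conn_map")
}

test_that("identical groups give z ~ 0 and label swap negates the map", {
  dims <- c(6, 6, 6)
  set.seed(1)
  maps <- lapply(1:8, function(i) mk_zmap(rnorm(216, sd = 0.2), dims))
  a <- maps[1:4]; b <- maps[1:4]
  st <- voxelwise_group_test(a, b)
  expect_true(all(abs(st$values) < 1e-8))
  b2 <- maps[5:8]
  st1 <- voxelwise_group_test(a, b2, labels = c("A", "B"))
  st2 <- voxelwise_group_test(b2, a, labels = c("B", "A"))
  expect_equal(st1$values, -st2$values, tolerance = 1e-10)
  expect_error(voxelwise_group_test(maps[1], maps[2:4]), "at least 2")
})

test_that("power under a planted shift matches the noncentral-t prediction", {
  dims <- c(40, 25, 1)   # 1000 independent "voxels"
  nA <- nB <- 16
  delta <- 0.35; sdv <- 0.3
  set.seed(2)
  a <- lapply(seq_len(nA), function(i) mk_zmap(rnorm(1000, delta, sdv), dims))
  b <- lapply(seq_len(nB), function(i) mk_zmap(rnorm(1000, 0, sdv), dims))
  st <- voxelwise_group_test(a, b)
  zcrit <- qnorm(0.975)
  emp_power <- mean(st$values > zcrit)
  pred <- power.t.test(n = 16, delta = delta, sd = sdv,
                       sig.level = 0.05)$power
  expect_equal(emp_power, pred, tolerance = 4 * sqrt(pred * (1 - pred) / 1000))
})

test_that("smoothness estimates track the applied kernel and its ordering", {
  g <- volume_grid(c(24, 24, 24))
  mask <- array(TRUE, g$dims)
  set.seed(3)
  mk <- function(fwhm) {
    lapply(1:6, function(i) {
      x <- smooth_array(array(rnorm(prod(g$dims)), g$dims), g, fwhm)
      x / sd(x)
    })
  }
  est0 <- estimate_smoothness(mk(0), mask, g$voxel_mm)
  est4 <- estimate_smoothness(mk(4), mask, g$voxel_mm)
  est6 <- estimate_smoothness(mk(6), mask, g$voxel_mm)
  expect_lt(abs(est0 - 3), 1)            # white noise ~ voxel size
  expect_lt(abs(est6 - 6), 1)
  expect_true(est0 < est4 && est4 < est6) # monotone in applied smoothing
  cmap <- list(array(1, g$dims), array(1, g$dims))
  expect_error(estimate_smoothness(cmap, mask, g$voxel_mm), "constant")
})

test_that("the Monte Carlo cutoff degenerates to 1 and is monotone in the threshold", {
  ph <- null_phantom()
  mc_hi <- mc_cluster_threshold(ph$mask, ph$grid, 4, per_voxel_z = 20,
                                n_iter = 100, seed = 5)
  expect_equal(mc_hi$min_cluster_vox, 1L)
  expect_true(all(mc_hi$max_sizes == 0))
  mc_lo <- mc_cluster_threshold(ph$mask, ph$grid, 4, per_voxel_z = 2.0,
                                n_iter = 150, seed = 5)
  mc_mid <- mc_cluster_threshold(ph$mask, ph$grid, 4, per_voxel_z = 2.576,
                                 n_iter = 150, seed = 5)
  expect_gte(mc_lo$min_cluster_vox, mc_mid$min_cluster_vox)
  expect_gte(mc_mid$min_cluster_vox, mc_hi$min_cluster_vox)
  # determinism given the seed
  mc_mid2 <- mc_cluster_threshold(ph$mask, ph$grid, 4, per_voxel_z = 2.576,
                                  n_iter = 150, seed = 5)
  expect_identical(mc_mid$max_sizes, mc_mid2$max_sizes)
  expect_error(mc_cluster_threshold(array(FALSE, ph$grid$dims), ph$grid, 4,
                                    n_iter = 100), "empty mask")
})

test_that("cluster finding respects thresholds, signs and connectivity", {
  g <- volume_grid(c(12, 12, 12))
  vals <- array(0, g$dims)
  st <- structure(list(values = vals, nA = 8, nB = 8, df = 14,
                       labels = c("adults", "children"), seed = "s",
                       contrast = "adults - children"), class = "stat_map")
  expect_equal(nrow(find_clusters(st, g, report_floor_mm3 = 0)), 0)

  # one connected 33-voxel positive blob (11 x 3 x 1): 891 mm^3 at 27 mm^3/voxel
  blob <- vals
  blob[1:11, 1:3, 6] <- 5
  st$values <- blob
  recs <- find_clusters(st, g, per_voxel_z = 2.576, min_size_vox = 1,
                        report_floor_mm3 = 300)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$size_vox, 33)
  expect_equal(recs$size_mm3, 891)
  expect_equal(recs$contrast, "adults > children")

  # negative blob keeps its sign and direction
  st$values <- -blob
  nrecs <- find_clusters(st, g, per_voxel_z = 2.576, min_size_vox = 1,
                         report_floor_mm3 = 300)
  expect_equal(nrecs$contrast, "children > adults")
  expect_equal(nrecs$max_z, -5)

  # two diagonal blobs: merged under 26-connectivity, split under 6
  two <- array(0, g$dims)
  two[2:6, 2:6, 2:3] <- 4
  two[7:11, 7:11, 4:5] <- 4   # touches only diagonally at (6,6,3)/(7,7,4)
  st$values <- two
  r26 <- find_clusters(st, g, min_size_vox = 1, report_floor_mm3 = 0,
                       connectivity = 26)
  r6 <- find_clusters(st, g, min_size_vox = 1, report_floor_mm3 = 0,
                      connectivity = 6)
  expect_equal(nrow(r26), 1)
  expect_equal(nrow(r6), 2)

  # report floor drops small survivors
  small <- array(0, g$dims); small[1:2, 1, 1] <- 5
  st$values <- small
  expect_equal(nrow(find_clusters(st, g, min_size_vox = 1,
                                  report_floor_mm3 = 300)), 0)
  expect_equal(nrow(find_clusters(st, g, min_size_vox = 1,
                                  report_floor_mm3 = 0)), 1)
})

test_that("cluster tables format, sort and round-trip", {
  recs <- data.frame(
    seed = c("s1", "s1", "s1"),
    region = c("L_pSTS", "L_PCG", "R_PCG"),
    contrast = c("adults > children", "children > adults", "children > adults"),
    x = c(-57, -48, 51), y = c(-39, -6, 3), z = c(18, 15, 36),
    max_z = c(3.27, -3.66, -2.95),
    size_vox = c(33, 44, 18), size_mm3 = c(891, 1188, 486),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  cluster_table(recs, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 3)
  expect_equal(names(back), c("Seed", "Region", "Contrast", "Location",
                              "Maximum", "Size"))
  # within a contrast, sizes descend
  cc <- back[back$Contrast == "children > adults", ]
  expect_true(all(diff(cc$Size) <= 0))
  expect_equal(back$Location[back$Region == "L_pSTS"], "-57 -39 18")
  # empty records give a header-only file
  p2 <- tempfile(fileext = ".csv")
  cluster_table(recs[0, ], p2)
  expect_equal(nrow(read.csv(p2)), 0)
})
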