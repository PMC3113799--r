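test_that("seeds resolve to the 7-voxel face-neighbor sphere (189 mm^3)", {
  g <- default_phantom()$grid
  for (i in seq_len(nrow(default_seeds()))) {
    sd_ <- seed_spec(default_seeds()$name[i],
                     as.numeric(default_seeds()[i, c("x", "y", "z")]))
    vox <- resolve_seed(sd_, g)
    expect_equal(nrow(vox), 7)
    expect_equal(nrow(unique(as.data.frame(vox))), 7)
    expect_equal(mask_volume_mm3(nrow(vox), g), 189)
    ctr <- mm_to_index(sd_$center_mm, g)
    expect_true(any(apply(vox, 1, function(v) all(v == ctr))))
    # 6 face neighbors at L1 distance exactly 1 from the center
    d1 <- apply(vox, 1, function(v) sum(abs(v - ctr)))
    expect_equal(sort(d1), c(0, rep(1, 6)))
  }
})

test_that("seeds 9 mm apart or more have disjoint spheres", {
  g <- volume_grid(c(15, 15, 15))
  a <- resolve_seed(seed_spec("a", c(0, 0, 0)), g)
  b <- resolve_seed(seed_spec("b", c(9, 0, 0)), g)
  key <- function(m) apply(m, 1, paste, collapse = ",")
  expect_length(intersect(key(a), key(b)), 0)
})

test_that("seed spheres touching the grid edge error", {
  g <- volume_grid(c(9, 9, 9), origin_mm = c(0, 0, 0))
  expect_error(resolve_seed(seed_spec("edge", c(0, 12, 12)), g),
               "face neighbor")
})

test_that("seed time course is the unweighted voxel mean", {
  g <- tiny_grid(5)
  sd_ <- seed_spec("s", c(0, 0, 0))
  vox <- resolve_seed(sd_, g)
  s <- sin(seq_len(40))
  run <- run_from_fun(g, 40, fun = function(v) s)
  expect_equal(seed_timecourse(run, vox), s)
  # mixed series: mean matches direct recomputation
  set.seed(6)
  run2 <- run_from_fun(g, 40, fun = function(v) rnorm(40, mean = v))
  flat <- lffconn:::flat_index(vox, g$dims)
  manual <- rowMeans(sapply(flat, function(f) {
    idx <- arrayInd(f, g$dims)
    run2$data[idx[1], idx[2], idx[3], ]
  }))
  expect_equal(seed_timecourse(run2, vox), manual, tolerance = 1e-12)
  # series canceling pointwise average to zero
  signs <- c(3, -1, -1, -1, 1, 1, -2)
  run3 <- run_from_fun(g, 40, fun = function(v) rep(0, 40))
  M <- matrix(run3$data, prod(g$dims), 40)
  for (k in seq_len(7)) M[flat[k], ] <- signs[k] * s
  run3$data <- array(M, c(g$dims, 40))
  expect_equal(seed_timecourse(run3, vox), rep(0, 40), tolerance = 1e-12)
})

test_that("correlation maps hit the self, negated and SNR-predicted values", {
  g <- tiny_grid(5)
  mask <- array(TRUE, g$dims)
  nt <- 5000
  set.seed(7)
  seed_series <- rnorm(nt)
  snr <- 2  # signal variance / noise variance
  run <- run_from_fun(g, nt, fun = function(v) {
    if (v == 1) seed_series
    else if (v == 2) -seed_series
    else seed_series + rnorm(nt, sd = sqrt(1 / snr))
  })
  cm <- correlation_map(seed_series, run, mask)
  vals <- cm$values
  expect_equal(vals[1, 1, 1], 1)
  expect_equal(vals[2, 1, 1], -1)
  # analytic r = 1 / sqrt(1 + 1/SNR), Monte Carlo tolerance ~ 3/sqrt(nt)
  pred <- 1 / sqrt(1 + 1 / snr)
  others <- vals[-c(1, 2)]
  expect_equal(mean(others), pred, tolerance = 3 / sqrt(nt))
  expect_true(all(abs(vals) <= 1, na.rm = TRUE))
})

test_that("zero-variance voxels are undefined; zero-variance seeds error", {
  g <- tiny_grid(3)
  mask <- array(TRUE, g$dims)
  set.seed(8)
  run <- run_from_fun(g, 30, fun = function(v) if (v == 5) rep(1, 30) else rnorm(30))
  cm <- correlation_map(rnorm(30), run, mask)
  expect_true(is.na(cm$values[5]))
  expect_error(correlation_map(rep(2, 30), run, mask), "zero-variance seed")
})

test_that("the Fisher transform matches its closed form and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.45), 0.5 * log(1.45 / 0.55), tolerance = 1e-12)
  r <- seq(-0.999, 0.999, length.out = 101)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), ">= 1")
  expect_identical(fisher_z(c(1, -1), allow_infinite = TRUE), c(Inf, -Inf))
})

test_that("group mean maps average z then invert to r", {
  g <- tiny_grid(3)
  mask <- array(TRUE, g$dims)
  set.seed(9)
  mk <- function(rvals) {
    vals <- array(rvals, g$dims)
    structure(list(values = vals, type = "r", seed = "s",
                   subject_id = "x", group = "g"), class = "conn_map")
  }
  r1 <- mk(runif(27, -0.5, 0.9))
  # single subject: inverse(forward(r)) is the identity
  gm1 <- group_mean_rmap(list(z_map(r1)))
  expect_equal(gm1$values, r1$values, tolerance = 1e-12)
  # antisymmetric pair averages to zero
  z1 <- z_map(r1)
  z2 <- z1; z2$values <- -z1$values
  gm0 <- group_mean_rmap(list(z1, z2))
  expect_equal(gm0$values, array(0, g$dims), tolerance = 1e-12)
  # three maps: scalar recomputation oracle per voxel
  rs <- list(mk(runif(27, -0.3, 0.8)), mk(runif(27, -0.3, 0.8)),
             mk(runif(27, -0.3, 0.8)))
  gm3 <- group_mean_rmap(lapply(rs, z_map))
  manual <- tanh((atanh(rs[[1]]$values) + atanh(rs[[2]]$values) +
                    atanh(rs[[3]]$values)) / 3)
  expect_equal(gm3$values, manual, tolerance = 1e-12)
  # display thresholding only marks values, never changes them
  th <- threshold_map(gm3, 0.45)
  kept <- !is.na(th$values)
  expect_true(all(abs(th$values[kept]) >= 0.45))
})

test_that("group mean rejects mismatched seeds", {
  g <- tiny_grid(3)
  mk <- function(seed_name) {
    structure(list(values = array(0.1, g$dims), type = "z", seed = seed_name,
                   subject_id = "x", group = "g"), class = "conn_map")
  }
  expect_error(group_mean_rmap(list(mk("a"), mk("b"))), "different seeds")
})
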