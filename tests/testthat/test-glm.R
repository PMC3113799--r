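make_design_fixture <- function(nt = 64, TR = 2) {
  ev <- default_events(nt, TR)
  build_design(ev, nt, TR)
}

test_that("a run lying exactly in the design span has zero residuals", {
  g <- tiny_grid(5)
  d <- make_design_fixture()
  set.seed(1)
  beta <- rnorm(ncol(d$values))
  y <- as.numeric(d$values %*% beta)
  run <- run_from_fun(g, 64, fun = function(v) y)
  res <- glm_residuals(run, d)
  expect_lt(max(abs(res$data)), 1e-9)
})

test_that("a planted design-orthogonal component passes through unchanged", {
  g <- tiny_grid(5)
  d <- make_design_fixture()
  X <- d$values
  set.seed(2)
  s <- sin(2 * pi * 0.05 * (0:63) * 2)
  # explicit projection: remove the design span from the sinusoid
  s_perp <- s - X %*% solve(crossprod(X), crossprod(X, s))
  beta <- rnorm(ncol(X))
  y <- as.numeric(X %*% beta + s_perp)
  run <- run_from_fun(g, 64, fun = function(v) y)
  res <- glm_residuals(run, d)
  expect_equal(res$data[3, 3, 3, ], as.numeric(s_perp), tolerance = 1e-8)
})

test_that("residuals are orthogonal to every design column", {
  g <- tiny_grid(5)
  d <- make_design_fixture()
  set.seed(3)
  run <- run_from_fun(g, 64, fun = function(v) rnorm(64))
  res <- glm_residuals(run, d)
  E <- t(matrix(res$data, prod(g$dims), 64))
  ortho <- crossprod(d$values, E)
  expect_lt(max(abs(ortho)), 1e-8)
})

test_that("rank-deficient designs error naming the collinear column", {
  g <- tiny_grid(5)
  d <- make_design_fixture()
  d$values <- cbind(d$values, dup = d$values[, "cond1"])
  d$columns <- colnames(d$values)
  run <- run_from_fun(g, 64, fun = function(v) rnorm(64))
  expect_error(glm_residuals(run, d), "collinear column\\(s\\) (dup|cond1)")
})

test_that("out-of-mask voxels are zeroed", {
  g <- tiny_grid(5)
  d <- make_design_fixture()
  mask <- array(FALSE, g$dims); mask[1:2, , ] <- TRUE
  set.seed(4)
  run <- run_from_fun(g, 64, fun = function(v) rnorm(64))
  res <- glm_residuals(run, d, mask = mask)
  expect_true(all(res$data[5, , , ] == 0))
  expect_false(all(res$data[1, , , ] == 0))
})
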