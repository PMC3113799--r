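test_that("the Gamma kernel is a unit-sum density peaking at time-to-peak", {
  h <- gamma_hrf(2, time_to_peak = 6)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_true(all(h >= 0))
  t_s <- seq(0, 32, by = 2)
  expect_lte(abs(t_s[which.max(h)] - 6), 2)   # within one TR of the mode
  # finer sampling localizes the analytic mode (shape-1)*scale exactly
  h1 <- gamma_hrf(0.1, time_to_peak = 6)
  t1 <- seq(0, 32, by = 0.1)
  expect_lte(abs(t1[which.max(h1)] - 6), 0.1)
  expect_error(gamma_hrf(-1), "positive")
  expect_error(gamma_hrf(2, time_to_peak = -3), "positive")
})

test_that("convolving a constant with the unit-sum kernel is the identity", {
  h <- gamma_hrf(2)
  x <- rep(3.7, 200)
  y <- stats::convolve(x, rev(as.numeric(h)), type = "open")[seq_along(x)]
  # after the kernel support has filled in, the constant passes through
  expect_equal(y[length(h):length(x)], x[length(h):length(x)],
               tolerance = 1e-9)
})

test_that("a single impulse at t = 0 reproduces the kernel", {
  ev <- data.frame(onset_s = 0, duration_s = 0, condition = "c1")
  d <- build_design(ev, 64, 2)
  h <- gamma_hrf(2)
  expect_equal(unname(d$values[seq_along(h), "c1"]), as.numeric(h),
               tolerance = 1e-12)
  expect_equal(unname(d$values[(length(h) + 1):64, "c1"]),
               rep(0, 64 - length(h)))
})

test_that("four conditions plus intercept give P = 5 columns", {
  ev <- default_events(540, 2)
  d <- build_design(ev, 540, 2)
  expect_equal(ncol(d$values), 5)
  expect_equal(d$columns[1], "intercept")
  expect_setequal(d$columns[-1], paste0("cond", 1:4))
})

test_that("events outside the run and all-zero columns are rejected", {
  ev <- data.frame(onset_s = c(10, 2000), duration_s = 4,
                   condition = c("a", "b"))
  expect_error(build_design(ev, 540, 2), "outside the run")
  # an impulse in the final time step contributes nothing (the kernel starts
  # at 0), leaving that condition's column all zero
  ev2 <- data.frame(onset_s = c(10, 126), duration_s = c(4, 0),
                    condition = c("a", "b"))
  expect_error(build_design(ev2, 64, 2), "all-zero")
})
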