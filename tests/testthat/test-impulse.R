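test_that("impulse_value matches its closed forms", {
  # constant limit: h0 = h1 = h2 = c
  p <- list(h0 = 2.5, h1 = 2.5, h2 = 2.5, t1 = 5, t2 = 15, beta = 3)
  expect_equal(impulse_value(p, seq(0, 24, 0.5)), rep(2.5, 49))

  # sigmoid saturation: f -> h0 for beta*(t1 - t) large
  p2 <- list(h0 = 1, h1 = 4, h2 = 2, t1 = 10, t2 = 20, beta = 5)
  expect_equal(impulse_value(p2, 10 - 21 / 5), 1, tolerance = 1e-6)

  # midpoint of the first sigmoid when the second is inactive (h2 = h1)
  p3 <- list(h0 = 1, h1 = 3, h2 = 3, t1 = 5, t2 = 50, beta = 10)
  expect_equal(impulse_value(p3, 5), (1 + 3) / 2, tolerance = 1e-6)

  expect_error(impulse_value(list(h0 = 1, h1 = 0, h2 = 1, t1 = 1, t2 = 2,
                                  beta = 1), 0), "h1")
})

test_that("impulse_value is symmetric under swapping the two sigmoids", {
  # with t1 = t2 and h0 = h2 the two bracket factors swap roles
  t <- seq(0, 24, 0.25)
  p <- list(h0 = 1.5, h1 = 4, h2 = 1.5, t1 = 8, t2 = 8, beta = 2)
  f <- impulse_value(p, t)
  # time-reverse around t1: the curve must be symmetric
  expect_equal(impulse_value(p, 8 + (t - 8)), impulse_value(p, 8 - (t - 8)),
               tolerance = 1e-12)
})

test_that("onset time hits sigmoid midpoints and is sign/affine invariant", {
  up <- list(h0 = 1, h1 = 3, h2 = 3, t1 = 5, t2 = 50, beta = 10)
  expect_equal(onset_time(up, c(0, 24))$t_half, 5, tolerance = 0.05)

  down <- list(h0 = 3, h1 = 1, h2 = 1, t1 = 5, t2 = 50, beta = 10)
  expect_equal(onset_time(down, c(0, 24))$t_half,
               onset_time(up, c(0, 24))$t_half, tolerance = 1e-6)

  # affine rescaling of the level axis leaves the onset unchanged
  pulse <- list(h0 = 1, h1 = 4, h2 = 1, t1 = 5, t2 = 15, beta = 2)
  t0 <- onset_time(pulse, c(0, 24))$t_half
  grid <- seq(0, 24, 0.01)
  f <- impulse_value(pulse, grid)
  a <- -2.3; b <- 7
  g <- abs((a * f + b) - (a * f[1] + b))
  i <- which(g >= max(g) / 2)[1]
  expect_equal(grid[i], t0, tolerance = 0.02)

  # brute-force dense scan oracle for the pulse
  g0 <- abs(f - f[1])
  i0 <- which(g0 >= max(g0) / 2)[1]
  expect_equal(t0, grid[i0], tolerance = 0.02)

  flat <- list(h0 = 2, h1 = 2, h2 = 2, t1 = 5, t2 = 15, beta = 2)
  expect_true(is.na(onset_time(flat, c(0, 24))$t_half))
})

test_that("noiseless planted impulses are recovered", {
  times <- c(0, 1, 3, 5, 7, 11, 15, 19, 24)
  truth <- list(h0 = 1, h1 = 3.5, h2 = 2, t1 = 4, t2 = 14, beta = 1.2)
  fit <- fit_impulse(times, impulse_value(truth, times), seed = 1)
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$t_half, onset_time(truth, range(times))$t_half,
               tolerance = 0.1)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 6)
  expect_equal(glance(fit)$sse, fit$sse)
})

test_that("degenerate inputs are flagged, short series rejected", {
  times <- c(0, 1, 3, 5, 7, 11, 15, 19, 24)
  fit <- fit_impulse(times, rep(2, 9))
  expect_equal(fit$flag, "flat")
  expect_true(is.na(fit$t_half))
  expect_lt(fit$sse, 1e-12)
  expect_error(fit_impulse(0:5, 1:6), "at least 7")
})

test_that("onset recovery tolerates observation noise", {
  times <- c(0, 1, 3, 5, 7, 11, 15, 19, 24)
  truth <- list(h0 = 1, h1 = 3, h2 = 2.5, t1 = 5, t2 = 16, beta = 1.5)
  t_true <- onset_time(truth, range(times))$t_half
  errs <- sapply(1:20, function(s) {
    lv <- impulse_value(truth, times) + withr::with_seed(s, rnorm(9, 0, 0.05))
    fit <- fit_impulse(times, lv, seed = s)
    abs(fit$t_half - t_true)
  })
  expect_lt(median(errs), 2)
})

test_that("random planted parameter sets are recovered at low noise", {
  times <- seq(0, 24, 2)
  errs <- withr::with_seed(77, sapply(1:50, function(i) {
    truth <- list(h0 = runif(1, 0.5, 2), h1 = runif(1, 2.5, 5),
                  h2 = runif(1, 0.5, 4), t1 = runif(1, 2, 10),
                  t2 = runif(1, 12, 20), beta = exp(runif(1, log(0.5), log(5))))
    lv <- impulse_value(truth, times) + rnorm(length(times), 0, 0.02)
    fit <- fit_impulse(times, lv, seed = i)
    t_true <- onset_time(truth, range(times))$t_half
    abs(fit$t_half - t_true)
  }))
  expect_lt(median(errs), 0.5)
})
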