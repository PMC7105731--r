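test_that("cell_params validates its inputs", {
  expect_s3_class(cell_params("detailed", variant = "M", gKs_mult = 10),
                  "cell_params")
  expect_error(cell_params("detailed", variant = "midwall"))
  expect_error(cell_params("nonexistent"))
  expect_error(cell_params("detailed", gKs_mult = -1))
})

test_that("apd90 matches a hand-computed piecewise-linear oracle", {
  # rest -85 mV; +120 mV/ms upstroke at t = 50 -> 51; plateau +35 to t = 100;
  # -1 mV/ms fall to rest at t = 220. The 90% level is -73 mV, crossed on the
  # fall at t = 208; onset (steepest rise endpoint) is t = 51 -> APD90 = 157.
  tt <- 0:599
  vm <- rep(-85, 600)
  vm[tt >= 51 & tt <= 100] <- 35
  fall <- tt > 100 & tt <= 220
  vm[fall] <- 35 - (tt[fall] - 100)
  expect_equal(apd90(list(time = tt, vm = vm, bcl = 600), 1), 157)
})

test_that("detect_upstrokes interpolates crossings exactly", {
  tt <- seq(0, 100, by = 1)
  ta <- 20.4                              # activation time of a linear ramp
  vm <- ifelse(tt < ta, -85, pmin(-85 + 40 * (tt - ta), 35))
  ups <- detect_upstrokes(tt, vm, threshold = -40)
  expect_length(ups, 1)
  expect_equal(ups, ta + 45 / 40, tolerance = 1e-10)
})

test_that("Rush-Larsen and forward-Euler integrators agree at small dt", {
  p <- cell_params("detailed")
  s <- cell_state_init(p)
  rl <- step_ionic(s, p, dt = 0.001, n = 2000, istim = -52)
  fe <- step_ionic(s, p, dt = 0.001, n = 2000, istim = -52, method = "euler")
  expect_lt(abs(rl[1] - fe[1]), 0.05)
  rl <- step_ionic(rl, p, dt = 0.001, n = 48000)
  fe <- step_ionic(fe, p, dt = 0.001, n = 48000, method = "euler")
  expect_lt(abs(rl[1] - fe[1]), 0.05)
})

test_that("halving the time step moves APD90 by less than 1 ms", {
  p <- cell_params("detailed")
  a1 <- apd90(run_paced(p, 500, 2, dt = 0.02), 2)
  a2 <- apd90(run_paced(p, 500, 2, dt = 0.01), 2)
  expect_lt(abs(a1 - a2), 1)
})

test_that("APD90 shortens monotonically along the conductance ladder", {
  lad <- vapply(c(1, 10, 100), function(m)
    apd90(run_paced(cell_params("reduced", gKs_mult = m), 600, 4), 4),
    numeric(1))
  expect_true(all(diff(lad) < 0))
})

test_that("transmural variants order as M > epi > endo", {
  a <- vapply(c("endo", "epi", "M"), function(v)
    apd90(run_paced(cell_params("detailed", variant = v), 1000, 3), 3),
    numeric(1))
  expect_true(a[["M"]] > a[["epi"]])
  expect_true(a[["epi"]] > a[["endo"]])
})

test_that("ap_trace CSV round trip preserves the recording", {
  tr <- run_paced(cell_params("reduced"), 500, 2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_ap_trace(tr, path)
  back <- read_ap_trace(path)
  expect_equal(back$time, tr$time, tolerance = 1e-8)
  expect_equal(back$vm, tr$vm, tolerance = 1e-8)
})
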