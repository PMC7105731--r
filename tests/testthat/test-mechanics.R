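test_that("cross-bridge tension matches an independent R reference", {
  times <- seq(0, 800, by = 5)
  ca <- test_ca_transient(times)
  mv <- voltage_movie(matrix(-86, length(times), 1), times, c(1, 1, 1), 0.25,
                      ca = matrix(ca, ncol = 1))
  tf <- run_crossbridge(mv)
  ref <- reference_crossbridge(ca, times)
  expect_lt(max(abs(tf$tension[, 1] - ref$tension)), 1e-8)
})

test_that("larger calcium transients recruit more tension", {
  times <- seq(0, 800, by = 5)
  peaks <- vapply(c(3e-4, 6e-4, 1.2e-3), function(amp) {
    ca <- test_ca_transient(times, amp = amp)
    mv <- voltage_movie(matrix(-86, length(times), 1), times, c(1, 1, 1),
                        0.25, ca = matrix(ca, ncol = 1))
    max(run_crossbridge(mv)$tension)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("amp_tens is the node-mean temporal standard deviation", {
  times <- seq(0, 400, by = 10)
  set.seed(9)
  tens <- matrix(abs(rnorm(length(times) * 3)), length(times), 3)
  tf <- structure(list(tension = tens, times = times),
                  class = "tension_field")
  # documented as the population SD (divisor n), not the sample SD
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(amp_tens(tf), mean(apply(tens, 2, pop_sd)), tolerance = 1e-12)
})

test_that("activation_from_tension is min-max normalized into [0, 1]", {
  times <- seq(0, 800, by = 5)
  ca <- test_ca_transient(times)
  mv <- voltage_movie(matrix(-86, length(times), 2), times, c(2, 1, 1), 0.25,
                      ca = cbind(ca, ca * 1.5))
  yv <- activation_from_tension(run_crossbridge(mv))
  expect_equal(min(yv$yv), 0)
  expect_equal(max(yv$yv), 1)
  expect_equal(yv$times, times)
})

test_that("closed-loop circulation conserves blood volume", {
  times <- seq(0, 20000, by = 10)
  tr <- run_circulation(test_activation(times, 1), times)
  drift <- diff(range(tr$total_volume)) / tr$total_volume[1]
  expect_lt(drift, 1e-6)
})

test_that("stroke volume falls as the activation rate rises", {
  times <- seq(0, 20000, by = 10)
  svs <- vapply(c(1, 3, 6), function(f) {
    tr <- run_circulation(test_activation(times, f), times)
    stroke_volume(tr$vlv, tr$time)$sv
  }, numeric(1))
  expect_true(all(diff(svs) < 0))
})

test_that("a sustained contraction produces no ejection cycles", {
  times <- seq(0, 10000, by = 10)
  tr <- run_circulation(rep(0.8, length(times)), times)
  sv <- stroke_volume(tr$vlv, tr$time)
  expect_true(sv$no_ejection)
  expect_equal(sv$sv, 0)
})
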