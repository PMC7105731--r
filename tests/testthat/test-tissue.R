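test_that("tissue_grid validates its geometry", {
  g <- tissue_grid(10, 8, 1, h = 0.25, D = 0.1)
  expect_s3_class(g, "tissue_grid")
  expect_error(tissue_grid(2, 2))           # too small for propagation
  expect_error(tissue_grid(10, 10, h = -1))
  expect_error(tissue_grid(10, 10, D = -0.1))
})

test_that("diffusion with no-flux boundaries conserves the spatial mean", {
  p <- cell_params("reduced")
  n <- 31
  g <- tissue_grid(n, n, 1, h = 0.25, D = 0.1)
  s0 <- cell_state_init(p)
  state <- matrix(rep(s0, n * n), nrow = length(s0))
  set.seed(4)
  state[1, ] <- runif(n * n, -80, 20)
  m0 <- mean(state[1, ])
  r <- run_monodomain(g, p, duration = 20, state = state, dt = 0.05,
                      frame_dt = 5, ionic_off = TRUE)
  means <- rowMeans(r$movie$frames)
  expect_lt(max(abs(means - m0)), 1e-8)
  # and the field homogenizes: spatial variance strictly decreases
  vars <- apply(r$movie$frames, 1, var)
  expect_true(all(diff(vars) < 0))
})

test_that("stimulus_protocol and phase_plan validate their inputs", {
  expect_error(stimulus_protocol(s2_site = "TOP_HALF"))
  expect_s3_class(tissue_grid(10, 10), "tissue_grid")
  expect_error(phase_plan(gen_cv = -5))
  expect_error(phase_plan(gen_duration = 0))
})

test_that("measure_cv recovers the generator velocity exactly", {
  for (cv in c(20, 68.5)) {
    mv <- gen_plane_wave_movie(cv, c(120, 3))
    expect_equal(measure_cv(mv, "x"), cv, tolerance = 1e-6)
  }
})

test_that("reduced-model calibration hits its conduction-velocity target", {
  p <- cell_params("reduced")
  D <- calibrate_diffusion(p, 6.5, h = 0.25)
  achieved <- attr(D, "achieved_cv")
  expect_lt(abs(achieved - 6.5) / 6.5, 0.005 + 0.01)
  expect_gt(as.numeric(D), 0)
})

test_that("run_s1s2 induces reentry that outlives the final stimulus", {
  p <- cell_params("reduced", gKs_mult = 8)
  D <- as.numeric(calibrate_diffusion(p, 5, h = 0.25))
  g <- tissue_grid(48, 48, 1, h = 0.25, D = D)
  r <- run_s1s2(g, p, plan = phase_plan(gen_cv = 5, gen_duration = 3000,
                                        maint_cv = 6.5, maint_duration = 3000))
  expect_true(is.finite(r$s2_time))
  late <- r$movie$frames[r$movie$times > r$s2_time + 800, , drop = FALSE]
  expect_gt(nrow(late), 0)
  # self-sustained activity: depolarized tissue present well after S2
  expect_true(all(apply(late, 1, max) > -40))
})
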