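test_that("phase_difference wraps into [-pi, pi)", {
  th <- seq(-10, 10, by = 0.37)
  d <- phase_difference(th, rev(th))
  expect_true(all(d >= -pi & d < pi))
  # wrapped difference is congruent to the raw difference mod 2 pi
  raw <- th - rev(th)
  m <- (d - raw) %% (2 * pi)
  expect_lt(max(pmin(m, 2 * pi - m)), 1e-10)
})

test_that("detect_ps localizes an analytic vortex core to one plaquette", {
  core <- data.frame(x0 = 5, y0 = 5, chirality = 1)
  sp <- gen_spiral_movie(c(40, 40), 0.25, core, period = 200)
  ph <- compute_phase(sp$movie)
  d <- detect_ps(ph, frame = 8)
  expect_equal(nrow(d), 1)
  expect_equal(d$charge, 1)
  expect_lt(abs(d$x_mm - 5), 2 * 0.25)
  expect_lt(abs(d$y_mm - 5), 2 * 0.25)
})

test_that("charge sign follows chirality and opposite pairs cancel", {
  neg <- gen_spiral_movie(c(40, 40), 0.25,
                          data.frame(x0 = 5, y0 = 5, chirality = -1),
                          period = 200)
  expect_equal(unique(ps_count(neg$movie)$records$charge), -1)
  pair <- gen_spiral_movie(c(40, 40), 0.25,
                           data.frame(x0 = c(3, 7), y0 = c(5, 5),
                                      chirality = c(1, -1)), period = 200)
  rec <- ps_count(pair$movie)$records
  net <- tapply(rec$charge, rec$frame, sum)
  expect_true(all(net == 0))
  expect_true(all(table(rec$frame) == 2))
})

test_that("dominant frequency of a uniform oscillation is 1/period", {
  core <- data.frame(x0 = 2.5, y0 = 2.5, chirality = 1)
  mv <- gen_spiral_movie(c(20, 20), 0.25, core, period = 200,
                         duration = 2400)$movie
  d <- dominant_frequency_map(mv)
  expect_equal(d$mean_df, 5, tolerance = 0.02)
  expect_lt(diff(range(d$df_hz)), 0.05)
})

test_that("mean_reentry_apd recovers the duty cycle of the rotation", {
  core <- data.frame(x0 = 5, y0 = 5, chirality = 1)
  mv <- gen_spiral_movie(c(40, 40), 0.25, core, period = 200,
                         duration = 1000, frame_dt = 2)$movie
  a <- mean_reentry_apd(mv)
  expect_true(is.finite(a$mean_apd))
  expect_gt(a$mean_apd, 0)
  expect_lt(a$mean_apd, 200)   # cannot exceed the rotation period
  expect_gte(a$n_activations, 2)
  expect_equal(mean(a$apds), a$mean_apd)
})

test_that("filament detection refuses 2D sheets and case_metrics records it", {
  core <- data.frame(x0 = 5, y0 = 5, chirality = 1)
  mv <- gen_spiral_movie(c(40, 40), 0.25, core, period = 200)$movie
  expect_error(detect_filaments(mv, 2), "3D movie")
  cm <- case_metrics(mv)
  expect_true(is.na(cm$filament))
  expect_equal(cm$ps, 1)
})

test_that("scroll filaments scale with thickness on the frozen fixture", {
  core <- data.frame(x0 = 4, y0 = 4, chirality = 1)
  sc <- gen_scroll_movie(c(33, 33), 0.25, core, period = 120, nz = 5,
                         frame_dt = 2, duration = 240)
  fd <- detect_filaments(sc$movie, 10, v_iso = -75, eps = 5)
  expect_equal(fd$n_components, 1)
  expect_equal(fd$n_elements %% (5 - 1), 0)  # equal elements in each layer pair
})
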