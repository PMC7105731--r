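test_that("spiral generator emits truth that the detector confirms", {
  core <- data.frame(x0 = 6, y0 = 6, chirality = 1)
  sp <- gen_spiral_movie(c(40, 40), 0.25, core, period = 200,
                         drift = c(5, 0), duration = 400)
  expect_true(all(sp$movie$frames >= -86 - 1e-9 &
                  sp$movie$frames <= 34 + 1e-9))
  rec <- ps_count(sp$movie)$records
  m <- merge(rec, sp$ps_truth, by = "frame")
  expect_lt(max(abs(m$x_mm.x - m$x_mm.y)), 2 * 0.25)
  expect_lt(max(abs(m$y_mm.x - m$y_mm.y)), 2 * 0.25)
})

test_that("generators validate their inputs", {
  core <- data.frame(x0 = 5, y0 = 5, chirality = 1)
  expect_error(gen_scroll_movie(c(20, 20), 0.25, core, period = 100, nz = 2))
  expect_error(gen_spiral_movie(c(20, 20), 0.25,
                                data.frame(x0 = 50, y0 = 5, chirality = 1),
                                period = 100))
  expect_error(gen_spiral_movie(c(20, 20), 0.25, core, period = 100,
                                duration = 100))
  expect_error(gen_plane_wave_movie(-3, c(20, 20)))
})

test_that("plane-wave movies carry their velocity exactly", {
  mv <- gen_plane_wave_movie(68.5, c(120, 3))
  expect_equal(measure_cv(mv, "x"), 68.5, tolerance = 1e-6)
})

test_that("correlated tables are reproducible and seed-sensitive", {
  a <- gen_correlated_table(48, seed = 7)
  b <- gen_correlated_table(48, seed = 7)
  c <- gen_correlated_table(48, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(all(a$ps >= 0 & a$ps == round(a$ps)))
  expect_true(all(a$filament >= 0 & a$filament == round(a$filament)))
})

test_that("correlated tables do not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(gen_correlated_table(10, seed = 99))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("movie save/load round trip preserves frames and metadata", {
  core <- data.frame(x0 = 4, y0 = 4, chirality = 1)
  mv <- gen_spiral_movie(c(20, 20), 0.25, core, period = 100)$movie
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  save_movie(mv, path)
  back <- load_movie(path)
  expect_identical(back$frames, mv$frames)
  expect_equal(back$times, mv$times)
  expect_equal(back$dims, mv$dims)
  expect_equal(back$h, mv$h)
})
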