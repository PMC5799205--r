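test_that("denoise implements the kernel average with reflected edges", {
  m <- matrix(runif(25), 5, 5)
  expect_identical(denoise(m, 1L), m)
  const <- matrix(0.4, 7, 7)
  expect_equal(denoise(const, 3L), const)
  # center pixel of a 3x3 kernel is the mean of its neighborhood
  out <- denoise(m, 3L)
  expect_equal(out[3, 3], mean(m[2:4, 2:4]))
  expect_equal(out[2, 4], mean(m[1:3, 3:5]))
  # reflected edge: corner kernel reuses mirrored pixels
  refl <- m[c(1, 1:5, 5), c(1, 1:5, 5)]
  expect_equal(out[1, 1], mean(refl[1:3, 1:3]))
  expect_error(denoise(m, 2L), class = "wellcount_parameter_error")
  expect_error(denoise(m, 7L), class = "wellcount_parameter_error")
})

test_that("all wells are found with sub-pixel accuracy on dye-filled panels", {
  # the well-recognition scenario: every well filled with dye, no
  # particles, both imaging modes
  g <- panel_geom()
  for (mod in c("brightfield", "fluorescence")) {
    tr <- seed_particles(g, density = 0, rng_seed = 5)
    img <- render_panel(g, tr, mod,
                        noise_spec(additive_sigma = 0,
                                   illumination_gradient = 0, rng_seed = 1))
    circ <- find_wells(denoise(img), g)
    expect_identical(nrow(circ), 900L)
    # match each detection to its nearest true center
    d <- vapply(seq_len(nrow(circ)), function(i)
      min(sqrt((tr$x_px - circ$x_px[i])^2 + (tr$y_px - circ$y_px[i])^2)),
      numeric(1))
    expect_lt(max(d), 1)
  }
})

test_that("detection F1 is 1.0 over ten random noise-free layouts", {
  g <- small_geom()
  half_pitch <- g$pitch / g$pixel_scale / 2
  for (s in 1:10) {
    tr <- seed_particles(g, density = s * 1e4, rng_seed = s)
    img <- render_panel(g, tr, "brightfield",
                        noise_spec(additive_sigma = 0,
                                   illumination_gradient = 0, rng_seed = s))
    circ <- find_wells(denoise(img), g)
    expect_identical(nrow(circ), g$wells_per_panel)   # no FN and no FP
    d <- vapply(seq_len(nrow(circ)), function(i)
      min(sqrt((tr$x_px - circ$x_px[i])^2 + (tr$y_px - circ$y_px[i])^2)),
      numeric(1))
    # every detection matches its well unambiguously; most are sub-pixel
    # (multi-particle wells that erase rim arcs can shift a raw detection
    # by a few px -- the lattice fit absorbs this downstream)
    expect_lt(max(d), half_pitch)
    expect_lt(stats::median(d), 1)
  }
})

test_that("missing wells reduce detections but never the fitted grid", {
  g <- panel_geom()
  withr::with_seed(21, miss <- sample(900, 60))
  tr <- seed_particles(g, density = 2e4, rng_seed = 6, missing_wells = miss)
  img <- render_panel(g, tr, "brightfield", noise_spec(rng_seed = 2))
  circ <- find_wells(denoise(img), g)
  expect_identical(nrow(circ), 840L)
  grid <- fit_grid(circ, g)
  expect_identical(nrow(grid$centers), 900L)
  m <- merge(grid$centers, as.data.frame(tr), by = c("row", "col"))
  err <- sqrt((m$x_px.x - m$x_px.y)^2 + (m$y_px.x - m$y_px.y)^2)
  expect_lt(max(err), 1)
})

test_that("the radius band rejects circles of the wrong size", {
  # a well twice the nominal diameter must not be detected with the
  # standard geometry's radius band
  big <- array_geometry(well_diameter = 40, pitch = 80, rows = 2, cols = 2,
                        panels = 1)
  tr <- seed_particles(big, density = 0, rng_seed = 1)
  img <- render_panel(big, tr, "brightfield",
                      noise_spec(additive_sigma = 0, illumination_gradient = 0))
  g <- array_geometry(rows = 2, cols = 2, panels = 1)
  circ <- find_wells(denoise(img), g)
  expect_identical(nrow(circ), 0L)
})

test_that("detection errors on an image smaller than one well", {
  g <- panel_geom()
  expect_error(find_wells(matrix(0.5, 8, 8), g),
               class = "wellcount_detection_error")
})

test_that("aggregates inside wells do not create or destroy detections", {
  g <- small_geom()
  tr <- seed_particles(g, density = 3 / g$well_volume, aggregation = 0.9,
                       rng_seed = 8)
  img <- render_panel(g, tr, "brightfield", noise_spec(rng_seed = 3))
  circ <- find_wells(denoise(img), g)
  expect_identical(nrow(circ), g$wells_per_panel)
})

test_that("fit_grid reproduces an exact lattice with zero residual", {
  g <- panel_geom()
  tr <- seed_particles(g, density = 0, rng_seed = 1)
  circ <- data.frame(x_px = tr$x_px, y_px = tr$y_px, radius_px = 5)
  grid <- fit_grid(circ, g)
  expect_identical(nrow(grid$centers), 900L)
  expect_lt(grid$rms_residual, 1e-8)
  expect_equal(grid$centers$x_px[order(tr$row, tr$col)], tr$x_px,
               tolerance = 1e-8)
  expect_equal(grid$pitch_x_px, g$pitch / g$pixel_scale, tolerance = 1e-8)
})

test_that("fit_grid recovers all centers from decimated detections", {
  g <- panel_geom()
  tr <- seed_particles(g, density = 0, rng_seed = 2)
  withr::with_seed(31, keep <- sample(900, 840))
  circ <- data.frame(x_px = tr$x_px[keep], y_px = tr$y_px[keep])
  grid <- fit_grid(circ, g)
  expect_identical(nrow(grid$centers), 900L)
  m <- merge(grid$centers, as.data.frame(tr), by = c("row", "col"))
  expect_lt(max(abs(m$x_px.x - m$x_px.y)), 1)
  expect_lt(max(abs(m$y_px.x - m$y_px.y)), 1)
  expect_identical(sum(grid$centers$detected), 840L)
})

test_that("fit_grid is idempotent", {
  g <- panel_geom()
  tr <- seed_particles(g, density = 0, rng_seed = 3)
  withr::with_seed(5, keep <- sample(900, 700))
  grid1 <- fit_grid(data.frame(x_px = tr$x_px[keep], y_px = tr$y_px[keep]), g)
  grid2 <- fit_grid(grid1$centers[, c("x_px", "y_px")], g)
  expect_equal(grid2$centers$x_px, grid1$centers$x_px, tolerance = 1e-6)
  expect_equal(grid2$centers$y_px, grid1$centers$y_px, tolerance = 1e-6)
})

test_that("fit_grid names degenerate and inconsistent inputs", {
  g <- panel_geom()
  pitch_px <- g$pitch / g$pixel_scale
  # one row only
  one_row <- data.frame(x_px = 40 + (0:29) * pitch_px, y_px = 40)
  err <- tryCatch(fit_grid(one_row, g), wellcount_gridfit_error = identity)
  expect_match(conditionMessage(err), "single row")
  # two interleaved lattices with inconsistent pitch
  a <- expand.grid(x = 40 + (0:14) * pitch_px, y = 40 + (0:14) * pitch_px)
  b <- expand.grid(x = 47 + (0:14) * 1.31 * pitch_px,
                   y = 47 + (0:14) * 1.31 * pitch_px)
  expect_error(fit_grid(data.frame(x_px = c(a$x, b$x), y_px = c(a$y, b$y)), g),
               class = "wellcount_gridfit_error")
  expect_error(fit_grid(one_row[1:2, ], g), class = "wellcount_gridfit_error")
})

test_that("grid fit tolerates a slight lattice rotation", {
  g <- panel_geom()
  tr <- seed_particles(g, density = 0, rng_seed = 4)
  th <- 0.01  # radians, about half a degree
  cx <- mean(tr$x_px); cy <- mean(tr$y_px)
  x <- cx + cos(th) * (tr$x_px - cx) - sin(th) * (tr$y_px - cy)
  y <- cy + sin(th) * (tr$x_px - cx) + cos(th) * (tr$y_px - cy)
  grid <- fit_grid(data.frame(x_px = x, y_px = y), g)
  expect_identical(nrow(grid$centers), 900L)
  expect_lt(grid$rms_residual, 0.5)
  ord <- order(tr$row, tr$col)
  expect_lt(max(abs(grid$centers$x_px - x[ord])), 0.5)
})
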