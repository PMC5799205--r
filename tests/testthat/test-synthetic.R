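test_that("seed_particles is deterministic and validates inputs", {
  g <- panel_geom()
  t1 <- seed_particles(g, density = 3e4, rng_seed = 42)
  t2 <- seed_particles(g, density = 3e4, rng_seed = 42)
  expect_identical(t1, t2)
  t3 <- seed_particles(g, density = 3e4, rng_seed = 43)
  expect_false(identical(t1$particles, t3$particles))
  expect_error(seed_particles(g, density = -1), class = "wellcount_domain_error")
  expect_error(seed_particles(g, 1e4, aggregation = 1),
               class = "wellcount_domain_error")
})

test_that("density 0 loads no particles", {
  tr <- seed_particles(panel_geom(), density = 0, rng_seed = 1)
  expect_true(all(tr$particles == 0))
  expect_true(all(!tr$occupied))
})

test_that("occupancy tracks 1 - exp(-lambda) at the half-occupancy point", {
  # lambda = ln 2 over 14,400 wells: occupied fraction 0.5 within 3 sigma
  g <- array_geometry(rows = 120, cols = 120, panels = 1)
  dens <- log(2) / g$well_volume
  tr <- seed_particles(g, density = dens, rng_seed = 7)
  expect_lt(abs(mean(tr$occupied) - 0.5), 3 * sqrt(0.25 / 14400))
})

test_that("particle counts are Poisson under no aggregation (chi-square GOF)", {
  g <- array_geometry(rows = 120, cols = 120, panels = 1)
  for (lam in c(0.1, 0.7, 2)) {
    tr <- seed_particles(g, density = lam / g$well_volume, rng_seed = 101)
    tab <- tabulate(tr$particles + 1L, nbins = max(tr$particles) + 1L)
    expected <- 14400 * stats::dpois(0:(length(tab) - 1L), lam)
    # pool the tail so all expected counts are >= 5
    while (length(expected) > 2 && expected[length(expected)] < 5) {
      n <- length(expected)
      expected[n - 1] <- expected[n - 1] + expected[n]
      tab[n - 1] <- tab[n - 1] + tab[n]
      expected <- expected[-n]; tab <- tab[-n]
    }
    expected[length(expected)] <- expected[length(expected)] +
      14400 * stats::ppois(length(expected) - 1, lam, lower.tail = FALSE)
    chi2 <- sum((tab - expected)^2 / expected)
    p <- stats::pchisq(chi2, df = length(tab) - 1, lower.tail = FALSE)
    expect_gt(p, 0.01)
  }
})

test_that("aggregation suppresses occupancy below the Poisson prediction", {
  g <- panel_geom()
  lam <- 3
  p_poisson <- 1 - exp(-lam)
  frac <- vapply(1:20, function(s)
    mean(seed_particles(g, lam / g$well_volume, aggregation = 0.9,
                        rng_seed = s)$occupied), numeric(1))
  # strictly below in every one of 20 seeds (one-sided)
  expect_true(all(frac < p_poisson))
  # but the expected number of particles is conserved
  npart <- vapply(1:20, function(s)
    mean(seed_particles(g, lam / g$well_volume, aggregation = 0.9,
                        rng_seed = s)$particles), numeric(1))
  expect_equal(mean(npart), lam, tolerance = 0.1)
})

test_that("rendering is bit-reproducible and respects the image contract", {
  g <- small_geom()
  tr <- seed_particles(g, density = 5e4, rng_seed = 3)
  for (mod in c("brightfield", "fluorescence")) {
    i1 <- render_panel(g, tr, mod, noise_spec(rng_seed = 9))
    i2 <- render_panel(g, tr, mod, noise_spec(rng_seed = 9))
    expect_identical(i1$pixels, i2$pixels)
    expect_true(all(i1$pixels >= 0 & i1$pixels <= 1))
    # frame holds the full grid
    expect_gte(nrow(i1$pixels), g$pitch * g$rows / g$pixel_scale)
    expect_gte(ncol(i1$pixels), g$pitch * g$cols / g$pixel_scale)
  }
  i3 <- render_panel(g, tr, "brightfield", noise_spec(rng_seed = 10))
  expect_false(identical(
    render_panel(g, tr, "brightfield", noise_spec(rng_seed = 9))$pixels,
    i3$pixels))
})

test_that("render rejects a truth/geometry mismatch", {
  g <- small_geom()
  tr <- seed_particles(g, density = 1e4, rng_seed = 1)
  expect_error(render_panel(panel_geom(), tr, "brightfield"),
               class = "wellcount_consistency_error")
})

test_that("zero-noise unoccupied panels have identical well means", {
  g <- small_geom()
  tr <- seed_particles(g, density = 0, rng_seed = 1)
  img <- render_panel(g, tr, "brightfield",
                      noise_spec(additive_sigma = 0, illumination_gradient = 0))
  grid <- detect_panel(img, g)
  ints <- well_intensities(img, grid)
  expect_lt(diff(range(ints)), 1e-6)
})

test_that("occupied/unoccupied contrast resolves the bimodal histogram", {
  # mean interior intensities of the two classes separated by >= 5 sigma
  g <- panel_geom()
  ns <- noise_spec()   # default additive_sigma
  for (s in 1:5) {
    tr <- seed_particles(g, density = 0.7 / g$well_volume, rng_seed = s)
    ns$rng_seed <- 50 + s
    img <- render_panel(g, tr, "brightfield", ns)
    grid <- detect_panel(denoise(img), g)
    ints <- well_intensities(denoise(img), grid)
    occ <- truth_occupied(tr)
    gap <- mean(ints[!occ]) - mean(ints[occ])
    expect_gt(gap, 5 * ns$additive_sigma)
  }
})

test_that("panel images round-trip through PNG and 16-bit TIFF", {
  g <- small_geom()
  tr <- seed_particles(g, density = 3e4, rng_seed = 2)
  img <- render_panel(g, tr, "brightfield", noise_spec(rng_seed = 5))
  tif <- withr::local_tempfile(fileext = ".tiff")
  write_panel_image(img, tif)
  back <- read_panel_image(tif, "brightfield", g$pixel_scale)
  expect_equal(back$pixels, img$pixels, tolerance = 1 / 65535)
  pngf <- withr::local_tempfile(fileext = ".png")
  write_panel_image(img, pngf)
  back8 <- read_panel_image(pngf, "brightfield", g$pixel_scale)
  expect_equal(back8$pixels, img$pixels, tolerance = 1 / 255)
  expect_error(write_panel_image(img, "x.bmp"), class = "wellcount_io_error")
})
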