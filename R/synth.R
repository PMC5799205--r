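#' Noise model for synthetic panel images
#'
#' @param additive_sigma Standard deviation of additive Gaussian pixel noise,
#'   in intensity units (images live in `[0, 1]`). Non-negative.
#' @param illumination_gradient Maximum fractional intensity tilt across the
#'   frame (0 = flat illumination), in `[0, 0.5]`. A value `g` scales pixel
#'   intensities linearly from `1 - g/2` at one corner to `1 + g/2` at the
#'   opposite corner, emulating uneven illumination.
#' @param rng_seed Integer seed; rendering is bit-reproducible given the seed.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(additive_sigma = 0.02, illumination_gradient = 0.05,
                       rng_seed = 1L) {
  wc_check(is.numeric(additive_sigma) && length(additive_sigma) == 1L &&
             additive_sigma >= 0,
           "wellcount_domain_error", "additive_sigma must be >= 0")
  wc_check(is.numeric(illumination_gradient) && length(illumination_gradient) == 1L &&
             illumination_gradient >= 0 && illumination_gradient <= 0.5,
           "wellcount_domain_error", "illumination_gradient must be in [0, 0.5]")
  wc_check(is.numeric(rng_seed) && length(rng_seed) == 1L && is.finite(rng_seed),
           "wellcount_domain_error", "rng_seed must be a finite integer")
  structure(list(additive_sigma = additive_sigma,
                 illumination_gradient = illumination_gradient,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_spec")
}

# Frame layout for one panel: well centers on an exact lattice with a random
# sub-pitch offset (the stage never lands on integer pixels), margin of one
# pitch around the grid.
.panel_frame <- function(geometry) {
  pitch_px <- geometry$pitch / geometry$pixel_scale
  margin <- pitch_px
  list(pitch_px = pitch_px, margin = margin,
       width = as.integer(ceiling((geometry$cols - 1) * pitch_px + 2 * margin)),
       height = as.integer(ceiling((geometry$rows - 1) * pitch_px + 2 * margin)))
}

#' Seed particles into the wells of one panel
#'
#' Simulates loading a particle suspension of known number density into one
#' panel of a microwell array. With `aggregation = 0` the number of particles
#' per well is i.i.d. Poisson with mean `lambda = density * well_volume`
#' (random, independent partitioning). With `aggregation > 0` particles
#' arrive in clumps: clumps per well are Poisson with mean
#' `lambda * (1 - aggregation)` and clump sizes are geometric with mean
#' `1 / (1 - aggregation)`, so the expected particle count per well is still
#' `lambda` but the occupied fraction falls below the Poisson prediction
#' `1 - exp(-lambda)` -- the mechanism behind under-counting of aggregating
#' particles at high density.
#'
#' @param geometry An [array_geometry()].
#' @param density Particle number density in particles per uL; non-negative.
#' @param aggregation Clumping strength in `[0, 1)`; 0 disables clumping.
#' @param rng_seed Integer seed; output is bit-reproducible given the seed.
#' @param missing_wells Integer vector of well indices (row-major,
#'   `(row-1)*cols + col`) to be rendered absent from the image, emulating
#'   fabrication defects. These wells still appear in the truth table.
#' @return An object of class `"ground_truth"`: a data frame with one row per
#'   well (`row`, `col`, `x_px`, `y_px`, `particles`, `occupied`) and
#'   attributes `missing_wells`, `frame` (pixel layout), `density`,
#'   `aggregation`, `rng_seed`, `pitch_px`.
#' @examples
#' g <- array_geometry(panels = 1)
#' tr <- seed_particles(g, density = 5e4, rng_seed = 7)
#' mean(tr$occupied)            # close to 1 - exp(-5e4 * g$well_volume)
#' @export
seed_particles <- function(geometry, density, aggregation = 0, rng_seed = 1L,
                           missing_wells = integer(0)) {
  stopifnot(inherits(geometry, "array_geometry"))
  wc_check(is.numeric(density) && length(density) == 1L && is.finite(density) &&
             density >= 0,
           "wellcount_domain_error", "density must be a non-negative number")
  wc_check(is.numeric(aggregation) && length(aggregation) == 1L &&
             aggregation >= 0 && aggregation < 1,
           "wellcount_domain_error", "aggregation must be in [0, 1)")
  n <- geometry$wells_per_panel
  wc_check(all(missing_wells %in% seq_len(n)),
           "wellcount_domain_error", "missing_wells out of range")
  lambda <- density * geometry$well_volume
  fr <- .panel_frame(geometry)
  res <- withr::with_seed(as.integer(rng_seed), {
    off <- stats::runif(2, 0, fr$pitch_px / 4)
    clumps <- stats::rpois(n, lambda * (1 - aggregation))
    particles <- clumps
    if (aggregation > 0 && any(clumps > 0)) {
      idx <- clumps > 0
      particles[idx] <- clumps[idx] +
        stats::rnbinom(sum(idx), size = clumps[idx], prob = 1 - aggregation)
    }
    list(off = off, particles = particles)
  })
  rows <- rep(seq_len(geometry$rows), each = geometry$cols)
  cols <- rep(seq_len(geometry$cols), times = geometry$rows)
  truth <- data.frame(
    row = rows, col = cols,
    x_px = fr$margin + (cols - 1) * fr$pitch_px + res$off[1],
    y_px = fr$margin + (rows - 1) * fr$pitch_px + res$off[2],
    particles = res$particles,
    occupied = res$particles >= 1L
  )
  structure(truth,
            missing_wells = as.integer(missing_wells),
            frame = fr, pitch_px = fr$pitch_px,
            density = density, aggregation = aggregation,
            rng_seed = as.integer(rng_seed),
            class = c("ground_truth", "data.frame"))
}

# Default rendering contrast constants, overridable via render_panel(contrast=).
# Bright-field: bright background, darker fluid-filled well interior, dark rim
# annulus, dark particles. Fluorescence: dark background, faintly visible rims,
# bright fluorescent particles.
.default_contrast <- function(modality) {
  if (modality == "brightfield")
    list(background = 0.85, well = 0.75, rim = 0.35, particle = 0.12)
  else
    list(background = 0.05, well = 0.05, rim = 0.22, particle = 0.85)
}


#' Render a synthetic micrograph of one panel
#'
#' Draws the panel described by a [seed_particles()] ground truth as a
#' grayscale image in `[0, 1]`. In bright-field mode the background is
#' bright, well rims are dark annuli and particles are dark disks inside
#' occupied wells (particles block transmission); in fluorescence mode the
#' background is dark, rims are faint and particles are bright disks.
#' Wells listed in the truth's `missing_wells` are not drawn at all. An
#' illumination gradient and additive Gaussian noise are applied last and
#' intensities clipped to `[0, 1]`. Rendering is deterministic given
#' `noise$rng_seed` (which also seeds the sub-well particle placement).
#'
#' @param geometry An [array_geometry()]; must match the truth's layout.
#' @param truth A `"ground_truth"` object from [seed_particles()].
#' @param modality `"brightfield"` or `"fluorescence"`.
#' @param noise A [noise_spec()].
#' @param contrast Optional named list overriding any of the rendering
#'   constants `background`, `well`, `rim`, `particle`.
#' @param particle_diameter Rendered particle diameter in um.
#' @return An object of class `"panel_image"`: list with `pixels` (numeric
#'   matrix, row = image y, column = image x), `modality`, `pixel_scale`.
#' @export
render_panel <- function(geometry, truth,
                         modality = c("brightfield", "fluorescence"),
                         noise = noise_spec(), contrast = list(),
                         particle_diameter = 10) {
  modality <- match.arg(modality)
  stopifnot(inherits(geometry, "array_geometry"), inherits(noise, "noise_spec"))
  wc_check(inherits(truth, "ground_truth") &&
             nrow(truth) == geometry$wells_per_panel &&
             max(truth$row) == geometry$rows && max(truth$col) == geometry$cols,
           "wellcount_consistency_error",
           "ground truth does not match the array geometry")
  fr <- attr(truth, "frame")
  cc <- utils::modifyList(.default_contrast(modality), contrast)
  r_px <- (geometry$well_diameter / 2) / geometry$pixel_scale
  pr_px <- (particle_diameter / 2) / geometry$pixel_scale
  rim_w <- max(1.5, 3 / geometry$pixel_scale)
  img <- matrix(cc$background, fr$height, fr$width)
  h <- fr$height; w <- fr$width
  missing <- attr(truth, "missing_wells")
  drawn <- setdiff(seq_len(nrow(truth)), missing)

  # draw all random numbers first so painting can modify img in place
  rand <- withr::with_seed(noise$rng_seed, {
    np <- pmin(truth$particles, 8L)      # deeper stacks are occluded anyway
    ntot <- sum(np[drawn])
    # particles sit at random sub-well positions; the offset cap keeps at
    # least ~half of each particle inside the sampled well interior, so a
    # lone rim-hugging particle still darkens (or brightens) its well
    list(np = np,
         u = max(0, r_px - 0.6 * pr_px) * sqrt(stats::runif(ntot)),
         a = stats::runif(ntot, 0, 2 * pi),
         noise = if (noise$additive_sigma > 0)
           stats::rnorm(h * w, 0, noise$additive_sigma))
  })

  paint_window <- function(cx, cy, r) {
    xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
    ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
    list(xs = xs, ys = ys, d2 = outer((ys - cy)^2, (xs - cx)^2, `+`))
  }
  pi_ <- 0L
  for (i in drawn) {
    cx <- truth$x_px[i]; cy <- truth$y_px[i]
    win <- paint_window(cx, cy, r_px + rim_w)
    sub <- img[win$ys, win$xs]
    sub[win$d2 <= (r_px + rim_w)^2] <- cc$rim
    sub[win$d2 <= r_px^2] <- cc$well
    img[win$ys, win$xs] <- sub
    for (j in seq_len(rand$np[i])) {
      pi_ <- pi_ + 1L
      px <- cx + rand$u[pi_] * cos(rand$a[pi_])
      py <- cy + rand$u[pi_] * sin(rand$a[pi_])
      pw <- paint_window(px, py, pr_px)
      sub <- img[pw$ys, pw$xs]
      sub[pw$d2 <= pr_px^2] <- cc$particle
      img[pw$ys, pw$xs] <- sub
    }
  }
  if (noise$illumination_gradient > 0) {
    ramp <- outer((seq_len(h) - 1) / (h - 1), (seq_len(w) - 1) / (w - 1), `+`)
    img <- img * (1 + noise$illumination_gradient * (ramp / 2 - 0.5))
  }
  if (!is.null(rand$noise))
    img <- img + rand$noise
  img <- matrix(pmin(pmax(img, 0), 1), h, w)
  panel_image(img, modality, geometry$pixel_scale)
}

#' Construct a panel image object
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`; rows are image
#'   rows (y), columns are image columns (x), origin top-left.
#' @param modality `"brightfield"` or `"fluorescence"`.
#' @param pixel_scale um per pixel.
#' @return Object of class `"panel_image"`.
#' @export
panel_image <- function(pixels, modality = c("brightfield", "fluorescence"),
                        pixel_scale = 2) {
  modality <- match.arg(modality)
  wc_check(is.matrix(pixels) && is.numeric(pixels) &&
             all(pixels >= 0 & pixels <= 1),
           "wellcount_domain_error", "pixels must be a numeric matrix in [0, 1]")
  structure(list(pixels = pixels, modality = modality,
                 pixel_scale = pixel_scale),
            class = "panel_image")
}

#' @export
print.panel_image <- function(x, ...) {
  cat(sprintf("panel_image: %d x %d px, %s, %g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$modality, x$pixel_scale))
  invisible(x)
}

#' Write a panel image to PNG or TIFF
#'
#' TIFF output is 16-bit grayscale; PNG output is 8-bit grayscale. The format
#' is chosen from the file extension.
#'
#' @param image A [panel_image()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_panel_image <- function(image, path) {
  stopifnot(inherits(image, "panel_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image$pixels, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels, path, bits.per.sample = 16L)
  } else {
    wc_abort("wellcount_io_error",
             paste0("unsupported image format: .", ext, " (use png/tif/tiff)"))
  }
  invisible(path)
}

#' Read a panel image from PNG or TIFF
#'
#' RGB images are converted to grayscale by Rec. 709 luminance weighting
#' (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @param modality `"brightfield"` or `"fluorescence"`.
#' @param pixel_scale um per pixel of the image.
#' @return A [panel_image()].
#' @export
read_panel_image <- function(path, modality = c("brightfield", "fluorescence"),
                             pixel_scale = 2) {
  modality <- match.arg(modality)
  wc_check(file.exists(path), "wellcount_io_error",
           paste0("image not found: ", path))
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") png::readPNG(path)
        else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
        else wc_abort("wellcount_io_error",
                      paste0("unsupported image format: .", ext))
  if (length(dim(px)) == 3L)
    px <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
  panel_image(pmin(pmax(px, 0), 1), modality, pixel_scale)
}

#' Write ground truth to CSV
#'
#' Columns: `panel`, `row`, `col`, `x_px`, `y_px`, `particles`, `occupied`.
#'
#' @param truth A `"ground_truth"` object or a list of them (one per panel).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  if (inherits(truth, "ground_truth")) truth <- list(truth)
  tabs <- lapply(seq_along(truth), function(p)
    cbind(panel = p, as.data.frame(truth[[p]])))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}
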