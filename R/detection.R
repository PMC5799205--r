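# Well recognition: kernel-average denoising, radius-bounded circular Hough
# transform, and reconstruction of the full rows x cols lattice from the
# (possibly incomplete) set of detected wells.

.as_pixels <- function(image) {
  if (inherits(image, "panel_image")) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else wc_abort("wellcount_domain_error",
                "image must be a panel_image or numeric matrix")
}

# Separable box mean with symmetric (reflect) edge padding.
.box_mean <- function(mat, k) {
  if (k == 1L) return(mat)
  pad <- (k - 1L) %/% 2L
  n <- nrow(mat); m <- ncol(mat)
  p <- mat[c(pad:1, 1:n, n:(n - pad + 1L)), c(pad:1, 1:m, m:(m - pad + 1L))]
  f <- rep(1 / k, k)
  p <- stats::filter(p, f, sides = 2)
  p <- t(stats::filter(t(p), f, sides = 2))
  matrix(p[(pad + 1L):(pad + n), (pad + 1L):(pad + m)], n, m)
}

#' Kernel-average denoising
#'
#' Replaces each pixel by the arithmetic mean of its `kernel_size` x
#' `kernel_size` neighborhood (a box filter), the noise-removal step applied
#' before well detection. Image edges are handled by symmetric reflection, so
#' the output has the same dimensions as the input and a constant image is
#' unchanged.
#'
#' @param image A [panel_image()] or numeric matrix in `[0, 1]`.
#' @param kernel_size Odd positive integer, smaller than either image
#'   dimension. `1` is the identity.
#' @return Same type as `image`, denoised.
#' @export
denoise <- function(image, kernel_size = 3L) {
  mat <- .as_pixels(image)
  wc_check(is.numeric(kernel_size) && length(kernel_size) == 1L &&
             kernel_size == round(kernel_size) && kernel_size >= 1 &&
             kernel_size %% 2 == 1,
           "wellcount_parameter_error",
           "kernel_size must be an odd integer >= 1")
  wc_check(kernel_size < nrow(mat) && kernel_size < ncol(mat),
           "wellcount_parameter_error",
           "kernel_size must be smaller than both image dimensions")
  out <- .box_mean(mat, as.integer(kernel_size))
  out <- pmin(pmax(out, 0), 1)
  if (inherits(image, "panel_image")) {
    image$pixels <- out
    image
  } else out
}

#' Detect circular microwells by a radius-bounded Hough transform
#'
#' Classical circular Hough transform restricted to radii within
#' `radius_tol` (um) of the nominal well radius: gradient-magnitude edge
#' pixels vote for candidate centers one radius away, the accumulator is
#' normalised by the ring perimeter, and peaks above `accumulator_threshold`
#' become detections. Bounding the radius band suppresses false circles from
#' structured boundaries and from particles or aggregates inside wells.
#' Candidate centers closer than half a pitch are merged, keeping the
#' stronger accumulator peak, so no two returned centers are closer than
#' `pitch / 2`. Peak positions are refined to sub-pixel precision by a local
#' accumulator centroid.
#'
#' @param image A [panel_image()] or numeric matrix (already denoised;
#'   see [denoise()]).
#' @param geometry An [array_geometry()] supplying the nominal well radius,
#'   pitch and pixel scale.
#' @param radius_tol Half-width of the accepted radius band, in um
#'   (default 1).
#' @param edge_threshold Gradient magnitude (intensity units per pixel, via
#'   central differences) above which a pixel counts as an edge.
#' @param accumulator_threshold Minimum normalised accumulator value (1 =
#'   a fully edged rim) for a detection; the user-facing sensitivity knob
#'   of the transform.
#' @param radius_step Radius sampling step of the accumulator, in pixels.
#' @return A data frame of class `"detected_circles"` with columns `x_px`,
#'   `y_px` (sub-pixel center, x = image column, y = image row, 1-based),
#'   `radius_px`, `score`.
#' @export
find_wells <- function(image, geometry, radius_tol = 1,
                       edge_threshold = 0.08, accumulator_threshold = 0.35,
                       radius_step = 0.5) {
  mat <- .as_pixels(image)
  stopifnot(inherits(geometry, "array_geometry"))
  wc_check(radius_tol > 0, "wellcount_parameter_error", "radius_tol must be > 0")
  scale <- geometry$pixel_scale
  r0 <- (geometry$well_diameter / 2) / scale
  tol_px <- radius_tol / scale
  radii <- seq(max(r0 - tol_px, 1), r0 + tol_px, by = radius_step)
  pitch_px <- geometry$pitch / scale
  h <- nrow(mat); w <- ncol(mat)
  rmax <- as.integer(ceiling(max(radii) + 1))
  wc_check(h >= 2 * rmax + 3 && w >= 2 * rmax + 3,
           "wellcount_detection_error",
           "image too small to contain a single well")

  gx <- mat[, c(2:w, w)] - mat[, c(1, 1:(w - 1))]
  gy <- mat[c(2:h, h), ] - mat[c(1, 1:(h - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  edge <- which(mag > edge_threshold)
  er <- ((edge - 1L) %% h) + 1L
  ec <- ((edge - 1L) %/% h) + 1L
  keep <- er > rmax & er <= h - rmax & ec > rmax & ec <= w - rmax
  edge <- edge[keep]
  if (length(edge) == 0L)
    return(structure(data.frame(x_px = numeric(0), y_px = numeric(0),
                                radius_px = numeric(0), score = numeric(0)),
                     class = c("detected_circles", "data.frame")))

  # ring voting: each edge pixel votes for all candidate centers one radius
  # away; the accumulator is normalised by the ring size so a fully edged
  # rim scores about 1 per transition
  best <- numeric(h * w)
  best_r <- numeric(h * w)
  for (r in radii) {
    rr <- as.integer(ceiling(r + 0.5))
    dx <- rep(-rr:rr, each = 2L * rr + 1L)
    dy <- rep(-rr:rr, times = 2L * rr + 1L)
    ring <- abs(sqrt(dx^2 + dy^2) - r) <= 0.5
    off <- dx[ring] * h + dy[ring]
    votes <- numeric(h * w)
    for (o in off) {            # edge indices are unique, so this is a
      idx <- edge + o           # conflict-free scatter-add per offset
      votes[idx] <- votes[idx] + 1
    }
    votes <- votes / sum(ring)
    upd <- votes > best
    best[upd] <- votes[upd]
    best_r[upd] <- r
  }

  cand <- which(best >= accumulator_threshold)
  if (length(cand)) {
    nb <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
    is_max <- rep(TRUE, length(cand))
    for (o in nb) is_max <- is_max & best[cand] >= best[cand + o]
    cand <- cand[is_max]
  }
  if (length(cand) == 0L)
    return(structure(data.frame(x_px = numeric(0), y_px = numeric(0),
                                radius_px = numeric(0), score = numeric(0)),
                     class = c("detected_circles", "data.frame")))

  cy <- ((cand - 1L) %% h) + 1L
  cx <- ((cand - 1L) %/% h) + 1L
  sc <- best[cand]
  ord <- order(sc, decreasing = TRUE)
  # merge radius: weak secondary peaks (e.g. arcs of two facing rims voting
  # at the mid-point between wells, exactly pitch/2 away) must collapse onto
  # the stronger true peak, so the exclusion radius sits above pitch/2 but
  # below the pitch
  min_sep2 <- (0.7 * pitch_px)^2
  ax <- numeric(0); ay <- numeric(0); ai <- integer(0)
  for (i in ord) {
    if (length(ax) == 0L || all((ax - cx[i])^2 + (ay - cy[i])^2 >= min_sep2)) {
      ax <- c(ax, cx[i]); ay <- c(ay, cy[i]); ai <- c(ai, i)
    }
  }

  # per-circle refinement and validation: edge pixels in the radius band
  # whose gradients are radially aligned (i) measure how much of the rim's
  # circumference is present, rejecting accumulator ghosts (arcs of
  # neighbouring rims, circles of the wrong size), and (ii) feed an
  # algebraic least-squares circle fit giving the sub-pixel center.
  emat <- mag > edge_threshold
  n_acc <- length(ai)
  out_x <- numeric(n_acc); out_y <- numeric(n_acc)
  out_r <- numeric(n_acc); out_s <- numeric(n_acc)
  valid <- logical(n_acc)
  for (j in seq_len(n_acc)) {
    x0 <- cx[ai[j]]; y0 <- cy[ai[j]]
    r <- best_r[cand[ai[j]]]
    rr <- as.integer(ceiling(r + 2))
    ys <- max(1L, y0 - rr):min(h, y0 + rr)
    xs <- max(1L, x0 - rr):min(w, x0 + rr)
    sub <- which(emat[ys, xs, drop = FALSE], arr.ind = TRUE)
    if (nrow(sub) == 0L) next
    py <- ys[sub[, 1]]; px <- xs[sub[, 2]]
    ddx <- px - x0; ddy <- py - y0
    dist <- sqrt(ddx^2 + ddy^2)
    band <- dist >= r - 1.5 & dist <= r + 1.5
    if (sum(band) < 6L) next
    py <- py[band]; px <- px[band]
    ddx <- ddx[band]; ddy <- ddy[band]; dist <- dist[band]
    gix <- gx[cbind(py, px)]; giy <- gy[cbind(py, px)]
    gm <- pmax(sqrt(gix^2 + giy^2), 1e-12)
    dots <- (gix * ddx + giy * ddy) / (gm * dist)
    # radially aligned in either polarity: fluid-rim edges point inward,
    # particle-rim edges outward, both belong to the same physical rim
    aligned <- abs(dots) >= 0.7
    coverage <- sum(aligned) / (2 * pi * r)
    # a real rim subtends (almost) the full circle; accumulator ghosts --
    # arcs of neighbouring or wrong-sized rims -- cover only a few sectors
    sect <- unique(floor(6 * (atan2(ddy[aligned], ddx[aligned]) + pi) / pi))
    if (coverage < accumulator_threshold || sum(aligned) < 6L ||
        length(sect) < 8L) next
    # center refinement by a fixed-radius circular fit (Gauss-Newton on
    # sum(|p - c| - r1)^2). The band holds two concentric edge rings (the
    # rim's inner and outer transitions), so the fit uses only the inner
    # one, selected by gradient polarity: in bright-field the well fluid is
    # brighter than the rim and the inner-transition gradient points
    # inward; in fluorescence the rim is brighter and the sign flips.
    # Particle-blob boundaries share neither ring nor (mostly) polarity.
    pol <- if (inherits(image, "panel_image") &&
               image$modality == "fluorescence") 1 else -1
    pure <- pol * dots >= 0.7
    fit_set <- if (sum(pure) >= 12L) pure else aligned
    # keep only the transition core, anchored on the median magnitude: the
    # weak skirt of a thick thresholded edge ring is pixel-phase dependent
    # (biasing the fit by up to ~1.5 px), while much stronger gradients
    # belong to particle boundaries, not to the rim
    gmed <- stats::median(gm[fit_set])
    core <- fit_set & gm >= 0.5 * gmed & gm <= 2 * gmed
    if (sum(core) >= 6L) fit_set <- core
    qx <- px[fit_set]; qy <- py[fit_set]
    qw <- gm[fit_set]   # gradient-magnitude weights approximate the
                        # continuous edge centroid within the core
    fx <- x0; fy <- y0
    r1 <- stats::median(dist[fit_set])
    for (it in 1:8) {
      dd <- pmax(sqrt((qx - fx)^2 + (qy - fy)^2), 1e-9)
      keep_q <- abs(dd - r1) <= if (it == 1) 1.5 else 1.0
      if (sum(keep_q) < 6L) break
      res <- dd[keep_q] - r1
      wt <- qw[keep_q] / sum(qw[keep_q])
      fx <- fx + sum(wt * res * (qx[keep_q] - fx) / dd[keep_q])
      fy <- fy + sum(wt * res * (qy[keep_q] - fy) / dd[keep_q])
      # the radius is re-estimated jointly (a peak displaced by a pixel
      # inflates distance medians and would otherwise lock the center onto
      # an off-center equilibrium), but stays clamped to the Hough band
      dd <- pmax(sqrt((qx - fx)^2 + (qy - fy)^2), 1e-9)
      keep_q <- abs(dd - r1) <= 1.5
      if (sum(keep_q) < 6L) break
      wt <- qw[keep_q] / sum(qw[keep_q])
      r1 <- min(max(sum(wt * dd[keep_q]), min(radii) - 1), max(radii) + 1)
    }
    fr <- r1
    if (!is.finite(fx) || (fx - x0)^2 + (fy - y0)^2 > 4) {
      fx <- x0; fy <- y0; fr <- r   # degenerate fit: keep the peak position
    }
    valid[j] <- TRUE
    out_x[j] <- fx; out_y[j] <- fy
    out_r[j] <- fr; out_s[j] <- coverage
  }
  structure(data.frame(x_px = out_x[valid], y_px = out_y[valid],
                       radius_px = out_r[valid], score = out_s[valid]),
            class = c("detected_circles", "data.frame"))
}

# 1-D clustering by gap threshold: sorted values split where consecutive
# differences exceed `gap`; returns cluster medians and per-point assignment.
.cluster1d <- function(v, gap) {
  ord <- order(v)
  sv <- v[ord]
  grp_sorted <- cumsum(c(1, diff(sv) > gap))
  grp <- integer(length(v))
  grp[ord] <- grp_sorted
  list(medians = as.numeric(tapply(v, grp, stats::median)),
       counts = as.integer(table(grp)),
       assignment = grp)
}

#' Fit the known rectangular well lattice to detected circles
#'
#' Reconstructs the complete `rows` x `cols` grid of well centers from a
#' partial set of detections: circle coordinates are clustered into rows and
#' columns (gap threshold pitch/2, median coordinate per cluster), clusters
#' are mapped to integer lattice indices via the nominal pitch, and an affine
#' lattice model (x and y each linear in row and column index, absorbing
#' small rotation or shear) is fitted by least squares. Every well receives a
#' fitted center whether or not it was detected, so the number of analysed
#' wells never depends on occupancy or missing detections.
#'
#' @param circles A data frame with columns `x_px`, `y_px` (and optionally
#'   `radius_px`), e.g. from [find_wells()]. Must cover at least two distinct
#'   rows and two distinct columns of the lattice.
#' @param geometry An [array_geometry()].
#' @param residual_tol Maximum acceptable RMS residual of detections about
#'   the fitted lattice, in pixels; defaults to a quarter pitch. Exceeding it
#'   raises a grid-fit error (the detections are not one consistent lattice).
#' @return An object of class `"well_grid"`: list with `rows`, `cols`,
#'   `origin`, `pitch_x_px`, `pitch_y_px`, `radius_px`, `rms_residual`,
#'   `n_detected`, and `centers`, a row-major data frame (`row`, `col`,
#'   `x_px`, `y_px`, `detected`).
#' @export
fit_grid <- function(circles, geometry, residual_tol = NULL) {
  stopifnot(inherits(geometry, "array_geometry"))
  wc_check(is.data.frame(circles) && all(c("x_px", "y_px") %in% names(circles)),
           "wellcount_domain_error", "circles must have x_px and y_px columns")
  pitch_px <- geometry$pitch / geometry$pixel_scale
  if (is.null(residual_tol)) residual_tol <- pitch_px / 4
  wc_check(nrow(circles) >= 4, "wellcount_gridfit_error",
           "too few detected circles to fit a lattice (need >= 4)")

  rc <- .cluster1d(circles$y_px, pitch_px / 2)
  cc <- .cluster1d(circles$x_px, pitch_px / 2)
  if (length(rc$medians) < 2)
    wc_abort("wellcount_gridfit_error",
             "grid fit failed: single row detected (need >= 2 distinct rows)")
  if (length(cc$medians) < 2)
    wc_abort("wellcount_gridfit_error",
             "grid fit failed: single column detected (need >= 2 distinct columns)")
  if (length(rc$medians) > geometry$rows || length(cc$medians) > geometry$cols)
    wc_abort("wellcount_gridfit_error",
             "grid fit failed: more row/column clusters than lattice rows/columns (inconsistent lattice)")

  iy_cl <- round((rc$medians - min(rc$medians)) / pitch_px)
  ix_cl <- round((cc$medians - min(cc$medians)) / pitch_px)
  if (anyDuplicated(iy_cl) || anyDuplicated(ix_cl) ||
      max(iy_cl) > geometry$rows - 1 || max(ix_cl) > geometry$cols - 1)
    wc_abort("wellcount_gridfit_error",
             "grid fit failed: detected rows/columns are not consistent with the nominal pitch")

  iy <- iy_cl[rc$assignment]
  ix <- ix_cl[cc$assignment]
  X <- cbind(1, ix, iy)
  bx <- stats::lm.fit(X, circles$x_px)$coefficients
  by <- stats::lm.fit(X, circles$y_px)$coefficients
  res2 <- (circles$x_px - X %*% bx)^2 + (circles$y_px - X %*% by)^2
  rms <- sqrt(mean(res2))
  if (rms > residual_tol)
    wc_abort("wellcount_gridfit_error",
             sprintf("grid fit failed: RMS residual %.2f px exceeds tolerance %.2f px (detections not a single lattice)",
                     rms, residual_tol))
  if (abs(bx[2] - pitch_px) / pitch_px > 0.25 ||
      abs(by[3] - pitch_px) / pitch_px > 0.25)
    wc_abort("wellcount_gridfit_error",
             "grid fit failed: fitted pitch deviates more than 25% from the nominal pitch")

  gr <- rep(seq_len(geometry$rows), each = geometry$cols)
  gc <- rep(seq_len(geometry$cols), times = geometry$rows)
  gX <- cbind(1, gc - 1, gr - 1)
  centers <- data.frame(
    row = gr, col = gc,
    x_px = as.numeric(gX %*% bx),
    y_px = as.numeric(gX %*% by),
    detected = paste(gr - 1, gc - 1) %in% paste(iy, ix)
  )
  radius_px <- if ("radius_px" %in% names(circles) && nrow(circles))
    stats::median(circles$radius_px)
  else (geometry$well_diameter / 2) / geometry$pixel_scale

  structure(list(
    rows = geometry$rows, cols = geometry$cols,
    origin = c(x = unname(bx[1]), y = unname(by[1])),
    pitch_x_px = unname(bx[2]), pitch_y_px = unname(by[3]),
    skew = c(x_per_row = unname(bx[3]), y_per_col = unname(by[2])),
    radius_px = radius_px, rms_residual = rms,
    n_detected = nrow(circles), centers = centers
  ), class = "well_grid")
}

#' @export
print.well_grid <- function(x, ...) {
  cat(sprintf("well_grid: %d x %d = %d wells (%d detected), pitch (%.2f, %.2f) px\n",
              x$rows, x$cols, nrow(x$centers), x$n_detected,
              x$pitch_x_px, x$pitch_y_px))
  cat(sprintf("  origin (%.2f, %.2f) px, radius %.2f px, RMS residual %.3f px\n",
              x$origin["x"], x$origin["y"], x$radius_px, x$rms_residual))
  invisible(x)
}
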