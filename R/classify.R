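# Occupancy classification: per-well mean intensity, histogram-valley
# threshold between the two intensity modes, polarity by imaging modality.

#' Mean interior intensity of each fitted well
#'
#' For every well of a fitted grid, the arithmetic mean of pixel intensities
#' inside the disk of radius `radius_px * interior_fraction` centered at the
#' fitted well center. Shrinking the disk excludes rim pixels (dark in
#' bright-field) that would bias unoccupied-well means.
#'
#' @param image A [panel_image()] or numeric matrix.
#' @param grid A [fit_grid()] result.
#' @param interior_fraction Fraction of the fitted radius sampled (default
#'   0.8).
#' @return Numeric vector of length `rows * cols`, row-major (all columns of
#'   row 1, then row 2, ...).
#' @export
well_intensities <- function(image, grid, interior_fraction = 0.8) {
  mat <- .as_pixels(image)
  stopifnot(inherits(grid, "well_grid"))
  wc_check(interior_fraction > 0 && interior_fraction <= 1,
           "wellcount_parameter_error", "interior_fraction must be in (0, 1]")
  r <- grid$radius_px * interior_fraction
  h <- nrow(mat); w <- ncol(mat)
  cx <- grid$centers$x_px; cy <- grid$centers$y_px
  oob <- cx - r < 1 | cx + r > w | cy - r < 1 | cy + r > h
  if (any(oob))
    wc_abort("wellcount_bounds_error",
             paste0("fitted wells extend outside the image: ",
                    paste(sprintf("(%d,%d)", grid$centers$row[oob],
                                  grid$centers$col[oob])[seq_len(min(5, sum(oob)))],
                          collapse = " "),
                    if (sum(oob) > 5) sprintf(" and %d more", sum(oob) - 5)),
             wells = which(oob))
  out <- numeric(length(cx))
  for (i in seq_along(cx)) {
    xs <- floor(cx[i] - r):ceiling(cx[i] + r)
    ys <- floor(cy[i] - r):ceiling(cy[i] + r)
    mask <- outer((ys - cy[i])^2, (xs - cx[i])^2, `+`) <= r^2
    out[i] <- mean(mat[ys, xs][mask])
  }
  out
}

# Freedman-Diaconis bin count with a floor of 16 bins.
.fd_bins <- function(x) {
  iqr <- stats::IQR(x)
  rng <- diff(range(x))
  if (iqr <= 0 || rng <= 0) return(16L)
  max(16L, as.integer(ceiling(rng / (2 * iqr * length(x)^(-1 / 3)))))
}

#' Automatic occupancy threshold from the well-intensity histogram
#'
#' Occupied and unoccupied wells form two modes in the distribution of
#' per-well mean intensity (occupied darker in bright-field, brighter in
#' fluorescence). The unoccupied cluster is grown from the empty-side
#' extreme of the sorted intensities; the threshold is placed at the
#' midpoint of the first gap that dwarfs both the cluster's span so far
#' and the local point spacing -- the empty valley between the histogram's
#' two peaks, located from the data themselves rather than from a smoothed
#' density whose minimum is a numerical tie anywhere inside a wide empty
#' valley. If no such valley exists (no evidence of occupancy), a sentinel
#' threshold is returned that classifies every well as unoccupied (below
#' the minimum intensity for bright-field, above the maximum for
#' fluorescence).
#'
#' @param intensities Numeric vector of per-well mean intensities (length
#'   at least 2).
#' @param modality `"brightfield"` or `"fluorescence"`.
#' @return The threshold intensity, with attribute `unimodal` (logical).
#' @export
auto_threshold <- function(intensities, modality = c("brightfield", "fluorescence")) {
  modality <- match.arg(modality)
  wc_check(is.numeric(intensities) && length(intensities) >= 2,
           "wellcount_domain_error", "need at least 2 intensity values")
  sentinel <- function() {
    t <- if (modality == "brightfield") min(intensities) - 1
         else max(intensities) + 1
    structure(t, unimodal = TRUE)
  }
  if (diff(range(intensities)) < 1e-9) return(sentinel())
  # In bright-field occupied wells are darker than empty ones; in
  # fluorescence they are brighter. Work on a flipped axis so "occupied"
  # is always the low side.
  v <- if (modality == "brightfield") intensities else -intensities
  # Grow the unoccupied cluster downward from the empty-side extreme
  # through the sorted intensities. The valley between the two histogram
  # peaks is the first gap that dwarfs both the cluster's span so far and
  # the local point spacing; tail stragglers of a unimodal distribution
  # never produce such a gap, while the contrast between filled and empty
  # wells always does. This stays valid when multi-particle wells fragment
  # the occupied mass into sub-modes, or when the occupied mode is too
  # diffuse to register as a histogram peak of its own.
  s <- sort(v, decreasing = TRUE)
  nv <- length(s)
  spac <- -diff(s)
  core <- min(10L, nv - 1L)
  for (i in core:(nv - 1L)) {
    gap <- spac[i]
    span <- s[1] - s[i]
    local <- stats::median(spac[max(1L, i - 10L):(i - 1L)])
    if (gap > max(0.5 * span, 5 * local, 1e-3)) {
      thr <- (s[i] + s[i + 1L]) / 2
      return(structure(if (modality == "brightfield") thr else -thr,
                       unimodal = FALSE))
    }
  }
  sentinel()
}

#' Classify wells as occupied or unoccupied
#'
#' Applies the modality polarity rule: in bright-field, wells with mean
#' intensity strictly below the threshold are occupied (particles block
#' transmission); in fluorescence, wells strictly above it are occupied.
#' Ties (intensity exactly at the threshold) are classified unoccupied,
#' the conservative choice for density estimation.
#'
#' @param intensities Numeric vector of per-well mean intensities.
#' @param threshold Finite threshold intensity (e.g. from
#'   [auto_threshold()]).
#' @param modality `"brightfield"` or `"fluorescence"`.
#' @return An object of class `"occupancy_result"`: list with `intensities`,
#'   `threshold`, `modality`, `occupied` (logical vector), `k_occupied`,
#'   `n_total`, and `histogram` (`breaks`, `counts`; Freedman-Diaconis bins,
#'   minimum 16).
#' @export
classify <- function(intensities, threshold,
                     modality = c("brightfield", "fluorescence")) {
  modality <- match.arg(modality)
  wc_check(is.numeric(intensities) && length(intensities) >= 1,
           "wellcount_domain_error", "intensities must be non-empty numeric")
  wc_check(is.numeric(threshold) && length(threshold) == 1L && is.finite(threshold),
           "wellcount_domain_error", "threshold must be a finite number")
  occ <- if (modality == "brightfield") intensities < threshold
         else intensities > threshold
  rng <- range(intensities)
  breaks <- if (diff(rng) <= 0) c(rng[1] - 0.5, rng[1] + 0.5)
            else seq(rng[1], rng[2], length.out = .fd_bins(intensities) + 1L)
  hh <- graphics::hist(intensities, breaks = breaks, plot = FALSE,
                       include.lowest = TRUE)
  structure(list(intensities = intensities,
                 threshold = as.numeric(threshold), modality = modality,
                 occupied = occ,
                 k_occupied = sum(occ), n_total = length(intensities),
                 histogram = list(breaks = hh$breaks, counts = hh$counts)),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("occupancy_result (%s): %d / %d wells occupied (%.1f%%), threshold %.4f\n",
              x$modality, x$k_occupied, x$n_total,
              100 * x$k_occupied / x$n_total, x$threshold))
  invisible(x)
}
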