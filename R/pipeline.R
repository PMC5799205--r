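#' Count particles or cells from microwell panel images
#'
#' The end-to-end fitting function: for each panel image it denoises
#' ([denoise()]), detects wells by the radius-bounded Hough transform
#' ([find_wells()]), reconstructs the full well lattice ([fit_grid()]) and
#' measures per-well mean intensities ([well_intensities()]). Intensities
#' are then pooled across panels (or kept per panel), thresholded
#' ([auto_threshold()] unless `threshold` is given), classified into
#' occupied/unoccupied wells ([classify()]), and the pooled counts converted
#' into a number density with a confidence interval ([estimate_density()]).
#'
#' Panels whose grid fit fails are dropped with a warning and the estimate is
#' computed from the remaining panels, mirroring the exclusion of defective
#' panels from analysis; if every panel fails, an error is raised.
#'
#' @param images A single [panel_image()], a list of them, numeric matrices,
#'   or character paths to PNG/TIFF images (one image per panel).
#' @param geometry An [array_geometry()].
#' @param modality `"brightfield"` or `"fluorescence"`; defaults to the
#'   modality of the first `panel_image` input.
#' @param threshold Optional manual classification threshold; `NULL` (the
#'   default) selects it automatically from the pooled intensity histogram.
#' @param pool `"device"` (default): one threshold from all panels pooled;
#'   `"panel"`: a separate threshold per panel, counts then summed.
#' @param kernel_size Denoising kernel size (see [denoise()]).
#' @param interior_fraction Fraction of the well radius sampled for the mean
#'   intensity (see [well_intensities()]).
#' @param radius_tol Hough radius band half-width in um (see
#'   [find_wells()]).
#' @param conf_level,ci_method Passed to [estimate_density()].
#' @param ... Further arguments to [find_wells()] (e.g.
#'   `accumulator_threshold`).
#' @return A `"well_count"` object (see [estimate_density()]) with
#'   additional fields: `occupancy` (the pooled [classify()] result),
#'   `grids` (per-panel [fit_grid()] results), `panel_counts` (per-panel k
#'   and n), `failed_panels`, `geometry`, `modality`.
#' @examples
#' geom <- array_geometry(panels = 1)
#' truth <- seed_particles(geom, density = 4e4, rng_seed = 1)
#' img <- render_panel(geom, truth, "brightfield", noise_spec(rng_seed = 2))
#' fit <- wellcount(img, geom)
#' fit$k  # equals sum(truth$occupied)
#' @export
wellcount <- function(images, geometry, modality = NULL, threshold = NULL,
                      pool = c("device", "panel"), kernel_size = 3L,
                      interior_fraction = 0.8, radius_tol = 1,
                      conf_level = 0.95, ci_method = "wilson", ...) {
  pool <- match.arg(pool)
  stopifnot(inherits(geometry, "array_geometry"))
  if (inherits(images, "panel_image") || is.matrix(images) ||
      is.character(images))
    images <- if (is.character(images)) as.list(images) else list(images)
  wc_check(length(images) >= 1, "wellcount_domain_error",
           "need at least one panel image")

  load1 <- function(im) {
    if (is.character(im))
      read_panel_image(im, modality = modality %||% "brightfield",
                       pixel_scale = geometry$pixel_scale)
    else im
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  first <- load1(images[[1]])
  if (is.null(modality))
    modality <- if (inherits(first, "panel_image")) first$modality
                else "brightfield"

  grids <- vector("list", length(images))
  ints <- vector("list", length(images))
  failed <- character(0)
  for (p in seq_along(images)) {
    res <- tryCatch({
      img <- if (p == 1) first else load1(images[[p]])
      dn <- denoise(img, kernel_size)
      circ <- find_wells(dn, geometry, radius_tol = radius_tol, ...)
      grid <- fit_grid(circ, geometry)
      list(grid = grid,
           int = well_intensities(dn, grid, interior_fraction))
    }, wellcount_error = function(e) e)
    if (inherits(res, "condition")) {
      failed <- c(failed, sprintf("panel %d: %s", p, conditionMessage(res)))
    } else {
      grids[[p]] <- res$grid
      ints[[p]] <- res$int
    }
  }
  if (length(failed))
    warning(sprintf("%d panel(s) dropped from analysis:\n  %s",
                    length(failed), paste(failed, collapse = "\n  ")),
            call. = FALSE)
  ok <- !vapply(ints, is.null, logical(1))
  if (!any(ok))
    wc_abort("wellcount_detection_error",
             "all panels failed well detection or grid fitting")

  if (pool == "device") {
    pooled <- unlist(ints[ok])
    thr <- if (is.null(threshold)) auto_threshold(pooled, modality)
           else threshold
    occ <- classify(pooled, thr, modality)
    k <- occ$k_occupied; n <- occ$n_total
    panel_counts <- data.frame(
      panel = which(ok),
      k = vapply(ints[ok], function(v) classify(v, thr, modality)$k_occupied,
                 integer(1)),
      n = lengths(ints[ok]))
  } else {
    per <- lapply(ints[ok], function(v) {
      thr <- if (is.null(threshold)) auto_threshold(v, modality) else threshold
      classify(v, thr, modality)
    })
    k <- sum(vapply(per, `[[`, integer(1), "k_occupied"))
    n <- sum(vapply(per, `[[`, integer(1), "n_total"))
    pooled <- unlist(ints[ok])
    occ <- classify(pooled,
                    if (is.null(threshold))
                      mean(vapply(per, `[[`, numeric(1), "threshold"))
                    else threshold,
                    modality)
    occ$k_occupied <- k; occ$n_total <- n
    panel_counts <- data.frame(
      panel = which(ok),
      k = vapply(per, `[[`, integer(1), "k_occupied"),
      n = vapply(per, `[[`, integer(1), "n_total"))
  }

  est <- estimate_density(k, n, geometry$well_volume,
                          conf_level = conf_level, ci_method = ci_method)
  est$occupancy <- occ
  est$grids <- grids[ok]
  est$panel_counts <- panel_counts
  est$failed_panels <- failed
  est$geometry <- geometry
  est$modality <- modality
  est
}
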