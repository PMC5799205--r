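#' Physical description of a microwell array
#'
#' Constructs and validates the geometry of a rectangular array of circular
#' microwells: well dimensions, center-to-center pitch, grid shape, number of
#' panels per device, and the optical pixel scale. The per-well volume
#' defaults to the cylindrical volume implied by the well diameter and depth
#' (see [cylinder_volume()]); pass `well_volume` explicitly to override it,
#' e.g. with a calibrated or published value.
#'
#' The default geometry is a 14,400-well device: 16 panels, each a 30 x 30
#' array of 20 um diameter, 25 um deep wells (900 wells per panel). Chips
#' are often fabricated with more panel positions than are used for
#' counting; `panels` is free, and the per-device statistics simply scale
#' with `rows * cols * panels`.
#' The within-panel pitch defaults to 40 um and the pixel scale to 2 um/px;
#' both are free parameters of the imaging setup.
#'
#' @param well_diameter Well diameter in um. Must be positive.
#' @param well_depth Well depth in um. Must be positive.
#' @param pitch Center-to-center well spacing in um; at least `well_diameter`.
#' @param rows,cols Wells per panel along each axis; each at least 2.
#' @param panels Number of panels per device; at least 1.
#' @param pixel_scale Image resolution in um per pixel.
#' @param well_volume Per-well volume in uL, or `NULL` (the default) to use
#'   the cylindrical volume of a single well.
#'
#' @return An object of class `"array_geometry"`: a list with the fields
#'   above plus `wells_per_panel` and `wells_per_device`.
#' @seealso [cylinder_volume()], [load_config()], [write_config()]
#' @examples
#' g <- array_geometry()
#' g$wells_per_device   # 14400
#' g$well_volume        # 7.854e-06 uL (cylindrical)
#' @export
array_geometry <- function(well_diameter = 20, well_depth = 25, pitch = 40,
                           rows = 30, cols = 30, panels = 16,
                           pixel_scale = 2, well_volume = NULL) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  bad <- character(0)
  if (!num1(well_diameter) || well_diameter <= 0) bad <- c(bad, "well_diameter")
  if (!num1(well_depth) || well_depth <= 0) bad <- c(bad, "well_depth")
  if (!num1(pitch) || (num1(well_diameter) && pitch < well_diameter)) bad <- c(bad, "pitch")
  if (!num1(rows) || rows < 2 || rows != round(rows)) bad <- c(bad, "rows")
  if (!num1(cols) || cols < 2 || cols != round(cols)) bad <- c(bad, "cols")
  if (!num1(panels) || panels < 1 || panels != round(panels)) bad <- c(bad, "panels")
  if (!num1(pixel_scale) || pixel_scale <= 0) bad <- c(bad, "pixel_scale")
  if (!is.null(well_volume) && (!num1(well_volume) || well_volume <= 0))
    bad <- c(bad, "well_volume")
  if (length(bad))
    wc_abort("wellcount_geometry_error",
             paste0("invalid array geometry field(s): ",
                    paste(bad, collapse = ", ")),
             fields = bad)
  if (is.null(well_volume))
    well_volume <- cylinder_volume(well_diameter, well_depth)
  structure(list(
    well_diameter = well_diameter, well_depth = well_depth, pitch = pitch,
    rows = as.integer(rows), cols = as.integer(cols),
    panels = as.integer(panels), pixel_scale = pixel_scale,
    well_volume = well_volume,
    wells_per_panel = as.integer(rows) * as.integer(cols),
    wells_per_device = as.integer(rows) * as.integer(cols) * as.integer(panels)
  ), class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("Microwell array geometry: %d x %d wells/panel, %d panel(s)\n",
              x$rows, x$cols, x$panels))
  cat(sprintf("  well: %g um diameter, %g um deep; pitch %g um\n",
              x$well_diameter, x$well_depth, x$pitch))
  cat(sprintf("  pixel scale: %g um/px; well volume: %.4g uL\n",
              x$pixel_scale, x$well_volume))
  cat(sprintf("  wells per device: %d\n", x$wells_per_device))
  invisible(x)
}

#' Volume of a cylindrical microwell
#'
#' Volume of a right circular cylinder, in microliters, from its diameter and
#' depth in micrometers (1 uL = 1e9 um^3). For the default 20 um x 25 um well
#' this is `pi * 10^2 * 25` um^3 = 7.854e-6 uL.
#'
#' @param diameter Cylinder diameter in um; positive.
#' @param depth Cylinder depth in um; positive.
#' @return Volume in uL.
#' @examples
#' cylinder_volume(20, 25)
#' @export
cylinder_volume <- function(diameter, depth) {
  wc_check(is.numeric(diameter) && all(is.finite(diameter)) && all(diameter > 0),
           "wellcount_geometry_error", "diameter must be positive")
  wc_check(is.numeric(depth) && all(is.finite(depth)) && all(depth > 0),
           "wellcount_geometry_error", "depth must be positive")
  pi * (diameter / 2)^2 * depth * 1e-9
}

# Config keys <-> array_geometry fields (units fixed: um, uL).
.config_keys <- c(
  well_diameter_um = "well_diameter", well_depth_um = "well_depth",
  pitch_um = "pitch", rows = "rows", cols = "cols", panels = "panels",
  pixel_scale_um_per_px = "pixel_scale", well_volume_ul = "well_volume"
)

#' Read an array geometry from a flat key-value config file
#'
#' The config format is plain text, one `key = value` pair per line; `#`
#' starts a comment. Recognised keys: `well_diameter_um`, `well_depth_um`,
#' `pitch_um`, `rows`, `cols`, `panels`, `pixel_scale_um_per_px` and the
#' optional `well_volume_ul`. All keys except `well_volume_ul` are required.
#' When `well_volume_ul` is absent the per-well volume is computed from the
#' well diameter and depth ([cylinder_volume()]).
#'
#' @param path Path to the config file.
#' @return A validated [array_geometry()] object.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  wc_check(is.character(path) && length(path) == 1L && file.exists(path),
           "wellcount_io_error", paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  malformed <- lines[vapply(kv, length, 1L) != 2L]
  if (length(malformed))
    wc_abort("wellcount_config_error",
             paste0("malformed config line(s): ",
                    paste(malformed, collapse = "; ")))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  unknown <- setdiff(keys, names(.config_keys))
  missing <- setdiff(setdiff(names(.config_keys), "well_volume_ul"), keys)
  invalid <- keys[is.na(vals)]
  bad <- c(
    if (length(missing)) paste0("missing: ", paste(missing, collapse = ", ")),
    if (length(unknown)) paste0("unknown: ", paste(unknown, collapse = ", ")),
    if (length(invalid)) paste0("non-numeric: ", paste(invalid, collapse = ", "))
  )
  if (length(bad))
    wc_abort("wellcount_config_error",
             paste0("invalid config keys -- ", paste(bad, collapse = "; ")),
             missing = missing, unknown = unknown, invalid = invalid)
  args <- stats::setNames(as.list(vals), .config_keys[keys])
  geom <- tryCatch(do.call(array_geometry, args),
                   wellcount_geometry_error = function(e)
                     wc_abort("wellcount_config_error",
                              paste0("config values violate geometry constraints: ",
                                     conditionMessage(e))))
  geom
}

#' Write an array geometry as a flat key-value config file
#'
#' Inverse of [load_config()]: values are written at full precision so that
#' `load_config(write_config(g, path))` reproduces `g` exactly. The per-well
#' volume is always written, so an overridden volume survives the round trip.
#'
#' @param geometry An [array_geometry()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(geometry, path) {
  stopifnot(inherits(geometry, "array_geometry"))
  vals <- unlist(geometry[.config_keys])
  writeLines(paste(names(.config_keys), "=",
                   vapply(vals, format, "", digits = 17)), path)
  invisible(path)
}
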