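# Shared fixtures: everything is generated in code at test time.

# Small single-panel geometry for fast pipeline loops.
small_geom <- function(rows = 10, cols = 10)
  array_geometry(rows = rows, cols = cols, panels = 1)

# Full-size single panel, as in one device panel.
panel_geom <- function() array_geometry(panels = 1)

# Run the detection half of the pipeline on a rendered panel.
detect_panel <- function(img, geom, ...) {
  dn <- denoise(img)
  fit_grid(find_wells(dn, geom, ...), geom)
}

# Ground-truth occupancy in grid (row-major) order.
truth_occupied <- function(truth) truth$occupied[order(truth$row, truth$col)]
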