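## Per-cell cover proportions from the classified raster, by the two drone
## methods: full pixel enumeration within each cell, and virtual step-point
## transects overlaid on the classification.

## integer pixel index ranges of a cell (pixel-centre-in-cell, half-open)
cell_pixel_indices <- function(cls, cell) {
  crop_indices(cls, c(cell$xmin, cell$ymin, cell$xmax, cell$ymax))
}

#' Per-cell proportions from full pixel enumeration
#'
#' Pixel membership is by pixel centre in the cell with half-open edges
#' (west/south inclusive), so shared cell edges are never double counted.
#' `n` is the number of (non-missing) pixels in the cell.
#'
#' @param cls A `class_raster` covering all cells.
#' @param design A `survey_design`.
#' @param altitude_m Altitude tag carried into the table.
#' @return Cover table rows with `method = "drone_pixels"`.
#' @export
pixel_count_proportions <- function(cls, design, altitude_m = NA_real_) {
  stopifnot(inherits(cls, "class_raster"), inherits(design, "survey_design"))
  m <- unclass(cls)
  cells <- design$cells
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ix <- cell_pixel_indices(cls, cells[i, ])
    if (!length(ix$rows) || !length(ix$cols)) {
      stop(sprintf("cell %d contains no pixels", cells$cell_id[i]))
    }
    v <- m[ix$rows, ix$cols]
    v <- v[!is.na(v)]
    if (!length(v)) stop(sprintf("cell %d is all no-data", cells$cell_id[i]))
    cnt <- tabulate(v, nbins = 3L)
    rows[[i]] <- tibble::tibble(
      plot_id = cells$plot_id[i], cell_id = cells$cell_id[i],
      method = "drone_pixels", altitude_m = altitude_m,
      class = cover_class_names(),
      proportion = cnt / sum(cnt), n = as.integer(sum(cnt)))
  }
  cover_table(do.call(rbind, rows))
}

#' Per-cell proportions from virtual step-point transects
#'
#' The design's diagonal transects are overlaid on the classified raster and
#' the class is read every `spacing_m` metres — the drone analogue of the
#' field protocol. `n` is the total point count over both transects
#' (2 x 71 = 142 at 1 m spacing).
#'
#' @inheritParams pixel_count_proportions
#' @param spacing_m Sampling interval along the transects, metres.
#' @return Cover table rows with `method = "drone_transects"`.
#' @export
virtual_transect_proportions <- function(cls, design, spacing_m = 1,
                                         altitude_m = NA_real_) {
  stopifnot(inherits(cls, "class_raster"), inherits(design, "survey_design"))
  pts <- transect_sample_points(design, spacing_m)
  lab <- extract_at_points(cls, pts$x, pts$y)
  tab <- proportions_from_labels(pts$cell_id, pts$plot_id, lab,
                                 method = "drone_transects",
                                 altitude_m = altitude_m)
  cover_table(tab)
}

#' Study-wide class proportions over all plots
#'
#' Pooled over every cell pixel (the n-weighted mean of the per-cell pixel
#' proportions), as conventionally reported for the whole study area.
#'
#' @inheritParams pixel_count_proportions
#' @return Named numeric length 3 summing to 1.
#' @export
study_area_proportions <- function(cls, design) {
  tab <- pixel_count_proportions(cls, design)
  cnt <- tapply(tab$proportion * tab$n, tab$class, sum)
  p <- cnt / sum(cnt)
  stats::setNames(as.numeric(p[cover_class_names()]), cover_class_names())
}
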