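## Survey geometry: study plots, the 50 x 50 m cell grid, diagonal step-point
## transects, and the linear altitude -> ground-sampling-distance model.

CELL_SIDE_M <- 50

#' Construct a survey design from per-plot cell layouts
#'
#' Plots are axis-aligned rectangles of adjacent 50 x 50 m cells, laid out
#' side by side (west to east) with a shared southern edge at y = 0. Each cell
#' carries two diagonal transects: NW->SE and NE->SW.
#'
#' @param plot_cells Integer matrix-like list: for each plot, `c(ncol, nrow)`
#'   of cells. The default partitions 92 cells into 5 plots.
#' @return A `survey_design` list with tibbles `plots`, `cells`, `transects`.
#' @export
survey_design <- function(plot_cells = list(c(6, 4), c(5, 4), c(5, 4),
                                            c(4, 4), c(4, 3))) {
  stopifnot(length(plot_cells) >= 1)
  x0 <- 0
  plots <- cells <- transects <- list()
  cell_counter <- 0L
  for (p in seq_along(plot_cells)) {
    ncx <- plot_cells[[p]][1]; ncy <- plot_cells[[p]][2]
    stopifnot(ncx >= 1, ncy >= 1)
    w <- ncx * CELL_SIDE_M; h <- ncy * CELL_SIDE_M
    plots[[p]] <- tibble::tibble(plot_id = p, xmin = x0, ymin = 0,
                                 xmax = x0 + w, ymax = h)
    for (iy in seq_len(ncy)) {
      for (ix in seq_len(ncx)) {
        cell_counter <- cell_counter + 1L
        cx0 <- x0 + (ix - 1) * CELL_SIDE_M
        cy0 <- (iy - 1) * CELL_SIDE_M
        cells[[cell_counter]] <- tibble::tibble(
          plot_id = p, cell_id = cell_counter,
          xmin = cx0, ymin = cy0,
          xmax = cx0 + CELL_SIDE_M, ymax = cy0 + CELL_SIDE_M)
        # transect 1: NW -> SE corner; transect 2: NE -> SW corner
        transects[[length(transects) + 1L]] <- tibble::tibble(
          plot_id = p, cell_id = cell_counter, transect = c(1L, 2L),
          x_start = c(cx0, cx0 + CELL_SIDE_M),
          y_start = c(cy0 + CELL_SIDE_M, cy0 + CELL_SIDE_M),
          x_end = c(cx0 + CELL_SIDE_M, cx0),
          y_end = c(cy0, cy0))
      }
    }
    x0 <- x0 + w
  }
  out <- list(plots = do.call(rbind, plots),
              cells = do.call(rbind, cells),
              transects = do.call(rbind, transects),
              cell_side_m = CELL_SIDE_M)
  class(out) <- "survey_design"
  out
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf("<survey_design> %d plots, %d cells of %g x %g m, %d transects\n",
              nrow(x$plots), nrow(x$cells), x$cell_side_m, x$cell_side_m,
              nrow(x$transects)))
  invisible(x)
}

#' The default 92-cell, 5-plot study design
#'
#' 92 adjacent 50 x 50 m cells (23 ha total) in five rectangular plots with
#' cell counts 24/20/20/16/12. Per-plot shapes are configurable through
#' [survey_design()]; the totals are what the downstream analysis uses.
#'
#' @param plot_cells Optional alternative per-plot layout; must still contain
#'   92 cells in total.
#' @return A `survey_design`.
#' @export
default_design <- function(plot_cells = NULL) {
  d <- if (is.null(plot_cells)) survey_design() else survey_design(plot_cells)
  if (nrow(d$cells) != 92L) {
    stop(sprintf("default design must contain 92 cells, got %d", nrow(d$cells)))
  }
  d
}

#' Total surveyed area of a design, in hectares
#' @param design A `survey_design`.
#' @return Numeric, hectares.
#' @export
design_area_ha <- function(design) {
  nrow(design$cells) * design$cell_side_m^2 / 1e4
}

#' Linear altitude to ground-sampling-distance model
#'
#' GSD scales linearly with flight altitude for a fixed camera:
#' `gsd_m = k * altitude_m`.
#'
#' @param k Metres of GSD per metre of altitude.
#' @return A `gsd_model`.
#' @export
gsd_model <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1, k > 0)
  structure(list(k = k), class = "gsd_model")
}

#' Calibrate a GSD model from one altitude/GSD pair
#'
#' @param altitude_m Calibration altitude (m).
#' @param gsd_cm Observed GSD at that altitude (cm).
#' @return A `gsd_model`. The default pair (100 m, 3.2 cm) matches the study
#'   camera; `gsd_at_altitude` then gives 2.4 cm at 75 m and 3.8 cm at 120 m.
#' @export
calibrate_gsd <- function(altitude_m = 100, gsd_cm = 3.2) {
  stopifnot(altitude_m > 0, gsd_cm > 0)
  gsd_model(gsd_cm / 100 / altitude_m)
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' GSD at a flight altitude
#'
#' @param model A `gsd_model`.
#' @param altitude_m Positive altitude(s) in metres.
#' @return Tibble with `altitude_m`, `gsd_cm` (exact) and `gsd_cm_rounded`
#'   (half-away-from-zero to 1 decimal, as conventionally reported).
#' @export
gsd_at_altitude <- function(model, altitude_m) {
  stopifnot(inherits(model, "gsd_model"))
  if (any(altitude_m <= 0)) stop("altitude must be positive")
  gsd_cm <- model$k * altitude_m * 100
  tibble::tibble(altitude_m = altitude_m, gsd_cm = gsd_cm,
                 gsd_cm_rounded = round_half_up(gsd_cm, 1))
}

#' Sample points along every transect of a design
#'
#' Points are placed at arc length 0, s, 2s, ... from the start corner of each
#' diagonal; the far corner is included only when the transect length is an
#' exact multiple of the spacing.
#'
#' @param design A `survey_design`.
#' @param spacing_m Point spacing along the transect, metres.
#' @return Tibble with `plot_id`, `cell_id`, `transect`, `position_m`, `x`, `y`.
#' @export
transect_sample_points <- function(design, spacing_m = 1) {
  stopifnot(inherits(design, "survey_design"), spacing_m > 0)
  tr <- design$transects
  L <- sqrt((tr$x_end - tr$x_start)^2 + (tr$y_end - tr$y_start)^2)
  npts <- floor(L / spacing_m + 1e-9) + 1L
  idx <- rep(seq_len(nrow(tr)), npts)
  pos <- unlist(lapply(npts, function(n) (seq_len(n) - 1) * spacing_m),
                use.names = FALSE)
  frac <- pos / L[idx]
  tibble::tibble(
    plot_id = tr$plot_id[idx],
    cell_id = tr$cell_id[idx],
    transect = tr$transect[idx],
    position_m = pos,
    x = tr$x_start[idx] + frac * (tr$x_end[idx] - tr$x_start[idx]),
    y = tr$y_start[idx] + frac * (tr$y_end[idx] - tr$y_start[idx]))
}

#' Export the cell polygons of a design as GeoJSON
#'
#' @param design A `survey_design`.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
design_to_geojson <- function(design, path) {
  feats <- lapply(seq_len(nrow(design$cells)), function(i) {
    cl <- design$cells[i, ]
    ring <- list(c(cl$xmin, cl$ymin), c(cl$xmax, cl$ymin),
                 c(cl$xmax, cl$ymax), c(cl$xmin, cl$ymax),
                 c(cl$xmin, cl$ymin))
    list(type = "Feature",
         properties = list(plot_id = cl$plot_id, cell_id = cl$cell_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a survey design as a flat text config
#'
#' @param design A `survey_design`.
#' @param path File path.
#' @return `path` (write) or a `survey_design` (read).
#' @export
write_design <- function(design, path) {
  ncx <- (design$plots$xmax - design$plots$xmin) / design$cell_side_m
  ncy <- (design$plots$ymax - design$plots$ymin) / design$cell_side_m
  writeLines(c(sprintf("cell_side_m=%g", design$cell_side_m),
               sprintf("plot%d=%d,%d", seq_len(nrow(design$plots)), ncx, ncy)),
             path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  pv <- vals[grepl("^plot", keys)]
  layout <- lapply(strsplit(pv, ","), as.integer)
  survey_design(layout)
}
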