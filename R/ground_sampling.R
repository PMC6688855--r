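## Simulated field crew: step-point records along the diagonal transects of
## each cell, read off the true class map, with an optional uniform observer
## misclassification rate.

#' Walk the step-point transects over a true class map
#'
#' Every sample point (spacing `spacing_m` along each diagonal, start corner
#' included) records the class of the truth pixel under foot. With probability
#' `misclass_rate` the recorded class is replaced by one of the other two
#' classes uniformly at random (observer error).
#'
#' @param truth A `class_raster` covering the design extent.
#' @param design A `survey_design`.
#' @param spacing_m Step spacing in metres (default 1, the field protocol).
#' @param misclass_rate Observer error probability in `[0, 1)`.
#' @param seed Integer seed for the observer-error draws.
#' @return Tibble of step-point records: `plot_id`, `cell_id`, `transect`,
#'   `position_m`, `class` (integer label), `class_name`.
#' @export
walk_transects <- function(truth, design, spacing_m = 1,
                           misclass_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "class_raster"), inherits(design, "survey_design"),
            misclass_rate >= 0, misclass_rate < 1)
  pts <- transect_sample_points(design, spacing_m)
  cls <- extract_at_points(truth, pts$x, pts$y)
  if (anyNA(cls)) stop("step point fell on a no-data pixel")
  if (misclass_rate > 0) {
    set.seed(seed)
    flip <- runif(nrow(pts)) < misclass_rate
    if (any(flip)) {
      # replace by one of the other two classes, uniformly
      shift <- sample(1:2, sum(flip), replace = TRUE)
      cls[flip] <- ((cls[flip] - 1L + shift) %% 3L) + 1L
    }
  }
  tibble::tibble(plot_id = pts$plot_id, cell_id = pts$cell_id,
                 transect = pts$transect, position_m = pts$position_m,
                 class = as.integer(cls),
                 class_name = cover_class_names()[cls])
}

#' Per-cell cover proportions from step-point records
#'
#' For each cell, each class's proportion is its point count divided by the
#' cell's total point count over both transects; `n` is that total.
#'
#' @param records Output of [walk_transects()].
#' @param altitude_m Optional altitude tag carried into the table (ground
#'   records have none; default `NA`).
#' @return A cover table (see [cover_table()]) with `method = "ground"`.
#' @export
cell_proportions_from_points <- function(records, altitude_m = NA_real_) {
  stopifnot(nrow(records) >= 1)
  proportions_from_labels(records$cell_id, records$plot_id, records$class,
                          method = "ground", altitude_m = altitude_m)
}

## shared tabulation: labels -> long cover table rows
proportions_from_labels <- function(cell_id, plot_id, class, method,
                                    altitude_m = NA_real_) {
  keep <- !is.na(class)
  cell_id <- cell_id[keep]; plot_id <- plot_id[keep]; class <- class[keep]
  if (!length(class)) stop("no labelled points/pixels to tabulate")
  cells <- sort(unique(cell_id))
  plot_of <- plot_id[match(cells, cell_id)]
  cnt <- table(factor(cell_id, levels = cells),
               factor(class, levels = COVER_CLASSES))
  n <- rowSums(cnt)
  if (any(n == 0)) stop("cell with no points")
  prop <- cnt / n
  tibble::tibble(
    plot_id = rep(plot_of, each = 3L),
    cell_id = rep(cells, each = 3L),
    method = method,
    altitude_m = altitude_m,
    class = rep(cover_class_names(), times = length(cells)),
    proportion = as.vector(t(prop)),
    n = rep(as.integer(n), each = 3L))
}

#' Validate and canonicalize a cover table
#'
#' A cover table is long-form: one row per (cell, method, altitude, class)
#' with the estimated `proportion` and the count `n` of points or pixels
#' behind it. Proportions must sum to 1 within each (cell, method, altitude)
#' group and `n` must be constant within the group.
#'
#' @param x A data frame with columns `plot_id`, `cell_id`, `method`,
#'   `altitude_m`, `class`, `proportion`, `n`.
#' @return The validated tibble.
#' @export
cover_table <- function(x) {
  req <- c("plot_id", "cell_id", "method", "altitude_m", "class",
           "proportion", "n")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing cover-table columns: ",
                         paste(miss, collapse = ", "))
  if (any(x$proportion < -1e-12 | x$proportion > 1 + 1e-12)) {
    stop("proportions must lie in [0, 1]")
  }
  key <- interaction(x$cell_id, x$method, x$altitude_m, drop = TRUE)
  sums <- tapply(x$proportion, key, sum)
  if (any(abs(sums - 1) > 1e-9)) stop("per-cell proportions must sum to 1")
  nvar <- tapply(x$n, key, function(v) length(unique(v)))
  if (any(nvar != 1)) stop("n must be constant within a cell/method group")
  tibble::as_tibble(x)
}

#' Write / read a cover table as CSV
#' @param tab A cover table.
#' @param path CSV path.
#' @return `path` (write) or the validated tibble (read).
#' @export
write_cover_table <- function(tab, path) {
  write.csv(cover_table(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cover_table
#' @export
read_cover_table <- function(path) {
  cover_table(read.csv(path, stringsAsFactors = FALSE))
}
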