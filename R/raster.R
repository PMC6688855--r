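#' @useDynLib dronecover, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd cor optim optimHess dbeta plogis
#'   qlogis pf rbeta kmeans complete.cases setNames
#' @importFrom utils read.csv write.csv head tail modifyList combn capture.output
#' @importFrom tools md5sum
NULL

#' Land-cover class codes
#'
#' Integer labels used throughout the package for the three grouped
#' land-cover categories: 1 = barren, 2 = non-shrub (graminoids/forbs),
#' 3 = shrub. `NA` marks no-data.
#'
#' @format Named integer vector of length 3.
#' @export
COVER_CLASSES <- c(barren = 1L, nonshrub = 2L, shrub = 3L)

#' Names of the cover classes in label order
#' @return Character vector `c("barren", "nonshrub", "shrub")`.
#' @export
cover_class_names <- function() names(COVER_CLASSES)

## ---- raster containers ------------------------------------------------------
## A raster is a matrix (class_raster) or nrow x ncol x 3 array (rgb_raster)
## with attributes gsd (metres/pixel) and origin (SW corner, metres).
## Row 1 is the northern edge; column 1 the western edge. Pixel (r, c) covers
## x in [x0+(c-1)g, x0+cg), y in [y0+(R-r)g, y0+(R-r+1)g)  (half-open).

#' Construct a classified (label) raster
#'
#' @param m Integer matrix of class labels (row 1 = north edge).
#' @param gsd Ground sampling distance in metres per pixel.
#' @param origin Numeric length-2, (x, y) of the raster's south-west corner
#'   in planar metres.
#' @return A `class_raster` object.
#' @export
class_raster <- function(m, gsd, origin = c(0, 0)) {
  stopifnot(is.matrix(m), gsd > 0, length(origin) == 2)
  storage.mode(m) <- "integer"
  structure(m, gsd = gsd, origin = as.numeric(origin), class = "class_raster")
}

#' Construct an RGB raster
#'
#' @param a Numeric array `nrow x ncol x 3`, values in 0–255
#'   (row 1 = north edge).
#' @inheritParams class_raster
#' @return An `rgb_raster` object.
#' @export
rgb_raster <- function(a, gsd, origin = c(0, 0)) {
  stopifnot(is.array(a), length(dim(a)) == 3, dim(a)[3] == 3, gsd > 0)
  structure(a, gsd = gsd, origin = as.numeric(origin), class = "rgb_raster")
}

#' @export
print.class_raster <- function(x, ...) {
  cat(sprintf("<class_raster> %d x %d px, gsd %.4g m, origin (%g, %g)\n",
              nrow(x), ncol(x), attr(x, "gsd"),
              attr(x, "origin")[1], attr(x, "origin")[2]))
  tab <- table(factor(x[!is.na(x)], levels = COVER_CLASSES,
                      labels = cover_class_names()))
  print(round(tab / max(1, sum(tab)), 4))
  invisible(x)
}

#' @export
print.rgb_raster <- function(x, ...) {
  cat(sprintf("<rgb_raster> %d x %d px x 3 bands, gsd %.4g m, origin (%g, %g)\n",
              dim(x)[1], dim(x)[2], attr(x, "gsd"),
              attr(x, "origin")[1], attr(x, "origin")[2]))
  invisible(x)
}

raster_gsd <- function(x) attr(x, "gsd")
raster_origin <- function(x) attr(x, "origin")
raster_dim <- function(x) dim(x)[1:2]

same_geometry <- function(a, b) {
  isTRUE(all.equal(raster_gsd(a), raster_gsd(b))) &&
    isTRUE(all.equal(raster_origin(a), raster_origin(b))) &&
    all(raster_dim(a) == raster_dim(b))
}

#' Map planar points to pixel indices
#'
#' Half-open pixel intervals: a point on a pixel's west/south edge belongs to
#' that pixel. Points exactly on the raster's east/north outer boundary are
#' assigned to the last pixel so that cell-corner sample points remain valid.
#'
#' @param raster A `class_raster` or `rgb_raster`.
#' @param x,y Point coordinates in metres.
#' @return List with integer vectors `row`, `col` (1-based).
#' @export
point_to_pixel <- function(raster, x, y) {
  g <- raster_gsd(raster); o <- raster_origin(raster)
  nr <- raster_dim(raster)[1]; nc <- raster_dim(raster)[2]
  col <- floor((x - o[1]) / g) + 1L
  rowy <- floor((y - o[2]) / g)        # 0 at south edge
  row <- nr - as.integer(rowy)
  # close the outer east/north boundary
  col[x == o[1] + nc * g] <- nc
  row[y == o[2] + nr * g] <- 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  if (any(bad)) {
    stop(sprintf("%d point(s) fall outside the raster extent", sum(bad)))
  }
  list(row = as.integer(row), col = as.integer(col))
}

#' Read raster values at planar points
#'
#' @inheritParams point_to_pixel
#' @return Integer vector of class labels (for `class_raster`).
#' @export
extract_at_points <- function(raster, x, y) {
  ix <- point_to_pixel(raster, x, y)
  raster[cbind(ix$row, ix$col)]
}

#' Nearest-neighbour resampling of a classified raster
#'
#' Resamples to a new ground sampling distance over the same extent; each
#' output pixel takes the label of the input pixel containing its centre.
#'
#' @param truth A `class_raster`.
#' @param gsd_out Target ground sampling distance, metres.
#' @return A `class_raster` at `gsd_out`.
#' @export
resample_nn <- function(truth, gsd_out) {
  stopifnot(inherits(truth, "class_raster"), gsd_out > 0)
  g <- raster_gsd(truth)
  if (isTRUE(all.equal(g, gsd_out))) return(truth)
  o <- raster_origin(truth)
  nr <- nrow(truth); nc <- ncol(truth)
  wx <- nc * g; wy <- nr * g
  # cover the full source extent (edge pixels clamp to the nearest source px)
  nc2 <- max(1L, ceiling(wx / gsd_out - 1e-9))
  nr2 <- max(1L, ceiling(wy / gsd_out - 1e-9))
  # centres of output pixels in source pixel indices
  xc <- (seq_len(nc2) - 0.5) * gsd_out
  yc <- (nr2 - seq_len(nr2) + 0.5) * gsd_out  # from the output top row down
  sc <- pmin(nc, floor(xc / g) + 1L)
  sr <- pmin(nr, pmax(1L, nr - floor(yc / g)))
  m <- truth[sr, sc, drop = FALSE]
  class_raster(m, gsd_out, o)
}

## ---- raster I/O -------------------------------------------------------------

#' Write a raster as TIFF with a plain-text world file
#'
#' The image is written as an 8-bit TIFF; georeferencing (ground sampling
#' distance and origin) goes to an ESRI world file (`.tfw`) next to it.
#'
#' @param raster A `class_raster` or `rgb_raster`.
#' @param path Output path ending in `.tif`.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(raster, path) {
  g <- raster_gsd(raster); o <- raster_origin(raster)
  nr <- raster_dim(raster)[1]
  if (inherits(raster, "class_raster")) {
    m <- unclass(raster)
    m[is.na(m)] <- 255L
    img <- m / 255
  } else {
    img <- unclass(raster) / 255
  }
  tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "none")
  # world file: pixel size, rotation, centre of upper-left pixel
  tfw <- sub("\\.tiff?$", ".tfw", path)
  ul <- c(o[1] + g / 2, o[2] + nr * g - g / 2)
  writeLines(format(c(g, 0, 0, -g, ul[1], ul[2]), digits = 15), tfw)
  invisible(path)
}

#' Read a raster written by [write_raster_tiff()]
#'
#' @param path Path to the `.tif`; the sibling `.tfw` must exist.
#' @param type `"class"` or `"rgb"`.
#' @return A `class_raster` or `rgb_raster`.
#' @export
read_raster_tiff <- function(path, type = c("class", "rgb")) {
  type <- match.arg(type)
  img <- tiff::readTIFF(path)
  tfw <- as.numeric(readLines(sub("\\.tiff?$", ".tfw", path)))
  g <- tfw[1]
  nr <- dim(img)[1]
  origin <- c(tfw[5] - g / 2, tfw[6] + g / 2 - nr * g)
  if (type == "class") {
    m <- round(img * 255)
    m[m == 255] <- NA
    class_raster(matrix(as.integer(m), nr, dim(img)[2]), g, origin)
  } else {
    rgb_raster(img * 255, g, origin)
  }
}
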