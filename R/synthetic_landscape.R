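## Synthetic salt-marsh landscapes: seeded Gaussian-random-field truth maps
## with prescribed barren / non-shrub / shrub proportions, rendered to 3-band
## 8-bit RGB with class spectra, dark-soil confusability and cast shadows.

#' Default class spectra for the synthetic landscape
#'
#' RGB means (0-255) for barren (pale dry sediment), non-shrub (dark graminoid
#' mat) and shrub (green canopy), plus the dark-soil barren sub-spectrum that
#' the non-shrub mean is pulled towards under confusability.
#'
#' @return List with matrix `means` (3 x 3, one row per class) and numeric
#'   `dark_soil` (length 3).
#' @export
default_spectra <- function() {
  list(means = rbind(barren = c(186, 172, 150),
                     nonshrub = c(96, 88, 62),
                     shrub = c(70, 110, 58)),
       dark_soil = c(92, 84, 70))
}

#' Scene specification for the synthetic landscape generator
#'
#' @param seed Integer seed; all randomness in the scene derives from it.
#' @param gsd_m Ground sampling distance, metres per pixel.
#' @param target_props Length-3 proportions (barren, non-shrub, shrub)
#'   summing to 1. Defaults to the study-area cover at the best-resolution
#'   altitude: 0.755 / 0.035 / 0.210.
#' @param spatial_corr_length_m Gaussian smoothing length of the underlying
#'   random field, metres (patch scale).
#' @param class_spectra As returned by [default_spectra()]; `$means` may be
#'   replaced, and an optional `$cov` (3 x 3 positive semi-definite, common to
#'   all classes) shapes the spectral scatter.
#' @param shadow_fraction Fraction of shrub-adjacent pixels (on the shadow
#'   bearing) that are darkened, in `[0, 1)`.
#' @param confusability In `[0, 1]`: 0 leaves the non-shrub spectrum at its
#'   own mean, 1 moves it onto the dark-soil barren sub-spectrum. The
#'   dark-soil sub-population of barren engages in step (see [render_rgb()]),
#'   so at 0 the classes are as separable as the spectra allow and at 1
#'   dark-soil barren and non-shrub are spectrally indistinguishable.
#' @param dark_soil_fraction Fraction of barren pixels belonging to the
#'   dark-soil sub-population.
#' @param noise_sd Per-band spectral noise SD (8-bit counts).
#' @return A `scene_spec`.
#' @export
scene_spec <- function(seed = 1L,
                       gsd_m = 0.10,
                       target_props = c(0.755, 0.035, 0.210),
                       spatial_corr_length_m = 4,
                       class_spectra = default_spectra(),
                       shadow_fraction = 0.08,
                       confusability = 0.6,
                       dark_soil_fraction = 0.2,
                       noise_sd = 12) {
  stopifnot(gsd_m > 0, length(target_props) == 3, all(target_props >= 0),
            abs(sum(target_props) - 1) < 1e-9,
            spatial_corr_length_m > 0,
            shadow_fraction >= 0, shadow_fraction < 1,
            confusability >= 0, confusability <= 1,
            dark_soil_fraction >= 0, dark_soil_fraction <= 1, noise_sd >= 0)
  if (!is.null(class_spectra$cov)) {
    ev <- eigen(class_spectra$cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("class spectral covariance must be positive semi-definite")
  }
  structure(list(seed = as.integer(seed), gsd_m = gsd_m,
                 target_props = target_props,
                 spatial_corr_length_m = spatial_corr_length_m,
                 class_spectra = class_spectra,
                 shadow_fraction = shadow_fraction,
                 confusability = confusability,
                 dark_soil_fraction = dark_soil_fraction,
                 noise_sd = noise_sd),
            class = "scene_spec")
}

#' Write / read a scene spec as a flat key-value file
#' @param spec A `scene_spec`.
#' @param path File path.
#' @return `path` (write) or a `scene_spec` (read).
#' @export
write_scene_spec <- function(spec, path) {
  num <- function(x) paste(format(x, digits = 15), collapse = ",")
  writeLines(c(
    sprintf("seed=%d", spec$seed),
    sprintf("gsd_m=%s", num(spec$gsd_m)),
    sprintf("target_props=%s", num(spec$target_props)),
    sprintf("spatial_corr_length_m=%s", num(spec$spatial_corr_length_m)),
    sprintf("shadow_fraction=%s", num(spec$shadow_fraction)),
    sprintf("confusability=%s", num(spec$confusability)),
    sprintf("dark_soil_fraction=%s", num(spec$dark_soil_fraction)),
    sprintf("noise_sd=%s", num(spec$noise_sd)),
    sprintf("spectra_means=%s", num(as.vector(spec$class_spectra$means))),
    sprintf("spectra_dark_soil=%s", num(spec$class_spectra$dark_soil))),
    path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  kv <- read_flat_config(path)
  sp <- default_spectra()
  sp$means[] <- kv_num(kv, "spectra_means")
  sp$dark_soil <- kv_num(kv, "spectra_dark_soil")
  scene_spec(seed = as.integer(kv_num(kv, "seed")),
             gsd_m = kv_num(kv, "gsd_m"),
             target_props = kv_num(kv, "target_props"),
             spatial_corr_length_m = kv_num(kv, "spatial_corr_length_m"),
             class_spectra = sp,
             shadow_fraction = kv_num(kv, "shadow_fraction"),
             confusability = kv_num(kv, "confusability"),
             dark_soil_fraction = kv_num(kv, "dark_soil_fraction"),
             noise_sd = kv_num(kv, "noise_sd"))
}

read_flat_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) paste(p[-1], collapse = "="), ""),
                  vapply(kv, `[`, "", 1))
}
kv_num <- function(kv, key) as.numeric(strsplit(kv[[key]], ",")[[1]])

## Gaussian smoothing of white noise by FFT (circular convolution); the
## kernel SD equals the correlation length in pixels.
smooth_field <- function(z, sigma_px) {
  nr <- nrow(z); nc <- ncol(z)
  kx <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  ky <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  # Fourier transform of a Gaussian kernel, separable
  gx <- exp(-2 * pi^2 * sigma_px^2 * kx^2)
  gy <- exp(-2 * pi^2 * sigma_px^2 * ky^2)
  K <- outer(gx, gy)
  Re(stats::fft(stats::fft(z) * K, inverse = TRUE)) / (nr * nc)
}

#' Generate a true class map by thresholding a smoothed random field
#'
#' White noise is smoothed with a Gaussian kernel whose SD equals
#' `spatial_corr_length_m`, then cut at the empirical quantiles of the field
#' so the realized per-class pixel proportions track `target_props` closely
#' (ties aside, to within 1/n_pixels). Classes are assigned to quantile bins
#' in label order, so non-shrub forms transition bands between barren lows
#' and shrub highs.
#'
#' @param spec A `scene_spec`.
#' @param extent Numeric `c(xmin, ymin, xmax, ymax)` in metres, or a
#'   `survey_design` (its bounding box is used).
#' @return A `class_raster` of labels in `COVER_CLASSES`.
#' @export
generate_truth_map <- function(spec, extent) {
  stopifnot(inherits(spec, "scene_spec"))
  if (inherits(extent, "survey_design")) {
    extent <- c(min(extent$plots$xmin), min(extent$plots$ymin),
                max(extent$plots$xmax), max(extent$plots$ymax))
  }
  stopifnot(length(extent) == 4, extent[3] > extent[1], extent[4] > extent[2])
  if (spec$spatial_corr_length_m < 2 * spec$gsd_m) {
    stop("spatial_corr_length_m must be at least 2 * gsd_m")
  }
  g <- spec$gsd_m
  nc <- max(1L, round((extent[3] - extent[1]) / g))
  nr <- max(1L, round((extent[4] - extent[2]) / g))
  if (nr * nc < 1) stop("degenerate extent: zero pixels")
  set.seed(spec$seed)
  z <- matrix(rnorm(nr * nc), nr, nc)
  f <- smooth_field(z, spec$spatial_corr_length_m / g)
  p <- spec$target_props
  qs <- quantile(f, probs = cumsum(p)[1:2], names = FALSE, type = 7)
  m <- matrix(1L, nr, nc)
  m[f > qs[1]] <- 2L
  m[f > qs[2]] <- 3L
  # absent classes: a zero-width quantile bin may still catch ties; enforce
  if (p[2] == 0) m[m == 2L] <- 1L
  if (p[3] == 0) m[m == 3L] <- if (p[2] > 0) 2L else 1L
  if (p[1] == 0) m[m == 1L] <- if (p[2] > 0) 2L else 3L
  class_raster(m, g, extent[1:2])
}

## shadow-bearing offset: shadows fall one pixel to the SE of shrub canopy
SHADOW_OFFSET <- c(1L, 1L)   # (row down, col right)
SHADOW_DIM_FACTOR <- 0.45

shrub_adjacent_mask <- function(truth) {
  m <- unclass(truth)
  nr <- nrow(m); nc <- ncol(m)
  sh <- !is.na(m) & m == COVER_CLASSES[["shrub"]]
  adj <- matrix(FALSE, nr, nc)
  dr <- SHADOW_OFFSET[1]; dc <- SHADOW_OFFSET[2]
  adj[(1 + dr):nr, (1 + dc):nc] <- sh[1:(nr - dr), 1:(nc - dc)]
  adj & !sh
}

#' Render a true class map to 8-bit RGB
#'
#' Each pixel draws its class's spectral distribution: class mean plus
#' correlated noise (`noise_sd` scaling the Cholesky factor of the spectral
#' covariance, identity by default). With confusability `c` the non-shrub mean
#' is moved fraction `c` of the way to the dark-soil barren sub-spectrum, and
#' a seeded `dark_soil_fraction` of barren pixels is rendered at the matching
#' sub-spectrum mean `(1-c) * barren + c * dark_soil`; at `c = 0` barren is
#' spectrally uniform, at `c = 1` dark-soil barren and non-shrub coincide.
#' A seeded shadow mask (fraction `shadow_fraction` of pixels immediately
#' south-east of shrub canopy) multiplies intensity by 0.45. Values are
#' clipped to 0-255.
#'
#' @param truth A `class_raster`.
#' @param spec The `scene_spec` (its `seed` also drives rendering noise).
#' @return An `rgb_raster`; the logical shadow mask is attached as attribute
#'   `"shadow_mask"` and the shrub-adjacent candidate mask as
#'   `"shadow_candidates"`.
#' @export
render_rgb <- function(truth, spec) {
  stopifnot(inherits(truth, "class_raster"), inherits(spec, "scene_spec"))
  m <- unclass(truth)
  nr <- nrow(m); nc <- ncol(m)
  if (nr * nc == 0) stop("empty truth raster")
  cf <- spec$confusability
  mu <- spec$class_spectra$means
  ds <- spec$class_spectra$dark_soil
  mu["nonshrub", ] <- (1 - cf) * mu["nonshrub", ] + cf * ds
  set.seed(spec$seed + 1L)
  idx <- as.vector(m)
  rgbv <- mu[idx, , drop = FALSE]
  # dark-soil sub-population of barren, engaging with confusability
  if (spec$dark_soil_fraction > 0 && cf > 0) {
    bar <- which(idx == COVER_CLASSES[["barren"]])
    if (length(bar)) {
      dark <- bar[runif(length(bar)) < spec$dark_soil_fraction]
      mu_dark <- (1 - cf) * spec$class_spectra$means["barren", ] + cf * ds
      rgbv[dark, ] <- rep(mu_dark, each = length(dark))
    }
  }
  if (spec$noise_sd > 0) {
    z <- matrix(rnorm(3 * nr * nc), ncol = 3)
    if (!is.null(spec$class_spectra$cov)) {
      L <- chol(spec$class_spectra$cov + diag(1e-10, 3))
      z <- z %*% L
    }
    rgbv <- rgbv + spec$noise_sd * z
  }
  cand <- shrub_adjacent_mask(truth)
  shadow <- matrix(FALSE, nr, nc)
  if (spec$shadow_fraction > 0 && any(cand)) {
    pick <- runif(sum(cand)) < spec$shadow_fraction
    shadow[cand] <- pick
  }
  dim(rgbv) <- c(nr * nc, 3)
  rgbv[as.vector(shadow), ] <- rgbv[as.vector(shadow), ] * SHADOW_DIM_FACTOR
  rgbv <- pmin(255, pmax(0, rgbv))
  a <- array(rgbv, dim = c(nr, nc, 3))
  out <- rgb_raster(a, raster_gsd(truth), raster_origin(truth))
  attr(out, "shadow_mask") <- shadow
  attr(out, "shadow_candidates") <- cand
  out
}

#' Simulate the multi-altitude drone study over one landscape
#'
#' One truth map is generated at the finest altitude's GSD and resampled by
#' nearest neighbour to each altitude's GSD (same seed, same underlying
#' landscape), then rendered to RGB per altitude.
#'
#' @param spec A `scene_spec`; `spec$gsd_m` is overridden per altitude by the
#'   GSD model.
#' @param design A `survey_design` giving the extent.
#' @param altitudes_m Positive flight altitudes, metres.
#' @param gsd_mod A `gsd_model`; default calibrated so 75 m flies at the
#'   spec's native `gsd_m`.
#' @return Named list (one element per altitude) of `synthetic_scene` lists
#'   with `rgb`, `truth`, `spec`, `altitude_m`, `gsd_m`.
#' @export
simulate_study <- function(spec, design, altitudes_m = c(75, 100, 120),
                           gsd_mod = NULL) {
  stopifnot(inherits(spec, "scene_spec"), inherits(design, "survey_design"))
  if (any(altitudes_m <= 0)) stop("altitudes must be positive")
  if (is.null(gsd_mod)) gsd_mod <- gsd_model(spec$gsd_m / min(altitudes_m))
  gsds <- gsd_at_altitude(gsd_mod, altitudes_m)$gsd_cm / 100
  native <- spec
  native$gsd_m <- min(c(gsds, spec$gsd_m))
  truth0 <- generate_truth_map(native, design)
  out <- lapply(seq_along(altitudes_m), function(i) {
    tr <- resample_nn(truth0, gsds[i])
    sp <- spec; sp$gsd_m <- gsds[i]
    rgb <- render_rgb(tr, sp)
    structure(list(rgb = rgb, truth = tr, spec = sp,
                   altitude_m = altitudes_m[i], gsd_m = gsds[i]),
              class = "synthetic_scene")
  })
  names(out) <- paste0("alt_", altitudes_m)
  out
}

#' Realized class proportions of a class raster
#' @param truth A `class_raster`.
#' @return Named numeric length 3 (barren, nonshrub, shrub), summing to 1
#'   over non-missing pixels.
#' @export
class_proportions <- function(truth) {
  v <- unclass(truth)[!is.na(unclass(truth))]
  tab <- tabulate(v, nbins = 3L)
  stats::setNames(tab / sum(tab), cover_class_names())
}
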