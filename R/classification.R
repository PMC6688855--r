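## Unsupervised spectral classification: Lloyd's k-means on raw RGB values
## with k-means++ seeding (default K = 30), then reclassification of clusters
## into the three grouped land-cover categories.

#' Fit a K-cluster spectral model to an RGB raster
#'
#' Lloyd iterations from k-means++ seeding on the pixels' raw RGB values.
#' For large mosaics the centroids are fitted on a seeded random subsample
#' (`max_fit_pixels`); full-raster labels always come from nearest-centroid
#' assignment of every pixel.
#'
#' @param rgb An `rgb_raster`.
#' @param K Number of spectral clusters (default 30).
#' @param seed Integer seed (k-means++ and subsampling).
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Relative change in the within-cluster sum of squares at which
#'   iteration stops.
#' @param max_fit_pixels Subsample cap for the fitting stage.
#' @return A `cluster_model` with `centers` (K x 3), the `objective` trace
#'   (within-cluster sum of squares per iteration, non-increasing), `K`,
#'   `seed`, and `iterations`.
#' @export
fit_clusters <- function(rgb, K = 30L, seed = 1L, max_iter = 100L,
                         tol = 1e-4, max_fit_pixels = 200000L) {
  stopifnot(inherits(rgb, "rgb_raster"), K >= 1, K <= 255)
  np <- prod(raster_dim(rgb))
  if (np == 0) stop("empty raster")
  X <- matrix(as.numeric(rgb), ncol = 3)
  set.seed(seed)
  if (nrow(X) > max_fit_pixels) {
    X <- X[sample.int(nrow(X), max_fit_pixels), , drop = FALSE]
  }
  Xd <- unique(X)
  if (nrow(Xd) < K) {
    warning(sprintf("only %d distinct colours; reducing K from %d",
                    nrow(Xd), K))
    K <- nrow(Xd)
  }
  centers <- kmeanspp_init(X, K)
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    lab <- nn_assign_cpp(X, centers)
    obj <- c(obj, sum((X - centers[lab, , drop = FALSE])^2))
    sums <- rowsum(X, lab)
    cnt <- tabulate(lab, nbins = K)
    filled <- cnt > 0
    centers[filled, ] <- sums[, , drop = FALSE] / cnt[filled]
    if (it > 1 && (obj[it - 1] - obj[it]) <= tol * obj[it - 1]) break
  }
  structure(list(centers = centers, K = K, seed = as.integer(seed),
                 objective = obj, iterations = length(obj)),
            class = "cluster_model")
}

## k-means++ seeding: first centre uniform, then proportional to squared
## distance from the nearest chosen centre.
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (k in seq_len(K)[-1]) {
    if (sum(d2) <= 0) {
      centers[k, ] <- X[sample.int(n, 1), ]
    } else {
      centers[k, ] <- X[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums((X - matrix(centers[k, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d, %d Lloyd iterations, WCSS %.4g\n",
              x$K, x$iterations, tail(x$objective, 1)))
  invisible(x)
}

#' Assign every pixel of a raster to its nearest cluster
#'
#' @param model A `cluster_model`.
#' @param rgb An `rgb_raster`.
#' @param chunk_px Pixels per assignment chunk (memory control).
#' @return Integer matrix of cluster ids (1..K) with the raster's geometry.
#' @export
predict_clusters <- function(model, rgb, chunk_px = 2000000L) {
  stopifnot(inherits(model, "cluster_model"), inherits(rgb, "rgb_raster"))
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  np <- nr * nc
  a <- unclass(rgb)
  lab <- integer(np)
  start <- 1L
  while (start <= np) {
    end <- min(np, start + chunk_px - 1L)
    idx <- start:end
    X <- cbind(as.numeric(a[idx]), as.numeric(a[np + idx]),
               as.numeric(a[2L * np + idx]))
    lab[idx] <- nn_assign_cpp(X, model$centers)
    start <- end + 1L
  }
  matrix(lab, nr, nc)
}

#' Reclassify spectral clusters into the three land-cover categories
#'
#' Automatic mode (the stand-in for analyst inspection): each cluster maps to
#' the grouped class holding the plurality of reference pixels among the
#' cluster's members; ties break by the fixed priority barren > shrub >
#' non-shrub. Manual mode applies a user-supplied map verbatim. Empty clusters
#' map to barren with a warning.
#'
#' @param model A `cluster_model`.
#' @param rgb The `rgb_raster` the model is applied to.
#' @param reference A `class_raster` aligned with `rgb` (automatic mode), or
#'   `NULL` when `reclass_map` is given.
#' @param reclass_map Optional integer vector of length K mapping cluster id
#'   to class label (manual mode).
#' @return A `class_raster`; the cluster->class map is attached as attribute
#'   `"reclass_map"`.
#' @export
reclassify_clusters <- function(model, rgb, reference = NULL,
                                reclass_map = NULL) {
  stopifnot(inherits(model, "cluster_model"), inherits(rgb, "rgb_raster"))
  cl <- predict_clusters(model, rgb)
  K <- model$K
  if (is.null(reclass_map)) {
    if (is.null(reference)) stop("automatic mode needs a reference raster")
    if (!same_geometry(rgb, reference)) {
      stop("reference raster is not aligned with the RGB raster")
    }
    ref <- as.vector(unclass(reference))
    ok <- !is.na(ref)
    counts <- table(factor(cl[ok], levels = seq_len(K)),
                    factor(ref[ok], levels = COVER_CLASSES))
    # plurality with tie priority barren (1) > shrub (3) > non-shrub (2)
    prio <- c(1L, 3L, 2L)
    reclass_map <- apply(counts, 1, function(r) {
      if (sum(r) == 0) return(NA_integer_)
      prio[which.max(r[prio])]
    })
    if (anyNA(reclass_map)) {
      warning(sprintf("%d empty cluster(s) mapped to barren",
                      sum(is.na(reclass_map))))
      reclass_map[is.na(reclass_map)] <- COVER_CLASSES[["barren"]]
    }
  } else {
    if (length(reclass_map) != K) stop("reclass_map must have length K")
    if (!all(reclass_map %in% COVER_CLASSES)) {
      stop("reclass_map must use the 3 class labels")
    }
  }
  out <- matrix(as.integer(reclass_map)[cl], nrow(cl), ncol(cl))
  res <- class_raster(out, raster_gsd(rgb), raster_origin(rgb))
  attr(res, "reclass_map") <- as.integer(reclass_map)
  res
}

#' Classify an RGB mosaic into the three cover categories
#'
#' Convenience wrapper: fit clusters, assign all pixels, reclassify against
#' the reference. When `design` is given, each plot is classified with its own
#' cluster model (the pipeline default, absorbing plot-to-plot differences in
#' light conditions); pixels outside every plot become no-data.
#'
#' @inheritParams fit_clusters
#' @param reference Aligned `class_raster` used for cluster reclassification.
#' @param design Optional `survey_design` for per-plot models.
#' @return A `class_raster`.
#' @export
classify_raster <- function(rgb, reference, K = 30L, seed = 1L,
                            design = NULL, max_iter = 100L, tol = 1e-4,
                            max_fit_pixels = 200000L) {
  if (is.null(design)) {
    model <- fit_clusters(rgb, K = K, seed = seed, max_iter = max_iter,
                          tol = tol, max_fit_pixels = max_fit_pixels)
    return(reclassify_clusters(model, rgb, reference))
  }
  g <- raster_gsd(rgb); o <- raster_origin(rgb)
  out <- matrix(NA_integer_, dim(rgb)[1], dim(rgb)[2])
  for (p in seq_len(nrow(design$plots))) {
    pl <- design$plots[p, ]
    sub <- crop_indices(rgb, c(pl$xmin, pl$ymin, pl$xmax, pl$ymax))
    rgb_p <- rgb_raster(unclass(rgb)[sub$rows, sub$cols, , drop = FALSE], g,
                        c(o[1] + (sub$cols[1] - 1) * g,
                          o[2] + (dim(rgb)[1] - sub$rows[length(sub$rows)]) * g))
    ref_p <- class_raster(unclass(reference)[sub$rows, sub$cols, drop = FALSE],
                          g, raster_origin(rgb_p))
    model <- fit_clusters(rgb_p, K = K, seed = seed + p, max_iter = max_iter,
                          tol = tol, max_fit_pixels = max_fit_pixels)
    cls_p <- reclassify_clusters(model, rgb_p, ref_p)
    out[sub$rows, sub$cols] <- unclass(cls_p)
  }
  class_raster(out, g, o)
}

## pixel index ranges whose centres fall inside an extent (half-open)
crop_indices <- function(raster, extent) {
  g <- raster_gsd(raster); o <- raster_origin(raster)
  nr <- raster_dim(raster)[1]; nc <- raster_dim(raster)[2]
  xc <- o[1] + (seq_len(nc) - 0.5) * g
  yc <- o[2] + (nr - seq_len(nr) + 0.5) * g   # row 1 = north
  list(rows = which(yc >= extent[2] & yc < extent[4]),
       cols = which(xc >= extent[1] & xc < extent[3]))
}
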