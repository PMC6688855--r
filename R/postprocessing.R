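## Salt-and-pepper clean-up of classified rasters: neighbourhood majority
## filter, expand/shrink boundary smoothing by class priority, and a
## minimum-mapping-unit sieve with nearest-neighbour replacement.

#' Neighbourhood majority filter
#'
#' Replaces each pixel by the strict-majority class of its neighbourhood
#' (centre included); where no class holds a strict majority the pixel is
#' unchanged. No-data neighbours are ignored in the counts.
#'
#' @param cls A `class_raster`.
#' @param kernel `"8-neighbour"` (3 x 3 box, default) or `"4-neighbour"`
#'   (plus-shaped).
#' @return The filtered `class_raster`.
#' @export
majority_filter <- function(cls, kernel = c("8-neighbour", "4-neighbour")) {
  stopifnot(inherits(cls, "class_raster"))
  kernel <- match.arg(kernel)
  m <- majority_filter_cpp(unclass(cls), 3L, kernel == "8-neighbour")
  class_raster(m, raster_gsd(cls), raster_origin(cls))
}

#' Boundary clean: expand/shrink smoothing by class priority
#'
#' For each class in ascending priority, the class mask is morphologically
#' closed (one-pixel dilation then erosion, 3 x 3 box); the closed masks are
#' composited so higher-priority classes overwrite lower ones, and pixels
#' claimed by no closed mask keep their original label. Repeated `iterations`
#' times. Every pixel keeps some label, so total pixel count is conserved and
#' no new label can appear.
#'
#' @param cls A `class_raster`.
#' @param priority Permutation of the class labels `1:3`, highest priority
#'   first. Default: classes in decreasing area.
#' @param iterations Number of expand/shrink passes (default 2).
#' @return The smoothed `class_raster`.
#' @export
boundary_clean <- function(cls, priority = NULL, iterations = 2L) {
  stopifnot(inherits(cls, "class_raster"), iterations >= 1)
  m <- unclass(cls)
  if (is.null(priority)) {
    area <- tabulate(m[!is.na(m)], nbins = 3L)
    priority <- order(area, decreasing = TRUE)
  }
  if (!identical(sort(as.integer(priority)), 1:3)) {
    stop("priority must be a permutation of the class labels 1:3")
  }
  for (it in seq_len(iterations)) {
    out <- m
    for (cl in rev(as.integer(priority))) {   # low priority first, high wins
      mask <- !is.na(m) & m == cl
      if (!any(mask)) next
      closed <- morph3_cpp(morph3_cpp(mask, TRUE), FALSE)
      out[closed] <- cl
    }
    out[is.na(m)] <- NA_integer_
    m <- out
  }
  class_raster(m, raster_gsd(cls), raster_origin(cls))
}

#' Patch table of a classified raster
#'
#' Connected components per class with pixel counts and areas.
#'
#' @param cls A `class_raster`.
#' @param connectivity 8 (default) or 4.
#' @return Tibble with `class`, `patch_id`, `n_pixels`, `area_m2`.
#' @export
patch_table <- function(cls, connectivity = 8) {
  stopifnot(inherits(cls, "class_raster"), connectivity %in% c(4, 8))
  m <- unclass(cls)
  g <- raster_gsd(cls)
  out <- list()
  for (cl in COVER_CLASSES) {
    mask <- !is.na(m) & m == cl
    if (!any(mask)) next
    lab <- label_components_cpp(mask, connectivity == 8)
    nlab <- max(lab)
    sz <- component_sizes_cpp(lab, nlab)
    out[[length(out) + 1L]] <- tibble::tibble(
      class = cover_class_names()[cl], patch_id = seq_len(nlab),
      n_pixels = as.integer(sz), area_m2 = sz * g^2)
  }
  do.call(rbind, out)
}

#' Minimum-mapping-unit sieve with nearest-neighbour replacement
#'
#' Connected components smaller than `min_area_m2` are dissolved: each of
#' their pixels takes the class of the nearest pixel (Euclidean distance on
#' pixel centres) belonging to a surviving patch, ties broken towards the
#' lowest class label. Donors are the pre-pass survivors, so removal within a
#' pass is order-independent. Passes repeat until no sub-MMU patch remains or
#' `max_passes` is reached (a warning is issued if not converged).
#'
#' @param cls A `class_raster`.
#' @param min_area_m2 Minimum patch area retained (default 0.25 m^2).
#' @param connectivity Patch connectivity, 8 (default) or 4.
#' @param max_passes Maximum sieve passes (default 10).
#' @return The sieved `class_raster`, with attribute `"converged"`.
#' @export
mmu_sieve <- function(cls, min_area_m2 = 0.25, connectivity = 8,
                      max_passes = 10L) {
  stopifnot(inherits(cls, "class_raster"), min_area_m2 >= 0,
            connectivity %in% c(4, 8))
  g <- raster_gsd(cls)
  min_px <- min_area_m2 / g^2   # patches with n_pixels < min_px are removed
  m <- unclass(cls)
  converged <- FALSE
  for (pass in seq_len(max_passes)) {
    small <- matrix(FALSE, nrow(m), ncol(m))
    any_small <- FALSE
    for (cl in COVER_CLASSES) {
      mask <- !is.na(m) & m == cl
      if (!any(mask)) next
      lab <- label_components_cpp(mask, connectivity == 8)
      sz <- component_sizes_cpp(lab, max(lab))
      rm_ids <- which(sz < min_px - 1e-9)
      if (length(rm_ids)) {
        small <- small | (lab %in% rm_ids & mask)
        any_small <- TRUE
      }
    }
    if (!any_small) { converged <- TRUE; break }
    if (all(small[!is.na(m)])) stop("all patches are below the MMU: no surviving donor")
    # class of nearest surviving pixel, per-class distance maps, ties -> lowest label
    best_d <- matrix(Inf, nrow(m), ncol(m))
    donor <- matrix(NA_integer_, nrow(m), ncol(m))
    for (cl in COVER_CLASSES) {
      dm <- !is.na(m) & m == cl & !small
      if (!any(dm)) next
      d <- edt_sq_cpp(dm)
      upd <- d < best_d - 1e-9
      donor[upd] <- cl
      best_d[upd] <- d[upd]
    }
    m[small] <- donor[small]
  }
  if (!converged) warning("mmu_sieve did not converge within max_passes")
  out <- class_raster(m, g, raster_origin(cls))
  attr(out, "converged") <- converged
  out
}

#' Full post-processing chain
#'
#' Majority filter, then boundary clean, then the MMU sieve — the standard
#' salt-and-pepper treatment for high-resolution classified mosaics.
#'
#' @param cls A `class_raster`.
#' @param kernel Majority-filter kernel (see [majority_filter()]).
#' @param priority Boundary-clean priority (see [boundary_clean()]).
#' @param bc_iterations Boundary-clean passes.
#' @param min_area_m2 MMU threshold, m^2.
#' @param connectivity Patch connectivity.
#' @return The cleaned `class_raster`.
#' @export
postprocess_chain <- function(cls, kernel = "8-neighbour", priority = NULL,
                              bc_iterations = 2L, min_area_m2 = 0.25,
                              connectivity = 8) {
  out <- majority_filter(cls, kernel)
  out <- boundary_clean(out, priority, bc_iterations)
  mmu_sieve(out, min_area_m2, connectivity)
}
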