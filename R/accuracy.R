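## Thematic-map accuracy: stratified random assessment points (allocation
## proportional to class area), per-plot confusion matrices, overall accuracy,
## Cohen's kappa, omission/commission errors, and the across-plot summary.

#' Largest-remainder apportionment
#'
#' Allocates `n` integer seats to categories proportionally to `shares`;
#' floors first, then one extra seat per largest fractional remainder
#' (ties to the earlier category).
#'
#' @param shares Non-negative weights (normalized internally).
#' @param n Total to allocate.
#' @return Integer vector summing to `n`.
#' @export
largest_remainder <- function(shares, n) {
  stopifnot(all(shares >= 0), sum(shares) > 0, n >= 0)
  q <- shares / sum(shares) * n
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Stratified random accuracy-assessment points for one plot
#'
#' `n_points` points are allocated to classes proportionally to each class's
#' pixel area within the plot (largest-remainder rule) and drawn uniformly
#' without replacement from that class's pixels. If a class has fewer pixels
#' than its allocation, the excess moves to the next class by area (with a
#' warning).
#'
#' @param cls The mapped `class_raster`.
#' @param plot One row of `design$plots` (or any extent-like list with
#'   `xmin`, `ymin`, `xmax`, `ymax`).
#' @param n_points Points per plot (default 100).
#' @param seed Integer seed.
#' @return Tibble with point coordinates (`x`, `y` at pixel centres), `row`,
#'   `col`, and the `mapped` class label.
#' @export
stratified_points <- function(cls, plot, n_points = 100L, seed = 1L) {
  stopifnot(inherits(cls, "class_raster"))
  ix <- crop_indices(cls, c(plot$xmin, plot$ymin, plot$xmax, plot$ymax))
  sub <- unclass(cls)[ix$rows, ix$cols, drop = FALSE]
  ok <- !is.na(sub)
  if (sum(ok) < n_points) stop("plot has fewer pixels than assessment points")
  area <- tabulate(sub[ok], nbins = 3L)
  alloc <- largest_remainder(area, n_points)
  # reallocate any excess over availability towards the next class by area
  if (any(alloc > area)) {
    warning("class allocation exceeded available pixels; reallocating excess")
    alloc <- pmin(alloc, area)
    short <- n_points - sum(alloc)
    for (c_ in order(area, decreasing = TRUE)) {
      if (short <= 0) break
      take <- min(short, area[c_] - alloc[c_])
      alloc[c_] <- alloc[c_] + take
      short <- short - take
    }
  }
  set.seed(seed)
  picks <- list()
  for (cl in COVER_CLASSES) {
    if (alloc[cl] == 0) next
    cand <- which(ok & sub == cl)
    sel <- if (length(cand) == 1) cand else
      cand[sample.int(length(cand), alloc[cl])]
    picks[[length(picks) + 1L]] <- tibble::tibble(idx = sel, mapped = cl)
  }
  pk <- do.call(rbind, picks)
  nrs <- length(ix$rows)
  r_loc <- ((pk$idx - 1L) %% nrs) + 1L
  c_loc <- ((pk$idx - 1L) %/% nrs) + 1L
  row <- ix$rows[r_loc]; col <- ix$cols[c_loc]
  g <- raster_gsd(cls); o <- raster_origin(cls); nr <- raster_dim(cls)[1]
  tibble::tibble(
    x = o[1] + (col - 0.5) * g,
    y = o[2] + (nr - row + 0.5) * g,
    row = row, col = col, mapped = as.integer(pk$mapped))
}

#' Confusion matrix at assessment points
#'
#' Rows are the mapped class, columns the reference class. Points falling on
#' no-data in either raster are excluded with a warning.
#'
#' @param points Tibble from [stratified_points()] (needs `row`, `col`).
#' @param mapped The mapped `class_raster`.
#' @param reference The reference `class_raster` (synthetic truth, or a
#'   photointerpreted layer), aligned with `mapped`.
#' @return 3 x 3 integer matrix with dimnames (mapped x reference).
#' @export
confusion_matrix <- function(points, mapped, reference) {
  if (!same_geometry(mapped, reference)) {
    stop("mapped and reference rasters are not aligned")
  }
  mp <- unclass(mapped)[cbind(points$row, points$col)]
  rf <- unclass(reference)[cbind(points$row, points$col)]
  ok <- !is.na(mp) & !is.na(rf)
  if (any(!ok)) warning(sprintf("%d point(s) on no-data excluded", sum(!ok)))
  cm <- table(factor(mp[ok], levels = COVER_CLASSES),
              factor(rf[ok], levels = COVER_CLASSES))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(mapped = cover_class_names(),
                               reference = cover_class_names()))
  cm
}

#' Accuracy metrics from a confusion matrix
#'
#' Overall accuracy is trace/total. Cohen's kappa is
#' `(p_o - p_e) / (1 - p_e)` with the chance agreement `p_e` computed from the
#' row and column marginals. Per-class omission error is
#' `1 - diag/column-sum` and commission error `1 - diag/row-sum`.
#'
#' @param cm Square integer matrix, rows = mapped, columns = reference.
#' @return List with `overall_accuracy`, `kappa`, `omission`, `commission`,
#'   `n`. A degenerate matrix with `p_e = 1` returns kappa 0 with a warning;
#'   empty marginals give `NaN` errors for the affected class.
#' @export
accuracy_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate single-class matrix: kappa defined as 0")
    kappa <- 0
  } else {
    kappa <- (po - pe) / (1 - pe)
  }
  list(overall_accuracy = po, kappa = kappa,
       omission = 1 - diag(cm) / colSums(cm),
       commission = 1 - diag(cm) / rowSums(cm),
       n = n)
}

#' Across-plot accuracy summary
#'
#' Mean, sample SD (n-1), and range of per-plot overall accuracy and kappa —
#' the per-altitude summary conventionally reported for thematic maps.
#'
#' @param metrics List of per-plot results from [accuracy_metrics()].
#' @return Tibble with one row per statistic (`oa`, `kappa`): mean, sd, min,
#'   max, n_plots. With a single plot, SD is reported as 0 and flagged.
#' @export
summarize_accuracy <- function(metrics) {
  stopifnot(length(metrics) >= 1)
  oa <- vapply(metrics, `[[`, 0, "overall_accuracy")
  ka <- vapply(metrics, `[[`, 0, "kappa")
  single <- length(metrics) == 1
  sdv <- function(x) if (single) 0 else sd(x)
  tibble::tibble(
    statistic = c("oa", "kappa"),
    mean = c(mean(oa), mean(ka)),
    sd = c(sdv(oa), sdv(ka)),
    min = c(min(oa), min(ka)),
    max = c(max(oa), max(ka)),
    n_plots = length(metrics),
    sd_undefined = single)
}

#' Per-plot accuracy assessment of a classified raster
#'
#' Runs [stratified_points()], [confusion_matrix()] and [accuracy_metrics()]
#' for every plot of the design.
#'
#' @param cls Mapped `class_raster`.
#' @param reference Aligned reference `class_raster`.
#' @param design A `survey_design`.
#' @param n_points Points per plot (default 100).
#' @param seed Integer seed (one substream per plot).
#' @return List with `per_plot` (list of metrics + confusion matrices),
#'   `summary` (from [summarize_accuracy()]), and `points_total`.
#' @export
assess_accuracy <- function(cls, reference, design, n_points = 100L,
                            seed = 1L) {
  res <- list(); pts_tot <- 0L
  for (p in seq_len(nrow(design$plots))) {
    pts <- stratified_points(cls, design$plots[p, ], n_points,
                             seed = seed + p)
    cm <- confusion_matrix(pts, cls, reference)
    met <- accuracy_metrics(cm)
    met$confusion <- cm
    met$plot_id <- p
    res[[p]] <- met
    pts_tot <- pts_tot + nrow(pts)
  }
  list(per_plot = res, summary = summarize_accuracy(res),
       points_total = pts_tot)
}
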