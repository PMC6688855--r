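## End-to-end orchestration of the synthetic study: configuration, seed
## fan-out, per-altitude classification/post-processing/estimation/assessment,
## the statistical comparison, and a reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles every stage's settings. All stage seeds are derived
#' deterministically from `master_seed` via named substreams, so partial
#' re-runs reproduce stage-for-stage.
#'
#' @param master_seed Integer master seed.
#' @param scene A `scene_spec` (its own seed is overridden by the master
#'   seed's `"scene"` substream).
#' @param design A `survey_design`.
#' @param altitudes_m Flight altitudes (default 75/100/120 m).
#' @param gsd_k GSD model slope (m GSD per m altitude); default calibrated so
#'   the lowest altitude flies at the scene's native GSD.
#' @param K Spectral clusters (default 30).
#' @param kernel Majority-filter kernel.
#' @param bc_iterations Boundary-clean passes.
#' @param min_area_m2 MMU threshold.
#' @param connectivity Patch connectivity.
#' @param n_accuracy_points Assessment points per plot (default 100).
#' @param transect_spacing_m Virtual/ground transect spacing (default 1 m).
#' @param ground_misclass_rate Observer error for the simulated ground crew.
#' @param quadrature_nodes Gauss-Hermite nodes for the GLMMs.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1L,
                            scene = scene_spec(),
                            design = default_design(),
                            altitudes_m = c(75, 100, 120),
                            gsd_k = NULL,
                            K = 30L,
                            kernel = "8-neighbour",
                            bc_iterations = 2L,
                            min_area_m2 = 0.25,
                            connectivity = 8,
                            n_accuracy_points = 100L,
                            transect_spacing_m = 1,
                            ground_misclass_rate = 0,
                            quadrature_nodes = 15L,
                            out_dir = NULL) {
  if (is.null(gsd_k)) gsd_k <- scene$gsd_m / min(altitudes_m)
  structure(list(master_seed = as.integer(master_seed), scene = scene,
                 design = design, altitudes_m = altitudes_m, gsd_k = gsd_k,
                 K = as.integer(K), kernel = kernel,
                 bc_iterations = as.integer(bc_iterations),
                 min_area_m2 = min_area_m2, connectivity = connectivity,
                 n_accuracy_points = as.integer(n_accuracy_points),
                 transect_spacing_m = transect_spacing_m,
                 ground_misclass_rate = ground_misclass_rate,
                 quadrature_nodes = as.integer(quadrature_nodes),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Deterministic stage seed from a master seed and a stage name
#'
#' A small string hash mixed with the master seed, kept inside the 32-bit
#' integer range, so each named stage gets its own reproducible substream.
#'
#' @param master_seed Integer.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(master_seed) * 2654435 + h * 97 + 12345) %% 2147483647)
}

#' Write / read a pipeline config as a flat key-value file
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  num <- function(x) paste(format(x, digits = 15), collapse = ",")
  ncx <- (config$design$plots$xmax - config$design$plots$xmin) /
    config$design$cell_side_m
  ncy <- (config$design$plots$ymax - config$design$plots$ymin) /
    config$design$cell_side_m
  writeLines(c(
    sprintf("master_seed=%d", config$master_seed),
    sprintf("altitudes_m=%s", num(config$altitudes_m)),
    sprintf("gsd_k=%s", num(config$gsd_k)),
    sprintf("K=%d", config$K),
    sprintf("kernel=%s", config$kernel),
    sprintf("bc_iterations=%d", config$bc_iterations),
    sprintf("min_area_m2=%s", num(config$min_area_m2)),
    sprintf("connectivity=%s", num(config$connectivity)),
    sprintf("n_accuracy_points=%d", config$n_accuracy_points),
    sprintf("transect_spacing_m=%s", num(config$transect_spacing_m)),
    sprintf("ground_misclass_rate=%s", num(config$ground_misclass_rate)),
    sprintf("quadrature_nodes=%d", config$quadrature_nodes),
    sprintf("design_plots=%s",
            paste(sprintf("%gx%g", ncx, ncy), collapse = ";")),
    sprintf("scene.gsd_m=%s", num(config$scene$gsd_m)),
    sprintf("scene.target_props=%s", num(config$scene$target_props)),
    sprintf("scene.spatial_corr_length_m=%s",
            num(config$scene$spatial_corr_length_m)),
    sprintf("scene.shadow_fraction=%s", num(config$scene$shadow_fraction)),
    sprintf("scene.confusability=%s", num(config$scene$confusability)),
    sprintf("scene.noise_sd=%s", num(config$scene$noise_sd))),
    path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  kv <- read_flat_config(path)
  layout <- lapply(strsplit(strsplit(kv[["design_plots"]], ";")[[1]], "x"),
                   as.integer)
  scene <- scene_spec(
    seed = as.integer(kv_num(kv, "master_seed")),
    gsd_m = kv_num(kv, "scene.gsd_m"),
    target_props = kv_num(kv, "scene.target_props"),
    spatial_corr_length_m = kv_num(kv, "scene.spatial_corr_length_m"),
    shadow_fraction = kv_num(kv, "scene.shadow_fraction"),
    confusability = kv_num(kv, "scene.confusability"),
    noise_sd = kv_num(kv, "scene.noise_sd"))
  pipeline_config(
    master_seed = as.integer(kv_num(kv, "master_seed")),
    scene = scene, design = survey_design(layout),
    altitudes_m = kv_num(kv, "altitudes_m"),
    gsd_k = kv_num(kv, "gsd_k"),
    K = as.integer(kv_num(kv, "K")),
    kernel = kv[["kernel"]],
    bc_iterations = as.integer(kv_num(kv, "bc_iterations")),
    min_area_m2 = kv_num(kv, "min_area_m2"),
    connectivity = kv_num(kv, "connectivity"),
    n_accuracy_points = as.integer(kv_num(kv, "n_accuracy_points")),
    transect_spacing_m = kv_num(kv, "transect_spacing_m"),
    ground_misclass_rate = kv_num(kv, "ground_misclass_rate"),
    quadrature_nodes = as.integer(kv_num(kv, "quadrature_nodes")))
}

#' Run the full synthetic study
#'
#' Generates the landscape, simulates the ground crew, and, per altitude:
#' renders RGB, classifies per plot, post-processes, estimates per-cell cover
#' by both drone methods, and assesses accuracy against the synthetic truth.
#' Finishes with the correlation and beta-GLMM comparison and (optionally)
#' writes every artifact plus a hash manifest.
#'
#' @param config A `pipeline_config`.
#' @param run_stats Fit the GLMM suite (default TRUE).
#' @param verbose Log stage progress.
#' @return A `pipeline_result` list: `scenes`, `classified`, `cover`
#'   (combined cover table), `accuracy` (per altitude), `stats`
#'   (method-comparison report), `study_proportions`, `manifest`.
#' @export
run_pipeline <- function(config, run_stats = TRUE, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) {
    if (verbose) message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, units = "secs")),
                         sprintf(fmt, ...))
  }
  design <- config$design
  scene <- config$scene
  scene$seed <- stage_seed(config$master_seed, "scene")
  gsd_mod <- gsd_model(config$gsd_k)

  log_stage("simulating landscape at %d altitude(s)", length(config$altitudes_m))
  scenes <- simulate_study(scene, design, config$altitudes_m, gsd_mod)

  # ground crew walks the finest truth map
  finest <- which.min(vapply(scenes, `[[`, 0, "gsd_m"))
  log_stage("ground transects (spacing %g m)", config$transect_spacing_m)
  ground <- walk_transects(scenes[[finest]]$truth, design,
                           spacing_m = config$transect_spacing_m,
                           misclass_rate = config$ground_misclass_rate,
                           seed = stage_seed(config$master_seed, "ground"))
  cover <- list(cell_proportions_from_points(ground))

  classified <- list(); accuracy <- list(); study_props <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    alt <- sc$altitude_m
    log_stage("altitude %g m: classifying (%d x %d px, K=%d, per plot)",
              alt, nrow(sc$truth), ncol(sc$truth), config$K)
    cls <- classify_raster(sc$rgb, sc$truth, K = config$K,
                           seed = stage_seed(config$master_seed,
                                             paste0("classify", alt)),
                           design = design)
    log_stage("altitude %g m: post-processing", alt)
    cls <- postprocess_chain(cls, kernel = config$kernel,
                             bc_iterations = config$bc_iterations,
                             min_area_m2 = config$min_area_m2,
                             connectivity = config$connectivity)
    classified[[names(scenes)[i]]] <- cls
    log_stage("altitude %g m: cover estimators", alt)
    cover[[length(cover) + 1L]] <-
      pixel_count_proportions(cls, design, altitude_m = alt)
    cover[[length(cover) + 1L]] <-
      virtual_transect_proportions(cls, design,
                                   spacing_m = config$transect_spacing_m,
                                   altitude_m = alt)
    study_props[[names(scenes)[i]]] <- study_area_proportions(cls, design)
    log_stage("altitude %g m: accuracy assessment", alt)
    accuracy[[names(scenes)[i]]] <-
      assess_accuracy(cls, sc$truth, design,
                      n_points = config$n_accuracy_points,
                      seed = stage_seed(config$master_seed,
                                        paste0("assess", alt)))
  }
  cover_tab <- cover_table(do.call(rbind, cover))

  stats_rep <- NULL
  if (run_stats) {
    log_stage("beta GLMM suite")
    ref_alt <- config$altitudes_m[which.min(
      gsd_at_altitude(gsd_mod, config$altitudes_m)$gsd_cm)]
    stats_rep <- method_comparison_report(
      cover_tab, reference_altitude_m = ref_alt,
      quadrature_nodes = config$quadrature_nodes)
  }

  result <- structure(list(
    config = config, scenes = scenes, classified = classified,
    ground_records = ground, cover = cover_tab, accuracy = accuracy,
    study_proportions = study_props, stats = stats_rep,
    elapsed_s = as.numeric(Sys.time() - t0, units = "secs")),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    result$manifest <- write_pipeline_outputs(result, config$out_dir)
  }
  log_stage("done (%.1f s)", result$elapsed_s)
  result
}

## write all artifacts and a manifest of md5 hashes
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfgp <- file.path(dir, "config.txt")
  write_pipeline_config(result$config, cfgp)
  paths <- cfgp
  for (nm in names(result$scenes)) {
    sc <- result$scenes[[nm]]
    p1 <- file.path(dir, paste0("truth_", nm, ".tif"))
    p2 <- file.path(dir, paste0("rgb_", nm, ".tif"))
    p3 <- file.path(dir, paste0("classified_", nm, ".tif"))
    write_raster_tiff(sc$truth, p1)
    write_raster_tiff(sc$rgb, p2)
    write_raster_tiff(result$classified[[nm]], p3)
    paths <- c(paths, p1, p2, p3)
  }
  cvp <- file.path(dir, "cover_table.csv")
  write_cover_table(result$cover, cvp)
  paths <- c(paths, cvp)
  acc <- do.call(rbind, lapply(names(result$accuracy), function(nm) {
    s <- result$accuracy[[nm]]$summary
    s$altitude <- nm
    s
  }))
  accp <- file.path(dir, "accuracy_summary.csv")
  write.csv(acc, accp, row.names = FALSE)
  paths <- c(paths, accp)
  for (nm in names(result$accuracy)) {
    for (pp in result$accuracy[[nm]]$per_plot) {
      cmp <- file.path(dir, sprintf("confusion_%s_plot%d.csv", nm, pp$plot_id))
      write.csv(as.data.frame(pp$confusion), cmp, row.names = TRUE)
      paths <- c(paths, cmp)
    }
  }
  if (!is.null(result$stats)) {
    sdir <- file.path(dir, "stats")
    write_method_comparison(result$stats, sdir)
    paths <- c(paths, list.files(sdir, full.names = TRUE))
  }
  manifest <- tibble::tibble(
    file = basename(paths),
    md5 = unname(vapply(paths, function(p) unname(tools::md5sum(p)), "")))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Table-1-style accuracy / proportion summary
#'
#' Formats per-altitude study-area proportions and the across-plot accuracy
#' summaries of a pipeline result into the conventional report layout
#' (proportion rows, then mean +/- SD and range of overall accuracy and
#' kappa).
#'
#' @param result A `pipeline_result`.
#' @return Tibble with one column per altitude.
#' @export
table1_summary <- function(result) {
  alts <- names(result$accuracy)
  cols <- lapply(alts, function(nm) {
    pr <- result$study_proportions[[nm]]
    s <- result$accuracy[[nm]]$summary
    oa <- s[s$statistic == "oa", ]
    ka <- s[s$statistic == "kappa", ]
    c(sprintf("%.3f", pr),
      sprintf("%.1f%%+/-%.3f Range: %.2f-%.2f",
              100 * oa$mean, oa$sd, oa$min, oa$max),
      sprintf("%.2f+/-%.3f Range: %.2f-%.2f",
              ka$mean, ka$sd, ka$min, ka$max))
  })
  out <- tibble::tibble(metric = c("Proportion Barren", "Proportion Non-Shrubs",
                                   "Proportion Shrubs", "Overall Accuracy",
                                   "Kappa Coefficient"))
  for (i in seq_along(alts)) out[[alts[i]]] <- cols[[i]]
  out
}

#' Read a deposited per-cell proportion table
#'
#' Ingests the long- or wide-form per-cell cover table layout used for the
#' deposited supplementary data (one proportion per cell x method x class)
#' from CSV, or from XLSX when the `readxl` package is available. Headers are
#' mapped case-insensitively; wide layouts with one column per method/class
#' pair (e.g. `ground_barren`) are melted to the canonical long form.
#'
#' @param path CSV or XLSX file.
#' @param altitude_m Altitude tag for the drone methods (default 75).
#' @param default_n Fallback count when the table carries no `n` column:
#'   point-based methods get 142 (2 x 71 step points), pixel counts get
#'   `NA` (must be supplied for exact SV transforms).
#' @return A validated cover table.
#' @export
read_s1_data <- function(path, altitude_m = 75, default_n = 142L) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package")
    }
    df <- as.data.frame(readxl::read_excel(path))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  names(df) <- tolower(gsub("[^A-Za-z0-9]+", "_", names(df)))
  method_alias <- c(ground = "ground", ground_transects = "ground",
                    drone_transects = "drone_transects",
                    drone_pixels = "drone_pixels",
                    drone_pixel_counts = "drone_pixels")
  class_alias <- c(barren = "barren", nonshrub = "nonshrub",
                   non_shrub = "nonshrub", non_shrubs = "nonshrub",
                   "non-shrub" = "nonshrub", "non-shrubs" = "nonshrub",
                   shrub = "shrub", shrubs = "shrub")
  if (all(c("cell_id", "method", "class", "proportion") %in% names(df))) {
    long <- df
    long$method <- unname(method_alias[tolower(long$method)])
    long$class <- unname(class_alias[tolower(long$class)])
  } else {
    # wide: method_class columns
    combos <- expand.grid(method = names(method_alias),
                          class = names(class_alias),
                          stringsAsFactors = FALSE)
    combos$col <- paste(combos$method, combos$class, sep = "_")
    hit <- combos[combos$col %in% names(df), ]
    if (!nrow(hit) || !"cell_id" %in% names(df)) {
      stop("unmappable headers; expected cell_id + method/class/proportion ",
           "columns or wide <method>_<class> columns such as ground_barren")
    }
    found <- unique(unname(method_alias[hit$method]))
    cls_found <- unique(unname(class_alias[hit$class]))
    if (length(cls_found) < 3) {
      stop("missing class column(s) for: ",
           paste(setdiff(cover_class_names(), cls_found), collapse = ", "))
    }
    long <- do.call(rbind, lapply(seq_len(nrow(hit)), function(i) {
      data.frame(plot_id = if ("plot_id" %in% names(df)) df$plot_id else NA,
                 cell_id = df$cell_id,
                 method = unname(method_alias[hit$method[i]]),
                 class = unname(class_alias[hit$class[i]]),
                 proportion = df[[hit$col[i]]],
                 n = if ("n" %in% names(df)) df$n else NA,
                 stringsAsFactors = FALSE)
    }))
  }
  if (anyNA(long$method) || anyNA(long$class)) {
    stop("unmappable method or class values in the table")
  }
  if (!"plot_id" %in% names(long)) long$plot_id <- NA_integer_
  if (!"n" %in% names(long) || all(is.na(long$n))) {
    long$n <- ifelse(long$method %in% c("ground", "drone_transects"),
                     default_n, NA_integer_)
  }
  if (!"altitude_m" %in% names(long)) {
    long$altitude_m <- ifelse(long$method == "ground", NA_real_, altitude_m)
  }
  if (any(long$proportion < 0 | long$proportion > 1, na.rm = TRUE)) {
    stop("parsed proportions outside [0, 1]")
  }
  cover_table(long[, c("plot_id", "cell_id", "method", "altitude_m",
                       "class", "proportion", "n")])
}
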