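# Shared fixtures: everything is generated in code, no stored rasters.

# small 2-plot / 8-cell design for fast end-to-end tests
small_design <- function() survey_design(list(c(2, 2), c(2, 2)))

# a scene spec that classifies perfectly: disjoint spectra, no noise,
# no shadows, no confusability
separable_spec <- function(seed = 1L, gsd_m = 0.5) {
  scene_spec(seed = seed, gsd_m = gsd_m, spatial_corr_length_m = 4,
             shadow_fraction = 0, confusability = 0, noise_sd = 0)
}

# tiny class raster from an integer matrix (gsd 1 m, origin 0)
cr <- function(m, gsd = 1) class_raster(as.matrix(m), gsd)

# independent slow majority vote used as an oracle
brute_majority <- function(m, eight = TRUE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    votes <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (!eight && di != 0 && dj != 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      v <- m[ii, jj]
      if (!is.na(v)) votes <- c(votes, v)
    }
    tab <- tabulate(votes, 3)
    win <- which(2 * tab > length(votes))
    if (length(win) == 1) out[i, j] <- win
  }
  out
}
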