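test_that("SV transform hits its forced boundary values and round-trips", {
  expect_equal(sv_transform(0, 100), 0.005)
  expect_equal(sv_transform(1, 100), 0.995)
  expect_equal(sv_transform(0.5, 7), 0.5)      # fixed point at one half
  y <- seq(0, 1, by = 0.05)
  for (n in c(1, 10, 142, 10000)) {
    yt <- sv_transform(y, n)
    expect_true(all(yt > 0 & yt < 1))
    if (n > 1) {
      expect_equal(sv_inverse(yt, n), y, tolerance = 1e-12)
      expect_true(all(diff(yt) > 0))           # strictly monotone
    }
  }
  expect_error(sv_transform(0.5, 0))
})

test_that("Gauss-Hermite rule reproduces known nodes and Gaussian moments", {
  gh2 <- gauss_hermite(2)
  expect_equal(gh2$nodes, c(-1, 1) / sqrt(2))
  expect_equal(gh2$weights, rep(sqrt(pi) / 2, 2))
  gh <- gauss_hermite(15)
  # moments of N(0, 1/2) under weight exp(-z^2)
  expect_equal(sum(gh$weights), sqrt(pi))
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2)
  expect_equal(sum(gh$weights * gh$nodes^4), 3 * sqrt(pi) / 4)
})

test_that("fit agrees with an independent engine (glmmTMB) on simulated data", {
  skip_if_not_installed("glmmTMB")
  d <- simulate_beta_glmm(beta = c(1.0, -0.3, 0.5), sigma2 = 0.7, phi = 40,
                          n_cells = 92, seed = 11)
  f <- fit_beta_glmm(d, response = "y", fixed = "level")
  g <- glmmTMB::glmmTMB(y ~ level + (1 | cell_id),
                        family = glmmTMB::beta_family(), data = d)
  co <- summary(g)$coefficients$cond
  expect_equal(f$coefficients$estimate, unname(co[, 1]), tolerance = 2e-3)
  expect_equal(f$coefficients$se, unname(co[, 2]), tolerance = 0.02)
  expect_equal(f$phi, glmmTMB::sigma(g), tolerance = 0.02)
  expect_equal(f$sigma2_cell,
               glmmTMB::VarCorr(g)$cond$cell_id[1, 1], tolerance = 0.02)
  # AGQ marginal likelihood can only improve on the Laplace value
  expect_gte(f$loglik, as.numeric(stats::logLik(g)) - 1e-3)
})

test_that("with no cell variance the fixed effects match plain beta ML", {
  d <- simulate_beta_glmm(beta = c(0.4, -0.5, 0.3), sigma2 = 0, phi = 30,
                          n_cells = 92, seed = 20)
  f <- suppressWarnings(fit_beta_glmm(d, response = "y", fixed = "level"))
  # independent oracle: beta regression without random effect by direct ML
  X <- stats::model.matrix(~level, d)
  nll0 <- function(th) {
    mu <- plogis(as.vector(X %*% th[1:3])); phi <- exp(th[4])
    -sum(dbeta(d$y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  o <- optim(c(0, 0, 0, log(10)), nll0, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-13))
  expect_equal(f$coefficients$estimate, o$par[1:3], tolerance = 1e-4)
  expect_lt(f$sigma2_cell, 1e-4)
  expect_true(f$boundary)
})

test_that("likelihood improves from the fixed start and df follow containment", {
  d <- simulate_beta_glmm(beta = c(1.2, 0.1, -0.1), sigma2 = 0.5, phi = 25,
                          n_cells = 92, seed = 31)
  f <- fit_beta_glmm(d, response = "y", fixed = "level")
  expect_gt(f$loglik, f$loglik_start)
  expect_equal(f$F_test$df1, 2)
  expect_equal(f$F_test$df2, 276 - 92 - 2)   # = 182
  expect_equal(f$n_obs, 276)
  expect_equal(f$n_cells, 92)
  # dispersion near 1 for a well-specified model
  expect_lt(abs(f$dispersion - 1), 0.25)
})

test_that("doubling the quadrature nodes leaves the estimates unchanged", {
  d <- simulate_beta_glmm(beta = c(0.8, -0.2, 0.4), sigma2 = 0.6, phi = 35,
                          n_cells = 92, seed = 41)
  f15 <- fit_beta_glmm(d, response = "y", fixed = "level",
                       quadrature_nodes = 15)
  f30 <- fit_beta_glmm(d, response = "y", fixed = "level",
                       quadrature_nodes = 30)
  expect_lt(max(abs(f15$coefficients$estimate - f30$coefficients$estimate)),
            1e-4)
})

test_that("pearson_r matches cor() and flags degenerate input", {
  x <- rnorm(92)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x + 3), -1)
  y <- rnorm(92)
  expect_equal(pearson_r(x, y), cor(x, y))
  expect_error(pearson_r(x, rep(0.5, 92)), "constant")
})

test_that("method comparison runs the nine-model suite on matched data", {
  # build a small synthetic cover table: 20 cells x 3 methods x 3 classes,
  # drone methods biased against non-shrub
  set.seed(7)
  ncell <- 20
  base <- cbind(runif(ncell, .5, .9))
  mk <- function(method, alt, bias) {
    p2 <- pmax(0.01, 0.2 - bias + rnorm(ncell, 0, 0.02))
    p1 <- pmin(0.98, base + bias / 2 + rnorm(ncell, 0, 0.02))
    p3 <- pmax(0.01, 1 - p1 - p2)
    tot <- p1 + p2 + p3
    tibble::tibble(plot_id = 1, cell_id = rep(1:ncell, 3),
                   method = method, altitude_m = alt,
                   class = rep(cover_class_names(), each = ncell),
                   proportion = c(p1, p2, p3) / rep(tot, 3),
                   n = 142L)
  }
  tab <- rbind(mk("ground", NA, 0),
               mk("drone_pixels", 75, 0.12), mk("drone_pixels", 100, 0.12),
               mk("drone_pixels", 120, 0.15),
               mk("drone_transects", 75, 0.12), mk("drone_transects", 100, 0.12),
               mk("drone_transects", 120, 0.15))
  rep <- suppressWarnings(method_comparison_report(tab, reference_altitude_m = 75,
                                                   quadrature_nodes = 7))
  expect_length(rep$fits, 9)
  expect_equal(nrow(rep$f_tests), 9)
  expect_equal(nrow(rep$estimates), 27)  # 9 models x 3 levels
  # drone methods underestimate non-shrub: negative method coefficients
  ns <- rep$coefficients[rep$coefficients$family == "method" &
                           rep$coefficients$class == "nonshrub" &
                           rep$coefficients$term != "(Intercept)", ]
  expect_true(all(ns$estimate < 0))
  d <- tempfile()
  write_method_comparison(rep, d)
  expect_true(file.exists(file.path(d, "glmm_f_tests.csv")))
  # a missing method level is an error naming the absentee
  expect_error(method_comparison_report(tab[tab$method != "ground", ]),
               "ground")
})
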