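## Proportion-cover statistics: Smithson-Verkuilen boundary transform, beta
## GLMM (logit link, random cell intercept) fitted by maximum marginal
## likelihood with adaptive Gauss-Hermite quadrature, Wald F tests with
## containment denominator df, dispersion diagnostic, and Pearson
## correlations among estimation methods.

#' Smithson-Verkuilen boundary transformation
#'
#' `y' = (y * (n - 1) + 0.5) / n` squeezes exact 0s and 1s half a detection
#' limit inside the unit interval, so a beta likelihood applies; `n` is the
#' number of points or pixels behind the proportion.
#'
#' @param y Proportions in `[0, 1]`.
#' @param n Positive integer count(s) behind each proportion.
#' @return Transformed values in `(0, 1)`.
#' @export
sv_transform <- function(y, n) {
  stopifnot(all(y >= 0 & y <= 1), all(n >= 1))
  (y * (n - 1) + 0.5) / n
}

#' @rdname sv_transform
#' @param y_prime Transformed values.
#' @export
sv_inverse <- function(y_prime, n) {
  stopifnot(all(n >= 1))
  (y_prime * n - 0.5) / (n - 1)
}

#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch eigen-decomposition of the Hermite Jacobi matrix, for the
#' weight function `exp(-z^2)`.
#'
#' @param k Number of nodes.
#' @return List with `nodes` and `weights`.
#' @export
gauss_hermite <- function(k) {
  stopifnot(k >= 1)
  if (k == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(k - 1) / 2)
  J <- matrix(0, k, k)
  J[cbind(1:(k - 1), 2:k)] <- off
  J[cbind(2:k, 1:(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

## per-observation beta log-density terms and derivatives wrt the linear
## predictor eta (mean-precision parameterization); mu is clamped away from
## the boundary so extreme optimizer excursions stay finite
mu_of_eta <- function(eta) plogis(pmin(30, pmax(-30, eta)))
beta_ll <- function(y, eta, phi) {
  mu <- mu_of_eta(eta)
  dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}
beta_ll_d1 <- function(y, eta, phi) {
  mu <- mu_of_eta(eta)
  ystar <- qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  phi * (ystar - mustar) * mu * (1 - mu)
}
beta_ll_d2 <- function(y, eta, phi) {
  mu <- mu_of_eta(eta)
  ystar <- qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  w <- mu * (1 - mu)
  -phi^2 * (trigamma(mu * phi) + trigamma((1 - mu) * phi)) * w^2 +
    phi * (ystar - mustar) * w * (1 - 2 * mu)
}

## marginal log-likelihood by adaptive GH quadrature; cells indexed 1..m.
## b_init warm-starts the inner Newton (successive optimizer calls move
## theta little, so the previous modes are an excellent start).
agq_loglik <- function(theta, y, X, cell, gh, return_modes = FALSE,
                       b_init = NULL) {
  p <- ncol(X)
  beta <- theta[1:p]
  sigma2 <- exp(theta[p + 1])
  phi <- exp(theta[p + 2])
  m <- max(cell)
  off <- as.vector(X %*% beta)
  joint_val <- function(b) {
    rowsum(beta_ll(y, off + b[cell], phi), cell)[, 1] - b^2 / (2 * sigma2)
  }
  # inner Newton with per-cell backtracking for the conditional modes b-hat
  b <- if (is.null(b_init)) numeric(m) else b_init
  jv <- joint_val(b)
  if (any(!is.finite(jv))) { b <- numeric(m); jv <- joint_val(b) }
  for (it in 1:100) {
    eta <- off + b[cell]
    g1 <- rowsum(beta_ll_d1(y, eta, phi), cell)[, 1] - b / sigma2
    g2 <- rowsum(beta_ll_d2(y, eta, phi), cell)[, 1] - 1 / sigma2
    g2 <- pmin(g2, -1e-8)
    step <- -g1 / g2                      # ascent direction (g2 < 0)
    step <- pmax(pmin(step, 10), -10)
    t_ <- rep(1, m)
    for (h in 1:12) {
      jv_try <- joint_val(b + t_ * step)
      worse <- !is.finite(jv_try) | jv_try < jv - 1e-12
      if (!any(worse)) break
      t_[worse] <- t_[worse] / 2
    }
    b_new <- b + t_ * step
    jv <- joint_val(b_new)
    if (max(abs(b_new - b)) < 1e-9) { b <- b_new; break }
    b <- b_new
  }
  eta <- off + b[cell]
  h <- -(rowsum(beta_ll_d2(y, eta, phi), cell)[, 1] - 1 / sigma2)  # > 0
  h <- pmax(h, 1e-8)
  tau <- 1 / sqrt(h)
  K <- length(gh$nodes)
  # log integrand at shifted/scaled nodes, cells x nodes
  lg <- matrix(0, m, K)
  for (k in seq_len(K)) {
    bk <- b + sqrt(2) * tau * gh$nodes[k]
    etak <- off + bk[cell]
    joint <- rowsum(beta_ll(y, etak, phi), cell)[, 1] -
      bk^2 / (2 * sigma2) - 0.5 * log(2 * pi * sigma2)
    lg[, k] <- joint + gh$nodes[k]^2 + log(gh$weights[k])
  }
  mx <- apply(lg, 1, max)
  li <- mx + log(rowSums(exp(lg - mx))) + 0.5 * log(2) + log(tau)
  if (return_modes) return(list(loglik = sum(li), modes = b, tau = tau))
  structure(sum(li), modes = b)
}

#' Fit a beta GLMM with logit link and a random cell intercept
#'
#' `logit(mu_ij) = x_ij' beta + b_i`, `y_ij ~ Beta(mu_ij phi, (1-mu_ij) phi)`,
#' `b_i ~ N(0, sigma2_cell)`. Maximum marginal likelihood with per-cell
#' adaptive Gauss-Hermite quadrature; quasi-Newton (BFGS) on
#' `(beta, log sigma2, log phi)` from the fixed start `beta = 0,
#' sigma2 = 0.5, phi = 10`. Standard errors come from the observed
#' information at the optimum. The Wald F for the fixed factor uses the
#' containment-style denominator df `N - n_cells - (p - 1)` (182 for the
#' default 276-observation, 92-cell design with a 3-level factor).
#'
#' @param data Data frame with one row per observation.
#' @param response Name of the column holding the (already SV-transformed)
#'   proportions, strictly inside (0, 1).
#' @param fixed Name of the fixed-factor column (a factor; its first level is
#'   the baseline).
#' @param cell Name of the cell-identifier column.
#' @param quadrature_nodes Number of Gauss-Hermite nodes (default 15).
#' @param max_iter Optimizer iteration cap.
#' @return A `beta_glmm` fit: coefficient table, `sigma2_cell` (+SE), `phi`,
#'   `loglik`, Wald `F` test, `dispersion` (Pearson chi-square / df on
#'   conditional residuals), residuals, and convergence info.
#' @export
fit_beta_glmm <- function(data, response = "y", fixed, cell = "cell_id",
                          quadrature_nodes = 15L, max_iter = 500L) {
  y <- data[[response]]
  if (is.null(y)) stop("response column not found")
  if (any(y <= 0 | y >= 1)) {
    stop("responses must be strictly inside (0,1); apply sv_transform() first")
  }
  f <- data[[fixed]]
  if (!is.factor(f)) f <- factor(f)
  if (anyNA(f)) stop("missing values in the fixed factor")
  cid <- factor(data[[cell]])
  cells <- as.integer(cid)
  X <- stats::model.matrix(~f)
  colnames(X) <- c("(Intercept)", paste0(fixed, levels(f)[-1]))
  p <- ncol(X)
  N <- length(y)
  m <- nlevels(cid)
  gh <- gauss_hermite(quadrature_nodes)
  b_warm <- NULL
  nll <- function(th) {
    v <- suppressWarnings(
      tryCatch(agq_loglik(th, y, X, cells, gh, b_init = b_warm),
               error = function(e) NA))
    if (!is.finite(v)) return(1e10)
    b_warm <<- attr(v, "modes")
    -as.numeric(v)
  }
  start <- c(rep(0, p), log(0.5), log(10))
  ll0 <- -nll(start)
  ctrl <- list(maxit = max_iter, reltol = 1e-12,
               ndeps = rep(1e-5, length(start)))
  opt <- optim(start, nll, method = "BFGS", control = ctrl)
  # one polishing restart: BFGS curvature resets, helping boundary-ish fits
  opt2 <- optim(opt$par, nll, method = "BFGS", control = ctrl)
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0) {
    stop(sprintf("beta GLMM did not converge (optim code %d): %s",
                 opt$convergence, paste(opt$message, collapse = " ")))
  }
  th <- opt$par
  H <- optimHess(th, nll)
  V <- tryCatch(solve(H), error = function(e) {
    warning("singular information matrix; SEs from pseudo-inverse")
    ev <- eigen(H, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    ev$vectors[, pos, drop = FALSE] %*%
      diag(1 / ev$values[pos], sum(pos)) %*% t(ev$vectors[, pos, drop = FALSE])
  })
  beta <- th[1:p]
  sigma2 <- exp(th[p + 1]); phi <- exp(th[p + 2])
  se_beta <- sqrt(pmax(0, diag(V)[1:p]))
  se_sigma2 <- sigma2 * sqrt(max(0, V[p + 1, p + 1]))  # delta method
  se_phi <- phi * sqrt(max(0, V[p + 2, p + 2]))
  boundary <- sigma2 < 1e-6
  if (boundary) warning("sigma2_cell at the boundary (~0)")
  # Wald F for the fixed factor
  df2 <- N - m - (p - 1)
  Fstat <- p_value <- NA_real_
  if (p > 1) {
    L <- cbind(matrix(0, p - 1, 1), diag(p - 1))
    Vb <- V[1:p, 1:p, drop = FALSE]
    lb <- L %*% beta
    Fstat <- drop(t(lb) %*% solve(L %*% Vb %*% t(L)) %*% lb) / (p - 1)
    if (df2 >= 1) {
      p_value <- pf(Fstat, p - 1, df2, lower.tail = FALSE)
    } else {
      warning("no denominator df left for the Wald F (too few cells)")
    }
  }
  # conditional residuals and dispersion at the optimum
  md <- agq_loglik(th, y, X, cells, gh, return_modes = TRUE)
  eta <- as.vector(X %*% beta) + md$modes[cells]
  mu <- plogis(eta)
  v <- mu * (1 - mu) / (1 + phi)
  pearson <- (y - mu) / sqrt(v)
  chisq <- sum(pearson^2)
  # containment df: the conditional modes absorb about one df per cell
  disp <- if (df2 >= 1) chisq / df2 else NA_real_
  coef_tab <- tibble::tibble(term = colnames(X), estimate = beta,
                             se = se_beta)
  structure(list(
    coefficients = coef_tab,
    sigma2_cell = sigma2, sigma2_cell_se = se_sigma2,
    phi = phi, phi_se = se_phi,
    loglik = -opt$value, loglik_start = ll0,
    F_test = list(statistic = Fstat, df1 = p - 1, df2 = df2,
                  p_value = p_value),
    dispersion = disp,
    residuals = list(pearson = pearson,
                     studentized = pearson / sqrt(pmax(1e-12, 1 - p / N))),
    fitted = mu, modes = md$modes,
    boundary = boundary, theta = th, vcov = V,
    n_obs = N, n_cells = m, fixed = fixed,
    levels = levels(f), quadrature_nodes = quadrature_nodes),
    class = "beta_glmm")
}

#' @export
print.beta_glmm <- function(x, ...) {
  cat(sprintf("Beta GLMM (logit link, random cell intercept), %d obs / %d cells\n",
              x$n_obs, x$n_cells))
  print(as.data.frame(x$coefficients), digits = 4)
  cat(sprintf("sigma2_cell = %.4f +/- %.4f   phi = %.3f\n",
              x$sigma2_cell, x$sigma2_cell_se, x$phi))
  if (!is.na(x$F_test$statistic)) {
    cat(sprintf("%s: F_%d,%d = %.2f, P = %.4g\n", x$fixed, x$F_test$df1,
                x$F_test$df2, x$F_test$statistic, x$F_test$p_value))
  }
  cat(sprintf("Pearson chi-square / DF = %.3f   logLik = %.2f\n",
              x$dispersion, x$loglik))
  invisible(x)
}

#' Simulate data from the beta GLMM
#'
#' Generator used for parameter-recovery and type-I-error studies: each of
#' `n_cells` cells is observed once per factor level.
#'
#' @param beta Fixed-effect vector (intercept first, treatment contrasts).
#' @param sigma2 Random-intercept variance.
#' @param phi Beta precision.
#' @param n_cells Number of cells.
#' @param n_levels Number of factor levels (length(beta) must equal it).
#' @param seed Integer seed.
#' @return Tibble with `cell_id`, `level` (factor) and `y`.
#' @export
simulate_beta_glmm <- function(beta, sigma2, phi, n_cells = 92L,
                               n_levels = length(beta), seed = 1L) {
  stopifnot(length(beta) == n_levels)
  set.seed(seed)
  b <- rnorm(n_cells, 0, sqrt(sigma2))
  lev <- factor(rep(seq_len(n_levels), each = n_cells))
  X <- stats::model.matrix(~lev)
  eta <- as.vector(X %*% beta) + rep(b, times = n_levels)
  mu <- plogis(eta)
  y <- rbeta(length(eta), mu * phi, (1 - mu) * phi)
  # guard against numerical 0/1 from rbeta at extreme mu
  y <- pmin(1 - 1e-12, pmax(1e-12, y))
  tibble::tibble(cell_id = rep(seq_len(n_cells), times = n_levels),
                 level = lev, y = y)
}

#' Pearson product-moment correlation between two per-cell series
#'
#' @param x,y Numeric vectors paired by cell (same length, >= 3, nonzero
#'   variance).
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("constant method: zero variance")
  sum((x - mean(x)) * (y - mean(y))) /
    ((length(x) - 1) * sd(x) * sd(y))
}

#' Pairwise method correlations per cover class
#'
#' Pairs the per-cell proportions of each pair of methods (at one drone
#' altitude) and reports Pearson's r for every cover class.
#'
#' @param table A cover table containing the methods to compare.
#' @param altitude_m Drone altitude used for the drone methods.
#' @return Tibble with `class`, `method_a`, `method_b`, `r`, `n_cells`.
#' @export
method_correlations <- function(table, altitude_m = 75) {
  tab <- cover_table(table)
  keep <- tab$method == "ground" |
    (!is.na(tab$altitude_m) & tab$altitude_m == altitude_m)
  tab <- tab[keep, ]
  methods <- intersect(c("ground", "drone_transects", "drone_pixels"),
                       unique(tab$method))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  out <- list()
  for (cl in cover_class_names()) {
    sub <- tab[tab$class == cl, ]
    wide <- lapply(methods, function(mm) {
      s <- sub[sub$method == mm, ]
      s$proportion[order(s$cell_id)]
    })
    names(wide) <- methods
    for (pr in pairs) {
      out[[length(out) + 1L]] <- tibble::tibble(
        class = cl, method_a = pr[1], method_b = pr[2],
        r = pearson_r(wide[[pr[1]]], wide[[pr[2]]]),
        n_cells = length(wide[[pr[1]]]))
    }
  }
  do.call(rbind, out)
}

#' Altitude- and method-comparison beta GLMMs over a cover table
#'
#' The full model suite: per drone method (pixel counts, transects), a model
#' per cover class with altitude as the fixed factor (baseline = lowest
#' altitude); and, at the reference altitude, a model per cover class with
#' method as the fixed factor (baseline = ground transects). Responses are
#' SV-transformed per cell using that row's `n`. Fixed-effect estimates are
#' also back-transformed (inverse logit) to the proportion scale.
#'
#' @param table A cover table with all three methods.
#' @param reference_altitude_m Altitude of the drone data entering the method
#'   models (default 75).
#' @param quadrature_nodes Gauss-Hermite nodes per fit.
#' @return A `method_comparison` list: `fits` (named list of `beta_glmm`),
#'   `coefficients` (long tibble), `f_tests`, `estimates` (back-transformed
#'   per level), `correlations`, and `skipped` (model families dropped for
#'   missing levels, with a notice).
#' @export
method_comparison_report <- function(table, reference_altitude_m = 75,
                                     quadrature_nodes = 15L) {
  tab <- cover_table(table)
  tab$y <- sv_transform(tab$proportion, tab$n)
  fits <- list(); skipped <- character(0)
  altitudes <- sort(unique(tab$altitude_m[!is.na(tab$altitude_m)]))
  # altitude models, one per drone method x cover class
  for (mm in c("drone_pixels", "drone_transects")) {
    sub_m <- tab[tab$method == mm & !is.na(tab$altitude_m), ]
    if (length(unique(sub_m$altitude_m)) < 2) {
      skipped <- c(skipped, sprintf("altitude:%s (needs >= 2 altitudes)", mm))
      next
    }
    for (cl in cover_class_names()) {
      sub <- sub_m[sub_m$class == cl, ]
      sub$altitude <- factor(sub$altitude_m, levels = altitudes)
      fits[[sprintf("altitude|%s|%s", mm, cl)]] <-
        fit_beta_glmm(sub, response = "y", fixed = "altitude",
                      quadrature_nodes = quadrature_nodes)
    }
  }
  # method models at the reference altitude
  methods <- c("ground", "drone_pixels", "drone_transects")
  have <- vapply(methods, function(mm) any(
    tab$method == mm & (mm == "ground" | (!is.na(tab$altitude_m) &
                                            tab$altitude_m == reference_altitude_m))), TRUE)
  if (!all(have)) {
    stop("missing method level(s): ", paste(methods[!have], collapse = ", "))
  }
  for (cl in cover_class_names()) {
    sub <- tab[tab$class == cl &
                 (tab$method == "ground" |
                    (!is.na(tab$altitude_m) &
                       tab$altitude_m == reference_altitude_m)), ]
    sub$method_f <- factor(sub$method, levels = methods)
    fits[[sprintf("method|%dm|%s", reference_altitude_m, cl)]] <-
      fit_beta_glmm(sub, response = "y", fixed = "method_f",
                    quadrature_nodes = quadrature_nodes)
  }
  coefs <- do.call(rbind, lapply(names(fits), function(nm) {
    ft <- fits[[nm]]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    cbind(tibble::tibble(family = parts[1], subset = parts[2],
                         class = parts[3]),
          ft$coefficients,
          tibble::tibble(sigma2_cell = ft$sigma2_cell,
                         sigma2_cell_se = ft$sigma2_cell_se,
                         dispersion = ft$dispersion))
  }))
  f_tests <- do.call(rbind, lapply(names(fits), function(nm) {
    ft <- fits[[nm]]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    tibble::tibble(family = parts[1], subset = parts[2], class = parts[3],
                   F = ft$F_test$statistic, df1 = ft$F_test$df1,
                   df2 = ft$F_test$df2, p_value = ft$F_test$p_value)
  }))
  estimates <- do.call(rbind, lapply(names(fits), function(nm) {
    ft <- fits[[nm]]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    b <- ft$coefficients$estimate
    eta <- c(b[1], b[1] + b[-1])
    tibble::tibble(family = parts[1], subset = parts[2], class = parts[3],
                   level = ft$levels, proportion = plogis(eta))
  }))
  corr <- tryCatch(method_correlations(tab, reference_altitude_m),
                   error = function(e) NULL)
  if (length(skipped)) {
    message("skipped model families: ", paste(skipped, collapse = "; "))
  }
  structure(list(fits = fits, coefficients = coefs, f_tests = f_tests,
                 estimates = estimates, correlations = corr,
                 skipped = skipped,
                 reference_altitude_m = reference_altitude_m),
            class = "method_comparison")
}

#' Write a method-comparison report to CSV + text
#'
#' @param report A `method_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_method_comparison <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$coefficients, file.path(dir, "glmm_coefficients.csv"),
            row.names = FALSE)
  write.csv(report$f_tests, file.path(dir, "glmm_f_tests.csv"),
            row.names = FALSE)
  write.csv(report$estimates, file.path(dir, "glmm_estimates.csv"),
            row.names = FALSE)
  if (!is.null(report$correlations)) {
    write.csv(report$correlations, file.path(dir, "method_correlations.csv"),
              row.names = FALSE)
  }
  txt <- c("Beta GLMM method/altitude comparison",
           sprintf("reference altitude: %g m", report$reference_altitude_m),
           "", utils::capture.output(print(as.data.frame(report$f_tests))))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
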