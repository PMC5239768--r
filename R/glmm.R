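#' Standardize a predictor to zero mean and unit SD
#'
#' `(x - mean(x)) / sd(x)` with the sample SD, so vegetation measures on very
#' different scales become comparable as mixed-model predictors.
#'
#' @param x Numeric vector.
#' @param name Variable name used in error messages.
#' @return Standardized vector.
#' @examples
#' standardize(c(1, 2, 3))  # -1 0 1
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  if (anyNA(x)) stop("'", name, "' has missing values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize constant variable '", name, "'")
  (x - mean(x)) / s
}

#' Negative-binomial mixed model of a community metric on vegetation
#'
#' Fits a negative-binomial GLMM (log link) of a per-trap count metric on a
#' set of standardized vegetation predictors with a random intercept for
#' plot, accounting for the repeated traps within each plot. Estimation is by
#' Laplace-approximate maximum likelihood (via glmmTMB's `nbinom2` family,
#' whose dispersion parameter matches the NB `theta` used elsewhere in the
#' package).
#'
#' @param response Non-negative integer counts, one per trap.
#' @param predictors data.frame or matrix of standardized predictors
#'   (typically the eight vegetation measures). A warning is issued if a
#'   column is visibly unstandardized.
#' @param plot Plot identifier per trap (the random-intercept grouping).
#' @return Object of class `nb_glmm`: `coefficients` (data.frame term,
#'   estimate, se, z, p), `plot_sd`, `theta`, `loglik`, `converged`,
#'   `boundary` (TRUE when the random-intercept SD collapsed to ~0),
#'   `model`.
#' @export
fit_nb_glmm <- function(response, predictors, plot) {
  check_counts(response)
  predictors <- as.data.frame(predictors)
  if (length(unique(plot)) < 2) stop("need >= 2 plots for a random intercept")
  if (nrow(predictors) != length(response) ||
      length(plot) != length(response))
    stop("response, predictors and plot must have matching lengths")
  bad <- vapply(predictors, function(v)
    abs(mean(v)) > 0.01 || abs(stats::sd(v) - 1) > 0.1, TRUE)
  if (any(bad))
    warning("predictor(s) not standardized: ",
            paste(names(predictors)[bad], collapse = ", "))

  dat <- data.frame(.y = response, predictors, .plot = factor(plot))
  fml <- stats::reformulate(c(colnames(predictors), "(1 | .plot)"),
                            response = ".y")
  fit <- glmmTMB::glmmTMB(fml, data = dat, family = glmmTMB::nbinom2())

  co <- summary(fit)$coefficients$cond
  vc <- glmmTMB::VarCorr(fit)$cond$.plot
  plot_sd <- attr(vc, "stddev")[[1]]
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], z = co[, 3], p = co[, 4],
                              row.names = NULL),
    plot_sd = plot_sd,
    theta = glmmTMB::sigma(fit),
    loglik = as.numeric(stats::logLik(fit)),
    converged = isTRUE(fit$fit$convergence == 0) &&
      isTRUE(fit$sdr$pdHess),
    boundary = plot_sd < 1e-3,
    model = fit
  ), class = "nb_glmm")
}

#' Moran's I permutation test for residual spatial autocorrelation
#'
#' Computes Moran's I for model residuals at the sampling coordinates with
#' inverse-distance (or k-nearest-neighbour), row-standardized spatial
#' weights, and tests it two-sidedly against `E[I] = -1/(n-1)` by a Monte
#' Carlo permutation of the residuals over the fixed coordinates.
#'
#' @param residuals Model residuals, one per location.
#' @param coords Two-column matrix/data.frame of coordinates (same units in
#'   both axes); duplicated coordinates make inverse-distance weights
#'   undefined and raise an error.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @param weights `"inverse_distance"` (default) or `"knn"`.
#' @param k Neighbour count for `weights = "knn"`.
#' @return Object of class `moran_test`: `I`, `expected` (-1/(n-1)),
#'   `p_value`, `n_perm`, `weights`.
#' @export
morans_i_test <- function(residuals, coords, n_perm = 1000, seed = NULL,
                          weights = c("inverse_distance", "knn"), k = 4) {
  weights <- match.arg(weights)
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (n < 4) stop("need >= 4 locations")
  if (nrow(coords) != n || ncol(coords) != 2)
    stop("coords must be an n x 2 matrix")
  D <- as.matrix(stats::dist(coords))
  if (any(D[upper.tri(D)] == 0))
    stop("coincident coordinates: inverse-distance weight undefined")
  if (!is.null(seed)) set.seed(seed)

  if (weights == "inverse_distance") {
    W <- 1 / D
    diag(W) <- 0
  } else {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(k + 1)]
      W[i, nb] <- 1
    }
  }
  W <- W / rowSums(W)

  moran_i <- function(x) {
    z <- x - mean(x)
    (n / sum(W)) * sum(W * tcrossprod(z)) / sum(z^2)
  }
  I_obs <- moran_i(residuals)
  E_I <- -1 / (n - 1)
  I_perm <- vapply(seq_len(n_perm), function(b)
    moran_i(residuals[sample.int(n)]), 0.0)
  p <- (1 + sum(abs(I_perm - E_I) >= abs(I_obs - E_I) - 1e-12)) / (n_perm + 1)

  structure(list(I = I_obs, expected = E_I, p_value = p, n_perm = n_perm,
                 weights = weights),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), p = %.4g (%d permutations)\n",
              x$I, x$expected, x$p_value, x$n_perm))
  invisible(x)
}
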