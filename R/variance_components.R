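# Step II: maximum-likelihood variance components via the delta
# reparameterization, and the spectral rotation that whitens the
# mixed-model covariance sigma_u^2 * K + sigma_e^2 * I.

# Floor applied to gamma_i + delta before inversion; guards rank-deficient
# relationship matrices (p < n, duplicated samples).
.EIG_FLOOR <- 1e-10

#' Genomic relationship matrix
#'
#' Sample-by-sample relationship `K = W W' / p` from the column-standardized
#' genotype matrix `W` (each variant centered and scaled to unit variance).
#' Monomorphic variants carry no relatedness information and are dropped
#' from the computation with a warning.
#'
#' @param data A [genotype_dataset] (imputed) or a numeric dosage matrix.
#'
#' @return Symmetric positive semi-definite `n x n` matrix.
#' @export
genomic_relationship_matrix <- function(data) {
  x <- if (inherits(data, "genotype_dataset")) data$genotypes else as.matrix(data)
  if (anyNA(x)) stop("genotypes contain missing calls; impute first",
                     call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    stop("all variants are monomorphic; relationship matrix undefined",
         call. = FALSE)
  }
  if (!all(keep)) {
    warning(sum(!keep), " monomorphic variant(s) dropped from the ",
            "relationship matrix", call. = FALSE)
  }
  w <- scale(x[, keep, drop = FALSE])
  k <- tcrossprod(w) / sum(keep)
  (k + t(k)) / 2
}

#' Spectral decomposition of a relationship matrix
#'
#' Eigendecomposition `K = V diag(gamma) V'` with eigenvalues in descending
#' order; tiny negative eigenvalues from floating-point noise are clamped
#' to zero.
#'
#' @param k Symmetric `n x n` matrix.
#'
#' @return List with `gamma` (length-n eigenvalues, descending) and
#'   `rotation` (orthogonal `n x n` matrix `V`).
#' @export
spectral_decompose <- function(k) {
  k <- as.matrix(k)
  if (!all(is.finite(k))) stop("relationship matrix has non-finite entries",
                               call. = FALSE)
  if (max(abs(k - t(k))) > 1e-8 * max(1, max(abs(k)))) {
    stop("relationship matrix is not symmetric", call. = FALSE)
  }
  e <- eigen((k + t(k)) / 2, symmetric = TRUE)
  list(gamma = pmax(e$values, 0), rotation = e$vectors)
}

# Components that carry no information about delta: eigenvalue and rotated
# residual both (numerically) zero.  The standardized relationship matrix
# always has such a component along the constant vector (centering), and its
# log(gamma + delta) term would otherwise push the likelihood without bound
# as delta -> 0.
.degenerate_components <- function(r, gamma) {
  gamma < 1e-8 * max(gamma, 1) & abs(r) < 1e-8 * sqrt(sum(r^2))
}

# Profile log-likelihood of the rotated residual at a given delta, over the
# informative components; profiled sigma_u^2 = mean(r_i^2 / (gamma_i + delta)).
.profile_loglik <- function(log10_delta, r, gamma) {
  delta <- 10^log10_delta
  m <- length(r)
  d <- pmax(gamma + delta, .EIG_FLOOR)
  s2 <- sum(r^2 / d) / m
  -0.5 * (m * log(2 * pi) + m * log(s2) + sum(log(d)) + m)
}

#' Estimate variance components by profile maximum likelihood
#'
#' Fits the Gaussian model `y' - mean(y') ~ N(0, sigma_u^2 K + sigma_e^2 I)`
#' by maximizing over `delta = sigma_e^2 / sigma_u^2`: given the spectral
#' factors of `K`, the likelihood is a one-dimensional function of
#' `log10(delta)`, scanned on a grid over `[-5, 5]` (101 points) and refined
#' by golden-section search.  Given `delta`, the genetic variance has the
#' closed form `sigma_u^2 = mean(r_i^2 / (gamma_i + delta))` where the
#' rotated centered residual is `V'(y' - mean(y'))`.
#'
#' @param y_resid Residual phenotype from [residualize_phenotype()].
#' @param gamma,rotation Spectral factors from [spectral_decompose()].
#' @param grid_points Number of grid points over `log10(delta) in [-5, 5]`.
#' @param tol Relative tolerance of the golden-section refinement.
#'
#' @return An object of class `variance_components`: `sigma_u2`, `sigma_e2`,
#'   `delta`, `gamma`, `rotation`, `log_likelihood`.
#' @export
fit_delta <- function(y_resid, gamma, rotation, grid_points = 101L,
                      tol = 1e-4) {
  y_resid <- as.numeric(y_resid)
  n <- length(y_resid)
  stopifnot(length(gamma) == n, nrow(rotation) == n, ncol(rotation) == n)
  r_full <- as.numeric(crossprod(rotation, y_resid - mean(y_resid)))
  drop <- .degenerate_components(r_full, gamma)
  r <- r_full[!drop]
  gamma_used <- gamma[!drop]
  grid <- seq(-5, 5, length.out = grid_points)
  if (diff(range(gamma_used)) < 1e-12 * max(1, max(abs(gamma_used)))) {
    warning("all eigenvalues equal: delta is unidentifiable, only the total ",
            "variance is estimated; delta fixed at the grid midpoint",
            call. = FALSE)
    best <- grid[(grid_points + 1L) %/% 2L]
  } else {
    ll <- vapply(grid, .profile_loglik, numeric(1), r = r,
                 gamma = gamma_used)
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(grid_points, i + 1L)]
    best <- .golden_section(function(x) .profile_loglik(x, r, gamma_used),
                            lo, hi, tol = tol)
    # guard: never return less than the best grid point
    if (.profile_loglik(best, r, gamma_used) < ll[i]) best <- grid[i]
  }
  delta <- 10^best
  d <- pmax(gamma_used + delta, .EIG_FLOOR)
  sigma_u2 <- sum(r^2 / d) / length(r)
  structure(
    list(sigma_u2 = sigma_u2, sigma_e2 = delta * sigma_u2, delta = delta,
         gamma = gamma, rotation = rotation,
         log_likelihood = .profile_loglik(best, r, gamma_used)),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>\n",
      "  sigma_u^2 = ", signif(x$sigma_u2, 5),
      ", sigma_e^2 = ", signif(x$sigma_e2, 5),
      ", delta = ", signif(x$delta, 5), "\n",
      "  profile log-likelihood = ", signif(x$log_likelihood, 8), "\n",
      sep = "")
  invisible(x)
}

# Golden-section maximization of f on [lo, hi] to relative x tolerance tol.
.golden_section <- function(f, lo, hi, tol = 1e-4, max_iter = 200L) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(max_iter)) {
    if (abs(b - a) <= tol * max(1, abs(a) + abs(b))) break
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  if (f1 >= f2) x1 else x2
}

#' Rotate genotypes and residual phenotype
#'
#' Applies the whitening transform
#' `(diag(gamma) + delta I)^(-1/2) V'` to the candidate genotype columns and
#' the residual phenotype.  Under the fitted model the transformed residual
#' has isotropic covariance `sigma_u^2 I`, so ordinary sparse regression
#' machinery applies afterwards.
#'
#' @param data A [genotype_dataset] or numeric matrix.
#' @param y_resid Residual phenotype.
#' @param vc A [fit_delta()] result.
#' @param columns Optional integer vector restricting which genotype columns
#'   are rotated (e.g. the candidate, non-known variants).
#'
#' @return An object of class `rotated_data`: `x_rot` (n x p'), `y_rot`,
#'   `columns` (the original column indices), `delta`.
#' @export
rotate_data <- function(data, y_resid, vc, columns = NULL) {
  stopifnot(inherits(vc, "variance_components"))
  x <- if (inherits(data, "genotype_dataset")) data$genotypes else as.matrix(data)
  if (is.null(columns)) columns <- seq_len(ncol(x))
  d <- 1 / sqrt(pmax(vc$gamma + vc$delta, .EIG_FLOOR))
  vt <- t(vc$rotation)
  x_rot <- d * (vt %*% x[, columns, drop = FALSE])
  y_rot <- d * as.numeric(vt %*% as.numeric(y_resid))
  structure(
    list(x_rot = x_rot, y_rot = y_rot, columns = as.integer(columns),
         delta = vc$delta),
    class = "rotated_data"
  )
}
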