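# Step I: fit the known (strong) variants jointly by OLS, take the
# phenotype residual forward, and provide the Wald-scan fallback used when
# no prior file is available.

#' Fit fixed effects of the known variants
#'
#' Joint ordinary-least-squares fit of the phenotype on the known-variant
#' dosages plus an intercept.  The fitted coefficients quantify the strong
#' effects that the later sparse scan conditions on; the magnitude-ordering
#' constraint of the model compares discovered coefficients against the
#' smallest of these.
#'
#' @param data A [genotype_dataset] (imputed).
#' @param y A [phenotype_vector] or numeric vector of length `n`.
#'   Case/control traits are used as 0/1 numeric: the linear machinery is
#'   applied unchanged.
#' @param known A [known_set].
#'
#' @return A list with `known` (the set with `coefficients` and `intercept`
#'   filled) and `effects`, an [effect_vector] over all `p` variants.
#' @export
fit_known_effects <- function(data, y, known) {
  stopifnot(inherits(data, "genotype_dataset"), inherits(known, "known_set"))
  y <- as.numeric(y)
  n <- nrow(data$genotypes)
  if (length(y) != n) stop("phenotype length does not match sample count",
                           call. = FALSE)
  if (length(known$indices) >= n) {
    stop("more known variants than samples; the OLS fit is underdetermined",
         call. = FALSE)
  }
  xk <- cbind(`(Intercept)` = 1, data$genotypes[, known$indices, drop = FALSE])
  qrx <- qr(xk)
  if (qrx$rank < ncol(xk)) {
    dropped <- qrx$pivot[(qrx$rank + 1):ncol(xk)]
    bad <- known$ids[dropped - 1L]  # offset for the intercept column
    stop("known-variant block is rank deficient; collinear variant(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrx, y)
  known$intercept <- unname(coefs[1])
  known$coefficients <- unname(coefs[-1])
  effects <- effect_vector(ncol(data$genotypes))
  effects$values[known$indices] <- known$coefficients
  effects$provenance[known$indices] <- "known"
  effects$support <- which(effects$values != 0)
  list(known = known, effects = effects)
}

#' Construct an effect vector
#'
#' Sparse coefficient vector over all `p` variants with a per-variant
#' provenance flag (`"known"` for prior variants, `"discovered"` for
#' variants picked up by the sparse scan).
#'
#' @param p Number of variants.
#'
#' @return An object of class `effect_vector` with fields `values`,
#'   `support` and `provenance`.
#' @export
effect_vector <- function(p) {
  structure(
    list(values = numeric(p), support = integer(0),
         provenance = rep(NA_character_, p)),
    class = "effect_vector"
  )
}

#' Residualize the phenotype on the known variants
#'
#' Subtracts the fitted known-variant contribution (intercept included) from
#' the phenotype: `y' = y - b0 - sum_i X^i beta_i`.  With an empty known
#' set this reduces to mean-centering.  The residual is what the
#' variance-component step and the sparse scan see.
#'
#' @param y Phenotype (numeric or [phenotype_vector]).
#' @param data A [genotype_dataset].
#' @param known A fitted [known_set] (coefficients filled), or `NULL` for
#'   intercept-only.
#'
#' @return Numeric residual vector with mean (numerically) zero.
#' @export
residualize_phenotype <- function(y, data, known = NULL) {
  y <- as.numeric(y)
  if (is.null(known)) return(y - mean(y))
  stopifnot(inherits(known, "known_set"))
  if (anyNA(known$coefficients) || is.na(known$intercept)) {
    stop("known set has no fitted coefficients; run fit_known_effects() first",
         call. = FALSE)
  }
  fitted <- known$intercept +
    data$genotypes[, known$indices, drop = FALSE] %*% known$coefficients
  y - as.numeric(fitted)
}

#' Per-variant Wald scan
#'
#' Marginal simple linear regression of the phenotype on each variant with
#' an intercept.  The Wald statistic is `beta / se(beta)` with a two-sided
#' p-value from the t distribution on `n - 2` degrees of freedom;
#' Benjamini-Hochberg q-values control the FDR across variants.
#' Monomorphic variants get statistic 0 and p-value 1 and are flagged.
#'
#' @param data A [genotype_dataset] (imputed).
#' @param y Phenotype (numeric or [phenotype_vector]).
#'
#' @return A tibble with one row per variant: `index`, `id`, `chr`, `pos`,
#'   `statistic`, `p_value`, `q_value`, `monomorphic`.
#' @export
wald_scan <- function(data, y) {
  stopifnot(inherits(data, "genotype_dataset"))
  y <- as.numeric(y)
  n <- nrow(data$genotypes)
  if (n < 3) stop("Wald scan needs at least 3 samples", call. = FALSE)
  x <- data$genotypes
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  syy <- sum(yc^2)
  sxy <- as.numeric(crossprod(xc, yc))
  mono <- sxx <= .Machine$double.eps * n
  sxx_safe <- ifelse(mono, 1, sxx)
  beta <- sxy / sxx_safe
  sse <- pmax(syy - beta^2 * sxx_safe, 0)
  se <- sqrt(sse / (n - 2) / sxx_safe)
  stat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  stat[mono] <- 0
  pval <- 2 * stats::pt(-abs(stat), df = n - 2)
  pval[mono] <- 1
  tibble::tibble(
    index = seq_len(ncol(x)),
    id = data$variants$id,
    chr = data$variants$chr,
    pos = data$variants$pos,
    statistic = stat,
    p_value = pval,
    q_value = stats::p.adjust(pval, method = "BH"),
    monomorphic = mono
  )
}

#' Pick a prior set from a Wald scan
#'
#' Fallback when no known-association file is available: take the
#' `n_known` variants with the smallest p-values (ties broken by larger
#' absolute statistic, then chromosome/position) as the prior set.
#'
#' @param scan Tibble from [wald_scan()].
#' @param n_known Number of variants to select (at least 1).
#' @param data The [genotype_dataset] the scan came from.
#'
#' @return A [known_set()].
#' @export
select_prior_by_wald <- function(scan, n_known, data) {
  n_known <- as.integer(n_known)
  if (n_known < 1) stop("n_known must be at least 1", call. = FALSE)
  if (n_known > nrow(scan)) {
    stop("asked for ", n_known, " prior variants but only ", nrow(scan),
         " were scanned", call. = FALSE)
  }
  ord <- order(scan$p_value, -abs(scan$statistic), scan$chr, scan$pos)
  known_set(data, indices = scan$index[ord[seq_len(n_known)]])
}
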