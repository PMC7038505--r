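# The full CS-LMM pipeline: Step I (known-effect OLS), Step II (variance
# components + rotation), Step III (sparse scan with stability selection),
# assembled into one fitted object.

#' Fit a constrained sparse linear mixed model
#'
#' Conditions on a set of known, strongly associated variants to discover
#' additional variants with weaker coefficients while correcting for
#' population structure:
#'
#' 1. **Step I** - joint OLS fit of the known variants; the phenotype is
#'    residualized on their fitted contribution.
#' 2. **Step II** - variance components of the residual under the mixed
#'    model `y' ~ N(0, sigma_u^2 K + sigma_e^2 I)` via the
#'    `delta = sigma_e^2 / sigma_u^2` profile likelihood; genotypes and
#'    residual are rotated so the covariance becomes isotropic.
#' 3. **Step III** - L1-penalized multi-locus regression of the rotated
#'    residual on the rotated candidate (non-known) variants by proximal
#'    gradient descent, with the penalty either fixed (`lambda`) or
#'    searched to reach a requested support size (`target_k`), wrapped in
#'    stability selection over random half-subsamples.  Candidate dosages
#'    are standardized to unit variance before rotation so the shared
#'    penalty does not favour common variants over rare ones; reported
#'    coefficients are rescaled back to per-allele units.
#'
#' The model's magnitude-ordering constraint (every discovered coefficient
#' smaller than every known one) is checked post hoc and reported, not
#' enforced.
#'
#' @param data A [genotype_dataset]; imputed automatically if missing calls
#'   are present.
#' @param phenotype A [phenotype_vector] or numeric vector.  Case/control
#'   traits are used as 0/1 numeric.
#' @param known A [known_set], or `NULL` to use the Wald fallback.
#' @param target_k Requested number of discovered variants (exactly one of
#'   `target_k` / `lambda` must be given).
#' @param lambda Fixed penalty weight (see [lasso_pgd()] for the scale).
#' @param wald_fallback When `known` is `NULL`, the number of top Wald-scan
#'   variants to use as the prior set.
#' @param stability Run stability selection (default `TRUE`); when
#'   `FALSE` the discovered set is the plain Step III support.
#' @param stability_runs,subsample_fraction,threshold Stability-selection
#'   parameters (defaults 100, 0.5, 0.75).
#' @param seed Integer seed driving all subsampling.
#' @param tol,max_iter Optimizer controls passed to [lasso_pgd()].
#'
#' @return An object of class `cslmm_fit` with elements `known`, `vc`
#'   (variance components), `stability` (or `NULL`), `search` (penalty
#'   search result), `results` (ranked tibble), `violations` (indices
#'   failing the ordering check), `candidate_columns`, `call`.
#' @examples
#' sim <- simulate_gwas(simulation_config(n = 150, p = 300, seed = 7))
#' known <- known_set(sim$data, indices = sim$truth$causal_known)
#' fit <- cs_lmm(sim$data, sim$phenotype, known, target_k = 8,
#'               stability_runs = 10, seed = 7)
#' tidy(fit)
#' glance(fit)
#' @export
cs_lmm <- function(data, phenotype, known = NULL, target_k = NULL,
                   lambda = NULL, wald_fallback = NULL, stability = TRUE,
                   stability_runs = 100L, subsample_fraction = 0.5,
                   threshold = 0.75, seed = 1L, tol = 1e-6,
                   max_iter = 1000L) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (is.null(target_k) == is.null(lambda)) {
    stop("supply exactly one of target_k or lambda", call. = FALSE)
  }
  y <- as.numeric(phenotype)
  if (anyNA(data$genotypes)) data <- impute_missing_mode(data)
  if (is.null(known)) {
    if (is.null(wald_fallback)) {
      stop("no known-association set; supply `known` or set `wald_fallback`",
           call. = FALSE)
    }
    scan <- wald_scan(data, y)
    known <- select_prior_by_wald(scan, wald_fallback, data)
    message("Wald fallback prior: ", paste(known$ids, collapse = ", "))
  }

  step1 <- fit_known_effects(data, y, known)
  known <- step1$known
  y_resid <- residualize_phenotype(y, data, known)

  k_mat <- genomic_relationship_matrix(data)
  sp <- spectral_decompose(k_mat)
  vc <- fit_delta(y_resid, sp$gamma, sp$rotation)

  candidates <- setdiff(seq_len(ncol(data$genotypes)), known$indices)
  cand_sd <- apply(data$genotypes[, candidates, drop = FALSE], 2, stats::sd)
  if (any(cand_sd == 0)) {
    message(sum(cand_sd == 0), " monomorphic candidate variant(s) excluded ",
            "from the sparse scan")
    candidates <- candidates[cand_sd > 0]
    cand_sd <- cand_sd[cand_sd > 0]
  }
  # candidate dosages are standardized so the common L1 penalty weighs rare
  # and common variants equitably; coefficients are rescaled to per-allele
  # units for reporting
  xc <- scale(data$genotypes[, candidates, drop = FALSE])
  rot <- rotate_data(xc, y_resid, vc)
  rot$columns <- candidates

  search <- if (is.null(lambda)) {
    suppressWarnings(
      lambda_for_support(rot, target_k = target_k, tol = tol,
                         max_iter = max_iter)
    )
  } else {
    fit <- lasso_pgd(rot, lambda = lambda, tol = tol, max_iter = max_iter)
    list(lambda = lambda, fit = fit, support = which(fit$beta != 0),
         exact = NA, path = NULL)
  }

  stab <- NULL
  if (stability) {
    stab <- stability_select(
      rot, target_k = target_k, lambda = lambda, runs = stability_runs,
      subsample_fraction = subsample_fraction, threshold = threshold,
      seed = seed, tol = tol, max_iter = max_iter
    )
  } else {
    # plain Step III support presented through the same result shape
    sel <- search$support
    freq <- numeric(length(candidates))
    freq[sel] <- 1
    stab <- structure(
      list(frequencies = freq, selected = sel, runs = 0L,
           threshold = threshold, lambda_full = search$lambda,
           final_coefficients = stats::setNames(search$fit$beta[sel],
                                                as.character(sel)),
           full_fit = search$fit),
      class = "stability_result"
    )
  }
  # back to per-allele dosage units for reporting and the ordering check
  beta_dosage <- stab$full_fit$beta / cand_sd
  stab$final_coefficients <- stats::setNames(beta_dosage[stab$selected],
                                             as.character(stab$selected))
  violations <- suppressWarnings(
    check_magnitude_ordering(beta_dosage, known)
  )
  results <- assemble_result_table(known, stab, data,
                                   candidate_columns = candidates)
  structure(
    list(known = known, vc = vc, stability = stab, search = search,
         results = results, violations = violations,
         candidate_columns = candidates, seed = seed,
         n = nrow(data$genotypes), p = ncol(data$genotypes),
         call = match.call()),
    class = "cslmm_fit"
  )
}

#' @export
print.cslmm_fit <- function(x, ...) {
  cat("Constrained sparse linear mixed model fit\n")
  cat("  samples: ", x$n, ", variants: ", x$p, " (", length(x$known$indices),
      " known)\n", sep = "")
  cat("  delta = ", signif(x$vc$delta, 4), " (sigma_u^2 = ",
      signif(x$vc$sigma_u2, 4), ", sigma_e^2 = ",
      signif(x$vc$sigma_e2, 4), ")\n", sep = "")
  cat("  lambda = ", signif(x$stability$lambda_full, 4), ", discovered ",
      length(x$stability$selected), " variant(s)",
      if (x$stability$runs > 0)
        paste0(" stable over ", x$stability$runs, " runs"),
      "\n", sep = "")
  if (length(x$violations) > 0) {
    cat("  ! ", length(x$violations),
        " coefficient(s) violate the magnitude-ordering constraint\n",
        sep = "")
  }
  print(utils::head(x$results, 10))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the ranked result table of a CS-LMM fit
#'
#' @param x A `cslmm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per reported variant: `rank`, `snp`, `chr`,
#'   `pos`, `coef`, `maf`, `source`.
#' @export
tidy.cslmm_fit <- function(x, ...) {
  x$results
}

#' One-row model summary of a CS-LMM fit
#'
#' @param x A `cslmm_fit`.
#' @param ... Unused.
#' @return One-row tibble: sample/variant counts, variance components,
#'   penalty, discovery count, ordering-violation count, log-likelihood.
#' @export
glance.cslmm_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    p = x$p,
    n_known = length(x$known$indices),
    sigma_u2 = x$vc$sigma_u2,
    sigma_e2 = x$vc$sigma_e2,
    delta = x$vc$delta,
    log_likelihood = x$vc$log_likelihood,
    lambda = x$stability$lambda_full,
    n_discovered = length(x$stability$selected),
    n_ordering_violations = length(x$violations),
    stability_runs = x$stability$runs
  )
}

#' Plot stability-selection frequencies of a CS-LMM fit
#'
#' Selection frequency per candidate variant with the stability threshold
#' as a horizontal line; stable discoveries are highlighted.
#'
#' @param object A `cslmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cslmm_fit <- function(object, ...) {
  stab <- object$stability
  df <- tibble::tibble(
    candidate = seq_along(stab$frequencies),
    frequency = stab$frequencies,
    stable = seq_along(stab$frequencies) %in% stab$selected
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$candidate, y = .data$frequency,
                                   colour = .data$stable)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = stab$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "candidate variant", y = "selection frequency",
                  colour = "stable") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A [pr_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  subtitle = sprintf("auROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}
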