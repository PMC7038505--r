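# Discovery-performance scoring on simulated truth: methods are compared
# only on their ability to recover associated SNPs that are NOT already
# known, each selecting exactly K variants.

#' Score a selected variant set against simulation truth
#'
#' Known variants are removed from both the selection and the causal set
#' before scoring, so the metrics measure discovery of new associations
#' only.  Precision is `tp / |selected|`, recall is `tp / |causal|` over
#' the remaining causal set (with the tier-v causal SNPs as the known set,
#' the recall denominator is the weak tier-u causal set).
#'
#' @param selected Integer vector of selected SNP column indices.
#' @param truth A `simulation_truth`.
#' @param known Optional [known_set] or integer vector of known indices.
#'
#' @return One-row tibble: `precision`, `recall`, `true_positives`,
#'   `false_positives`, `n_selected`, `empty_selection`.
#' @export
score_selection <- function(selected, truth, known = NULL) {
  known_idx <- if (inherits(known, "known_set")) known$indices
               else as.integer(known)
  causal <- union(truth$causal_weak, setdiff(truth$causal_known, known_idx))
  selected <- setdiff(as.integer(selected), known_idx)
  tp <- length(intersect(selected, causal))
  fp <- length(selected) - tp
  empty <- length(selected) == 0
  tibble::tibble(
    precision = if (empty) 0 else tp / length(selected),
    recall = if (length(causal) == 0) NA_real_ else tp / length(causal),
    true_positives = tp,
    false_positives = fp,
    n_selected = length(selected),
    empty_selection = empty
  )
}

#' Area under the ROC curve by the rank-sum formulation
#'
#' Mann-Whitney statistic normalized by the number of positive-negative
#' pairs; tied scores share the mean rank, so a constant score gives 0.5.
#'
#' @param scores Numeric scores (higher = more likely associated).
#' @param labels Logical (or 0/1) truth labels, same length.
#'
#' @return Scalar in `[0, 1]`, or `NA` if a class is empty.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall curve over a candidate ranking
#'
#' Sweeps thresholds over the distinct score values (descending) and
#' records recall and precision of the set scoring at or above each
#' threshold; also reports the rank-sum auROC.  Known variants are excluded
#' from candidates and truth before the sweep.
#'
#' @param scores Numeric vector of per-SNP scores indexed by genotype
#'   column (e.g. stability frequencies or `|beta|`); higher means more
#'   strongly associated.
#' @param truth A `simulation_truth`.
#' @param known Optional [known_set] or integer vector of known indices.
#'
#' @return An object of class `pr_curve`: `curve` (tibble `threshold`,
#'   `recall`, `precision`, `n_selected`) and `auroc`.
#' @export
pr_curve <- function(scores, truth, known = NULL) {
  known_idx <- if (inherits(known, "known_set")) known$indices
               else as.integer(known)
  candidates <- setdiff(seq_along(scores), known_idx)
  causal <- union(truth$causal_weak, setdiff(truth$causal_known, known_idx))
  s <- scores[candidates]
  lab <- candidates %in% causal
  thresholds <- sort(unique(s), decreasing = TRUE)
  rows <- lapply(thresholds, function(t) {
    sel <- s >= t
    tp <- sum(lab & sel)
    tibble::tibble(
      threshold = t,
      recall = tp / sum(lab),
      precision = tp / sum(sel),
      n_selected = sum(sel)
    )
  })
  structure(
    list(curve = dplyr::bind_rows(rows), auroc = auroc(s, lab)),
    class = "pr_curve"
  )
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve> ", nrow(x$curve), " threshold(s), auROC = ",
      signif(x$auroc, 4), "\n", sep = "")
  invisible(x)
}

# Select exactly K variants with each method on one simulated dataset.
# Returns a named list of integer index vectors (original SNP columns).
.select_k_by_method <- function(sim, methods, target_k, tol = 1e-6,
                                max_iter = 1000L) {
  data <- sim$data
  y <- as.numeric(sim$phenotype)
  known_idx <- sim$truth$causal_known
  out <- list()
  if ("cs_lmm" %in% methods) {
    known <- known_set(data, indices = known_idx)
    step1 <- fit_known_effects(data, y, known)
    y_resid <- residualize_phenotype(y, data, step1$known)
    k_mat <- genomic_relationship_matrix(data)
    sp <- spectral_decompose(k_mat)
    vc <- fit_delta(y_resid, sp$gamma, sp$rotation)
    cand <- setdiff(seq_len(ncol(data$genotypes)), known_idx)
    cand_sd <- apply(data$genotypes[, cand, drop = FALSE], 2, stats::sd)
    cand <- cand[cand_sd > 0]
    xc <- scale(data$genotypes[, cand, drop = FALSE])
    rot <- rotate_data(xc, y_resid, vc)
    rot$columns <- cand
    k_disc <- max(1L, target_k - length(known_idx))
    search <- suppressWarnings(
      lambda_for_support(rot, target_k = k_disc, tol = tol,
                         max_iter = max_iter)
    )
    out$cs_lmm <- cand[search$support]
  }
  if ("lasso" %in% methods) {
    x <- data$genotypes
    sds <- apply(x, 2, stats::sd)
    keep <- which(sds > 0)
    xs <- scale(x[, keep, drop = FALSE])
    yc <- y - mean(y)
    search <- suppressWarnings(
      lambda_for_support(xs, yc, target_k = target_k, tol = tol,
                         max_iter = max_iter)
    )
    out$lasso <- keep[search$support]
  }
  if ("wald" %in% methods) {
    scan <- wald_scan(data, y)
    ord <- order(scan$p_value, -abs(scan$statistic), scan$chr, scan$pos)
    out$wald <- scan$index[ord[seq_len(target_k)]]
  }
  out
}

#' Benchmark CS-LMM against baseline selectors on simulated data
#'
#' Repeats the simulate/select/score cycle: each replicate simulates a
#' structured GWAS dataset, lets every method select exactly `k` variants
#' (the evaluation convention: no cross-validation, a fixed support size),
#' and scores discovery of the weak causal SNPs.  CS-LMM receives the
#' tier-v causal SNPs as its known set (its support target is reduced
#' accordingly so each method reports `k` variants in total); the baselines
#' receive no prior.  Baselines are the per-SNP Wald+BH scan (top `k` by
#' p-value) and the plain Lasso on standardized genotypes, both run through
#' the same machinery as the core method.
#'
#' @param config A [simulation_config()]; each replicate uses a seed
#'   derived from `config$seed` and the replicate index.
#' @param methods Subset of `c("cs_lmm", "lasso", "wald")`.
#' @param reps Number of simulation replicates (default 10).
#'
#' @return Tibble with columns `method`, `rep`, `realized_h2` and the
#'   [score_selection()] metrics, one row per method and replicate.
#' @export
benchmark_against_baselines <- function(config = simulation_config(),
                                        methods = c("cs_lmm", "lasso",
                                                    "wald"),
                                        reps = 10L) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (i in seq_len(reps)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, i)
    sim <- simulate_gwas(cfg_i)
    sel <- .select_k_by_method(sim, methods, target_k = config$k)
    for (m in names(sel)) {
      sc <- score_selection(sel[[m]], sim$truth,
                            known = sim$truth$causal_known)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(method = m, rep = i,
                       realized_h2 = sim$truth$realized_h2),
        sc
      )
    }
  }
  dplyr::bind_rows(rows)
}
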