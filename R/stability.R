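# Stability selection around the sparse scan: repeated half-subsampling,
# selection-frequency thresholding, and a full-data refit for the reported
# coefficients.

# Counter-based per-run seed so runs are order-independent and the whole
# procedure is reproducible from (seed, run index).  Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 1000003) * 2039 +
               (as.double(index) %% 104729) * 7919) %% 2147483629L + 1L
}

# Evaluate code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Stability selection for the sparse scan
#'
#' Runs the support-size search (or a fixed-penalty Lasso) on repeated
#' random half-subsamples of the rotated data and keeps the candidates
#' selected in strictly more than `threshold` of the runs.  Reported
#' coefficients come from a single full-data refit at the penalty chosen on
#' the full data, restricted to the stable set.
#'
#' @param x_rot,y_rot Rotated candidate design and response (or a
#'   `rotated_data` object as `x_rot`).
#' @param target_k Requested support size per run (see
#'   [lambda_for_support()]); ignored when `lambda` is given.
#' @param lambda Optional fixed penalty; when supplied each run fits
#'   [lasso_pgd()] at this value instead of searching.
#' @param runs Number of subsample runs (default 100).
#' @param subsample_fraction Fraction of samples drawn without replacement
#'   per run (default 0.5).
#' @param threshold Selection-frequency cutoff; a candidate is kept when
#'   its frequency is strictly greater (default 0.75).
#' @param seed Integer seed; each run derives its own stream from
#'   `(seed, run)`.
#' @param tol,max_iter Passed to the per-run fits.
#'
#' @return An object of class `stability_result`: `frequencies`,
#'   `selected` (candidate indices), `runs`, `threshold`, `lambda_full`,
#'   `final_coefficients` (named by candidate index, stable set only),
#'   `full_fit`.
#' @export
stability_select <- function(x_rot, y_rot = NULL, target_k = NULL,
                             lambda = NULL, runs = 100L,
                             subsample_fraction = 0.5, threshold = 0.75,
                             seed = 1L, tol = 1e-6, max_iter = 1000L) {
  if (inherits(x_rot, "rotated_data")) {
    y_rot <- x_rot$y_rot
    x_rot <- x_rot$x_rot
  }
  runs <- as.integer(runs)
  if (runs < 1) stop("runs must be at least 1", call. = FALSE)
  if (subsample_fraction <= 0 || subsample_fraction >= 1) {
    stop("subsample_fraction must be in (0, 1)", call. = FALSE)
  }
  if (is.null(target_k) && is.null(lambda)) {
    stop("supply target_k or lambda", call. = FALSE)
  }
  n <- nrow(x_rot)
  p <- ncol(x_rot)
  m <- floor(n * subsample_fraction)
  if (m < 3) stop("subsample of ", m, " samples is too small (need >= 3)",
                  call. = FALSE)
  y <- as.numeric(y_rot)

  counts <- integer(p)
  for (r in seq_len(runs)) {
    idx <- with_seed(derive_seed(seed, r), sample.int(n, m))
    xs <- x_rot[idx, , drop = FALSE]
    ys <- y[idx]
    support <- if (is.null(lambda)) {
      suppressWarnings(
        lambda_for_support(xs, ys, target_k = min(target_k, ncol(xs)),
                           tol = tol, max_iter = max_iter)$support
      )
    } else {
      which(lasso_pgd(xs, ys, lambda = lambda, tol = tol,
                      max_iter = max_iter)$beta != 0)
    }
    counts[support] <- counts[support] + 1L
  }
  freq <- counts / runs
  selected <- which(freq > threshold)

  if (is.null(lambda)) {
    full <- suppressWarnings(
      lambda_for_support(x_rot, y, target_k = target_k, tol = tol,
                         max_iter = max_iter)
    )
    lambda_full <- full$lambda
    full_fit <- full$fit
  } else {
    lambda_full <- lambda
    full_fit <- lasso_pgd(x_rot, y, lambda = lambda, tol = tol,
                          max_iter = max_iter)
  }
  final <- full_fit$beta[selected]
  names(final) <- as.character(selected)
  structure(
    list(frequencies = freq, selected = selected, runs = runs,
         threshold = threshold, lambda_full = lambda_full,
         final_coefficients = final, full_fit = full_fit),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result> ", x$runs, " runs, threshold ", x$threshold,
      ": ", length(x$selected), " stable candidate(s)\n", sep = "")
  invisible(x)
}

#' Assemble the ranked result table
#'
#' Combines the known variants (Step I coefficients) with the stable
#' discoveries (full-data refit coefficients) into a single table ranked by
#' absolute coefficient, the format of the final association report.
#'
#' @param known Fitted [known_set].
#' @param stab A [stability_select()] result over the candidate columns.
#' @param data The [genotype_dataset] (imputed; used for metadata and MAFs).
#' @param candidate_columns Integer vector mapping candidate indices (the
#'   columns of the rotated design) back to columns of `data`.  Defaults to
#'   all columns not in the known set.
#'
#' @return A tibble with columns `rank`, `snp`, `chr`, `pos`, `coef`,
#'   `maf`, `source`, sorted by `|coef|` descending (ties by chromosome
#'   then position).
#' @export
assemble_result_table <- function(known, stab, data,
                                  candidate_columns = NULL) {
  stopifnot(inherits(known, "known_set"),
            inherits(stab, "stability_result"),
            inherits(data, "genotype_dataset"))
  if (is.null(candidate_columns)) {
    candidate_columns <- setdiff(seq_len(ncol(data$genotypes)), known$indices)
  }
  maf <- minor_allele_frequency(data)
  v <- data$variants
  known_rows <- tibble::tibble(
    snp = known$ids,
    chr = v$chr[known$indices],
    pos = v$pos[known$indices],
    coef = known$coefficients,
    maf = unname(maf[known$indices]),
    source = "known"
  )
  disc_cols <- candidate_columns[stab$selected]
  disc_rows <- tibble::tibble(
    snp = v$id[disc_cols],
    chr = v$chr[disc_cols],
    pos = v$pos[disc_cols],
    coef = unname(stab$final_coefficients),
    maf = unname(maf[disc_cols]),
    source = "discovered"
  )
  rank_results(dplyr::bind_rows(known_rows, disc_rows))
}
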