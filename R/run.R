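# Single-call entry points mirroring the command-line interface: read a
# PLINK fileset, run the full pipeline, write the ranked table; and the
# simulation counterpart that writes a fixture plus its truth.

#' Run the association pipeline on a PLINK fileset
#'
#' Reads `bfile.bed/.bim/.fam`, imputes missing genotypes by the
#' per-variant mode, resolves the prior set (from a known-variants file or
#' the Wald fallback), fits [cs_lmm()] and writes the ranked result table.
#' Exactly one of `target_k` / `lambda` must be supplied; there is no
#' automatic cross-validation (a fixed support size avoids the inflated
#' false-positive rates that CV-chosen penalties tend to produce).
#'
#' @param bfile PLINK path stem.
#' @param known_path Optional path to a known-variants file (one id per
#'   line).
#' @param target_k,lambda Support-size inquiry or fixed penalty (exactly
#'   one).
#' @param wald_fallback Number of top Wald-scan variants used as the prior
#'   when `known_path` is absent.
#' @param binary_trait Force case/control interpretation of the `.fam`
#'   phenotype.
#' @param stability_runs,subsample_fraction,threshold,seed,tol,max_iter
#'   Passed to [cs_lmm()].
#' @param out Optional output path for the TSV result table.
#' @param quiet Suppress the progress log.
#'
#' @return The `cslmm_fit`, invisibly.  The log records the variance
#'   components, penalty, iteration counts and any ordering violations.
#' @export
run_association <- function(bfile, known_path = NULL, target_k = NULL,
                            lambda = NULL, wald_fallback = NULL,
                            binary_trait = FALSE, stability_runs = 100L,
                            subsample_fraction = 0.5, threshold = 0.75,
                            seed = 1L, tol = 1e-6, max_iter = 1000L,
                            out = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (!is.null(target_k) && !is.null(lambda)) {
    stop("supply either target_k or lambda, not both", call. = FALSE)
  }
  if (is.null(target_k) && is.null(lambda)) {
    stop("supply target_k (support-size inquiry) or lambda (fixed penalty)",
         call. = FALSE)
  }
  data <- read_plink_binary(bfile)
  say("read ", nrow(data$genotypes), " samples x ", ncol(data$genotypes),
      " variants from ", bfile)
  n_miss <- sum(is.na(data$genotypes))
  if (n_miss > 0) {
    data <- impute_missing_mode(data)
    say("imputed ", n_miss, " missing call(s) by the per-variant mode")
  }
  y <- as_phenotype(data)
  if (binary_trait && attr(y, "trait_kind") != "case_control") {
    stop("--binary-trait given but the .fam phenotype is not coded 1/2",
         call. = FALSE)
  }
  say("phenotype: ", attr(y, "trait_kind"))
  known <- NULL
  if (!is.null(known_path)) {
    known <- read_known_variants(known_path, data)
    say("known-association set: ", paste(known$ids, collapse = ", "))
  } else {
    if (is.null(wald_fallback)) {
      stop("no known-variants file; set wald_fallback to pick a prior from ",
           "the Wald scan", call. = FALSE)
    }
    say("no known-variants file; using the top ", wald_fallback,
        " Wald-scan variant(s) as the prior")
  }
  fit <- cs_lmm(data, y, known = known, target_k = target_k,
                lambda = lambda, wald_fallback = wald_fallback,
                stability_runs = stability_runs,
                subsample_fraction = subsample_fraction,
                threshold = threshold, seed = seed, tol = tol,
                max_iter = max_iter)
  say("variance components: sigma_u^2 = ", signif(fit$vc$sigma_u2, 5),
      ", sigma_e^2 = ", signif(fit$vc$sigma_e2, 5),
      ", delta = ", signif(fit$vc$delta, 5))
  say("penalty lambda = ", signif(fit$stability$lambda_full, 5),
      "; full-data fit: ", fit$stability$full_fit$n_iter, " iteration(s)")
  say("discovered ", length(fit$stability$selected), " variant(s)",
      if (fit$stability$runs > 0)
        paste0(" stable over ", fit$stability$runs, " subsample runs"))
  if (length(fit$violations) > 0) {
    say("WARNING: ", length(fit$violations), " discovered coefficient(s) ",
        "violate the magnitude-ordering constraint")
  }
  if (!is.null(out)) {
    write_results(fit$results, out)
    say("wrote ", nrow(fit$results), " ranked variant(s) to ", out)
  }
  invisible(fit)
}

#' Simulate a dataset and write it as a PLINK fixture plus truth table
#'
#' @param config A [simulation_config()] or the path of a `key = value`
#'   config file ([read_simulation_config()]).
#' @param prefix Output path stem for the `.bed/.bim/.fam` trio; the truth
#'   table goes to `prefix.truth.tsv` with columns `snp`, `tier`,
#'   `causal`, `beta_true` and the realized heritability in a header
#'   comment.
#' @param quiet Suppress the progress log.
#'
#' @return The `gwas_simulation`, invisibly.
#' @export
run_simulation <- function(config, prefix, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.character(config)) config <- read_simulation_config(config)
  stopifnot(inherits(config, "simulation_config"))
  sim <- simulate_gwas(config)
  pheno <- if (config$binary) as.numeric(sim$phenotype) + 1 else
    as.numeric(sim$phenotype)
  write_plink_binary(sim$data, prefix, phenotype = pheno)
  truth_path <- paste0(prefix, ".truth.tsv")
  con <- file(truth_path, "w")
  writeLines(sprintf("# realized_h2 = %.6f", sim$truth$realized_h2), con)
  utils::write.table(
    data.frame(
      snp = sim$data$variants$id,
      tier = sim$tiers,
      causal = seq_len(config$p) %in%
        c(sim$truth$causal_known, sim$truth$causal_weak),
      beta_true = sim$truth$beta_true
    ),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  close(con)
  say("wrote ", config$n, " x ", config$p, " fixture to ", prefix,
      " (realized h2 = ", signif(sim$truth$realized_h2, 3), ")")
  invisible(sim)
}
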