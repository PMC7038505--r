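# Structured-population GWAS simulator: hierarchical (population /
# subpopulation) allele frequencies by a two-level Balding-Nichols model,
# two MAF tiers of SNPs, tiered effect sizes, heritability-controlled
# quantitative traits, and an optional binary trait via inverse-logit
# Bernoulli sampling.

#' Simulation configuration
#'
#' Parameters of the synthetic GWAS generator.  SNPs fall in two tiers:
#' tier v (20% of SNPs, the common/strong tier from which the "known"
#' variants are drawn) with ancestral MAF `m_v` and effect multiplier
#' `e_v`, and tier u (80%, the rare/weak discovery tier) with MAF `m_u`
#' and multiplier `e_u`.  Of the `k` causal SNPs, 20% come from tier v and
#' the rest from tier u; each causal coefficient is `e * c` with
#' `c ~ U(0, 1)`.  Individuals are split evenly across `g` populations
#' times `f` subpopulations, with allele-frequency drift `fst1` between
#' populations and `fst2` between subpopulations.
#'
#' @param n Samples (default 500).
#' @param p SNPs (default 5000; genome-scale runs can raise this).
#' @param g Populations (default 3).
#' @param f Subpopulations per population (default 2).
#' @param k Causal SNPs (default 10).
#' @param m_u,m_v Ancestral MAFs of tiers u and v (defaults 0.01 and 0.1).
#' @param e_u,e_v Effect multipliers of tiers u and v (defaults 25 and 50).
#' @param h2 Target heritability in (0, 1) (default 0.5).
#' @param fst1,fst2 Drift at the two hierarchy levels (defaults 0.05, 0.01).
#' @param binary Emit a binary trait (default `FALSE`).
#' @param seed Integer seed.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n = 500L, p = 5000L, g = 3L, f = 2L, k = 10L,
                              m_u = 0.01, m_v = 0.1, e_u = 25, e_v = 50,
                              h2 = 0.5, fst1 = 0.05, fst2 = 0.01,
                              binary = FALSE, seed = 1L) {
  cfg <- list(n = as.integer(n), p = as.integer(p), g = as.integer(g),
              f = as.integer(f), k = as.integer(k), m_u = m_u, m_v = m_v,
              e_u = e_u, e_v = e_v, h2 = h2, fst1 = fst1, fst2 = fst2,
              binary = isTRUE(binary), seed = as.integer(seed))
  if (cfg$n < 1 || cfg$p < 1) stop("n and p must be positive", call. = FALSE)
  if (cfg$k > cfg$p) stop("k cannot exceed p", call. = FALSE)
  if (cfg$m_u <= 0 || cfg$m_u > 0.5 || cfg$m_v <= 0 || cfg$m_v > 0.5) {
    stop("MAFs must lie in (0, 0.5]", call. = FALSE)
  }
  if (cfg$h2 <= 0 || cfg$h2 >= 1) stop("h2 must lie in (0, 1)", call. = FALSE)
  if (cfg$g < 1 || cfg$f < 1) stop("g and f must be at least 1", call. = FALSE)
  if (cfg$fst1 < 0 || cfg$fst1 >= 1 || cfg$fst2 < 0 || cfg$fst2 >= 1) {
    stop("fst parameters must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> n=", x$n, " p=", x$p, " (", x$g, " pops x ",
      x$f, " subpops), k=", x$k, ", tiers: v(maf=", x$m_v, ", e=", x$e_v,
      ") u(maf=", x$m_u, ", e=", x$e_u, "), h2=", x$h2,
      if (x$binary) ", binary" else "", ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

# Balding-Nichols draw: frequencies with mean pi (vectorized) and variance
# fst * pi * (1 - pi); fst = 0 returns pi unchanged.  Draws outside (0, 1)
# are clamped to [1e-4, 1 - 1e-4].
.bn_draw <- function(pi, fst) {
  if (fst == 0) return(pi)
  a <- pi * (1 - fst) / fst
  b <- (1 - pi) * (1 - fst) / fst
  pmin(pmax(stats::rbeta(length(pi), a, b), 1e-4), 1 - 1e-4)
}

#' Simulate structured genotypes
#'
#' Draws per-SNP ancestral frequencies from the tier MAFs, lets them drift
#' along the population / subpopulation hierarchy with a two-level
#' Balding-Nichols model, and samples dosages as `Binomial(2, freq)` within
#' each subpopulation.  Individuals are split as evenly as possible across
#' the `g * f` subpopulations.  Consumes the current RNG stream; seed via
#' [simulate_gwas()] or `set.seed()`.
#'
#' @param config A [simulation_config()].
#'
#' @return List with `data` (a [genotype_dataset]), `labels` (tibble:
#'   `sample`, `population`, `subpopulation`) and `tiers` (length-p factor
#'   `"u"`/`"v"`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$p
  n <- config$n
  n_v <- round(0.2 * p)
  tier <- rep("u", p)
  tier[sample.int(p, n_v)] <- "v"
  ancestral <- ifelse(tier == "v", config$m_v, config$m_u)

  n_sub <- config$g * config$f
  sub_of <- rep_len(seq_len(n_sub), n)
  sub_of <- sort(sub_of)  # contiguous blocks, sizes differing by at most 1
  pop_of_sub <- rep(seq_len(config$g), each = config$f)

  # population- then subpopulation-level frequencies, SNP x subpop
  pop_freq <- matrix(NA_real_, nrow = p, ncol = config$g)
  for (gi in seq_len(config$g)) {
    pop_freq[, gi] <- .bn_draw(ancestral, config$fst1)
  }
  sub_freq <- matrix(NA_real_, nrow = p, ncol = n_sub)
  for (si in seq_len(n_sub)) {
    sub_freq[, si] <- .bn_draw(pop_freq[, pop_of_sub[si]], config$fst2)
  }

  geno <- matrix(0, nrow = n, ncol = p)
  for (si in seq_len(n_sub)) {
    rows <- which(sub_of == si)
    geno[rows, ] <- matrix(
      stats::rbinom(length(rows) * p, 2L, rep(sub_freq[, si], each = length(rows))),
      nrow = length(rows)
    )
  }
  data <- genotype_dataset(geno)
  labels <- tibble::tibble(
    sample = seq_len(n),
    population = pop_of_sub[sub_of],
    subpopulation = sub_of
  )
  list(data = data, labels = labels, tiers = tier)
}

#' Assign causal effects
#'
#' Draws the causal set: `round(0.2 * k)` SNPs from tier v with coefficient
#' `e_v * c` and the remainder from tier u with coefficient `e_u * c`,
#' `c ~ U(0, 1)` i.i.d.; all other coefficients are zero.  The tier-v
#' causal SNPs play the role of the already-known strong associations in
#' benchmarks.  Consumes the current RNG stream.
#'
#' @param config A [simulation_config()].
#' @param tiers Tier labels from [simulate_genotypes()].
#'
#' @return An object of class `simulation_truth`: `beta_true`,
#'   `causal_known` (tier-v causal indices), `causal_weak` (tier-u causal
#'   indices), `realized_h2` (`NA` until the phenotype is simulated).
#' @export
assign_effects <- function(config, tiers) {
  stopifnot(inherits(config, "simulation_config"))
  k_v <- round(0.2 * config$k)
  k_u <- config$k - k_v
  in_v <- which(tiers == "v")
  in_u <- which(tiers == "u")
  if (length(in_v) < k_v || length(in_u) < k_u) {
    stop("a tier is too small for its causal quota (need ", k_v,
         " in v, ", k_u, " in u)", call. = FALSE)
  }
  causal_v <- sort(sample(in_v, k_v))
  causal_u <- sort(sample(in_u, k_u))
  beta <- numeric(config$p)
  beta[causal_v] <- config$e_v * stats::runif(k_v)
  beta[causal_u] <- config$e_u * stats::runif(k_u)
  structure(
    list(beta_true = beta, causal_known = causal_v, causal_weak = causal_u,
         realized_h2 = NA_real_),
    class = "simulation_truth"
  )
}

#' Simulate the phenotype
#'
#' Builds the genetic value `Xb`, adds Gaussian noise whose variance is set
#' to `var(Xb) * (1 - h2) / h2` so the heritability
#' `var(Xb) / (var(Xb) + var(e))` targets `h2`, and (optionally) converts
#' to a binary trait by standardizing the continuous value and sampling
#' `Bernoulli(logistic(z))`.  Consumes the current RNG stream.
#'
#' @param data A [genotype_dataset] from [simulate_genotypes()].
#' @param truth A [assign_effects()] result.
#' @param config A [simulation_config()].
#'
#' @return List with `phenotype` (a [phenotype_vector]) and `truth` (with
#'   `realized_h2` filled from the drawn noise).  For binary traits
#'   `realized_h2` refers to the latent continuous trait.
#' @export
simulate_phenotype <- function(data, truth, config) {
  stopifnot(inherits(data, "genotype_dataset"),
            inherits(truth, "simulation_truth"),
            inherits(config, "simulation_config"))
  gv <- as.numeric(data$genotypes %*% truth$beta_true)
  var_g <- stats::var(gv)
  if (var_g == 0) {
    stop("genetic value has zero variance; cannot target h2 > 0",
         call. = FALSE)
  }
  sigma2_e <- var_g * (1 - config$h2) / config$h2
  eps <- stats::rnorm(config$n, 0, sqrt(sigma2_e))
  y_cont <- gv + eps
  truth$realized_h2 <- var_g / (var_g + stats::var(eps))
  if (config$binary) {
    z <- as.numeric(scale(y_cont))
    y <- phenotype_vector(stats::rbinom(config$n, 1L, stats::plogis(z)),
                          trait_kind = "case_control")
  } else {
    y <- phenotype_vector(y_cont, trait_kind = "quantitative")
  }
  list(phenotype = y, truth = truth)
}

#' Simulate a complete structured GWAS dataset
#'
#' Runs [simulate_genotypes()], [assign_effects()] and
#' [simulate_phenotype()] under the configuration seed in one call.
#'
#' @param config A [simulation_config()].
#'
#' @return List of class `gwas_simulation` with `data`, `phenotype`,
#'   `truth`, `labels`, `tiers`, `config`.
#' @export
simulate_gwas <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    gen <- simulate_genotypes(config)
    truth <- assign_effects(config, gen$tiers)
    ph <- simulate_phenotype(gen$data, truth, config)
    structure(
      list(data = gen$data, phenotype = ph$phenotype, truth = ph$truth,
           labels = gen$labels, tiers = gen$tiers, config = config),
      class = "gwas_simulation"
    )
  })
}

#' @export
print.gwas_simulation <- function(x, ...) {
  cat("<gwas_simulation> n=", x$config$n, " p=", x$config$p, ", ",
      length(x$truth$causal_known), " known + ",
      length(x$truth$causal_weak), " weak causal SNPs, realized h2 = ",
      signif(x$truth$realized_h2, 3), "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset as a PLINK fixture
#'
#' Convenience wrapper around [write_plink_binary()] for tests and
#' command-line round trips.
#'
#' @param data A [genotype_dataset].
#' @param phenotype Optional phenotype for the `.fam` file.
#' @param prefix Output path stem.
#'
#' @return `prefix`, invisibly.
#' @export
make_plink_fixture <- function(data, phenotype = NULL, prefix) {
  write_plink_binary(data, prefix, phenotype = phenotype)
}

#' Read a simulation configuration file
#'
#' Plain `key = value` text (one pair per line, `#` comments); keys are the
#' arguments of [simulation_config()].  `binary` accepts true/false.
#'
#' @param path File path.
#'
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  allowed <- names(formals(simulation_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- stats::setNames(as.list(vals), keys)
  for (nm in names(args)) {
    args[[nm]] <- if (nm == "binary") {
      tolower(args[[nm]]) %in% c("true", "1", "yes")
    } else {
      as.numeric(args[[nm]])
    }
  }
  do.call(simulation_config, args)
}
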