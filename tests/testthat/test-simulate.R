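test_that("configuration validation catches out-of-range parameters", {
  expect_error(simulation_config(h2 = 1.5), "h2")
  expect_error(simulation_config(h2 = 0), "h2")
  expect_error(simulation_config(m_u = 0.6), "MAF")
  expect_error(simulation_config(k = 100, p = 50), "k cannot exceed p")
  expect_error(simulation_config(fst1 = 1), "fst")
  cfg <- simulation_config(n = 100, p = 200)
  expect_s3_class(cfg, "simulation_config")
})

test_that("same seed reproduces the dataset exactly", {
  cfg <- simulation_config(n = 80, p = 120, seed = 5)
  a <- simulate_gwas(cfg)
  b <- simulate_gwas(cfg)
  expect_identical(a$data$genotypes, b$data$genotypes)
  expect_identical(a$truth$beta_true, b$truth$beta_true)
  expect_identical(as.numeric(a$phenotype), as.numeric(b$phenotype))
})

test_that("tier MAFs converge to their targets without drift", {
  set.seed(1)
  cfg <- simulation_config(n = 2000, p = 800, m_u = 0.01, m_v = 0.1,
                           fst1 = 0, fst2 = 0, seed = 1)
  gen <- simulate_genotypes(cfg)
  maf <- minor_allele_frequency(gen$data)
  expect_lt(abs(mean(maf[gen$tiers == "v"]) - 0.1), 0.01)
  expect_lt(abs(mean(maf[gen$tiers == "u"]) - 0.01), 0.003)
  expect_equal(sum(gen$tiers == "v"), round(0.2 * 800))
})

test_that("no structure means centered relatedness off-diagonals", {
  set.seed(2)
  cfg <- simulation_config(n = 150, p = 600, g = 1, f = 1, m_u = 0.2,
                           m_v = 0.4, seed = 2)
  gen <- simulate_genotypes(cfg)
  k <- genomic_relationship_matrix(gen$data)
  off <- k[upper.tri(k)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("strong drift separates populations in the relationship matrix", {
  set.seed(3)
  cfg <- simulation_config(n = 200, p = 500, g = 2, f = 1, fst1 = 0.2,
                           fst2 = 0, m_u = 0.2, m_v = 0.3, seed = 3)
  gen <- simulate_genotypes(cfg)
  k <- suppressWarnings(genomic_relationship_matrix(gen$data))
  pop <- gen$labels$population
  same <- outer(pop, pop, "==") & upper.tri(k)
  diff_pop <- outer(pop, pop, "!=") & upper.tri(k)
  expect_gt(mean(k[same]), mean(k[diff_pop]))
  # leading eigenvector separates the populations
  v1 <- eigen(k, symmetric = TRUE)$vectors[, 1]
  between <- (mean(v1[pop == 1]) - mean(v1[pop == 2]))^2
  within <- var(v1[pop == 1]) + var(v1[pop == 2])
  expect_gt(between / within, 1)
})

test_that("within-subpopulation relatedness exceeds between-population", {
  set.seed(4)
  cfg <- simulation_config(n = 240, p = 600, g = 2, f = 2, fst1 = 0.1,
                           fst2 = 0.02, m_u = 0.2, m_v = 0.3, seed = 4)
  gen <- simulate_genotypes(cfg)
  k <- suppressWarnings(genomic_relationship_matrix(gen$data))
  sub <- gen$labels$subpopulation
  pop <- gen$labels$population
  ut <- upper.tri(k)
  same_sub <- outer(sub, sub, "==") & ut
  diff_pop <- outer(pop, pop, "!=") & ut
  expect_gt(mean(k[same_sub]), mean(k[diff_pop]))
})

test_that("causal effects follow the tier split and uniform base draws", {
  cfg <- simulation_config(n = 50, p = 400, k = 10, seed = 6)
  set.seed(6)
  gen <- simulate_genotypes(cfg)
  truth <- assign_effects(cfg, gen$tiers)
  expect_length(truth$causal_known, 2)  # 20% of k = 10
  expect_length(truth$causal_weak, 8)
  expect_true(all(gen$tiers[truth$causal_known] == "v"))
  expect_true(all(gen$tiers[truth$causal_weak] == "u"))
  expect_equal(sum(truth$beta_true != 0), 10)
  expect_true(all(abs(truth$beta_true[truth$causal_known]) <= cfg$e_v))
  expect_true(all(abs(truth$beta_true[truth$causal_weak]) <= cfg$e_u))
  expect_true(all(truth$beta_true[c(truth$causal_known,
                                    truth$causal_weak)] != 0))

  cfg0 <- simulation_config(n = 50, p = 400, k = 10, e_u = 0, seed = 6)
  truth0 <- assign_effects(cfg0, gen$tiers)
  expect_true(all(truth0$beta_true[truth0$causal_weak] == 0))

  tiny <- simulation_config(n = 50, p = 10, k = 9, seed = 1)
  expect_error(assign_effects(tiny, rep("u", 10)), "quota")
})

test_that("realized heritability brackets the target", {
  set.seed(7)
  h2s <- replicate(20, {
    cfg <- simulation_config(n = 500, p = 2000, h2 = 0.5,
                             seed = sample.int(1e6, 1))
    sim <- simulate_gwas(cfg)
    sim$truth$realized_h2
  })
  expect_lt(abs(median(h2s) - 0.5), 0.05)

  # near-deterministic limit
  cfg_hi <- simulation_config(n = 300, p = 500, h2 = 0.999, seed = 8)
  sim_hi <- simulate_gwas(cfg_hi)
  gv <- as.numeric(sim_hi$data$genotypes %*% sim_hi$truth$beta_true)
  expect_gt(cor(gv, as.numeric(sim_hi$phenotype)), 0.999)
})

test_that("binary traits are Bernoulli draws with sensible prevalence", {
  cfg <- simulation_config(n = 400, p = 300, binary = TRUE, seed = 9)
  sim <- simulate_gwas(cfg)
  y <- as.numeric(sim$phenotype)
  expect_true(all(y %in% c(0, 1)))
  expect_gt(mean(y), 0.05)
  expect_lt(mean(y), 0.95)
  expect_equal(attr(sim$phenotype, "trait_kind"), "case_control")
})

test_that("all-null effects cannot target positive heritability", {
  cfg <- simulation_config(n = 50, p = 100, seed = 10)
  set.seed(10)
  gen <- simulate_genotypes(cfg)
  truth <- assign_effects(cfg, gen$tiers)
  truth$beta_true[] <- 0
  expect_error(simulate_phenotype(gen$data, truth, cfg), "zero variance")
})

test_that("PLINK fixtures have the exact expected byte count", {
  set.seed(11)
  cfg <- simulation_config(n = 250, p = 400, m_u = 0.1, seed = 11)
  sim <- simulate_gwas(cfg)
  prefix <- file.path(tempdir(), "sized")
  make_plink_fixture(sim$data, as.numeric(sim$phenotype), prefix)
  expect_equal(file.size(paste0(prefix, ".bed")),
               ceiling(250 / 4) * 400 + 3)
  back <- read_plink_binary(prefix)
  expect_identical(back$genotypes, sim$data$genotypes)
})

test_that("config files round-trip through the key = value parser", {
  f <- tempfile()
  writeLines(c("# test config", "n = 120", "p = 300", "k = 6",
               "h2 = 0.3", "binary = true", "seed = 42"), f)
  cfg <- read_simulation_config(f)
  expect_equal(cfg$n, 120L)
  expect_equal(cfg$h2, 0.3)
  expect_true(cfg$binary)
  expect_equal(cfg$seed, 42L)

  writeLines("h2 = 1.5", f)
  expect_error(read_simulation_config(f), "h2")
  writeLines("nonsense_key = 3", f)
  expect_error(read_simulation_config(f), "unknown config key")
})
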