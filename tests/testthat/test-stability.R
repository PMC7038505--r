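# Shared small rotated-scale fixture: a few strong signals among nulls.
make_signal_design <- function(n, p, strong, effect = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p)
  beta[strong] <- effect
  y <- as.numeric(x %*% beta + rnorm(n))
  list(x = x, y = y, strong = strong)
}

test_that("stability selection is deterministic given the seed", {
  fx <- make_signal_design(60, 30, strong = c(3, 11), seed = 2)
  a <- stability_select(fx$x, fx$y, target_k = 2, runs = 15, seed = 99)
  b <- stability_select(fx$x, fx$y, target_k = 2, runs = 15, seed = 99)
  expect_identical(a$frequencies, b$frequencies)
  expect_identical(a$selected, b$selected)
  expect_identical(a$final_coefficients, b$final_coefficients)
  # different seeds draw different subsamples
  s1 <- cslmm:::with_seed(cslmm:::derive_seed(99, 1), sample.int(60, 30))
  s2 <- cslmm:::with_seed(cslmm:::derive_seed(100, 1), sample.int(60, 30))
  expect_false(identical(s1, s2))
})

test_that("a single run yields binary frequencies equal to its support", {
  fx <- make_signal_design(40, 12, strong = 5, seed = 3)
  res <- stability_select(fx$x, fx$y, target_k = 3, runs = 1, seed = 1)
  expect_true(all(res$frequencies %in% c(0, 1)))
  expect_setequal(res$selected, which(res$frequencies == 1))
})

test_that("strong signals are kept and frequencies are conserved", {
  fx <- make_signal_design(120, 60, strong = c(7, 23, 41), effect = 4,
                           seed = 4)
  res <- stability_select(fx$x, fx$y, target_k = 3, runs = 40, seed = 5)
  expect_true(all(res$frequencies[fx$strong] > 0.75))
  nulls <- setdiff(seq_len(60), fx$strong)
  expect_gte(mean(res$frequencies[nulls] <= 0.75), 0.95)
  # conservation: frequencies encode an integer count of selections per run
  total <- sum(res$frequencies) * res$runs
  expect_equal(total %% 1, 0)
  expect_lte(total, res$runs * 60)
  expect_true(all(res$frequencies >= 0 & res$frequencies <= 1))
})

test_that("raising the threshold never grows the selected set", {
  fx <- make_signal_design(80, 25, strong = c(2, 14), seed = 6)
  res <- stability_select(fx$x, fx$y, target_k = 2, runs = 20, seed = 7)
  sel_sizes <- vapply(seq(0, 1, by = 0.05),
                      function(t) sum(res$frequencies > t), numeric(1))
  expect_true(all(diff(sel_sizes) <= 0))
})

test_that("selection uses a strict threshold", {
  fx <- make_signal_design(40, 10, strong = 1, seed = 8)
  res <- stability_select(fx$x, fx$y, target_k = 1, runs = 4, seed = 9,
                          threshold = 0.75)
  at_75 <- which(abs(res$frequencies - 0.75) < 1e-12)
  expect_true(all(!at_75 %in% res$selected))
})

test_that("tiny subsamples are rejected", {
  fx <- make_signal_design(5, 4, strong = 1, seed = 10)
  expect_error(
    stability_select(fx$x, fx$y, target_k = 1, runs = 2,
                     subsample_fraction = 0.4, seed = 1),
    "too small"
  )
})

test_that("result tables combine known and discovered rows", {
  set.seed(11)
  sim <- simulate_gwas(simulation_config(n = 120, p = 150, k = 6,
                                         m_u = 0.05, seed = 11))
  d <- sim$data
  known <- known_set(d, indices = sim$truth$causal_known)
  step1 <- fit_known_effects(d, as.numeric(sim$phenotype), known)
  known <- step1$known
  cand <- setdiff(seq_len(150), known$indices)

  stab <- structure(
    list(frequencies = rep(0, length(cand)), selected = c(5L, 40L),
         runs = 10L, threshold = 0.75, lambda_full = 1,
         final_coefficients = stats::setNames(c(0.3, -0.1),
                                              c("5", "40")),
         full_fit = NULL),
    class = "stability_result"
  )
  tab <- assemble_result_table(known, stab, d, candidate_columns = cand)
  expect_equal(nrow(tab), length(known$indices) + 2)
  expect_equal(sum(tab$source == "known"), length(known$indices))
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(abs(tab$coef)) <= 1e-12))

  empty <- stab
  empty$selected <- integer(0)
  empty$final_coefficients <- stats::setNames(numeric(0), character(0))
  tab2 <- assemble_result_table(known, empty, d, candidate_columns = cand)
  expect_equal(nrow(tab2), length(known$indices))
  expect_true(all(tab2$source == "known"))
})

test_that("known plus discovered counts add up in the final table", {
  # 4 known + 17 discovered and 2 known + 20 discovered layouts
  set.seed(12)
  d <- random_dataset(30, 40)
  for (shape in list(c(4, 17), c(2, 20))) {
    known <- known_set(d, indices = seq_len(shape[1]))
    known$coefficients <- rnorm(shape[1], sd = 1000)
    known$intercept <- 0
    cand <- setdiff(1:40, known$indices)
    sel <- seq_len(shape[2])
    stab <- structure(
      list(frequencies = rep(1, length(cand)), selected = sel,
           runs = 1L, threshold = 0.75, lambda_full = 1,
           final_coefficients = stats::setNames(rnorm(shape[2], sd = 1e-4),
                                                as.character(sel)),
           full_fit = NULL),
      class = "stability_result"
    )
    tab <- assemble_result_table(known, stab, d, candidate_columns = cand)
    expect_equal(nrow(tab), sum(shape))
    expect_equal(tab$source[seq_len(shape[1])], rep("known", shape[1]))
  }
})
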