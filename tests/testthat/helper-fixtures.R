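# Fixture builders shared across the suite.  Everything is generated in
# code under fixed seeds; nothing is read from disk except files the tests
# themselves write to tempdir().

# Random dosage matrix with optional missingness, wrapped as a dataset.
random_dataset <- function(n, p, miss_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  if (miss_rate > 0) {
    g[runif(n * p) < miss_rate] <- NA
  }
  genotype_dataset(g)
}

# Small dense design + response for optimizer tests (n > p, well scaled).
random_regression <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p)
  beta[seq_len(min(3, p))] <- c(2, -1.5, 1)[seq_len(min(3, p))]
  y <- as.numeric(x %*% beta + rnorm(n, sd = 0.5))
  list(x = x, y = y, beta = beta)
}

# Independent textbook Benjamini-Hochberg step-up, for cross-checking.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Random symmetric PSD matrix with given size and rank.
random_psd <- function(n, rank = n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(a) / rank
}

skip_if_no_glmnet <- function() {
  testthat::skip_if_not_installed("glmnet")
}

# Lasso solution for ||y - Xb||^2 + lambda ||b||_1 via glmnet coordinate
# descent (independent oracle; note glmnet's (1/2n)-scaled loss).
glmnet_lasso <- function(x, y, lambda) {
  n <- nrow(x)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = lambda / (2 * n), standardize = FALSE,
                        intercept = FALSE, thresh = 1e-12)
  as.numeric(fit$beta)
}
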