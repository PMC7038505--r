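test_that("relationship matrix matches the direct standardized product", {
  set.seed(1)
  d <- random_dataset(15, 40)
  k <- genomic_relationship_matrix(d)
  w <- scale(d$genotypes)
  expect_equal(k, tcrossprod(w) / 40, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(k, t(k))
  expect_gt(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("identical samples get identical relationship rows", {
  set.seed(2)
  g <- matrix(sample(0:2, 10 * 30, replace = TRUE), 10, 30)
  g[2, ] <- g[1, ]
  k <- genomic_relationship_matrix(genotype_dataset(g))
  expect_equal(k[1, 1], k[1, 2], tolerance = 1e-12)
  expect_equal(k[1, ], k[2, ], tolerance = 1e-12)
})

test_that("monomorphic variants are dropped (all-monomorphic errors)", {
  g <- cbind(rep(1, 8), sample(0:2, 8, replace = TRUE))
  g[1, 2] <- 0; g[2, 2] <- 2  # ensure polymorphic
  expect_warning(k <- genomic_relationship_matrix(genotype_dataset(g)),
                 "monomorphic")
  expect_equal(dim(k), c(8, 8))
  expect_error(
    suppressWarnings(genomic_relationship_matrix(
      genotype_dataset(matrix(1, 4, 3)))),
    "monomorphic"
  )
})

test_that("spectral decomposition reconstructs, orders and clamps", {
  sp_i <- spectral_decompose(diag(3))
  expect_equal(sp_i$gamma, rep(1, 3))
  expect_equal(crossprod(sp_i$rotation), diag(3), tolerance = 1e-10)

  sp_d <- spectral_decompose(diag(c(3, 1)))
  expect_equal(sp_d$gamma, c(3, 1))

  set.seed(3)
  for (i in 1:10) {
    k <- random_psd(10, rank = sample(3:10, 1))
    sp <- spectral_decompose(k)
    expect_true(all(diff(sp$gamma) <= 1e-12))
    expect_true(all(sp$gamma >= 0))
    rec <- sp$rotation %*% diag(sp$gamma) %*% t(sp$rotation)
    expect_lt(norm(rec - k, "F") / max(norm(k, "F"), 1e-12), 1e-8)
  }
  expect_error(spectral_decompose(matrix(c(0, NA, NA, 1), 2)), "finite")
  expect_error(spectral_decompose(matrix(c(1, 5, 0, 1), 2)), "symmetric")
})

test_that("profile ML recovers delta generatively (median within [0.5, 2])", {
  set.seed(4)
  d <- random_dataset(200, 300)
  sp <- spectral_decompose(genomic_relationship_matrix(d))
  deltas <- replicate(50, {
    z <- rnorm(200, sd = sqrt(sp$gamma + 1))  # sigma_u2 = 1, delta = 1
    yp <- as.numeric(sp$rotation %*% z)
    fit_delta(yp, sp$gamma, sp$rotation)$delta
  })
  expect_gt(median(deltas), 0.5)
  expect_lt(median(deltas), 2)
})

test_that("zero-noise generative limit drives delta to the grid floor", {
  set.seed(5)
  d <- random_dataset(60, 200)
  sp <- spectral_decompose(genomic_relationship_matrix(d))
  z <- rnorm(60, sd = sqrt(pmax(sp$gamma, 1e-8)))
  yp <- as.numeric(sp$rotation %*% z)
  vc <- fit_delta(yp, sp$gamma, sp$rotation)
  expect_lte(vc$delta, 10^-4.8)
})

test_that("returned delta attains the profile-likelihood maximum", {
  set.seed(6)
  d <- random_dataset(50, 80)
  sp <- spectral_decompose(genomic_relationship_matrix(d))
  yp <- rnorm(50)
  vc <- fit_delta(yp, sp$gamma, sp$rotation)
  r_all <- as.numeric(crossprod(sp$rotation, yp - mean(yp)))
  # degenerate components (zero eigenvalue, zero residual: the centering
  # direction) carry no delta information and are excluded
  degen <- sp$gamma < 1e-8 * max(sp$gamma, 1) &
    abs(r_all) < 1e-8 * sqrt(sum(r_all^2))
  r <- r_all[!degen]
  gam <- sp$gamma[!degen]
  m <- length(r)
  prof <- function(l10d) {
    delta <- 10^l10d
    dd <- pmax(gam + delta, 1e-10)
    s2 <- mean(r^2 / dd)
    -0.5 * (m * log(2 * pi) + m * log(s2) + sum(log(dd)) + m)
  }
  grid_ll <- vapply(seq(-5, 5, length.out = 101), prof, numeric(1))
  expect_gte(vc$log_likelihood + 1e-10, max(grid_ll))
  expect_equal(vc$delta, vc$sigma_e2 / vc$sigma_u2, tolerance = 1e-10)
})

test_that("profile maximum matches a brute-force 2-D grid at n=30", {
  set.seed(7)
  d <- random_dataset(30, 60)
  k <- genomic_relationship_matrix(d)
  sp <- spectral_decompose(k)
  yp <- as.numeric(sp$rotation %*% rnorm(30, sd = sqrt(sp$gamma + 0.5)))
  vc <- fit_delta(yp, sp$gamma, sp$rotation)
  yc <- yp - mean(yp)
  ll2d <- function(su2, se2) {
    sig <- su2 * k + se2 * diag(30)
    -0.5 * (30 * log(2 * pi) + determinant(sig)$modulus[1] +
              sum(yc * solve(sig, yc)))
  }
  su_grid <- vc$sigma_u2 * 10^seq(-1, 1, length.out = 41)
  se_grid <- vc$sigma_e2 * 10^seq(-1, 1, length.out = 41)
  brute <- max(outer(su_grid, se_grid, Vectorize(ll2d)))
  expect_gte(vc$log_likelihood + 1e-4, brute)
})

test_that("delta is invariant to rescaling the residual", {
  set.seed(8)
  d <- random_dataset(40, 100)
  sp <- spectral_decompose(genomic_relationship_matrix(d))
  yp <- rnorm(40, sd = 2)
  vc1 <- fit_delta(yp, sp$gamma, sp$rotation)
  vc2 <- fit_delta(3.7 * yp, sp$gamma, sp$rotation)
  expect_equal(vc2$delta, vc1$delta, tolerance = 1e-3)
  expect_equal(vc2$sigma_u2, 3.7^2 * vc1$sigma_u2, tolerance = 1e-3)
  expect_equal(vc2$sigma_e2, 3.7^2 * vc1$sigma_e2, tolerance = 1e-3)
})

test_that("equal eigenvalues make delta unidentifiable with a warning", {
  expect_warning(
    vc <- fit_delta(rnorm(10), rep(2, 10), diag(10)),
    "unidentifiable"
  )
  expect_equal(vc$delta, 1)  # grid midpoint, log10 delta = 0
})

test_that("rotation satisfies the whitening identity", {
  set.seed(9)
  for (i in 1:50) {
    n <- 20
    k <- random_psd(n, rank = sample(c(n, n - 5, 10), 1))
    sp <- spectral_decompose(k)
    delta <- 10^runif(1, -2, 2)
    sigma_u2 <- 10^runif(1, -1, 1)
    vc <- structure(
      list(sigma_u2 = sigma_u2, sigma_e2 = delta * sigma_u2, delta = delta,
           gamma = sp$gamma, rotation = sp$rotation, log_likelihood = NA),
      class = "variance_components"
    )
    tr <- diag(1 / sqrt(pmax(sp$gamma + delta, 1e-10))) %*% t(sp$rotation)
    sig <- sigma_u2 * k + vc$sigma_e2 * diag(n)
    white <- tr %*% sig %*% t(tr)
    expect_lt(norm(white - sigma_u2 * diag(n), "F") /
                norm(sigma_u2 * diag(n), "F"), 1e-6)
  }
})

test_that("isotropic relationship rescales norms by 1/sqrt(1 + delta)", {
  set.seed(10)
  n <- 12
  sp <- spectral_decompose(diag(n))
  delta <- 0.8
  vc <- structure(
    list(sigma_u2 = 1, sigma_e2 = delta, delta = delta, gamma = sp$gamma,
         rotation = sp$rotation, log_likelihood = NA),
    class = "variance_components"
  )
  d <- random_dataset(n, 5)
  yp <- rnorm(n)
  rot <- rotate_data(d, yp, vc)
  expect_equal(sqrt(sum(rot$y_rot^2)), sqrt(sum(yp^2) / (1 + delta)),
               tolerance = 1e-10)
  expect_equal(dim(rot$x_rot), dim(d$genotypes))
})

test_that("rotation of data matches the explicit matrix formula", {
  set.seed(11)
  d <- random_dataset(20, 10)
  k <- random_psd(20)
  sp <- spectral_decompose(k)
  vc <- structure(
    list(sigma_u2 = 2, sigma_e2 = 1.4, delta = 0.7, gamma = sp$gamma,
         rotation = sp$rotation, log_likelihood = NA),
    class = "variance_components"
  )
  yp <- rnorm(20)
  rot <- rotate_data(d, yp, vc, columns = 2:6)
  tr <- diag(1 / sqrt(sp$gamma + 0.7)) %*% t(sp$rotation)
  expect_equal(rot$x_rot, tr %*% d$genotypes[, 2:6], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rot$y_rot, as.numeric(tr %*% yp), tolerance = 1e-10)
})
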