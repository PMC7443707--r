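test_that("Gram matrix equals brute-force summation over masked voxels", {
  mask <- full_mask(c(6, 6, 6))
  basis <- build_basis_system(c(6, 6, 6), 1, knot_spacing_mm = 3, degree_r = 2,
                              mask = mask)
  gm <- compute_gram_matrix(basis)
  Dd <- dense_design(basis, mask)
  K <- ncol(Dd)
  W_oracle <- matrix(0, K, K)
  for (k in seq_len(K)) {
    for (l in seq_len(k)) {
      s <- sum(Dd[, k] * Dd[, l])   # explicit sum over voxels of phi_k phi_l
      W_oracle[k, l] <- W_oracle[l, k] <- s
    }
  }
  expect_lt(max(abs(gm$W - W_oracle)), 1e-12)
  expect_lt(max(abs(gm$W - t(gm$W))), 1e-10)
  expect_gt(min(eigen(gm$W, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8 * max(gm$W))
})

test_that("two-image antithetic training set has one eigenvalue 2 c'Wc", {
  set.seed(41)
  K <- 20
  B <- matrix(rnorm(3 * K * K), 3 * K)
  W <- crossprod(B) / nrow(B)
  cvec <- rnorm(K)
  C <- rbind(cvec, -cvec)              # already column-centered
  es <- fit_fpca(C, W, pve_threshold = 1)
  expect_equal(es$M_max, 1L)
  expect_equal(es$lambda[1], 2 * sum(cvec * (W %*% cvec)), tolerance = 1e-10)
  # eigenfunction proportional to the image itself (coefficients prop. to c)
  ratio <- es$xi[, 1] / cvec
  expect_lt(stats::sd(ratio) / abs(mean(ratio)), 1e-8)
})

test_that("Cholesky/SVD route matches the dense unsymmetric eigenproblem", {
  set.seed(42)
  N <- 20; K <- 30
  W <- crossprod(matrix(rnorm(2 * K * K), 2 * K)) / (2 * K)
  C <- scale(matrix(rnorm(N * K), N), center = TRUE, scale = FALSE)
  es <- fit_fpca(C, W, pve_threshold = 0.8)

  # oracle: eigen of (N-1)^{-1} C'C W, the operator eigenproblem in
  # coefficient space
  Mmat <- crossprod(C) %*% W / (N - 1)
  eo <- eigen(Mmat)
  lam_oracle <- Re(eo$values[seq_len(es$M_max)])
  expect_rel_equal(es$lambda, lam_oracle, 1e-8)

  # eigenvectors match up to sign after W-normalisation
  for (m in seq_len(min(10, es$M_max))) {
    v <- Re(eo$vectors[, m])
    v <- v / sqrt(sum(v * (W %*% v)))
    err <- min(max(abs(v - es$xi[, m])), max(abs(v + es$xi[, m])))
    expect_lt(err, 1e-7)
  }

  # W-orthonormality of eigenfunctions
  G <- t(es$xi) %*% W %*% es$xi
  expect_lt(max(abs(G - diag(es$M_max))), 1e-8)
})

test_that("training scores are centered, variance lambda, uncorrelated", {
  set.seed(43)
  N <- 40; K <- 25
  W <- crossprod(matrix(rnorm(2 * K * K), 2 * K)) / (2 * K)
  C <- scale(matrix(rnorm(N * K), N), center = TRUE, scale = FALSE)
  es <- fit_fpca(C, W, pve_threshold = 1)
  nu <- compute_scores(C, W, es, es$M_max)
  expect_lt(max(abs(colMeans(nu))), 1e-8 * sqrt(max(es$lambda)))
  expect_rel_equal(apply(nu, 2, stats::var), es$lambda, 1e-6)
  cv <- crossprod(nu) / (N - 1)
  off <- abs(cv - diag(diag(cv)))
  lim <- 1e-6 * sqrt(outer(es$lambda, es$lambda))
  expect_true(all(off <= lim + 1e-12))

  # score of the training mean image is zero
  nu0 <- compute_scores(rep(0, K), W, es, es$M_max)
  expect_equal(as.numeric(nu0), rep(0, es$M_max))

  expect_error(compute_scores(C, W, es, es$M_max + 5), "truncation")
})

test_that("truncation selection follows cumulative PVE", {
  fake <- structure(list(lambda = c(3, 1), pve = cumsum(c(3, 1)) / 4,
                         M_max = 2L), class = "eigen_system")
  expect_equal(select_truncation(fake, 0.5), 1L)
  expect_equal(select_truncation(fake, 0.8), 2L)
  expect_equal(select_truncation(fake, 1.0), 2L)
  expect_error(select_truncation(fake, 1.5), "pve_threshold")
})

test_that("scores equal voxelwise inner products for in-span images", {
  shape <- c(8, 8, 8)
  mask <- full_mask(shape)
  basis <- build_basis_system(shape, 1, knot_spacing_mm = 3, degree_r = 2,
                              mask = mask)
  set.seed(44)
  N <- 12
  vols <- span_cohort(basis, mask, matrix(rnorm(basis$K_active * N), basis$K_active))
  proj <- project_cohort(vols, basis, mask)
  es <- fit_fpca(proj$coeffs_centered, basis$gram, pve_threshold = 0.9)
  nu <- compute_scores(proj$coeffs_centered, basis$gram, es, es$M)

  # Eq.-style oracle: nu_im = sum over voxels of (x_i - mu)(t) psi_m(t)
  Xmat <- vapply(vols, mask_vectorize, numeric(mask$n_active), mask = mask)
  mu_vox <- rowMeans(Xmat)
  for (m in seq_len(es$M)) {
    psi_vox <- as.numeric(basis$design %*% es$xi[, m])
    nu_oracle <- colSums((Xmat - mu_vox) * psi_vox)
    expect_rel_equal(nu[, m], nu_oracle, 1e-6)
  }
})

test_that("eigen signs are deterministic and predictions ignore W rescaling", {
  set.seed(45)
  N <- 30; K <- 15
  W <- crossprod(matrix(rnorm(2 * K * K), 2 * K)) / (2 * K)
  C <- scale(matrix(rnorm(N * K), N), center = TRUE, scale = FALSE)
  ages <- 75 + rnorm(N, sd = 5)

  es1 <- fit_fpca(C, W, pve_threshold = 0.9)
  es2 <- fit_fpca(C, W, pve_threshold = 0.9)
  expect_identical(es1$xi, es2$xi)

  kappa <- 7.3
  es_k <- fit_fpca(C, kappa * W, pve_threshold = 0.9)
  expect_rel_equal(es_k$lambda, kappa * es1$lambda, 1e-8)
  expect_equal(es_k$M, es1$M)

  nu1 <- compute_scores(C, W, es1, es1$M)
  nu_k <- compute_scores(C, kappa * W, es_k, es_k$M)
  m1 <- fit_quantile_lasso(ages, nu1, 0.5, 0)
  mk <- fit_quantile_lasso(ages, nu_k, 0.5, 0)
  expect_equal(predict_quantile(m1, nu1), predict_quantile(mk, nu_k),
               tolerance = 1e-6)
})

test_that("pivoted Cholesky fallback handles a numerically indefinite Gram", {
  set.seed(46)
  N <- 15; K <- 12
  W0 <- crossprod(matrix(rnorm(2 * K * K), 2 * K)) / (2 * K)
  # a Gram matrix whose smallest eigenvalue is pushed marginally negative,
  # as accumulated rounding does for near-collinear bases: still inside the
  # PSD tolerance, but the plain factorization hits a negative pivot
  ew <- eigen(W0, symmetric = TRUE)
  vals <- ew$values
  vals[K] <- -1e-10 * vals[1]
  W <- ew$vectors %*% (vals * t(ew$vectors))
  W <- (W + t(W)) / 2
  expect_error(chol(W))                      # fixture sanity
  C <- scale(matrix(rnorm(N * K), N), center = TRUE, scale = FALSE)
  expect_message(es <- fit_fpca(C, W, pve_threshold = 0.9), "pivoted")
  expect_equal(es$cholesky_mode, "pivoted")
  G <- t(es$xi) %*% W %*% es$xi
  expect_lt(max(abs(G - diag(es$M_max))), 1e-6)
  expect_error(fit_fpca(C, W, cholesky_mode = "plain"), "factorization")
})
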