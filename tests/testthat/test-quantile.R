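test_that("check loss formula and its empirical minimiser", {
  expect_equal(check_loss(c(3, -3), 0.5), 1.5)
  expect_equal(check_loss(1, 0.9), 0.9)
  expect_equal(check_loss(-1, 0.9), 0.1)
  expect_equal(check_loss(0, 0.3), 0)
  expect_error(check_loss(1, 1), "tau")

  # grid-search oracle: minimiser of the summed check loss is the tau-quantile
  set.seed(51)
  y <- rnorm(37)
  for (tau in c(0.2, 0.5, 0.8)) {
    grid <- sort(y)
    losses <- vapply(grid, function(q) check_loss(y - q, tau), numeric(1))
    q_oracle <- grid[which.min(losses)]
    expect_equal(unname(stats::quantile(y, tau, type = 1)), q_oracle)
  }
})

test_that("unpenalised fits are exact: noiseless recovery and LP-vertex oracle", {
  set.seed(52)
  nu <- matrix(rnorm(100), 50, 2)
  y <- 2 + nu %*% c(1, -3)
  m <- fit_quantile_lasso(y, nu, 0.5, 0)
  expect_equal(m$alpha_hat, 2, tolerance = 1e-6)
  expect_equal(m$b_hat, c(1, -3), tolerance = 1e-6)

  for (rep in 1:5) {
    nu <- matrix(rnorm(50), 25, 2)
    y <- 1 + nu %*% c(2, -1) + rnorm(25)
    for (tau in c(0.25, 0.5, 0.75)) {
      m <- fit_quantile_lasso(y, nu, tau, 0)
      sds <- m$standardization
      obj_oracle <- vertex_oracle_objective(cbind(1, sweep(nu, 2, sds, "/")),
                                            y, tau)
      expect_equal(m$objective, obj_oracle, tolerance = 1e-8)
    }
  }
})

test_that("residual sign fractions satisfy the quantile gradient condition", {
  set.seed(53)
  n <- 200
  nu <- matrix(rnorm(n * 3), n)
  y <- 70 + nu %*% c(1, -2, 0.5) + rnorm(n)
  for (tau in c(0.1, 0.5, 0.9)) {
    m <- fit_quantile_lasso(y, nu, tau, 0)
    resid <- y - predict_quantile(m, nu)
    frac_below <- mean(resid < 0)
    expect_lte(abs(frac_below - tau), (3 + 1) / n + 1 / n)
  }
})

test_that("penalty path: h_max nulls the model, support shrinks with h", {
  set.seed(54)
  n <- 150
  nu <- matrix(rnorm(n * 8), n) %*% diag(sqrt(c(25, 16, 9, 4, 2, 1, 1, 1)))
  y <- 70 + nu %*% c(0.8, -0.6, 0.5, 0, 0, 0, 0, 0) + 2 * rnorm(n)
  tau <- 0.5
  h_max <- lasso_h_max(y, nu, tau)
  m_null <- fit_quantile_lasso(y, nu, tau, h_max)
  expect_length(m_null$support, 0)
  expect_equal(m_null$alpha_hat, unname(stats::quantile(y, tau, type = 1)))

  hs <- exp(seq(log(h_max), log(h_max * 1e-3), length.out = 12))
  sizes <- vapply(hs, function(h) length(fit_quantile_lasso(y, nu, tau, h)$support),
                  integer(1))
  expect_true(all(diff(sizes) >= 0))   # h decreasing along hs -> support grows

  # penalised objective at any fitted solution <= objective of the null model
  m_mid <- fit_quantile_lasso(y, nu, tau, hs[6])
  null_obj <- sum((tau - ((y - m_null$alpha_hat) <= 0)) * (y - m_null$alpha_hat))
  expect_lte(m_mid$objective, null_obj + 1e-8)

  # constant response -> intercept-only model
  m_const <- fit_quantile_lasso(rep(5, 20), matrix(rnorm(40), 20), 0.5, 0.1)
  expect_equal(m_const$alpha_hat, 5)
  expect_length(m_const$support, 0)
})

test_that("penalty tuning: degenerate grid, null data, signal recovery", {
  set.seed(55)
  # degenerate grid of one value
  nu <- matrix(rnorm(200), 100, 2)
  y <- 70 + nu %*% c(1, -1) + rnorm(100)
  tr <- tune_h(y, nu, 0.5, h_grid = 0.37, seed = 5)
  expect_equal(tr$h_best, 0.37)
  expect_error(tune_h(y[1:6], nu[1:6, ], 0.5, n_folds = 5), "fold-size")

  # pure noise: the chosen model is empty or near-empty in most replicates
  # (the cross-validation surface is flat under the null, so occasional small
  # penalties are expected at desk scale)
  sizes <- integer(12)
  for (rep in 1:12) {
    set.seed(100 + rep)
    nuN <- matrix(rnorm(120 * 10), 120)
    yN <- 75 + 3 * rnorm(120)
    trN <- tune_h(yN, nuN, 0.5, seed = 100 + rep, grid_size = 15)
    mN <- fit_quantile_lasso(yN, nuN, 0.5, trN$h_best)
    sizes[rep] <- length(mN$support)
  }
  expect_gte(sum(sizes <= 2), 8L)
  expect_lte(stats::median(sizes), 1)

  # strong 2-variable signal among 20 noise scores at N = 400
  recovered <- 0L
  for (rep in 1:10) {
    nuS <- cbind(matrix(rnorm(400 * 2), 400) %*% diag(c(5, 4)),
                 matrix(rnorm(400 * 20), 400))
    yS <- 70 + nuS[, 1] * 1.0 - nuS[, 2] * 0.8 + 2 * rnorm(400)
    trS <- tune_h(yS, nuS, 0.5, seed = 200 + rep, grid_size = 15)
    mS <- fit_quantile_lasso(yS, nuS, 0.5, trS$h_best)
    if (all(c(1, 2) %in% mS$support)) recovered <- recovered + 1L
  }
  expect_gte(recovered, 9L)
})

test_that("post-l1 refit debiases the selected support", {
  set.seed(56)
  nu <- matrix(rnorm(200 * 4), 200)
  y <- 70 + nu %*% c(2, -1.5, 0, 0) + rnorm(200)

  # full support at h -> 0: refit equals the h = 0 fit
  m0 <- fit_quantile_lasso(y, nu, 0.5, 0)
  m_small <- fit_quantile_lasso(y, nu, 0.5, 1e-9)
  if (length(m_small$support) == 4) {
    refit <- post_l1_refit(m_small, y, nu)
    expect_equal(refit$b_hat, m0$b_hat, tolerance = 1e-6)
  }

  # empty support -> empirical tau-quantile intercept
  h_max <- lasso_h_max(y, nu, 0.25)
  m_null <- fit_quantile_lasso(y, nu, 0.25, h_max)
  refit_null <- post_l1_refit(m_null, y, nu)
  expect_equal(refit_null$alpha_hat, unname(stats::quantile(y, 0.25, type = 1)))
  expect_true(refit_null$post_l1)

  # shrinkage bias is reduced on average over replicates
  truth <- c(2, -1.5)
  err_shrunk <- err_refit <- numeric(20)
  for (rep in 1:20) {
    nuR <- matrix(rnorm(120 * 2), 120)
    yR <- 70 + nuR %*% truth + rnorm(120)
    hR <- 0.4 * lasso_h_max(yR, nuR, 0.5)
    mR <- fit_quantile_lasso(yR, nuR, 0.5, hR)
    rR <- post_l1_refit(mR, yR, nuR)
    err_shrunk[rep] <- mean(abs(mR$b_hat - truth))
    err_refit[rep] <- mean(abs(rR$b_hat - truth))
  }
  expect_lt(mean(err_refit), mean(err_shrunk))
})

test_that("prediction arithmetic and slope stability across quantiles", {
  m <- brainquantile:::new_quantile_model(0.5, alpha = 70, b = c(1, -2),
                                          gamma = NULL, h = 0, sds = c(1, 1),
                                          post_l1 = FALSE, objective = 0,
                                          converged = TRUE)
  expect_equal(predict_quantile(m, c(0, 0)), 70)
  expect_equal(predict_quantile(m, c(3, 1)), 71)
  expect_error(predict_quantile(m, c(1, 2, 3)), "shape")

  # under a pure location-shift linear model the slope is constant in tau
  set.seed(57)
  n <- 800
  z <- matrix(rnorm(n), n)
  y <- 10 + 2 * z[, 1] + rnorm(n)
  b25 <- fit_quantile_lasso(y, z, 0.25, 0)$b_hat
  b75 <- fit_quantile_lasso(y, z, 0.75, 0)$b_hat
  expect_equal(b25, 2, tolerance = 0.15)
  expect_equal(b75, 2, tolerance = 0.15)
  expect_lt(abs(b25 - b75), 0.2)
})

test_that("scalar covariates enter unpenalised alongside penalised scores", {
  set.seed(58)
  n <- 300
  nu <- matrix(rnorm(n * 3), n)
  zc <- stats::rbinom(n, 1, 0.5)
  y <- 70 + nu %*% c(1, -1, 0) + 3 * zc + rnorm(n)
  m <- fit_quantile_lasso(y, nu, 0.5, 0.5, covariates = cbind(zc))
  expect_length(m$gamma_hat, 1)
  expect_equal(m$gamma_hat, 3, tolerance = 0.6)
  pred <- predict_quantile(m, nu, covariates_new = cbind(zc))
  expect_length(pred, n)
  expect_error(predict_quantile(m, nu), "covariates_new")
})
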