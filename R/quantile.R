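#' Check (quantile) loss
#'
#' `rho_tau(u) = [tau - 1(u <= 0)] * u`: `tau * u` for positive residuals,
#' `(tau - 1) * u` otherwise. The empirical minimiser of the summed check loss
#' is the tau-quantile.
#'
#' @param u numeric vector of residuals.
#' @param tau quantile level in (0, 1).
#' @return mean check loss over the entries (nonnegative).
#' @export
check_loss <- function(u, tau) {
  if (tau <= 0 || tau >= 1) stop("`tau` must lie in (0, 1)", call. = FALSE)
  mean((tau - (u <= 0)) * u)
}

# total (summed) check loss, internal
check_loss_sum <- function(u, tau) sum((tau - (u <= 0)) * u)

# type-1 (left-continuous inverse CDF) empirical quantile: a minimiser of the
# summed check loss that is always an observed value
quantile_type1 <- function(y, tau) unname(stats::quantile(y, tau, type = 1))

# ---------------------------------------------------------------------------
# Interior-point solver for the quantile-regression linear program
#
# Primal: min_b sum_i rho_tau(y_i - x_i'b)
# Dual:   max_a y'a  s.t.  X'a = (1 - tau) X'1,  0 <= a <= 1
#
# Primal-dual path following (Frisch-Newton style) with Mehrotra
# predictor-corrector steps; feasibility is maintained exactly so only the
# complementarity gap is driven to zero. After convergence the solution is
# polished to an exact LP vertex: the p observations with the smallest
# absolute residuals are interpolated exactly and the polished coefficients
# are kept whenever they do not worsen the objective.
# ---------------------------------------------------------------------------
rq_fit_ip <- function(X, y, tau, tol = 1e-11, maxit = 100L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)

  a <- rep(1 - tau, n)
  s <- 1 - a
  b <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(0, p))
  b[is.na(b)] <- 0
  r <- as.numeric(y - X %*% b)
  eps0 <- max(1e-6, 1e-4 * stats::sd(y))
  w <- pmax(r, 0) + eps0
  z <- w - r                      # keeps z - w = -(y - Xb) exactly

  gap <- sum(z * a + w * s)
  scale_ref <- 1 + abs(sum(y * a))
  it <- 0L
  while (gap > tol * scale_ref && it < maxit) {
    it <- it + 1L
    q <- 1 / (z / a + w / s)
    Xq <- X * q
    H <- crossprod(X, Xq)
    Hc <- tryCatch(chol(H + diag(1e-12 * max(diag(H)), p)),
                   error = function(e) chol(H + diag(1e-8 * max(diag(H)) + 1e-300, p)))
    ip_solve <- function(rhs) {
      db <- backsolve(Hc, backsolve(Hc, crossprod(Xq, rhs), transpose = TRUE))
      as.numeric(db)
    }
    # predictor (affine scaling, mu = 0); dual feasibility is exact so the
    # reduced rhs is just the current residual vector
    db_a <- ip_solve(r)
    da_a <- q * (r - as.numeric(X %*% db_a))
    dz_a <- -z - (z / a) * da_a
    dw_a <- -w + (w / s) * da_a

    ap <- step_length(a, da_a, s, -da_a)
    ad <- step_length(z, dz_a, w, dw_a)
    gap_aff <- sum((z + ad * dz_a) * (a + ap * da_a) + (w + ad * dw_a) * (s - ap * da_a))
    sigma <- max(1e-8, min(1, (gap_aff / gap)^3))
    mu <- sigma * gap / (2 * n)

    # corrector with Mehrotra second-order terms
    rhs <- r + (mu - da_a * dz_a) / a - (mu + da_a * dw_a) / s
    db <- ip_solve(rhs)
    da <- q * (rhs - as.numeric(X %*% db))
    dz <- (mu - da_a * dz_a) / a - z - (z / a) * da
    dw <- (mu + da_a * dw_a) / s - w + (w / s) * da

    ap <- step_length(a, da, s, -da)
    ad <- step_length(z, dz, w, dw)
    a <- a + ap * da; s <- 1 - a
    z <- z + ad * dz; w <- w + ad * dw
    b <- b + ad * db
    r <- as.numeric(y - X %*% b)
    gap <- sum(z * a + w * s)
    scale_ref <- 1 + abs(sum(y * a))
  }

  obj <- check_loss_sum(r, tau)
  pol <- rq_polish(X, y, tau, r)
  if (!is.null(pol) && pol$obj <= obj + 1e-9 * (1 + obj)) {
    b <- pol$b; r <- pol$r; obj <- pol$obj
  }
  list(coefficients = as.numeric(b), residuals = r, objective = obj,
       iterations = it, converged = gap <= tol * scale_ref)
}

step_length <- function(x1, d1, x2, d2, damp = 0.9995) {
  ratio <- function(x, d) {
    neg <- d < 0
    if (!any(neg)) Inf else min(-x[neg] / d[neg])
  }
  min(1, damp * min(ratio(x1, d1), ratio(x2, d2)))
}

# exact-vertex polish: interpolate the p observations nearest the fit
rq_polish <- function(X, y, tau, r) {
  p <- ncol(X); n <- nrow(X)
  if (n < p) return(NULL)
  idx <- order(abs(r))[seq_len(p)]
  qr_b <- qr(X[idx, , drop = FALSE])
  if (qr_b$rank < p) return(NULL)
  b <- qr.coef(qr_b, y[idx])
  if (any(!is.finite(b))) return(NULL)
  r2 <- as.numeric(y - X %*% b)
  list(b = b, r = r2, obj = check_loss_sum(r2, tau))
}

# smallest penalty that zeroes every coefficient when the intercept sits at
# the empirical tau-quantile: h_max = max_m over both coordinate directions of
# minus the one-sided directional derivative of the check loss
lasso_h_max_std <- function(Xs, y, tau) {
  q <- quantile_type1(y, tau)
  r <- y - q
  dirderiv <- function(delta) ifelse(r > 0, tau * delta,
                              ifelse(r < 0, (tau - 1) * delta,
                                     ifelse(delta > 0, tau * delta, (tau - 1) * delta)))
  h <- 0
  for (m in seq_len(ncol(Xs))) {
    for (d in c(1, -1)) {
      h <- max(h, -sum(dirderiv(-d * Xs[, m])))
    }
  }
  h
}

#' Largest useful LASSO penalty for a quantile fit
#'
#' Computes `h_max`, the smallest penalty at which the penalised quantile
#' regression of `y` on the (internally standardized) scores returns the null
#' (intercept-only) model. The default tuning grid runs geometrically from
#' `h_max` down to `h_max * 1e-3`.
#'
#' @inheritParams fit_quantile_lasso
#' @return positive scalar.
#' @export
lasso_h_max <- function(y, scores, tau) {
  Xs <- standardize_scores(as.matrix(scores))$Xs
  lasso_h_max_std(Xs, y, tau)
}

standardize_scores <- function(scores) {
  sds <- apply(scores, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  list(Xs = sweep(scores, 2, sds, "/"), sds = sds)
}

#' LASSO-penalised linear quantile regression of age on scores
#'
#' Minimises `sum_i rho_tau(y_i - alpha - nu_i'b) + h * sum_m |b_m|`. Score
#' columns are standardized to unit variance internally before penalisation
#' (so the penalty acts comparably across components whose variances differ by
#' orders of magnitude) and coefficients are reported back on the original
#' score scale. The intercept is never penalised unless
#' `penalize_intercept = TRUE`. Optional scalar covariates are appended as
#' unpenalised columns.
#'
#' The l1 penalty is folded into the check-loss objective exactly through
#' paired pseudo-observations (`rho_tau(v) + rho_tau(-v) = |v|`), so a single
#' exact solver covers the whole path; `h = 0` is plain quantile regression.
#'
#' @param y numeric response (ages, years).
#' @param scores N x M matrix of FPC scores (or any design of penalised
#'   covariates).
#' @param tau quantile level in (0, 1).
#' @param h_lasso nonnegative penalty.
#' @param covariates optional N x P matrix of unpenalised scalar covariates.
#' @param penalize_intercept penalise the intercept too (default `FALSE`).
#' @return object of class `quantile_model`: `tau`, `alpha_hat`, `b_hat`
#'   (original score scale), `gamma_hat` (or `NULL`), `h_lasso`, `support`,
#'   `standardization`, `post_l1`, `objective` (penalised, in-sample),
#'   `converged`.
#' @export
fit_quantile_lasso <- function(y, scores, tau, h_lasso = 0, covariates = NULL,
                               penalize_intercept = FALSE) {
  if (tau <= 0 || tau >= 1) stop("`tau` must lie in (0, 1)", call. = FALSE)
  scores <- as.matrix(scores)
  n <- length(y); M <- ncol(scores)
  if (nrow(scores) != n) stop("`y` and `scores` sizes disagree", call. = FALSE)
  if (!all(is.finite(y)) || !all(is.finite(scores)))
    stop("non-finite inputs", call. = FALSE)
  if (h_lasso < 0) stop("`h_lasso` must be nonnegative", call. = FALSE)
  P <- if (is.null(covariates)) 0L else ncol(covariates)
  if (P > 0) covariates <- as.matrix(covariates)

  std <- standardize_scores(scores)

  if (stats::sd(y) == 0) {
    return(new_quantile_model(tau, alpha = y[1], b = rep(0, M),
                              gamma = if (P) rep(0, P) else NULL,
                              h = h_lasso, sds = std$sds, post_l1 = FALSE,
                              objective = 0, converged = TRUE))
  }

  if (h_lasso > 0 && h_lasso >= lasso_h_max_std(std$Xs, y, tau) && P == 0 &&
      !penalize_intercept) {
    alpha <- quantile_type1(y, tau)
    return(new_quantile_model(tau, alpha = alpha, b = rep(0, M), gamma = NULL,
                              h = h_lasso, sds = std$sds, post_l1 = FALSE,
                              objective = check_loss_sum(y - alpha, tau),
                              converged = TRUE))
  }

  Xfull <- cbind(intercept = 1, std$Xs,
                 if (P) covariates else NULL)
  if (h_lasso > 0) {
    pen_cols <- seq.int(2L, 1L + M)
    if (penalize_intercept) pen_cols <- c(1L, pen_cols)
    aug <- matrix(0, 2L * length(pen_cols), ncol(Xfull))
    for (k in seq_along(pen_cols)) {
      aug[2L * k - 1L, pen_cols[k]] <- h_lasso
      aug[2L * k, pen_cols[k]] <- -h_lasso
    }
    Xa <- rbind(Xfull, aug)
    ya <- c(y, rep(0, nrow(aug)))
  } else {
    Xa <- Xfull
    ya <- y
  }

  fit <- rq_fit_ip(Xa, ya, tau)
  co <- fit$coefficients
  alpha <- co[1]
  b_std <- co[seq.int(2L, 1L + M)]
  b_std[abs(b_std) < 1e-9 * max(1, max(abs(b_std)))] <- 0
  b <- b_std / std$sds
  gamma <- if (P) co[seq.int(2L + M, 1L + M + P)] else NULL
  new_quantile_model(tau, alpha = alpha, b = b, gamma = gamma, h = h_lasso,
                     sds = std$sds, post_l1 = FALSE,
                     objective = fit$objective, converged = fit$converged)
}

new_quantile_model <- function(tau, alpha, b, gamma, h, sds, post_l1,
                               objective, converged) {
  structure(list(tau = tau, alpha_hat = unname(alpha), b_hat = unname(b),
                 gamma_hat = if (is.null(gamma)) NULL else unname(gamma),
                 h_lasso = h, support = which(b != 0),
                 standardization = unname(sds), post_l1 = post_l1,
                 objective = unname(objective), converged = converged),
            class = "quantile_model")
}

#' @export
print.quantile_model <- function(x, ...) {
  cat(sprintf("<quantile_model> tau = %.3g, h = %.4g%s: intercept %.3f, %d/%d nonzero slopes\n",
              x$tau, x$h_lasso, if (x$post_l1) " (post-l1 refit)" else "",
              x$alpha_hat, length(x$support), length(x$b_hat)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.quantile_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("score_", seq_along(x$b_hat)),
             if (length(x$gamma_hat)) paste0("covariate_", seq_along(x$gamma_hat))),
    estimate = c(x$alpha_hat, x$b_hat, x$gamma_hat),
    penalized = c(FALSE, rep(TRUE, length(x$b_hat)),
                  rep(FALSE, length(x$gamma_hat))))
}

#' @exportS3Method generics::glance
glance.quantile_model <- function(x, ...) {
  tibble::tibble(tau = x$tau, h_lasso = x$h_lasso,
                 n_support = length(x$support), objective = x$objective,
                 post_l1 = x$post_l1, converged = x$converged)
}

#' Tune the LASSO penalty by cross-validated check loss
#'
#' Evaluates a geometric grid of penalties (default 25 values from `h_max`
#' down to `h_max * 1e-3`) by k-fold cross validation with the out-of-fold
#' check loss at level `tau` as the criterion. Folds are shuffled once per
#' call from `seed` and reused across the whole grid for comparability; ties
#' in cross-validation loss go to the largest `h` (sparser model).
#'
#' @inheritParams fit_quantile_lasso
#' @param h_grid optional penalty grid (decreasing or any order).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @param grid_size grid length when `h_grid` is not given.
#' @return object of class `tuning_result`: tibble `grid` (`h`, `cv_loss`),
#'   `h_best`, `seed`, `n_folds`.
#' @export
tune_h <- function(y, scores, tau, h_grid = NULL, n_folds = 5, seed = 1,
                   grid_size = 25) {
  scores <- as.matrix(scores)
  n <- length(y)
  if (n_folds < 2) stop("`n_folds` must be >= 2", call. = FALSE)
  if (floor(n / n_folds) < 2) stop("fold-size error: folds would have < 2 observations", call. = FALSE)
  if (is.null(h_grid)) {
    h_max <- lasso_h_max(y, scores, tau)
    if (h_max <= 0) h_max <- 1
    h_grid <- exp(seq(log(h_max), log(h_max * 1e-3), length.out = grid_size))
  }
  if (length(h_grid) == 0) stop("empty penalty grid", call. = FALSE)

  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  cv <- vapply(h_grid, function(h) {
    losses <- vapply(seq_len(n_folds), function(f) {
      tr <- fold_id != f
      m <- fit_quantile_lasso(y[tr], scores[tr, , drop = FALSE], tau, h)
      pred <- predict_quantile(m, scores[!tr, , drop = FALSE])
      check_loss(y[!tr] - pred, tau)
    }, numeric(1))
    mean(losses)
  }, numeric(1))

  best <- which(cv <= min(cv) + 1e-12)
  h_best <- max(h_grid[best])
  structure(list(grid = tibble::tibble(h = h_grid, cv_loss = cv),
                 h_best = h_best, seed = seed, n_folds = n_folds),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d penalties, %d folds (seed %d): h_best = %.5g\n",
              nrow(x$grid), x$n_folds, x$seed, x$h_best))
  invisible(x)
}

#' Post-l1 refit: unpenalised quantile regression on the selected support
#'
#' The LASSO is used only for model selection; the coefficients are then
#' re-estimated without penalty on the selected covariates, reducing shrinkage
#' bias. An empty support yields the intercept-only model (empirical
#' tau-quantile).
#'
#' @param model a penalised [fit_quantile_lasso()] model.
#' @param y,scores the training data the model was fitted on.
#' @return a debiased `quantile_model` with the same support.
#' @export
post_l1_refit <- function(model, y, scores) {
  scores <- as.matrix(scores)
  sup <- model$support
  if (length(sup) == 0) {
    alpha <- quantile_type1(y, model$tau)
    out <- new_quantile_model(model$tau, alpha = alpha,
                              b = rep(0, length(model$b_hat)), gamma = NULL,
                              h = model$h_lasso, sds = model$standardization,
                              post_l1 = TRUE,
                              objective = check_loss_sum(y - alpha, model$tau),
                              converged = TRUE)
    return(out)
  }
  refit <- fit_quantile_lasso(y, scores[, sup, drop = FALSE], model$tau, h_lasso = 0)
  b <- rep(0, length(model$b_hat))
  b[sup] <- refit$b_hat
  new_quantile_model(model$tau, alpha = refit$alpha_hat, b = b, gamma = NULL,
                     h = model$h_lasso, sds = model$standardization,
                     post_l1 = TRUE, objective = refit$objective,
                     converged = refit$converged)
}

#' Predict conditional age quantiles from scores
#'
#' `Q_hat = alpha_hat + nu %*% b_hat (+ z %*% gamma_hat)`.
#'
#' @param model a `quantile_model`.
#' @param scores_new matrix (or vector) of scores with the model's M columns.
#' @param covariates_new scalar covariates, required iff the model has
#'   `gamma_hat`.
#' @return numeric vector of predicted ages.
#' @export
predict_quantile <- function(model, scores_new, covariates_new = NULL) {
  if (is.null(dim(scores_new))) scores_new <- matrix(scores_new, nrow = 1)
  scores_new <- as.matrix(scores_new)
  if (ncol(scores_new) != length(model$b_hat))
    stop("shape error: score columns do not match the model", call. = FALSE)
  out <- model$alpha_hat + as.numeric(scores_new %*% model$b_hat)
  if (!is.null(model$gamma_hat)) {
    if (is.null(covariates_new))
      stop("model has scalar covariates; `covariates_new` required", call. = FALSE)
    out <- out + as.numeric(as.matrix(covariates_new) %*% model$gamma_hat)
  }
  out
}

#' @export
predict.quantile_model <- function(object, newdata, ...) {
  predict_quantile(object, newdata, ...)
}
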