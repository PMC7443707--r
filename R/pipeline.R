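#' Prediction-interval specification
#'
#' A nominal `1 - delta` central prediction interval is formed by quantile
#' fits at `tau_lower = delta/2` and `tau_upper = 1 - delta/2`, with the point
#' prediction at the median (`tau = 0.5`). `delta = 0.1` gives the usual 90%
#' interval (tau 0.05/0.95); `delta = 0.2` the 80% interval (tau 0.1/0.9).
#'
#' @param delta miscoverage level in (0, 1).
#' @return object of class `interval_spec`.
#' @export
interval_spec <- function(delta = 0.1) {
  if (delta <= 0 || delta >= 1) stop("`delta` must lie in (0, 1)", call. = FALSE)
  structure(list(delta = delta, tau_lower = delta / 2, tau_mid = 0.5,
                 tau_upper = 1 - delta / 2),
            class = "interval_spec")
}

#' @export
print.interval_spec <- function(x, ...) {
  cat(sprintf("<interval_spec> nominal %.0f%% interval: tau = (%g, %g, %g)\n",
              100 * (1 - x$delta), x$tau_lower, x$tau_mid, x$tau_upper))
  invisible(x)
}

# align table rows to coefficient-matrix rownames
align_table <- function(projected, table) {
  ids <- rownames(projected$coeffs_raw)
  if (!all(ids %in% table$id))
    stop("table is missing ids present in the projected dataset", call. = FALSE)
  table[match(ids, table$id), ]
}

#' Fit the full normative brain-age model on a training cohort
#'
#' Centers the basis coefficients on the training mean, runs FPCA under the
#' basis Gram inner product, truncates by PVE, and fits one LASSO-penalised
#' quantile regression of age on the scores per quantile level (penalty tuned
#' by seeded cross-validated check loss; optional post-l1 debiasing refit).
#'
#' @param projected a [project_cohort()] result for the training images.
#' @param basis the [build_basis_system()] used for projection.
#' @param table subject tibble (`id`, `age_years`, ...), matched by id.
#' @param spec an [interval_spec()].
#' @param pve proportion-of-variance threshold for the score truncation
#'   (default 0.8).
#' @param seed integer seed controlling penalty-tuning folds (tuning is seeded
#'   independently per quantile level).
#' @param post_l1 refit unpenalised on the selected support (default `FALSE`:
#'   point/interval metrics do not improve after debiasing).
#' @param tuning_folds,grid_size penalty-tuning cross-validation settings.
#' @param cholesky_mode passed to [fit_fpca()].
#' @return object of class `brainage_fit`.
#' @export
fit_brainage <- function(projected, basis, table, spec = interval_spec(0.1),
                         pve = 0.8, seed = 1, post_l1 = FALSE,
                         tuning_folds = 5, grid_size = 25,
                         cholesky_mode = "auto") {
  tab <- align_table(projected, table)
  ages <- tab$age_years
  W <- basis$gram
  C <- projected$coeffs_centered
  eig <- fit_fpca(C, W, pve_threshold = pve, cholesky_mode = cholesky_mode)
  M <- select_truncation(eig, pve)
  nu <- compute_scores(C, W, eig, M)

  taus <- c(spec$tau_lower, spec$tau_mid, spec$tau_upper)
  names(taus) <- c("lower", "median", "upper")
  models <- vector("list", 3L); names(models) <- names(taus)
  tuning <- vector("list", 3L); names(tuning) <- names(taus)
  for (k in seq_along(taus)) {
    tune <- tune_h(ages, nu, taus[[k]], n_folds = tuning_folds,
                   seed = seed + 7 * k, grid_size = grid_size)
    m <- fit_quantile_lasso(ages, nu, taus[[k]], tune$h_best)
    if (post_l1) m <- post_l1_refit(m, ages, nu)
    models[[k]] <- m
    tuning[[k]] <- tune
  }

  structure(list(mean_coeffs = projected$mean_coeffs, eigen = eig, M = M,
                 models = models, tuning = tuning, spec = spec, pve = pve,
                 seed = seed, post_l1 = post_l1, W = W,
                 basis_ref = projected$basis_ref,
                 train_ids = rownames(projected$coeffs_raw)),
            class = "brainage_fit")
}

#' @export
print.brainage_fit <- function(x, ...) {
  cat(sprintf("<brainage_fit> N = %d training subjects, M = %d scores (PVE %.2f), tau = (%g, %g, %g)\n",
              length(x$train_ids), x$M, x$pve,
              x$spec$tau_lower, x$spec$tau_mid, x$spec$tau_upper))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.brainage_fit <- function(x, ...) {
  tibble::tibble(n_train = length(x$train_ids), M = x$M, pve = x$pve,
                 delta = x$spec$delta,
                 h_lower = x$models$lower$h_lasso,
                 h_median = x$models$median$h_lasso,
                 h_upper = x$models$upper$h_lasso,
                 cholesky_mode = x$eigen$cholesky_mode)
}

make_records <- function(ids, ages, groups, q_lower, q_median, q_upper,
                         fold = NA_integer_) {
  lo <- pmin(q_lower, q_upper)
  hi <- pmax(q_lower, q_upper)
  out <- tibble::tibble(
    id = ids, age_years = ages, group = groups,
    q_lower = q_lower, q_median = q_median, q_upper = q_upper,
    brainpad = q_median - ages,
    covered = ages > lo & ages < hi,
    star_pos = ages < lo,
    star_neg = ages > hi,
    crossed = q_upper < q_lower,
    fold = fold)
  class(out) <- c("brainage_records", class(out))
  out
}

#' Predict brain age with intervals for a new cohort
#'
#' Images are centered with the training mean, scored with the training
#' eigenfunctions, and predicted at the three quantile levels of the fit.
#' For non-control cohorts the prediction reads as the equivalent brain age of
#' a healthy individual with the same image; its difference from chronological
#' age is the brainPAD.
#'
#' @param fit a [fit_brainage()] result.
#' @param projected a [project_cohort()] result for the new images (any
#'   cohort; only its raw coefficients are used). Must come from a basis
#'   compatible with the training basis.
#' @param table subject tibble with `id`, `age_years` (and optionally
#'   `group`).
#' @return a `brainage_records` tibble: one row per subject with `q_lower`,
#'   `q_median`, `q_upper`, `brainpad`, coverage and star flags.
#' @export
predict_brainage <- function(fit, projected, table) {
  if (!identical(fit$basis_ref, projected$basis_ref))
    stop("compatibility error: projection basis differs from the training basis",
         call. = FALSE)
  if (nrow(projected$coeffs_raw) == 0) return(make_records(character(), numeric(),
                                                           character(), numeric(),
                                                           numeric(), numeric()))
  tab <- align_table(projected, table)
  Cc <- center_coeffs(projected$coeffs_raw, fit$mean_coeffs)
  nu <- compute_scores(Cc, fit$W, fit$eigen, fit$M)
  make_records(tab$id, tab$age_years,
               tab$group %||% rep("unknown", nrow(tab)),
               predict_quantile(fit$models$lower, nu),
               predict_quantile(fit$models$median, nu),
               predict_quantile(fit$models$upper, nu))
}

#' @export
predict.brainage_fit <- function(object, projected, table, ...) {
  predict_brainage(object, projected, table)
}

#' Normative cross-validated training on controls
#'
#' Splits the control cohort into seeded folds; for each fold the training
#' mean, eigenfunctions, truncation and quantile models are estimated on the
#' other folds only, and the held-out subjects are centered, scored and
#' predicted with those training quantities — every control prediction is
#' strictly out-of-sample. Fold assignment is a seeded uniform shuffle without
#' stratification.
#'
#' @inheritParams fit_brainage
#' @param folds number of cross-validation folds (default 10); reduced with a
#'   warning when the cohort is too small.
#' @return a `brainage_records` tibble with a `fold` column; attributes
#'   `fold_assignments` (tibble id/fold), `train_ids` (list of per-fold
#'   training ids), `seed`, `spec`, `cholesky_modes`.
#' @export
run_normative_cv <- function(projected, basis, table, spec = interval_spec(0.1),
                             pve = 0.8, folds = 10, seed = 1, post_l1 = FALSE,
                             tuning_folds = 5, grid_size = 25) {
  tab <- align_table(projected, table)
  N <- nrow(tab)
  folds_eff <- folds
  if (N < 2 * folds) {
    folds_eff <- max(2L, N %/% 2L)
    warning(sprintf("cohort too small for %d folds; using %d", folds, folds_eff),
            call. = FALSE)
  }
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds_eff), N)))

  rec_list <- vector("list", folds_eff)
  train_ids <- vector("list", folds_eff)
  chol_modes <- character(folds_eff)
  for (f in seq_len(folds_eff)) {
    tr <- fold_id != f
    train_ids[[f]] <- tab$id[tr]
    sub_proj <- subset_projected(projected, tab$id[tr])
    fit <- fit_brainage(sub_proj, basis, tab[tr, ], spec = spec, pve = pve,
                        seed = seed + 1000 * f, post_l1 = post_l1,
                        tuning_folds = tuning_folds, grid_size = grid_size)
    chol_modes[f] <- fit$eigen$cholesky_mode
    held <- subset_projected(projected, tab$id[!tr])
    rec <- predict_brainage(fit, held, tab[!tr, ])
    rec$fold <- f
    rec_list[[f]] <- rec
  }
  out <- dplyr::bind_rows(rec_list)
  out <- out[match(tab$id, out$id), ]
  class(out) <- c("brainage_records", class(tibble::as_tibble(out)))
  attr(out, "fold_assignments") <- tibble::tibble(id = tab$id, fold = fold_id)
  attr(out, "train_ids") <- train_ids
  attr(out, "seed") <- seed
  attr(out, "spec") <- spec
  attr(out, "cholesky_modes") <- chol_modes
  out
}

subset_projected <- function(projected, ids) {
  raw <- projected$coeffs_raw[ids, , drop = FALSE]
  mean_coeffs <- colMeans(raw)
  structure(list(coeffs_raw = raw, mean_coeffs = mean_coeffs,
                 coeffs_centered = sweep(raw, 2, mean_coeffs),
                 r_squared = projected$r_squared[ids],
                 basis_ref = projected$basis_ref),
            class = "projected_dataset")
}

#' Prediction summary metrics
#'
#' MAE and RMSE of the median prediction (via brainPAD), Pearson correlation
#' between predicted and chronological age with a Fisher-z 95% confidence
#' interval, empirical interval coverage, star-positive/negative rates, and
#' the quantile-crossing count. Crossed intervals are counted but still score
#' coverage as the ordered pair (min, max).
#'
#' @param records a `brainage_records` tibble.
#' @return one-row tibble.
#' @export
compute_metrics <- function(records) {
  n <- nrow(records)
  r <- if (n >= 2) stats::cor(records$q_median, records$age_years) else NA_real_
  ci <- if (n >= 4 && is.finite(r) && abs(r) < 1) fisher_z_ci(r, n) else c(NA_real_, NA_real_)
  tibble::tibble(
    n = n,
    mae = mean(abs(records$brainpad)),
    rmse = sqrt(mean(records$brainpad^2)),
    cor = r,
    cor_ci_low = ci[1],
    cor_ci_high = ci[2],
    coverage = mean(records$covered),
    star_pos_rate = mean(records$star_pos),
    star_neg_rate = mean(records$star_neg),
    crossing_count = sum(records$crossed))
}

#' @exportS3Method generics::glance
glance.brainage_records <- function(x, ...) compute_metrics(x)

#' Fisher-z confidence interval for a correlation
#'
#' `tanh(atanh(r) +- z_{1-(1-level)/2} / sqrt(n - 3))`.
#'
#' @param r sample Pearson correlation.
#' @param n sample size (must be >= 4).
#' @param level confidence level (default 0.95).
#' @return length-2 numeric (lower, upper).
#' @export
fisher_z_ci <- function(r, n, level = 0.95) {
  if (n < 4) stop("Fisher-z interval needs n >= 4", call. = FALSE)
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Detect quantile crossings
#'
#' Subjects whose upper-level predicted age falls below the lower-level one
#' (the fitted quantile curves are not guaranteed monotone in tau). Crossings
#' are reported, never corrected.
#'
#' @param records a `brainage_records` tibble.
#' @return tibble of crossed subjects (`id`, `q_lower`, `q_upper`) with
#'   attribute `count`.
#' @export
detect_crossings <- function(records) {
  out <- dplyr::select(dplyr::filter(records, .data$crossed),
                       "id", "q_lower", "q_upper")
  out <- tibble::as_tibble(out)
  attr(out, "count") <- nrow(out)
  out
}

#' Sensitivity grid over PVE, knot spacing and nominal coverage
#'
#' Reruns the normative cross-validation for every combination of
#' proportion-of-variance threshold, knot spacing and nominal interval
#' coverage, reporting the median-model MAE (which depends only on PVE and
#' knot spacing), the coverage relative difference `1 - observed/nominal`,
#' and the crossing count. A failing combination is recorded as `NA` and the
#' grid continues; pivoted-Cholesky activations are logged per combination.
#'
#' @param volumes named list of control [volume3d()].
#' @param mask analysis [build_smooth_mask()].
#' @param table subject tibble.
#' @param pve_set,ks_set,coverage_set grid values (defaults: PVE
#'   {0.65, 0.8, 0.95}, knot spacing {6, 9, 12, 15} mm, nominal coverage
#'   {0.8, 0.9}).
#' @param degree_r spline degree.
#' @param folds,seed,... passed to [run_normative_cv()].
#' @return tibble with one row per combination.
#' @export
sensitivity_grid <- function(volumes, mask, table,
                             pve_set = c(0.65, 0.8, 0.95),
                             ks_set = c(6, 9, 12, 15),
                             coverage_set = c(0.8, 0.9),
                             degree_r = 2, folds = 10, seed = 1, ...) {
  grid_shape <- dim(volumes[[1]])
  vox <- voxel_size(volumes[[1]])
  rows <- list()
  for (ks in ks_set) {
    proj <- NULL
    basis <- tryCatch({
      b <- build_basis_system(grid_shape, vox, knot_spacing_mm = ks,
                              degree_r = degree_r, mask = mask)
      proj <- project_cohort(volumes, b, mask)
      b
    }, error = function(e) {
      message(sprintf("knot spacing %g failed: %s", ks, conditionMessage(e)))
      NULL
    })
    for (pve in pve_set) for (nominal in coverage_set) {
      row <- tibble::tibble(pve = pve, knot_spacing_mm = ks, nominal = nominal,
                            mae = NA_real_, coverage = NA_real_,
                            coverage_rel_diff = NA_real_,
                            crossing_count = NA_integer_,
                            pivoted_cholesky = NA)
      if (!is.null(basis)) {
        res <- tryCatch({
          cv <- run_normative_cv(proj, basis, table,
                                 spec = interval_spec(1 - nominal),
                                 pve = pve, folds = folds, seed = seed, ...)
          met <- compute_metrics(cv)
          row$mae <- met$mae
          row$coverage <- met$coverage
          row$coverage_rel_diff <- 1 - met$coverage / nominal
          row$crossing_count <- met$crossing_count
          row$pivoted_cholesky <- any(attr(cv, "cholesky_modes") == "pivoted")
          row
        }, error = function(e) {
          message(sprintf("combination (pve=%g, ks=%g, nominal=%g) failed: %s",
                          pve, ks, nominal, conditionMessage(e)))
          row
        })
        row <- res
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Plot prediction intervals against chronological age
#'
#' One interval per subject, sorted by predicted (median) age, with subjects
#' whose chronological age falls outside the interval flagged.
#'
#' @param object a `brainage_records` tibble.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.brainage_records <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$q_median)
  df$rank <- seq_len(nrow(df))
  df$flag <- dplyr::case_when(df$star_pos ~ "star-positive",
                              df$star_neg ~ "star-negative",
                              TRUE ~ "covered")
  ggplot2::ggplot(df, ggplot2::aes(y = .data$rank)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$q_lower, xend = .data$q_upper,
                                       yend = .data$rank), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$q_median), size = 0.8) +
    ggplot2::geom_point(ggplot2::aes(x = .data$age_years, colour = .data$flag),
                        shape = 18, size = 1.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "subject (sorted by predicted age)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
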