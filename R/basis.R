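#' Tensor-product B-spline basis restricted to a mask
#'
#' Builds the 3D tensor product of univariate B-spline bases with equidistant
#' distinct knots on each axis, evaluates it on the voxel grid, and restricts
#' it to the masked voxels. With `l_j` distinct knots (both endpoints
#' included, boundary knots repeated to full multiplicity so the basis is
#' clamped and spans constants) and spline degree `r`, each axis carries
#' `Q_j = l_j + r - 1` basis functions; the full tensor design has
#' `P1*P2*P3` rows and `Q1*Q2*Q3` columns before mask restriction. Columns
#' with no support on any masked voxel are dropped (`active_columns` indexes
#' the survivors).
#'
#' Knots are equidistant from 0 to the axis extent `(P_j - 1) * voxel_size`;
#' when the spacing does not divide the extent, the last interval is clipped
#' so the knots end exactly at the boundary.
#'
#' The Gram matrix `W = t(D) %*% D` of the masked design (unit-weight cross
#' product over masked voxels) and its Cholesky factor are computed once here
#' and reused for every projection.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_size_mm numeric length-3 (or scalar), voxel size in mm.
#' @param knot_spacing_mm distance between distinct knots, in mm (default 12,
#'   the main-analysis value; 6/9/12/15 are typical sensitivity settings).
#' @param degree_r spline degree (default 2, quadratic).
#' @param mask a [build_smooth_mask()] result on the same grid.
#' @return object of class `basis_system`.
#' @export
build_basis_system <- function(grid_shape, voxel_size_mm, knot_spacing_mm = 12,
                               degree_r = 2, mask) {
  grid_shape <- as.integer(grid_shape)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (knot_spacing_mm <= 0) stop("knot spacing must be positive", call. = FALSE)
  if (degree_r < 1) stop("degree must be >= 1", call. = FALSE)
  if (!identical(mask$grid_shape, grid_shape))
    stop("mask grid does not match `grid_shape`", call. = FALSE)

  axes <- lapply(1:3, function(j) {
    extent <- (grid_shape[j] - 1) * voxel_size_mm[j]
    if (knot_spacing_mm > extent)
      stop("degenerate basis: knot spacing exceeds the axis extent", call. = FALSE)
    knots <- seq(0, extent, by = knot_spacing_mm)
    if (utils::tail(knots, 1) < extent) knots <- c(knots, extent)  # clipped last interval
    full <- c(rep(knots[1], degree_r), knots, rep(knots[length(knots)], degree_r))
    x <- (seq_len(grid_shape[j]) - 1) * voxel_size_mm[j]
    S <- splines::splineDesign(full, x, ord = degree_r + 1, outer.ok = FALSE)
    list(knots = knots, S = S, Q = ncol(S))
  })

  S_sparse <- lapply(axes, function(a) Matrix::Matrix(a$S, sparse = TRUE))
  # raster order: axis 1 fastest => phi = S3 (x) S2 (x) S1
  phi <- S_sparse[[3]] %x% S_sparse[[2]] %x% S_sparse[[1]]
  mask_idx <- which(as.vector(mask$indicator))
  D_all <- phi[mask_idx, , drop = FALSE]
  col_norms <- sqrt(Matrix::colSums(D_all^2))
  active_columns <- which(col_norms > 0)
  D <- D_all[, active_columns, drop = FALSE]

  W <- as.matrix(Matrix::crossprod(D))
  W <- (W + t(W)) / 2
  fact <- gram_factor(W)

  structure(list(
    degree_r = degree_r,
    knot_spacing_mm = knot_spacing_mm,
    knots = lapply(axes, `[[`, "knots"),
    S = lapply(axes, `[[`, "S"),
    Q = vapply(axes, `[[`, integer(1), "Q"),
    active_columns = active_columns,
    K_active = length(active_columns),
    design = D,
    gram = W,
    gram_factor = fact,
    grid_shape = grid_shape,
    voxel_size_mm = voxel_size_mm,
    n_mask = length(mask_idx)
  ), class = "basis_system")
}

#' @export
print.basis_system <- function(x, ...) {
  cat(sprintf(paste0("<basis_system> degree %d, knot spacing %g mm, ",
                     "Q = (%s), K_active = %d of %d on %d masked voxels\n"),
              x$degree_r, x$knot_spacing_mm, paste(x$Q, collapse = ", "),
              x$K_active, prod(x$Q), x$n_mask))
  invisible(x)
}

# Factor W once for reuse: Cholesky when positive definite, otherwise an
# eigen-based pseudo-inverse (minimum-norm solutions) with a warning.
# Rank tolerance: 1e-10 relative to the largest eigenvalue.
gram_factor <- function(W) {
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (!is.null(R)) return(list(mode = "chol", R = R))
  warning("masked design is rank-deficient; projections use minimum-norm least squares",
          call. = FALSE)
  e <- eigen(W, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  list(mode = "pinv", U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
}

gram_solve <- function(fact, b) {
  if (fact$mode == "chol") {
    backsolve(fact$R, backsolve(fact$R, b, transpose = TRUE))
  } else {
    fact$U %*% (crossprod(fact$U, b) / fact$d)
  }
}

#' Project one image onto the basis by least squares
#'
#' Solves the ordinary least squares problem of the masked voxel values on the
#' masked design matrix, returning the basis coefficients and the per-image
#' R-squared (1 - SSR/SST with SST about the masked-voxel mean of the image;
#' a constant image is reported as R-squared 1 by convention).
#'
#' @param volume a [volume3d()] on the basis grid.
#' @param basis a [build_basis_system()] result.
#' @param mask the [build_smooth_mask()] the basis was built with.
#' @return list with `coeffs` (length `K_active`) and `r_squared`.
#' @export
project_image <- function(volume, basis, mask) {
  x <- mask_vectorize(volume, mask)
  if (!all(is.finite(x))) stop("input error: non-finite voxel values", call. = FALSE)
  cf <- as.numeric(gram_solve(basis$gram_factor, as.numeric(Matrix::crossprod(basis$design, x))))
  fitted <- as.numeric(basis$design %*% cf)
  ssr <- sum((x - fitted)^2)
  sst <- sum((x - mean(x))^2)
  r2 <- if (sst == 0) 1 else max(0, min(1, 1 - ssr / sst))
  list(coeffs = cf, r_squared = r2)
}

#' Project a cohort of images and center the coefficients
#'
#' Projects every image with the shared design factorization (per-image
#' projections are independent) and centers the coefficient matrix with the
#' mean over the designated training subset, so held-out images can be
#' centered consistently with [center_coeffs()].
#'
#' @param volumes named list of [volume3d()].
#' @param basis a [build_basis_system()] result.
#' @param mask matching [build_smooth_mask()].
#' @param train_ids ids over which the mean is computed (default: all).
#' @return object of class `projected_dataset`: `coeffs_raw` (N x K_active,
#'   rownames = ids), `mean_coeffs`, `coeffs_centered`, `r_squared`,
#'   `basis_ref` (basis parameters for compatibility checks).
#' @export
project_cohort <- function(volumes, basis, mask, train_ids = NULL) {
  if (length(volumes) == 0) stop("empty cohort", call. = FALSE)
  ids <- names(volumes) %||% as.character(seq_along(volumes))
  X <- vapply(volumes, mask_vectorize, numeric(mask$n_active), mask = mask)
  if (!all(is.finite(X))) stop("input error: non-finite voxel values", call. = FALSE)
  Ct <- t(as.matrix(gram_solve(basis$gram_factor, as.matrix(Matrix::crossprod(basis$design, X)))))
  rownames(Ct) <- ids
  fitted <- basis$design %*% t(Ct)
  ssr <- colSums((X - as.matrix(fitted))^2)
  sst <- colSums(sweep(X, 2, colMeans(X))^2)
  r2 <- ifelse(sst == 0, 1, pmax(0, pmin(1, 1 - ssr / sst)))

  train_ids <- train_ids %||% ids
  if (length(train_ids) == 0 || !all(train_ids %in% ids))
    stop("invalid or empty training subset", call. = FALSE)
  mean_coeffs <- colMeans(Ct[train_ids, , drop = FALSE])

  structure(list(
    coeffs_raw = Ct,
    mean_coeffs = mean_coeffs,
    coeffs_centered = sweep(Ct, 2, mean_coeffs),
    r_squared = stats::setNames(as.numeric(r2), ids),
    basis_ref = basis_fingerprint(basis)
  ), class = "projected_dataset")
}

basis_fingerprint <- function(basis) {
  list(degree_r = basis$degree_r, knot_spacing_mm = basis$knot_spacing_mm,
       Q = basis$Q, K_active = basis$K_active,
       grid_shape = basis$grid_shape, n_mask = basis$n_mask)
}

#' Center coefficients of new images with a training mean
#'
#' @param coeffs matrix (or vector) of raw basis coefficients.
#' @param mean_coeffs training-set mean coefficient vector.
#' @return centered coefficients, same shape as `coeffs`.
#' @export
center_coeffs <- function(coeffs, mean_coeffs) {
  if (is.null(dim(coeffs))) return(coeffs - mean_coeffs)
  sweep(coeffs, 2, mean_coeffs)
}

#' @export
print.projected_dataset <- function(x, ...) {
  cat(sprintf("<projected_dataset> %d images x %d basis coefficients, median R^2 = %.4f\n",
              nrow(x$coeffs_raw), ncol(x$coeffs_raw), stats::median(x$r_squared)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.projected_dataset <- function(x, ...) {
  tibble::tibble(id = rownames(x$coeffs_raw), r_squared = unname(x$r_squared))
}
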