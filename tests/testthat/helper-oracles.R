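# Independent oracles and small fixture builders used across the suite.

# Brute-force LP-vertex oracle for (unpenalised) quantile regression: the
# optimum of the piecewise-linear objective is attained at a basic solution
# interpolating p observations, so exhaustive enumeration over all p-subsets
# is exact on small instances.
vertex_oracle_objective <- function(X, y, tau) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  combs <- utils::combn(n, p)
  best <- Inf
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    Xi <- X[idx, , drop = FALSE]
    if (abs(det(Xi)) < 1e-12) next
    bb <- solve(Xi, y[idx])
    r <- y - X %*% bb
    obj <- sum((tau - (r <= 0)) * r)
    if (obj < best) best <- obj
  }
  best
}

# Dense tensor design built independently of the package's sparse path:
# explicit kronecker of the per-axis evaluation matrices.
dense_design <- function(basis, mask) {
  Dd <- kronecker(basis$S[[3]], kronecker(basis$S[[2]], basis$S[[1]]))
  Dd <- Dd[as.vector(mask$indicator), basis$active_columns, drop = FALSE]
  Dd
}

# full-grid mask (all voxels active) for a given shape
full_mask <- function(grid_shape, voxel_size_mm = 1) {
  raw <- volume3d(array(1, grid_shape), voxel_size_mm = rep_len(voxel_size_mm, 3))
  build_smooth_mask(raw, sigma_voxels = 2, threshold = 0.5)
}

# cohort of volumes lying exactly in the span of a basis
span_cohort <- function(basis, mask, coeff_matrix) {
  vox <- as.matrix(basis$design %*% coeff_matrix)
  vols <- lapply(seq_len(ncol(vox)), function(i) mask_embed(vox[, i], mask))
  names(vols) <- sprintf("img%03d", seq_len(ncol(vox)))
  vols
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(1e-300, max(abs(expected))), tol)
}
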