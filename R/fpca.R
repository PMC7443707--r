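#' Gram matrix of the masked basis
#'
#' Returns the symmetric basis product matrix `W` with entries
#' `w_kl = <phi_k, phi_l>`, computed as the unit-weight cross product over
#' masked voxels (`W = t(D) %*% D` for the masked design `D`). The cross
#' product trades a little boundary accuracy for speed relative to quadrature;
#' any positive rescaling of `W` is absorbed downstream by the regression
#' slopes, so predictions are invariant to the integration weight.
#'
#' @param basis a [build_basis_system()] result.
#' @return object of class `gram_matrix` with fields `W` and
#'   `integration_rule`.
#' @export
compute_gram_matrix <- function(basis) {
  structure(list(W = basis$gram,
                 integration_rule = "cross-product over masked voxels (unit weight)"),
            class = "gram_matrix")
}

as_gram <- function(W) {
  if (inherits(W, "gram_matrix")) W$W else as.matrix(W)
}

#' Functional PCA in basis-coefficient space
#'
#' Eigendecomposes the sample covariance operator of the projected images
#' under the `W` inner product. With centered coefficient matrix `C` and
#' Cholesky factorization `W = L L'`, the operator eigenproblem reduces to the
#' SVD of `A = (N-1)^(-1/2) C L`: eigenvalues are the squared singular values
#' and the eigenfunction coefficients are `xi = (L')^{-1} u` for right
#' singular vectors `u`, which makes `xi' W xi = I` (W-orthonormal
#' eigenfunctions). When the plain Cholesky factorization of `W` fails
#' numerically, a pivoted Cholesky factorization is used instead and the
#' triangular solve is permutation-corrected, truncating to the pivoted rank.
#'
#' Numerical rank: singular values below `rank_tol` times the largest are
#' discarded. Signs are fixed deterministically by flipping each eigenfunction
#' so that its coefficient of largest absolute value is positive.
#'
#' @param C centered coefficient matrix, N x K (column means zero over the
#'   training set).
#' @param W Gram matrix (a [compute_gram_matrix()] result or a plain matrix).
#' @param pve_threshold proportion of variance explained used to preselect the
#'   truncation `M` (default 0.8); [select_truncation()] can re-derive `M` for
#'   any other threshold.
#' @param rank_tol relative singular-value cutoff (default 1e-10).
#' @param cholesky_mode `"auto"` (pivot only on failure), `"plain"`, or
#'   `"pivoted"`.
#' @return object of class `eigen_system`: `xi` (K x M_max), `lambda`,
#'   `pve` (cumulative), `M`, `M_max`, `cholesky_mode`.
#' @export
fit_fpca <- function(C, W, pve_threshold = 0.8, rank_tol = 1e-10,
                     cholesky_mode = c("auto", "plain", "pivoted")) {
  cholesky_mode <- match.arg(cholesky_mode)
  C <- as.matrix(C)
  W <- as_gram(W)
  N <- nrow(C)
  if (N < 2) stop("sample-size error: FPCA needs N >= 2", call. = FALSE)
  K <- ncol(C)
  if (ncol(W) != K) stop("C and W dimensions disagree", call. = FALSE)

  piv <- NULL
  mode_used <- "plain"
  R <- NULL
  if (cholesky_mode != "pivoted") {
    R <- tryCatch(chol(W), error = function(e) NULL)
  }
  if (is.null(R)) {
    if (cholesky_mode == "plain")
      stop("factorization error: plain Cholesky of W failed", call. = FALSE)
    if (cholesky_mode == "auto")
      message("plain Cholesky of W failed; retrying with pivoted Cholesky")
    Rp <- suppressWarnings(chol(W, pivot = TRUE))
    rank_w <- attr(Rp, "rank")
    piv <- attr(Rp, "pivot")
    R <- Rp[seq_len(rank_w), , drop = FALSE]  # rank x K, upper-trapezoidal in pivoted order
    mode_used <- "pivoted"
  }

  if (is.null(piv)) {
    A <- C %*% t(R) / sqrt(N - 1)             # = C L / sqrt(N-1), L = t(R)
  } else {
    A <- C[, piv, drop = FALSE] %*% t(R) / sqrt(N - 1)
  }
  sv <- svd(A)
  keep <- which(sv$d > rank_tol * sv$d[1] & sv$d > 0)
  M_max <- length(keep)
  if (M_max == 0) stop("degenerate data: all eigenvalues are zero", call. = FALSE)
  lambda <- sv$d[keep]^2
  u <- sv$v[, keep, drop = FALSE]

  if (is.null(piv)) {
    xi <- backsolve(R, u)
  } else {
    rank_w <- nrow(R)
    xi_perm <- matrix(0, K, M_max)
    xi_perm[seq_len(rank_w), ] <- backsolve(R[, seq_len(rank_w), drop = FALSE], u)
    xi <- matrix(0, K, M_max)
    xi[piv, ] <- xi_perm
  }

  # deterministic sign convention
  for (m in seq_len(M_max)) {
    i <- which.max(abs(xi[, m]))
    if (xi[i, m] < 0) xi[, m] <- -xi[, m]
  }

  pve <- cumsum(lambda) / sum(lambda)
  es <- structure(list(xi = xi, lambda = lambda, pve = pve,
                       M = NA_integer_, M_max = M_max,
                       cholesky_mode = mode_used),
                  class = "eigen_system")
  es$M <- select_truncation(es, pve_threshold)
  es
}

#' @export
print.eigen_system <- function(x, ...) {
  cat(sprintf("<eigen_system> %d components (M = %d selected), leading PVE %s, Cholesky: %s\n",
              x$M_max, x$M,
              paste(sprintf("%.1f%%", 100 * x$pve[seq_len(min(3, x$M_max))]), collapse = ", "),
              x$cholesky_mode))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eigen_system <- function(x, ...) {
  tibble::tibble(component = seq_len(x$M_max),
                 eigenvalue = x$lambda,
                 pve = x$lambda / sum(x$lambda),
                 cumulative_pve = x$pve,
                 selected = seq_len(x$M_max) <= x$M)
}

#' @exportS3Method ggplot2::autoplot
autoplot.eigen_system <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$cumulative_pve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected)) +
    ggplot2::labs(x = "component", y = "cumulative proportion of variance explained") +
    ggplot2::theme_minimal()
}

#' Select the score truncation by proportion of variance explained
#'
#' @param eigen an [fit_fpca()] result.
#' @param pve_threshold target cumulative PVE in (0, 1].
#' @return the smallest `M` whose cumulative PVE reaches the threshold.
#' @export
select_truncation <- function(eigen, pve_threshold = 0.8) {
  if (pve_threshold <= 0 || pve_threshold > 1)
    stop("`pve_threshold` must lie in (0, 1]", call. = FALSE)
  if (all(eigen$lambda == 0)) stop("degenerate data: all eigenvalues are zero", call. = FALSE)
  as.integer(which(eigen$pve >= pve_threshold - 1e-12)[1])
}

#' Functional principal component scores
#'
#' Scores are W-inner products of each (training-mean-centered) image with the
#' training eigenfunctions: `nu = C W xi[, 1..M]`. The same formula applies to
#' held-out images centered with the training mean; only training scores have
#' mean zero and variance `lambda_m`.
#'
#' @param centered_coeffs N x K matrix of coefficients centered with the
#'   training mean.
#' @param W Gram matrix.
#' @param eigen an [fit_fpca()] result.
#' @param M number of leading components (default `eigen$M`).
#' @return N x M score matrix (rownames preserved).
#' @export
compute_scores <- function(centered_coeffs, W, eigen, M = eigen$M) {
  if (M > eigen$M_max) stop("truncation error: M exceeds available components", call. = FALSE)
  Cc <- as.matrix(centered_coeffs)
  if (is.null(dim(centered_coeffs))) Cc <- matrix(centered_coeffs, nrow = 1)
  nu <- Cc %*% as_gram(W) %*% eigen$xi[, seq_len(M), drop = FALSE]
  colnames(nu) <- paste0("score_", seq_len(M))
  nu
}
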