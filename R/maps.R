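#' Reconstruct the functional coefficient map on the voxel grid
#'
#' The score-space slopes define the functional coefficient
#' `beta_tau(t) = sum_m b_m,tau psi_m(t)`; its basis-coefficient vector
#' `xi %*% b_hat` is expanded through the masked design onto the grid and
#' embedded with zeros outside the mask. In a positive voxel a unit increase
#' (local expansion) in the observed image raises the predicted age at that
#' quantile; a negative voxel lowers it.
#'
#' Because the Gram matrix uses unit-weight voxel sums, the plug-in integral
#' `<X - mu, beta>` is the unit-weight voxel sum too: score-space and
#' voxel-space predictions agree under that convention.
#'
#' @param model a `quantile_model` fitted on the leading scores.
#' @param eigen the training [fit_fpca()] result.
#' @param basis the training [build_basis_system()].
#' @param mask the matching [build_smooth_mask()].
#' @return object of class `coefficient_map`: `tau` and `volume` (a
#'   [volume3d()], zero outside the mask).
#' @export
reconstruct_beta <- function(model, eigen, basis, mask) {
  M <- length(model$b_hat)
  if (M > eigen$M_max)
    stop("shape error: model has more components than the eigen system", call. = FALSE)
  coef_vec <- eigen$xi[, seq_len(M), drop = FALSE] %*% model$b_hat
  vox <- as.numeric(basis$design %*% coef_vec)
  structure(list(tau = model$tau, volume = mask_embed(vox, mask)),
            class = "coefficient_map")
}

#' @export
print.coefficient_map <- function(x, ...) {
  rng <- range(unclass(x$volume))
  cat(sprintf("<coefficient_map> tau = %g, value range [%.4g, %.4g]\n",
              x$tau, rng[1], rng[2]))
  invisible(x)
}

#' Render one eigenfunction on the voxel grid
#'
#' @param eigen a [fit_fpca()] result.
#' @param basis,mask the training basis and mask.
#' @param m component index.
#' @return a [volume3d()].
#' @export
eigenfunction_volume <- function(eigen, basis, mask, m = 1) {
  if (m > eigen$M_max) stop("component index out of range", call. = FALSE)
  mask_embed(as.numeric(basis$design %*% eigen$xi[, m]), mask)
}

#' Export a map or volume as NIfTI against a reference geometry
#'
#' @param x a `coefficient_map` or [volume3d()].
#' @param path output NIfTI path.
#' @param reference object carrying the training geometry (a `smooth_mask`,
#'   `basis_system`, or [volume3d()]); the export fails if grids or voxel
#'   sizes disagree.
#' @return `path`, invisibly.
#' @export
export_volume <- function(x, path, reference = NULL) {
  vol <- if (inherits(x, "coefficient_map")) x$volume else x
  if (!is.null(reference)) {
    ref_shape <- if (inherits(reference, "smooth_mask")) reference$grid_shape
                 else if (inherits(reference, "basis_system")) reference$grid_shape
                 else dim(reference)
    ref_vox <- if (inherits(reference, c("smooth_mask", "basis_system")))
                 reference$voxel_size_mm else voxel_size(reference)
    if (!identical(as.integer(dim(vol)), as.integer(ref_shape)) ||
        !isTRUE(all.equal(voxel_size(vol), as.numeric(ref_vox))))
      stop("geometry error: volume does not match the reference grid", call. = FALSE)
  }
  write_volume(vol, path)
}

#' Plot axial slices of a volume or coefficient map
#'
#' @param x a [volume3d()] or `coefficient_map`.
#' @param slices z-indices to display (default: three evenly spaced).
#' @return a ggplot object.
#' @export
plot_slices <- function(x, slices = NULL) {
  vol <- if (inherits(x, "coefficient_map")) x$volume else x
  d <- dim(vol)
  slices <- slices %||% unique(round(stats::quantile(seq_len(d[3]), c(0.25, 0.5, 0.75))))
  df <- purrr::map_dfr(slices, function(z) {
    tibble::tibble(x = rep(seq_len(d[1]), d[2]),
                   y = rep(seq_len(d[2]), each = d[1]),
                   value = as.vector(unclass(vol)[, , z]),
                   slice = paste0("z = ", z))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$slice)) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
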