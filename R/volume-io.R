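#' Construct a 3D volume
#'
#' Light container for a registered 3D image on a regular voxel grid, e.g. a
#' tensor-based morphometry (TBM) map where each voxel holds the Jacobian
#' determinant of the deformation to a common template.
#'
#' Voxel indices are 0-based with voxel centers at integer grid coordinates in
#' voxel units; physical coordinates are `index * voxel_size_mm`.
#'
#' @param data numeric 3D array (all values finite).
#' @param voxel_size_mm positive length-3 numeric, voxel edge lengths in mm.
#' @param orientation axis-convention label; volumes are assumed pre-registered
#'   and identically oriented, only shape is ever validated.
#' @return object of class `volume3d` (a 3D array with attributes).
#' @export
volume3d <- function(data, voxel_size_mm = c(1, 1, 1), orientation = "RAS") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(data))) stop("volume contains non-finite values", call. = FALSE)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  structure(data,
            voxel_size_mm = voxel_size_mm,
            orientation = orientation,
            class = c("volume3d", "array"))
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume3d> %d x %d x %d voxels, voxel size %s mm\n",
              d[1], d[2], d[3],
              paste(signif(attr(x, "voxel_size_mm"), 4), collapse = " x ")))
  invisible(x)
}

voxel_size <- function(volume) attr(volume, "voxel_size_mm") %||% c(1, 1, 1)

#' Read a cohort of registered volumes and its subject table
#'
#' Loads NIfTI volumes and a delimited subject table (columns `id`, `age`,
#' `group`), validates that all volumes share one grid and voxel size and that
#' volume ids and table ids match one-to-one, and returns the volumes ordered
#' as in the table. Fails atomically: any inconsistency raises before anything
#' is returned.
#'
#' @param volume_paths character vector of NIfTI paths; names are taken as
#'   subject ids (unnamed paths use the base filename without extensions).
#' @param table_path path to a CSV file with header `id,age,group`.
#' @return list with elements `volumes` (named list of [volume3d()]) and
#'   `table` (tibble with `id`, `age_years`, `group`).
#' @export
read_cohort <- function(volume_paths, table_path) {
  ids <- names(volume_paths)
  if (is.null(ids)) {
    ids <- sub("\\.nii(\\.gz)?$", "", basename(volume_paths))
  }
  tab <- readr::read_csv(table_path, show_col_types = FALSE)
  need <- c("id", "age")
  if (!all(need %in% names(tab)))
    stop("subject table must have columns `id` and `age`", call. = FALSE)
  tab <- tibble::tibble(
    id = as.character(tab$id),
    age_years = as.numeric(tab$age),
    group = if ("group" %in% names(tab)) as.character(tab$group) else "control"
  )
  if (anyDuplicated(tab$id))
    stop("join error: duplicate subject ids in table", call. = FALSE)
  if (!all(is.finite(tab$age_years)) || any(tab$age_years <= 0))
    stop("ages must be finite and positive", call. = FALSE)
  if (anyDuplicated(ids))
    stop("join error: duplicate volume ids", call. = FALSE)
  if (!setequal(ids, tab$id))
    stop("join error: volume ids and table ids do not match", call. = FALSE)

  vols <- lapply(volume_paths, function(p) {
    img <- tryCatch(RNifti::readNifti(p),
                    error = function(e) stop(sprintf("I/O error reading %s: %s", p, conditionMessage(e)),
                                             call. = FALSE))
    pd <- RNifti::pixdim(img)[seq_len(3)]
    volume3d(array(as.numeric(img), dim = dim(img)), voxel_size_mm = pd)
  })
  names(vols) <- ids

  shapes <- vapply(vols, function(v) paste(dim(v), collapse = "x"), character(1))
  if (length(unique(shapes)) > 1L)
    stop("cohort inconsistency: volumes have differing shapes (",
         paste(unique(shapes), collapse = ", "), ")", call. = FALSE)
  vox <- vapply(vols, function(v) paste(signif(voxel_size(v), 8), collapse = "x"), character(1))
  if (length(unique(vox)) > 1L)
    stop("cohort inconsistency: volumes have differing voxel sizes", call. = FALSE)

  list(volumes = vols[tab$id], table = tab)
}

#' Write a volume to NIfTI
#'
#' @param volume a [volume3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- array(as.numeric(volume), dim(volume))
  attr(arr, "pixdim") <- voxel_size(volume)
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "double")
  invisible(path)
}

# -- separable Gaussian smoothing with reflective boundaries ------------------

gaussian_kernel <- function(sigma) {
  radius <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k / sum(k)
}

# P x P convolution operator for one axis; indices outside [1, P] are
# reflected about the boundary (symmetric, edge voxel included).
reflect_conv_matrix <- function(P, kernel) {
  radius <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, P, P)
  for (off in seq(-radius, radius)) {
    j <- seq_len(P) + off
    repeat {
      bad_lo <- j < 1L
      bad_hi <- j > P
      if (!any(bad_lo) && !any(bad_hi)) break
      j[bad_lo] <- 1L - j[bad_lo]
      j[bad_hi] <- 2L * P + 1L - j[bad_hi]
    }
    M[cbind(seq_len(P), j)] <- M[cbind(seq_len(P), j)] + kernel[off + radius + 1L]
  }
  M
}

gaussian_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- gaussian_kernel(sigma)
  d <- dim(arr)
  # axis 1
  out <- reflect_conv_matrix(d[1], k) %*% matrix(arr, d[1], d[2] * d[3])
  out <- array(out, d)
  # axis 2
  out <- aperm(out, c(2, 1, 3))
  out <- array(reflect_conv_matrix(d[2], k) %*% matrix(out, d[2], d[1] * d[3]),
               c(d[2], d[1], d[3]))
  out <- aperm(out, c(2, 1, 3))
  # axis 3
  out <- aperm(out, c(3, 1, 2))
  out <- array(reflect_conv_matrix(d[3], k) %*% matrix(out, d[3], d[1] * d[2]),
               c(d[3], d[1], d[2]))
  aperm(out, c(2, 3, 1))
}

#' Build a smooth analysis mask from a raw binary mask
#'
#' Smooths the raw 0/1 mask with an isotropic Gaussian kernel (default SD of
#' 2 voxels) and thresholds the smoothed field (default 0.5), regularising the
#' mask boundary. Smoothing uses reflective boundary handling so the mask is
#' not artificially eroded at grid edges.
#'
#' @param raw_mask a [volume3d()] with binary (0/1) data.
#' @param sigma_voxels Gaussian standard deviation in voxel units.
#' @param threshold inclusion threshold on the smoothed field, in (0, 1).
#' @return object of class `smooth_mask` with fields `indicator` (logical 3D
#'   array), `sigma_voxels`, `threshold`, `n_active`, `grid_shape`,
#'   `voxel_size_mm`.
#' @export
build_smooth_mask <- function(raw_mask, sigma_voxels = 2, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  arr <- unclass(raw_mask)
  if (!all(arr %in% c(0, 1)))
    stop("`raw_mask` must be binary (0/1)", call. = FALSE)
  if (sum(arr) == 0)
    stop("degenerate mask: raw mask has no nonzero voxel", call. = FALSE)
  smoothed <- gaussian_smooth_3d(arr, sigma_voxels)
  indicator <- smoothed > threshold
  n_active <- sum(indicator)
  if (n_active == 0)
    stop("degenerate mask: no voxel survives smoothing and thresholding", call. = FALSE)
  structure(list(indicator = indicator,
                 sigma_voxels = sigma_voxels,
                 threshold = threshold,
                 n_active = n_active,
                 grid_shape = dim(arr),
                 voxel_size_mm = voxel_size(raw_mask)),
            class = "smooth_mask")
}

#' @export
print.smooth_mask <- function(x, ...) {
  cat(sprintf("<smooth_mask> %s grid, %d active voxels (sigma = %g vox, threshold = %g)\n",
              paste(x$grid_shape, collapse = "x"), x$n_active,
              x$sigma_voxels, x$threshold))
  invisible(x)
}

#' Convert between grid and masked-vector representations
#'
#' `mask_vectorize()` extracts the masked voxels of a volume as a vector in
#' fixed raster order (first axis fastest, then second, then third — R's
#' native array order, matching the Kronecker order of the tensor-product
#' design so design rows align with vectorized voxels).
#' `mask_embed()` is its right inverse: it places a vector back on the grid,
#' with zeros outside the mask.
#'
#' @param volume a [volume3d()] (or plain 3D array) matching the mask grid.
#' @param mask a [build_smooth_mask()] result.
#' @return `mask_vectorize()`: numeric vector of length `mask$n_active`.
#' @export
mask_vectorize <- function(volume, mask) {
  arr <- unclass(volume)
  if (!identical(dim(arr), mask$grid_shape))
    stop("shape error: volume and mask grids differ", call. = FALSE)
  as.numeric(arr[mask$indicator])
}

#' @param values numeric vector of length `mask$n_active`.
#' @rdname mask_vectorize
#' @return `mask_embed()`: a [volume3d()], zero outside the mask.
#' @export
mask_embed <- function(values, mask) {
  if (length(values) != mask$n_active)
    stop("shape error: vector length does not match mask$n_active", call. = FALSE)
  arr <- array(0, mask$grid_shape)
  arr[mask$indicator] <- values
  volume3d(arr, voxel_size_mm = mask$voxel_size_mm)
}
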