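#' 3D volume grid
#'
#' A `volume_grid` is the package's in-memory representation of one 3D scalar
#' image: a numeric array plus voxel dimensions (mm) and a 4x4 affine mapping
#' voxel indices to MNI mm coordinates. The affine follows the NIfTI
#' convention: it is applied to zero-based indices, so R's 1-based array index
#' `(i, j, k)` maps to `affine %*% c(i - 1, j - 1, k - 1, 1)`.
#'
#' @param values numeric 3D array of voxel values.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param affine optional 4x4 voxel-to-mm matrix. Defaults to a diagonal
#'   affine with the grid centre at the mm origin.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, voxel_size = c(1, 1, 1), affine = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (any(!is.finite(values)))
    stop("'values' must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop("voxel dimensions must be positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (dim(values) - 1) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be an invertible 4x4 matrix")
  structure(list(values = values, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 3), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Convert between voxel indices and mm coordinates
#'
#' `voxel_to_mm` maps 1-based voxel indices to mm coordinates through the
#' grid's affine; `mm_to_voxel` inverts the map (returning fractional,
#' 1-based indices).
#'
#' @param grid a [volume_grid()].
#' @param ijk integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @param mm numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @return an n x 3 numeric matrix.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- rbind_coords(ijk)
  xyz1 <- cbind(ijk - 1, 1) %*% t(grid$affine)
  xyz1[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_mm
#' @export
mm_to_voxel <- function(grid, mm) {
  mm <- rbind_coords(mm)
  ijk0 <- cbind(mm, 1) %*% t(solve(grid$affine))
  ijk0[, 1:3, drop = FALSE] + 1
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  x
}

# mm coordinates of every voxel centre, in array (linear index) order
grid_coordinates <- function(grid) {
  d <- dim(grid$values)
  ijk <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
               rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               rep(seq_len(d[3]), each = d[1] * d[2]))
  voxel_to_mm(grid, ijk)
}

#' Read and write volume grids as NIfTI-1
#'
#' Thin wrappers around RNifti. `write_volume` stores the grid's affine as
#' both qform and sform; `read_volume` reconstructs the `volume_grid` from
#' the image xform.
#'
#' @param grid a [volume_grid()].
#' @param file path to a `.nii` or `.nii.gz` file.
#' @return `read_volume` returns a [volume_grid()]; `write_volume` returns
#'   `file` invisibly.
#' @export
write_volume <- function(grid, file) {
  img <- RNifti::asNifti(grid$values)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_volume
#' @export
read_volume <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- RNifti::xform(img)
  # RNifti reports an RAS xform; pixdim gives voxel sizes
  vox <- attr(img, "pixdim")[1:3]
  volume_grid(as.array(img), voxel_size = abs(vox), affine = aff)
}

gaussian_kernel_matrix <- function(n, sigma_vox, wrap = FALSE) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  if (wrap) d <- pmin(d, n - d)
  K <- exp(-d^2 / (2 * sigma_vox^2))
  K[d > r] <- 0
  K / rowSums(K)  # renormalised truncated kernel
}

apply_along <- function(x, K, axis) {
  d <- dim(x)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  yp <- K %*% matrix(xp, nrow = dp[1])
  dim(yp) <- dp
  aperm(yp, order(perm))
}

#' Smooth a 3D array with a separable Gaussian kernel
#'
#' FWHM is converted to the kernel standard deviation by
#' FWHM = sqrt(8 ln 2) * sigma (~ 2.3548 sigma). With `wrap = TRUE` the
#' convolution is circulant, producing a stationary field with exactly the
#' requested autocorrelation everywhere; with `wrap = FALSE` the truncated
#' kernel is renormalised at the edges.
#'
#' @param x numeric 3D array.
#' @param fwhm smoothing kernel FWHM in mm (scalar or per axis).
#' @param voxel_size voxel edge lengths in mm.
#' @param wrap logical, use periodic boundary conditions.
#' @return a smoothed array of the same dimensions.
#' @export
smooth_volume <- function(x, fwhm, voxel_size = c(1, 1, 1), wrap = FALSE) {
  if (length(fwhm) == 1L) fwhm <- rep(fwhm, 3L)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(fwhm < 0)) stop("FWHM must be nonnegative")
  sigma <- fwhm / (sqrt(8 * log(2)) * voxel_size)
  for (ax in 1:3) {
    if (sigma[ax] > 0) {
      if (wrap && 4 * sigma[ax] > dim(x)[ax] / 2)
        stop("smoothing kernel exceeds the grid extent on axis ", ax)
      K <- gaussian_kernel_matrix(dim(x)[ax], sigma[ax], wrap = wrap)
      x <- apply_along(x, K, ax)
    }
  }
  x
}

#' Generate a smooth Gaussian random field
#'
#' White Gaussian noise convolved (periodically) with a Gaussian kernel of
#' the requested FWHM, then standardised to zero mean and unit variance over
#' the whole grid. The periodic convolution makes the field stationary, so
#' its true autocorrelation equals the kernel's, which is what the
#' smoothness estimator assumes.
#'
#' @param dim integer length-3 grid shape.
#' @param fwhm smoothness in mm (scalar or per axis); 0 gives white noise.
#' @param voxel_size voxel edge lengths in mm.
#' @return a numeric 3D array with mean 0 and SD 1.
#' @export
gaussian_field <- function(dim, fwhm = 0, voxel_size = c(1, 1, 1)) {
  x <- array(stats::rnorm(prod(dim)), dim = dim)
  if (any(fwhm > 0)) x <- smooth_volume(x, fwhm, voxel_size, wrap = TRUE)
  (x - mean(x)) / stats::sd(x)
}
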