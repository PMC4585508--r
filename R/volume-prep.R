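#' Build a tissue mask from a template
#'
#' Voxels with template tissue probability strictly greater than the
#' threshold are retained; analyses are constrained to this mask to avoid
#' edge effects between tissue classes.
#'
#' @param template a [volume_grid()] with values in [0, 1].
#' @param threshold probability cut (default 0.25); comparison is strict.
#' @return ordered integer vector of 1-based linear voxel indices.
#' @export
build_mask <- function(template, threshold = 0.25) {
  v <- as.numeric(template$values)
  if (any(v < 0 | v > 1)) stop("template values must lie in [0, 1]")
  idx <- which(v > threshold)
  if (length(idx) == 0L) stop("empty mask: no voxel exceeds the threshold")
  idx
}

#' Total tissue volume of a map
#'
#' Sums the partial volume estimates over the whole map and converts to
#' cubic centimetres using the voxel volume.
#'
#' @param map a [volume_grid()] with nonnegative values.
#' @return total volume in cm^3.
#' @export
total_tissue_volume <- function(map) {
  if (any(map$values < 0)) stop("negative voxel values")
  sum(map$values) * prod(map$voxel_size) / 1000
}

#' Rescale a map to relative regional volume
#'
#' Divides every voxel by the subject's total tissue volume (cm^3), giving
#' maps of regional volume relative to individual total volume. When the
#' total was computed from the same map, the rescaled map integrates to 1.
#'
#' @param map a [volume_grid()].
#' @param total total tissue volume in cm^3 (> 0).
#' @return a [volume_grid()] of relative volumes.
#' @export
scale_to_relative <- function(map, total) {
  if (!is.numeric(total) || length(total) != 1L || total <= 0)
    stop("'total' must be a single positive volume in cm^3")
  map$values <- map$values / total
  map
}

#' Assemble a cohort matrix
#'
#' A `cohort_matrix` holds one tissue class for all subjects as a dense
#' subjects x masked-voxels matrix, together with the mask's voxel-index
#' register and the template grid (for mapping columns back to space).
#'
#' @param data subjects x voxels matrix over the full grid, or already
#'   restricted to `mask_index` columns (detected by column count).
#' @param mask_index 1-based linear voxel indices, as from [build_mask()].
#' @param grid the template [volume_grid()].
#' @param tissue `"GM"` or `"WM"`.
#' @param subjects character vector of subject ids (row order).
#' @param totals optional per-subject total volumes (cm^3); when supplied,
#'   rows are rescaled to relative volume.
#' @return an object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(data, mask_index, grid, tissue = c("GM", "WM"),
                          subjects = rownames(data), totals = NULL) {
  tissue <- match.arg(tissue)
  data <- as.matrix(data)
  if (ncol(data) == prod(dim(grid$values))) {
    data <- data[, mask_index, drop = FALSE]
  } else if (ncol(data) != length(mask_index)) {
    stop("column count matches neither the grid nor the mask")
  }
  if (!is.null(totals)) {
    if (length(totals) != nrow(data)) stop("one total per subject required")
    if (any(totals <= 0)) stop("totals must be positive")
    data <- data / totals
  }
  if (any(!is.finite(data))) stop("cohort matrix contains non-finite values")
  if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(nrow(data)))
  rownames(data) <- subjects
  structure(list(data = data, mask_index = as.integer(mask_index),
                 grid = grid, tissue = tissue, subjects = subjects),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("<cohort_matrix> ", x$tissue, ": ", nrow(x$data), " subjects x ",
      ncol(x$data), " masked voxels\n", sep = "")
  invisible(x)
}

#' Scatter masked values back onto the full grid
#'
#' @param values numeric vector, one value per masked voxel.
#' @param mask_index mask voxel indices.
#' @param grid the template [volume_grid()].
#' @param fill value for voxels outside the mask.
#' @return a [volume_grid()] carrying the scattered values.
#' @export
unmask <- function(values, mask_index, grid, fill = 0) {
  full <- rep(fill, prod(dim(grid$values)))
  full[mask_index] <- values
  grid$values <- array(full, dim(grid$values))
  grid
}

#' Standardize a cohort matrix by age
#'
#' Per voxel, removes the linear effect of age by ordinary least squares
#' and restores the voxel's cross-subject mean: the result has zero sample
#' correlation with age at every voxel but keeps the original means and
#' residual scale. The operation is idempotent.
#'
#' @param matrix a [cohort_matrix()].
#' @param ages numeric vector of ages in years, one per subject.
#' @return a [cohort_matrix()] of the same shape.
#' @export
standardize_by_age <- function(matrix, ages) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  if (length(ages) != nrow(matrix$data)) stop("one age per subject required")
  if (nrow(matrix$data) < 3L) stop("need at least 3 subjects")
  a <- ages - mean(ages)
  ssa <- sum(a^2)
  if (ssa == 0) stop("constant age vector: cannot standardize by age")
  mu <- colMeans(matrix$data)
  yc <- sweep(matrix$data, 2, mu)
  beta <- crossprod(a, yc) / ssa           # 1 x V slopes
  matrix$data <- yc - outer(a, as.numeric(beta)) +
    matrix(mu, nrow(matrix$data), ncol(matrix$data), byrow = TRUE)
  rownames(matrix$data) <- matrix$subjects
  matrix
}
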