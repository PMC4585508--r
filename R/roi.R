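#' Build a sphere ROI around an MNI coordinate
#'
#' Membership is a closed ball on voxel centres: a voxel belongs to the
#' ROI when its centre lies at Euclidean mm distance <= radius from the
#' given MNI coordinate. Radius 0 therefore yields exactly the voxel
#' containing the centre.
#'
#' @param center_mm length-3 MNI coordinate in mm.
#' @param radius_mm sphere radius in mm (default 6).
#' @param grid the template [volume_grid()].
#' @return an object of class `sphere_roi`: list with `center_mm`,
#'   `radius_mm` and `voxel_index` (1-based linear indices).
#' @export
make_sphere_roi <- function(center_mm, radius_mm = 6, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  d <- dim(grid$values)
  vc <- mm_to_voxel(grid, center_mm)
  if (any(vc < 0.5) || any(vc > d + 0.5))
    stop("ROI centre falls outside the grid")
  # search only the bounding cube of the sphere
  halo <- ceiling(radius_mm / grid$voxel_size) + 1
  rng <- lapply(1:3, function(k)
    max(1, floor(vc[k] - halo[k])):min(d[k], ceiling(vc[k] + halo[k])))
  ijk <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  mm <- voxel_to_mm(grid, ijk)
  d2 <- (mm[, 1] - center_mm[1])^2 + (mm[, 2] - center_mm[2])^2 +
    (mm[, 3] - center_mm[3])^2
  keep <- d2 <= radius_mm^2
  if (!any(keep)) {
    # radius smaller than the voxel: take the voxel containing the centre
    ijk0 <- pmin(pmax(round(vc), 1), d)
    keep_idx <- ijk0[1] + d[1] * (ijk0[2] - 1) + d[1] * d[2] * (ijk0[3] - 1)
  } else {
    sel <- ijk[keep, , drop = FALSE]
    keep_idx <- sel[, 1] + d[1] * (sel[, 2] - 1) + d[1] * d[2] * (sel[, 3] - 1)
  }
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 voxel_index = sort(as.integer(keep_idx))),
            class = "sphere_roi")
}

#' @export
print.sphere_roi <- function(x, ...) {
  cat("<sphere_roi> centre (", paste(x$center_mm, collapse = ", "),
      ") mm, radius ", x$radius_mm, " mm, ", length(x$voxel_index),
      " voxels\n", sep = "")
  invisible(x)
}

#' Extract per-subject mean regional volume for an ROI
#'
#' Arithmetic mean of the cohort matrix over the ROI voxels (restricted to
#' the analysis mask; out-of-mask ROI voxels are dropped with a message).
#'
#' @param matrix a [cohort_matrix()] (absolute or relative volumes).
#' @param roi a [make_sphere_roi()] result.
#' @return named numeric vector, one mean per subject.
#' @export
extract_roi_means <- function(matrix, roi) {
  stopifnot(inherits(matrix, "cohort_matrix"), inherits(roi, "sphere_roi"))
  cols <- match(roi$voxel_index, matrix$mask_index)
  dropped <- sum(is.na(cols))
  cols <- cols[!is.na(cols)]
  if (length(cols) == 0L) stop("ROI lies entirely outside the analysis mask")
  if (dropped > 0)
    message(dropped, " ROI voxel(s) outside the mask were dropped")
  out <- rowMeans(matrix$data[, cols, drop = FALSE])
  names(out) <- matrix$subjects
  out
}

#' Two-group ROI comparison
#'
#' Pooled-variance independent-sample t-test on per-subject regional
#' volumes, with the unsigned Cohen's d (pooled-SD denominator).
#'
#' @param values numeric vector of per-subject ROI means.
#' @param labels two-level factor of group membership.
#' @return list with `t`, `df`, `p` (two-sided), `d`, and per-group `n`,
#'   `mean`, `sd`.
#' @export
roi_group_test <- function(values, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("'labels' must have exactly 2 levels")
  g1 <- values[labels == levels(labels)[1]]
  g2 <- values[labels == levels(labels)[2]]
  if (length(g1) < 2L || length(g2) < 2L) stop("need >= 2 subjects per group")
  s1 <- summarize_group(g1); s2 <- summarize_group(g2)
  sp <- pooled_sd(s1, s2)
  tt <- t_from_summary(s1, s2)
  list(t = tt$t, df = tt$df,
       p = 2 * stats::pt(abs(tt$t), tt$df, lower.tail = FALSE),
       d = cohens_d_from_summary(s1, s2),
       groups = stats::setNames(list(s1, s2), levels(labels)),
       pooled_sd = sp)
}

#' MANCOVA with the Hotelling-Lawley trace
#'
#' Multivariate group comparison over a set of ROI volumes with nuisance
#' covariates: the covariates (plus intercept) form the reduced model, the
#' group factor is added for the full model, and the Hotelling-Lawley
#' trace tr(H E^-1) is computed from the hypothesis and error SSCP
#' matrices, with the conventional F approximation. For a 2-level group
#' this is Hotelling's T^2: F = trace * (ve - p + 1) / p on (p, ve - p + 1)
#' degrees of freedom, where ve = n - rank(full design).
#'
#' @param responses subjects x ROIs numeric matrix.
#' @param group factor of group membership.
#' @param covariates optional data frame / matrix of nuisance covariates
#'   (numeric columns entered as-is, factors as dummies).
#' @return list with `trace`, `F`, `df1`, `df2`, `p`.
#' @export
mancova_hotelling <- function(responses, group, covariates = NULL) {
  Y <- as.matrix(responses)
  group <- droplevels(as.factor(group))
  n <- nrow(Y); p <- ncol(Y); q <- nlevels(group) - 1L
  if (q < 1L) stop("'group' must have at least 2 levels")
  Xr <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    Xr <- stats::model.matrix(~., data = covariates)
  }
  Xf <- cbind(Xr, stats::model.matrix(~group)[, -1, drop = FALSE])
  if (n <= ncol(Xf) + p)
    stop("too few subjects for ", p, " responses and ", ncol(Xf), " regressors")
  check_full_rank(Xf)
  res_f <- stats::lm.fit(Xf, Y)$residuals
  res_r <- stats::lm.fit(Xr, Y)$residuals
  E <- crossprod(res_f)
  H <- crossprod(res_r) - E
  Ei <- tryCatch(solve(E), error = function(e)
    stop("singular within-group covariance"))
  trace <- sum(diag(H %*% Ei))
  ve <- n - ncol(Xf)
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (ve - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- 2 * (s * nn + 1)
  Fstat <- df2 * trace / (s * df1)
  list(trace = trace, F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Bundled ROI coordinate tables
#'
#' `published_delay_rois()` returns the six 6-mm sphere ROI centres (MNI
#' mm) at which earlier voxel-based morphometry studies reported
#' volumetric differences between autistic individuals with and without
#' early language delay, with the originally reported direction
#' (`delay_gt_nodelay`). `canonical_language_rois()` returns nominal
#' centroids for thirteen canonical language regions; these centroids are
#' synthetic stand-ins for testing the multivariate ROI machinery, not a
#' validated parcellation (see the file's header comment).
#'
#' @return a `data.frame` with columns `label`, `tissue`, `x`, `y`, `z`
#'   (and `direction` for the published set).
#' @export
published_delay_rois <- function() {
  utils::read.csv(system.file("extdata", "published_delay_rois.csv",
                              package = "langmorph"),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname published_delay_rois
#' @export
canonical_language_rois <- function() {
  utils::read.csv(system.file("extdata", "canonical_language_rois_synthetic.csv",
                              package = "langmorph"),
                  comment.char = "#", stringsAsFactors = FALSE)
}
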