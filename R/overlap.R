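#' Estimate the spatial smoothness (FWHM) of a statistic map
#'
#' Per-axis FWHM from the variance of first differences of the map after
#' standardization on the mask. For a stationary field with Gaussian
#' autocorrelation, adjacent-voxel differences satisfy
#' var(diff) = 2 (1 - exp(-1 / (4 sigma^2))) with sigma in voxels, which
#' inverts to FWHM_k = voxel_k * sqrt(-2 ln 2 / ln(1 - var(diff)/2)).
#' Only difference pairs with both voxels inside the mask contribute.
#'
#' @param stat a `stat_map`, or a [volume_grid()] together with
#'   `mask_index`.
#' @param mask_index mask voxel indices (taken from `stat` if omitted).
#' @return an object of class `smoothness_estimate`: list with `fwhm_mm`
#'   (per axis), `fwhm_vox` and `resel_count`.
#' @export
estimate_smoothness <- function(stat, mask_index = NULL) {
  if (inherits(stat, "stat_map")) {
    grid <- stat$grid
    if (is.null(mask_index)) mask_index <- stat$mask_index
    vals <- stat$t
  } else if (inherits(stat, "volume_grid")) {
    grid <- stat
    if (is.null(mask_index)) mask_index <- seq_len(prod(dim(grid$values)))
    vals <- as.numeric(grid$values)[mask_index]
  } else stop("'stat' must be a stat_map or a volume_grid")
  if (stats::sd(vals) == 0) stop("map is constant on the mask")

  d <- dim(grid$values)
  full <- rep(NA_real_, prod(d))
  full[mask_index] <- (vals - mean(vals)) / stats::sd(vals)
  z <- array(full, d)

  fwhm_vox <- numeric(3)
  for (ax in 1:3) {
    hi <- lo <- lapply(d, seq_len)
    lo[[ax]] <- seq_len(d[ax] - 1L)
    hi[[ax]] <- lo[[ax]] + 1L
    dif <- z[hi[[1]], hi[[2]], hi[[3]]] - z[lo[[1]], lo[[2]], lo[[3]]]
    dif <- dif[!is.na(dif)]
    if (length(dif) < 2L) stop("too few within-mask difference pairs on axis ", ax)
    vd <- stats::var(dif)
    rho <- 1 - vd / 2
    fwhm_vox[ax] <- if (rho <= 0) 0 else sqrt(-2 * log(2) / log(rho))
  }
  fwhm_mm <- fwhm_vox * grid$voxel_size
  resel <- length(mask_index) / prod(pmax(fwhm_vox, 1))
  structure(list(fwhm_mm = fwhm_mm, fwhm_vox = fwhm_vox,
                 resel_count = resel),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat("<smoothness_estimate> FWHM =",
      paste(signif(x$fwhm_mm, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Threshold a statistic map at a voxel-level p
#'
#' @param stat a `stat_map`.
#' @param p_level one-tailed voxel-level threshold in (0, 1).
#' @param direction contrast direction, as in [stat_p()].
#' @return integer vector of suprathreshold mask positions (indices into
#'   the mask register, not the full grid).
#' @export
threshold_map <- function(stat, p_level, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (p_level <= 0 || p_level >= 1) stop("p_level must lie in (0, 1)")
  which(stat_p(stat, direction) < p_level)
}

#' Conjunction overlap of two suprathreshold voxel sets
#'
#' Logical-AND conjunction, quantified as the intersection expressed as a
#' proportion of each map's suprathreshold count, averaged over the two
#' maps: 100 * ((|A n B| / |A|) + (|A n B| / |B|)) / 2. If either set is
#' empty the overlap is undefined and `NA` is returned (not zero).
#'
#' @param setA,setB integer index vectors over the same mask.
#' @return overlap percentage in [0, 100], or `NA` if undefined.
#' @export
conjunction_overlap <- function(setA, setB) {
  if (length(setA) == 0L || length(setB) == 0L) return(NA_real_)
  inter <- length(intersect(setA, setB))
  100 * (inter / length(setA) + inter / length(setB)) / 2
}

#' Monte-Carlo null distribution of random overlap
#'
#' For each iteration, two independent Gaussian random fields are
#' generated over the grid with the target smoothness of each observed
#' map, standardized on the mask, converted to one-tailed normal p-values,
#' thresholded at every requested level, and the conjunction overlap is
#' recorded. This is the null of spatially random (smoothness-matched)
#' map pairs against which observed overlap is judged.
#'
#' @param smoothA,smoothB `smoothness_estimate`s (or per-axis FWHM mm
#'   vectors) for the two maps.
#' @param mask_index mask voxel indices.
#' @param grid the template [volume_grid()].
#' @param p_levels vector of voxel-level thresholds.
#' @param n_iter number of Monte-Carlo iterations (>= 100).
#' @return matrix of null overlap percentages, `n_iter` x
#'   `length(p_levels)` (NA where a simulated set was empty).
#' @export
simulate_null_overlap <- function(smoothA, smoothB, mask_index, grid,
                                  p_levels, n_iter = 5000) {
  if (n_iter < 100) stop("n_iter must be at least 100")
  fA <- if (inherits(smoothA, "smoothness_estimate")) smoothA$fwhm_mm else smoothA
  fB <- if (inherits(smoothB, "smoothness_estimate")) smoothB$fwhm_mm else smoothB
  d <- dim(grid$values)
  zcrit <- stats::qnorm(1 - p_levels)
  out <- matrix(NA_real_, n_iter, length(p_levels))
  for (it in seq_len(n_iter)) {
    a <- as.numeric(gaussian_field(d, fA, grid$voxel_size))[mask_index]
    b <- as.numeric(gaussian_field(d, fB, grid$voxel_size))[mask_index]
    a <- (a - mean(a)) / stats::sd(a)
    b <- (b - mean(b)) / stats::sd(b)
    for (j in seq_along(p_levels)) {
      sa <- a > zcrit[j]
      sb <- b > zcrit[j]
      na <- sum(sa); nb <- sum(sb)
      if (na > 0 && nb > 0)
        out[it, j] <- 100 * (sum(sa & sb) / na + sum(sa & sb) / nb) / 2
    }
  }
  colnames(out) <- signif(p_levels, 4)
  out
}

#' Observed-versus-null overlap across a threshold sweep
#'
#' Computes the conjunction overlap of two statistic maps at each
#' voxel-level threshold, together with the Monte-Carlo null's 0.5, 50 and
#' 99.5 percentiles and a counting p-value: the proportion of null
#' iterations whose overlap is greater than or equal to the observed one.
#' With `protected = TRUE` the (k+1)/(n+1) variant is used instead of the
#' plain counting rule.
#'
#' @param statA,statB `stat_map`s over the same mask.
#' @param p_grid descending vector of voxel-level thresholds (within
#'   (0, 0.05] by convention; the reference sweep is 0.05 down to 0.0001
#'   in steps of 0.0001).
#' @param null null overlap matrix from [simulate_null_overlap()] whose
#'   columns follow `p_grid`.
#' @param direction contrast direction applied to both maps.
#' @param protected use the (k+1)/(n+1) p-value variant.
#' @return an object of class `overlap_curve`: data frame with columns
#'   `threshold`, `observed`, `null_p005`, `null_p50`, `null_p995`,
#'   `p_value`, plus `n_iterations` as an attribute.
#' @export
overlap_pvalue_sweep <- function(statA, statB, p_grid, null,
                                 direction = c("positive", "negative"),
                                 protected = FALSE) {
  direction <- match.arg(direction)
  if (ncol(null) != length(p_grid))
    stop("null columns must match the threshold grid")
  pa <- stat_p(statA, direction)
  pb <- stat_p(statB, direction)
  n_iter <- nrow(null)
  res <- lapply(seq_along(p_grid), function(j) {
    q <- p_grid[j]
    sa <- which(pa < q); sb <- which(pb < q)
    obs <- conjunction_overlap(sa, sb)
    nl <- null[, j]
    nl_ok <- nl[!is.na(nl)]
    pv <- if (is.na(obs)) NA_real_
    else if (protected) (sum(nl_ok >= obs) + 1) / (length(nl_ok) + 1)
    else mean(nl_ok >= obs)
    qs <- stats::quantile(nl_ok, c(0.005, 0.5, 0.995), na.rm = TRUE,
                          names = FALSE)
    data.frame(threshold = q, observed = obs, null_p005 = qs[1],
               null_p50 = qs[2], null_p995 = qs[3], p_value = pv)
  })
  out <- do.call(rbind, res)
  attr(out, "n_iterations") <- n_iter
  class(out) <- c("overlap_curve", class(out))
  out
}

#' The reference voxel-level threshold sweep
#'
#' Descending grid from 0.05 to 0.0001 in steps of 0.0001 (500 levels).
#' @return numeric vector of thresholds.
#' @export
overlap_threshold_grid <- function() {
  seq(0.05, 0.0001, by = -0.0001)
}
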