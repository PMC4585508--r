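#' Design matrix for voxel-wise group comparison
#'
#' Builds the mass-univariate design: an intercept, a binary group
#' indicator, and optional nuisance covariates — age as a continuous
#' regressor and scanning center as reference-coded categorical dummies.
#' The group factor's second level is coded 1, so a +1 contrast on the
#' group column tests level2 > level1.
#'
#' @param group factor (or coercible) with exactly 2 levels.
#' @param age optional numeric covariate (years).
#' @param center optional factor of scanning centers; also used as the
#'   exchangeability strata for permutation inference.
#' @return an object of class `vbm_design` with elements `X` (the matrix),
#'   `group`, `strata` and `group_col`.
#' @export
vbm_design <- function(group, age = NULL, center = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("'group' must have exactly 2 levels")
  n <- length(group)
  X <- cbind(intercept = 1, group = as.numeric(group == levels(group)[2]))
  if (!is.null(age)) {
    stopifnot(length(age) == n)
    X <- cbind(X, age = as.numeric(age))
  }
  if (!is.null(center)) {
    center <- droplevels(as.factor(center))
    stopifnot(length(center) == n)
    if (nlevels(center) > 1L) {
      D <- stats::model.matrix(~center)[, -1, drop = FALSE]
      colnames(D) <- paste0("center_", levels(center)[-1])
      X <- cbind(X, D)
    }
  }
  structure(list(X = X, group = group,
                 strata = if (is.null(center)) factor(rep(1, n)) else center,
                 group_col = "group"),
            class = "vbm_design")
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(qrX)
}

glm_tmap <- function(X, Y, cvec) {
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  cb <- as.numeric(cvec %*% beta)
  se <- sqrt(as.numeric(cvec %*% XtXi %*% cvec) * sigma2)
  # voxels with (numerically) zero residual variance carry no evidence
  degenerate <- sigma2 <= .Machine$double.eps * pmax(colMeans(Y^2), 1e-300)
  t <- ifelse(se > 0 & !degenerate, cb / se, 0)
  list(t = t, df = df)
}

#' Fit the voxel-wise general linear model
#'
#' Ordinary least squares at every masked voxel, with the t-statistic for a
#' contrast of the coefficients: t = c'beta / SE(c'beta) on n - p degrees
#' of freedom. One-tailed p maps in either direction are derived from the
#' returned `stat_map` with [stat_p()].
#'
#' @param matrix a [cohort_matrix()].
#' @param design a [vbm_design()] whose rows match the matrix subjects.
#' @param contrast a numeric weight vector (length = design columns) or the
#'   name of a single design column (default the group indicator).
#' @return an object of class `stat_map` with `t`, `df`, `mask_index`,
#'   `grid`.
#' @export
fit_voxelwise_glm <- function(matrix, design, contrast = "group") {
  stopifnot(inherits(matrix, "cohort_matrix"), inherits(design, "vbm_design"))
  X <- design$X
  if (nrow(X) != nrow(matrix$data))
    stop("design rows do not match matrix subjects")
  check_full_rank(X)
  cvec <- resolve_contrast(contrast, X)
  fit <- glm_tmap(X, matrix$data, cvec)
  structure(list(t = fit$t, df = fit$df, mask_index = matrix$mask_index,
                 grid = matrix$grid, contrast = cvec),
            class = "stat_map")
}

resolve_contrast <- function(contrast, X) {
  if (is.character(contrast)) {
    if (!contrast %in% colnames(X)) stop("unknown design column: ", contrast)
    cvec <- as.numeric(colnames(X) == contrast)
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != ncol(X))
      stop("contrast length must equal the number of design columns")
  }
  cvec
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", length(x$t), " voxels, df = ", x$df,
      ", max |t| = ", signif(max(abs(x$t)), 4), "\n", sep = "")
  invisible(x)
}

#' One-tailed p-values of a statistic map
#'
#' @param stat a `stat_map`.
#' @param direction `"positive"` tests contrast > 0, `"negative"` < 0.
#' @return vector of one-tailed p-values per masked voxel.
#' @export
stat_p <- function(stat, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (direction == "positive") stats::pt(stat$t, stat$df, lower.tail = FALSE)
  else stats::pt(stat$t, stat$df)
}

connectivity_offsets <- function(connectivity = 18) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(off)) == 1,
                 "18" = rowSums(abs(off)) <= 2,
                 "26" = rep(TRUE, nrow(off)),
                 stop("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  lo <- pmax(1, 1 - off)
  hi <- pmin(d, d - off)
  if (any(lo > hi)) return(out)
  src <- lapply(1:3, function(k) lo[k]:hi[k])
  dst <- lapply(1:3, function(k) src[[k]] + off[k])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Label connected components of a 3D binary mask
#'
#' Iterative minimum-label propagation under 6-, 18- (default, the SPM
#' convention) or 26-neighbour connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return list with `labels` (integer array, 0 outside clusters, labels
#'   numbered by first linear occurrence) and `sizes` (extent per label).
#' @export
label_clusters <- function(mask, connectivity = 18) {
  d <- dim(mask)
  out <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(list(labels = out, sizes = integer(0)))
  # crop to the bounding box of the mask
  ijk <- arrayInd(idx, d)
  lo <- apply(ijk, 2, min); hi <- apply(ijk, 2, max)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub) <- hi - lo + 1
  lab <- array(0, dim(sub))
  lab[sub] <- seq_len(sum(sub))
  offs <- connectivity_offsets(connectivity)
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      s <- shift_array(lab, offs[r, ])
      upd <- sub & s > 0 & s < new
      new[upd] <- s[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # relabel consecutively in order of first occurrence
  u <- unique(lab[lab > 0])
  lab2 <- array(0L, dim(sub))
  lab2[sub] <- match(lab[sub], u)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- lab2
  list(labels = out, sizes = tabulate(lab2[sub], nbins = length(u)))
}

#' Form suprathreshold clusters from a statistic map
#'
#' Voxels whose one-tailed p falls below the cluster-forming height
#' threshold are grouped by 18-connectivity; each cluster's extent, peak t
#' and peak MNI mm coordinate are tabulated.
#'
#' @param stat a `stat_map`.
#' @param height_p cluster-forming voxel-level threshold (default 0.025).
#' @param direction contrast direction, as in [stat_p()].
#' @param connectivity neighbourhood for clustering (default 18).
#' @return a `data.frame` (possibly empty) with columns `cluster`,
#'   `extent`, `peak_x`, `peak_y`, `peak_z`, `peak_t`, `p`, `q`, plus the
#'   label array as attribute `"labels"`.
#' @export
form_clusters <- function(stat, height_p = 0.025,
                          direction = c("positive", "negative"),
                          connectivity = 18) {
  direction <- match.arg(direction)
  if (height_p <= 0 || height_p > 0.5) stop("height_p must lie in (0, 0.5]")
  supra <- stat_p(stat, direction) < height_p
  d <- dim(stat$grid$values)
  mask_arr <- array(FALSE, d)
  mask_arr[stat$mask_index[supra]] <- TRUE
  cl <- label_clusters(mask_arr, connectivity)
  k <- length(cl$sizes)
  tab <- data.frame(cluster = integer(0), extent = integer(0),
                    peak_x = numeric(0), peak_y = numeric(0),
                    peak_z = numeric(0), peak_t = numeric(0),
                    p = numeric(0), q = numeric(0))
  if (k > 0) {
    tfull <- rep(NA_real_, prod(d))
    tfull[stat$mask_index] <- stat$t
    rows <- lapply(seq_len(k), function(j) {
      vox <- which(cl$labels == j)
      tv <- tfull[vox]
      peak <- vox[if (direction == "positive") which.max(tv) else which.min(tv)]
      mm <- voxel_to_mm(stat$grid, arrayInd(peak, d))
      data.frame(cluster = j, extent = cl$sizes[j],
                 peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
                 peak_t = tfull[peak], p = NA_real_, q = NA_real_)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$extent), ]
    tab$cluster <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  }
  attr(tab, "labels") <- cl$labels
  attr(tab, "direction") <- direction
  attr(tab, "height_p") <- height_p
  tab
}

max_cluster_extent <- function(supra, mask_index, dims, connectivity = 18) {
  idx <- mask_index[supra]
  if (length(idx) == 0L) return(0L)
  if (length(idx) == 1L) return(1L)
  if (length(idx) <= 2000L)
    return(uf_max_extent(arrayInd(idx, dims), connectivity))
  mask_arr <- array(FALSE, dims)
  mask_arr[idx] <- TRUE
  max(label_clusters(mask_arr, connectivity)$sizes)
}

# union-find over pairwise voxel adjacency; efficient for small voxel sets
uf_max_extent <- function(ijk, connectivity = 18) {
  n <- nrow(ijk)
  a1 <- abs(outer(ijk[, 1], ijk[, 1], "-"))
  a2 <- abs(outer(ijk[, 2], ijk[, 2], "-"))
  a3 <- abs(outer(ijk[, 3], ijk[, 3], "-"))
  s <- a1 + a2 + a3
  adj <- a1 <= 1 & a2 <= 1 & a3 <= 1 & s > 0
  adj <- adj & switch(as.character(connectivity),
                      "6" = s == 1, "18" = s <= 2, "26" = TRUE)
  e <- which(adj, arr.ind = TRUE)
  e <- e[e[, 1] < e[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(e))) {
    ra <- find(e[k, 1]); rb <- find(e[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  max(tabulate(match(roots, unique(roots))))
}

count_strata_permutations <- function(group, strata) {
  g2 <- levels(group)[2]
  total <- 0
  for (s in levels(strata)) {
    ns <- sum(strata == s)
    ks <- sum(strata == s & group == g2)
    total <- total + lchoose(ns, ks)
  }
  exp(total)
}

permute_within_strata <- function(group, strata) {
  out <- group
  for (s in levels(strata)) {
    i <- which(strata == s)
    out[i] <- group[i][sample.int(length(i))]
  }
  out
}

all_strata_permutations <- function(group, strata) {
  # exhaustive set of distinct within-strata label assignments
  g2 <- levels(group)[2]
  per_stratum <- lapply(levels(strata), function(s) {
    i <- which(strata == s)
    ks <- sum(group[i] == g2)
    combs <- utils::combn(length(i), ks, simplify = FALSE)
    lapply(combs, function(cc) {
      v <- rep(levels(group)[1], length(i))
      v[cc] <- g2
      list(idx = i, labels = v)
    })
  })
  grids <- do.call(expand.grid, lapply(per_stratum, seq_along))
  lapply(seq_len(nrow(grids)), function(r) {
    out <- as.character(group)
    for (s in seq_along(per_stratum)) {
      part <- per_stratum[[s]][[grids[r, s]]]
      out[part$idx] <- part$labels
    }
    factor(out, levels = levels(group))
  })
}

#' Cluster-level FDR by permutation of maximum cluster extent
#'
#' Cluster-level inference without Gaussian-random-field assumptions:
#' group labels are permuted within scanning-center strata, the voxel-wise
#' GLM and clustering are recomputed, and each observed cluster's p-value
#' is the proportion of permutations whose maximum cluster extent reaches
#' its extent. Benjamini-Hochberg adjustment over the observed clusters
#' then controls the FDR at the cluster level.
#'
#' @param stat the observed `stat_map` (provides direction-consistent df).
#' @param clusters the observed cluster table from [form_clusters()].
#' @param matrix,design the data and design used to compute `stat`.
#' @param contrast contrast used for `stat` (default the group column).
#' @param n_perm number of permutations (>= 100).
#' @param q_level FDR level for the significance flag (default 0.05).
#' @return the cluster table with `p`, `q` and `significant` filled in,
#'   and the permutation null of maximum extent as attribute `"null_max"`.
#' @export
cluster_fdr <- function(stat, clusters, matrix, design, contrast = "group",
                        n_perm = 1000, q_level = 0.05) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (nrow(clusters) == 0L) {
    attr(clusters, "null_max") <- integer(0)
    return(clusters)
  }
  direction <- attr(clusters, "direction")
  height_p <- attr(clusters, "height_p")
  X <- design$X
  cvec <- resolve_contrast(contrast, X)
  gcol <- match(design$group_col, colnames(X))
  dims <- dim(matrix$grid$values)
  df <- nrow(X) - ncol(X)
  tcrit <- stats::qt(1 - height_p, df)

  n_distinct <- count_strata_permutations(design$group, design$strata)
  if (n_distinct < n_perm) {
    warning("fewer distinct permutations (", round(n_distinct),
            ") than n_perm; using the exhaustive set")
    perms <- all_strata_permutations(design$group, design$strata)
  } else {
    # identity permutation included, so the smallest attainable p is 1/n_perm
    perms <- c(list(design$group),
               replicate(n_perm - 1,
                         permute_within_strata(design$group, design$strata),
                         simplify = FALSE))
  }
  group_only <- all(cvec == as.numeric(seq_along(cvec) == gcol))
  if (group_only) {
    # Frisch-Waugh fast path: residualize data and the permuted group
    # indicator against the nuisance block once; the contrast t equals the
    # full-model t exactly
    qz <- qr(X[, -gcol, drop = FALSE])
    Yt <- qr.resid(qz, matrix$data)
    ssy <- colSums(Yt^2)
    null_max <- vapply(perms, function(gp) {
      gt <- qr.resid(qz, as.numeric(gp == levels(design$group)[2]))
      gg <- sum(gt^2)
      if (gg < .Machine$double.eps) return(0L)
      a <- as.numeric(crossprod(gt, Yt))
      s2 <- pmax(ssy - a^2 / gg, 0) / df
      tv <- ifelse(s2 > 0, a / sqrt(gg * s2), 0)
      supra <- if (direction == "positive") tv > tcrit else tv < -tcrit
      max_cluster_extent(supra, matrix$mask_index, dims)
    }, integer(1))
  } else {
    null_max <- vapply(perms, function(gp) {
      Xp <- X
      Xp[, gcol] <- as.numeric(gp == levels(design$group)[2])
      fit <- glm_tmap(Xp, matrix$data, cvec)
      supra <- if (direction == "positive") fit$t > tcrit else fit$t < -tcrit
      max_cluster_extent(supra, matrix$mask_index, dims)
    }, integer(1))
  }

  clusters$p <- vapply(clusters$extent,
                       function(k) mean(null_max >= k), numeric(1))
  clusters$q <- stats::p.adjust(clusters$p, method = "BH")
  clusters$significant <- clusters$q < q_level
  attr(clusters, "null_max") <- null_max
  clusters
}
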