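#' Stack brain-behavior correlation matrices
#'
#' For every block — one per (group x condition), where conditions are
#' tissue classes such as GM and WM — computes the Pearson correlation of
#' each behavioral measure with each masked voxel across subjects, and
#' stacks the blocks row-wise into a (measures x blocks) by voxels matrix.
#' This is the matrix whose singular value decomposition yields the latent
#' variable pairs.
#'
#' @param brain named list of subjects x voxels matrices, one per
#'   condition, with aligned subject rows.
#' @param behavior subjects x measures matrix (no missing values; columns
#'   must have positive SD within every block).
#' @param groups optional factor splitting subjects into groups (the
#'   multi-group variant); `NULL` treats all subjects as one group.
#' @return the stacked correlation matrix with blocks in (group outer,
#'   condition inner, measure innermost) row order; attributes `blocks`
#'   (data frame describing each row) and `zero_variance` (count of
#'   zero-variance voxel-block combinations, whose correlations were set
#'   to 0).
#' @export
build_correlation_stack <- function(brain, behavior, groups = NULL) {
  if (!is.list(brain) || is.null(names(brain)))
    stop("'brain' must be a named list of condition matrices")
  behavior <- as.matrix(behavior)
  if (any(is.na(behavior))) stop("behavior matrix must have no missing values")
  n <- nrow(behavior)
  if (any(vapply(brain, nrow, 0L) != n))
    stop("brain and behavior subject counts differ")
  if (is.null(groups)) groups <- factor(rep("all", n))
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) < 3L)) stop("every block needs at least 3 subjects")

  zero_count <- 0L
  rows <- list(); info <- list()
  for (g in levels(groups)) {
    i <- which(groups == g)
    for (cond in names(brain)) {
      if (any(apply(behavior[i, , drop = FALSE], 2, stats::sd) == 0))
        stop("zero-variance behavioral column in block ", g, "/", cond)
      R <- suppressWarnings(stats::cor(behavior[i, , drop = FALSE],
                                       brain[[cond]][i, , drop = FALSE]))
      nz <- is.na(R)
      if (any(nz)) {
        zero_count <- zero_count + sum(colSums(nz) > 0)
        R[nz] <- 0
      }
      rownames(R) <- paste(colnames(behavior), cond, g, sep = ".")
      rows[[length(rows) + 1L]] <- R
      info[[length(info) + 1L]] <- data.frame(
        group = g, condition = cond, measure = colnames(behavior))
    }
  }
  stack <- do.call(rbind, rows)
  attr(stack, "blocks") <- do.call(rbind, info)
  attr(stack, "zero_variance") <- zero_count
  stack
}

#' Fit the PLS decomposition
#'
#' Singular value decomposition of the stacked brain-behavior correlation
#' matrix. Latent variables (LVs) are ordered by singular value; the
#' covariance explained by LV i is lambda_i^2 / sum(lambda^2). Behavior
#' saliences are the left singular vectors, brain saliences the right
#' singular vectors (both unit norm). Brain scores — the projection of
#' each subject's voxel data onto the brain saliences — are computed per
#' condition when the voxel data are supplied.
#'
#' @param stack correlation stack from [build_correlation_stack()].
#' @param brain optional named list of condition matrices for brain
#'   scores.
#' @return an object of class `pls_model`: list with `singular_values`,
#'   `covariance_explained`, `behavior_saliences`, `brain_saliences`,
#'   `brain_scores` (list per condition, subjects x LVs) and `blocks`.
#' @export
fit_pls <- function(stack, brain = NULL) {
  stack <- as.matrix(stack)
  if (any(!is.finite(stack))) stop("correlation stack must be finite")
  if (all(stack == 0)) stop("all-zero correlation stack")
  sv <- svd(stack)
  k <- min(dim(stack))
  model <- list(singular_values = sv$d[seq_len(k)],
                covariance_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                behavior_saliences = sv$u[, seq_len(k), drop = FALSE],
                brain_saliences = sv$v[, seq_len(k), drop = FALSE],
                blocks = attr(stack, "blocks"),
                brain_scores = NULL)
  rownames(model$behavior_saliences) <- rownames(stack)
  if (!is.null(brain)) {
    model$brain_scores <- lapply(brain, function(X)
      scale(X, center = TRUE, scale = FALSE) %*% model$brain_saliences)
  }
  class(model) <- "pls_model"
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", length(x$singular_values), " LVs; singular values: ",
      paste(signif(x$singular_values, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Permutation test on PLS latent variables
#'
#' Behavior rows are permuted across subjects (within group for the
#' multi-group variant), the correlation stack rebuilt and re-decomposed,
#' and each LV's p-value is the proportion of permutations whose singular
#' value at the same rank position reaches the observed one (plain
#' counting rule; `protected = TRUE` uses (k+1)/(n+1)).
#'
#' @param brain,behavior,groups as in [build_correlation_stack()].
#' @param n_perm number of permutations (>= 100; the reference protocol
#'   uses 10,000).
#' @param protected use the protected p-value variant.
#' @param permute_within_groups permute behavior within groups (default)
#'   or across all subjects in the multi-group variant.
#' @return list with `perm_p` (per LV), `observed` singular values, and
#'   the permutation singular-value matrix `null` (n_perm x LVs).
#' @export
pls_permutation <- function(brain, behavior, groups = NULL, n_perm = 500,
                            protected = FALSE, permute_within_groups = TRUE) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  behavior <- as.matrix(behavior)
  n <- nrow(behavior)
  if (is.null(groups)) groups <- factor(rep("all", n))
  groups <- droplevels(as.factor(groups))
  obs <- fit_pls(build_correlation_stack(brain, behavior, groups))$singular_values
  null <- matrix(NA_real_, n_perm, length(obs))
  for (b in seq_len(n_perm)) {
    idx <- if (permute_within_groups) {
      out <- seq_len(n)
      for (g in levels(groups)) {
        i <- which(groups == g)
        out[i] <- i[sample.int(length(i))]
      }
      out
    } else sample.int(n)
    stack_b <- build_correlation_stack(brain, behavior[idx, , drop = FALSE],
                                       groups)
    null[b, ] <- fit_pls(stack_b)$singular_values
  }
  perm_p <- vapply(seq_along(obs), function(i) {
    if (protected) (sum(null[, i] >= obs[i]) + 1) / (n_perm + 1)
    else mean(null[, i] >= obs[i])
  }, numeric(1))
  list(perm_p = perm_p, observed = obs, null = null)
}

#' Bootstrap ratios for PLS saliences
#'
#' Subjects are resampled with replacement within group; each resample's
#' decomposition is sign-aligned to the original (per LV, by the sign of
#' the dot product of brain saliences) before the voxel-wise standard
#' error is computed. The bootstrap ratio is the original salience divided
#' by its bootstrap SE; a ratio of 2.5 corresponds to roughly p < 0.012
#' and is the conventional visualization cut. Per-measure correlations
#' between brain scores and behavior get percentile 95% confidence
#' intervals from the same resamples.
#'
#' @param brain,behavior,groups as in [build_correlation_stack()].
#' @param n_boot number of resamples (>= 100; the reference protocol uses
#'   10,000).
#' @param lv which LV the brain-score correlation CIs are computed for.
#' @return list with `bootstrap_ratio` (voxels x LVs), `salience_se`,
#'   `score_correlations` (data frame: block, measure, r, lower, upper)
#'   and the original `model`.
#' @export
pls_bootstrap <- function(brain, behavior, groups = NULL, n_boot = 500,
                          lv = 1L) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  behavior <- as.matrix(behavior)
  n <- nrow(behavior)
  if (is.null(groups)) groups <- factor(rep("all", n))
  groups <- droplevels(as.factor(groups))
  model <- fit_pls(build_correlation_stack(brain, behavior, groups), brain)
  k <- length(model$singular_values)
  V <- nrow(model$brain_saliences)

  boot_sal <- array(NA_real_, c(V, k, n_boot))
  # per-resample correlation between brain scores and each measure, per block
  blocks <- expand.grid(condition = names(brain), group = levels(groups),
                        stringsAsFactors = FALSE)
  nr <- nrow(blocks) * ncol(behavior)
  boot_r <- matrix(NA_real_, n_boot, nr)

  for (b in seq_len(n_boot)) {
    repeat {
      idx <- unlist(lapply(levels(groups), function(g) {
        i <- which(groups == g)
        sample(i, length(i), replace = TRUE)
      }), use.names = FALSE)
      ok <- length(unique(idx)) >= 3 &&
        all(apply(behavior[idx, , drop = FALSE], 2, stats::sd) > 0)
      if (ok) break  # degenerate resamples are redrawn
    }
    brain_b <- lapply(brain, function(X) X[idx, , drop = FALSE])
    beh_b <- behavior[idx, , drop = FALSE]
    grp_b <- groups[idx]
    fit_b <- tryCatch(fit_pls(build_correlation_stack(brain_b, beh_b, grp_b)),
                      error = function(e) NULL)
    if (is.null(fit_b)) next
    signs <- vapply(seq_len(k), function(i)
      sign(sum(fit_b$brain_saliences[, i] * model$brain_saliences[, i])),
      numeric(1))
    signs[signs == 0] <- 1
    boot_sal[, , b] <- sweep(fit_b$brain_saliences, 2, signs, `*`)

    r <- 1L
    for (jb in seq_len(nrow(blocks))) {
      ig <- which(grp_b == blocks$group[jb])
      sc <- scale(brain_b[[blocks$condition[jb]]], center = TRUE,
                  scale = FALSE) %*% (signs[lv] * fit_b$brain_saliences[, lv])
      for (m in seq_len(ncol(behavior))) {
        boot_r[b, r] <- stats::cor(sc[ig], beh_b[ig, m])
        r <- r + 1L
      }
    }
  }

  se <- apply(boot_sal, c(1, 2), stats::sd, na.rm = TRUE)
  br <- model$brain_saliences / se
  br[se == 0 & model$brain_saliences == 0] <- 0
  br[se == 0 & model$brain_saliences != 0] <- Inf

  obs_r <- numeric(nr); labels <- character(nr); meas <- character(nr)
  r <- 1L
  for (jb in seq_len(nrow(blocks))) {
    ig <- which(groups == blocks$group[jb])
    sc <- model$brain_scores[[blocks$condition[jb]]][, lv]
    for (m in seq_len(ncol(behavior))) {
      obs_r[r] <- stats::cor(sc[ig], behavior[ig, m])
      labels[r] <- paste(blocks$condition[jb], blocks$group[jb], sep = ".")
      meas[r] <- colnames(behavior)[m]
      r <- r + 1L
    }
  }
  ci <- t(apply(boot_r, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  score_correlations <- data.frame(block = labels, measure = meas,
                                   r = obs_r, lower = ci[, 1], upper = ci[, 2])
  list(bootstrap_ratio = br, salience_se = se,
       score_correlations = score_correlations, model = model)
}

#' Threshold a bootstrap-ratio map for visualization
#'
#' Retains voxels with |bootstrap ratio| above the cut that belong to
#' clusters of at least `min_cluster` voxels (18-connectivity). This is a
#' display convention only; LV inference rests on the permutation test.
#'
#' @param br_values bootstrap ratios per masked voxel (one LV).
#' @param mask_index,grid the mask register and template grid.
#' @param br_cut bootstrap-ratio magnitude threshold (default 2.5).
#' @param min_cluster minimum cluster extent in voxels (default 400).
#' @return a [volume_grid()] holding the retained bootstrap ratios (0
#'   elsewhere).
#' @export
pls_visualize_threshold <- function(br_values, mask_index, grid,
                                    br_cut = 2.5, min_cluster = 400) {
  d <- dim(grid$values)
  keep_pos <- array(FALSE, d); keep_neg <- array(FALSE, d)
  keep_pos[mask_index[br_values > br_cut]] <- TRUE
  keep_neg[mask_index[br_values < -br_cut]] <- TRUE
  retained <- array(FALSE, d)
  for (m in list(keep_pos, keep_neg)) {
    cl <- label_clusters(m, connectivity = 18)
    big <- which(cl$sizes >= min_cluster)
    if (length(big)) retained[cl$labels %in% big & m] <- TRUE
  }
  full <- rep(0, prod(d))
  full[mask_index] <- br_values
  full[!retained] <- 0
  grid$values <- array(full, d)
  grid
}
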