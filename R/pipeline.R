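#' Pipeline run configuration
#'
#' Collects every tunable of the analysis pipeline with the reference
#' defaults: tissue-probability mask threshold 0.25, cluster-forming
#' height threshold P < 0.025, cluster-level FDR q < 0.05, the overlap
#' threshold sweep 0.05 down to 0.0001 in 0.0001 steps, 5000 Monte-Carlo
#' overlap iterations, 10,000 permutations and 10,000 bootstrap resamples.
#' The `"test"` profile scales the iteration counts down (500 / 500 / 500
#' and 300 cluster permutations) without touching any threshold, for
#' desk-scale runs.
#'
#' @param volume_dir directory of per-subject NIfTI maps plus
#'   `subjects.csv` (as written by [write_cohort()]); `NULL` when a cohort
#'   object is passed to [run_pipeline()] directly.
#' @param out_dir output directory.
#' @param mask_threshold tissue probability cut (strict >).
#' @param height_p cluster-forming voxel-level threshold.
#' @param cluster_q cluster-level FDR level.
#' @param overlap_grid descending voxel-level threshold sweep.
#' @param n_iterations overlap Monte-Carlo iterations.
#' @param n_perm permutations (PLS and cluster inference).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed driving all randomness of the run.
#' @param profile `"paper"` keeps the reference iteration counts,
#'   `"test"` scales them down.
#' @param spec optional [cohort_spec()] for the `simulate` stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(volume_dir = NULL, out_dir = tempfile("langmorph_"),
                       mask_threshold = 0.25, height_p = 0.025,
                       cluster_q = 0.05, overlap_grid = overlap_threshold_grid(),
                       n_iterations = 5000, n_perm = 10000, n_boot = 10000,
                       seed = 1L, profile = c("paper", "test"), spec = NULL) {
  profile <- match.arg(profile)
  if (profile == "test") {
    n_iterations <- min(n_iterations, 500)
    n_perm <- min(n_perm, 500)
    n_boot <- min(n_boot, 500)
  }
  stopifnot(mask_threshold >= 0, mask_threshold < 1,
            height_p > 0, height_p <= 0.5, cluster_q > 0, cluster_q < 1)
  structure(list(volume_dir = volume_dir, out_dir = out_dir,
                 mask_threshold = mask_threshold, height_p = height_p,
                 cluster_q = cluster_q, overlap_grid = overlap_grid,
                 n_iterations = n_iterations, n_perm = n_perm,
                 n_boot = n_boot, seed = as.integer(seed),
                 profile = profile, spec = spec),
            class = "run_config")
}

#' Read a cohort from disk
#'
#' Loads the `subjects.csv` table and the per-subject `<id>_gm.nii.gz` /
#' `<id>_wm.nii.gz` maps written by [write_cohort()]. Subjects present in
#' the table but missing a volume (or vice versa) raise an error naming
#' the orphan ids.
#'
#' @param dir the cohort directory.
#' @return a list shaped like a [generate_cohort()] result (`subjects`,
#'   `gm`, `wm`, `template_gm`, `template_wm`), with templates taken as
#'   the across-subject mean map clipped to [0, 1].
#' @export
read_cohort <- function(dir) {
  tab_file <- file.path(dir, "subjects.csv")
  if (!file.exists(tab_file)) stop("no subjects.csv in ", dir)
  subjects <- utils::read.csv(tab_file, stringsAsFactors = FALSE)
  gm_files <- file.path(dir, paste0(subjects$id, "_gm.nii.gz"))
  wm_files <- file.path(dir, paste0(subjects$id, "_wm.nii.gz"))
  missing <- subjects$id[!file.exists(gm_files) | !file.exists(wm_files)]
  if (length(missing))
    stop("subject table and volumes mismatch; missing volumes for: ",
         paste(missing, collapse = ", "))
  orphans <- setdiff(sub("_gm\\.nii\\.gz$", "",
                         basename(Sys.glob(file.path(dir, "*_gm.nii.gz")))),
                     subjects$id)
  if (length(orphans))
    stop("volumes without a subject-table row: ", paste(orphans, collapse = ", "))
  grid <- read_volume(gm_files[1])
  nv <- prod(dim(grid$values))
  gm <- matrix(0, nrow(subjects), nv)
  wm <- matrix(0, nrow(subjects), nv)
  for (i in seq_len(nrow(subjects))) {
    gm[i, ] <- as.numeric(read_volume(gm_files[i])$values)
    wm[i, ] <- as.numeric(read_volume(wm_files[i])$values)
  }
  tpl_gm <- grid; tpl_gm$values <- array(pmin(colMeans(gm), 1), dim(grid$values))
  tpl_wm <- grid; tpl_wm$values <- array(pmin(colMeans(wm), 1), dim(grid$values))
  list(subjects = subjects, gm = gm, wm = wm,
       template_gm = tpl_gm, template_wm = tpl_wm)
}

#' Prepare masked relative-volume cohort matrices
#'
#' Builds the tissue masks from the templates (probability strictly above
#' the threshold), computes per-subject total tissue volumes, and
#' assembles [cohort_matrix()] objects of relative regional volume
#' (voxel / individual total).
#'
#' @param cohort a [generate_cohort()] or [read_cohort()] result.
#' @param mask_threshold tissue probability cut.
#' @param subset optional logical/integer subject selector.
#' @return list with `gm`, `wm` (relative [cohort_matrix()]s), `gm_abs`,
#'   `wm_abs` (absolute), `subjects` (the selected table rows) and the
#'   masks.
#' @export
prepare_cohort <- function(cohort, mask_threshold = 0.25, subset = NULL) {
  subjects <- cohort$subjects
  gm <- cohort$gm; wm <- cohort$wm
  if (!is.null(subset)) {
    subjects <- subjects[subset, , drop = FALSE]
    gm <- gm[subset, , drop = FALSE]
    wm <- wm[subset, , drop = FALSE]
  }
  mask_gm <- build_mask(cohort$template_gm, mask_threshold)
  mask_wm <- build_mask(cohort$template_wm, mask_threshold)
  vv <- prod(cohort$template_gm$voxel_size) / 1000
  tot_gm <- rowSums(gm) * vv
  tot_wm <- rowSums(wm) * vv
  list(
    gm = cohort_matrix(gm, mask_gm, cohort$template_gm, "GM",
                       subjects$id, totals = tot_gm),
    wm = cohort_matrix(wm, mask_wm, cohort$template_wm, "WM",
                       subjects$id, totals = tot_wm),
    gm_abs = cohort_matrix(gm, mask_gm, cohort$template_gm, "GM", subjects$id),
    wm_abs = cohort_matrix(wm, mask_wm, cohort$template_wm, "WM", subjects$id),
    subjects = subjects, mask_gm = mask_gm, mask_wm = mask_wm,
    total_gm = tot_gm, total_wm = tot_wm)
}

#' Run a pipeline stage
#'
#' Orchestrates the analyses end to end: `simulate` writes a synthetic
#' cohort; `vbm` runs the delay-history voxel-wise GLM with cluster-level
#' permutation FDR (both contrast directions); `overlap` computes the
#' commonality of the two versus-neurotypical contrasts across the
#' threshold sweep against the smoothness-matched Monte-Carlo null; `pls`
#' runs the 1-group behavioral PLS with permutation and bootstrap; `roi`
#' runs the sphere-ROI replication tests and the canonical-language-ROI
#' MANCOVA. Outputs (CSV/NIfTI) and a JSON provenance record are written
#' under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param analysis which stage to run.
#' @param cohort optional in-memory cohort (otherwise read from
#'   `config$volume_dir`).
#' @return the stage's result object, invisibly; file outputs under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config,
                         analysis = c("simulate", "vbm", "overlap", "pls", "roi"),
                         cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  analysis <- match.arg(analysis)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  t0 <- Sys.time()

  if (analysis == "simulate") {
    spec <- if (is.null(config$spec)) cohort_spec(seed = config$seed) else config$spec
    cohort <- generate_cohort(spec)
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    result <- cohort
    outputs <- file.path(config$out_dir, "cohort")
  } else {
    if (is.null(cohort)) {
      if (is.null(config$volume_dir)) stop("no cohort and no volume_dir")
      cohort <- read_cohort(config$volume_dir)
    }
    result <- switch(analysis,
      vbm = stage_vbm(config, cohort),
      overlap = stage_overlap(config, cohort),
      pls = stage_pls(config, cohort),
      roi = stage_roi(config, cohort))
    outputs <- attr(result, "outputs")
  }

  prov <- list(analysis = analysis, seed = config$seed,
               profile = config$profile,
               package_version = as.character(utils::packageVersion("langmorph")),
               r_version = R.version.string,
               timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
               elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
               config = config[c("mask_threshold", "height_p", "cluster_q",
                                 "n_iterations", "n_perm", "n_boot")],
               outputs = outputs)
  jsonlite::write_json(prov,
                       file.path(config$out_dir,
                                 paste0("provenance_", analysis, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

stage_vbm <- function(config, cohort) {
  asc <- cohort$subjects$group %in% c("ASC_delay", "ASC_nodelay")
  prep <- prepare_cohort(cohort, config$mask_threshold, subset = asc)
  des <- vbm_design(factor(prep$subjects$group,
                           levels = c("ASC_nodelay", "ASC_delay")),
                    age = prep$subjects$age,
                    center = prep$subjects$center)
  stat <- fit_voxelwise_glm(prep$gm, des)
  tabs <- list()
  for (dirn in c("positive", "negative")) {
    cl <- form_clusters(stat, config$height_p, dirn)
    cl <- cluster_fdr(stat, cl, prep$gm, des,
                      n_perm = max(100, min(config$n_perm, 1000)),
                      q_level = config$cluster_q)
    if (nrow(cl)) cl$direction <- if (dirn == "positive")
      "delay>no_delay" else "no_delay>delay"
    tabs[[dirn]] <- cl
  }
  tab <- do.call(rbind, lapply(tabs, as.data.frame))
  f_csv <- file.path(config$out_dir, "vbm_gm_clusters.csv")
  utils::write.csv(tab, f_csv, row.names = FALSE)
  f_nii <- file.path(config$out_dir, "vbm_gm_tmap.nii.gz")
  write_volume(unmask(stat$t, stat$mask_index, stat$grid), f_nii)
  out <- list(stat = stat, clusters = tab, design = des)
  attr(out, "outputs") <- c(f_csv, f_nii)
  out
}

versus_nt_stat <- function(prep, groups, which_group) {
  keep <- groups %in% c(which_group, "NT")
  sub <- prep$subjects[keep, , drop = FALSE]
  mat <- prep$gm
  mat$data <- mat$data[keep, , drop = FALSE]
  mat$subjects <- sub$id
  des <- vbm_design(factor(ifelse(sub$group == "NT", "NT", "ASC"),
                           levels = c("NT", "ASC")),
                    age = sub$age, center = sub$center)
  fit_voxelwise_glm(mat, des)
}

stage_overlap <- function(config, cohort) {
  if (!any(cohort$subjects$group == "NT"))
    stop("overlap analysis needs a neurotypical (NT) group")
  prep <- prepare_cohort(cohort, config$mask_threshold)
  statA <- versus_nt_stat(prep, prep$subjects$group, "ASC_delay")
  statB <- versus_nt_stat(prep, prep$subjects$group, "ASC_nodelay")
  smA <- estimate_smoothness(statA)
  smB <- estimate_smoothness(statB)
  grid_p <- config$overlap_grid
  null <- simulate_null_overlap(smA, smB, statA$mask_index, statA$grid,
                                grid_p, n_iter = config$n_iterations)
  curves <- lapply(c("positive", "negative"), function(dirn)
    cbind(direction = dirn,
          overlap_pvalue_sweep(statA, statB, grid_p, null, dirn)))
  curve <- do.call(rbind, lapply(curves, as.data.frame))
  f_csv <- file.path(config$out_dir, "overlap_curve.csv")
  utils::write.csv(curve, f_csv, row.names = FALSE)
  out <- list(curve = curve, smoothness = list(A = smA, B = smB))
  attr(out, "outputs") <- f_csv
  out
}

stage_pls <- function(config, cohort) {
  measures <- intersect(c("VIQ", "FAS", "NWR"), names(cohort$subjects))
  asc <- cohort$subjects$group %in% c("ASC_delay", "ASC_nodelay")
  complete <- asc & stats::complete.cases(cohort$subjects[, measures])
  prep <- prepare_cohort(cohort, config$mask_threshold, subset = complete)
  mask <- sort(union(prep$mask_gm, prep$mask_wm))
  gm <- cohort_matrix(cohort$gm[complete, , drop = FALSE], mask,
                      cohort$template_gm, "GM", prep$subjects$id,
                      totals = prep$total_gm)
  wm <- cohort_matrix(cohort$wm[complete, , drop = FALSE], mask,
                      cohort$template_wm, "WM", prep$subjects$id,
                      totals = prep$total_wm)
  gm <- standardize_by_age(gm, prep$subjects$age)
  wm <- standardize_by_age(wm, prep$subjects$age)
  brain <- list(GM = gm$data, WM = wm$data)
  behavior <- as.matrix(prep$subjects[, measures])
  model <- fit_pls(build_correlation_stack(brain, behavior), brain)
  perm <- pls_permutation(brain, behavior, n_perm = config$n_perm)
  boot <- pls_bootstrap(brain, behavior, n_boot = config$n_boot)
  lv_tab <- data.frame(lv = seq_along(model$singular_values),
                       singular_value = model$singular_values,
                       covariance_explained_pct =
                         100 * model$covariance_explained,
                       perm_p = perm$perm_p)
  f_lv <- file.path(config$out_dir, "pls_lv_summary.csv")
  utils::write.csv(lv_tab, f_lv, row.names = FALSE)
  f_corr <- file.path(config$out_dir, "pls_correlation_overview.csv")
  utils::write.csv(boot$score_correlations, f_corr, row.names = FALSE)
  f_br <- file.path(config$out_dir, "pls_lv1_bootstrap_ratio.nii.gz")
  write_volume(unmask(boot$bootstrap_ratio[, 1], mask, cohort$template_gm),
               f_br)
  out <- list(model = model, permutation = perm, bootstrap = boot,
              lv_table = lv_tab, mask = mask)
  attr(out, "outputs") <- c(f_lv, f_corr, f_br)
  out
}

stage_roi <- function(config, cohort) {
  asc <- cohort$subjects$group %in% c("ASC_delay", "ASC_nodelay")
  prep <- prepare_cohort(cohort, config$mask_threshold, subset = asc)
  labels <- factor(prep$subjects$group, levels = c("ASC_nodelay", "ASC_delay"))
  rois <- published_delay_rois()
  rows <- list()
  for (i in seq_len(nrow(rois))) {
    mat_rel <- if (rois$tissue[i] == "GM") prep$gm else prep$wm
    mat_abs <- if (rois$tissue[i] == "GM") prep$gm_abs else prep$wm_abs
    roi <- make_sphere_roi(c(rois$x[i], rois$y[i], rois$z[i]), 6, mat_rel$grid)
    res <- tryCatch({
      rel <- roi_group_test(extract_roi_means(mat_rel, roi), labels)
      abs_ <- roi_group_test(extract_roi_means(mat_abs, roi), labels)
      data.frame(label = rois$label[i], tissue = rois$tissue[i],
                 t_relative = rel$t, p_relative = rel$p, d_relative = rel$d,
                 t_absolute = abs_$t, p_absolute = abs_$p)
    }, error = function(e) NULL)
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  lang <- canonical_language_rois()
  Y <- sapply(seq_len(nrow(lang)), function(i) {
    roi <- make_sphere_roi(c(lang$x[i], lang$y[i], lang$z[i]), 6,
                           prep$gm$grid)
    extract_roi_means(prep$gm, roi)
  })
  colnames(Y) <- lang$label
  man <- mancova_hotelling(Y, labels,
                           covariates = data.frame(
                             age = prep$subjects$age,
                             center = factor(prep$subjects$center)))
  f_csv <- file.path(config$out_dir, "roi_group_tests.csv")
  utils::write.csv(tab, f_csv, row.names = FALSE)
  out <- list(roi_tests = tab, mancova = man)
  attr(out, "outputs") <- f_csv
  out
}
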