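#' Specification of a synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study conditions the analyses were designed for: two autism-spectrum
#' subgroups defined by early language delay (38 with delay, 42 without)
#' plus 57 neurotypical adults scanned at three centres, 4-mm FWHM smoothed
#' modulated tissue maps, a ~5% larger total gray-matter volume in the delay
#' subgroup, localized group-difference blobs, and behavioral scores (VIQ,
#' F-A-S, non-word repetition) driven by a latent language factor that is
#' also expressed spatially in the brain maps.
#'
#' @param n_per_group named integer vector of group sizes; names are group
#'   labels (`ASC_delay`, `ASC_nodelay`, `NT`).
#' @param grid_shape integer length-3, voxels per axis (each >= 8).
#' @param voxel_size voxel edge lengths in mm.
#' @param smoothing_fwhm residual-noise smoothness in mm (default 4).
#' @param global_gm_offset fractional total-GM increase for the delay
#'   subgroup (default 0.05).
#' @param effect_blobs list of group-difference blobs; each a list with
#'   `center_mm`, `radius_mm` (Gaussian profile, sigma = radius/2),
#'   `amplitude`, `sign` (+1/-1), `groups` (character vector of affected
#'   group labels) and `tissue` ("GM" or "WM").
#' @param latent_loadings named numeric vector, per-measure loading on the
#'   latent language factor (in [0, 1]).
#' @param latent_spatial_pattern list of blobs (as in `effect_blobs`, minus
#'   `sign`/`groups`) expressing the latent factor in the maps.
#' @param score_scales named list of `c(mean, sd)` pairs per measure, on the
#'   instruments' native scales.
#' @param group_factor_shift named numeric, mean latent-factor offset per
#'   group (captures the delay subgroup's lower current-language scores).
#' @param noise_sd residual voxel noise SD, in template-intensity units.
#' @param age_range numeric length-2, years.
#' @param age_slope fractional tissue change per year of age.
#' @param centers named numeric vector of additive center offsets
#'   (fractional, applied multiplicatively to the template term).
#' @param center_probs sampling probabilities per center.
#' @param seed integer seed; fixing it fixes every output byte.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(ASC_delay = 38, ASC_nodelay = 42, NT = 57),
                        grid_shape = c(32, 32, 32),
                        voxel_size = c(6, 6, 6),
                        smoothing_fwhm = 4,
                        global_gm_offset = 0.05,
                        effect_blobs = default_effect_blobs(),
                        latent_loadings = c(VIQ = 0.6, FAS = 0.6, NWR = 0.5),
                        latent_spatial_pattern = default_latent_pattern(),
                        score_scales = list(VIQ = c(108.7, 14.3),
                                            FAS = c(37.7, 11.4),
                                            NWR = c(21.5, 4.2)),
                        group_factor_shift = c(ASC_delay = -0.3,
                                               ASC_nodelay = 0.3, NT = 0.3),
                        noise_sd = 0.05,
                        age_range = c(18, 41),
                        age_slope = -0.002,
                        centers = c(KCL = 0.02, Cambridge = 0, Oxford = -0.02),
                        center_probs = c(KCL = 36, Cambridge = 28, Oxford = 16),
                        seed = 1L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L)
  if (any(grid_shape < 8))
    stop("grid too small to smooth: every axis needs >= 8 voxels")
  if (any(voxel_size <= 0)) stop("voxel dimensions must be positive")
  if (smoothing_fwhm < 0) stop("FWHM must be >= 0")
  if (any(n_per_group < 0) || is.null(names(n_per_group)))
    stop("'n_per_group' must be a named vector of nonnegative counts")
  if (any(!is.finite(latent_loadings)) || any(abs(latent_loadings) > 1))
    stop("latent loadings must be finite and within [-1, 1]")
  if (diff(age_range) <= 0) stop("'age_range' must be increasing")
  spec <- list(n_per_group = n_per_group, grid_shape = as.integer(grid_shape),
               voxel_size = voxel_size, smoothing_fwhm = smoothing_fwhm,
               global_gm_offset = global_gm_offset, effect_blobs = effect_blobs,
               latent_loadings = latent_loadings,
               latent_spatial_pattern = latent_spatial_pattern,
               score_scales = score_scales,
               group_factor_shift = group_factor_shift,
               noise_sd = noise_sd, age_range = age_range,
               age_slope = age_slope, centers = centers,
               center_probs = center_probs / sum(center_probs),
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' @rdname cohort_spec
#' @export
default_effect_blobs <- function() {
  # insula-like bilateral reductions and a brainstem-like increase in the
  # delay subgroup, at spatial scales resolvable on a coarse synthetic grid
  list(list(center_mm = c(-35, 5, 0), radius_mm = 16, amplitude = 0.08,
            sign = -1, groups = "ASC_delay", tissue = "GM"),
       list(center_mm = c(40, 0, 5), radius_mm = 16, amplitude = 0.08,
            sign = -1, groups = "ASC_delay", tissue = "GM"),
       list(center_mm = c(5, -25, -30), radius_mm = 16, amplitude = 0.08,
            sign = 1, groups = "ASC_delay", tissue = "GM"))
}

#' @rdname cohort_spec
#' @export
default_latent_pattern <- function() {
  # a distributed temporal/fronto-parietal expression of the language
  # factor in GM plus a frontal WM component
  list(list(center_mm = c(45, 0, -10), radius_mm = 26, amplitude = 0.1,
            tissue = "GM"),
       list(center_mm = c(-45, -15, 5), radius_mm = 26, amplitude = 0.1,
            tissue = "GM"),
       list(center_mm = c(0, 35, 15), radius_mm = 20, amplitude = 0.08,
            tissue = "WM"))
}

#' Classify early language delay from developmental milestones
#'
#' A positive history of language delay is defined as first single words
#' later than 24 months, or first phrases later than 33 months, or both.
#' The boundary values themselves (exactly 24 / 33 months) count as no
#' delay. If one milestone is missing the other decides; if both are
#' missing the status is `"undetermined"`.
#'
#' @param first_words_months,first_phrases_months ages in months
#'   (vectors, `NA` allowed).
#' @return a character vector with values `"delay"`, `"no_delay"` or
#'   `"undetermined"`.
#' @export
classify_delay <- function(first_words_months, first_phrases_months) {
  n <- max(length(first_words_months), length(first_phrases_months))
  w <- rep_len(as.numeric(first_words_months), n)
  p <- rep_len(as.numeric(first_phrases_months), n)
  if (any(w < 0, na.rm = TRUE) || any(p < 0, na.rm = TRUE))
    stop("milestone ages must be nonnegative")
  delay <- (w > 24 & !is.na(w)) | (p > 33 & !is.na(p))
  out <- ifelse(delay, "delay", "no_delay")
  out[is.na(w) & is.na(p)] <- "undetermined"
  out
}

# unit-peak Gaussian blob profile over a coordinate list (mm); sigma = r/2
blob_profile <- function(coords, center_mm, radius_mm) {
  d2 <- (coords[, 1] - center_mm[1])^2 + (coords[, 2] - center_mm[2])^2 +
    (coords[, 3] - center_mm[3])^2
  exp(-d2 / (2 * (radius_mm / 2)^2))
}

blob_field <- function(grid, blobs, tissue) {
  field <- numeric(prod(dim(grid$values)))
  coords <- NULL
  for (b in blobs) {
    if (!identical(b$tissue, tissue)) next
    if (is.null(coords)) coords <- grid_coordinates(grid)
    v <- mm_to_voxel(grid, b$center_mm)
    if (any(v < 1) || any(v > dim(grid$values)))
      stop("blob centre falls outside the grid")
    field <- field + b$amplitude * blob_profile(coords, b$center_mm, b$radius_mm)
  }
  field
}

ellipsoid_template <- function(grid_shape, voxel_size, frac) {
  grid <- volume_grid(array(0, grid_shape), voxel_size)
  coords <- grid_coordinates(grid)
  half <- grid_shape * voxel_size / 2
  r2 <- (coords[, 1] / (frac * half[1]))^2 +
    (coords[, 2] / (frac * half[2]))^2 +
    (coords[, 3] / (frac * half[3]))^2
  x <- array(as.numeric(r2 <= 1), grid_shape)
  x <- smooth_volume(x, fwhm = 2 * voxel_size, voxel_size = voxel_size)
  grid$values <- pmin(pmax(x, 0), 1)
  grid
}

#' Generate a synthetic cohort of tissue maps and behavioral scores
#'
#' Draws per-subject modulated GM and WM maps and a behavioral table with
#' the structure the downstream analyses assume: a smooth tissue template
#' scaled per subject (global GM offset for the delay subgroup, age slope,
#' center offsets), additive group-difference blobs, a latent language
#' factor expressed both in the behavioral scores (through the loadings)
#' and spatially in the maps, and smooth residual noise at the requested
#' FWHM. All maps are clipped to be nonnegative.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`: a list with `subjects`
#'   (data frame), `gm` and `wm` (subjects x voxels matrices over the full
#'   grid), `template_gm`/`template_wm` ([volume_grid()]s), `latent_gm`/
#'   `latent_wm` (true spatial patterns as vectors), `factor` (true latent
#'   scores) and the generating `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape; vs <- spec$voxel_size
  template_gm <- ellipsoid_template(gs, vs, 0.9)
  template_wm <- ellipsoid_template(gs, vs, 0.55)
  nvox <- prod(gs)

  groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
  n <- length(groups)
  id <- sprintf("S%03d", seq_len(n))
  center <- sample(names(spec$centers), n, replace = TRUE,
                   prob = spec$center_probs)
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])

  # developmental milestones consistent with the group label
  words <- phrases <- rep(NA_real_, n)
  is_delay <- groups == "ASC_delay"
  is_nodelay <- groups == "ASC_nodelay"
  words[is_delay] <- 25 + stats::rexp(sum(is_delay), 1 / 8)
  phrases[is_delay] <- words[is_delay] + 6 + stats::rexp(sum(is_delay), 1 / 6)
  words[is_nodelay] <- stats::runif(sum(is_nodelay), 9, 24)
  phrases[is_nodelay] <- pmin(words[is_nodelay] + stats::runif(sum(is_nodelay), 3, 9), 33)
  delay_status <- ifelse(is_delay, "delay", ifelse(is_nodelay, "no_delay", NA))

  shift <- spec$group_factor_shift[groups]
  shift[is.na(shift)] <- 0
  fac <- stats::rnorm(n) + as.numeric(shift)

  scores <- sapply(names(spec$latent_loadings), function(m) {
    lam <- spec$latent_loadings[[m]]
    sc <- spec$score_scales[[m]]
    sc[1] + sc[2] * (lam * fac + sqrt(1 - lam^2) * stats::rnorm(n))
  })
  colnames(scores) <- names(spec$latent_loadings)

  latent_gm <- blob_field(template_gm, spec$latent_spatial_pattern, "GM")
  latent_wm <- blob_field(template_wm, spec$latent_spatial_pattern, "WM")
  blob_gm <- lapply(spec$effect_blobs, function(b)
    if (identical(b$tissue, "GM")) b$sign * blob_field(template_gm, list(b), "GM"))
  blob_wm <- lapply(spec$effect_blobs, function(b)
    if (identical(b$tissue, "WM")) b$sign * blob_field(template_wm, list(b), "WM"))

  tgm <- as.numeric(template_gm$values)
  twm <- as.numeric(template_wm$values)
  gm <- matrix(0, n, nvox)
  wm <- matrix(0, n, nvox)
  mean_age <- mean(spec$age_range)
  for (i in seq_len(n)) {
    scale_i <- (1 + spec$age_slope * (age[i] - mean_age)) *
      (1 + spec$centers[[center[i]]])
    gm_i <- tgm * scale_i * (1 + if (is_delay[i]) spec$global_gm_offset else 0)
    wm_i <- twm * scale_i
    for (k in seq_along(spec$effect_blobs)) {
      b <- spec$effect_blobs[[k]]
      if (groups[i] %in% b$groups) {
        if (!is.null(blob_gm[[k]])) gm_i <- gm_i + blob_gm[[k]]
        if (!is.null(blob_wm[[k]])) wm_i <- wm_i + blob_wm[[k]]
      }
    }
    gm_i <- gm_i + fac[i] * latent_gm
    wm_i <- wm_i + fac[i] * latent_wm
    if (spec$noise_sd > 0) {
      gm_i <- gm_i + spec$noise_sd * gaussian_field(gs, spec$smoothing_fwhm, vs)
      wm_i <- wm_i + spec$noise_sd * gaussian_field(gs, spec$smoothing_fwhm, vs)
    }
    gm[i, ] <- pmax(gm_i, 0)
    wm[i, ] <- pmax(wm_i, 0)
  }

  vv_cm3 <- prod(vs) / 1000
  subjects <- data.frame(
    id = id, group = groups,
    diagnosis = ifelse(groups == "NT", "NT", "ASC"),
    delay_status = delay_status, age = age, center = center,
    first_words_months = words, first_phrases_months = phrases,
    total_gm_cm3 = rowSums(gm) * vv_cm3,
    total_wm_cm3 = rowSums(wm) * vv_cm3,
    total_csf_cm3 = pmax(stats::rnorm(n, 270, 75), 50),
    stringsAsFactors = FALSE)
  subjects <- cbind(subjects, as.data.frame(scores))

  structure(list(subjects = subjects, gm = gm, wm = wm,
                 template_gm = template_gm, template_wm = template_wm,
                 latent_gm = latent_gm, latent_wm = latent_wm,
                 factor = fac, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$subjects), " subjects (",
      paste(sprintf("%s=%d", names(table(x$subjects$group)),
                    as.integer(table(x$subjects$group))), collapse = ", "),
      "), grid ", paste(x$spec$grid_shape, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one gzipped NIfTI-1 GM and WM map per subject, the subject table
#' as CSV, and the generating specification as YAML.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort$template_gm
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$id[i]
    g <- grid; g$values <- array(cohort$gm[i, ], dim(grid$values))
    write_volume(g, file.path(dir, paste0(id, "_gm.nii.gz")))
    g$values <- array(cohort$wm[i, ], dim(grid$values))
    write_volume(g, file.path(dir, paste0(id, "_wm.nii.gz")))
  }
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  spec <- cohort$spec
  spec$effect_blobs <- lapply(spec$effect_blobs, unclass)
  yaml::write_yaml(unclass(spec), file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}
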