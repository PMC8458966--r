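# Deterministic longitudinal dual-contrast brain phantom simulator.
#
# Geometry: nested ellipsoids (CSF shell > cortical GM shell > WM core),
# one central deep-GM ellipsoid, and six bilateral (mirrored) subcortical
# blobs placed inside the WM core.  The 12-month geometry is the 6-month
# geometry scaled about the volume centre by growth_factor.  Intensities
# are age- and contrast-specific tissue means plus Gaussian noise, then
# Gaussian-smoothed (partial-volume stand-in) and min-max normalized to
# [-1, 1] with the zero background excluded.

#' Default tissue intensity table for the phantom
#'
#' Mean intensities (arbitrary units) per tissue, contrast, and age, plus a
#' per-tissue noise standard deviation.  The table encodes the contrast
#' dynamics of the first year of life qualitatively: the white-matter /
#' gray-matter intensity gap is small at 6 months and large at 12 months in
#' the T1-like contrast, and has the opposite sign (larger at 6 months) in
#' the T2-like contrast, emulating myelination.  All means are pairwise
#' distinct within each contrast/age so that intensity-based tissue
#' classification is well defined.
#'
#' @return A data.frame with columns `tissue`, `label`, `t1_6m`, `t1_12m`,
#'   `t2_6m`, `t2_12m`, `sd`.
#' @export
default_tissue_params <- function() {
  data.frame(
    tissue = c("csf", "cortical_gm", "wm", "deep_gm", "thalamus", "caudate",
               "putamen", "pallidum", "hippocampus", "amygdala"),
    label  = 1:10,
    t1_6m  = c(20, 55, 60, 50, 52, 48, 51, 57, 46, 44),
    t1_12m = c(18, 55, 80, 58, 62, 56, 60, 68, 54, 52),
    t2_6m  = c(95, 60, 45, 65, 57, 68, 63, 52, 70, 72),
    t2_12m = c(96, 62, 30, 55, 50, 60, 53, 42, 64, 66),
    sd     = rep(2, 10),
    stringsAsFactors = FALSE
  )
}

# Subcortical blob layout: centres and radii in units of the brain radius,
# mirrored across the midline (x axis).
blob_layout <- function() {
  data.frame(
    tissue = c("thalamus", "caudate", "putamen", "pallidum",
               "hippocampus", "amygdala"),
    cx = c(0.16, 0.16, 0.40, 0.34, 0.30, 0.18),
    cy = c(0.06, 0.28, 0.12, -0.04, -0.28, -0.34),
    cz = c(0.02, 0.12, 0.02, -0.14, -0.12, 0.08),
    r  = c(0.11, 0.09, 0.10, 0.08, 0.09, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Specification of the synthetic longitudinal phantom
#'
#' @param shape Grid size per axis in voxels; every axis must be divisible
#'   by 8 (the generator downsamples three times by 2).
#' @param spacing Voxel size in mm per axis.
#' @param tissue_params Tissue intensity table, see [default_tissue_params()].
#' @param growth_factor Ratio of the 12-month to the 6-month brain radius
#'   (> 1); the default 1.07 corresponds to roughly +23% brain volume.
#' @param smoothing_fwhm Gaussian smoothing FWHM in mm applied to the raw
#'   intensities to emulate partial-volume effects.
#' @param seed Integer seed controlling the cohort-level randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), spacing = c(1, 1, 1),
                         tissue_params = default_tissue_params(),
                         growth_factor = 1.07, smoothing_fwhm = 1,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape %% 8L != 0L))
    stop("phantom shape axes must each be divisible by 8")
  if (!is.finite(growth_factor) || growth_factor <= 1)
    stop("growth_factor must be > 1")
  if (any(tissue_params$sd < 0)) stop("noise sds must be >= 0")
  for (col in c("t1_6m", "t1_12m", "t2_6m", "t2_12m")) {
    if (anyDuplicated(tissue_params[[col]]))
      stop("tissue intensity means must be pairwise distinct (column ", col, ")")
  }
  structure(
    list(shape = shape, spacing = as.numeric(spacing),
         tissue_params = tissue_params, growth_factor = growth_factor,
         smoothing_fwhm = smoothing_fwhm, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Analytic label volume for one age.  scale multiplies the brain radius.
phantom_labels <- function(spec, scale = 1, jitter = 1) {
  d <- spec$shape
  centre <- (d + 1) / 2
  # mildly anisotropic brain: longest along x
  ax_frac <- c(1.00, 0.92, 0.85)
  rad <- 0.40 * min(d) * ax_frac * jitter * scale
  g <- expand_grid_vox(d)
  u <- sweep(sweep(g, 2, centre, "-"), 2, rad, "/")
  rho <- sqrt(rowSums(u * u))
  lab <- integer(nrow(g))
  lab[rho <= 1.00] <- 1L   # csf shell
  lab[rho <= 0.90] <- 2L   # cortical gm shell
  lab[rho <= 0.74] <- 3L   # wm core
  lab[rho <= 0.30] <- 4L   # deep gm
  bl <- blob_layout()
  tp <- spec$tissue_params
  for (i in seq_len(nrow(bl))) {
    lbl <- tp$label[match(bl$tissue[i], tp$tissue)]
    for (sgn in c(1, -1)) {
      ctr <- c(sgn * bl$cx[i], bl$cy[i], bl$cz[i])
      ub <- sweep(u, 2, ctr, "-") / bl$r[i]
      lab[rowSums(ub * ub) <= 1] <- lbl
    }
  }
  array(lab, dim = d)
}

expand_grid_vox <- function(d) {
  cbind(
    rep.int(seq_len(d[1]), d[2] * d[3]),
    rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2])
  )
}

# Separable Gaussian blur with edge renormalization.
gaussian_blur3 <- function(arr, fwhm, spacing) {
  if (fwhm <= 0) return(arr)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  for (ax in 1:3) {
    n <- d[ax]
    pos <- seq_len(n) * spacing[ax]
    K <- outer(pos, pos, function(a, b) exp(-((a - b)^2) / (2 * sigma^2)))
    K <- K / rowSums(K)
    if (ax == 1) {
      arr <- array(K %*% matrix(arr, n, prod(d[-1])), dim = d)
    } else {
      perm <- if (ax == 2) c(2, 1, 3) else c(3, 2, 1)
      a2 <- aperm(arr, perm)
      d2 <- dim(a2)
      a2 <- array(K %*% matrix(a2, n, prod(d2[-1])), dim = d2)
      arr <- aperm(a2, order(perm))
    }
  }
  arr
}

phantom_intensity <- function(lab, means, sds, fwhm, spacing) {
  img <- array(0, dim = dim(lab))
  for (i in seq_along(means)) {
    sel <- lab == i
    nsel <- sum(sel)
    if (nsel > 0)
      img[sel] <- means[i] + stats::rnorm(nsel, 0, sds[i])
  }
  img[img < 0] <- 0   # keep zero reserved for background
  gaussian_blur3(img, fwhm, spacing)
}

#' Generate one longitudinal phantom subject
#'
#' Produces a complete subject record: T1-like and T2-like volumes plus a
#' ground-truth label map at both 6 and 12 months.  The 12-month geometry is
#' the 6-month geometry scaled by `spec$growth_factor` about the volume
#' centre.  Identical `(spec, subject_seed)` give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param subject_seed Integer seed for this subject's randomness.
#' @param subject_id Identifier stored in the record.
#' @return An object of class `subject_record` with elements `subject_id`,
#'   `timepoints` (named list `6m`/`12m`, each with `T1w`, `T2w`,
#'   `labels`), `missing_tag`, and `split`.
#' @export
generate_subject <- function(spec, subject_seed, subject_id = "sub") {
  stopifnot(inherits(spec, "phantom_spec"))
  tp <- spec$tissue_params
  with_seed(as.integer(subject_seed) %% .Machine$integer.max, {
    jitter <- stats::runif(1, 0.97, 1.03)
    tps <- list()
    for (age in c("6m", "12m")) {
      scale <- if (age == "6m") 1 else spec$growth_factor
      lab <- phantom_labels(spec, scale = scale, jitter = jitter)
      vols <- list()
      for (con in c("T1w", "T2w")) {
        col <- paste0(if (con == "T1w") "t1_" else "t2_", age)
        img <- phantom_intensity(lab, tp[[col]], tp$sd,
                                 spec$smoothing_fwhm, spec$spacing)
        v <- volume(img, spacing = spec$spacing, contrast = con, age_tag = age)
        vols[[con]] <- normalize_intensity(v)
      }
      vols$labels <- label_map(lab, spacing = spec$spacing,
                               label_names = stats::setNames(tp$tissue,
                                                             tp$label))
      tps[[age]] <- vols
    }
    structure(
      list(subject_id = subject_id, timepoints = tps,
           missing_tag = NA_character_, split = NA_character_),
      class = "subject_record"
    )
  })
}

#' Generate a longitudinal cohort with configurable missingness
#'
#' Simulates `n_subjects` phantom subjects, removes one timepoint from
#' `round(missing_fraction * n_subjects)` of them (alternating which
#' timepoint is removed so both prediction directions are exercised), and
#' assigns train/val/test splits.  Subjects with a missing timepoint are
#' always assigned to the training split, never to val/test.  The whole
#' cohort is a pure function of `(spec, n_subjects, missing_fraction,
#' split)`.
#'
#' @param spec A [phantom_spec()]; `spec$seed` drives all cohort-level
#'   randomness.
#' @param n_subjects Number of subjects (>= 3).
#' @param missing_fraction Proportion in \[0, 1) of subjects with one
#'   timepoint removed.
#' @param split Length-3 proportions `(train, val, test)` summing to 1.
#' @return An object of class `cohort`: a list with `subjects` (named list
#'   of subject records) and the generating parameters.
#' @export
generate_cohort <- function(spec, n_subjects, missing_fraction = 0,
                            split = c(train = 0.6, val = 0.2, test = 0.2)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)")
  if (abs(sum(split) - 1) > 1e-9)
    stop("split proportions must sum to 1")
  n_missing <- round(missing_fraction * n_subjects)
  n_val <- round(split[2] * n_subjects)
  n_test <- round(split[3] * n_subjects)
  if (n_val + n_test > n_subjects - n_missing)
    stop("not enough complete subjects to fill val/test splits")

  ids <- sprintf("sub%03d", seq_len(n_subjects))
  subjects <- vector("list", n_subjects)
  names(subjects) <- ids
  for (i in seq_len(n_subjects)) {
    sseed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    subjects[[i]] <- generate_subject(spec, sseed, subject_id = ids[i])
  }

  with_seed(spec$seed, {
    perm <- sample.int(n_subjects)
    missing_idx <- if (n_missing > 0) perm[seq_len(n_missing)] else integer()
    complete_idx <- setdiff(perm, missing_idx)
    val_idx <- if (n_val > 0) complete_idx[seq_len(n_val)] else integer()
    test_idx <- if (n_test > 0) complete_idx[n_val + seq_len(n_test)] else integer()
    for (j in seq_along(missing_idx)) {
      i <- missing_idx[j]
      tag <- if (j %% 2L == 1L) "6m" else "12m"
      subjects[[i]]$timepoints[[tag]] <- NULL
      subjects[[i]]$missing_tag <- tag
      subjects[[i]]$split <- "train"
    }
    for (i in val_idx) subjects[[i]]$split <- "val"
    for (i in test_idx) subjects[[i]]$split <- "test"
    for (i in seq_len(n_subjects))
      if (is.na(subjects[[i]]$split)) subjects[[i]]$split <- "train"
  })

  structure(
    list(subjects = subjects, spec = spec, n_subjects = n_subjects,
         missing_fraction = missing_fraction, split = split),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  splits <- vapply(x$subjects, function(s) s$split, character(1))
  miss <- sum(!is.na(vapply(x$subjects, function(s) s$missing_tag,
                            character(1))))
  cat(sprintf("<cohort> %d subjects (%s), %d with a missing timepoint\n",
              x$n_subjects,
              paste(sprintf("%s=%d", names(table(splits)), table(splits)),
                    collapse = ", "),
              miss))
  invisible(x)
}

#' Write a cohort as a NIfTI directory tree with a manifest
#'
#' One directory per subject, one file per (age, contrast) volume plus the
#' label maps; `manifest.csv` lists subject_id, age_tag, contrast, path,
#' split, missing_tag, imputed.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cohort$subjects) {
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (age in names(s$timepoints)) {
      tp <- s$timepoints[[age]]
      if (is.null(tp)) next
      for (con in c("T1w", "T2w")) {
        p <- file.path(sdir, sprintf("%s_%s.nii.gz", age, con))
        write_volume(tp[[con]], p, sidecar = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, age_tag = age, contrast = con,
          path = p, split = s$split, missing_tag = s$missing_tag,
          imputed = isTRUE(tp$imputed), stringsAsFactors = FALSE)
      }
      if (!is.null(tp$labels)) {
        p <- file.path(sdir, sprintf("%s_labels.nii.gz", age))
        write_volume(tp$labels, p)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, age_tag = age, contrast = "labels",
          path = p, split = s$split, missing_tag = s$missing_tag,
          imputed = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  spec <- cohort$spec
  yaml::write_yaml(
    list(shape = spec$shape, spacing = spec$spacing,
         growth_factor = spec$growth_factor,
         smoothing_fwhm = spec$smoothing_fwhm, seed = spec$seed,
         tissue_params = lapply(as.list(spec$tissue_params), unlist)),
    file.path(dir, "phantom.yaml"))
  invisible(manifest)
}

#' Read a cohort back from a directory tree
#'
#' Reconstructs a cohort written by [write_cohort()] from its
#' `manifest.csv`, the per-volume NIfTI files, and the `phantom.yaml`
#' parameter snapshot.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv under ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  spec <- NULL
  ppath <- file.path(dir, "phantom.yaml")
  if (file.exists(ppath)) {
    p <- yaml::read_yaml(ppath)
    spec <- phantom_spec(shape = p$shape, spacing = p$spacing,
                         tissue_params = as.data.frame(p$tissue_params,
                                                       stringsAsFactors = FALSE),
                         growth_factor = p$growth_factor,
                         smoothing_fwhm = p$smoothing_fwhm, seed = p$seed)
  }
  label_names <- if (!is.null(spec))
    stats::setNames(spec$tissue_params$tissue, spec$tissue_params$label)
  else character()
  ids <- unique(manifest$subject_id)
  subjects <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    rows <- manifest[manifest$subject_id == id, ]
    tps <- list()
    for (age in unique(rows$age_tag)) {
      arow <- rows[rows$age_tag == age, ]
      tp <- list()
      for (j in seq_len(nrow(arow))) {
        con <- arow$contrast[j]
        if (con == "labels") {
          tp$labels <- read_label_map(arow$path[j], label_names)
        } else {
          tp[[con]] <- read_volume(arow$path[j], contrast = con,
                                   age_tag = age)
        }
        if (isTRUE(arow$imputed[j])) tp$imputed <- TRUE
      }
      tps[[age]] <- tp
    }
    subjects[[id]] <- structure(
      list(subject_id = id, timepoints = tps,
           missing_tag = as.character(rows$missing_tag[1]),
           split = rows$split[1]),
      class = "subject_record")
  }
  n_missing <- sum(!is.na(vapply(subjects, function(s) s$missing_tag,
                                 character(1))))
  structure(
    list(subjects = subjects, spec = spec, n_subjects = length(ids),
         missing_fraction = n_missing / length(ids), split = NA),
    class = "cohort"
  )
}

#' Intensity-based tissue classification of phantom images
#'
#' A synthetic stand-in for an automatic segmentation algorithm: each
#' above-background voxel is assigned to the tissue whose expected
#' normalized mean intensity (joint over the available contrasts) is
#' nearest in Euclidean distance.  Well defined because the phantom's
#' tissue means are pairwise distinct per contrast and age.
#'
#' @param vols Named list with elements `T1w` and/or `T2w`, normalized
#'   [volume()]s of one subject at one age.
#' @param spec The [phantom_spec()] that generated the images.
#' @param age_tag `"6m"` or `"12m"`.
#' @param background Threshold below which (in every contrast) a voxel is
#'   called background.
#' @return A [label_map()] with the phantom's label vocabulary.
#' @export
segment_by_intensity <- function(vols, spec, age_tag,
                                 background = -0.95) {
  tp <- spec$tissue_params
  cons <- intersect(c("T1w", "T2w"), names(vols))
  if (length(cons) == 0) stop("need at least one of T1w/T2w")
  suffix <- if (age_tag == "6m") "6m" else "12m"
  exp_means <- sapply(cons, function(con) {
    raw <- tp[[paste0(if (con == "T1w") "t1_" else "t2_", suffix)]]
    a <- 2 / (max(raw) - min(raw))
    a * raw - 1 - a * min(raw)
  })
  exp_means <- matrix(exp_means, ncol = length(cons))
  d <- dim(vols[[cons[1]]]$data)
  x <- sapply(cons, function(con) as.vector(vols[[con]]$data))
  x <- matrix(x, ncol = length(cons))
  bg <- rowSums(x > background) == 0
  # squared distance from every voxel to every tissue mean
  d2 <- matrix(0, nrow(x), nrow(tp))
  for (j in seq_len(ncol(x)))
    d2 <- d2 + outer(x[, j], exp_means[, j], "-")^2
  lab <- max.col(-d2, ties.method = "first")
  lab[bg] <- 0L
  label_map(array(as.integer(lab), dim = d), spacing = spec$spacing,
            label_names = stats::setNames(tp$tissue, tp$label))
}
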