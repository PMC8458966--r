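#' Construct a 3D image volume
#'
#' A `volume` is the package's container for one 3D scalar MR image: a
#' three-axis numeric array plus per-axis voxel spacing in millimetres and
#' lightweight acquisition metadata (contrast and timepoint tags).
#'
#' @param data Numeric 3D array.
#' @param spacing Numeric length-3 vector of voxel sizes in mm (all > 0).
#' @param contrast One of `"T1w"`, `"T2w"`, `"synthetic"`.
#' @param age_tag Free-form timepoint label (e.g. `"6m"`, `"12m"`).
#' @param normalized Logical; `TRUE` asserts every value lies in \[-1, 1\].
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), contrast = "synthetic",
                   age_tag = "", normalized = FALSE) {
  v <- structure(
    list(data = data, spacing = as.numeric(spacing), contrast = contrast,
         age_tag = age_tag, normalized = isTRUE(normalized)),
    class = "volume"
  )
  validate_volume(v)
  v
}

validate_volume <- function(v) {
  d <- dim(v$data)
  if (is.null(d) || length(d) != 3L || any(d < 1L))
    stop("volume data must have exactly 3 axes, each of length >= 1")
  if (length(v$spacing) != 3L || any(!is.finite(v$spacing)) || any(v$spacing <= 0))
    stop("voxel spacing must be 3 strictly positive finite values (mm)")
  if (!v$contrast %in% c("T1w", "T2w", "synthetic"))
    stop("contrast must be one of 'T1w', 'T2w', 'synthetic'")
  if (v$normalized) {
    rng <- range(v$data, na.rm = TRUE)
    if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
      stop("normalized volume has values outside [-1, 1]")
  }
  invisible(v)
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s [%s] %s  spacing %s mm  normalized=%s\n",
              paste(dim(x$data), collapse = "x"), x$contrast,
              if (nzchar(x$age_tag)) x$age_tag else "-",
              paste(format(x$spacing), collapse = "x"), x$normalized))
  invisible(x)
}

#' Construct a 3D label map
#'
#' Integer-valued segmentation aligned voxel-for-voxel with the volume it
#' annotates.  Label 0 is reserved for background.
#'
#' @param data Integer 3D array of non-negative labels.
#' @param spacing Voxel spacing in mm, as for [volume()].
#' @param label_names Named character vector mapping label integers
#'   (as names) to structure names.
#' @return An object of class `label_map`.
#' @export
label_map <- function(data, spacing = c(1, 1, 1), label_names = character()) {
  storage.mode(data) <- "integer"
  lm <- structure(
    list(data = data, spacing = as.numeric(spacing), label_names = label_names),
    class = "label_map"
  )
  d <- dim(data)
  if (is.null(d) || length(d) != 3L)
    stop("label map data must have exactly 3 axes")
  if (any(data < 0L, na.rm = TRUE))
    stop("labels must be non-negative integers (0 = background)")
  lm
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads a single 3D scalar image (`.nii` or `.nii.gz`).  If a JSON sidecar
#' `<path-without-ext>.json` with fields `contrast` and/or `age_tag` exists,
#' its tags are attached; otherwise defaults are used.
#'
#' @param path Path to an existing NIfTI-1 file.
#' @param contrast,age_tag Defaults used when no sidecar is present.
#' @return A [volume()].
#' @export
read_volume <- function(path, contrast = "synthetic", age_tag = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d)) d <- length(img)
  if (length(d) > 3L)
    stop("unsupported content: expected a 3D scalar image, got ",
         length(d), " dimensions")
  d <- c(d, rep(1L, 3L - length(d)))  # singleton axes are dropped on read
  spacing <- c(abs(RNifti::pixdim(img)), rep(1, 3))[1:3]
  spacing[spacing == 0] <- 1
  sidecar <- sidecar_path(path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$contrast)) contrast <- meta$contrast
    if (!is.null(meta$age_tag)) age_tag <- meta$age_tag
  }
  dat <- array(as.numeric(img), dim = d)
  rng <- range(dat, na.rm = TRUE)
  volume(dat, spacing = spacing, contrast = contrast, age_tag = age_tag,
         normalized = rng[1] >= -1 && rng[2] <= 1 && rng[1] < 0)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v A [volume()] (or [label_map()]).
#' @param path Destination `.nii` or `.nii.gz` path.
#' @param sidecar Write a JSON sidecar with the contrast/age tags?
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, sidecar = FALSE) {
  if (inherits(v, "volume")) validate_volume(v)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("destination directory does not exist: ", dir)
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  if (sidecar && inherits(v, "volume")) {
    jsonlite::write_json(list(contrast = v$contrast, age_tag = v$age_tag),
                         sidecar_path(path), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a label map from a NIfTI-1 file
#'
#' @param path Path to the file.
#' @param label_names Optional named character vector of structure names.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, label_names = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("unsupported content: expected a 3D label image")
  label_map(array(as.integer(round(img)), dim = d),
            spacing = abs(RNifti::pixdim(img))[1:3],
            label_names = label_names)
}

#' Min-max intensity normalization to \[-1, 1\]
#'
#' Applies the affine map `a*x + b` with `a = 2/(max - min)`,
#' `b = -1 - a*min`, so the minimum maps to -1 and the maximum to +1.
#' By default the min/max are computed over the nonzero support only
#' (skull-stripped images carry an exact-zero exterior) and background
#' voxels are mapped to -1, so that a large zero background cannot
#' compress the brain contrast.  A constant-valued volume maps to all
#' zeros (the midpoint of the target range) rather than erroring, keeping
#' batch pipelines total.
#'
#' @param v A [volume()].
#' @param exclude_zero Exclude exact-zero voxels from the min/max and map
#'   them to -1 (default `TRUE`).  Set to `FALSE` for images without a
#'   zero-coded background, in which case the plain min-max map is used.
#' @return A normalized [volume()] with `normalized = TRUE`.
#' @export
normalize_intensity <- function(v, exclude_zero = TRUE) {
  x <- v$data
  if (all(is.na(x))) stop("cannot normalize an all-NaN volume")
  support <- is.finite(x)
  if (exclude_zero) support <- support & (x != 0)
  if (!any(support)) {
    # all-zero (or no finite nonzero support): degenerate constant volume
    out <- array(0, dim = dim(x))
  } else {
    mn <- min(x[support])
    mx <- max(x[support])
    if (mx == mn) {
      out <- array(0, dim = dim(x))
      if (exclude_zero) out[!support & is.finite(x)] <- -1
      # a truly constant volume (no excluded voxels) stays all zero
      if (!exclude_zero || all(support | !is.finite(x))) out[] <- 0
    } else {
      a <- 2 / (mx - mn)
      b <- -1 - a * mn
      out <- a * x + b
      if (exclude_zero) out[is.finite(x) & x == 0] <- -1
      out[out < -1] <- -1
      out[out > 1] <- 1
    }
  }
  volume(out, spacing = v$spacing, contrast = v$contrast, age_tag = v$age_tag,
         normalized = TRUE)
}
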