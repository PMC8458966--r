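# Segmentation-agreement metrics: relative absolute volume difference
# (AVD, %), average symmetric surface distance (ASD, mm), Dice overlap,
# Tanimoto error (%), and the reference-scaled fused score.
#
# Surface definition: a border voxel is a foreground voxel with at least
# one 6-connected (face) neighbour that is background; out-of-grid counts
# as background.  Distances are Euclidean between voxel centres in mm,
# computed with an exact separable distance transform.

#' Construct a binary mask
#'
#' @param data Logical (or coercible) 3D array.
#' @param spacing Voxel size in mm per axis.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L)
    stop("mask data must have exactly 3 axes")
  m <- array(as.logical(data), dim = d)
  m[is.na(m)] <- FALSE
  structure(list(data = m, spacing = as.numeric(spacing)),
            class = "binary_mask")
}

as_mask <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "binary_mask")) x else binary_mask(x, spacing)
}

mask_volume_mm3 <- function(s) sum(s$data) * prod(s$spacing)

#' Relative absolute volume difference (percent)
#'
#' `|V1 - V2| / V1 * 100`, with volumes as foreground voxel counts times
#' the voxel volume.  Asymmetric: the first mask is the reference in the
#' denominator.
#'
#' @param s1 Reference [binary_mask()] (must be non-empty).
#' @param s2 Comparison mask.
#' @return Percentage >= 0.
#' @export
avd <- function(s1, s2) {
  s1 <- as_mask(s1)
  s2 <- as_mask(s2)
  v1 <- mask_volume_mm3(s1)
  if (v1 == 0)
    stop("avd is undefined: the reference mask (s1) is empty")
  abs(v1 - mask_volume_mm3(s2)) / v1 * 100
}

#' Border voxels of a mask (6-connectivity)
#'
#' Foreground voxels with at least one face neighbour that is background;
#' voxels on the grid boundary count their out-of-grid neighbours as
#' background.
#'
#' @param s A [binary_mask()].
#' @return A [binary_mask()] of the border voxels.
#' @export
border_voxels <- function(s) {
  s <- as_mask(s)
  m <- s$data
  d <- dim(m)
  shift_bg <- function(ax, by) {
    out <- array(FALSE, dim = d)  # FALSE = "neighbour is background"
    idx_src <- lapply(seq_len(3L), function(a) seq_len(d[a]))
    idx_dst <- idx_src
    if (by == 1L) {
      idx_dst[[ax]] <- seq_len(d[ax] - 1L) + 1L
      idx_src[[ax]] <- seq_len(d[ax] - 1L)
    } else {
      idx_dst[[ax]] <- seq_len(d[ax] - 1L)
      idx_src[[ax]] <- seq_len(d[ax] - 1L) + 1L
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  has_bg_neighbour <- array(FALSE, dim = d)
  for (ax in 1:3) for (by in c(1L, -1L))
    has_bg_neighbour <- has_bg_neighbour | !shift_bg(ax, by)
  binary_mask(m & has_bg_neighbour, s$spacing)
}

#' Average symmetric surface distance (mm)
#'
#' Mean of the nearest-border distances from the border of `s1` to the
#' border of `s2` and vice versa, weighted by border sizes:
#' `(sum_{x in B1} d(x, B2) + sum_{x in B2} d(x, B1)) / (|B1| + |B2|)`.
#'
#' @param s1,s2 Non-empty [binary_mask()]s on the same grid and spacing.
#' @return Distance in mm >= 0; 0 for identical masks.
#' @export
asd <- function(s1, s2) {
  s1 <- as_mask(s1)
  s2 <- as_mask(s2)
  if (!any(s1$data) || !any(s2$data))
    stop("asd is undefined for an empty mask")
  b1 <- border_voxels(s1)$data
  b2 <- border_voxels(s2)$data
  d <- dim(b1)
  dt2 <- edt3(as.vector(b2), d, s1$spacing)
  dt1 <- edt3(as.vector(b1), d, s1$spacing)
  (sum(dt2[as.vector(b1)]) + sum(dt1[as.vector(b2)])) /
    (sum(b1) + sum(b2))
}

#' Dice overlap coefficient
#'
#' `2|S1 n S2| / (|S1| + |S2|)`, in \[0, 1\]; symmetric.
#'
#' @param s1,s2 Binary masks; at least one must be non-empty.
#' @return Unitless overlap in \[0, 1\].
#' @export
dice <- function(s1, s2) {
  s1 <- as_mask(s1)
  s2 <- as_mask(s2)
  n1 <- sum(s1$data)
  n2 <- sum(s2$data)
  if (n1 + n2 == 0) stop("dice is undefined: both masks are empty")
  2 * sum(s1$data & s2$data) / (n1 + n2)
}

#' Tanimoto error (percent)
#'
#' `(|union| - |intersection|) / |union| * 100`: the Jaccard complement,
#' symmetric, 0 for identical and 100 for disjoint masks.
#'
#' @param s1,s2 Binary masks with non-empty union.
#' @return Percentage in \[0, 100\].
#' @export
tanimoto_error <- function(s1, s2) {
  s1 <- as_mask(s1)
  s2 <- as_mask(s2)
  u <- sum(s1$data | s2$data)
  if (u == 0) stop("tanimoto_error is undefined: both masks are empty")
  (u - sum(s1$data & s2$data)) / u * 100
}

#' Reference constants for the fused score
#'
#' Inter-expert manual-segmentation variability used to put the three
#' component metrics on a common scale: 5.6% (AVD), 0.27 mm (ASD), 15.8%
#' (Tanimoto error).
#'
#' @param refAVD,refASD,refTanimotoError Strictly positive reference
#'   values.
#' @return An object of class `metric_refs`.
#' @export
metric_refs <- function(refAVD = 5.6, refASD = 0.27,
                        refTanimotoError = 15.8) {
  if (any(c(refAVD, refASD, refTanimotoError) <= 0))
    stop("reference constants must be strictly positive")
  structure(list(refAVD = refAVD, refASD = refASD,
                 refTanimotoError = refTanimotoError),
            class = "metric_refs")
}

#' Fused segmentation-agreement score
#'
#' Mean of the three metrics each scaled by its expert reference:
#' `(AVD/refAVD + ASD/refASD + TE/refTE) / 3`.  Lower is better; a value
#' of 1 means agreement at the level of inter-expert variability.
#'
#' @param avd AVD in percent.
#' @param asd ASD in mm.
#' @param te Tanimoto error in percent.
#' @param refs A [metric_refs()].
#' @return Unitless score >= 0.
#' @export
fused_score <- function(avd, asd, te, refs = metric_refs()) {
  if (any(c(avd, asd, te) < 0)) stop("metric inputs must be >= 0")
  (avd / refs$refAVD + asd / refs$refASD + te / refs$refTanimotoError) / 3
}

#' Per-structure segmentation-agreement report
#'
#' Computes all five metrics for every non-background label present in
#' the reference vocabulary.  Labels empty in either map are reported as
#' undefined (NA metrics with a reason) rather than silently dropped.
#'
#' @param pred_labels,ref_labels Aligned [label_map()]s sharing a label
#'   vocabulary; `ref_labels` is the reference (AVD denominator).
#' @param refs A [metric_refs()].
#' @return A data.frame of class `metric_report` with one row per
#'   structure plus columns `AVD`, `ASD`, `Dice`, `TanimotoError`,
#'   `FusedScore`, `defined`; across-structure means and sds of the
#'   defined rows are attached as attribute `"summary"`.
#' @export
per_structure_report <- function(pred_labels, ref_labels,
                                 refs = metric_refs()) {
  if (!identical(dim(pred_labels$data), dim(ref_labels$data)))
    stop("label maps are not aligned")
  vocab_r <- ref_labels$label_names
  vocab_p <- pred_labels$label_names
  if (length(vocab_r) && length(vocab_p) && !identical(vocab_r, vocab_p))
    stop("label vocabularies differ")
  labels <- sort(unique(c(
    setdiff(unique(as.vector(ref_labels$data)), 0L),
    as.integer(names(vocab_r))
  )))
  rows <- lapply(labels, function(lb) {
    m_ref <- binary_mask(ref_labels$data == lb, ref_labels$spacing)
    m_prd <- binary_mask(pred_labels$data == lb, pred_labels$spacing)
    nm <- if (as.character(lb) %in% names(vocab_r))
      vocab_r[[as.character(lb)]] else paste0("label", lb)
    if (!any(m_ref$data) || !any(m_prd$data)) {
      return(data.frame(label = lb, structure = nm, AVD = NA_real_,
                        ASD = NA_real_, Dice = NA_real_,
                        TanimotoError = NA_real_, FusedScore = NA_real_,
                        defined = FALSE, stringsAsFactors = FALSE))
    }
    a <- avd(m_ref, m_prd)
    s <- asd(m_ref, m_prd)
    dc <- dice(m_ref, m_prd)
    te <- tanimoto_error(m_ref, m_prd)
    data.frame(label = lb, structure = nm, AVD = a, ASD = s, Dice = dc,
               TanimotoError = te, FusedScore = fused_score(a, s, te, refs),
               defined = TRUE, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  ok <- rep[rep$defined, , drop = FALSE]
  cols <- c("AVD", "ASD", "Dice", "TanimotoError", "FusedScore")
  attr(rep, "summary") <- data.frame(
    metric = cols,
    mean = vapply(cols, function(cl) mean(ok[[cl]]), numeric(1)),
    sd = vapply(cols, function(cl) stats::sd(ok[[cl]]), numeric(1)),
    row.names = NULL
  )
  class(rep) <- c("metric_report", "data.frame")
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  print.data.frame(x, digits = 4)
  cat("\nAcross-structure summary (defined rows):\n")
  print(attr(x, "summary"), digits = 4)
  invisible(x)
}
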