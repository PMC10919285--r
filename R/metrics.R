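# Segmentation overlap and surface metrics: Dice similarity coefficient,
# relative volume error, and Hausdorff distance, plus per-subject evaluation
# across a label vocabulary.

as_binary_mask <- function(x) {
  if (inherits(x, "msk_labelmap") || inherits(x, "msk_volume")) x <- unclass(x)
  if (!is.array(x) || length(dim(x)) != 3)
    stop("masks must be 3D arrays or label maps")
  x != 0
}

metric_spacing <- function(x, spacing) {
  if (!is.null(spacing)) return(as.numeric(spacing))
  if (inherits(x, "msk_labelmap") || inherits(x, "msk_volume"))
    return(msk_spacing(x))
  c(1, 1, 1)
}

check_metric_pair <- function(predicted, reference) {
  if (!identical(dim(predicted), dim(reference)))
    stop("predicted and reference masks have different grid dimensions")
}

#' Dice similarity coefficient of two binary masks
#'
#' DSC = 2 |A intersect B| / (|A| + |B|). Any non-zero voxel counts as
#' foreground. Two empty masks are in perfect agreement, so DSC = 1.
#'
#' @param predicted,reference 3D binary arrays or [msk_labelmap()]s on the
#'   same grid.
#' @return DSC in [0, 1].
#' @export
dsc <- function(predicted, reference) {
  a <- as_binary_mask(predicted)
  b <- as_binary_mask(reference)
  check_metric_pair(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Relative volume error of two binary masks
#'
#' RVE = |V_pred - V_ref| / V_ref, with volumes in mm^3 (voxel count times
#' voxel volume, so the voxel volume cancels on a shared grid). An empty
#' reference has no defined relative error and raises an error.
#'
#' @inheritParams dsc
#' @param spacing voxel spacing in mm; taken from the inputs when they are
#'   label maps, else 1 mm isotropic.
#' @return non-negative relative volume error.
#' @export
rve <- function(predicted, reference, spacing = NULL) {
  sp <- metric_spacing(reference, spacing)
  a <- as_binary_mask(predicted)
  b <- as_binary_mask(reference)
  check_metric_pair(a, b)
  vref <- sum(b) * prod(sp)
  if (vref == 0) stop("reference mask is empty: relative volume error undefined")
  abs(sum(a) * prod(sp) - vref) / vref
}

#' Symmetric Hausdorff distance between two binary masks
#'
#' The maximum over both directed distances between the boundary voxel
#' centres of the two masks, in mm. Distances are computed with an exact
#' Euclidean distance transform of each boundary, so the result is the true
#' max-min distance over boundary voxel centres.
#'
#' @inheritParams rve
#' @return Hausdorff distance in mm (0 when the masks coincide).
#' @export
hausdorff <- function(predicted, reference, spacing = NULL) {
  sp <- metric_spacing(reference, spacing)
  a <- as_binary_mask(predicted)
  b <- as_binary_mask(reference)
  check_metric_pair(a, b)
  if (sum(a) == 0) stop("predicted mask is empty: Hausdorff distance undefined")
  if (sum(b) == 0) stop("reference mask is empty: Hausdorff distance undefined")
  ba <- boundary_mask(a)
  bb <- boundary_mask(b)
  # exact EDT to each boundary set; directed HD = max over the other boundary
  da <- cpp_edt(ba, sp)
  db <- cpp_edt(bb, sp)
  max(max(db[ba]), max(da[bb]))
}

#' Evaluate a predicted label map against a reference, per label
#'
#' Computes DSC, RVE and Hausdorff distance for every label present in the
#' reference. A label missing from the prediction is scored as a total miss:
#' DSC 0, RVE 1, Hausdorff `NA` (no surface to measure) with `missing = TRUE`.
#'
#' @param predicted,reference [msk_labelmap()]s on the same grid.
#' @param labels integer labels to evaluate; defaults to all non-zero labels
#'   of the reference.
#' @return data.frame with columns `label`, `dsc`, `rve`, `hausdorff_mm`,
#'   `missing`.
#' @export
evaluate_subject <- function(predicted, reference, labels = NULL) {
  stopifnot(inherits(predicted, "msk_labelmap"),
            inherits(reference, "msk_labelmap"))
  check_same_grid(predicted, reference)
  if (is.null(labels)) labels <- label_values(reference)
  labels <- sort(as.integer(labels))
  rows <- lapply(labels, function(l) {
    ref <- unclass(reference) == l
    prd <- unclass(predicted) == l
    if (!any(ref))
      stop("label ", l, " is absent from the reference")
    if (!any(prd))
      return(data.frame(label = l, dsc = 0, rve = 1, hausdorff_mm = NA_real_,
                        missing = TRUE))
    data.frame(label = l,
               dsc = dsc(prd, ref),
               rve = rve(prd, ref, spacing = msk_spacing(reference)),
               hausdorff_mm = hausdorff(prd, ref,
                                        spacing = msk_spacing(reference)),
               missing = FALSE)
  })
  do.call(rbind, rows)
}
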