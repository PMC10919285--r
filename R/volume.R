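#' @useDynLib musclesegkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var prcomp ks.test wilcox.test quantile
#' @importFrom utils head tail
NULL

#' 3D image volume with voxel spacing
#'
#' A `msk_volume` is a plain 3D numeric array carrying a per-axis voxel
#' spacing in millimetres. It is the in-memory form of a grayscale MR volume.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size in mm per axis (default 1 mm
#'   isotropic, the resolution the pipeline assumes after sequence merging).
#' @return An object of class `msk_volume`.
#' @export
msk_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, length(spacing) == 3L,
            all(spacing > 0))
  storage.mode(data) <- "double"
  structure(data, spacing = as.numeric(spacing),
            class = c("msk_volume", "array"))
}

#' 3D integer label map
#'
#' Voxel value 0 is background; values 1..C name muscle compartments.
#'
#' @param data 3D integer (or coercible) array.
#' @param spacing numeric length-3 voxel size in mm.
#' @return An object of class `msk_labelmap`.
#' @export
msk_labelmap <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, length(spacing) == 3L)
  if (is.double(data) && any(abs(data - round(data)) > 1e-9, na.rm = TRUE))
    stop("label values must be integers")
  storage.mode(data) <- "integer"
  if (any(data < 0L, na.rm = TRUE)) stop("label values must be >= 0")
  structure(data, spacing = as.numeric(spacing),
            class = c("msk_labelmap", "array"))
}

#' Voxel spacing of a volume or label map
#' @param x a `msk_volume`, `msk_labelmap` or array with a spacing attribute.
#' @return numeric length-3 spacing in mm.
#' @export
msk_spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) c(1, 1, 1) else s
}

#' A subject: matched image volume and label map
#'
#' @param id character subject identifier.
#' @param volume a [msk_volume()].
#' @param labels a [msk_labelmap()] on the same grid.
#' @param provenance list; `type` is "original" or "augmented", augmented
#'   subjects additionally record the reference id, the shape-space target
#'   coordinate and the displacement field that produced them.
#' @return An object of class `msk_subject`.
#' @export
msk_subject <- function(id, volume, labels,
                        provenance = list(type = "original")) {
  stopifnot(inherits(volume, "msk_volume"), inherits(labels, "msk_labelmap"))
  if (!identical(dim(volume), dim(labels)))
    stop("volume and labels must share a grid shape")
  if (max(abs(msk_spacing(volume) - msk_spacing(labels))) > 1e-9)
    stop("volume and labels must share voxel spacing")
  structure(list(id = id, volume = volume, labels = labels,
                 provenance = provenance),
            class = "msk_subject")
}

#' @export
print.msk_subject <- function(x, ...) {
  cat(sprintf("<msk_subject %s> grid %s, spacing %s mm, labels {%s}, %s\n",
              x$id, paste(dim(x$volume), collapse = "x"),
              paste(signif(msk_spacing(x$volume), 3), collapse = "x"),
              paste(sort(setdiff(unique(as.vector(x$labels)), 0L)),
                    collapse = ","),
              x$provenance$type))
  invisible(x)
}

#' Non-zero labels present in a label map
#' @param labels a [msk_labelmap()] (or integer array).
#' @return sorted integer vector of the distinct non-zero labels.
#' @export
label_values <- function(labels) sort(setdiff(unique(as.vector(labels)), 0L))

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("inputs are on different grids: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  if (max(abs(msk_spacing(a) - msk_spacing(b))) > 1e-9)
    stop("inputs have different voxel spacings")
  invisible(TRUE)
}

#' Write a volume or label map as NIfTI
#'
#' @param x `msk_volume` or `msk_labelmap`.
#' @param path output path, conventionally ending in `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  img <- RNifti::asNifti(unclass(x))
  RNifti::pixdim(img) <- msk_spacing(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a volume or label map
#'
#' @param path NIfTI file path.
#' @param labels logical; read as an integer label map instead of an image.
#' @return `msk_volume` or `msk_labelmap`.
#' @export
read_nifti <- function(path, labels = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.vector(img), dim = dim(img)[1:3])
  if (labels) msk_labelmap(round(arr), spacing = sp)
  else msk_volume(arr, spacing = sp)
}

#' Write a subject pair (`<id>_img.nii.gz`, `<id>_lab.nii.gz`)
#' @param subject a `msk_subject`.
#' @param dir output directory (created if missing).
#' @return named character vector of the two paths, invisibly.
#' @export
write_subject <- function(subject, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pi <- file.path(dir, paste0(subject$id, "_img.nii.gz"))
  pl <- file.path(dir, paste0(subject$id, "_lab.nii.gz"))
  write_nifti(subject$volume, pi)
  write_nifti(subject$labels, pl)
  invisible(c(image = pi, labels = pl))
}
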